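test_that("pair-split enumeration is exhaustive, sized and duplicate-free", {
  pool <- sprintf("p%02d", 1:57)
  plans <- enumeratePairSplits(sprintf("e%02d", 1:12), pool,
                               nPoolTrain = 45, seed = 3)
  expect_length(plans, choose(12, 2))      # 66
  pairs <- vapply(plans, function(p)
    paste(sort(p$experimentalPair), collapse = "+"), character(1))
  expect_false(anyDuplicated(pairs) > 0)
  for (p in plans[c(1, 30, 66)]) {
    expect_length(p$testIds, 7)            # 2 experimental + 5 pool
    expect_length(intersect(p$testIds, sprintf("e%02d", 1:12)), 2)
    expect_length(p$trainIds, 55)          # 10 experimental + 45 pool
    expect_length(intersect(p$trainIds, p$testIds), 0)
  }
  expect_length(enumeratePairSplits(letters[1:4], pool), 6)
  p2 <- enumeratePairSplits(letters[1:2], pool)
  expect_length(p2, 1)
  expect_true(all(c("a", "b") %in% p2[[1]]$testIds))
  expect_error(enumeratePairSplits("a", pool), "at least 2")
  expect_error(enumeratePairSplits(letters[1:3], pool[1:3], nPoolTest = 5),
               "pool too small")
})

test_that("excluded ligands never appear in any plan", {
  plans <- enumeratePairSplits(letters[1:5], sprintf("p%d", 1:30),
                               excluded = c("p7", "c"), seed = 1)
  expect_length(plans, choose(4, 2))
  for (p in plans) {
    expect_false("p7" %in% c(p$trainIds, p$testIds))
    expect_false("c" %in% c(p$trainIds, p$testIds))
  }
})

test_that("the ensemble recovers a noiseless truth exactly", {
  ds <- generateDataset(pfasLikeSpec(40, noiseSd = 0, seed = 51))
  ids <- ligandIds(ds)
  y <- setNames(ds@observedPic50, ids)
  plans <- enumeratePairSplits(ids[1:4], ids[5:40], nPoolTest = 3, seed = 2)
  out <- runEnsemble(plans, ds@descriptorTable, y)
  expect_equal(nrow(out$perModel), 6)
  expect_equal(out$averages$trainR2, 1, tolerance = 1e-8)
  expect_equal(out$averages$testR2, 1, tolerance = 1e-6)
})

test_that("training optimism: ensemble train R2 exceeds test R2 for noisy data", {
  wins <- vapply(1:60, function(seed) {
    ds <- generateDataset(pfasLikeSpec(62, noiseSd = 0.3, seed = 600 + seed))
    ids <- ligandIds(ds)
    y <- setNames(ds@observedPic50, ids)
    plans <- enumeratePairSplits(ids[1:12], ids[13:62], nPoolTest = 5,
                                 nPoolTrain = 45, seed = seed)
    out <- runEnsemble(plans[1:6], ds@descriptorTable, y)
    out$averages$trainR2 > out$averages$testR2
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("score cutoff retains scores at or below the threshold", {
  expect_equal(scoreCutoffFilter(c(a = -6.9, b = -7.0, c = -7.1), -7.0),
               c("b", "c"))
  expect_equal(scoreCutoffFilter(numeric(), -7), integer())
  set.seed(52)
  s <- rnorm(1000, -7, 1)
  kept <- scoreCutoffFilter(setNames(s, seq_along(s)), -8)
  expect_length(kept, sum(s <= -8))
})

test_that("refinement removes floor-exact, disjoint sets and keeps the split ratio", {
  ds <- generateDataset(pfasLikeSpec(100, seed = 53))
  y <- setNames(ds@observedPic50, ligandIds(ds))
  out <- iterativeOutlierRefinement(ds@descriptorTable, y,
                                    fractions = c(0.10, 0.20), splitSeed = 5)
  expect_equal(out$trajectory$nRemaining, c(100, 90, 72))
  expect_equal(out$trajectory$nRemoved, c(0, 10, 18))
  expect_length(intersect(out$removedIds[[1]], out$removedIds[[2]]), 0)
  # zero fraction leaves the metrics untouched
  keep <- iterativeOutlierRefinement(ds@descriptorTable, y, fractions = 0,
                                     splitSeed = 5)
  expect_equal(keep$trajectory$trainR2[1], keep$trajectory$trainR2[2])
  expect_equal(keep$trajectory$nRemaining, c(100, 100))
})

test_that("refinement removes planted contamination and lifts train R2", {
  improves <- vapply(1:100, function(seed) {
    ds <- generateDataset(pfasLikeSpec(200, noiseSd = 0.35,
                                       seed = 7000 + seed))
    y <- ds@observedPic50
    set.seed(seed)
    bad <- sample(200, 10)                      # 5% contamination
    y[bad] <- y[bad] + sample(c(-3, 3), 10, replace = TRUE)
    names(y) <- ligandIds(ds)
    out <- iterativeOutlierRefinement(ds@descriptorTable, y,
                                      fractions = 0.10, splitSeed = seed)
    diff(out$trajectory$trainR2) > 0
  }, logical(1))
  expect_gte(mean(improves), 0.95)
})

test_that("refined coefficients move closer to the truth under contamination", {
  truth <- coef(publishedModel("TB-ERalpha"))
  closer <- vapply(1:50, function(seed) {
    ds <- generateDataset(pfasLikeSpec(200, noiseSd = 0.35,
                                       seed = 8000 + seed))
    y <- ds@observedPic50
    set.seed(seed)
    bad <- sample(200, 10)
    y[bad] <- y[bad] + sample(c(-3, 3), 10, replace = TRUE)
    names(y) <- ligandIds(ds)
    tab <- ds@descriptorTable
    f0 <- fitQspr(tab, y)
    out <- iterativeOutlierRefinement(tab, y, fractions = 0.10,
                                      splitSeed = seed)
    keep <- setdiff(ligandIds(tab), out$removedIds[[1]])
    f1 <- fitQspr(pfasER:::subsetTable(tab, match(keep, ligandIds(tab))),
                  y[keep])
    tr <- truth[descriptorNames(tab)]
    sqrt(sum((coef(f1) - tr)^2)) < sqrt(sum((coef(f0) - tr)^2))
  }, logical(1))
  expect_gte(mean(closer), 0.90)
})

test_that("benchmark separation equals a brute-force scan and powers of ten", {
  out <- benchmarkSeparation(c(8, 7.5, 4.1, 3.9),
                             c("active", "active", "decoy", "decoy"))
  expect_equal(out$separation, 7.5 - 4.1)
  expect_equal(out$foldRatio, 10^3.4)
  # separation 2 => 100-fold
  expect_equal(benchmarkSeparation(c(6, 4), c("active", "decoy"))$foldRatio,
               100)
  set.seed(54)
  pred <- rnorm(60)
  lab <- sample(c("active", "decoy"), 60, replace = TRUE)
  out2 <- benchmarkSeparation(pred, lab)
  expect_equal(out2$separation,
               min(pred[lab == "active"]) - max(pred[lab == "decoy"]))
  expect_error(benchmarkSeparation(pred, rep("active", 60)), "decoy")
})

test_that("decoy standardization floors decoys at 100,000 nM and spares actives", {
  df <- data.frame(ligand_id = c("a1", "a2", "d1", "d2"),
                   ic50_nM = c(10, 250, 3, 99),
                   is_decoy = c(FALSE, FALSE, TRUE, TRUE))
  out <- standardizeDecoys(df)
  expect_equal(out$ic50_nM, c(10, 250, 1e5, 1e5))
  expect_equal(out$pic50, c(8, ic50ToPic50(250), 4, 4))
  expect_equal(attr(out, "kiPolicy"), "identity")
  # no decoys: table unchanged
  act <- df[!df$is_decoy, ]
  expect_equal(standardizeDecoys(act)$ic50_nM, act$ic50_nM)
})
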