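test_that("OLS matches the normal-equations oracle on random instances", {
  for (seed in 1:5) {
    n <- sample(30:200, 1)
    p <- sample(2:12, 1)
    tab <- randomTable(n, p, seed = seed, corr = 0.4)
    X <- as.matrix(tab)
    set.seed(seed + 100)
    y <- rnorm(n)
    fit <- fitQspr(tab, y)
    beta <- oracleOls(X, y)
    expect_equal(unname(c(fit@intercept, coef(fit))), unname(beta),
                 tolerance = 1e-8)
    # residuals orthogonal to predictors and the constant
    res <- y - predict(fit, tab)
    expect_lt(max(abs(crossprod(cbind(1, X), res))), 1e-8 * n)
  }
})

test_that("noiseless linear truth is recovered exactly", {
  tab <- randomTable(50, 6, seed = 3)
  b <- c(1.5, -2, 0.3, 0, 4, -0.7)
  y <- drop(as.matrix(tab) %*% b) + 2.5
  fit <- fitQspr(tab, y)
  expect_equal(unname(coef(fit)), b, tolerance = 1e-8)
  expect_equal(fit@intercept, 2.5, tolerance = 1e-8)
  expect_equal(fit@fitMetrics$r2, 1, tolerance = 1e-10)
  # single predictor: slope = cov(x,y)/var(x)
  one <- randomTable(40, 1, seed = 8)
  x <- as.matrix(one)[, 1]
  set.seed(9); y1 <- 2 * x + rnorm(40)
  f1 <- fitQspr(one, y1)
  expect_equal(unname(coef(f1)), cov(x, y1) / var(x), tolerance = 1e-10)
})

test_that("degenerate and invalid designs are rejected or conventionalized", {
  tab <- randomTable(30, 3, seed = 4)
  # constant y: zero coefficients, intercept = constant, R2 = 0 by convention
  fit <- fitQspr(tab, rep(7, 30))
  expect_equal(unname(coef(fit)), rep(0, 3), tolerance = 1e-12)
  expect_equal(fit@intercept, 7, tolerance = 1e-12)
  expect_equal(fit@fitMetrics$r2, 0)
  # rank-deficient design errors and names a dependent column
  X <- as.matrix(tab)
  X <- cbind(X, D99 = X[, 1] * 2)
  expect_error(fitQspr(DescriptorTable(X), rnorm(30)), "D99")
  expect_error(fitQspr(randomTable(4, 3), rnorm(4)), "more ligands")
})

test_that("prediction evaluates the published equations at the zero vector", {
  z <- matrix(0, 1, 11,
              dimnames = list(NULL, canonicalDescriptors()$name))
  expect_equal(unname(predict(publishedModel("TB-ERalpha"), z)), 8.03)
  expect_equal(unname(predict(publishedModel("TB-ERbeta"), z)), 8.02)
  expect_equal(unname(predict(publishedModel("CE-ERalpha"), z)), 5.95)
  expect_equal(unname(predict(publishedModel("CE-ERbeta"), z)), 6.02)
  expect_error(predict(publishedModel("TB-ERalpha"),
                       matrix(0, 1, 2, dimnames = list(NULL, c("A", "B")))),
               "missing descriptor")
})

test_that("published fixture models carry the 4-decimal coefficient sets", {
  for (name in c("TB-ERalpha", "TB-ERbeta", "CE-ERalpha", "CE-ERbeta")) {
    m <- publishedModel(name)
    expect_length(coef(m), 11)
    expect_setequal(descriptorNames(m), canonicalDescriptors()$name)
    # stored normalized values satisfy the raw * sd convention
    expect_equal(unname(m@normalizedCoefficients),
                 unname(coef(m) * m@descriptorSds), tolerance = 1e-10)
  }
  era <- publishedModel("TB-ERalpha")
  expect_equal(coef(era)[["FreelyRotatingBonds"]], -0.3843)
  expect_equal(coef(era)[["AverageMass"]], 0.2222)
  expect_equal(coef(publishedModel("CE-ERbeta"))[["Density"]], 0.3057)
  # implied SD for average mass reproduces the published A/B ratio
  expect_equal(era@descriptorSds[["AverageMass"]], 49.2514 / 0.2222,
               tolerance = 1e-6)
})

test_that("fit metrics match a hand-rolled residual-sum oracle", {
  tab <- randomTable(40, 3, seed = 6)
  set.seed(7); y <- rnorm(40)
  fit <- fitQspr(tab, y)
  ev <- evaluateFit(fit, tab, y)
  res <- y - predict(fit, tab)
  expect_equal(ev$r2, 1 - sum(res^2) / sum((y - mean(y))^2),
               tolerance = 1e-10)
  expect_equal(ev$rmse, sqrt(mean(res^2)), tolerance = 1e-10)
  expect_equal(ev$mae, mean(abs(res)), tolerance = 1e-10)
  expect_lte(ev$mae, ev$rmse)
  # perfect predictions and the null model
  expect_equal(evaluateFit(fit, tab, predict(fit, tab))$rmse, 0)
  null <- QsprModel(setNames(rep(0, 3), descriptorNames(tab)), mean(y))
  expect_equal(evaluateFit(null, tab, y)$r2, 0, tolerance = 1e-10)
  # zero-variance target: undefined R2 marker
  expect_true(is.na(evaluateFit(fit, tab, rep(1, 40))$r2))
})

test_that("PRESS-shortcut Q2 equals leave-one-out refitting", {
  tab <- randomTable(30, 4, seed = 12)
  set.seed(13); y <- rnorm(30)
  q2 <- crossValidateQ2(tab, y)
  X <- as.matrix(tab)
  press <- sum(vapply(seq_len(30), function(i) {
    beta <- oracleOls(X[-i, ], y[-i])
    (y[i] - drop(c(1, X[i, ]) %*% beta))^2
  }, numeric(1)))
  expect_equal(q2, 1 - press / sum((y - mean(y))^2), tolerance = 1e-8)
  # noiseless linear data: Q2 = 1
  yl <- drop(X %*% c(1, -1, 2, 0.5)) + 3
  expect_equal(crossValidateQ2(tab, yl), 1, tolerance = 1e-8)
})

test_that("coefficient normalization is the stated convention and invertible", {
  tab <- randomTable(50, 3, seed = 14)
  set.seed(15); y <- rnorm(50)
  fit <- fitQspr(tab, y)
  sds <- apply(as.matrix(tab), 2, sd)
  norm <- normalizeCoefficients(fit, sds)
  expect_equal(unname(norm@normalizedCoefficients),
               unname(coef(fit) * sds), tolerance = 1e-12)
  expect_equal(norm@intercept, fit@intercept)
  back <- denormalizeCoefficients(norm@normalizedCoefficients, sds)
  expect_equal(back, coef(fit), tolerance = 1e-12)
  # sd = 1 leaves coefficients unchanged
  unit <- normalizeCoefficients(fit, setNames(rep(1, 3), names(sds)))
  expect_equal(unit@normalizedCoefficients, coef(fit))
  # beta variant divides by sd(y)
  beta <- normalizeCoefficients(fit, sds, responseSd = sd(y))
  expect_equal(unname(beta@normalizedCoefficients),
               unname(coef(fit) * sds / sd(y)), tolerance = 1e-12)
  expect_error(normalizeCoefficients(fit, setNames(c(1, -1, 1), names(sds))),
               "positive")
})

test_that("confidence intervals cover the truth at nominal rate on synthetic data", {
  # 200 replicates, n = 200, noise 0.3: per-coefficient 95% CI coverage
  truth <- coef(publishedModel("TB-ERalpha"))
  hits <- 0L; total <- 0L
  for (seed in 1:200) {
    ds <- generateDataset(pfasLikeSpec(200, noiseSd = 0.3, seed = seed))
    fit <- fitQspr(ds@descriptorTable, ds@observedPic50)
    se <- sqrt(diag(fit@xtxInv))[-1] * fit@sigma
    crit <- qt(0.975, 200 - 11 - 1)
    covered <- abs(coef(fit) - truth[descriptorNames(ds@descriptorTable)]) <=
      crit * se
    hits <- hits + sum(covered); total <- total + length(covered)
  }
  expect_gt(hits / total, 0.90)
  expect_lt(hits / total, 1.00)
})
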