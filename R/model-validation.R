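#' @include AllClasses.R qspr-mlr.R affinity.R
NULL

#' Enumerate pairwise experimental-compound split plans
#'
#' One plan per unique pair of experimental compounds: the pair joins the
#' test set together with `nPoolTest` pool compounds sampled without
#' replacement (fresh per plan, driven by one master seed); the remaining
#' experimental compounds and `nPoolTrain` pool compounds form the training
#' set. With 12 experimental compounds this yields the full set of
#' `choose(12, 2) = 66` models. A fixed exclusion list keeps designated
#' ligands (e.g. a ligand already consumed by earlier test sets) out of
#' every plan.
#'
#' @param experimentalIds identifiers of compounds with experimental
#'   affinities (n >= 2).
#' @param poolIds identifiers of the modelled (e.g. docked) compound pool.
#' @param nPoolTest pool compounds per test set (default 5).
#' @param nPoolTrain pool compounds per training set; `NULL` (default) uses
#'   all remaining pool compounds.
#' @param excluded identifiers removed from consideration entirely.
#' @param seed integer master RNG seed.
#' @return list of split plans, each a list with `testIds`, `trainIds`,
#'   `excludedIds`, `experimentalPair`, `seed`.
#' @examples
#' length(enumeratePairSplits(letters[1:12], sprintf("p%d", 1:57))) # 66
#' @export
enumeratePairSplits <- function(experimentalIds, poolIds, nPoolTest = 5,
                                nPoolTrain = NULL, excluded = character(),
                                seed = 1L) {
  experimentalIds <- setdiff(experimentalIds, excluded)
  poolIds <- setdiff(poolIds, excluded)
  n <- length(experimentalIds)
  if (n < 2L) stop("at least 2 experimental compounds are required")
  need <- nPoolTest + if (is.null(nPoolTrain)) 0L else nPoolTrain
  if (length(poolIds) < need)
    stop("pool too small: ", length(poolIds), " compound(s) for ", need)
  pairs <- combn(experimentalIds, 2, simplify = FALSE)
  set.seed(seed)
  lapply(seq_along(pairs), function(i) {
    pair <- pairs[[i]]
    poolTest <- sample(poolIds, nPoolTest)
    rest <- setdiff(poolIds, poolTest)
    poolTrain <- if (is.null(nPoolTrain)) rest else sample(rest, nPoolTrain)
    list(testIds = c(pair, poolTest),
         trainIds = c(setdiff(experimentalIds, pair), poolTrain),
         excludedIds = excluded, experimentalPair = pair,
         seed = as.integer(seed))
  })
}

#' Run the pairwise ensemble of QSAR models
#'
#' Fits one OLS model per split plan and evaluates training R2, test R2 and
#' leave-one-out Q2, then averages across plans.
#'
#' @param plans list of split plans from [enumeratePairSplits()].
#' @param table a complete [DescriptorTable-class] covering every id.
#' @param y named pIC50 vector covering every id.
#' @return list with `perModel` (data.frame: model, trainR2, testR2, q2) and
#'   `averages` (list of the three means).
#' @export
runEnsemble <- function(plans, table, y) {
  if (is.null(names(y))) stop("y must be named by ligand id")
  idx <- function(ids) match(ids, table@ligandIds)
  rows <- lapply(seq_along(plans), function(i) {
    plan <- plans[[i]]
    if (anyNA(idx(c(plan$trainIds, plan$testIds))))
      stop("plan ", i, " references unknown ligand ids")
    trTab <- subsetTable(table, rows = idx(plan$trainIds))
    teTab <- subsetTable(table, rows = idx(plan$testIds))
    fit <- fitQspr(trTab, y[plan$trainIds])
    data.frame(model = i,
               trainR2 = fit@fitMetrics$r2,
               testR2 = evaluateFit(fit, teTab, y[plan$testIds])$r2,
               q2 = crossValidateQ2(trTab, y[plan$trainIds]))
  })
  perModel <- do.call(rbind, rows)
  list(perModel = perModel,
       averages = list(trainR2 = mean(perModel$trainR2),
                       testR2 = mean(perModel$testR2),
                       q2 = mean(perModel$q2)))
}

#' Filter ligands by docking-score cutoff
#'
#' Retains ligands whose score is at least as favorable as the cutoff
#' (score <= cutoff, inclusive; more negative = stronger binding).
#'
#' @param scores named numeric vector of docking scores in kcal/mol.
#' @param cutoff score cutoff in kcal/mol (e.g. -7.0).
#' @return character vector of retained ligand ids (names of `scores`); an
#'   unnamed input returns retained indices.
#' @examples
#' scoreCutoffFilter(c(a = -6.9, b = -7, c = -7.1), -7)   # b, c
#' @export
scoreCutoffFilter <- function(scores, cutoff) {
  keep <- which(scores <= cutoff)
  if (is.null(names(scores))) keep else names(scores)[keep]
}

#' Iterative residual-outlier refinement of a large-set QSAR model
#'
#' Round k: fit on the current 80/20 split, rank every current compound by
#' absolute residual (training residuals from the fit, test residuals from
#' prediction — pooled by default), drop the top `fractions[k]` of the
#' current compound count (floor arithmetic), re-split with a seed derived
#' from `splitSeed`, refit. The trajectory records the metrics before any
#' removal and after each round.
#'
#' @param table a complete [DescriptorTable-class].
#' @param y named pIC50 vector aligned with the table's ligand ids.
#' @param fractions ordered removal fractions in (0, 1) — default
#'   `c(0.10, 0.20)`, each applied to the then-current compound count
#'   (cumulative removal).
#' @param splitSeed integer seed; round k re-splits with `splitSeed + k`.
#' @param trainFraction training fraction of each split (default 0.8).
#' @param ranking `"pooled"` (default) ranks train and test residuals
#'   together; `"train"` ranks training compounds only.
#' @return list with `trajectory` (data.frame: round, fractionRemoved,
#'   nRemoved, nRemaining, trainR2, testR2) and `removedIds` (list of id
#'   vectors per round, pairwise disjoint).
#' @export
iterativeOutlierRefinement <- function(table, y, fractions = c(0.10, 0.20),
                                       splitSeed = 1L, trainFraction = 0.8,
                                       ranking = c("pooled", "train")) {
  ranking <- match.arg(ranking)
  if (any(fractions < 0) || any(fractions >= 1))
    stop("fractions must lie in [0, 1)")
  if (is.null(names(y))) y <- setNames(y, table@ligandIds)
  currentIds <- table@ligandIds
  idx <- function(ids) match(ids, table@ligandIds)

  fitRound <- function(ids, seed) {
    sp <- splitLigands(ids, "fraction", trainFraction, seed)
    trTab <- subsetTable(table, rows = idx(sp$trainIds))
    teTab <- subsetTable(table, rows = idx(sp$testIds))
    fit <- fitQspr(trTab, y[sp$trainIds])
    resTrain <- y[sp$trainIds] - predict(fit, trTab)
    resTest <- y[sp$testIds] - predict(fit, teTab)
    list(fit = fit, split = sp,
         testR2 = evaluateFit(fit, teTab, y[sp$testIds])$r2,
         residuals = c(resTrain, resTest), trainIds = sp$trainIds)
  }

  r0 <- fitRound(currentIds, splitSeed)
  trajectory <- data.frame(round = 0L, fractionRemoved = 0, nRemoved = 0L,
                           nRemaining = length(currentIds),
                           trainR2 = r0$fit@fitMetrics$r2,
                           testR2 = r0$testR2)
  removedIds <- list()
  state <- r0
  for (k in seq_along(fractions)) {
    frac <- fractions[k]
    nDrop <- floor(frac * length(currentIds))
    if (nDrop == 0L) {
      removedIds[[k]] <- character(0)
      trajectory <- rbind(trajectory,
        data.frame(round = k, fractionRemoved = frac, nRemoved = 0L,
                   nRemaining = length(currentIds),
                   trainR2 = state$fit@fitMetrics$r2, testR2 = state$testR2))
      next
    }
    res <- abs(state$residuals)
    if (ranking == "train") res <- res[names(res) %in% state$trainIds]
    drop <- names(sort(res, decreasing = TRUE))[seq_len(nDrop)]
    if (length(currentIds) - nDrop <= ncol(table@data) + 2L)
      stop("removal would leave too few compounds to refit")
    currentIds <- setdiff(currentIds, drop)
    removedIds[[k]] <- drop
    state <- fitRound(currentIds, splitSeed + k)
    trajectory <- rbind(trajectory,
      data.frame(round = k, fractionRemoved = frac, nRemoved = nDrop,
                 nRemaining = length(currentIds),
                 trainR2 = state$fit@fitMetrics$r2, testR2 = state$testR2))
  }
  list(trajectory = trajectory, removedIds = removedIds)
}

#' Active/decoy separation of benchmark predictions
#'
#' `separation = min(active predictions) - max(decoy predictions)` in pIC50
#' units; `foldRatio = 10^separation` is the IC50 fold-change between the
#' weakest predicted active and the strongest predicted decoy. Positive
#' separation (fold ratio > 1) means the model ranks every active above
#' every decoy.
#'
#' @param predictions numeric vector of predicted pIC50.
#' @param labels parallel vector: `"active"`/`"decoy"` (or logical where
#'   `TRUE` = active).
#' @return list with `separation`, `foldRatio`, `nActive`, `nDecoy`.
#' @examples
#' benchmarkSeparation(c(8, 7.5, 4.1, 3.9),
#'                     c("active", "active", "decoy", "decoy"))
#' @export
benchmarkSeparation <- function(predictions, labels) {
  if (is.logical(labels)) labels <- ifelse(labels, "active", "decoy")
  active <- predictions[labels == "active"]
  decoy <- predictions[labels == "decoy"]
  if (!length(active) || !length(decoy))
    stop("both an active and a decoy class are required")
  sep <- min(active) - max(decoy)
  list(separation = sep, foldRatio = 10^sep,
       nActive = length(active), nDecoy = length(decoy))
}

#' Standardize decoy affinities in a benchmark table
#'
#' Every decoy is assigned IC50 = 100,000 nM (pIC50 = 4.0), the conventional
#' ">100,000 nM" floor reported for benchmark decoys. Actives are left
#' untouched; actives whose affinity is labelled as Ki are passed through
#' unchanged (Ki treated as IC50 — an identity mapping, flagged in the
#' returned metadata, not a pharmacological correction).
#'
#' @param records data.frame with columns `ligand_id`, `ic50_nM`,
#'   `is_decoy` (logical) and optionally `affinity_type` (`"IC50"`/`"Ki"`).
#' @param decoy_nM the standardization floor, default 1e5 nM.
#' @return the table with `ic50_nM` standardized and a `pic50` column
#'   appended; attribute `kiPolicy = "identity"` records the Ki handling.
#' @export
standardizeDecoys <- function(records, decoy_nM = 1e5) {
  stopifnot(all(c("ligand_id", "ic50_nM", "is_decoy") %in% names(records)))
  out <- records
  out$ic50_nM[out$is_decoy] <- decoy_nM
  out$pic50 <- ic50ToPic50(out$ic50_nM)
  attr(out, "kiPolicy") <- "identity"
  out
}
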