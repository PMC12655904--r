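#' @include AllClasses.R qspr-mlr.R
NULL

#' Accumulated local effects of one descriptor
#'
#' First-order ALE: the descriptor's observed range is partitioned into
#' `gridSize` intervals (quantile edges by default, so each interval carries
#' comparable data mass); within each interval the mean prediction change
#' from moving every observation's descriptor to the interval's upper versus
#' lower edge is taken as the local effect; local effects are accumulated
#' across the grid and the curve is centered by its observation-weighted
#' mean, so values read as deviations (in pIC50 units) from the average
#' prediction. Empty intervals contribute zero local effect. ALE curves are
#' robust to descriptor correlation, unlike naive partial-dependence sweeps.
#'
#' @param model a [QsprModel-class] (or any object with a `predict` method
#'   accepting a matrix with named columns).
#' @param table a complete [DescriptorTable-class] containing the descriptor.
#' @param descriptor name of the profiled descriptor.
#' @param gridSize number of grid intervals (default 20).
#' @param gridType `"quantile"` (default) or `"uniform"` edge placement.
#' @return an [ALEProfile-class].
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("A", "B")))
#' fit <- fitQspr(DescriptorTable(m), 2 * m[, 1] + rnorm(100, 0, 0.1))
#' aleCurve(fit, DescriptorTable(m), "A")
#' @export
aleCurve <- function(model, table, descriptor, gridSize = 20,
                     gridType = c("quantile", "uniform")) {
  gridType <- match.arg(gridType)
  X <- designMatrix(table)
  if (!descriptor %in% colnames(X))
    stop("descriptor not present: ", descriptor)
  x <- X[, descriptor]
  if (length(unique(x)) < 2L) stop("constant descriptor: ", descriptor)
  edges <- if (gridType == "quantile")
    unique(quantile(x, probs = seq(0, 1, length.out = gridSize + 1),
                    names = FALSE, type = 7))
  else seq(min(x), max(x), length.out = gridSize + 1)
  K <- length(edges) - 1L
  idx <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  nPer <- tabulate(idx, nbins = K)
  local <- numeric(K)
  for (k in which(nPer > 0)) {
    rows <- idx == k
    hi <- X[rows, , drop = FALSE]; hi[, descriptor] <- edges[k + 1]
    lo <- X[rows, , drop = FALSE]; lo[, descriptor] <- edges[k]
    local[k] <- mean(predict(model, hi) - predict(model, lo))
  }
  acc <- c(0, cumsum(local))
  # observation-weighted centering: each interval contributes its data mass
  # at the midpoint of the accumulated curve
  center <- sum(nPer * (acc[-length(acc)] + acc[-1]) / 2) / sum(nPer)
  ale <- acc - center
  new("ALEProfile", descriptor = descriptor, edges = edges, ale = ale,
      aleRaw = acc, deltaRange = range(ale))
}

#' ALE summary across descriptors
#'
#' One profile per descriptor, summarized as the min-max span of the
#' centered curve (the expected change in predicted pIC50 across the
#' descriptor's observed range), ordered by decreasing span width. The
#' uncentered (raw accumulated) range is reported alongside.
#'
#' @param model a [QsprModel-class].
#' @param table a complete [DescriptorTable-class].
#' @param descriptors descriptor names to profile (default: the model's).
#' @param gridSize,gridType passed to [aleCurve()].
#' @return data.frame with columns `descriptor`, `lo`, `hi`, `width`,
#'   `rawLo`, `rawHi`, ordered by `width` descending; the profiles are
#'   attached as attribute `profiles`.
#' @export
aleSummary <- function(model, table, descriptors = descriptorNames(model),
                       gridSize = 20, gridType = "quantile") {
  profiles <- lapply(descriptors, function(d)
    aleCurve(model, table, d, gridSize = gridSize, gridType = gridType))
  df <- data.frame(
    descriptor = descriptors,
    lo = vapply(profiles, function(p) p@deltaRange[1], numeric(1)),
    hi = vapply(profiles, function(p) p@deltaRange[2], numeric(1)),
    rawLo = vapply(profiles, function(p) min(p@aleRaw), numeric(1)),
    rawHi = vapply(profiles, function(p) max(p@aleRaw), numeric(1)),
    stringsAsFactors = FALSE)
  df$width <- df$hi - df$lo
  df <- df[order(-df$width), c("descriptor", "lo", "hi", "width",
                               "rawLo", "rawHi")]
  rownames(df) <- NULL
  attr(df, "profiles") <- setNames(profiles, descriptors)
  df
}
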