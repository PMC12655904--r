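#' @include AllClasses.R qspr-mlr.R
NULL

#' Critical leverage of a Williams plot
#'
#' `h* = 3 (M + 1) / N` with `M` descriptors and `N` training compounds.
#' Training points with leverage above `h*` lie outside the model's
#' structural domain.
#'
#' @param M number of descriptors (>= 1).
#' @param N number of training compounds (>= M + 2).
#' @return numeric(1) critical leverage.
#' @examples
#' criticalLeverage(11, 55)   # 0.6545...
#' @export
criticalLeverage <- function(M, N) {
  if (M < 1) stop("M must be at least 1")
  if (N < M + 2) stop("N must be at least M + 2")
  3 * (M + 1) / N
}

#' Leverages of training and query ligands
#'
#' For training ligands, the hat-matrix diagonal of the intercept-augmented
#' training design (values in (0, 1], summing to M + 1). For query ligands,
#' the quadratic form `x' (X'X)^-1 x` under the training projection — no
#' refit, the standard Williams-plot practice for external points.
#'
#' @param model a fitted [QsprModel-class] (from [fitQspr()]).
#' @param newdata optional query [DescriptorTable-class]/matrix; when `NULL`
#'   the training leverages are returned.
#' @return numeric vector of leverages.
#' @export
leverages <- function(model, newdata = NULL) {
  if (!nrow(model@xtxInv))
    stop("model carries no training design (published fixture model?)")
  if (is.null(newdata)) return(model@trainLeverages)
  X <- designMatrix(newdata, model@descriptorNames)
  D <- cbind(1, X)
  unname(rowSums((D %*% model@xtxInv) * D))
}

#' Standardized residuals under the training error scale
#'
#' `(y - prediction) / s` with `s = sqrt(RSS / (N - M - 1))` from the
#' training fit; the same scale is applied to external ligands so that the
#' +-3 band means the same thing on both sides of the Williams plot.
#'
#' @param model a fitted [QsprModel-class].
#' @param table descriptor data.
#' @param y observed pIC50 values.
#' @param studentized logical; divide each training residual additionally by
#'   `sqrt(1 - h)` (internally studentized variant).
#' @return numeric vector of standardized residuals.
#' @export
standardizedResiduals <- function(model, table, y, studentized = FALSE) {
  if (!is.finite(model@sigma) || model@sigma < 1e-8)
    stop("degenerate fit: residual standard deviation is (numerically) zero")
  res <- y - predict(model, table)
  if (studentized) {
    h <- leverages(model, table)
    res <- res / sqrt(pmax(1 - h, .Machine$double.eps))
  }
  unname(res / model@sigma)
}

#' Williams-plot applicability-domain classification
#'
#' Classifies every ligand by its leverage and standardized residual:
#' `residual_outlier` when `|residual| > residualLimit` (default 3),
#' `leverage_outlier` when `leverage > h*`, `both` when both hold,
#' `in_domain` otherwise. Boundary values are in-domain (strict
#' inequalities).
#'
#' @param model a fitted [QsprModel-class].
#' @param table descriptor data for the ligands to classify.
#' @param y observed pIC50 values.
#' @param hStar critical leverage; defaults to
#'   `criticalLeverage(M, N_train)` from the model's own training set.
#' @param residualLimit residual band half-width, default 3.
#' @param studentized passed to [standardizedResiduals()].
#' @return an [ADResult-class].
#' @export
williamsClassify <- function(model, table, y, hStar = NULL,
                             residualLimit = 3, studentized = FALSE) {
  sameTrain <- is(table, "DescriptorTable") &&
    identical(table@ligandIds, model@trainingIds)
  h <- if (sameTrain) model@trainLeverages else leverages(model, table)
  r <- standardizedResiduals(model, table, y, studentized = studentized)
  if (is.null(hStar))
    hStar <- criticalLeverage(length(model@descriptorNames),
                              length(model@trainingIds))
  resOut <- abs(r) > residualLimit
  levOut <- h > hStar
  cls <- ifelse(resOut & levOut, "both",
         ifelse(resOut, "residual_outlier",
         ifelse(levOut, "leverage_outlier", "in_domain")))
  ids <- if (is(table, "DescriptorTable")) table@ligandIds
         else sprintf("lig%d", seq_along(h))
  new("ADResult", ligandIds = ids, leverage = h, stdResidual = r,
      hStar = hStar, residualLimit = residualLimit,
      classification = factor(cls, levels = c("in_domain",
        "residual_outlier", "leverage_outlier", "both")))
}

#' Williams-plot data for external rendering
#'
#' @param ad an [ADResult-class].
#' @return data.frame with ligand id, leverage, standardized residual and
#'   class; thresholds attached as attributes `hStar` and `residualLimit`.
#' @export
williamsPlotData <- function(ad) {
  df <- data.frame(ligandId = ad@ligandIds, leverage = ad@leverage,
                   stdResidual = ad@stdResidual,
                   class = as.character(ad@classification),
                   stringsAsFactors = FALSE)
  attr(df, "hStar") <- ad@hStar
  attr(df, "residualLimit") <- ad@residualLimit
  df
}
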