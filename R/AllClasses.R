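#' @import methods
#' @importFrom stats coef lm.fit predict quantile rnorm sd setNames var
#' @importFrom utils combn head
NULL

#' DescriptorTable: ligands by named physicochemical descriptors
#'
#' A numeric matrix of descriptor values (rows = ligands, columns =
#' descriptors) together with the ligand identifiers and per-descriptor
#' metadata (single-letter abbreviation, data source, units). Missing values
#' are permitted until [cleanDescriptors()] removes incomplete ligands.
#'
#' @slot ligandIds character vector of unique ligand identifiers, one per row.
#' @slot data numeric matrix with unique, non-empty column names.
#' @slot meta data.frame with columns `name`, `letter`, `source`, `units`;
#'   rows for descriptors the package knows about (others get `NA` metadata).
#'
#' @seealso [DescriptorTable()], [canonicalDescriptors()]
#' @exportClass DescriptorTable
setClass("DescriptorTable",
  representation(ligandIds = "character", data = "matrix", meta = "data.frame"))

setValidity("DescriptorTable", function(object) {
  d <- object@data
  if (!is.numeric(d))
    return("descriptor data must be a numeric matrix")
  if (is.null(colnames(d)) || anyDuplicated(colnames(d)) || any(!nzchar(colnames(d))))
    return("descriptor columns must have unique, non-empty names")
  if (nrow(d) != length(object@ligandIds))
    return("one ligand id per row is required")
  if (anyDuplicated(object@ligandIds))
    return("ligand ids must be unique")
  TRUE
})

#' QsprModel: a multiple-linear-regression descriptor-to-pIC50 model
#'
#' Holds the fitted (or published) coefficients on the raw descriptor scale,
#' the intercept, optional per-descriptor standard deviations with the
#' corresponding normalized coefficients, and — for models fitted in-package —
#' the training bookkeeping needed for applicability-domain diagnostics
#' (residual standard deviation, inverse cross-product matrix, leverages).
#'
#' @slot descriptorNames ordered descriptor identifiers.
#' @slot coefficients named numeric, raw coefficients (pIC50 per descriptor unit).
#' @slot intercept numeric(1), pIC50 units.
#' @slot descriptorSds named numeric (possibly length 0).
#' @slot normalizedCoefficients named numeric (possibly length 0); equals
#'   `coefficients * descriptorSds` when present.
#' @slot trainingIds ligand ids the model was fitted on (length 0 for
#'   published fixture models).
#' @slot sigma numeric, residual standard deviation `sqrt(RSS/(N-M-1))`
#'   (`NA` when not fitted).
#' @slot xtxInv inverse of `t(X) %*% X` for the intercept-augmented training
#'   design (0 x 0 matrix when not fitted); used for query-point leverage.
#' @slot trainLeverages hat-matrix diagonal of the training design.
#' @slot fitMetrics list with `r2`, `rmse`, `mae` and optionally `q2`.
#' @slot meta list of free-form metadata (split seeds, provenance label).
#'
#' @exportClass QsprModel
setClass("QsprModel",
  representation(descriptorNames = "character", coefficients = "numeric",
    intercept = "numeric", descriptorSds = "numeric",
    normalizedCoefficients = "numeric", trainingIds = "character",
    sigma = "numeric", xtxInv = "matrix", trainLeverages = "numeric",
    fitMetrics = "list", meta = "list"))

setValidity("QsprModel", function(object) {
  if (length(object@coefficients) != length(object@descriptorNames))
    return("coefficient count must equal descriptor count")
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    return("intercept must be a single finite number")
  if (length(object@descriptorSds)) {
    if (length(object@descriptorSds) != length(object@descriptorNames))
      return("descriptorSds must align with descriptorNames")
    if (any(object@descriptorSds <= 0))
      return("descriptor standard deviations must be positive")
    if (length(object@normalizedCoefficients)) {
      diff <- abs(object@normalizedCoefficients -
                  object@coefficients * object@descriptorSds)
      if (any(diff > 1e-10))
        return("normalized coefficients must equal raw * sd within 1e-10")
    }
  }
  TRUE
})

#' ADResult: Williams-plot applicability-domain classification
#'
#' @slot ligandIds identifiers of the classified ligands.
#' @slot leverage per-ligand hat values (training points lie in (0, 1]).
#' @slot stdResidual per-ligand standardized residuals.
#' @slot hStar critical leverage `3(M+1)/N`.
#' @slot residualLimit the residual band half-width (default 3).
#' @slot classification factor with levels `in_domain`, `residual_outlier`,
#'   `leverage_outlier`, `both`.
#'
#' @exportClass ADResult
setClass("ADResult",
  representation(ligandIds = "character", leverage = "numeric",
    stdResidual = "numeric", hStar = "numeric", residualLimit = "numeric",
    classification = "factor"))

setValidity("ADResult", function(object) {
  n <- length(object@ligandIds)
  if (length(object@leverage) != n || length(object@stdResidual) != n ||
      length(object@classification) != n)
    return("leverage, residuals and classification must align with ligand ids")
  if (object@hStar <= 0) return("hStar must be positive")
  want <- c("in_domain", "residual_outlier", "leverage_outlier", "both")
  if (!identical(levels(object@classification), want))
    return("classification levels must be in_domain/residual_outlier/leverage_outlier/both")
  res_out <- abs(object@stdResidual) > object@residualLimit
  lev_out <- object@leverage > object@hStar
  expect <- ifelse(res_out & lev_out, "both",
            ifelse(res_out, "residual_outlier",
            ifelse(lev_out, "leverage_outlier", "in_domain")))
  if (!identical(as.character(object@classification), expect))
    return("classification inconsistent with thresholds")
  TRUE
})

#' ALEProfile: accumulated local effects of one descriptor
#'
#' @slot descriptor descriptor name.
#' @slot edges grid edges partitioning the observed descriptor range.
#' @slot ale centered accumulated local effects at the edges (pIC50 units).
#' @slot aleRaw uncentered accumulated curve (starts at 0).
#' @slot deltaRange numeric(2), min and max of the centered curve.
#'
#' @exportClass ALEProfile
setClass("ALEProfile",
  representation(descriptor = "character", edges = "numeric", ale = "numeric",
    aleRaw = "numeric", deltaRange = "numeric"))

setValidity("ALEProfile", function(object) {
  if (length(object@ale) != length(object@edges))
    return("one ALE value per grid edge is required")
  if (length(object@deltaRange) != 2L)
    return("deltaRange must be (min, max)")
  TRUE
})

#' ComplexStructure: atoms of one receptor-ligand complex
#'
#' @slot complexId identifier (file stem or user label).
#' @slot atoms data.frame with columns `element`, `x`, `y`, `z`, `resname`,
#'   `resno`, `chain`, `ligand` (logical flag).
#'
#' @exportClass ComplexStructure
setClass("ComplexStructure",
  representation(complexId = "character", atoms = "data.frame"))

setValidity("ComplexStructure", function(object) {
  a <- object@atoms
  need <- c("element", "x", "y", "z", "resname", "resno", "chain", "ligand")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) && !all(is.finite(c(a$x, a$y, a$z))))
    return("atom coordinates must be finite")
  TRUE
})

#' ContactProfile: residue-type contact frequencies across complexes
#'
#' Counts are residue *instances*: a residue type contacted in k complexes
#' (or by k distinct residues of one complex) contributes k.
#'
#' @slot counts named integer vector, contacts per 3-letter residue type.
#' @slot percentages named numeric vector summing to 100 (length 0 when no
#'   contacts exist anywhere).
#' @slot nComplexes number of complexes aggregated.
#'
#' @exportClass ContactProfile
setClass("ContactProfile",
  representation(counts = "integer", percentages = "numeric",
    nComplexes = "integer"))

setValidity("ContactProfile", function(object) {
  if (any(object@counts < 0)) return("counts must be nonnegative")
  if (length(object@percentages)) {
    if (abs(sum(object@percentages) - 100) > 1e-6)
      return("percentages must sum to 100")
  }
  TRUE
})

#' SyntheticSpec: ground-truth recipe for a synthetic PFAS dataset
#'
#' @slot nLigands number of ligands to draw.
#' @slot descriptorNames descriptor identifiers (default: the canonical 11).
#' @slot meanVector per-descriptor means.
#' @slot covariance symmetric positive-semidefinite descriptor covariance.
#' @slot trueCoefficients per-descriptor linear coefficients (pIC50 scale).
#' @slot trueIntercept intercept in pIC50 units.
#' @slot noiseSd Gaussian observation noise on pIC50 (>= 0).
#' @slot scoreNoiseSd Gaussian noise on generated docking scores in kcal/mol
#'   (>= 0).
#' @slot temperatureK temperature for the score/affinity interconversion.
#' @slot seed integer RNG seed.
#'
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  representation(nLigands = "integer", descriptorNames = "character",
    meanVector = "numeric", covariance = "matrix",
    trueCoefficients = "numeric", trueIntercept = "numeric",
    noiseSd = "numeric", scoreNoiseSd = "numeric", temperatureK = "numeric",
    seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  p <- length(object@descriptorNames)
  if (object@nLigands < 0L) return("nLigands must be nonnegative")
  if (length(object@meanVector) != p)
    return("meanVector must align with descriptorNames")
  if (!all(dim(object@covariance) == c(p, p)))
    return("covariance dimension must equal descriptor count")
  if (max(abs(object@covariance - t(object@covariance))) > 1e-10)
    return("covariance must be symmetric within 1e-10")
  ev <- eigen(object@covariance, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8 * max(abs(ev), 1)))
    return(sprintf("covariance is not positive semidefinite (eigenvalue %.6g)",
                   min(ev)))
  if (length(object@trueCoefficients) != p)
    return("trueCoefficients must align with descriptorNames")
  if (object@noiseSd < 0) return("noiseSd must be nonnegative")
  if (object@scoreNoiseSd < 0) return("scoreNoiseSd must be nonnegative")
  if (object@temperatureK <= 0) return("temperatureK must be positive")
  TRUE
})

#' SyntheticDataset: descriptors plus affinity ground truth
#'
#' @slot descriptorTable the generated [DescriptorTable-class].
#' @slot truePic50 noiseless linear-model pIC50 per ligand.
#' @slot observedPic50 truePic50 plus Gaussian noise.
#' @slot dockingScores kcal/mol scores, the inverse affinity conversion of
#'   truePic50 (plus optional score noise).
#' @slot spec the [SyntheticSpec-class] that produced the data.
#'
#' @exportClass SyntheticDataset
setClass("SyntheticDataset",
  representation(descriptorTable = "DescriptorTable", truePic50 = "numeric",
    observedPic50 = "numeric", dockingScores = "numeric",
    spec = "SyntheticSpec"))

setValidity("SyntheticDataset", function(object) {
  n <- nrow(object@descriptorTable@data)
  if (length(object@truePic50) != n || length(object@observedPic50) != n ||
      length(object@dockingScores) != n)
    return("affinity vectors must share the ligand index of descriptorTable")
  if (object@spec@noiseSd == 0 &&
      any(object@observedPic50 != object@truePic50))
    return("observed pIC50 must equal true pIC50 when noiseSd is 0")
  TRUE
})

#' ValidationSummary: docking-vs-experiment agreement statistics
#'
#' @slot ligandIds identifiers of the compared ligands.
#' @slot differences predicted minus literature pIC50, per ligand.
#' @slot meanDifference mean of the differences.
#' @slot sd sample standard deviation (n - 1 denominator).
#' @slot standardError `sd / sqrt(n)`.
#'
#' @exportClass ValidationSummary
setClass("ValidationSummary",
  representation(ligandIds = "character", differences = "numeric",
    meanDifference = "numeric", sd = "numeric", standardError = "numeric"))

setValidity("ValidationSummary", function(object) {
  n <- length(object@differences)
  if (n < 2L) return("at least two ligand pairs are required")
  if (abs(object@standardError - object@sd / sqrt(n)) > 1e-12)
    return("standardError must equal sd/sqrt(n)")
  TRUE
})
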