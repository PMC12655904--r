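#' @include AllClasses.R
NULL

# gas constant, kcal / (mol K)
GAS_CONSTANT_KCAL <- 1.987e-3

#' Convert IC50 (nM) to pIC50
#'
#' `pIC50 = -log10(IC50 * 1e-9)`, i.e. the negative decadic log of the
#' half-maximal inhibitory concentration expressed in molar. Higher pIC50
#' means stronger binding.
#'
#' @param ic50_nM positive IC50 value(s) in nanomolar.
#' @return pIC50 value(s).
#' @examples
#' ic50ToPic50(40)      # 7.40
#' ic50ToPic50(1)       # 9
#' @export
ic50ToPic50 <- function(ic50_nM) {
  if (any(!is.finite(ic50_nM)) || any(ic50_nM <= 0))
    stop("IC50 must be positive and finite")
  -log10(ic50_nM * 1e-9)
}

#' Convert pIC50 to IC50 (nM)
#'
#' Exact inverse of [ic50ToPic50()].
#'
#' @param pic50 finite pIC50 value(s).
#' @return IC50 value(s) in nanomolar.
#' @examples
#' pic50ToIc50(9)   # 1 nM
#' pic50ToIc50(4)   # 1e5 nM
#' @export
pic50ToIc50 <- function(pic50) {
  if (any(!is.finite(pic50))) stop("pIC50 must be finite")
  10^(-pic50) * 1e9
}

#' Convert a docking score to IC50 (nM)
#'
#' Treats the docking score as a binding free energy and the implied
#' dissociation constant as the IC50: `IC50 = exp(dG / (R T))` in molar,
#' returned in nM, with `R = 1.987e-3 kcal/(mol K)`. A score of 0 maps to
#' 1 M (1e9 nM); more negative scores give lower IC50 (stronger binding).
#' Equating `Kd` and IC50 is an assumption, not a pharmacological identity.
#'
#' @param deltaG docking score(s) in kcal/mol (negative = favorable).
#' @param temperatureK absolute temperature, default 300 K.
#' @return IC50 value(s) in nanomolar.
#' @examples
#' scoreToIc50(-9)     # ~278 nM
#' scoreToIc50(0)      # 1e9 nM (1 M)
#' @export
scoreToIc50 <- function(deltaG, temperatureK = 300) {
  if (any(!is.finite(deltaG))) stop("docking score must be finite")
  if (temperatureK <= 0) stop("temperature must be positive")
  exp(deltaG / (GAS_CONSTANT_KCAL * temperatureK)) * 1e9
}

#' Convert a docking score directly to pIC50
#'
#' Composition of [scoreToIc50()] and [ic50ToPic50()].
#'
#' @inheritParams scoreToIc50
#' @return pIC50 value(s).
#' @examples
#' scoreToPic50(-10)   # ~7.28
#' scoreToPic50(0)     # 0 (pIC50 of 1 M)
#' @export
scoreToPic50 <- function(deltaG, temperatureK = 300) {
  ic50ToPic50(scoreToIc50(deltaG, temperatureK))
}

#' Invert the score conversion: pIC50 to docking score
#'
#' `dG = -ln(10) R T pIC50`; the exact inverse of [scoreToPic50()], used by
#' the synthetic-data generator so conversion round-trips are testable.
#'
#' @param pic50 pIC50 value(s).
#' @param temperatureK absolute temperature, default 300 K.
#' @return docking score(s) in kcal/mol.
#' @export
pic50ToScore <- function(pic50, temperatureK = 300) {
  if (any(!is.finite(pic50))) stop("pIC50 must be finite")
  -log(10) * GAS_CONSTANT_KCAL * temperatureK * pic50
}

#' Validate predicted against literature affinities
#'
#' Converts both IC50 columns to pIC50, takes per-ligand differences
#' (predicted minus literature) and summarizes them by mean, sample standard
#' deviation (n - 1 denominator) and standard error `SD / sqrt(n)`. A small
#' standard error indicates the docking-derived affinities track experiment.
#'
#' @param literature_nM experimental IC50 values in nM.
#' @param predicted_nM docking-derived IC50 values in nM.
#' @param ligandIds optional identifiers.
#' @return a [ValidationSummary-class].
#' @examples
#' validateAgainstExperiment(c(40, 26), c(278.38, 643.90))
#' @export
validateAgainstExperiment <- function(literature_nM, predicted_nM,
                                      ligandIds = NULL) {
  if (length(literature_nM) != length(predicted_nM))
    stop("literature and predicted columns must have equal length")
  n <- length(literature_nM)
  if (n < 2L) stop("at least 2 ligand pairs are required (SD undefined)")
  diffs <- ic50ToPic50(predicted_nM) - ic50ToPic50(literature_nM)
  if (is.null(ligandIds)) ligandIds <- sprintf("lig%d", seq_len(n))
  s <- sd(diffs)
  new("ValidationSummary", ligandIds = as.character(ligandIds),
      differences = diffs, meanDifference = mean(diffs), sd = s,
      standardError = s / sqrt(n))
}
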