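#' @include AllClasses.R affinity.R descriptors.R
NULL

#' Build a SyntheticSpec
#'
#' Recipe for a synthetic PFAS-like dataset: descriptors drawn from a
#' multivariate normal, pIC50 generated from a known linear model plus
#' Gaussian noise, and docking scores obtained by the exact inverse of the
#' score-to-affinity conversion (so conversion round-trips are testable).
#'
#' @param nLigands number of ligands.
#' @param descriptorNames descriptor identifiers (default: the canonical 11).
#' @param meanVector per-descriptor means (default 0).
#' @param covariance symmetric PSD covariance matrix (default identity).
#' @param trueCoefficients per-descriptor coefficients (default 0).
#' @param trueIntercept intercept, pIC50 units (default 0).
#' @param noiseSd observation noise SD on pIC50, default 0.
#' @param scoreNoiseSd noise SD on docking scores in kcal/mol, default 0.
#' @param temperatureK temperature of the score conversion, default 300.
#' @param seed integer RNG seed.
#' @return a [SyntheticSpec-class].
#' @export
SyntheticSpec <- function(nLigands,
                          descriptorNames = canonicalDescriptors()$name,
                          meanVector = NULL, covariance = NULL,
                          trueCoefficients = NULL, trueIntercept = 0,
                          noiseSd = 0, scoreNoiseSd = 0, temperatureK = 300,
                          seed = 1L) {
  p <- length(descriptorNames)
  if (is.null(meanVector)) meanVector <- rep(0, p)
  if (is.null(covariance)) covariance <- diag(p)
  if (is.null(trueCoefficients)) trueCoefficients <- rep(0, p)
  new("SyntheticSpec", nLigands = as.integer(nLigands),
      descriptorNames = descriptorNames, meanVector = meanVector,
      covariance = as.matrix(covariance),
      trueCoefficients = trueCoefficients, trueIntercept = trueIntercept,
      noiseSd = noiseSd, scoreNoiseSd = scoreNoiseSd,
      temperatureK = temperatureK, seed = as.integer(seed))
}

#' PFAS-like synthetic recipe
#'
#' A preset [SyntheticSpec-class] emulating the statistical structure of a
#' PFAS descriptor table. Descriptors are generated in *centered, scaled
#' units* (mean 0, SD 2 per descriptor): QSPR workflows standardize their
#' descriptor blocks anyway, and a common order-unity spread keeps every
#' coefficient of the reference equation statistically identifiable at the
#' sample sizes the models use, while the implied pIC50 signal spread
#' (about 0.7 units around the intercept) and the default observation noise
#' of 0.35 pIC50 units match the error scale the fitted models report. The
#' correlation structure carries a strong mass-size link (r = 0.8 between
#' average mass and polar surface area, with weaker links to rotatable
#' bonds and donor/acceptor counts) so collinearity diagnostics are
#' exercised, and the ground-truth linear model is the top-binder ERalpha
#' published equation (intercept 8.03).
#'
#' @param nLigands number of ligands.
#' @param noiseSd observation noise SD, default 0.35.
#' @param seed integer RNG seed.
#' @param descriptorSd common per-descriptor spread, default 2.
#' @param ... further arguments passed to [SyntheticSpec()].
#' @return a [SyntheticSpec-class].
#' @export
pfasLikeSpec <- function(nLigands, noiseSd = 0.35, seed = 1L,
                         descriptorSd = 2, ...) {
  canon <- canonicalDescriptors()$name
  means <- setNames(rep(0, length(canon)), canon)
  sds <- setNames(rep(descriptorSd, length(canon)), canon)
  corr <- diag(length(canon))
  dimnames(corr) <- list(canon, canon)
  setc <- function(a, b, r) {
    corr[a, b] <<- r
    corr[b, a] <<- r
  }
  setc("AverageMass", "PolarSurfaceArea", 0.8)
  setc("AverageMass", "FreelyRotatingBonds", 0.5)
  setc("PolarSurfaceArea", "FreelyRotatingBonds", 0.45)
  setc("PolarSurfaceArea", "HBondAcceptors", 0.35)
  setc("HBondAcceptors", "HBondDonors", 0.4)
  setc("LogD", "SurfaceTension", -0.3)
  setc("LogD", "PolarSurfaceArea", -0.15)
  covm <- diag(sds[canon]) %*% corr %*% diag(sds[canon])
  covm <- (covm + t(covm)) / 2
  dimnames(covm) <- list(canon, canon)
  truth <- coef(publishedModel("TB-ERalpha"))[canon]
  SyntheticSpec(nLigands, descriptorNames = canon,
                meanVector = means[canon], covariance = covm,
                trueCoefficients = truth, trueIntercept = 8.03,
                noiseSd = noiseSd, seed = seed, ...)
}

#' Generate a descriptor table from a spec
#'
#' Draws `nLigands` rows from the spec's multivariate normal via the
#' Cholesky (or, for semidefinite covariances, eigen) factor, seeded by the
#' spec so identical specs give bitwise-identical tables.
#'
#' @param spec a valid [SyntheticSpec-class].
#' @return a [DescriptorTable-class].
#' @export
generateDescriptors <- function(spec) {
  validObject(spec)
  p <- length(spec@descriptorNames)
  n <- spec@nLigands
  ch <- tryCatch(chol(spec@covariance), error = function(e) {
    eg <- eigen(spec@covariance, symmetric = TRUE)
    t(eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), p) %*% t(eg$vectors))
  })
  set.seed(spec@seed)
  Z <- matrix(rnorm(n * p), n, p)
  X <- Z %*% ch
  if (n > 0) X <- sweep(X, 2, spec@meanVector, "+")
  colnames(X) <- spec@descriptorNames
  DescriptorTable(X, ligandIds = if (n) sprintf("syn%04d", seq_len(n))
                                 else character(0))
}

#' Generate affinities and docking scores for a descriptor table
#'
#' `truePic50 = intercept + X beta`; `observedPic50 = truePic50 +
#' N(0, noiseSd)`; docking scores are the exact inverse affinity conversion
#' of the true pIC50 (at the spec temperature) plus optional Gaussian score
#' noise. Noise streams are seeded from `spec@seed` offset by 1 (pIC50) and
#' 2 (scores) so the table and affinities are independently reproducible.
#'
#' @param table a [DescriptorTable-class] whose columns match the spec.
#' @param spec a valid [SyntheticSpec-class].
#' @return a [SyntheticDataset-class].
#' @export
generateAffinities <- function(table, spec) {
  validObject(spec)
  missing <- setdiff(spec@descriptorNames, colnames(table@data))
  if (length(missing))
    stop("table lacks descriptor column(s): ",
         paste(missing, collapse = ", "))
  X <- table@data[, spec@descriptorNames, drop = FALSE]
  n <- nrow(X)
  true <- drop(X %*% spec@trueCoefficients) + spec@trueIntercept
  set.seed(spec@seed + 1L)
  observed <- if (spec@noiseSd > 0) true + rnorm(n, 0, spec@noiseSd)
              else true
  scores <- pic50ToScore(true, spec@temperatureK)
  if (spec@scoreNoiseSd > 0) {
    set.seed(spec@seed + 2L)
    scores <- scores + rnorm(n, 0, spec@scoreNoiseSd)
  }
  new("SyntheticDataset", descriptorTable = table, truePic50 = true,
      observedPic50 = observed, dockingScores = scores, spec = spec)
}

#' @rdname generateAffinities
#' @param spec a valid [SyntheticSpec-class].
#' @return `generateDataset()`: a [SyntheticDataset-class] built by chaining
#'   [generateDescriptors()] and [generateAffinities()].
#' @export
generateDataset <- function(spec) {
  generateAffinities(generateDescriptors(spec), spec)
}

#' Generate a toy receptor-ligand complex with a known contact set
#'
#' Builds a coordinate model with provable geometry: a 3-atom ligand within
#' 0.5 Angstrom of the origin and one 3-atom residue per receptor position,
#' each residue clustered within 0.3 Angstrom of a center placed on a
#' sphere. Designated contact residues sit at radius `cutoff - 0.5` (their
#' central atom is exactly `cutoff - 0.5` from the ligand atom at the
#' origin, hence within the cutoff); all other residues sit at radius
#' `cutoff + 1.5`, keeping every atom strictly farther than `cutoff + 0.5`
#' from every ligand atom. Residue names cycle through the 20 standard amino
#' acids; directions are random under the seed.
#'
#' @param nReceptorResidues number of receptor residues.
#' @param contactResidueIndices indices (within `1:nReceptorResidues`) that
#'   must contact the ligand.
#' @param cutoff contact cutoff in Angstrom (> 1.5 for feasible geometry).
#' @param seed integer RNG seed.
#' @param complexId identifier for the complex.
#' @return a [ComplexStructure-class].
#' @export
generateComplex <- function(nReceptorResidues, contactResidueIndices = integer(),
                            cutoff = 5.0, seed = 1L, complexId = "synthetic") {
  if (cutoff <= 1.5)
    stop("impossible geometry: cutoff must exceed 1.5 Angstrom so the ",
         "contact and exclusion shells do not overlap")
  if (length(contactResidueIndices) &&
      (any(contactResidueIndices < 1) ||
       any(contactResidueIndices > nReceptorResidues)))
    stop("contact indices must lie within 1..nReceptorResidues")
  aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
  set.seed(seed)
  unitDir <- function() {
    v <- rnorm(3)
    v / sqrt(sum(v^2))
  }
  lig <- data.frame(element = c("C", "F", "F"),
                    x = c(0, 0.4, -0.4), y = c(0, 0.2, 0.1),
                    z = c(0, -0.1, 0.3), resname = "LIG", resno = 1L,
                    chain = "L", ligand = TRUE, stringsAsFactors = FALSE)
  resRows <- lapply(seq_len(nReceptorResidues), function(i) {
    r <- if (i %in% contactResidueIndices) cutoff - 0.5 else cutoff + 1.5
    center <- unitDir() * r
    offsets <- rbind(c(0, 0, 0), c(0.25, 0.1, -0.1), c(-0.1, 0.25, 0.1))
    data.frame(element = c("N", "C", "C"),
               x = center[1] + offsets[, 1], y = center[2] + offsets[, 2],
               z = center[3] + offsets[, 3],
               resname = aa[((i - 1) %% 20) + 1], resno = i, chain = "A",
               ligand = FALSE, stringsAsFactors = FALSE)
  })
  atoms <- rbind(lig, do.call(rbind, c(resRows, list(make.row.names = FALSE))))
  new("ComplexStructure", complexId = complexId, atoms = atoms)
}
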