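#' @include AllClasses.R
NULL

#' The canonical 11-descriptor set
#'
#' The physicochemical descriptors used throughout the package, with their
#' single-letter abbreviations, data-source labels and units. The set is the
#' one that survives variance-inflation-factor elimination on PFAS descriptor
#' data: average mass, density, the hydrogen-bond donor/acceptor counts,
#' freely rotating bonds, LogD at pH 7.4, polar surface area, surface tension,
#' the HOMO/LUMO frontier-orbital energies and the maximum positive Fukui
#' index.
#'
#' @return data.frame with columns `name`, `letter`, `source`, `units`.
#' @examples
#' canonicalDescriptors()$letter
#' @export
canonicalDescriptors <- function() {
  data.frame(
    name = c("AverageMass", "HBondDonors", "Density", "LUMO",
             "FreelyRotatingBonds", "HBondAcceptors", "FukuiMax",
             "PolarSurfaceArea", "HOMO", "LogD", "SurfaceTension"),
    letter = c("a", "c", "d", "e", "f", "g", "h", "i", "j", "k", "s"),
    source = c("semi-empirical QM", "database", "database",
               "semi-empirical QM", "database", "database",
               "Fukui-index workflow", "database", "semi-empirical QM",
               "database", "database"),
    units = c("g/mol", "count", "g/cm^3", "eV", "count", "count",
              "unitless", "A^2", "eV", "log units (pH 7.4)", "dyn/cm"),
    stringsAsFactors = FALSE)
}

#' Descriptors excluded during the original manual curation
#'
#' The 15-to-11 reduction of the descriptor pool was expert judgment
#' (pH 5.5 variants dropped as physiologically irrelevant; redundant bulk
#' properties dropped), not an algorithm, so it is recorded as a fixture
#' list: the descriptors eliminated, in order, by the subsequent VIF pass.
#'
#' @return character vector of excluded descriptor names.
#' @export
curatedExclusions <- function() {
  c("EnthalpyOfVaporization", "LogP", "Polarizability", "BoilingPoint")
}

#' Construct a DescriptorTable
#'
#' @param data numeric matrix or data.frame (rows = ligands, columns =
#'   descriptors). A data.frame may carry the ligand ids in a first
#'   non-numeric column.
#' @param ligandIds optional character vector; defaults to rownames or
#'   `lig1..ligN`.
#' @param meta optional descriptor metadata; defaults to
#'   [canonicalDescriptors()] rows for recognized names, `NA` otherwise.
#' @return a [DescriptorTable-class].
#' @examples
#' m <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, c("A", "B", "C")))
#' DescriptorTable(m)
#' @export
DescriptorTable <- function(data, ligandIds = NULL, meta = NULL) {
  if (is.data.frame(data)) {
    if (ncol(data) && !is.numeric(data[[1]]) && is.null(ligandIds)) {
      ligandIds <- as.character(data[[1]])
      data <- data[, -1, drop = FALSE]
    }
    data <- as.matrix(data)
  }
  storage.mode(data) <- "double"
  if (is.null(ligandIds)) {
    ligandIds <- if (!is.null(rownames(data))) rownames(data)
                 else sprintf("lig%d", seq_len(nrow(data)))
  }
  rownames(data) <- NULL
  if (is.null(meta)) {
    canon <- canonicalDescriptors()
    idx <- match(colnames(data), canon$name)
    meta <- data.frame(name = colnames(data),
                       letter = canon$letter[idx],
                       source = canon$source[idx],
                       units = canon$units[idx],
                       stringsAsFactors = FALSE)
  }
  new("DescriptorTable", ligandIds = as.character(ligandIds), data = data,
      meta = meta)
}

subsetTable <- function(table, rows = NULL, cols = NULL) {
  d <- table@data
  ids <- table@ligandIds
  if (!is.null(rows)) {
    d <- d[rows, , drop = FALSE]
    ids <- ids[rows]
  }
  if (!is.null(cols)) d <- d[, cols, drop = FALSE]
  meta <- table@meta[match(colnames(d), table@meta$name), , drop = FALSE]
  rownames(meta) <- NULL
  new("DescriptorTable", ligandIds = ids, data = d, meta = meta)
}

#' Remove ligands with incomplete descriptor data
#'
#' Any missing cell disqualifies the whole ligand row; no imputation is
#' attempted. Row order of the survivors is preserved and surviving values
#' are untouched.
#'
#' @param table a [DescriptorTable-class].
#' @return the cleaned DescriptorTable. The number of ligands removed and
#'   their ids are attached as metadata, retrievable with [cleaningReport()].
#' @examples
#' m <- matrix(c(1, NA, 3, 4, 5, 6), 3, 2, dimnames = list(NULL, c("A", "B")))
#' cleaningReport(cleanDescriptors(DescriptorTable(m)))
#' @export
cleanDescriptors <- function(table) {
  stopifnot(is(table, "DescriptorTable"))
  keep <- stats::complete.cases(table@data)
  out <- subsetTable(table, rows = keep)
  if (!any(keep) && nrow(table@data) > 0)
    warning("all ligands removed: no complete descriptor rows")
  attr(out@data, "cleaning") <- list(nRemoved = sum(!keep),
                                     removedIds = table@ligandIds[!keep])
  out
}

#' @rdname cleanDescriptors
#' @return `cleaningReport()`: list with `nRemoved` and `removedIds`
#'   (`NULL` for tables that were not produced by `cleanDescriptors()`).
#' @export
cleaningReport <- function(table) attr(table@data, "cleaning")

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from regressing descriptor `j`
#' on all remaining descriptors (with intercept). Exact collinearity is
#' reported as `Inf`.
#'
#' @param table a complete (no missing values) [DescriptorTable-class] with
#'   at least two descriptors and more ligands than descriptors plus one.
#' @return named numeric vector of VIFs, one per descriptor.
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("A", "B", "C")))
#' computeVif(DescriptorTable(m))
#' @export
computeVif <- function(table) {
  stopifnot(is(table, "DescriptorTable"))
  X <- table@data
  p <- ncol(X)
  if (p < 2L) stop("VIF requires at least 2 descriptors")
  if (nrow(X) <= p + 1L) stop("VIF requires more ligands than descriptors + 1")
  if (anyNA(X)) stop("clean the table before computing VIFs")
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop("constant descriptor column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  vif <- vapply(seq_len(p), function(j) {
    fit <- lm.fit(cbind(`(Intercept)` = 1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- colnames(X)
  vif
}

#' Iterative VIF-based descriptor elimination
#'
#' Repeatedly removes the descriptor with the highest VIF (ties broken by
#' column order) until every remaining VIF is below `threshold`. A
#' substitution map redirects a removal: when the max-VIF descriptor is a
#' key of `substitutions`, its mapped partner is removed in its place — the
#' mechanism by which LogP can be sacrificed to keep the physiologically more
#' relevant LogD. With `verifyOnly = TRUE` no removal happens; violations are
#' only reported.
#'
#' @param table a complete [DescriptorTable-class].
#' @param threshold VIF threshold (default 5; must exceed 1).
#' @param substitutions named character vector mapping a descriptor to its
#'   preferred casualty, e.g. `c(LogD = "LogP")`.
#' @param verifyOnly logical; report violations without removing.
#' @return list with `table` (the reduced DescriptorTable), `vif` (final
#'   VIFs), `removalHistory` (data.frame of descriptor and VIF at removal)
#'   and, in verify-only mode, `violations`.
#' @export
iterativeVifElimination <- function(table, threshold = 5,
                                    substitutions = character(),
                                    verifyOnly = FALSE) {
  stopifnot(is(table, "DescriptorTable"), threshold > 1)
  current <- table
  history <- data.frame(descriptor = character(), vif = numeric(),
                        stringsAsFactors = FALSE)
  repeat {
    vif <- computeVif(current)
    if (verifyOnly)
      return(list(table = current, vif = vif,
                  removalHistory = history,
                  violations = vif[vif >= threshold]))
    if (all(vif < threshold)) break
    victim <- names(vif)[which.max(vif)]
    if (victim %in% names(substitutions)) {
      partner <- substitutions[[victim]]
      if (partner %in% names(vif)) victim <- partner
    }
    if (length(vif) - 1L < 2L)
      stop("elimination would leave fewer than 2 descriptors")
    history <- rbind(history,
                     data.frame(descriptor = victim, vif = vif[[victim]],
                                stringsAsFactors = FALSE))
    current <- subsetTable(current,
                           cols = setdiff(colnames(current@data), victim))
  }
  list(table = current, vif = vif, removalHistory = history)
}

#' Standardize descriptor columns
#'
#' Transforms every column to mean 0 and sample standard deviation 1 and
#' returns the centering/scaling constants needed to back-transform fitted
#' coefficients onto the raw descriptor scale.
#'
#' @param table a complete [DescriptorTable-class] without constant columns.
#' @return list with `table` (standardized DescriptorTable), `center`
#'   (per-column means) and `scale` (per-column sample SDs).
#' @export
standardizeDescriptors <- function(table) {
  stopifnot(is(table, "DescriptorTable"))
  X <- table@data
  if (anyNA(X)) stop("clean the table before standardizing")
  mu <- colMeans(X)
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop("constant descriptor column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  Z <- sweep(sweep(X, 2, mu), 2, sds, "/")
  out <- table
  out@data <- Z
  list(table = out, center = mu, scale = sds)
}
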