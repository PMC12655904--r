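#' @include AllClasses.R
NULL

#' Ligand identifiers of an object
#' @param x a DescriptorTable, SyntheticDataset or ADResult.
#' @return character vector of ligand ids.
#' @export
setGeneric("ligandIds", function(x) standardGeneric("ligandIds"))

#' Descriptor names of an object
#' @param x a DescriptorTable or QsprModel.
#' @return character vector of descriptor names.
#' @export
setGeneric("descriptorNames", function(x) standardGeneric("descriptorNames"))

#' Per-descriptor metadata (abbreviation letter, source, units)
#' @param x a DescriptorTable.
#' @return data.frame with columns name, letter, source, units.
#' @export
setGeneric("descriptorMeta", function(x) standardGeneric("descriptorMeta"))

#' Domain classification of an applicability-domain result
#' @param x an ADResult.
#' @return factor of per-ligand classes.
#' @export
setGeneric("classification", function(x) standardGeneric("classification"))

#' Contact counts per residue type
#' @param x a ContactProfile.
#' @return named integer vector.
#' @export
setGeneric("contactCounts", function(x) standardGeneric("contactCounts"))

#' Contact percentages per residue type
#' @param x a ContactProfile.
#' @return named numeric vector summing to 100 (length 0 when no contacts).
#' @export
setGeneric("contactPercentages", function(x) standardGeneric("contactPercentages"))

setMethod("ligandIds", "DescriptorTable", function(x) x@ligandIds)
setMethod("ligandIds", "SyntheticDataset",
          function(x) x@descriptorTable@ligandIds)
setMethod("ligandIds", "ADResult", function(x) x@ligandIds)

setMethod("descriptorNames", "DescriptorTable", function(x) colnames(x@data))
setMethod("descriptorNames", "QsprModel", function(x) x@descriptorNames)

setMethod("descriptorMeta", "DescriptorTable", function(x) x@meta)
setMethod("classification", "ADResult", function(x) x@classification)
setMethod("contactCounts", "ContactProfile", function(x) x@counts)
setMethod("contactPercentages", "ContactProfile", function(x) x@percentages)

#' @describeIn DescriptorTable-class the descriptor matrix (rows = ligands).
#' @param x a DescriptorTable.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "DescriptorTable", function(x, ...) {
  m <- x@data
  attr(m, "cleaning") <- NULL
  rownames(m) <- x@ligandIds
  m
})

#' @describeIn DescriptorTable-class dimensions (ligands, descriptors).
#' @export
setMethod("dim", "DescriptorTable", function(x) dim(x@data))

#' Raw model coefficients
#' @param object a QsprModel.
#' @param ... ignored.
#' @return named numeric vector of raw coefficients (no intercept).
#' @export
setMethod("coef", "QsprModel", function(object, ...) object@coefficients)

setMethod("show", "DescriptorTable", function(object) {
  cat(sprintf("DescriptorTable: %d ligand(s) x %d descriptor(s)\n",
              nrow(object@data), ncol(object@data)))
  if (ncol(object@data))
    cat("  descriptors:", paste(colnames(object@data), collapse = ", "), "\n")
  nmiss <- sum(!stats::complete.cases(object@data))
  if (nmiss) cat(sprintf("  %d ligand(s) with missing values\n", nmiss))
})

setMethod("show", "QsprModel", function(object) {
  cat(sprintf("QsprModel: %d descriptor(s), intercept %.4g\n",
              length(object@descriptorNames), object@intercept))
  if (!is.null(object@meta$label)) cat("  label:", object@meta$label, "\n")
  if (length(object@trainingIds))
    cat(sprintf("  fitted on %d ligand(s)", length(object@trainingIds)),
        if (length(object@fitMetrics))
          sprintf("(R2 = %.3f, RMSE = %.3f)",
                  object@fitMetrics$r2, object@fitMetrics$rmse), "\n")
})

setMethod("show", "ADResult", function(object) {
  cat(sprintf("ADResult: %d ligand(s), h* = %.4f, |residual| band = %.1f\n",
              length(object@ligandIds), object@hStar, object@residualLimit))
  print(table(object@classification))
})

setMethod("show", "ALEProfile", function(object) {
  cat(sprintf(
    "ALEProfile for %s: %d grid edges, delta pIC50 range [%.4g, %.4g]\n",
    object@descriptor, length(object@edges),
    object@deltaRange[1], object@deltaRange[2]))
})

setMethod("show", "ComplexStructure", function(object) {
  cat(sprintf("ComplexStructure '%s': %d atoms (%d ligand, %d receptor)\n",
              object@complexId, nrow(object@atoms),
              sum(object@atoms$ligand), sum(!object@atoms$ligand)))
})

setMethod("show", "ContactProfile", function(object) {
  cat(sprintf("ContactProfile over %d complex(es), %d contact instance(s)\n",
              object@nComplexes, sum(object@counts)))
  if (length(object@counts)) {
    df <- data.frame(residue = names(object@counts),
                     count = as.integer(object@counts),
                     percent = round(object@percentages, 2))
    print(df[order(-df$count), ], row.names = FALSE)
  }
})

setMethod("show", "ValidationSummary", function(object) {
  cat(sprintf(
    "ValidationSummary: n = %d, mean difference = %.3f, SD = %.3f, SE = %.2f\n",
    length(object@differences), object@meanDifference, object@sd,
    object@standardError))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: %d ligand(s), %d descriptor(s), noiseSd = %.3g, seed = %d\n",
    object@nLigands, length(object@descriptorNames), object@noiseSd,
    object@seed))
})

setMethod("show", "SyntheticDataset", function(object) {
  cat(sprintf("SyntheticDataset: %d ligand(s), noiseSd = %.3g\n",
              length(object@truePic50), object@spec@noiseSd))
})
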