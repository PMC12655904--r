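#' @include AllClasses.R descriptors.R qspr-mlr.R
NULL

#' Read a descriptor table from delimited text
#'
#' Comma-separated, UTF-8, header row, ligand id in the first column,
#' `.` decimal separator. Typographic minus signs are normalized to ASCII
#' hyphens before parsing.
#'
#' @param path input file path.
#' @return a [DescriptorTable-class].
#' @export
readDescriptorTable <- function(path) {
  txt <- readLines(path, encoding = "UTF-8")
  txt <- gsub("−", "-", txt)
  df <- utils::read.csv(text = txt, stringsAsFactors = FALSE,
                        check.names = FALSE)
  DescriptorTable(df)
}

#' Write a descriptor table as delimited text
#'
#' @param table a [DescriptorTable-class].
#' @param path output file path.
#' @param idColumn name for the leading ligand-id column.
#' @return `path`, invisibly.
#' @export
writeDescriptorTable <- function(table, path, idColumn = "ligand_id") {
  df <- data.frame(table@ligandIds, table@data, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- idColumn
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Augment an affinity table with converted units
#'
#' Fills in whichever of `ic50_nM` / `pic50` is derivable: from a docking
#' `score` column via the thermodynamic conversion, or between the two
#' affinity units.
#'
#' @param df data.frame with a `ligand_id` column and at least one of
#'   `score`, `ic50_nM`, `pic50`.
#' @param temperatureK temperature for the score conversion.
#' @return the data.frame with `ic50_nM` and `pic50` columns completed.
#' @export
convertAffinityTable <- function(df, temperatureK = 300) {
  if (!"ligand_id" %in% names(df)) stop("a ligand_id column is required")
  if (is.null(df$ic50_nM)) {
    if (!is.null(df$score)) df$ic50_nM <- scoreToIc50(df$score, temperatureK)
    else if (!is.null(df$pic50)) df$ic50_nM <- pic50ToIc50(df$pic50)
    else stop("need one of score, ic50_nM or pic50")
  }
  df$pic50 <- ic50ToPic50(df$ic50_nM)
  df
}

#' Serialize a QsprModel to JSON
#'
#' @param model a [QsprModel-class].
#' @param path optional output file; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to file).
#' @export
modelToJson <- function(model, path = NULL) {
  obj <- list(descriptorNames = model@descriptorNames,
              coefficients = as.list(model@coefficients),
              intercept = model@intercept,
              descriptorSds = as.list(model@descriptorSds),
              normalizedCoefficients = as.list(model@normalizedCoefficients),
              trainingIds = model@trainingIds, sigma = model@sigma,
              fitMetrics = model@fitMetrics, meta = model@meta)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Deserialize a QsprModel from JSON
#'
#' Round-trips the coefficient-level content of [modelToJson()]; the
#' training design internals (leverages, inverse cross-product) are not
#' serialized, so applicability-domain diagnostics require the fitted
#' object.
#'
#' @param json JSON string or path to a JSON file.
#' @return a [QsprModel-class].
#' @export
modelFromJson <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  model <- QsprModel(
    coefficients = unlist(obj$coefficients),
    intercept = obj$intercept,
    descriptorSds = if (length(obj$descriptorSds))
      unlist(obj$descriptorSds) else numeric(),
    normalizedCoefficients = if (length(obj$normalizedCoefficients))
      unlist(obj$normalizedCoefficients) else numeric(),
    meta = as.list(obj$meta))
  model@trainingIds <- as.character(obj$trainingIds)
  if (!is.null(obj$sigma)) model@sigma <- as.numeric(obj$sigma)
  if (length(obj$fitMetrics)) model@fitMetrics <- as.list(obj$fitMetrics)
  model
}

#' Load a packaged fixture
#'
#' Versioned copies of the printed reference data: the two docking-
#' validation ligand tables (`"table1_era_ligands"`, `"table2_erb_ligands"`;
#' columns ligand, CID, experimental IC50 in nM, docking score in kcal/mol,
#' predicted IC50 in nM), the descriptor abbreviation map
#' (`"table5_abbreviations"`), and the four reference equations
#' (`"eq3_tb_era"`, `"eq4_tb_erb"`, `"eq5_ce_era"`, `"eq6_ce_erb"`).
#'
#' @param name fixture name.
#' @return a data.frame or [QsprModel-class], per fixture.
#' @examples
#' loadFixture("table5_abbreviations")
#' @export
loadFixture <- function(name) {
  models <- c(eq3_tb_era = "TB-ERalpha", eq4_tb_erb = "TB-ERbeta",
              eq5_ce_era = "CE-ERalpha", eq6_ce_erb = "CE-ERbeta")
  if (name %in% names(models)) return(publishedModel(models[[name]]))
  files <- c(table1_era_ligands = "table1_era_ligands.csv",
             table2_erb_ligands = "table2_erb_ligands.csv",
             table5_abbreviations = "table5_abbreviations.csv")
  if (!name %in% names(files))
    stop("unknown fixture: ", name, " (available: ",
         paste(c(names(files), names(models)), collapse = ", "), ")")
  path <- system.file("extdata", files[[name]], package = "pfasER",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
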