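#' @include AllClasses.R io.R synthetic-data.R model-validation.R
#' @include applicability-domain.R ale.R
NULL

#' Build a pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with its default:
#' temperature of the score conversion (300 K), VIF threshold (5),
#' applicability-domain residual band (3), ALE grid size (20), docking-score
#' cutoff (-7 kcal/mol), refinement fractions (10% then 20%), and per-stage
#' seeds. The configuration round-trips losslessly through JSON and is
#' hashed into every manifest.
#'
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "clean", "vif", "fit", "ad", "ale", "refine",
#'   "affinity_validation")`.
#' @param nLigands synthetic dataset size.
#' @param noiseSd synthetic observation noise (pIC50 units).
#' @param seed master integer seed; stage seeds derive from it.
#' @param temperatureK score-conversion temperature.
#' @param vifThreshold VIF elimination threshold.
#' @param residualLimit applicability-domain residual band half-width.
#' @param aleGridSize ALE grid intervals.
#' @param scoreCutoff docking-score cutoff in kcal/mol.
#' @param refineFractions outlier-removal fractions.
#' @param trainFraction training fraction of QSAR splits.
#' @return a named list with class `pipelineConfig`.
#' @export
pipelineConfig <- function(stages = c("simulate", "clean", "vif", "fit",
                                      "ad", "ale"),
                           nLigands = 200, noiseSd = 0.35, seed = 1L,
                           temperatureK = 300, vifThreshold = 5,
                           residualLimit = 3, aleGridSize = 20,
                           scoreCutoff = -7, refineFractions = c(0.1, 0.2),
                           trainFraction = 0.8) {
  cfg <- list(stages = stages, nLigands = nLigands, noiseSd = noiseSd,
              seed = as.integer(seed), temperatureK = temperatureK,
              vifThreshold = vifThreshold, residualLimit = residualLimit,
              aleGridSize = aleGridSize, scoreCutoff = scoreCutoff,
              refineFractions = refineFractions,
              trainFraction = trainFraction)
  class(cfg) <- c("pipelineConfig", "list")
  cfg
}

#' Run the end-to-end pipeline
#'
#' Executes the enabled stages in order — synthetic data generation,
#' missing-data cleaning, VIF descriptor selection, OLS model fitting,
#' applicability-domain classification, ALE profiling, docking-score cutoff
#' plus iterative outlier refinement, and the packaged docking-validation
#' statistics — and returns each stage's result together with a manifest
#' recording the configuration, its hash, the seeds used and per-stage
#' ligand counts. A stage failure halts with an error naming the stage;
#' results of completed stages are retained in the error condition's
#' `partial` field.
#'
#' @param config a [pipelineConfig()] list.
#' @return list with one element per executed stage plus `manifest`.
#' @examples
#' res <- runPipeline(pipelineConfig(stages = "affinity_validation"))
#' res$affinity_validation$standardErrors
#' @export
runPipeline <- function(config = pipelineConfig()) {
  results <- list()
  counts <- list()
  runStage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      cond <- simpleError(sprintf("pipeline stage '%s' failed: %s", name,
                                  conditionMessage(e)))
      cond$partial <- results
      stop(cond)
    })
  }
  dataset <- NULL
  table <- NULL
  y <- NULL
  model <- NULL

  if ("affinity_validation" %in% config$stages) {
    results$affinity_validation <- runStage("affinity_validation", function() {
      t1 <- loadFixture("table1_era_ligands")
      t2 <- loadFixture("table2_erb_ligands")
      v1 <- validateAgainstExperiment(t1$ic50_nM, t1$predicted_ic50_nM,
                                      t1$ligand)
      v2 <- validateAgainstExperiment(t2$ic50_nM, t2$predicted_ic50_nM,
                                      t2$ligand)
      list(ERalpha = v1, ERbeta = v2,
           standardErrors = c(ERalpha = v1@standardError,
                              ERbeta = v2@standardError))
    })
  }
  if ("simulate" %in% config$stages) {
    results$simulate <- runStage("simulate", function() {
      spec <- pfasLikeSpec(config$nLigands, noiseSd = config$noiseSd,
                           seed = config$seed,
                           temperatureK = config$temperatureK)
      generateDataset(spec)
    })
    dataset <- results$simulate
    table <- dataset@descriptorTable
    y <- setNames(dataset@observedPic50, ligandIds(dataset))
    counts$simulated <- length(y)
  }
  if ("clean" %in% config$stages && !is.null(table)) {
    results$clean <- runStage("clean", function() cleanDescriptors(table))
    table <- results$clean
    y <- y[ligandIds(table)]
    counts$afterCleaning <- nrow(table@data)
  }
  if ("vif" %in% config$stages && !is.null(table)) {
    results$vif <- runStage("vif", function()
      iterativeVifElimination(table, threshold = config$vifThreshold))
    table <- results$vif$table
    counts$descriptorsAfterVif <- ncol(table@data)
  }
  if ("fit" %in% config$stages && !is.null(table)) {
    results$fit <- runStage("fit", function() {
      sp <- splitLigands(ligandIds(table), "fraction",
                         config$trainFraction, config$seed)
      idx <- match(sp$trainIds, ligandIds(table))
      fit <- fitQspr(subsetTable(table, rows = idx), y[sp$trainIds],
                     meta = list(splitSeed = sp$seed))
      testIdx <- match(sp$testIds, ligandIds(table))
      list(model = fit, split = sp,
           testMetrics = evaluateFit(fit, subsetTable(table, rows = testIdx),
                                     y[sp$testIds]),
           q2 = crossValidateQ2(subsetTable(table, rows = idx),
                                y[sp$trainIds]))
    })
    model <- results$fit$model
    counts$trained <- length(model@trainingIds)
  }
  if ("ad" %in% config$stages && !is.null(model)) {
    results$ad <- runStage("ad", function() {
      idx <- match(model@trainingIds, ligandIds(table))
      williamsClassify(model, subsetTable(table, rows = idx),
                       y[model@trainingIds],
                       residualLimit = config$residualLimit)
    })
  }
  if ("ale" %in% config$stages && !is.null(model)) {
    results$ale <- runStage("ale", function()
      aleSummary(model, table, gridSize = config$aleGridSize))
  }
  if ("refine" %in% config$stages && !is.null(dataset)) {
    results$refine <- runStage("refine", function() {
      keep <- scoreCutoffFilter(
        setNames(dataset@dockingScores, ligandIds(table)),
        config$scoreCutoff)
      counts$afterCutoff <<- length(keep)
      idx <- match(keep, ligandIds(table))
      iterativeOutlierRefinement(subsetTable(table, rows = idx), y[keep],
                                 fractions = config$refineFractions,
                                 splitSeed = config$seed,
                                 trainFraction = config$trainFraction)
    })
  }
  cfgPlain <- unclass(config)
  results$manifest <- list(
    config = cfgPlain,
    configHash = rlang::hash(cfgPlain),
    seed = config$seed,
    stages = intersect(config$stages, names(results)),
    counts = counts,
    packageVersion = as.character(utils::packageVersion("pfasER")))
  results
}
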