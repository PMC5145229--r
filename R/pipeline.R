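# End-to-end runs: generate (or load) a dataset, sweep every algorithm over
# every sensor combination, and write the results table, optional ROC point
# dumps and a run manifest capturing the full effective configuration.
# Outputs are a pure function of (dataset, config): two runs with the same
# config and seed produce byte-identical results files.

runDefaults <- function() {
  list(
    algorithms = algorithmIds(),
    nGrid = 200,
    spBounds = c(0.90, 0.95),
    excludedSubtypes = character(0),
    rho = 1,
    policy = "and",
    writeRoc = FALSE,
    seed = 1,
    generator = list())  # overrides forwarded to generatorConfig()
}

# precedence: explicit arguments > YAML config file > defaults
mergeConfig <- function(defaults, fileCfg, args) {
  cfg <- defaults
  for (src in list(fileCfg, args))
    for (nm in names(src)) if (!is.null(src[[nm]])) cfg[[nm]] <- src[[nm]]
  cfg
}

#' Run the full evaluation pipeline
#'
#' Generates a synthetic dataset (or uses/loads the one supplied), builds
#' the combination-by-algorithm results table, and writes to `outDir`:
#' `results.csv` (one row per sensor combination), optional per-(algorithm,
#' combination) ROC point files under `roc/`, and `manifest.json` recording
#' the effective configuration, seed, package and R versions and trial
#' counts. Settings follow the precedence explicit arguments > YAML config
#' file > defaults.
#'
#' @param outDir output directory (created; must be writable).
#' @param dataset a [FallDataset-class], a directory of trace files (see
#'   [readDataset()]), or `NULL` to generate synthetically.
#' @param configFile optional YAML file with any of: `algorithms`, `nGrid`,
#'   `spBounds`, `excludedSubtypes`, `rho`, `policy`, `writeRoc`, `seed`,
#'   and a `generator` block of [generatorConfig()] arguments.
#' @param algorithms,nGrid,spBounds,excludedSubtypes,rho,writeRoc,seed
#'   explicit overrides of the corresponding settings.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list: `results` (data.frame), `outDir`, `manifest`.
#' @export
runEvaluation <- function(outDir, dataset = NULL, configFile = NULL,
                          algorithms = NULL, nGrid = NULL, spBounds = NULL,
                          excludedSubtypes = NULL, rho = NULL,
                          writeRoc = NULL, seed = NULL, quiet = FALSE) {
  fileCfg <- if (!is.null(configFile)) yaml::read_yaml(configFile) else list()
  args <- list(algorithms = algorithms, nGrid = nGrid, spBounds = spBounds,
               excludedSubtypes = excludedSubtypes, rho = rho,
               writeRoc = writeRoc, seed = seed)
  cfg <- mergeConfig(runDefaults(), fileCfg, args)
  if (!all(cfg$spBounds >= 0 & cfg$spBounds <= 1))
    stop("spBounds must lie in [0, 1]")

  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logMsg <- function(...) if (!quiet) message(sprintf(...))

  datasetSource <- "supplied"
  if (is.null(dataset)) {
    genArgs <- cfg$generator
    genArgs$seed <- cfg$seed
    gen <- do.call(generatorConfig, genArgs)
    logMsg("generating synthetic dataset (seed %d)", cfg$seed)
    dataset <- genDataset(gen)
    datasetSource <- "generated"
  } else if (is.character(dataset)) {
    logMsg("loading dataset from %s", dataset)
    dataset <- readDataset(dataset)
    datasetSource <- "loaded"
  }
  labels <- datasetLabels(dataset)
  checkTwoClasses(labels)

  control <- detectorControl(rho = cfg$rho)
  logMsg("evaluating %d trials (%d FALL, %d ADL), algorithms: %s",
         nTrials(dataset), sum(labels == "FALL"), sum(labels == "ADL"),
         paste(cfg$algorithms, collapse = ", "))
  results <- buildResultsTable(dataset, algorithms = cfg$algorithms,
                               excludedSubtypes = cfg$excludedSubtypes,
                               spBounds = cfg$spBounds, n = cfg$nGrid,
                               control = control)
  resPath <- file.path(outDir, "results.csv")
  utils::write.csv(results, resPath, row.names = FALSE)

  if (isTRUE(cfg$writeRoc)) {
    rocDir <- file.path(outDir, "roc")
    dir.create(rocDir, showWarnings = FALSE)
    evalData <- filterActivities(dataset, cfg$excludedSubtypes)
    for (alg in cfg$algorithms)
      for (combo in enumerateCombinations(datasetPositions(evalData))) {
        sw <- sweepThresholds(evalData, alg, combo, n = cfg$nGrid,
                              control = control)
        utils::write.csv(rocPoints(sw),
                         file.path(rocDir, sprintf("roc_%s_%s.csv", alg,
                                                   paste(combo, collapse = "-"))),
                         row.names = FALSE)
      }
  }

  manifest <- list(
    package = as.character(utils::packageVersion("fallfusion")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    dataset_source = datasetSource,
    n_trials = nTrials(dataset),
    n_fall = sum(labels == "FALL"), n_adl = sum(labels == "ADL"),
    n_rows = nrow(results),
    config = cfg[setdiff(names(cfg), "generator")],
    generator = cfg$generator)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  logMsg("wrote %s (%d rows)", resPath, nrow(results))
  invisible(list(results = results, outDir = outDir, manifest = manifest))
}

#' Compare two evaluation runs cell by cell
#'
#' Aligns two results tables (from [runEvaluation()] output directories or
#' as data.frames), checks that they cover the same combinations and metric
#' columns, and returns per-cell deltas (B minus A) plus a per-algorithm
#' sign summary. Used for re-analysis comparisons such as including versus
#' excluding a confusable ADL.
#'
#' @param runA,runB results data.frames or run directories containing
#'   `results.csv`.
#' @return A list: `deltas` (combination column + metric deltas) and
#'   `signSummary` (per algorithm: negative/zero/positive cell counts).
#' @export
compareRuns <- function(runA, runB) {
  loadRun <- function(x) {
    if (is.character(x)) x <- utils::read.csv(file.path(x, "results.csv"))
    x
  }
  a <- loadRun(runA); b <- loadRun(runB)
  if (!identical(a$combination, b$combination))
    stop("runs cover different sensor combinations")
  metricCols <- setdiff(names(a), c(sensorPositions(), "combination"))
  if (!identical(sort(metricCols),
                 sort(setdiff(names(b), c(sensorPositions(), "combination")))))
    stop("runs have different algorithm/metric columns")
  deltas <- b[metricCols] - a[metricCols]
  deltas <- cbind(combination = a$combination, deltas)
  algs <- unique(sub("_.*$", "", metricCols))
  signSummary <- do.call(rbind, lapply(algs, function(alg) {
    d <- unlist(deltas[grep(paste0("^", alg, "_"), names(deltas))])
    data.frame(algorithm = alg, negative = sum(d < 0), zero = sum(d == 0),
               positive = sum(d > 0))
  }))
  list(deltas = deltas, signSummary = signSummary)
}
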