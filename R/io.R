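#' Save / load an ECG dataset as plain text
#'
#' A dataset directory holds `metadata.csv` (record id, labels, design
#' ids, sampling rate, fiducials, weight), `provenance.json` (provenance
#' plus the generator-config echo) and one 12-column signal CSV per
#' record under `signals/`, columns in fixed lead order. Numbers are
#' written with 17 significant digits so a save/load round trip is
#' bit-exact.
#'
#' @param dataset an [ECGDataset-class].
#' @param path dataset directory (created for save; must exist for
#'   load).
#' @return `saveDataset()` the path, invisibly; `loadDataset()` the
#'   reconstructed [ECGDataset-class].
#' @export
saveDataset <- function(dataset, path) {
  stopifnot(is(dataset, "ECGDataset"))
  dir.create(file.path(path, "signals"), recursive = TRUE,
             showWarnings = FALSE)
  recs <- dataset@records
  meta <- data.frame(
    record_id = recordIds(dataset),
    anatomy_id = vapply(recs, function(r) r@anatomyId, integer(1L)),
    sublocation = sublocationLabels(dataset),
    chamber = chamberLabels(dataset),
    electrode_config_id = vapply(recs, function(r) r@electrodeConfigId,
                                 integer(1L)),
    fs = vapply(recs, function(r) r@fs, numeric(1L)),
    onset = vapply(recs, function(r) r@qrsOnset, integer(1L)),
    offset = vapply(recs, function(r) r@qrsOffset, integer(1L)),
    r_peak = vapply(recs, function(r) r@rPeak, integer(1L)),
    weight = sampleWeights(dataset),
    stringsAsFactors = FALSE)
  meta$weight <- sprintf("%.17g", meta$weight)
  utils::write.csv(meta, file.path(path, "metadata.csv"),
                   row.names = FALSE, quote = TRUE)
  jsonlite::write_json(
    list(provenance = dataset@provenance,
         metadata = dataset@metadata[setdiff(names(dataset@metadata),
                                             "parents")]),
    file.path(path, "provenance.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  for (r in recs) {
    con <- file.path(path, "signals", paste0(r@recordId, ".csv"))
    lines <- c(paste(leadNames(), collapse = ","),
               apply(r@signal, 2L, function(col)
                 paste(sprintf("%.17g", col), collapse = ",")))
    writeLines(lines, con)
  }
  invisible(path)
}

#' @rdname saveDataset
#' @export
loadDataset <- function(path) {
  metaFile <- file.path(path, "metadata.csv")
  if (!file.exists(metaFile))
    stop(sprintf("no dataset at '%s': metadata.csv missing", path))
  meta <- utils::read.csv(metaFile, stringsAsFactors = FALSE)
  need <- c("record_id", "anatomy_id", "sublocation", "chamber",
            "electrode_config_id", "fs", "onset", "offset", "r_peak",
            "weight")
  if (!all(need %in% names(meta)))
    stop("malformed metadata.csv: missing columns")
  provFile <- file.path(path, "provenance.json")
  prov <- if (file.exists(provFile)) jsonlite::read_json(provFile)
          else list(provenance = "user", metadata = list())
  recs <- lapply(seq_len(nrow(meta)), function(i) {
    sigFile <- file.path(path, "signals", paste0(meta$record_id[i], ".csv"))
    if (!file.exists(sigFile))
      stop(sprintf("signal file missing for record '%s'", meta$record_id[i]))
    sig <- as.matrix(utils::read.csv(sigFile, check.names = FALSE))
    if (ncol(sig) != 12L)
      stop(sprintf("record '%s' has %d leads; expected 12",
                   meta$record_id[i], ncol(sig)))
    sig <- t(sig)
    rownames(sig) <- leadNames()
    colnames(sig) <- NULL
    methods::new("ECGRecord", signal = sig, fs = as.numeric(meta$fs[i]),
                 chamber = meta$chamber[i], sublocation = meta$sublocation[i],
                 anatomyId = as.integer(meta$anatomy_id[i]),
                 electrodeConfigId = as.integer(meta$electrode_config_id[i]),
                 qrsOnset = as.integer(meta$onset[i]),
                 qrsOffset = as.integer(meta$offset[i]),
                 rPeak = as.integer(meta$r_peak[i]),
                 recordId = meta$record_id[i],
                 weight = as.numeric(meta$weight[i]))
  })
  methods::new("ECGDataset", records = recs,
               provenance = prov$provenance,
               metadata = lapply(prov$metadata, identity))
}

#' Pipeline configuration
#'
#' Validated configuration for [runPipeline()]. Unknown section or key
#' names are rejected. The global `seed` is expanded into per-stage
#' child seeds by the package's deterministic hashing rule, so a run is
#' reproducible from the echoed config alone.
#'
#' @param generator a [generatorConfig()].
#' @param augmentation a [mixupConfig()], or `NULL` to skip mixup.
#' @param clinical `NULL`, or a list with keys among `n`,
#'   `lvotFraction`, `noiseSd`, `wanderAmplitude` describing a
#'   clinical-like test set to generate.
#' @param scenario `NULL`, or a list with keys among `scenario`,
#'   `representation`, `folds`, `C`, `gamma`, `nTop` forwarded to
#'   [runScenario()].
#' @param nBins bins for the raw representation.
#' @param seed global integer seed.
#' @return validated list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(generator = generatorConfig(),
                           augmentation = mixupConfig(),
                           clinical = NULL, scenario = NULL,
                           nBins = 10L, seed = 1L) {
  stopifnot(inherits(generator, "GeneratorConfig"))
  if (!is.null(augmentation)) stopifnot(inherits(augmentation, "MixupConfig"))
  if (!is.null(clinical)) {
    allowed <- c("n", "lvotFraction", "noiseSd", "wanderAmplitude")
    bad <- setdiff(names(clinical), allowed)
    if (length(bad)) stop(sprintf("unknown clinical config key '%s'", bad[1L]))
  }
  if (!is.null(scenario)) {
    allowed <- c("scenario", "representation", "folds", "C", "gamma", "nTop")
    bad <- setdiff(names(scenario), allowed)
    if (length(bad)) stop(sprintf("unknown scenario config key '%s'", bad[1L]))
  }
  structure(list(generator = generator, augmentation = augmentation,
                 clinical = clinical, scenario = scenario,
                 nBins = as.integer(nBins), seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Run the end-to-end pipeline
#'
#' Executes generate -> (clinical-like generation) -> (mixup) ->
#' (represent + train/evaluate) and writes the datasets' counts, stage
#' seeds and any scenario results to `results.json` under `outDir`. A
#' stage failure aborts with a stage-tagged error. Two runs with the
#' same config produce byte-identical results files.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created if needed).
#' @param saveDatasets logical; also serialize generated datasets under
#'   `outDir`.
#' @return the results list, invisibly.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = tempfile("run"),
                        saveDatasets = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  results <- list(config = list(seed = config$seed, nBins = config$nBins,
                                generator = unclass(config$generator)))

  gen <- config$generator
  gen$seed <- .childSeed(config$seed, "generate")
  simulated <- stage("generate", generateDatabase(gen))
  results$counts <- list(simulated = nRecords(simulated))
  message(sprintf("[generate] %d simulated-style records (seed %d)",
                  nRecords(simulated), gen$seed))

  clinical <- NULL
  if (!is.null(config$clinical)) {
    cc <- config$clinical
    genC <- config$generator
    genC$seed <- .childSeed(config$seed, "clinical")
    if (!is.null(cc$noiseSd)) genC$noiseSd <- cc$noiseSd
    clinical <- stage("clinical", generateClinicalLike(
      n = if (is.null(cc$n)) 334L else cc$n,
      lvotFraction = if (is.null(cc$lvotFraction)) 77 / 334
                     else cc$lvotFraction,
      config = genC,
      wanderAmplitude = if (is.null(cc$wanderAmplitude)) 0.05
                        else cc$wanderAmplitude))
    results$counts$clinical <- nRecords(clinical)
    message(sprintf("[clinical] %d clinical-like records", nRecords(clinical)))
  }

  augmented <- NULL
  if (!is.null(config$augmentation)) {
    aug <- config$augmentation
    aug$seed <- .childSeed(config$seed, "augment")
    augmented <- stage("augment", augmentDataset(simulated, aug))
    results$counts$augmented <- nRecords(augmented)
    message(sprintf("[augment] %d augmented records (ratio %d)",
                    nRecords(augmented), aug$ratio))
  }

  if (saveDatasets) {
    stage("save", {
      saveDataset(simulated, file.path(outDir, "simulated"))
      if (!is.null(clinical))
        saveDataset(clinical, file.path(outDir, "clinical"))
      if (!is.null(augmented))
        saveDataset(augmented, file.path(outDir, "augmented"))
    })
  }

  if (!is.null(config$scenario)) {
    sc <- config$scenario
    if (!is.null(sc$scenario) && sc$scenario != "sc1")
      stop("runPipeline orchestrates the simulated-training scenario (sc1); ",
           "call runScenario() directly for sc2/sc3 compositions")
    res <- stage("scenario", runScenario(
      scenario = "sc1",
      representation = if (is.null(sc$representation)) "raw10"
                       else sc$representation,
      simulated = simulated, augmented = augmented,
      clinicalTrain = NULL,
      tests = if (is.null(clinical)) stop("scenario needs a clinical section")
              else list(clinical = clinical),
      seed = .childSeed(config$seed, "scenario"),
      folds = if (is.null(sc$folds)) 5L else sc$folds,
      C = if (is.null(sc$C)) 1 else sc$C,
      gamma = sc$gamma,
      nTop = if (is.null(sc$nTop)) 10L else sc$nTop,
      nBins = config$nBins))
    results$scenario <- list(
      scenario = res@scenario, representation = res@representation,
      cvAccuracy = res@cvAccuracy,
      foldAccuracies = res@foldAccuracies,
      tests = lapply(res@testResults, function(t)
        list(balancedAccuracy = t$balancedAccuracy, n = t$n)))
    message(sprintf("[scenario] %s CV accuracy %.3f", res@scenario,
                    res@cvAccuracy))
  }

  results$stageSeeds <- list(
    generate = .childSeed(config$seed, "generate"),
    clinical = .childSeed(config$seed, "clinical"),
    augment = .childSeed(config$seed, "augment"),
    scenario = .childSeed(config$seed, "scenario"))
  jsonlite::write_json(results, file.path(outDir, "results.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  invisible(results)
}
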