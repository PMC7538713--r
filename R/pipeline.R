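#' @include AllClasses.R synthetic.R edf.R preprocess.R features.R stats.R classify.R
NULL

#' Default pipeline configuration
#'
#' A nested list mirroring the module options: input source (`simulate`
#' with a cohort specification, or an EDF directory), filter band, epoch
#' duration, Welch settings, mixing coefficients, statistics options,
#' classifier selection and cross-validation scheme. All keys can be
#' overridden in a YAML file read with [readPipelineConfig()].
#'
#' @param seed pipeline seed; every stochastic stage derives its own seed
#'   from it.
#' @return named list.
#' @export
defaultPipelineConfig <- function(seed = 1L) {
  list(
    input = list(type = "simulate", dir = NULL),
    simulate = list(n_mdd = 16L, n_hc = 16L, duration_s = 180,
                    sample_rate_hz = 250,
                    band_amp = c(theta = 4, alpha = 5, beta = 3),
                    asym_delta = c(theta = 0, alpha = 0.5, beta = 0),
                    asym_delta_hc = c(theta = 0, alpha = 0, beta = 0),
                    coupling_rho = c(theta = 0.5, alpha = 0.5, beta = 0.5),
                    coupling_rho_hc = c(theta = 0.2, alpha = 0.2,
                                        beta = 0.2),
                    noise_sigma = 1, artifact_rate = 0),
    reference = list(mastoids = c("M1", "M2")),
    filter = list(low_hz = 0.5, high_hz = 47),
    epoch = list(duration_s = 2),
    welch = list(nfft = 1024L, segment_samples = NULL,
                 overlap_fraction = 0.5),
    bands = list(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 40)),
    mix = list(k1 = 0.5, k2 = 0.5),
    stats = list(alpha = 0.05, unit = "epoch", adjust = "none"),
    classify = list(classifiers = "knn", feature_kind = "mixed",
                    folds = 10L, repeats = 10L, split_unit = "epoch",
                    knn = list(k = 7L),
                    svm = list(degree = 3L, gamma = 2,
                               max_iterations = 30000L, cost = 1),
                    cnn = list(n_filters = 2L, dropout = 0.5,
                               epochs = 30L, learning_rate = 1e-2,
                               batch_size = 32L)),
    seed = as.integer(seed),
    log_level = "info"
  )
}

.mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- .mergeConfig(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a YAML pipeline configuration
#'
#' Keys omitted from the file keep their [defaultPipelineConfig()] values.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- .mergeConfig(defaultPipelineConfig(), user)
  for (nm in c("band_amp", "asym_delta", "asym_delta_hc", "coupling_rho",
               "coupling_rho_hc")) {
    cfg$simulate[[nm]] <- unlist(cfg$simulate[[nm]])
  }
  cfg
}

.configBands <- function(config) {
  b <- config$bands
  list(theta = band("theta", b$theta[1], b$theta[2]),
       alpha = band("alpha", b$alpha[1], b$alpha[2]),
       beta = band("beta", b$beta[1], b$beta[2], closedUpper = TRUE))
}

#' Validate a pipeline configuration
#'
#' Checks band edges against the Nyquist frequency, filter settings,
#' epoch duration and classifier names before any computation runs.
#'
#' @param config configuration list.
#' @return invisibly TRUE; errors otherwise.
#' @export
validatePipelineConfig <- function(config) {
  rate <- if (identical(config$input$type, "simulate")) {
    config$simulate$sample_rate_hz
  } else NA_real_
  for (bn in names(config$bands)) {
    b <- config$bands[[bn]]
    stopIfNot(b[1] < b[2], paste("band", bn, "has low >= high"))
    if (!is.na(rate)) {
      stopIfNot(b[2] <= rate / 2,
                paste0("band ", bn, " (", b[1], "-", b[2],
                       " Hz) exceeds the Nyquist frequency at ",
                       rate, " Hz"))
    }
  }
  f <- config$filter
  stopIfNot(f$low_hz > 0 && f$low_hz < f$high_hz,
            "filter edges must satisfy 0 < low < high")
  if (!is.na(rate)) {
    stopIfNot(f$high_hz < rate / 2, "filter high edge above Nyquist")
  }
  stopIfNot(config$epoch$duration_s > 0, "epoch duration must be positive")
  bad <- setdiff(config$classify$classifiers, c("knn", "svm", "cnn"))
  stopIfNot(length(bad) == 0,
            paste("unknown classifier(s):", paste(bad, collapse = ", ")))
  stopIfNot(config$classify$feature_kind %in%
              c("mixed", "single_asymmetry", "single_crosscorr"),
            "unknown feature kind")
  invisible(TRUE)
}

.pipeLog <- function(config, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message(format(Sys.time(), "%H:%M:%S"), " [eegmdd] ", ...)
}

.cohortSpecFromConfig <- function(config, seed) {
  s <- config$simulate
  cohortSpec(nMdd = s$n_mdd, nHc = s$n_hc, durationS = s$duration_s,
             sampleRate = s$sample_rate_hz, bandAmp = s$band_amp,
             asymDelta = s$asym_delta, asymDeltaHc = s$asym_delta_hc,
             couplingRho = s$coupling_rho,
             couplingRhoHc = s$coupling_rho_hc,
             noiseSigma = s$noise_sigma, artifactRate = s$artifact_rate,
             seed = seed)
}

.classifierConfig <- function(config, name) {
  switch(name,
    knn = knnConfig(k = config$classify$knn$k),
    svm = svmConfig(degree = config$classify$svm$degree,
                    gamma = config$classify$svm$gamma,
                    maxIterations = config$classify$svm$max_iterations,
                    cost = config$classify$svm$cost),
    cnn = cnnConfig(nFilters = config$classify$cnn$n_filters,
                    dropoutRate = config$classify$cnn$dropout,
                    epochs = config$classify$cnn$epochs,
                    learningRate = config$classify$cnn$learning_rate,
                    batchSize = config$classify$cnn$batch_size),
    stop("unknown classifier: ", name))
}

#' Simulate a cohort and write it as EDF files
#'
#' Stage entry point: generates the configured synthetic cohort and
#' writes one EDF per subject plus `manifest.tsv` into `outdir`.
#'
#' @param config configuration list.
#' @param outdir output directory.
#' @return invisibly, the directory.
#' @export
stageSimulate <- function(config, outdir) {
  validatePipelineConfig(config)
  stopIfNot(identical(config$input$type, "simulate"),
            "stageSimulate requires input type 'simulate'")
  cohort <- generateCohort(.cohortSpecFromConfig(config, config$seed))
  .pipeLog(config, "simulated ", length(cohort), " recordings")
  writeCohort(cohort, outdir)
  invisible(outdir)
}

#' Compute the feature table from an EDF cohort directory
#'
#' Stage entry point: read, re-reference, filter, segment, extract
#' features; writes `features.tsv` (long format) into `outdir`.
#'
#' @param config configuration list.
#' @param indir EDF cohort directory (with `manifest.tsv`).
#' @param outdir output directory.
#' @return the wide feature data.frame, invisibly.
#' @export
stageFeatures <- function(config, indir, outdir) {
  validatePipelineConfig(config)
  stopIfNot(file.exists(file.path(indir, "manifest.tsv")),
            paste("missing upstream output:", file.path(indir,
                                                        "manifest.tsv")))
  registry <- defaultPairRegistry()
  cohort <- readCohort(indir, registry = NULL)
  .pipeLog(config, "read ", length(cohort), " recordings from ", indir)
  mast <- config$reference$mastoids
  prep <- lapply(cohort, function(rec) {
    if (all(mast %in% channelLabels(rec))) {
      rec <- rereferenceMastoids(rec, mast)
    }
    bandpassFilter(rec, config$filter$low_hz, config$filter$high_hz)
  })
  epochs <- segmentEpochs(prep, config$epoch$duration_s)
  .pipeLog(config, nEpochs(epochs), " epochs of ",
           config$epoch$duration_s, " s")
  feats <- epochFeatures(epochs, registry, .configBands(config),
                         nfft = config$welch$nfft,
                         segmentSamples = config$welch$segment_samples,
                         overlapFraction = config$welch$overlap_fraction)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  writeFeatureTable(feats, file.path(outdir, "features.tsv"),
                    k1 = config$mix$k1, k2 = config$mix$k2)
  saveWide <- file.path(outdir, "features_wide.tsv")
  utils::write.table(feats, saveWide, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  .pipeLog(config, "wrote ", file.path(outdir, "features.tsv"))
  invisible(feats)
}

.readWideFeatures <- function(dir) {
  p <- file.path(dir, "features_wide.tsv")
  stopIfNot(file.exists(p), paste("missing upstream output:", p))
  utils::read.table(p, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Compute the significance map from a features directory
#'
#' @param config configuration list.
#' @param indir directory containing `features_wide.tsv`.
#' @param outdir output directory (`stats.tsv`).
#' @return the significance map, invisibly.
#' @export
stageStats <- function(config, indir, outdir) {
  feats <- .readWideFeatures(indir)
  map <- significanceMap(feats, alpha = config$stats$alpha,
                         unit = config$stats$unit,
                         adjust = config$stats$adjust,
                         k1 = config$mix$k1, k2 = config$mix$k2)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  writeSignificanceMap(map, file.path(outdir, "stats.tsv"))
  .pipeLog(config, sum(map$flag != "ns"), " of ", nrow(map),
           " cells flagged at alpha = ", config$stats$alpha)
  invisible(map)
}

#' Run cross-validated classification from a features directory
#'
#' @param config configuration list.
#' @param indir directory containing `features_wide.tsv`.
#' @param outdir output directory (`cv_results.tsv`).
#' @return data.frame of summary rows, invisibly.
#' @export
stageClassify <- function(config, indir, outdir) {
  feats <- .readWideFeatures(indir)
  tensors <- buildTensorSet(feats, defaultPairRegistry(),
                            kind = config$classify$feature_kind,
                            k1 = config$mix$k1, k2 = config$mix$k2)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  out <- file.path(outdir, "cv_results.tsv")
  if (file.exists(out)) file.remove(out)
  rows <- lapply(config$classify$classifiers, function(cl) {
    .pipeLog(config, "cross-validating ", cl, " (",
             config$classify$folds, " folds x ",
             config$classify$repeats, " repeats)")
    res <- crossValidate(tensors, .classifierConfig(config, cl),
                         folds = config$classify$folds,
                         repeats = config$classify$repeats,
                         seed = config$seed,
                         splitUnit = config$classify$split_unit)
    cvResultRow(res, classifier = cl,
                feature = config$classify$feature_kind,
                window = config$epoch$duration_s, path = out)
  })
  invisible(do.call(rbind, rows))
}

#' Run the full pipeline
#'
#' Simulate (or read) a cohort, preprocess, extract features, map group
#' differences, and cross-validate the configured classifiers. Writes
#' `features.tsv`, `stats.tsv`, `cv_results.tsv` and a machine-readable
#' `run_manifest.json` into `outdir`. Identical configuration and seed
#' reproduce every output byte-identically. Simulated cohorts are routed
#' through EDF files (under `outdir/edf`), so running the stage entry
#' points by hand composes to exactly the same outputs.
#'
#' @param config configuration list (see [defaultPipelineConfig()]).
#' @param outdir output directory.
#' @return list with the feature table, significance map and CV summary.
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outdir) {
  validatePipelineConfig(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  edfDir <- if (identical(config$input$type, "simulate")) {
    d <- file.path(outdir, "edf")
    stageSimulate(config, d)
    d
  } else {
    stopIfNot(!is.null(config$input$dir), "input dir required")
    config$input$dir
  }
  feats <- stageFeatures(config, edfDir, outdir)
  map <- stageStats(config, outdir, outdir)
  cv <- stageClassify(config, outdir, outdir)
  manifest <- list(
    package = "eegmdd",
    version = as.character(utils::packageVersion("eegmdd")),
    seed = config$seed,
    config = config,
    n_epochs = length(unique(paste(feats$subjectId, feats$epochIndex))),
    n_feature_rows = nrow(feats)
  )
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .pipeLog(config, "pipeline complete: ", outdir)
  invisible(list(features = feats, stats = map, cv = cv))
}
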