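# End-to-end orchestration: input -> filtering -> SOBI artifact rejection
# -> epoching -> CompEn features -> ANOVA screening -> (LE) -> CV
# classification, driven by a nested config (YAML file or list).

#' Default pipeline configuration
#'
#' Nested list mirroring the YAML blocks `input`, `preprocess`, `epoch`,
#' `complexity`, `entropy`, `embedding`, `classify` and `seed`. The default
#' input is a synthetic recording (8 EEG + 1 EOG montage, 40 trials) with
#' the four classes planted at Hurst 0.35/0.5/0.65/0.8 on disjoint channel
#' groups; the epoch window is the 2–6 s cue-to-end imagery interval, the
#' only part of a trial carrying class information in the generator.
#'
#' @return nested configuration list.
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 1,
    input = list(type = "synthetic", n_trials = 40, n_eeg = 8, n_eog = 1,
                 fs = 250, hurst = c(0.35, 0.5, 0.65, 0.8),
                 erd_depth = 0.5, osc_amplitude = 5,
                 blink_rate = 12, blink_amplitude = 100,
                 line_amplitude = 5),
    preprocess = list(notch = 50, band = c(8, 30), ica = TRUE,
                      sobi_lags = 100, xcorr_threshold = 0.5),
    epoch = list(window = c(2, 6)),
    complexity = list(kmax = 20, min_subset = 64),
    entropy = list(m = 2, c = 2, d = 1),
    screening = list(alpha = 0.05),
    embedding = list(enabled = TRUE, n_neighbors = 5,
                     weight_scheme = "binary", r = 10),
    classify = list(classifiers = c("knn", "svm", "rf"), n_folds = 10,
                    knn_k = 5, svm_cost = 10, svm_sigma = 0.5,
                    rf_trees = 100)
  )
}

mergeConfig <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- mergeConfig(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Run the full motor-imagery analysis pipeline
#'
#' Executes, in order: input (synthetic generation or an EDF file), notch
#' and band-pass filtering, SOBI decomposition with cross-correlation
#' artifact zeroing, epoching, CompEn feature extraction, two-way-ANOVA
#' screening, and stratified cross-validated classification with optional
#' Laplacian-Eigenmap reduction (fitted per training fold). A failing stage
#' aborts with the stage name; artifacts produced so far are kept in
#' `outDir` when given.
#'
#' @param config a nested list (see [defaultPipelineConfig()]), or the path
#'   of a YAML file with the same blocks; missing entries take defaults.
#' @param outDir optional directory for stage artifacts (features TSV,
#'   screening report TSV, metrics TSV + JSON).
#' @param verbose log stage progress to stderr.
#' @return list with `recording`, `cleaned`, `decomposition`, `epochs`,
#'   `features`, `screening`, `report` (a
#'   [ClassificationReport-class]).
#' @export
runPipeline <- function(config = list(), outDir = NULL, verbose = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- mergeConfig(defaultPipelineConfig(), config)
  seed <- cfg$seed
  say <- function(...) if (verbose) message("[micompen] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (!is.null(outDir)) dir.create(outDir, showWarnings = FALSE,
                                   recursive = TRUE)

  say("input stage")
  truth <- NULL
  rec <- stage("input", {
    inp <- cfg$input
    if (identical(inp$type, "synthetic")) {
      montage <- defaultMontage(inp$n_eeg, inp$n_eog)
      sim <- simulateRecording(
        montage = montage, nTrials = inp$n_trials,
        signatures = defaultSignatures(montage, hurst = inp$hurst,
                                       erdDepth = inp$erd_depth,
                                       oscAmplitude = inp$osc_amplitude),
        artifacts = artifactSpec(blinkRate = inp$blink_rate,
                                 blinkAmplitude = inp$blink_amplitude,
                                 lineAmplitude = inp$line_amplitude),
        fs = inp$fs, seed = stageSeed(seed, "simulate"))
      truth <- sim$truth
      sim$recording
    } else {
      readRecording(inp$path, format = if (is.null(inp$format)) "edf"
                    else inp$format)
    }
  })

  say("preprocess stage")
  pp <- cfg$preprocess
  dec <- NULL
  # order: notch, then SOBI artifact zeroing, then band-pass. The ICA must
  # see the notched (not band-passed) data: ocular transients live below
  # the 8 Hz band edge, so a band-passed decomposition cannot correlate
  # with the EOG references it is screened against.
  cleaned <- stage("preprocess", {
    filt <- notchFilter(rec, pp$notch)
    if (isTRUE(pp$ica)) {
      dec <- sobi(filt, nLags = pp$sobi_lags)
      res <- removeArtifacts(dec, filt, threshold = pp$xcorr_threshold)
      dec <- res$decomposition
      filt <- res$cleaned
    }
    bandpassFilter(filt, pp$band[1], pp$band[2])
  })

  say("epoch stage")
  epochs <- stage("epoch", epochRecording(cleaned, window = cfg$epoch$window))

  say("feature stage")
  feats <- stage("features", computeFeatures(
    epochs, kmax = cfg$complexity$kmax,
    minSubset = cfg$complexity$min_subset,
    m = cfg$entropy$m, c = cfg$entropy$c, d = cfg$entropy$d))
  if (!is.null(outDir)) {
    tsv <- data.frame(label = as.character(classLabels(feats)),
                      featureMatrix(feats), check.names = FALSE)
    utils::write.table(tsv, file.path(outDir, "features.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  say("screening stage")
  screening <- stage("screening", screenFeatures(
    feats, alpha = cfg$screening$alpha, seed = stageSeed(seed, "screening")))
  if (!is.null(outDir))
    utils::write.table(featureReport(feats, screening),
                       file.path(outDir, "screening.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

  say("classification stage")
  emb <- cfg$embedding
  report <- stage("classify", crossValidate(
    feats, classifiers = cfg$classify$classifiers,
    nFolds = cfg$classify$n_folds,
    embed = isTRUE(emb$enabled), r = emb$r,
    nNeighbors = emb$n_neighbors, scheme = emb$weight_scheme,
    knnK = cfg$classify$knn_k, svmCost = cfg$classify$svm_cost,
    svmSigma = cfg$classify$svm_sigma, rfTrees = cfg$classify$rf_trees,
    seed = seed))
  if (!is.null(outDir)) {
    utils::write.table(report@metrics, file.path(outDir, "metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(seed = seed,
           metrics = report@metrics,
           confusion = lapply(report@confusion, unclass)),
      file.path(outDir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  say("done")
  list(recording = rec, truth = truth, cleaned = cleaned,
       decomposition = dec, epochs = epochs, features = feats,
       screening = screening, report = report)
}

#' Grid search over the SVM cost parameter
#'
#' Optional tuning mode reproducing the standard log-spaced cost grid
#' `10^-4 .. 10^4`: runs [crossValidate()] with the SVM only at each cost
#' and returns the accuracies. Default pipeline runs skip this and use
#' C = 10 directly.
#'
#' @param ft a [FeatureTable-class].
#' @param costs cost grid (default `10^(-4:4)`).
#' @param ... passed to [crossValidate()].
#' @return data.frame with columns cost and accuracy.
#' @export
tuneSvmCost <- function(ft, costs = 10^(-4:4), ...) {
  acc <- vapply(costs, function(C) {
    rep <- crossValidate(ft, classifiers = "svm", svmCost = C, ...)
    rep@metrics$accuracy[1]
  }, 0)
  data.frame(cost = costs, accuracy = acc)
}
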