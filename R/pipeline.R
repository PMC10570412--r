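# End-to-end pipeline: generate (or load) -> preprocess -> featurize ->
# graph -> split -> train -> evaluate -> stats, with all outputs written
# to a run directory and a single global seed fanned out to every
# component.

#' Pipeline run configuration
#'
#' @param outputDir run directory (created on demand).
#' @param seed global seed; generator, split, and training seeds are
#'   derived from it deterministically.
#' @param generator a [generatorConfig()]; its seed is overridden by the
#'   derived seed.
#' @param epochSeconds epoch length (1 s default).
#' @param band analysis band, a [bandSpec()] (fast ripples, 250-500 Hz).
#' @param complexity a [complexityParams()].
#' @param ratios train/validation/test fractions.
#' @param model a [gcnnConfig()].
#' @param train a [trainConfig()].
#' @param verbose log progress.
#' @export
runConfig <- function(outputDir = tempfile("epistage_run_"), seed = 42,
                      generator = generatorConfig(),
                      epochSeconds = 1, band = bandSpec(),
                      complexity = complexityParams(),
                      ratios = c(0.5, 0.2, 0.3),
                      model = gcnnConfig(), train = trainConfig(),
                      verbose = FALSE) {
  if (band$high > generator$fs / 2)
    stop("band.high exceeds fs/2 for the configured generator")
  generator$seed <- deriveSeed(seed, 1L)
  train$seed <- deriveSeed(seed, 2L)
  list(outputDir = outputDir, seed = as.integer(seed), generator = generator,
       epochSeconds = epochSeconds, band = band, complexity = complexity,
       ratios = ratios, model = model, train = train, verbose = verbose,
       splitSeed = deriveSeed(seed, 3L))
}

logMsg <- function(verbose, fmt, ...) {
  if (verbose) message(format(Sys.time(), "%H:%M:%S "), sprintf(fmt, ...))
}

# preprocess + featurize + graph for a list of recordings
featurizeRecordings <- function(recordings, cfg) {
  featuresByStage <- list(normal = list(), acute = list(), chronic = list())
  graphs <- list()
  for (rec in recordings) {
    eps <- preprocessRecording(rec, cfg$epochSeconds, cfg$band)
    fms <- extractFeatureList(eps, cfg$complexity)
    featuresByStage[[stage(rec)]] <-
      c(featuresByStage[[stage(rec)]], fms)
    graphs <- c(graphs, lapply(fms, buildGraph))
  }
  list(featuresByStage = featuresByStage, graphs = graphs)
}

#' Run the full staging pipeline
#'
#' Generates one synthetic recording per stage (unless \code{recordings}
#' is supplied), band-limits 1-s epochs, extracts the five complexity
#' measures, builds complete-graph samples, splits 50-20-30, trains the
#' graph convolutional classifier and evaluates it on the held-out test
#' set; the statistical layer (per-measure ANOVA/Tukey and 2-PC scores)
#' runs on the same features. All artefacts are written to the run
#' directory: features CSV, split manifest, model weights, training
#' history, evaluation report JSON, stats tables and a resolved-config
#' copy.
#'
#' @param cfg a [runConfig()].
#' @param recordings optional list of [EEGRecording-class] objects to use
#'   instead of synthetic data (stages must be labelled).
#' @return Invisibly, a list with the run directory, the
#'   [EvalReport-class], the trained model, training history and the
#'   stats report.
#' @export
runPipeline <- function(cfg = runConfig(), recordings = NULL) {
  dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
  logMsg(cfg$verbose, "run directory: %s", cfg$outputDir)
  if (is.null(recordings)) {
    logMsg(cfg$verbose, "generating synthetic recordings (fs=%g, %gs)",
           cfg$generator$fs, cfg$generator$duration)
    recordings <- generateDataset(cfg$generator, 1L)
  }
  if (!all(vapply(recordings, stage, "") %in% STAGES))
    stop("all recordings must carry a normal/acute/chronic stage label")

  logMsg(cfg$verbose, "preprocessing and extracting complexity features")
  fz <- featurizeRecordings(recordings, cfg)
  writeFeaturesCSV(unlist(fz$featuresByStage, recursive = FALSE),
                   file.path(cfg$outputDir, "features.csv"))

  split <- splitDataset(fz$graphs, cfg$ratios, seed = cfg$splitSeed)
  split <- standardizeFeatures(split)
  exportSplitCSV(split, file.path(cfg$outputDir, "dataset"))

  logMsg(cfg$verbose, "training GCNN (%d epochs)", cfg$train$epochs)
  tr <- trainModel(split, cfg$model, cfg$train, verbose = cfg$verbose)
  utils::write.csv(tr$history,
                   file.path(cfg$outputDir, "train_history.csv"),
                   row.names = FALSE)
  saveModelWeights(tr$model, file.path(cfg$outputDir, "model_weights.txt"))

  pred <- predictStages(tr$model, split@test)
  report <- evalReport(sampleLabels(split@test), pred$labels)
  reportToJSON(report, file.path(cfg$outputDir, "eval_report.json"),
               file.path(cfg$outputDir, "confusion.csv"))

  logMsg(cfg$verbose, "statistical comparison layer")
  statsRep <- stageSeparationReport(fz$featuresByStage)
  utils::write.csv(statsRep$table,
                   file.path(cfg$outputDir, "stage_separation.csv"),
                   row.names = FALSE)
  utils::write.csv(statsRep$pca, file.path(cfg$outputDir, "pca_scores.csv"),
                   row.names = FALSE)

  resolved <- cfg
  resolved$band <- cfg$band[c("low", "high", "wavelet")]
  jsonlite::write_json(resolved,
                       file.path(cfg$outputDir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  logMsg(cfg$verbose, "test accuracy %.4f", report@accuracy)
  invisible(list(dir = cfg$outputDir, report = report, model = tr$model,
                 history = tr$history, stats = statsRep, split = split,
                 graphs = fz$graphs))
}

# per-subject jitter of stage parameters, inducing heterogeneity between
# synthetic subjects
jitterParams <- function(params, seed) {
  withr::with_seed(seed, {
    lapply(params, function(sp) {
      sp$noise_sd <- sp$noise_sd * stats::runif(1, 0.8, 1.25)
      sp$burst_amp <- sp$burst_amp * stats::runif(1, 0.7, 1.3)
      sp$burst_freq <- min(500, max(250,
        sp$burst_freq + stats::runif(1, -30, 30)))
      sp$regularity <- min(1, sp$regularity * stats::runif(1, 0.8, 1.2))
      sp
    })
  })
}

#' Per-subject and combined classification runs
#'
#' Trains one model per synthetic subject plus one pooled model over all
#' subjects, mirroring the individual-versus-combined protocol. Subject
#' heterogeneity is induced by jittering the stage parameters per subject.
#' The published epoch counts are used: \code{epochsIndividual} (3) for
#' each subject, \code{epochsCombined} (50) for the pooled model.
#'
#' @param cfg a [runConfig()]; per-subject runs are written to
#'   subdirectories of \code{cfg$outputDir}.
#' @param subjects character vector of subject identifiers (>= 1).
#' @param epochsIndividual,epochsCombined training epochs for the
#'   per-subject and pooled models.
#' @return A list: \code{summary} (data.frame shaped subject, accuracy,
#'   per-stage F1, with a final "Combined" row) and \code{reports}
#'   (per-run [EvalReport-class] objects).
#' @export
runPerSubject <- function(cfg = runConfig(), subjects = paste0("rat", 1:4),
                          epochsIndividual = 3, epochsCombined = 50) {
  if (!length(subjects)) stop("need at least one subject")
  dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
  allGraphs <- list()
  summary <- NULL
  reports <- list()
  for (si in seq_along(subjects)) {
    sub <- subjects[si]
    scfg <- cfg
    scfg$outputDir <- file.path(cfg$outputDir, sub)
    scfg$generator$params <- jitterParams(cfg$generator$params,
                                          deriveSeed(cfg$seed, 500L + si))
    scfg$generator$seed <- deriveSeed(cfg$seed, 600L + si)
    scfg$train$epochs <- as.integer(epochsIndividual)
    recs <- lapply(STAGES, function(st)
      generateRecording(st, scfg$generator, subjectId = sub))
    res <- runPipeline(scfg, recordings = recs)
    reports[[sub]] <- res$report
    allGraphs <- c(allGraphs, res$graphs)  # raw (unstandardised) features
    summary <- rbind(summary, data.frame(
      subject = sub, accuracy = res$report@accuracy,
      f1_normal = res$report@f1["normal"],
      f1_acute = res$report@f1["acute"],
      f1_chronic = res$report@f1["chronic"], row.names = NULL))
  }
  # pooled model over the unstandardised union is rebuilt from raw graphs:
  # re-split and re-standardise so train statistics stay leakage-free
  comb <- splitDataset(allGraphs, cfg$ratios,
                       seed = deriveSeed(cfg$seed, 900L))
  comb <- standardizeFeatures(comb)
  tcfg <- cfg$train
  tcfg$epochs <- as.integer(epochsCombined)
  tr <- trainModel(comb, cfg$model, tcfg, verbose = cfg$verbose)
  pred <- predictStages(tr$model, comb@test)
  rep <- evalReport(sampleLabels(comb@test), pred$labels)
  reports[["Combined"]] <- rep
  summary <- rbind(summary, data.frame(
    subject = "Combined", accuracy = rep@accuracy,
    f1_normal = rep@f1["normal"], f1_acute = rep@f1["acute"],
    f1_chronic = rep@f1["chronic"], row.names = NULL))
  utils::write.csv(summary, file.path(cfg$outputDir, "subject_summary.csv"),
                   row.names = FALSE)
  list(summary = summary, reports = reports)
}
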