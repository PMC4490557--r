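# Pipeline orchestration: configuration, simulate/analyze/report entry
# points, manifests with input checksums. These functions (plus the thin
# Rscript wrapper in inst/scripts/ribofret) bind all stages together.

#' Pipeline configuration
#'
#' All tunable parameters of the analysis chain with their defaults. The
#' configuration round-trips losslessly through YAML
#' ([writePipelineConfig()] / [readPipelineConfig()]).
#'
#' @param beta donor-to-acceptor bleed-through coefficient (default 0.13).
#' @param smoothWindow smoothing window, frames (odd, default 3).
#' @param minLifetime minimal analyzable trace length, frames (default 10).
#' @param rThreshold anti-correlation acceptance threshold (default -0.3).
#' @param Kmax maximal HMM states per trace (default 4).
#' @param nRestarts EM restarts per K (default 5).
#' @param tol EM convergence tolerance (default 1e-6).
#' @param minDelta minimal FRET change counted as a transition (0.05).
#' @param syncThreshold post-synchronization FRET threshold (0.5).
#' @param window post-synchronization histogram window, frames (45).
#' @param binWidth histogram bin width (0.025).
#' @param minDwells minimal dwells per exponential fit (20).
#' @param observationTime observation time T in seconds (33).
#' @param pair canonical class set, "lt" or "tt".
#' @param seed integer seed governing all stochastic steps.
#' @return named list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(beta = 0.13, smoothWindow = 3, minLifetime = 10,
                           rThreshold = -0.3, Kmax = 4, nRestarts = 5,
                           tol = 1e-6, minDelta = 0.05, syncThreshold = 0.5,
                           window = 45, binWidth = 0.025, minDwells = 20,
                           observationTime = 33, pair = "lt", seed = 1) {
  cfg <- list(beta = beta, smoothWindow = smoothWindow,
              minLifetime = minLifetime, rThreshold = rThreshold,
              Kmax = Kmax, nRestarts = nRestarts, tol = tol,
              minDelta = minDelta, syncThreshold = syncThreshold,
              window = window, binWidth = binWidth, minDwells = minDwells,
              observationTime = observationTime, pair = pair, seed = seed)
  stopifnot(cfg$beta >= 0, cfg$beta < 1, cfg$smoothWindow %% 2 == 1,
            cfg$minLifetime >= 1, cfg$Kmax >= 1, cfg$minDelta > 0,
            cfg$window >= 1, cfg$pair %in% c("lt", "tt"))
  class(cfg) <- "pipelineConfig"
  cfg
}

#' @rdname pipelineConfig
#' @param path YAML file path.
#' @export
writePipelineConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipelineConfig
#' @param cfg a pipeline configuration.
#' @export
readPipelineConfig <- function(path) {
  do.call(pipelineConfig, yaml::read_yaml(path))
}

#' Simulate a dataset and write it to disk
#'
#' @param preset preset name or [ConditionPreset-class].
#' @param nTraces number of traces (>= 1).
#' @param seed integer seed.
#' @param out output directory.
#' @param photophysics,acquisition parameter objects.
#' @return the [TraceSet-class], invisibly.
#' @export
runSimulation <- function(preset, nTraces, seed, out,
                          photophysics = photophysicsParams(),
                          acquisition = acquisitionParams()) {
  ts <- generateDataset(preset, nTraces, seed, photophysics, acquisition)
  writeTraceSet(ts, out)
  invisible(ts)
}

#' Run the full analysis chain
#'
#' QC, idealization, transition extraction, static/dynamic classification,
#' post-synchronization, histograms/contours, populations and dwell-time
#' kinetics, writing every stage's table plus a manifest (configuration
#' snapshot and input checksum) when \code{out} is given.
#'
#' @param traces a [TraceSet-class], a dataset directory, or a trace-table
#'   file path.
#' @param config a [pipelineConfig()].
#' @param out optional output directory.
#' @return list with elements qc, fret, idealized, transitions, classes,
#'   sync, histogram, synced_histogram, contour, populations, kinetics,
#'   rate_table.
#' @export
runAnalysis <- function(traces, config = pipelineConfig(), out = NULL) {
  inputPath <- NULL
  if (is.character(traces)) {
    inputPath <- traces
    traces <- if (dir.exists(traces)) readTraceSet(traces)
              else readTraceTable(traces)
  }
  stopifnot(is(traces, "TraceSet"))
  set.seed(config$seed)

  qc <- runQC(traces, beta = config$beta,
              smoothWindow = config$smoothWindow,
              minLifetime = config$minLifetime,
              rThreshold = config$rThreshold)
  if (length(traceIDs(qc$fret)) == 0)
    stop("no accepted traces after quality control")

  centers <- canonicalCenters(config$pair)
  ideal <- idealizeTraces(qc$fret, Kmax = config$Kmax, centers = centers,
                          nRestarts = config$nRestarts, seed = config$seed,
                          tol = config$tol)
  trans <- extractTransitions(ideal, minDelta = config$minDelta)
  okIds <- setdiff(traceIDs(ideal),
                   modelSummary(ideal)$trace_id[modelSummary(ideal)$flagged])
  classesAll <- classifyTraces(trans, okIds, scope = "all")
  ps <- postsynchronize(ideal, threshold = config$syncThreshold,
                        minDelta = config$minDelta)
  histAll <- buildHistogram(qc$fret, binWidth = config$binWidth)
  histSync <- if (nrow(ps$sync))
    buildHistogram(qc$fret, sync = ps$sync, window = config$window,
                   binWidth = config$binWidth, timeResolved = TRUE)
    else NULL
  syncArg <- if (nrow(ps$sync)) ps$sync else NULL
  pops <- computePopulations(ideal, sync = syncArg, window = config$window)
  kin <- analyzeKinetics(ideal, sync = syncArg, qcReport = qc$report,
                         window = config$window,
                         minDwells = config$minDwells,
                         minDelta = config$minDelta)
  rateTab <- summarizeRateTable(setNames(list(kin), "analysis"), centers)

  res <- list(qc = qc$report, fret = qc$fret, idealized = ideal,
              transitions = trans, classes = classesAll, sync = ps,
              histogram = histAll, synced_histogram = histSync,
              populations = pops, kinetics = kin, rate_table = rateTab)
  if (!is.null(out)) .writeAnalysis(res, out, config, inputPath)
  res
}

.writeAnalysis <- function(res, out, config, inputPath) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  .writeTable(res$qc, file.path(out, "qc_report.tsv"))
  .writeTable(traceData(res$fret), file.path(out, "fret.tsv"))
  .writeTable(traceData(res$idealized), file.path(out, "idealized.tsv"))
  .writeTable(modelSummary(res$idealized),
              file.path(out, "model_summary.tsv"))
  .writeTable(res$transitions, file.path(out, "transitions.tsv"))
  .writeTable(res$classes, file.path(out, "trace_classes.tsv"))
  .writeTable(res$sync$sync, file.path(out, "sync.tsv"))
  hist <- data.frame(bin_lo = res$histogram$breaks[-length(res$histogram$breaks)],
                     bin_hi = res$histogram$breaks[-1],
                     count = res$histogram$counts)
  .writeTable(hist, file.path(out, "histogram.tsv"))
  if (!is.null(res$synced_histogram) &&
      !is.null(res$synced_histogram$matrix)) {
    m <- as.data.frame(res$synced_histogram$matrix)
    names(m) <- sprintf("bin%03d", seq_len(ncol(m)))
    m <- cbind(aligned_frame = as.integer(rownames(res$synced_histogram$matrix)), m)
    .writeTable(m, file.path(out, "contour.tsv"))
  }
  .writeTable(res$populations, file.path(out, "populations.tsv"))
  .writeTable(res$kinetics$rates, file.path(out, "rates.tsv"))
  .writeTable(res$rate_table, file.path(out, "rate_table.tsv"))
  manifest <- list(config = unclass(config),
                   package_version = as.character(utils::packageVersion("riboFRET")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(inputPath)) {
    f <- if (dir.exists(inputPath)) file.path(inputPath, "traces.tsv")
         else inputPath
    if (file.exists(f))
      manifest$input_checksum <- as.character(tools::md5sum(f))
  }
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  invisible(out)
}

#' Render a report from a completed analysis directory
#'
#' Writes the rate-table summary, the population/class tables and a contour
#' heatmap figure (PDF) built from the stage outputs of [runAnalysis()].
#'
#' @param analysisDir directory written by [runAnalysis()].
#' @param out output directory.
#' @return invisibly, the output directory.
#' @export
runReport <- function(analysisDir, out) {
  need <- c("rate_table.tsv", "populations.tsv", "trace_classes.tsv")
  for (f in need)
    if (!file.exists(file.path(analysisDir, f)))
      stop("missing stage output '", f, "' in ", analysisDir,
           "; run the analysis stage first")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  rateTab <- read.delim(file.path(analysisDir, "rate_table.tsv"))
  pops <- read.delim(file.path(analysisDir, "populations.tsv"))
  classes <- read.delim(file.path(analysisDir, "trace_classes.tsv"))
  .writeTable(rateTab, file.path(out, "summary_rate_table.tsv"))
  .writeTable(pops, file.path(out, "summary_populations.tsv"))
  fracDyn <- mean(classes$label == "dynamic")
  .writeTable(data.frame(metric = c("n_traces", "fraction_dynamic"),
                         value = c(nrow(classes), fracDyn)),
              file.path(out, "summary_classes.tsv"))
  tf <- file.path(analysisDir, "transitions.tsv")
  if (file.exists(tf)) {
    tr <- read.delim(tf)
    if (nrow(tr))
      .writeTable(countTransitionTypes(tr),
                  file.path(out, "summary_transition_types.tsv"))
    else
      writeLines("no transitions observed; rate section omitted",
                 file.path(out, "NOTES.txt"))
  }
  cf <- file.path(analysisDir, "contour.tsv")
  if (file.exists(cf)) {
    m <- as.matrix(read.delim(cf)[, -1])
    grDevices::pdf(file.path(out, "contour.pdf"), width = 6, height = 4)
    graphics::image(x = seq_len(nrow(m)), y = seq_len(ncol(m)), z = m,
                    xlab = "aligned frame", ylab = "FRET bin",
                    main = "post-synchronized FRET contour",
                    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE))
    grDevices::dev.off()
  }
  invisible(out)
}
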