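# Readers/writers: tab-delimited trace tables, ground-truth sidecars and
# YAML manifests. All tables are UTF-8, tab-delimited, with header rows and
# floats at 6 significant digits.

.writeTable <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Write and read a trace dataset
#'
#' Writes the trace table (\code{traces.tsv}: trace_id, frame, donor,
#' acceptor), the ground-truth sidecar (\code{ground_truth.tsv}) when
#' present, and a YAML manifest (\code{manifest.yaml}) with all generation
#' parameters. \code{readTraceSet} reads the same layout back.
#'
#' @param x a [TraceSet-class].
#' @param dir output directory (created if missing).
#' @return \code{writeTraceSet}: the directory, invisibly;
#'   \code{readTraceSet}: a [TraceSet-class].
#' @export
writeTraceSet <- function(x, dir) {
  stopifnot(is(x, "TraceSet"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .writeTable(traceData(x), file.path(dir, "traces.tsv"))
  if (nrow(groundTruth(x)))
    .writeTable(groundTruth(x), file.path(dir, "ground_truth.tsv"))
  if (length(x@manifest))
    yaml::write_yaml(x@manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname writeTraceSet
#' @export
readTraceSet <- function(dir) {
  tf <- file.path(dir, "traces.tsv")
  if (!file.exists(tf)) stop("no traces.tsv in ", dir)
  traces <- read.delim(tf, stringsAsFactors = FALSE)
  need <- c("trace_id", "frame", "donor", "acceptor")
  miss <- setdiff(need, names(traces))
  if (length(miss))
    stop("malformed trace table ", tf, ": missing column(s) ",
         paste(miss, collapse = ", "))
  gt <- file.path(dir, "ground_truth.tsv")
  truth <- if (file.exists(gt)) read.delim(gt, stringsAsFactors = FALSE)
           else data.frame()
  mf <- file.path(dir, "manifest.yaml")
  manifest <- if (file.exists(mf)) yaml::read_yaml(mf) else list()
  dt <- manifest$frame_interval %||% 0.033
  TraceSet(traces, dt, truth, manifest)
}

#' Read a bare trace table
#'
#' Reads a delimited trace table (columns trace_id, frame, donor, acceptor)
#' without sidecar or manifest, reporting the offending line on parse errors.
#'
#' @param path file path.
#' @param frameInterval frame interval in seconds.
#' @return a [TraceSet-class]
#' @export
readTraceTable <- function(path, frameInterval = 0.033) {
  traces <- tryCatch(read.delim(path, stringsAsFactors = FALSE),
                     error = function(e)
                       stop("cannot parse trace table ", path, ": ",
                            conditionMessage(e)))
  need <- c("trace_id", "frame", "donor", "acceptor")
  miss <- setdiff(need, names(traces))
  if (length(miss))
    stop("malformed trace table ", path, " (line 1): missing column(s) ",
         paste(miss, collapse = ", "))
  bad <- which(!complete.cases(traces[, need]))
  if (length(bad))
    stop("malformed trace table ", path, ": non-numeric or missing values ",
         "at line ", bad[1] + 1L)
  TraceSet(traces, frameInterval)
}
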