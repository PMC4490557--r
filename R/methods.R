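# Constructors, accessors and show methods for the core classes.

#' Create a kinetic scheme
#'
#' @param stateNames character vector of state labels.
#' @param fretMean per-state mean FRET efficiency.
#' @param fretSd per-state emission SD (FRET units).
#' @param rateMatrix square matrix of off-diagonal transition rates (1/s);
#'   may carry dimnames matching \code{stateNames}.
#' @return a [KineticScheme-class]
#' @examples
#' ks <- KineticScheme(c("0.6", "0.4"), c(0.56, 0.40), c(0.08, 0.09),
#'                     matrix(c(0, 1.2, 7.9, 0), 2, 2))
#' stationaryDistribution(ks)
#' @export
KineticScheme <- function(stateNames, fretMean, fretSd, rateMatrix) {
  rateMatrix <- as.matrix(rateMatrix)
  diag(rateMatrix) <- 0
  dimnames(rateMatrix) <- list(stateNames, stateNames)
  new("KineticScheme", stateNames = as.character(stateNames),
      fretMean = as.numeric(fretMean), fretSd = as.numeric(fretSd),
      rateMatrix = rateMatrix)
}

#' @rdname riboFRET-generics
#' @export
setMethod("stateNames", "KineticScheme", function(x) x@stateNames)

#' @rdname riboFRET-generics
#' @export
setMethod("fretMean", "KineticScheme",
          function(x) setNames(x@fretMean, x@stateNames))

#' @rdname riboFRET-generics
#' @export
setMethod("fretSd", "KineticScheme",
          function(x) setNames(x@fretSd, x@stateNames))

#' @rdname riboFRET-generics
#' @export
setMethod("rateMatrix", "KineticScheme", function(x) x@rateMatrix)

#' @rdname riboFRET-generics
#' @export
setMethod("nStates", "KineticScheme", function(x) length(x@stateNames))

#' @rdname stationaryDistribution
#' @export
setMethod("stationaryDistribution", "KineticScheme", function(x) {
  Q <- x@rateMatrix
  diag(Q) <- -rowSums(Q)
  n <- nrow(Q)
  if (n == 1L) return(setNames(1, x@stateNames))
  # solve pi Q = 0, sum(pi) = 1: replace one balance column by the constraint
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  pi <- as.numeric(qr.solve(A, b))
  pi[pi < 0 & pi > -1e-12] <- 0
  setNames(pi / sum(pi), x@stateNames)
})

setMethod("show", "KineticScheme", function(object) {
  cat(sprintf("KineticScheme with %d state(s): %s\n", nStates(object),
              paste(object@stateNames, collapse = ", ")))
  cat("  FRET mean +/- sd:",
      paste(sprintf("%.2f+/-%.2f", object@fretMean, object@fretSd),
            collapse = ", "), "\n")
  off <- object@rateMatrix[row(object@rateMatrix) != col(object@rateMatrix)]
  if (any(off > 0)) {
    idx <- which(object@rateMatrix > 0, arr.ind = TRUE)
    lab <- apply(idx, 1, function(i)
      sprintf("%s->%s: %.2g/s", object@stateNames[i[1]],
              object@stateNames[i[2]], object@rateMatrix[i[1], i[2]]))
    cat("  rates:", paste(lab, collapse = ", "), "\n")
  } else cat("  rates: none (static scheme)\n")
})

#' Photophysics parameters
#'
#' @param bleachRateDonor,bleachRateAcceptor bleaching rates (1/s); defaults
#'   0.05 each (combined 0.1/s, mean analyzable trace length ~10 s).
#' @param blinkOnRate,blinkOffRate dark-state entry/exit rates (1/s), 0 = off.
#' @param bleedthrough donor-to-acceptor bleed-through fraction (default 0.13).
#' @param noiseSd per-channel Gaussian noise (counts, default 60).
#' @param brightness total counts per frame (default 1000).
#' @param fretJitter add per-frame FRET jitter so state SDs match the
#'   scheme's \code{fretSd} (default TRUE).
#' @return a [PhotophysicsParams-class]
#' @export
photophysicsParams <- function(bleachRateDonor = 0.05,
                               bleachRateAcceptor = 0.05,
                               blinkOnRate = 0, blinkOffRate = 0,
                               bleedthrough = 0.13, noiseSd = 60,
                               brightness = 1000, fretJitter = TRUE) {
  new("PhotophysicsParams", bleachRateDonor = bleachRateDonor,
      bleachRateAcceptor = bleachRateAcceptor, blinkOnRate = blinkOnRate,
      blinkOffRate = blinkOffRate, bleedthrough = bleedthrough,
      noiseSd = noiseSd, brightness = brightness, fretJitter = fretJitter)
}

setMethod("show", "PhotophysicsParams", function(object) {
  cat("PhotophysicsParams:\n")
  cat(sprintf("  bleach donor/acceptor: %.3g / %.3g 1/s\n",
              object@bleachRateDonor, object@bleachRateAcceptor))
  cat(sprintf("  bleedthrough: %.3g, brightness: %g, noiseSd: %g\n",
              object@bleedthrough, object@brightness, object@noiseSd))
  if (object@blinkOnRate > 0)
    cat(sprintf("  blinking on/off: %.3g / %.3g 1/s\n", object@blinkOnRate,
                object@blinkOffRate))
})

#' Acquisition parameters
#'
#' @param frameInterval frame time in seconds (default 0.033; the alternative
#'   long-integration mode is 0.130).
#' @param observationWindow recording length in seconds (default 33).
#' @return an [AcquisitionParams-class]
#' @export
acquisitionParams <- function(frameInterval = 0.033, observationWindow = 33) {
  new("AcquisitionParams", frameInterval = frameInterval,
      observationWindow = observationWindow)
}

setMethod("show", "AcquisitionParams", function(object) {
  cat(sprintf("AcquisitionParams: %g ms frames, %g s window\n",
              1000 * object@frameInterval, object@observationWindow))
})

setMethod("show", "ConditionPreset", function(object) {
  cat(sprintf("ConditionPreset \"%s\" (static fraction %.2f)\n",
              object@name, object@staticFraction))
  show(object@scheme)
  if (length(object@forbiddenTransitions))
    cat("  forbidden:", paste(object@forbiddenTransitions, collapse = ", "),
        "\n")
})

#' Construct a TraceSet
#'
#' @param traces data.frame with columns trace_id, frame, donor, acceptor.
#' @param frameInterval frame interval in seconds.
#' @param groundTruth optional simulator sidecar data.frame.
#' @param manifest optional named list of parameters.
#' @return a [TraceSet-class]
#' @export
TraceSet <- function(traces, frameInterval = 0.033,
                     groundTruth = data.frame(), manifest = list()) {
  new("TraceSet", traces = as.data.frame(traces),
      frameInterval = frameInterval,
      groundTruth = as.data.frame(groundTruth), manifest = manifest)
}

#' @rdname riboFRET-generics
#' @export
setMethod("traceIDs", "TraceSet", function(x) unique(x@traces$trace_id))

#' @rdname riboFRET-generics
#' @export
setMethod("frameInterval", "TraceSet", function(x) x@frameInterval)

#' @rdname riboFRET-generics
#' @export
setMethod("traceData", "TraceSet", function(x) x@traces)

#' @rdname riboFRET-generics
#' @export
setMethod("groundTruth", "TraceSet", function(x) x@groundTruth)

setMethod("length", "TraceSet", function(x) length(traceIDs(x)))

setMethod("show", "TraceSet", function(object) {
  ids <- traceIDs(object)
  cat(sprintf("TraceSet: %d trace(s), %d frames total, %g ms frame interval\n",
              length(ids), nrow(object@traces),
              1000 * object@frameInterval))
  if (nrow(object@groundTruth)) cat("  with ground-truth sidecar\n")
  if (length(object@manifest))
    cat(sprintf("  manifest: preset=%s seed=%s\n",
                object@manifest$preset %||% "?",
                object@manifest$seed %||% "?"))
})

#' @rdname riboFRET-generics
#' @export
setMethod("traceIDs", "FRETTraceSet", function(x) unique(x@traces$trace_id))

#' @rdname riboFRET-generics
#' @export
setMethod("frameInterval", "FRETTraceSet", function(x) x@frameInterval)

#' @rdname riboFRET-generics
#' @export
setMethod("traceData", "FRETTraceSet", function(x) x@traces)

setMethod("length", "FRETTraceSet", function(x) length(traceIDs(x)))

setMethod("show", "FRETTraceSet", function(object) {
  cat(sprintf(
    "FRETTraceSet: %d trace(s), %d frames, smoothed over %d point(s)\n",
    length(traceIDs(object)), nrow(object@traces), object@smoothWindow))
})

#' @rdname riboFRET-generics
#' @export
setMethod("traceIDs", "IdealizedTraces", function(x) unique(x@frames$trace_id))

#' @rdname riboFRET-generics
#' @export
setMethod("frameInterval", "IdealizedTraces", function(x) x@frameInterval)

#' @rdname riboFRET-generics
#' @export
setMethod("traceData", "IdealizedTraces", function(x) x@frames)

#' @rdname riboFRET-generics
#' @export
setMethod("modelSummary", "IdealizedTraces", function(x) x@models)

setMethod("length", "IdealizedTraces", function(x) length(traceIDs(x)))

setMethod("show", "IdealizedTraces", function(object) {
  cat(sprintf("IdealizedTraces: %d trace(s), %d frames\n",
              length(traceIDs(object)), nrow(object@frames)))
  if (nrow(object@models)) {
    tab <- table(object@models$K)
    cat("  states per trace:",
        paste(sprintf("K=%s: %d", names(tab), as.integer(tab)),
              collapse = ", "), "\n")
    cat(sprintf("  flagged (poorly idealized): %d\n",
                sum(object@models$flagged)))
  }
})

`%||%` <- function(a, b) if (is.null(a)) b else a
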