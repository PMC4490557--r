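#' @import methods
#' @importFrom stats complete.cases cor dnorm mad median optim quantile rbinom
#'   rexp rnorm runif sd setNames
#' @importFrom utils read.delim write.table head tail
NULL

#' Kinetic scheme of FRET states
#'
#' A continuous-time Markov model of conformational dynamics: a set of named
#' FRET states with emission means and standard deviations, and a rate matrix
#' of first-order transition rates in 1/s. The diagonal is defined implicitly
#' as the negative row sum and is not stored.
#'
#' @slot stateNames character vector of state labels (e.g. \code{"0.6"}).
#' @slot fretMean numeric, per-state mean FRET efficiency in [0, 1].
#' @slot fretSd numeric, per-state emission standard deviation (FRET units).
#' @slot rateMatrix square numeric matrix of transition rates (1/s);
#'   off-diagonal entries only, diagonal entries are ignored/zero.
#'
#' @seealso [KineticScheme()], [stationaryDistribution()], [buildPreset()]
#' @export
setClass("KineticScheme",
  representation(
    stateNames = "character",
    fretMean = "numeric",
    fretSd = "numeric",
    rateMatrix = "matrix"
  )
)

setValidity("KineticScheme", function(object) {
  msg <- character()
  n <- length(object@stateNames)
  if (length(object@fretMean) != n || length(object@fretSd) != n)
    msg <- c(msg, "fretMean and fretSd must match the number of states")
  if (!all(dim(object@rateMatrix) == c(n, n)))
    msg <- c(msg, "rateMatrix must be n x n")
  off <- object@rateMatrix[row(object@rateMatrix) != col(object@rateMatrix)]
  if (any(off < 0)) msg <- c(msg, "off-diagonal rates must be >= 0")
  if (any(object@fretSd < 0)) msg <- c(msg, "fretSd must be >= 0")
  if (n > 1 && min(dist(object@fretMean)) < 0.05)
    msg <- c(msg, "state FRET means must be distinct by >= 0.05")
  if (length(msg)) msg else TRUE
})

#' Photophysics parameters for the trace renderer
#'
#' Bleaching, blinking, bleed-through and camera-noise parameters used when
#' rendering two-colour intensity traces. Defaults give a mean analyzable
#' trace length of ~10 s (combined bleach rate 0.1/s split evenly between the
#' two fluorophores) and a donor-to-acceptor bleed-through of 0.13.
#'
#' @slot bleachRateDonor,bleachRateAcceptor exponential bleaching rates (1/s).
#' @slot blinkOnRate,blinkOffRate blinking kinetics (1/s); 0 = disabled
#'   (default).
#' @slot bleedthrough fraction of donor counts added to the acceptor channel.
#' @slot noiseSd Gaussian read noise per channel (counts).
#' @slot brightness total emitted counts per frame.
#' @slot fretJitter logical; if TRUE (default) per-frame FRET is jittered so
#'   the observed state SD matches the scheme's \code{fretSd} (channel noise
#'   alone cannot reach the observed widths at the default SNR).
#' @export
setClass("PhotophysicsParams",
  representation(
    bleachRateDonor = "numeric",
    bleachRateAcceptor = "numeric",
    blinkOnRate = "numeric",
    blinkOffRate = "numeric",
    bleedthrough = "numeric",
    noiseSd = "numeric",
    brightness = "numeric",
    fretJitter = "logical"
  )
)

setValidity("PhotophysicsParams", function(object) {
  msg <- character()
  if (object@bleedthrough < 0 || object@bleedthrough >= 1)
    msg <- c(msg, "bleedthrough must be in [0, 1)")
  rates <- c(object@bleachRateDonor, object@bleachRateAcceptor,
             object@blinkOnRate, object@blinkOffRate)
  if (any(rates < 0)) msg <- c(msg, "all rates must be >= 0")
  if (object@brightness <= 0) msg <- c(msg, "brightness must be > 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Acquisition parameters
#'
#' Camera frame interval and total observation window. Defaults: 33 ms frames
#' (30 frames per second) and a 33 s observation window.
#'
#' @slot frameInterval frame integration time in seconds.
#' @slot observationWindow total recording time in seconds.
#' @export
setClass("AcquisitionParams",
  representation(frameInterval = "numeric", observationWindow = "numeric")
)

setValidity("AcquisitionParams", function(object) {
  msg <- character()
  if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be > 0")
  if (object@observationWindow < object@frameInterval)
    msg <- c(msg, "observationWindow must be >= frameInterval")
  if (length(msg)) msg else TRUE
})

#' Experimental condition preset
#'
#' A named experimental condition: a kinetic scheme, the fraction of static
#' (non-fluctuating) complexes, and transitions that are structurally
#' forbidden under that condition.
#'
#' @slot name condition label (e.g. "PRE", "XL").
#' @slot scheme a [KineticScheme-class].
#' @slot staticFraction fraction of traces frozen in a single state,
#'   sampled from the stationary distribution.
#' @slot forbiddenTransitions character vector of "from->to" state-name pairs
#'   whose rates are structurally zero.
#' @export
setClass("ConditionPreset",
  representation(
    name = "character",
    scheme = "KineticScheme",
    staticFraction = "numeric",
    forbiddenTransitions = "character"
  )
)

setValidity("ConditionPreset", function(object) {
  msg <- character()
  if (object@staticFraction < 0 || object@staticFraction > 1)
    msg <- c(msg, "staticFraction must be in [0, 1]")
  if (length(object@forbiddenTransitions)) {
    parts <- strsplit(object@forbiddenTransitions, "->", fixed = TRUE)
    ok <- vapply(parts, function(p)
      length(p) == 2 && all(p %in% object@scheme@stateNames), logical(1))
    if (!all(ok))
      msg <- c(msg, "forbiddenTransitions must reference existing states")
  }
  if (length(msg)) msg else TRUE
})

#' Set of raw two-colour intensity traces
#'
#' Container for per-frame donor/acceptor intensity traces, optionally with
#' the simulator's ground-truth sidecar and a parameter manifest.
#'
#' @slot traces data.frame with columns \code{trace_id}, \code{frame},
#'   \code{donor}, \code{acceptor}.
#' @slot frameInterval frame interval in seconds.
#' @slot groundTruth data.frame sidecar (columns \code{trace_id},
#'   \code{frame}, \code{state}, \code{fret}, plus per-trace
#'   \code{bleach_frame_donor}, \code{bleach_frame_acceptor},
#'   \code{is_static}) or an empty data.frame for experimental data.
#' @slot manifest named list of generation parameters.
#' @export
setClass("TraceSet",
  representation(
    traces = "data.frame",
    frameInterval = "numeric",
    groundTruth = "data.frame",
    manifest = "list"
  )
)

setValidity("TraceSet", function(object) {
  msg <- character()
  need <- c("trace_id", "frame", "donor", "acceptor")
  if (!all(need %in% names(object@traces)))
    msg <- c(msg, sprintf("traces must have columns %s",
                          paste(need, collapse = ", ")))
  if (length(object@frameInterval) != 1 || object@frameInterval <= 0)
    msg <- c(msg, "frameInterval must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Set of FRET efficiency trajectories
#'
#' Per-frame FRET efficiencies E = acceptor/(donor+acceptor) after quality
#' control. Efficiencies are not clipped to [0, 1]; noise excursions are kept
#' for histogramming over [-0.1, 1.1].
#'
#' @slot traces data.frame with columns \code{trace_id}, \code{frame},
#'   \code{efficiency}.
#' @slot frameInterval frame interval in seconds.
#' @slot smoothWindow width of the moving-average smoothing applied (frames).
#' @export
setClass("FRETTraceSet",
  representation(
    traces = "data.frame",
    frameInterval = "numeric",
    smoothWindow = "numeric"
  )
)

setValidity("FRETTraceSet", function(object) {
  need <- c("trace_id", "frame", "efficiency")
  if (!all(need %in% names(object@traces)))
    return(sprintf("traces must have columns %s", paste(need, collapse = ", ")))
  TRUE
})

#' Idealized (HMM-fitted) trajectories
#'
#' Piecewise-constant state sequences fitted per trace by a Gaussian hidden
#' Markov model, together with per-trace model summaries and quality flags.
#'
#' @slot frames data.frame with columns \code{trace_id}, \code{frame},
#'   \code{state} (fitted state index), \code{level} (fitted emission mean),
#'   \code{class} (canonical class label or NA).
#' @slot models data.frame, one row per trace: \code{trace_id}, \code{K},
#'   \code{logLik}, \code{bic}, \code{converged}, \code{flagged},
#'   \code{flag_reason}.
#' @slot frameInterval frame interval in seconds.
#' @slot canonicalCenters named numeric vector of canonical class centers.
#' @export
setClass("IdealizedTraces",
  representation(
    frames = "data.frame",
    models = "data.frame",
    frameInterval = "numeric",
    canonicalCenters = "numeric"
  )
)

setValidity("IdealizedTraces", function(object) {
  need <- c("trace_id", "frame", "state", "level")
  if (!all(need %in% names(object@frames)))
    return(sprintf("frames must have columns %s", paste(need, collapse = ", ")))
  TRUE
})
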