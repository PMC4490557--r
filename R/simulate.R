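# Synthetic two-colour smFRET trace generator: continuous-time Markov state
# paths, exponential photobleaching/blinking, and camera-frame rendering with
# donor-to-acceptor bleed-through.

#' Simulate a continuous-time Markov state path
#'
#' Gillespie-style simulation of the kinetic scheme: exponentially
#' distributed sojourns with the scheme's rates, jump probabilities
#' proportional to the outgoing rates. A state with no outgoing rates is
#' absorbing and yields a single sojourn spanning the remaining duration.
#'
#' @param scheme a [KineticScheme-class].
#' @param duration total simulated time in seconds (> 0).
#' @param startState starting state index or name, or \code{"stationary"}
#'   (default) to draw from the stationary distribution.
#' @param seed optional integer seed.
#' @return data.frame with columns \code{state} (index), \code{entry_time}
#'   (s) and \code{exit_time} (s); sojourns tile \code{[0, duration]}.
#' @examples
#' ks <- KineticScheme(c("A", "B"), c(0.8, 0.6), c(0.1, 0.1),
#'                     matrix(c(0, 2, 2, 0), 2, 2))
#' simulateStatePath(ks, duration = 1, seed = 1)
#' @export
simulateStatePath <- function(scheme, duration, startState = "stationary",
                              seed = NULL) {
  stopifnot(is(scheme, "KineticScheme"))
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be > 0")
  if (!is.null(seed)) set.seed(seed)
  Q <- rateMatrix(scheme)
  n <- nStates(scheme)
  if (identical(startState, "stationary")) {
    s <- sample.int(n, 1, prob = stationaryDistribution(scheme))
  } else if (is.character(startState)) {
    s <- match(startState, stateNames(scheme))
    if (is.na(s)) stop("unknown start state '", startState, "'")
  } else s <- as.integer(startState)

  states <- integer(0); entry <- numeric(0)
  t <- 0
  while (t < duration) {
    states <- c(states, s); entry <- c(entry, t)
    out <- Q[s, ]
    rate <- sum(out)
    if (rate <= 0) break                       # absorbing: single sojourn
    t <- t + rexp(1, rate)
    if (t >= duration) break
    s <- sample.int(n, 1, prob = out)
  }
  data.frame(state = states, entry_time = entry,
             exit_time = c(entry[-1], duration))
}

#' Draw photophysical event times
#'
#' Draws exponentially distributed donor and acceptor photobleaching times
#' and, when blinking is enabled, a list of reversible dark intervals of the
#' acceptor. Events beyond \code{duration} are reported as \code{Inf} (none).
#'
#' @param params a [PhotophysicsParams-class].
#' @param duration observation time in seconds.
#' @param seed optional integer seed.
#' @return list with \code{donorBleach}, \code{acceptorBleach} (s or Inf)
#'   and \code{blinks} (data.frame start/end, possibly empty).
#' @export
applyPhotophysics <- function(params, duration, seed = NULL) {
  stopifnot(is(params, "PhotophysicsParams"))
  if (!is.null(seed)) set.seed(seed)
  drawExp <- function(rate) if (rate > 0) rexp(1, rate) else Inf
  td <- drawExp(params@bleachRateDonor)
  ta <- drawExp(params@bleachRateAcceptor)
  if (td > duration) td <- Inf
  if (ta > duration) ta <- Inf
  blinks <- data.frame(start = numeric(0), end = numeric(0))
  if (params@blinkOnRate > 0 && params@blinkOffRate > 0) {
    t <- 0
    horizon <- min(td, ta, duration)
    while (t < horizon) {
      t <- t + rexp(1, params@blinkOnRate)
      if (t >= horizon) break
      dark <- rexp(1, params@blinkOffRate)
      blinks <- rbind(blinks,
                      data.frame(start = t, end = min(t + dark, horizon)))
      t <- t + dark
    }
  }
  list(donorBleach = td, acceptorBleach = ta, blinks = blinks)
}

# Channel-noise-induced SD of the computed FRET efficiency at efficiency E,
# after bleed-through correction (error propagation, first order).
.channelFretSd <- function(E, params) {
  (params@noiseSd / params@brightness) *
    sqrt((1 - E)^2 * (1 + params@bleedthrough^2) + E^2)
}

# Fraction of [a, b) overlapped by each frame of length dt (n frames).
.frameOverlap <- function(a, b, n, dt) {
  lo <- pmax(a, (seq_len(n) - 1) * dt)
  hi <- pmin(b, seq_len(n) * dt)
  pmax(hi - lo, 0) / dt
}

#' Render a state path into a two-colour intensity trace
#'
#' Integrates the state path over camera frames (mid-frame transitions give
#' occupancy-weighted FRET), applies photobleaching and blinking, and renders
#' donor/acceptor counts: donor = brightness (1 - E) + noise; acceptor =
#' brightness E + bleedthrough x donor signal + noise. After acceptor bleach
#' the acceptor falls to background and the donor rises (anti-correlation);
#' after donor bleach both channels fall to background.
#'
#' @param path state path from [simulateStatePath()].
#' @param events photophysics events from [applyPhotophysics()].
#' @param scheme the [KineticScheme-class] used for the path.
#' @param photophysics a [PhotophysicsParams-class].
#' @param acquisition an [AcquisitionParams-class].
#' @param seed optional integer seed (noise and FRET jitter).
#' @return list with \code{trace} (data.frame frame, donor, acceptor) and
#'   \code{truth} (data.frame frame, state, fret, plus attributes
#'   \code{bleach_frame_donor}, \code{bleach_frame_acceptor}).
#' @export
renderTrace <- function(path, events, scheme, photophysics,
                        acquisition = acquisitionParams(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dt <- acquisition@frameInterval
  nFrames <- floor(acquisition@observationWindow / dt + 1e-9)
  B <- photophysics@brightness
  beta <- photophysics@bleedthrough

  # occupancy weights: frames x states
  K <- nStates(scheme)
  occ <- matrix(0, nFrames, K)
  for (i in seq_len(nrow(path))) {
    s <- path$state[i]
    occ[, s] <- occ[, s] +
      .frameOverlap(path$entry_time[i], path$exit_time[i], nFrames, dt)
  }
  occ <- occ / pmax(rowSums(occ), 1e-12)
  Emean <- as.numeric(occ %*% scheme@fretMean)

  E <- Emean
  if (photophysics@fretJitter) {
    jitVar <- pmax(scheme@fretSd^2 -
                     .channelFretSd(scheme@fretMean, photophysics)^2, 0)
    frameVar <- as.numeric(occ %*% jitVar)
    E <- E + rnorm(nFrames, 0, sqrt(frameVar))
  }

  # active fractions per frame: both dyes, donor-only (acceptor dark), none
  td <- events$donorBleach
  ta <- events$acceptorBleach
  fDonor <- .frameOverlap(0, min(td, acquisition@observationWindow),
                          nFrames, dt)
  accDarkFrac <- rep(0, nFrames)
  if (is.finite(ta))
    accDarkFrac <- pmax(accDarkFrac,
                        .frameOverlap(ta, acquisition@observationWindow,
                                      nFrames, dt))
  if (nrow(events$blinks))
    for (i in seq_len(nrow(events$blinks)))
      accDarkFrac <- pmin(accDarkFrac +
        .frameOverlap(events$blinks$start[i], events$blinks$end[i],
                      nFrames, dt), 1)
  fBoth <- pmax(pmin(fDonor, 1 - accDarkFrac), 0)
  fDonly <- pmax(fDonor - fBoth, 0)

  donorSig <- B * (fBoth * (1 - E) + fDonly)
  acceptorSig <- B * fBoth * E
  noise <- photophysics@noiseSd
  donor <- donorSig + rnorm(nFrames, 0, noise)
  acceptor <- acceptorSig + beta * donorSig + rnorm(nFrames, 0, noise)

  frameOf <- function(t) if (is.finite(t) && t < acquisition@observationWindow)
    as.integer(floor(t / dt) + 1L) else NA_integer_
  majState <- max.col(occ, ties.method = "first")
  truth <- data.frame(frame = seq_len(nFrames), state = majState,
                      fret = Emean)
  attr(truth, "bleach_frame_donor") <- frameOf(td)
  attr(truth, "bleach_frame_acceptor") <- frameOf(ta)

  list(trace = data.frame(frame = seq_len(nFrames), donor = donor,
                          acceptor = acceptor),
       truth = truth)
}

#' Generate a synthetic smFRET dataset for a condition
#'
#' Draws \code{nTraces} traces from a condition preset. Each trace is
#' independently static (frozen in a state drawn from the stationary
#' distribution) with probability \code{staticFraction}, else dynamic.
#' Dynamic traces start from the stationary distribution; when the scheme has
#' absorbing states (e.g. rapid wild-type translocation into POST), dynamic
#' traces start from the stationary distribution of the transient sub-chain
#' so that the translocation event lies inside the observation window.
#'
#' @param preset a [ConditionPreset-class] or a preset name for
#'   [buildPreset()].
#' @param nTraces number of traces (>= 1).
#' @param seed integer seed; the full dataset is reproducible bit-for-bit.
#' @param photophysics a [PhotophysicsParams-class].
#' @param acquisition an [AcquisitionParams-class].
#' @return a [TraceSet-class] with ground-truth sidecar and manifest.
#' @examples
#' ts <- generateDataset("PRE", nTraces = 3, seed = 1)
#' ts
#' @export
generateDataset <- function(preset, nTraces, seed = 1,
                            photophysics = photophysicsParams(),
                            acquisition = acquisitionParams()) {
  if (is.character(preset)) preset <- buildPreset(preset)
  stopifnot(is(preset, "ConditionPreset"))
  if (!is.numeric(nTraces) || nTraces < 1)
    stop("nTraces must be >= 1")
  nTraces <- as.integer(nTraces)
  set.seed(seed)
  scheme <- preset@scheme
  Q <- rateMatrix(scheme)
  # zero out structurally forbidden transitions
  if (length(preset@forbiddenTransitions)) {
    for (ft in preset@forbiddenTransitions) {
      p <- strsplit(ft, "->", fixed = TRUE)[[1]]
      Q[p[1], p[2]] <- 0
    }
    scheme <- KineticScheme(stateNames(scheme), scheme@fretMean,
                            scheme@fretSd, Q)
  }
  pi <- stationaryDistribution(scheme)
  absorbing <- rowSums(Q) <= 0
  if (any(absorbing) && any(!absorbing)) {
    sub <- Q[!absorbing, !absorbing, drop = FALSE]
    if (nrow(sub) == 1) {
      piStart <- setNames(1, stateNames(scheme)[!absorbing])
    } else {
      subScheme <- KineticScheme(stateNames(scheme)[!absorbing],
                                 scheme@fretMean[!absorbing],
                                 scheme@fretSd[!absorbing], sub)
      piStart <- stationaryDistribution(subScheme)
    }
  } else piStart <- pi

  dur <- acquisition@observationWindow
  traceList <- vector("list", nTraces)
  truthList <- vector("list", nTraces)
  for (i in seq_len(nTraces)) {
    id <- sprintf("trace%04d", i)
    isStatic <- runif(1) < preset@staticFraction
    if (isStatic) {
      s0 <- sample.int(nStates(scheme), 1, prob = pi)
      path <- data.frame(state = s0, entry_time = 0, exit_time = dur)
    } else {
      start <- sample(names(piStart), 1, prob = piStart)
      path <- simulateStatePath(scheme, dur, startState = start)
    }
    ev <- applyPhotophysics(photophysics, dur)
    r <- renderTrace(path, ev, scheme, photophysics, acquisition)
    r$trace$trace_id <- id
    truth <- r$truth
    truth$trace_id <- id
    truth$bleach_frame_donor <- attr(truth, "bleach_frame_donor")
    truth$bleach_frame_acceptor <- attr(truth, "bleach_frame_acceptor")
    truth$is_static <- isStatic
    traceList[[i]] <- r$trace[, c("trace_id", "frame", "donor", "acceptor")]
    truthList[[i]] <- truth[, c("trace_id", "frame", "state", "fret",
                                "bleach_frame_donor",
                                "bleach_frame_acceptor", "is_static")]
  }
  manifest <- list(
    preset = preset@name, n_traces = nTraces, seed = seed,
    frame_interval = acquisition@frameInterval,
    observation_window = acquisition@observationWindow,
    state_names = stateNames(scheme),
    fret_mean = as.numeric(scheme@fretMean),
    fret_sd = as.numeric(scheme@fretSd),
    rate_matrix = as.numeric(Q),
    static_fraction = preset@staticFraction,
    bleach_rate_donor = photophysics@bleachRateDonor,
    bleach_rate_acceptor = photophysics@bleachRateAcceptor,
    bleedthrough = photophysics@bleedthrough,
    noise_sd = photophysics@noiseSd,
    brightness = photophysics@brightness,
    fret_jitter = photophysics@fretJitter
  )
  TraceSet(do.call(rbind, traceList), acquisition@frameInterval,
           do.call(rbind, truthList), manifest)
}
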