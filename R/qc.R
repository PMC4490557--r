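# Trace quality control: bleed-through correction, bleach/blink detection,
# anti-correlation based selection, truncation, smoothing, FRET conversion.
#
# Pipeline order (fixed): bleed-through correction -> bleach detection and
# truncation -> 3-point smoothing -> FRET. Truncating before smoothing keeps
# bleach steps from being smeared into the analyzed window.

#' Correct donor-to-acceptor bleed-through
#'
#' Subtracts a fixed fraction of the donor signal from the acceptor channel:
#' acceptor' = acceptor - beta * donor. The donor channel is unchanged.
#'
#' @param x a [TraceSet-class].
#' @param beta bleed-through coefficient in [0, 1); default 0.13.
#' @return a [TraceSet-class] with corrected acceptor counts.
#' @examples
#' ts <- generateDataset("POST", 1, seed = 1)
#' correctBleedthrough(ts, 0.13)
#' @export
correctBleedthrough <- function(x, beta = 0.13) {
  stopifnot(is(x, "TraceSet"))
  if (!is.numeric(beta) || length(beta) != 1 || beta < 0 || beta >= 1)
    stop("beta must be in [0, 1)")
  tr <- traceData(x)
  tr$acceptor <- tr$acceptor - beta * tr$donor
  initialize(x, traces = tr)
}

#' Centered moving average
#'
#' Smooths a numeric series over an odd window, preserving length. At the
#' edges the window shrinks to the available frames (no padding or
#' extrapolation).
#'
#' @param x numeric vector.
#' @param window odd window width in frames (default 3); 1 is the identity.
#' @return numeric vector of the same length.
#' @export
smoothSeries <- function(x, window = 3) {
  if (window %% 2 != 1 || window < 1) stop("window must be odd and >= 1")
  n <- length(x)
  if (window > n) stop("smoothing window larger than the trace")
  if (window == 1) return(x)
  h <- (window - 1) / 2
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# forward running mean: mean(x[t .. t+k-1]), shrinking at the tail
.runmeanFwd <- function(x, k) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  hi <- pmin(seq_len(n) + k - 1, n)
  (cs[hi + 1] - cs[seq_len(n)]) / (hi - seq_len(n) + 1)
}

# robust per-channel noise SD from first differences, floored for noiseless
# synthetic input
.noiseSd <- function(x) {
  s <- mad(diff(x)) / sqrt(2)
  max(s, 1e-8 + 1e-6 * max(abs(x), 1))
}

#' Detect photobleaching and blinking steps
#'
#' Change-point detection of downward intensity steps. Donor-side events are
#' detected on the total intensity (donor + corrected acceptor), which for a
#' single FRET pair is flat regardless of the FRET state, so FRET transitions
#' do not register; any persistent downward total step is reported, flagged
#' with whether it lands at background (a partial step indicates multiple
#' fluorophores). Acceptor-side events are sustained excursions of the
#' acceptor channel to background (acceptor bleach, or a blink when followed
#' by recovery). Thresholds: step statistic 4x the local noise SD over a
#' 5-frame window, background below 2.5x noise SD sustained for
#' \code{minRun} frames.
#'
#' @param donor,acceptor per-frame counts (acceptor already bleed-through
#'   corrected).
#' @param minRun minimal sustained run at the new level (frames, default 5).
#' @param stepFactor step threshold in local noise SDs (default 4).
#' @param bgFactor background threshold for donor-side steps, in noise SDs
#'   (default 2.5).
#' @param accBgFactor background threshold for the acceptor dark run, in
#'   channel-noise SDs (default 1.5).
#' @return data.frame with columns \code{channel} ("donor"/"acceptor"),
#'   \code{frame} (first frame of the new level) and \code{to_background},
#'   ordered by frame; zero rows when no step is found.
#' @export
detectBleachSteps <- function(donor, acceptor, minRun = 5, stepFactor = 4,
                              bgFactor = 2.5, accBgFactor = 1.5) {
  n <- length(donor)
  stopifnot(length(acceptor) == n)
  if (n < 2 * minRun)
    return(data.frame(channel = character(0), frame = integer(0),
                      to_background = logical(0)))
  total <- donor + acceptor
  sTot <- .noiseSd(total)
  sAcc <- sTot / sqrt(2)      # per-channel noise; FRET jitter cancels in total

  steps <- data.frame(channel = character(0), frame = integer(0),
                      to_background = logical(0))
  # donor-side: persistent downward steps in the total intensity
  w <- minRun
  post <- .runmeanFwd(total, w)
  pre <- rev(.runmeanFwd(rev(total), w))          # mean(total[t-w+1 .. t])
  d <- c(rep(0, 1), post[-1] - pre[-n])           # step at frame t
  cand <- which(d < -stepFactor * sTot)
  if (length(cand)) {
    grp <- cumsum(c(1, diff(cand) > w))
    for (g in unique(grp)) {
      idx <- cand[grp == g]
      t0 <- idx[which.min(d[idx])]
      # skip the step frame itself: it may hold partial (mid-frame) signal
      bg <- mean(total[min(t0 + 2, n):min(t0 + 2 * minRun + 1, n)]) <
        bgFactor * sTot
      steps <- rbind(steps, data.frame(channel = "donor", frame = t0,
                                       to_background = bg))
    }
  }
  # acceptor-side: sustained runs at background
  accRun <- .runmeanFwd(acceptor, 2 * minRun)
  dark <- accRun < accBgFactor * sAcc
  starts <- which(dark & !c(FALSE, dark[-n]))
  if (length(starts))
    steps <- rbind(steps,
                   data.frame(channel = "acceptor", frame = starts,
                              to_background = TRUE))
  steps[order(steps$frame), , drop = FALSE]
}

#' Donor/acceptor anti-correlation statistic
#'
#' Pearson correlation between donor and (corrected) acceptor counts. The
#' statistic is the minimum of the correlation over the pre-bleach window and
#' the correlation over a window straddling the first photophysical event
#' (when one exists): a dynamic trace is anti-correlated throughout, while a
#' static single-pair trace shows its anti-correlated signature at the
#' acceptor bleach step. A constant channel yields NA (undefined).
#'
#' @param donor,acceptor per-frame counts.
#' @param darkFrame frame of the first detected dark event, or NA.
#' @param straddle half-width of the straddling window (frames).
#' @return correlation statistic (numeric, possibly NA).
#' @export
checkAnticorrelation <- function(donor, acceptor, darkFrame = NA,
                                 straddle = 10) {
  n <- length(donor)
  corSafe <- function(a, b) {
    if (length(a) < 3 || sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b)
  }
  end <- if (is.na(darkFrame)) n else max(darkFrame - 1, 1)
  r <- corSafe(donor[1:end], acceptor[1:end])
  if (!is.na(darkFrame)) {
    lo <- max(1, darkFrame - straddle)
    hi <- min(n, darkFrame + straddle)
    r2 <- corSafe(donor[lo:hi], acceptor[lo:hi])
    r <- suppressWarnings(min(r, r2, na.rm = TRUE))
    if (!is.finite(r)) r <- NA_real_
  }
  r
}

#' Select and truncate traces
#'
#' Applies the trace selection rules: traces are truncated at the first
#' photobleaching or blinking event; traces with donor or acceptor lifetime
#' below \code{minLifetime} frames are rejected (\code{short_lifetime});
#' traces with multiple or partial donor-side bleach steps are rejected
#' (\code{multi_step_bleach}); traces failing the anti-correlation criterion
#' and the single-pair total-intensity check are rejected
#' (\code{not_anticorrelated}). Every input trace is accounted for in the
#' report.
#'
#' @param x a [TraceSet-class], bleed-through corrected.
#' @param minLifetime minimal analyzable length in frames (default 10).
#' @param rThreshold anti-correlation acceptance threshold (default -0.3).
#' @param minRun,stepFactor,bgFactor passed to [detectBleachSteps()].
#' @return list with \code{traces} (truncated [TraceSet-class] of accepted
#'   traces) and \code{report} (data.frame trace_id, accepted, reason,
#'   bleach_frame, truncated_length, r).
#' @export
selectAndTruncate <- function(x, minLifetime = 10, rThreshold = -0.3,
                              minRun = 5, stepFactor = 4, bgFactor = 2.5) {
  stopifnot(is(x, "TraceSet"))
  tr <- traceData(x)
  ids <- unique(tr$trace_id)
  keep <- vector("list", length(ids))
  rep_ <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    d <- tr[tr$trace_id == ids[i], ]
    d <- d[order(d$frame), ]
    steps <- detectBleachSteps(d$donor, d$acceptor, minRun = minRun,
                               stepFactor = stepFactor, bgFactor = bgFactor)
    darkFrame <- if (nrow(steps)) min(steps$frame) else NA_integer_
    # drop one extra frame: the frame preceding the detected dark run may
    # hold partial (mid-frame) signal from the bleach event itself
    truncLen <- if (is.na(darkFrame)) nrow(d) else max(darkFrame - 2L, 0L)
    r <- checkAnticorrelation(d$donor, d$acceptor, darkFrame)
    donorSteps <- steps[steps$channel == "donor", , drop = FALSE]
    reason <- NA_character_
    if (truncLen < minLifetime) {
      reason <- "short_lifetime"
    } else if (nrow(donorSteps) >= 2 || any(!donorSteps$to_background)) {
      reason <- "multi_step_bleach"
    } else {
      stable <- .stableSinglePair(d$donor, d$acceptor, truncLen)
      if ((is.na(r) || r > rThreshold) && !stable)
        reason <- "not_anticorrelated"
    }
    accepted <- is.na(reason)
    rep_[[i]] <- data.frame(trace_id = ids[i], accepted = accepted,
                            reason = reason, bleach_frame = darkFrame,
                            truncated_length = truncLen, r = r,
                            stringsAsFactors = FALSE)
    if (accepted) keep[[i]] <- d[seq_len(truncLen), ]
  }
  kept <- do.call(rbind, keep[!vapply(keep, is.null, logical(1))])
  if (is.null(kept))
    kept <- tr[0, ]
  list(traces = TraceSet(kept, frameInterval(x), groundTruth(x), x@manifest),
       report = do.call(rbind, rep_))
}

# single-FRET-pair intensity consistency: corrected total is flat at a
# characteristic positive level (junk/noise-only traces fail)
.stableSinglePair <- function(donor, acceptor, truncLen) {
  idx <- seq_len(max(truncLen - 2, 1))
  total <- donor[idx] + acceptor[idx]
  sPair <- sqrt(.noiseSd(donor[idx])^2 + .noiseSd(acceptor[idx])^2)
  sd(total) <= 3 * sPair && mean(total) > 5 * sPair
}

#' Smooth all traces of a set
#'
#' Applies the centered moving average of [smoothSeries()] per trace to both
#' channels (or to the efficiency for a [FRETTraceSet-class]).
#'
#' @param x a [TraceSet-class] or [FRETTraceSet-class].
#' @param window odd window in frames (default 3).
#' @return object of the same class.
#' @export
smoothTraces <- function(x, window = 3) {
  if (is(x, "TraceSet")) {
    tr <- traceData(x)
    sp <- split(seq_len(nrow(tr)), tr$trace_id)
    for (idx in sp) {
      tr$donor[idx] <- smoothSeries(tr$donor[idx], window)
      tr$acceptor[idx] <- smoothSeries(tr$acceptor[idx], window)
    }
    initialize(x, traces = tr)
  } else if (is(x, "FRETTraceSet")) {
    tr <- traceData(x)
    sp <- split(seq_len(nrow(tr)), tr$trace_id)
    for (idx in sp)
      tr$efficiency[idx] <- smoothSeries(tr$efficiency[idx], window)
    initialize(x, traces = tr, smoothWindow = window)
  } else stop("unsupported class")
}

#' Compute FRET efficiency trajectories
#'
#' E = acceptor / (donor + acceptor) per frame, on bleed-through corrected,
#' truncated traces. Frames with non-positive total intensity are flagged
#' invalid (NA); traces with more than \code{maxInvalid} invalid frames are
#' rejected and reported in the \code{"rejected"} attribute.
#'
#' @param x a [TraceSet-class].
#' @param smoothWindow smoothing already applied (metadata, default 1).
#' @param maxInvalid maximal tolerated fraction of invalid frames (0.05).
#' @return a [FRETTraceSet-class]; attribute \code{rejected} lists trace ids
#'   dropped for excess invalid frames.
#' @export
computeFRET <- function(x, smoothWindow = 1, maxInvalid = 0.05) {
  stopifnot(is(x, "TraceSet"))
  tr <- traceData(x)
  total <- tr$donor + tr$acceptor
  eff <- ifelse(total > 0, tr$acceptor / total, NA_real_)
  out <- data.frame(trace_id = tr$trace_id, frame = tr$frame,
                    efficiency = eff, stringsAsFactors = FALSE)
  invalidFrac <- tapply(is.na(eff), tr$trace_id, mean)
  bad <- names(invalidFrac)[invalidFrac > maxInvalid]
  out <- out[!(out$trace_id %in% bad), ]
  res <- new("FRETTraceSet", traces = out, frameInterval = frameInterval(x),
             smoothWindow = smoothWindow)
  attr(res, "rejected") <- bad
  res
}

#' Run the full trace quality-control chain
#'
#' Bleed-through correction, bleach/blink truncation with the selection
#' rules, smoothing, and FRET conversion, in that fixed order.
#'
#' @param x a raw [TraceSet-class].
#' @param beta bleed-through coefficient (default 0.13).
#' @param smoothWindow smoothing window in frames (default 3).
#' @param minLifetime minimal analyzable length in frames (default 10).
#' @param rThreshold anti-correlation threshold (default -0.3).
#' @return list with \code{fret} (a [FRETTraceSet-class]) and \code{report}
#'   (the QC report data.frame, one row per input trace).
#' @examples
#' ts <- generateDataset("PRE", 5, seed = 2)
#' qc <- runQC(ts)
#' table(qc$report$accepted)
#' @export
runQC <- function(x, beta = 0.13, smoothWindow = 3, minLifetime = 10,
                  rThreshold = -0.3) {
  corrected <- correctBleedthrough(x, beta)
  sel <- selectAndTruncate(corrected, minLifetime = minLifetime,
                           rThreshold = rThreshold)
  smoothed <- smoothTraces(sel$traces, smoothWindow)
  fret <- computeFRET(smoothed, smoothWindow = smoothWindow)
  rejected <- attr(fret, "rejected")
  if (length(rejected)) {
    sel$report$accepted[sel$report$trace_id %in% rejected] <- FALSE
    sel$report$reason[sel$report$trace_id %in% rejected] <- "other"
  }
  list(fret = fret, report = sel$report)
}
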