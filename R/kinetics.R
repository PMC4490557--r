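# Dwell-time kinetics: dwell extraction, exponential fits, photobleaching
# rate estimation, rate correction, and the per-condition rate table.

#' Extract dwell records from idealized traces
#'
#' State sojourns from the merged segments of [idealizedSegments()]. A dwell
#' ending in a transition is complete and carries its destination class; the
#' final dwell of each trace is censored by photobleaching or by the end of
#' the record and carries no destination. A dwell that begins at the trace
#' (or synchronization) start is still complete when it ends in a
#' transition: for an exponential sojourn the residual time is exponential
#' with the same rate. Complete plus censored dwells exactly tile each
#' trace's analyzed window.
#'
#' @param x an [IdealizedTraces-class].
#' @param sync optional sync table from [postsynchronize()]; when given,
#'   only the record from each trace's sync frame on is used.
#' @param qcReport optional QC report; used to label censoring as
#'   \code{"bleach"} (a bleach frame was detected) versus \code{"trace_end"}.
#' @param minDelta,includeFlagged passed to [idealizedSegments()].
#' @return data.frame with columns trace_id, class, level, frames, duration
#'   (s), terminated_by ("transition"/"bleach"/"trace_end"),
#'   destination_class.
#' @export
extractDwells <- function(x, sync = NULL, qcReport = NULL, minDelta = 0.05,
                          includeFlagged = FALSE) {
  seg <- idealizedSegments(x, minDelta, includeFlagged)
  dt <- frameInterval(x)
  if (!is.null(sync)) {
    sf <- setNames(sync$sync_frame, sync$trace_id)
    seg <- seg[seg$trace_id %in% sync$trace_id, ]
    seg <- seg[seg$start_frame >= sf[seg$trace_id], ]
  }
  bleached <- character(0)
  if (!is.null(qcReport))
    bleached <- qcReport$trace_id[!is.na(qcReport$bleach_frame)]
  out <- lapply(split(seg, seg$trace_id), function(s) {
    s <- s[order(s$start_frame), ]
    n <- nrow(s)
    dest <- c(s$class[-1], NA_character_)
    term <- c(rep("transition", n - 1),
              if (s$trace_id[1] %in% bleached) "bleach" else "trace_end")
    data.frame(trace_id = s$trace_id, class = s$class, level = s$level,
               frames = s$len, duration = s$len * dt,
               terminated_by = term, destination_class = dest,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(trace_id = character(0), class = character(0),
                      level = numeric(0), frames = integer(0),
                      duration = numeric(0), terminated_by = character(0),
                      destination_class = character(0))
  rownames(res) <- NULL
  res
}

#' Fit an exponential to a dwell-time histogram
#'
#' Bins dwell durations at the frame interval and fits
#' y = y0 + A exp(-t/tau) by nonlinear least squares. The fit starts from
#' the two-frame minimum dwell (the transition filter's floor) to avoid the
#' truncation artifact at one frame. The reported standard error is the
#' large-sample exponential approximation tau/sqrt(n).
#'
#' @param durations complete dwell durations in seconds.
#' @param frameInterval bin width in seconds.
#' @param minDwells minimal number of dwells for a fit (default 20); with
#'   fewer the fit is refused (\code{insufficient = TRUE}, tau = NA).
#' @param minFrames shortest dwell included, in frames (default 2).
#' @return list with y0, A, tau (s), tauSe, n_dwells, insufficient,
#'   degenerate.
#' @export
fitExponential <- function(durations, frameInterval, minDwells = 20,
                           minFrames = 2) {
  # quantize to frames first, then filter, so the first counted bin is not
  # half-truncated by a continuous-duration cut
  frames <- round(durations / frameInterval)
  frames <- frames[frames >= minFrames]
  durations <- frames * frameInterval
  n <- length(durations)
  if (n < minDwells)
    return(list(y0 = NA_real_, A = NA_real_, tau = NA_real_,
                tauSe = NA_real_, n_dwells = n, insufficient = TRUE,
                degenerate = FALSE))
  if (sd(durations) == 0)
    return(list(y0 = 0, A = n, tau = NA_real_, tauSe = NA_real_,
                n_dwells = n, insufficient = FALSE, degenerate = TRUE))
  maxF <- max(frames)
  t <- (minFrames:maxF) * frameInterval
  y <- tabulate(frames, nbins = maxF)[minFrames:maxF]
  tau0 <- max(mean(durations) - minFrames * frameInterval,
              frameInterval / 2)
  obj <- function(p) {
    yh <- p[1] + exp(p[2]) * exp(-t / exp(p[3]))
    sum((yh - y)^2)
  }
  opt <- optim(c(0, log(max(y) + 1), log(tau0)), obj,
               method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-10))
  tau <- exp(opt$par[3])
  list(y0 = opt$par[1], A = exp(opt$par[2]), tau = tau,
       tauSe = tau / sqrt(n), n_dwells = n, insufficient = FALSE,
       degenerate = FALSE)
}

#' Observed rate from a dwell-time fit
#'
#' k_obs = 1 / tau.
#'
#' @param fit result of [fitExponential()] (or a plain tau value).
#' @return rate in 1/s.
#' @examples
#' rateFromTau(list(tau = 0.125))   # 8 per second
#' @export
rateFromTau <- function(fit) {
  tau <- if (is.list(fit)) fit$tau else fit
  if (is.na(tau) || tau <= 0) return(NA_real_)
  1 / tau
}

#' Estimate photobleaching rates
#'
#' Exponential (censored maximum-likelihood) estimate of the photobleaching
#' rate from pre-bleach trace lengths: events / total observed time, where
#' traces without a detected bleach are censored at their record length.
#' With an [IdealizedTraces-class] given, the estimate is stratified by the
#' class occupied at the bleach point; classes with fewer than
#' \code{minEvents} events fall back to the global rate and are flagged.
#'
#' @param qcReport QC report from [runQC()].
#' @param frameInterval frame interval in seconds.
#' @param idealized optional [IdealizedTraces-class] for stratification.
#' @param minEvents minimal events per class (default 10).
#' @return list with \code{global} (1/s), \code{n_events}, and optionally
#'   \code{byClass} (named vector) and \code{fallback} (classes using the
#'   global rate).
#' @export
estimateBleachRates <- function(qcReport, frameInterval, idealized = NULL,
                                minEvents = 10) {
  events <- !is.na(qcReport$bleach_frame)
  totalTime <- sum(qcReport$truncated_length, na.rm = TRUE) * frameInterval
  if (sum(events) == 0) stop("no bleach events observed")
  global <- sum(events) / totalTime
  out <- list(global = global, n_events = sum(events))
  if (!is.null(idealized)) {
    fr <- traceData(idealized)
    classes <- sort(unique(fr$class[!is.na(fr$class)]))
    byClass <- setNames(rep(global, length(classes)), classes)
    fallback <- character(0)
    for (cl in classes) {
      sub <- fr[!is.na(fr$class) & fr$class == cl, ]
      expo <- nrow(sub) * frameInterval
      lastFrame <- tapply(fr$frame, fr$trace_id, max)
      endClass <- fr$class[match(paste(fr$trace_id, lastFrame[fr$trace_id]),
                                 paste(fr$trace_id, fr$frame))]
      bleachedIds <- qcReport$trace_id[events]
      nEv <- sum(vapply(bleachedIds, function(id) {
        i <- which(fr$trace_id == id)
        length(i) > 0 && !is.na(fr$class[i[which.max(fr$frame[i])]]) &&
          fr$class[i[which.max(fr$frame[i])]] == cl
      }, logical(1)))
      if (nEv >= minEvents && expo > 0) byClass[cl] <- nEv / expo
      else fallback <- c(fallback, cl)
    }
    out$byClass <- byClass
    out$fallback <- fallback
  }
  out
}

#' Correct observed rates for photobleaching and static traces
#'
#' Competing-risk baseline correction k_corr = k_obs - k_bleach(state): a
#' dwell ends either by a conformational transition or by photobleaching, so
#' the observed dwell rate is the sum of the two. Optionally, rates are
#' additionally multiplied by N_dynamic / (N_dynamic + N_static *
#' (1 - exp(-k_obs * T_eff))), down-weighting for apparently static traces
#' that a slow dynamic process would have left static within the analyzable
#' time; this is off by default because the default simulator's static
#' traces are structurally frozen.
#'
#' @param kObs observed rate(s), 1/s.
#' @param kBleach photobleaching rate of the originating state, 1/s.
#' @param nStatic,nDynamic static/dynamic trace counts (for the optional
#'   adjustment).
#' @param Teff mean analyzable trace length in seconds (default the
#'   observation time \code{T}).
#' @param T observation time in seconds (default 33).
#' @param staticAdjust apply the static-trace adjustment (default FALSE).
#' @param floor minimal corrected rate; corrections below it are floored and
#'   flagged (default 1e-3).
#' @return list with \code{k_corr} and \code{flagged} (TRUE where floored).
#' @examples
#' correctRates(4.3, 0.3)$k_corr   # about 4.0
#' @export
correctRates <- function(kObs, kBleach, nStatic = 0, nDynamic = NULL,
                         Teff = T, T = 33, staticAdjust = FALSE,
                         floor = 1e-3) {
  stopifnot(all(kObs >= 0, na.rm = TRUE), all(kBleach >= 0))
  k <- kObs - kBleach
  if (staticAdjust) {
    if (is.null(nDynamic)) stop("nDynamic required for the static adjustment")
    k <- k * nDynamic / (nDynamic + nStatic * (1 - exp(-kObs * Teff)))
  }
  flagged <- !is.na(k) & k < floor
  k[flagged] <- floor
  list(k_corr = k, flagged = flagged)
}

#' Reverse rate from the forward rate and the equilibrium constant
#'
#' k_reverse = k_forward / K_eq, as used for transitions with too few events
#' for a direct dwell-time fit.
#'
#' @param kForward forward rate (1/s).
#' @param keq equilibrium constant (> 0).
#' @return reverse rate (1/s).
#' @examples
#' backCalculateReverseRate(7.9, 6.7)   # 1.2
#' @export
backCalculateReverseRate <- function(kForward, keq) {
  if (any(keq <= 0)) stop("K_eq must be > 0")
  kForward / keq
}

#' Per-condition rate analysis
#'
#' Full dwell-time kinetics for one analyzed condition: per-state pooled
#' exponential dwell fits give the total exit rate of each state; branching
#' fractions over the observed destinations give per-transition rates; the
#' photobleaching rate is subtracted from the total exit rate before
#' branching. In a Markov chain the sojourn duration is independent of the
#' destination, so pooling destinations uses all dwells for tau while the
#' branching fractions carry the per-destination information.
#'
#' @param x an [IdealizedTraces-class].
#' @param sync optional sync table from [postsynchronize()].
#' @param qcReport QC report from [runQC()] (needed for bleach rates); when
#'   NULL the bleach rate is taken as zero.
#' @param window post-synchronization window for populations (frames).
#' @param minDwells minimal dwells per state fit (default 20).
#' @param minDelta,includeFlagged passed to the segment extraction.
#' @return list with \code{populations}, \code{dwells}, \code{fits} (per
#'   state class), \code{rates} (data.frame transition, k_obs, k_corr, n,
#'   k_bleach, insufficient), \code{k_bleach}.
#' @export
analyzeKinetics <- function(x, sync = NULL, qcReport = NULL, window = 45,
                            minDwells = 20, minDelta = 0.05,
                            includeFlagged = FALSE) {
  dt <- frameInterval(x)
  dwells <- extractDwells(x, sync, qcReport, minDelta, includeFlagged)
  pops <- computePopulations(x, sync, window, includeFlagged)
  kb <- if (!is.null(qcReport) && any(!is.na(qcReport$bleach_frame)))
    estimateBleachRates(qcReport, dt)$global else 0

  complete <- dwells[dwells$terminated_by == "transition" &
                       !is.na(dwells$class) &
                       !is.na(dwells$destination_class), ]
  classes <- unique(complete$class)
  fits <- list()
  rateRows <- list()
  for (cl in classes) {
    dcl <- complete[complete$class == cl, ]
    fit <- fitExponential(dcl$duration, dt, minDwells = minDwells)
    fits[[cl]] <- fit
    kTotObs <- rateFromTau(fit)
    kTotCorr <- if (!is.na(kTotObs))
      correctRates(kTotObs, kb)$k_corr else NA_real_
    dests <- table(dcl$destination_class)
    for (dn in names(dests)) {
      frac <- as.numeric(dests[dn]) / nrow(dcl)
      rateRows[[paste(cl, dn)]] <- data.frame(
        transition = paste0(cl, "->", dn),
        from_class = cl, to_class = dn,
        k_obs = frac * kTotObs, k_corr = frac * kTotCorr,
        n = as.integer(dests[dn]), tau = fit$tau, k_bleach = kb,
        insufficient = fit$insufficient, stringsAsFactors = FALSE)
    }
  }
  rates <- do.call(rbind, rateRows)
  if (is.null(rates))
    rates <- data.frame(transition = character(0), from_class = character(0),
                        to_class = character(0), k_obs = numeric(0),
                        k_corr = numeric(0), n = integer(0),
                        tau = numeric(0), k_bleach = numeric(0),
                        insufficient = logical(0))
  rownames(rates) <- NULL
  list(populations = pops, dwells = dwells, fits = fits, rates = rates,
       k_bleach = kb)
}

#' Summarize per-condition analyses into a rate table
#'
#' One row per condition and adjacent state pair: populations, K_eq =
#' P_low/P_high, Delta G = -ln(K_eq) in kBT, corrected rates in both
#' directions with transition counts, and the detailed-balance ratio
#' k_down / (k_up * K_eq) (1 at equilibrium).
#'
#' @param results named list of [analyzeKinetics()] results (names are the
#'   condition labels).
#' @param centers canonical class centers (default lt-FRET).
#' @return data.frame, one row per condition and state pair.
#' @export
summarizeRateTable <- function(results, centers = canonicalCenters("lt")) {
  centers <- sort(centers, decreasing = TRUE)
  rows <- list()
  for (cond in names(results)) {
    res <- results[[cond]]
    pops <- setNames(res$populations$P, res$populations$class)
    present <- names(centers)[names(centers) %in% names(pops)]
    if (length(present) < 2) {
      rows[[cond]] <- data.frame(
        condition = cond, high = present[1] %||% NA_character_,
        low = NA_character_,
        P_high = if (length(present)) pops[present[1]] else NA_real_,
        P_low = NA_real_, Keq = NA_real_, dG_kBT = NA_real_,
        k_down = NA_real_, n_down = NA_integer_, k_up = NA_real_,
        n_up = NA_integer_, balance = NA_real_, stringsAsFactors = FALSE)
      next
    }
    for (i in seq_len(length(present) - 1)) {
      hi <- present[i]; lo <- present[i + 1]
      keq <- computeKeq(pops[hi], pops[lo])
      rt <- res$rates
      kd <- rt[rt$from_class == hi & rt$to_class == lo, ]
      ku <- rt[rt$from_class == lo & rt$to_class == hi, ]
      kDown <- if (nrow(kd)) kd$k_corr[1] else NA_real_
      kUp <- if (nrow(ku)) ku$k_corr[1] else NA_real_
      rows[[paste(cond, hi, lo)]] <- data.frame(
        condition = cond, high = hi, low = lo,
        P_high = as.numeric(pops[hi]), P_low = as.numeric(pops[lo]),
        Keq = as.numeric(keq),
        dG_kBT = if (!is.na(keq) && keq > 0) -log(keq) else NA_real_,
        k_down = kDown, n_down = if (nrow(kd)) kd$n[1] else NA_integer_,
        k_up = kUp, n_up = if (nrow(ku)) ku$n[1] else NA_integer_,
        balance = if (!is.na(kDown) && !is.na(kUp) && !is.na(keq))
          kDown / (kUp * keq) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
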