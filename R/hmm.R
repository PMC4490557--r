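# Per-trace Gaussian HMM idealization with automatic state-number selection
# (EM + BIC by default), Viterbi decoding and canonical-class mapping.

#' Fit a Gaussian hidden Markov model to one FRET trajectory
#'
#' Baum-Welch expectation-maximization with multiple restarts (means
#' initialized at trace quantiles, jittered across restarts), keeping the
#' restart with the best log-likelihood, followed by global Viterbi decoding.
#' The log-likelihood is non-decreasing over EM iterations
#' (\code{logLikTrace}).
#'
#' @param x numeric vector of FRET efficiencies (>= 10 frames).
#' @param K number of states (>= 1).
#' @param nRestarts random restarts (default 5).
#' @param maxIter maximal EM iterations (default 500).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param sdFloor lower bound on emission SDs (default 1e-4).
#' @param nEff effective sample size used in the BIC penalty; defaults to
#'   \code{length(x)}. Pass \code{length(x)/smoothWindow} for smoothed
#'   trajectories whose noise is autocorrelated.
#' @param seed optional integer seed.
#' @return list with elements \code{mean}, \code{sd}, \code{trans},
#'   \code{init} (model parameters, states sorted by decreasing mean),
#'   \code{path} (Viterbi state sequence), \code{logLik}, \code{logLikTrace},
#'   \code{bic}, \code{K}, \code{converged}.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(50, 0.8, 0.05), rnorm(50, 0.4, 0.05))
#' fit <- fitHMM(x, K = 2, seed = 1)
#' fit$mean
#' @export
fitHMM <- function(x, K, nRestarts = 5, maxIter = 500, tol = 1e-6,
                   sdFloor = 1e-4, nEff = length(x), seed = NULL) {
  if (K < 1) stop("K must be >= 1")
  if (length(x) < 10) stop("trace must have at least 10 frames")
  if (!is.null(seed)) set.seed(seed)
  T_ <- length(x)
  if (K == 1) {                       # closed form: no EM needed
    mu <- mean(x)
    s <- max(sd(x) * sqrt((T_ - 1) / T_), sdFloor)
    ll <- sum(dnorm(x, mu, s, log = TRUE))
    return(list(mean = mu, sd = s,
                trans = matrix(1, 1, 1), init = 1,
                path = rep(1L, T_), logLik = ll, logLikTrace = ll,
                bic = -2 * ll + 2 * log(max(nEff, 2)),
                K = 1L, converged = TRUE))
  }
  sd0 <- max(sd(x) * 0.6, 0.02)
  best <- NULL
  for (r in seq_len(max(nRestarts, 1))) {
    mu0 <- as.numeric(quantile(x, probs = (seq_len(K) - 0.5) / K))
    if (r > 1) mu0 <- mu0 + rnorm(K, 0, 0.02)
    A0 <- matrix((1 - 0.95) / max(K - 1, 1), K, K)
    diag(A0) <- if (K > 1) 0.95 else 1
    fit <- .hmm_em_cpp(x, mu0, rep(sd0, K), A0, rep(1 / K, K),
                       maxIter, tol, sdFloor)
    if (is.null(best) || fit$logLik > best$logLik) best <- fit
  }
  ord <- order(best$mean, decreasing = TRUE)
  mean_ <- best$mean[ord]
  sd_ <- best$sd[ord]
  A <- best$trans[ord, ord, drop = FALSE]
  init <- best$init[ord]
  path <- .hmm_viterbi_cpp(x, mean_, sd_, A, init)
  p <- K^2 + 2 * K - 1                  # means, sds, free trans, free init
  list(mean = mean_, sd = sd_, trans = A, init = init, path = path,
       logLik = best$logLik, logLikTrace = best$logLikTrace,
       bic = -2 * best$logLik + p * log(max(nEff, 2)),
       K = K, converged = best$converged)
}

#' Select the number of HMM states
#'
#' Fits models with K = 1, ..., \code{Kmax} states and selects by BIC,
#' with an autocorrelation guard against smoothing artifacts. A moving
#' average over \code{smoothWindow} frames autocorrelates the noise over
#' exactly \code{smoothWindow - 1} lags, which a hidden Markov model
#' mistakes for slow state structure, inflating the state count on genuinely
#' static traces. A static trace has zero autocorrelation at lags >=
#' \code{smoothWindow}, while real dwell structure keeps it positive there;
#' and on the decimated series (every \code{smoothWindow}-th frame,
#' approximately independent) a static trace is unimodal while real states
#' stay separated. A trace is deemed static — K = 1 returned — only when
#' both guards agree: the mean autocorrelation over lags
#' \code{smoothWindow..smoothWindow + 2} is not significantly positive
#' (z < 3) and the decimated BIC (averaged over the interleaved phases)
#' prefers K = 1 over K = 2. Otherwise the number of states is chosen by
#' BIC with effective sample size length(x)/smoothWindow; the choice may
#' include one interior camera-blur state, which sharpens dwell boundaries
#' and is re-absorbed by canonical mapping.
#'
#' @param x numeric vector of FRET efficiencies.
#' @param Kmax maximal number of states considered (expected states + 1).
#' @param smoothWindow smoothing window already applied to \code{x}.
#' @param seed optional integer seed.
#' @param ... passed to [fitHMM()].
#' @return list with \code{K} (selected), \code{fit} (the selected model,
#'   possibly including one interior blur state), \code{bic} (per-K vector
#'   at full resolution), \code{static_guard} (TRUE when the guard forced
#'   K = 1).
#' @export
selectModel <- function(x, Kmax, smoothWindow = 1, seed = NULL, ...) {
  if (Kmax < 1) stop("Kmax must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  w <- max(smoothWindow, 1)
  nEff <- max(length(x) / w, 2)
  fits <- lapply(seq_len(Kmax), function(K)
    fitHMM(x, K, nEff = nEff, ...))
  bic <- vapply(fits, `[[`, numeric(1), "bic")
  kBest <- which.min(bic)
  guard <- FALSE
  if (kBest > 1 && w > 1 && length(x) >= 10 * w) {
    n <- length(x)
    lags <- w:(w + 2)
    xc <- x - mean(x)
    v <- sum(xc^2)
    ac <- vapply(lags, function(l)
      sum(xc[seq_len(n - l)] * xc[-seq_len(l)]) / v, numeric(1))
    z <- mean(ac) * sqrt(3 * n)
    if (z < 3) {
      dec <- rowMeans(vapply(seq_len(w), function(ph) {
        xd <- x[seq(ph, n, by = w)]
        vapply(1:2, function(K)
          fitHMM(xd, K, nEff = length(xd), ...)$bic, numeric(1))
      }, numeric(2)))
      if (dec[1] < dec[2]) {
        kBest <- 1L
        guard <- TRUE
      }
    }
  }
  list(K = kBest, fit = fits[[kBest]], bic = bic, static_guard = guard)
}

#' Assess idealization quality
#'
#' Flags trajectories that are poorly idealized: a fitted state occupied by
#' fewer than \code{minFrames} decoded frames, an excess fraction of frames
#' with standardized residuals beyond 3 fitted SDs, residual autocorrelation
#' beyond the smoothing horizon (drift or other non-piecewise-constant
#' structure), or non-convergence of the EM fit.
#'
#' @param x the fitted FRET trajectory.
#' @param fit a model from [fitHMM()].
#' @param minFrames minimal decoded frames per state (default 2).
#' @param maxResidFrac maximal tolerated fraction of |residual| > 3 SD
#'   frames (default 0.01).
#' @param smoothWindow smoothing window applied to \code{x}; residual
#'   autocorrelation is checked at this lag, where a moving average of that
#'   width leaves white noise uncorrelated (default 1).
#' @param maxResidAcf maximal residual autocorrelation at the smoothing lag
#'   (default 0.3).
#' @return character vector of flags (empty when the fit is acceptable).
#' @export
assessFit <- function(x, fit, minFrames = 2, maxResidFrac = 0.01,
                      smoothWindow = 1, maxResidAcf = 0.3) {
  flags <- character()
  counts <- tabulate(fit$path, nbins = fit$K)
  if (any(counts < minFrames)) flags <- c(flags, "sparse_state")
  resid <- (x - fit$mean[fit$path]) / fit$sd[fit$path]
  if (mean(abs(resid) > 3) > maxResidFrac) flags <- c(flags, "residuals")
  lag <- max(smoothWindow, 1)
  if (length(resid) > 3 * lag && sd(x - fit$mean[fit$path]) > 1e-6) {
    ac <- cor(resid[seq_len(length(resid) - lag)],
              resid[-seq_len(lag)])
    if (!is.na(ac) && ac > maxResidAcf)
      flags <- c(flags, "correlated_residuals")
  }
  if (!fit$converged) flags <- c(flags, "not_converged")
  flags
}

#' Map fitted levels to canonical FRET classes
#'
#' Assigns each fitted emission level to the nearest canonical class center
#' if within \code{tol}, else \code{NA} (unassigned).
#'
#' @param levels numeric vector of fitted emission means.
#' @param centers named numeric vector of class centers (default
#'   \code{canonicalCenters("lt")}); must be distinct by >= 0.1.
#' @param tol assignment half-width (default 0.1).
#' @return character vector of class labels (NA where unassigned).
#' @examples
#' mapToCanonical(c(0.76, 0.40, 0.95))
#' @export
mapToCanonical <- function(levels, centers = canonicalCenters("lt"),
                           tol = 0.1) {
  if (length(centers) > 1 && min(dist(centers)) < 0.1)
    stop("canonical centers must be distinct by >= 0.1")
  vapply(levels, function(l) {
    if (is.na(l)) return(NA_character_)
    d <- abs(centers - l)
    i <- which.min(d)
    if (d[i] <= tol) names(centers)[i] else NA_character_
  }, character(1))
}

#' Idealize a set of FRET trajectories
#'
#' Per-trace HMM fitting with state-number selection, Viterbi decoding,
#' quality assessment and canonical-class mapping.
#'
#' @param x a [FRETTraceSet-class].
#' @param Kmax maximal states per trace (default 4; use expected states + 1
#'   when the condition is known).
#' @param centers canonical class centers (default lt-FRET).
#' @param nRestarts EM restarts per K (default 5).
#' @param seed integer seed governing all restarts (default 1).
#' @param ... passed to [fitHMM()] via [selectModel()].
#' @return an [IdealizedTraces-class]. Traces with an unmappable fitted
#'   level are flagged \code{unmapped_level}; flagged traces are excluded by
#'   the downstream transition/kinetics steps by default.
#'
#' @details Two decodings are stored per trace. The selected model may
#'   include one interior "blur" state that absorbs camera-integration
#'   frames between two genuine levels; its decoding (\code{state},
#'   \code{level}, \code{class}) gives the sharpest dwell boundaries and
#'   drives transitions and kinetics. For occupancy-based populations a
#'   blur state is a bias (its frames all fall into whichever class covers
#'   the gap), so a second, physical decoding (\code{state_phys},
#'   \code{level_phys}, \code{class_phys}) refits the trace with exactly
#'   one state per represented canonical class; its Viterbi path splits
#'   integration frames at the likelihood midpoint, which is unbiased.
#' @export
idealizeTraces <- function(x, Kmax = 4, centers = canonicalCenters("lt"),
                           nRestarts = 5, seed = 1, ...) {
  stopifnot(is(x, "FRETTraceSet"))
  set.seed(seed)
  tr <- traceData(x)
  ids <- unique(tr$trace_id)
  frames <- vector("list", length(ids))
  models <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    d <- tr[tr$trace_id == ids[i], ]
    d <- d[order(d$frame), ]
    e <- d$efficiency
    ok <- !is.na(e)
    sel <- selectModel(e[ok], Kmax = Kmax, smoothWindow = x@smoothWindow,
                       nRestarts = nRestarts, ...)
    fit <- sel$fit
    flags <- assessFit(e[ok], fit, smoothWindow = x@smoothWindow)
    level <- rep(NA_real_, nrow(d))
    state <- rep(NA_integer_, nrow(d))
    state[ok] <- fit$path
    level[ok] <- fit$mean[fit$path]
    cls <- mapToCanonical(fit$mean, centers)
    if (anyNA(cls)) flags <- c(flags, "unmapped_level")
    # physical decoding: one state per represented canonical class
    kPhys <- length(unique(cls[!is.na(cls)]))
    physFit <- if (kPhys >= 1 && kPhys < fit$K)
      fitHMM(e[ok], kPhys, nEff = max(length(e[ok]) / x@smoothWindow, 2),
             nRestarts = nRestarts, ...)
      else fit
    clsPhys <- mapToCanonical(physFit$mean, centers)
    statePhys <- rep(NA_integer_, nrow(d))
    levelPhys <- rep(NA_real_, nrow(d))
    statePhys[ok] <- physFit$path
    levelPhys[ok] <- physFit$mean[physFit$path]
    frames[[i]] <- data.frame(trace_id = ids[i], frame = d$frame,
                              state = state, level = level,
                              class = ifelse(is.na(state), NA_character_,
                                             cls[state]),
                              state_phys = statePhys,
                              level_phys = levelPhys,
                              class_phys = ifelse(is.na(statePhys),
                                                  NA_character_,
                                                  clsPhys[statePhys]),
                              stringsAsFactors = FALSE)
    models[[i]] <- data.frame(trace_id = ids[i], K = fit$K,
                              logLik = fit$logLik, bic = fit$bic,
                              converged = fit$converged,
                              flagged = length(flags) > 0,
                              flag_reason = paste(flags, collapse = ";"),
                              stringsAsFactors = FALSE)
  }
  new("IdealizedTraces", frames = do.call(rbind, frames),
      models = do.call(rbind, models), frameInterval = frameInterval(x),
      canonicalCenters = centers)
}
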