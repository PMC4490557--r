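# FRET population analysis: histograms, post-synchronized contour matrices,
# Gaussian mixture fits, state populations, equilibrium constants and free
# energies in kBT.

#' Build a FRET histogram
#'
#' Pools FRET efficiencies into a histogram over \code{range} (default
#' [-0.1, 1.1], bin width 0.025). With a sync table from
#' [postsynchronize()], only the first \code{window} frames after the
#' synchronization point are pooled (frames beyond a trace's bleach are
#' simply absent). With \code{timeResolved = TRUE} a matrix of aligned frame
#' x FRET bin is returned as well (the contour-plot matrix).
#'
#' @param x a [FRETTraceSet-class].
#' @param sync optional sync table (data.frame trace_id, sync_frame).
#' @param window number of post-synchronization frames pooled (default 45,
#'   i.e. 1.5 s at 33 ms); ignored when \code{sync} is NULL.
#' @param binWidth histogram bin width in FRET units (default 0.025).
#' @param range histogram range (default c(-0.1, 1.1)).
#' @param timeResolved also return the aligned-frame x bin matrix.
#' @return list with \code{breaks}, \code{mids}, \code{counts},
#'   \code{n_frames}, and optionally \code{matrix}.
#' @export
buildHistogram <- function(x, sync = NULL, window = 45, binWidth = 0.025,
                           range = c(-0.1, 1.1), timeResolved = FALSE) {
  stopifnot(is(x, "FRETTraceSet"))
  tr <- traceData(x)
  aligned <- NULL
  if (!is.null(sync)) {
    sf <- setNames(sync$sync_frame, sync$trace_id)
    tr <- tr[tr$trace_id %in% sync$trace_id, ]
    aligned <- tr$frame - sf[tr$trace_id]
    keep <- aligned >= 0 & aligned < window
    tr <- tr[keep, ]
    aligned <- aligned[keep]
  }
  e <- tr$efficiency
  ok <- !is.na(e) & e >= range[1] & e <= range[2]
  e <- e[ok]
  breaks <- seq(range[1], range[2], by = binWidth)
  if (breaks[length(breaks)] < range[2]) breaks <- c(breaks, range[2])
  counts <- if (length(e))
    as.integer(table(cut(e, breaks, include.lowest = TRUE)))
    else integer(length(breaks) - 1)
  out <- list(breaks = breaks, mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
              counts = counts, n_frames = length(e))
  if (timeResolved) {
    idx <- if (is.null(aligned)) tr$frame[ok] - 1 else aligned[ok]
    nT <- if (is.null(aligned)) max(idx, 0) + 1 else window
    m <- matrix(0L, nT, length(breaks) - 1,
                dimnames = list(seq_len(nT) - 1, NULL))
    bin <- as.integer(cut(e, breaks, include.lowest = TRUE))
    for (i in seq_along(e))
      if (idx[i] >= 0 && idx[i] < nT) m[idx[i] + 1, bin[i]] <-
          m[idx[i] + 1, bin[i]] + 1L
    out$matrix <- m
  }
  out
}

#' Fit a sum of Gaussians to a FRET histogram
#'
#' Unweighted least squares of the binned density against a sum of Gaussian
#' components (Nelder-Mead, the analogue of an unconstrained nonlinear
#' minimization). Components collapsing below \code{sdFloor} are refit
#' against the floor and flagged.
#'
#' @param hist histogram from [buildHistogram()].
#' @param nComponents number of Gaussian components (>= 1).
#' @param init optional list with numeric vectors \code{mean}, \code{sd},
#'   \code{weight}; defaults to canonical-center-like spread means, SD 0.1,
#'   equal weights.
#' @param sdFloor minimal component SD (default 0.01).
#' @return list with \code{components} (data.frame mean, sd, weight, sorted
#'   by mean), \code{residual} (residual norm of the density fit) and
#'   \code{flagged} (TRUE when a component hit the SD floor).
#' @examples
#' set.seed(1)
#' x <- new("FRETTraceSet",
#'          traces = data.frame(trace_id = "t", frame = 1:2000,
#'                              efficiency = rnorm(2000, 0.4, 0.09)),
#'          frameInterval = 0.033, smoothWindow = 1)
#' h <- buildHistogram(x)
#' fitGaussianMixture(h, 1)$components
#' @export
fitGaussianMixture <- function(hist, nComponents, init = NULL,
                               sdFloor = 0.01) {
  if (nComponents < 1) stop("nComponents must be >= 1")
  if (sum(hist$counts) == 0) stop("empty histogram")
  binWidth <- diff(hist$breaks[1:2])
  dens <- hist$counts / (sum(hist$counts) * binWidth)
  if (is.null(init)) {
    qs <- (seq_len(nComponents) - 0.5) / nComponents
    cum <- cumsum(dens) / sum(dens)
    init <- list(mean = vapply(qs, function(q)
                   hist$mids[which.min(abs(cum - q))], numeric(1)),
                 sd = rep(0.1, nComponents),
                 weight = rep(1 / nComponents, nComponents))
  }
  par0 <- c(init$mean, log(pmax(init$sd - sdFloor, 1e-3)),
            log(pmax(init$weight, 1e-6)))
  obj <- function(p) {
    mu <- p[seq_len(nComponents)]
    s <- sdFloor + exp(p[nComponents + seq_len(nComponents)])
    w <- exp(p[2 * nComponents + seq_len(nComponents)])
    fit <- rowSums(vapply(seq_len(nComponents), function(i)
      w[i] * dnorm(hist$mids, mu[i], s[i]), numeric(length(hist$mids))))
    sum((fit - dens)^2)
  }
  opt <- optim(par0, obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-10))
  mu <- opt$par[seq_len(nComponents)]
  s <- sdFloor + exp(opt$par[nComponents + seq_len(nComponents)])
  w <- exp(opt$par[2 * nComponents + seq_len(nComponents)])
  ord <- order(mu)
  list(components = data.frame(mean = mu[ord], sd = s[ord],
                               weight = w[ord]),
       residual = sqrt(opt$value),
       flagged = any(s <= sdFloor * 1.01))
}

#' Compute relative state populations
#'
#' Relative population P of each canonical class as the fraction of analyzed
#' frames the class occupies, either over the whole record or over the first
#' \code{window} frames after post-synchronization. Populations sum to 1
#' over the occupied classes.
#'
#' By default occupancy is counted on the physical decoding of
#' [idealizeTraces()] (one fitted state per represented canonical class):
#' the blur-augmented decoding that sharpens dwell boundaries for kinetics
#' systematically drops camera-integration frames into whichever class
#' covers the gap between two genuine levels, which inflates intermediate
#' classes, whereas the physical Viterbi path splits those frames at the
#' likelihood midpoint.
#'
#' @param x an [IdealizedTraces-class].
#' @param sync optional sync table from [postsynchronize()].
#' @param window post-synchronization window in frames (default 45).
#' @param includeFlagged keep flagged traces (default FALSE).
#' @param usePhysical count occupancy on the physical decoding when present
#'   (default TRUE).
#' @return data.frame with columns class, n_frames, P (sorted by decreasing
#'   class center).
#' @export
computePopulations <- function(x, sync = NULL, window = 45,
                               includeFlagged = FALSE, usePhysical = TRUE) {
  stopifnot(is(x, "IdealizedTraces"))
  fr <- traceData(x)
  if (usePhysical && "class_phys" %in% names(fr)) fr$class <- fr$class_phys
  if (!includeFlagged && nrow(modelSummary(x))) {
    bad <- modelSummary(x)$trace_id[modelSummary(x)$flagged]
    fr <- fr[!(fr$trace_id %in% bad), ]
  }
  if (!is.null(sync)) {
    sf <- setNames(sync$sync_frame, sync$trace_id)
    fr <- fr[fr$trace_id %in% sync$trace_id, ]
    aligned <- fr$frame - sf[fr$trace_id]
    fr <- fr[aligned >= 0 & aligned < window, ]
  }
  fr <- fr[!is.na(fr$class), ]
  centers <- sort(x@canonicalCenters, decreasing = TRUE)
  n <- table(factor(fr$class, levels = names(centers)))
  n <- n[n > 0]
  total <- sum(n)
  data.frame(class = names(n), n_frames = as.integer(n),
             P = if (total > 0) as.numeric(n) / total else NA_real_,
             stringsAsFactors = FALSE)
}

#' Equilibrium constant from two state populations
#'
#' K_eq = P_S2 / P_S1. Undefined (NA) when P_S1 is zero.
#'
#' @param pS1 population of the first state (the denominator).
#' @param pS2 population of the second state.
#' @return numeric K_eq (NA when undefined).
#' @examples
#' computeKeq(0.13, 0.87)   # 6.7
#' @export
computeKeq <- function(pS1, pS2) {
  ifelse(pS1 > 0, pS2 / pS1, NA_real_)
}

#' Free-energy difference in kBT units
#'
#' Delta G = -ln(K_eq) in units of kBT; negative values favour the second
#' (forward) state.
#'
#' @param keq equilibrium constant (> 0).
#' @return numeric Delta G in kBT.
#' @examples
#' computeDeltaG(6.7)   # -1.90 kBT
#' @export
computeDeltaG <- function(keq) {
  if (any(!is.na(keq) & keq <= 0)) stop("K_eq must be > 0")
  -log(keq)
}
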