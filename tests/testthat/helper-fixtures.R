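# Shared fixtures: noiseless renderer settings, hand-built idealized traces,
# and an independent stationary-distribution oracle.

noiselessPhysics <- function(bleachDonor = 0, bleachAcceptor = 0,
                             beta = 0.13) {
  photophysicsParams(bleachRateDonor = bleachDonor,
                     bleachRateAcceptor = bleachAcceptor,
                     bleedthrough = beta, noiseSd = 0, fretJitter = FALSE)
}

# independent oracle: stationary distribution by power iteration of the
# uniformized transition kernel (no linear algebra shared with the package)
stationaryOracle <- function(Q) {
  diag(Q) <- 0
  G <- Q
  diag(G) <- -rowSums(Q)
  u <- max(rowSums(Q)) * 2 + 1
  P <- diag(nrow(Q)) + G / u
  for (i in 1:60) {
    P <- P %*% P
    P <- P / rowSums(P)        # keep the kernel stochastic numerically
  }
  as.numeric(P[1, ])
}

# build an IdealizedTraces object from per-trace vectors of levels
makeIdealized <- function(levelsList, centers = canonicalCenters("lt"),
                          dt = 0.033) {
  frames <- do.call(rbind, lapply(names(levelsList), function(id) {
    lv <- levelsList[[id]]
    data.frame(trace_id = id, frame = seq_along(lv),
               state = as.integer(factor(lv, levels = unique(lv))),
               level = lv,
               class = mapToCanonical(lv, centers),
               stringsAsFactors = FALSE)
  }))
  models <- data.frame(trace_id = names(levelsList),
                       K = vapply(levelsList, function(l)
                         length(unique(l)), integer(1)),
                       logLik = 0, bic = 0, converged = TRUE,
                       flagged = FALSE, flag_reason = "",
                       stringsAsFactors = FALSE)
  new("IdealizedTraces", frames = frames, models = models,
      frameInterval = dt, canonicalCenters = centers)
}

# FRETTraceSet from a list of efficiency vectors
makeFretSet <- function(effList, dt = 0.033, smoothWindow = 1) {
  tr <- do.call(rbind, lapply(names(effList), function(id)
    data.frame(trace_id = rep(id, length(effList[[id]])),
               frame = seq_along(effList[[id]]),
               efficiency = effList[[id]], stringsAsFactors = FALSE)))
  new("FRETTraceSet", traces = tr, frameInterval = dt,
      smoothWindow = smoothWindow)
}

# ground-truth class occupancy of synced traces over the post-sync window,
# computed from the simulator sidecar
truthOccupancy <- function(ts, sync, window = 45) {
  gt <- groundTruth(ts)
  stateNames <- ts@manifest$state_names
  counts <- setNames(numeric(length(stateNames)), stateNames)
  for (i in seq_len(nrow(sync))) {
    g <- gt[gt$trace_id == sync$trace_id[i], ]
    lastObs <- min(g$bleach_frame_donor[1], g$bleach_frame_acceptor[1],
                   Inf, na.rm = TRUE) - 1
    idx <- g$frame >= sync$sync_frame[i] &
      g$frame < sync$sync_frame[i] + window & g$frame <= lastObs
    tabs <- table(g$state[idx])
    counts[as.integer(names(tabs))] <- counts[as.integer(names(tabs))] + tabs
  }
  counts / sum(counts)
}
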