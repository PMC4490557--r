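# Transition filtering, static/dynamic classification and
# post-synchronization of idealized trajectories.

# Merged dwell segments of one trace. Merging order: one-frame dwells are
# absorbed first (into the neighbor with the closer level, ties to the
# earlier dwell), then adjacent segments closer than minDelta in level are
# combined (duration-weighted level), then adjacent segments mapping to the
# same canonical class are combined.
.mergeSegments <- function(frames, levels, classes, centers, minDelta = 0.05,
                           tol = 0.1) {
  r <- rle(levels)
  seg <- data.frame(level = r$values, len = r$lengths)
  seg$start <- cumsum(c(1, seg$len[-nrow(seg)]))

  combineEqual <- function(seg) {
    i <- 1
    while (i < nrow(seg)) {
      if (isTRUE(all.equal(seg$level[i], seg$level[i + 1]))) {
        seg$len[i] <- seg$len[i] + seg$len[i + 1]
        seg <- seg[-(i + 1), , drop = FALSE]
      } else i <- i + 1
    }
    seg$start <- cumsum(c(1, seg$len[-nrow(seg)]))
    seg
  }

  # 1-frame dwells
  repeat {
    ones <- which(seg$len == 1)
    if (!length(ones) || nrow(seg) == 1) break
    i <- ones[1]
    nb <- c(i - 1, i + 1)
    nb <- nb[nb >= 1 & nb <= nrow(seg)]
    d <- signif(abs(seg$level[nb] - seg$level[i]), 9)  # FP-stable ties
    j <- nb[which.min(d)]              # which.min takes the earlier on ties
    seg$len[j] <- seg$len[j] + 1
    seg <- seg[-i, , drop = FALSE]
    seg <- combineEqual(seg)
  }

  # sub-threshold level changes
  repeat {
    if (nrow(seg) == 1) break
    d <- abs(diff(seg$level))
    i <- which(d < minDelta)
    if (!length(i)) break
    i <- i[1]
    w <- seg$len[c(i, i + 1)]
    seg$level[i] <- sum(seg$level[c(i, i + 1)] * w) / sum(w)
    seg$len[i] <- sum(w)
    seg <- seg[-(i + 1), , drop = FALSE]
  }
  seg$start <- cumsum(c(1, seg$len[-nrow(seg)]))
  seg$class <- mapToCanonical(seg$level, centers, tol)

  # same canonical class
  repeat {
    if (nrow(seg) == 1) break
    same <- which(!is.na(seg$class[-nrow(seg)]) & !is.na(seg$class[-1]) &
                    seg$class[-nrow(seg)] == seg$class[-1])
    if (!length(same)) break
    i <- same[1]
    w <- seg$len[c(i, i + 1)]
    seg$level[i] <- sum(seg$level[c(i, i + 1)] * w) / sum(w)
    seg$len[i] <- sum(w)
    seg <- seg[-(i + 1), , drop = FALSE]
  }
  seg$start <- cumsum(c(1, seg$len[-nrow(seg)]))
  seg$start_frame <- frames[seg$start]
  seg$end_frame <- frames[seg$start + seg$len - 1]
  seg[, c("start_frame", "end_frame", "len", "level", "class")]
}

#' Merged dwell segments of idealized traces
#'
#' Applies the transition filters (one-frame dwells merged into the
#' closer-level neighbor; level changes below \code{minDelta} merged into the
#' surrounding dwell; adjacent same-class segments combined) and returns the
#' resulting piecewise-constant segments per trace.
#'
#' @param x an [IdealizedTraces-class].
#' @param minDelta minimal FRET change counted as a transition (default
#'   0.05).
#' @param includeFlagged keep traces flagged as poorly idealized (default
#'   FALSE).
#' @return data.frame with columns trace_id, start_frame, end_frame, len,
#'   level, class.
#' @export
idealizedSegments <- function(x, minDelta = 0.05, includeFlagged = FALSE) {
  stopifnot(is(x, "IdealizedTraces"))
  fr <- traceData(x)
  if (!includeFlagged && nrow(modelSummary(x))) {
    bad <- modelSummary(x)$trace_id[modelSummary(x)$flagged]
    fr <- fr[!(fr$trace_id %in% bad), ]
  }
  ids <- unique(fr$trace_id)
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    d <- fr[fr$trace_id == ids[i], ]
    d <- d[order(d$frame), ]
    d <- d[!is.na(d$level), ]
    if (!nrow(d)) next
    seg <- .mergeSegments(d$frame, d$level, d$class, x@canonicalCenters,
                          minDelta)
    seg$trace_id <- ids[i]
    out[[i]] <- seg[, c("trace_id", "start_frame", "end_frame", "len",
                        "level", "class")]
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(trace_id = character(0), start_frame = integer(0),
                      end_frame = integer(0), len = integer(0),
                      level = numeric(0), class = character(0))
  res
}

#' Extract filtered transition events
#'
#' State changes between the merged segments of [idealizedSegments()].
#' By construction no emitted transition has |delta| < \code{minDelta} and
#' every transition has at least two frames of dwell on both sides.
#'
#' @inheritParams idealizedSegments
#' @return data.frame with columns trace_id, frame (first frame of the new
#'   state), time (s), from_class, to_class, from_level, to_level, delta.
#' @examples
#' ts <- generateDataset("XL", 5, seed = 3)
#' qc <- runQC(ts)
#' ideal <- idealizeTraces(qc$fret, Kmax = 3, seed = 1)
#' head(extractTransitions(ideal))
#' @export
extractTransitions <- function(x, minDelta = 0.05, includeFlagged = FALSE) {
  seg <- idealizedSegments(x, minDelta, includeFlagged)
  dt <- frameInterval(x)
  out <- vector("list", length(unique(seg$trace_id)))
  k <- 0
  for (id in unique(seg$trace_id)) {
    s <- seg[seg$trace_id == id, ]
    if (nrow(s) < 2) next
    k <- k + 1
    i <- seq_len(nrow(s) - 1)
    out[[k]] <- data.frame(
      trace_id = id, frame = s$start_frame[i + 1],
      time = (s$start_frame[i + 1] - 1) * dt,
      from_class = s$class[i], to_class = s$class[i + 1],
      from_level = s$level[i], to_level = s$level[i + 1],
      delta = s$level[i + 1] - s$level[i], stringsAsFactors = FALSE)
  }
  res <- if (k) do.call(rbind, out[seq_len(k)]) else NULL
  if (is.null(res))
    res <- data.frame(trace_id = character(0), frame = integer(0),
                      time = numeric(0), from_class = character(0),
                      to_class = character(0), from_level = numeric(0),
                      to_level = numeric(0), delta = numeric(0))
  res
}

#' Classify traces as static or dynamic
#'
#' A trace is static when it shows no filtered transition within the scope,
#' dynamic otherwise. The scope is the whole record (\code{"all"}), the
#' frames strictly before each trace's synchronization point
#' (\code{"presync"}), or the frames from the synchronization point on
#' (\code{"postsync"}); the transition used for synchronization itself
#' belongs to neither side.
#'
#' @param transitions transition table from [extractTransitions()].
#' @param traceIds character vector of all analyzed trace ids.
#' @param scope one of "all", "presync", "postsync".
#' @param sync sync table from [postsynchronize()] (required for
#'   presync/postsync scopes; traces without a sync point keep their full
#'   record in "presync" scope and are dropped from "postsync" scope).
#' @return data.frame with columns trace_id, label ("static"/"dynamic"),
#'   n_transitions, scope.
#' @export
classifyTraces <- function(transitions, traceIds,
                           scope = c("all", "presync", "postsync"),
                           sync = NULL) {
  scope <- match.arg(scope)
  ids <- as.character(traceIds)
  if (scope != "all") {
    if (is.null(sync)) stop("sync table required for scope '", scope, "'")
    sf <- setNames(sync$sync_frame, sync$trace_id)[transitions$trace_id]
    keepTr <- switch(scope,
      presync = is.na(sf) | transitions$frame < sf,
      postsync = !is.na(sf) & transitions$frame > sf)
    transitions <- transitions[keepTr, , drop = FALSE]
    if (scope == "postsync") ids <- intersect(ids, sync$trace_id)
  }
  n <- table(factor(transitions$trace_id, levels = ids))
  data.frame(trace_id = ids, label = ifelse(n > 0, "dynamic", "static"),
             n_transitions = as.integer(n), scope = scope,
             stringsAsFactors = FALSE)
}

#' Post-synchronize trajectories at the onset of translocation
#'
#' Aligns traces at the first transition from a high-FRET class to a class
#' with canonical center <= \code{threshold} (evaluated on canonical class
#' centers of the idealized trajectory). Traces without such a transition
#' are excluded and reported.
#'
#' @param x an [IdealizedTraces-class].
#' @param threshold FRET threshold defining the low classes (default 0.5).
#' @param minDelta,includeFlagged passed to [extractTransitions()].
#' @return list with \code{sync} (data.frame trace_id, sync_frame),
#'   \code{frames} (data.frame trace_id, aligned_frame, frame, level, class;
#'   aligned_frame 0 is the sync frame) and \code{excluded} (trace ids with
#'   no qualifying transition).
#' @export
postsynchronize <- function(x, threshold = 0.5, minDelta = 0.05,
                            includeFlagged = FALSE) {
  stopifnot(is(x, "IdealizedTraces"))
  centers <- x@canonicalCenters
  tra <- extractTransitions(x, minDelta, includeFlagged)
  fr <- traceData(x)
  if (!includeFlagged && nrow(modelSummary(x))) {
    bad <- modelSummary(x)$trace_id[modelSummary(x)$flagged]
    fr <- fr[!(fr$trace_id %in% bad), ]
  }
  ids <- unique(fr$trace_id)
  qual <- tra[!is.na(tra$to_class) & !is.na(tra$from_class) &
                centers[tra$to_class] <= threshold &
                centers[tra$from_class] > threshold, ]
  sync <- do.call(rbind, lapply(split(qual, qual$trace_id), function(d)
    data.frame(trace_id = d$trace_id[1], sync_frame = min(d$frame),
               stringsAsFactors = FALSE)))
  if (is.null(sync))
    sync <- data.frame(trace_id = character(0), sync_frame = integer(0))
  rownames(sync) <- NULL
  frames <- fr[fr$trace_id %in% sync$trace_id, ]
  if (nrow(frames)) {
    sf <- setNames(sync$sync_frame, sync$trace_id)
    frames$aligned_frame <- frames$frame - sf[frames$trace_id]
    frames <- frames[, c("trace_id", "aligned_frame", "frame", "level",
                         "class")]
  } else {
    frames <- data.frame(trace_id = character(0), aligned_frame = integer(0),
                         frame = integer(0), level = numeric(0),
                         class = character(0))
  }
  list(sync = sync, frames = frames,
       excluded = setdiff(ids, sync$trace_id))
}

#' Tabulate transition types
#'
#' Fractions of the adjacent-class fluctuation types (0.8<->0.6, 0.6<->0.4,
#' 0.4<->0.2 for the lt-FRET classes) among all adjacent-class transitions;
#' other class pairs (e.g. direct 0.6<->0.2 events) are reported separately
#' with \code{fraction = NA}.
#'
#' @param transitions transition table from [extractTransitions()].
#' @param categories list of unordered class pairs to count (default the
#'   three adjacent lt-FRET pairs).
#' @return data.frame with columns category, n, fraction.
#' @export
countTransitionTypes <- function(transitions,
                                 categories = list(c("0.8", "0.6"),
                                                   c("0.6", "0.4"),
                                                   c("0.4", "0.2"))) {
  catLab <- vapply(categories, paste, character(1), collapse = "<->")
  tr <- transitions[!is.na(transitions$from_class) &
                      !is.na(transitions$to_class), , drop = FALSE]
  if (!nrow(tr))
    return(data.frame(category = catLab, n = 0L, fraction = NA_real_))
  pairLab <- vapply(seq_len(nrow(tr)), function(i) {
    p <- sort(c(tr$from_class[i], tr$to_class[i]), decreasing = TRUE)
    paste(p, collapse = "<->")
  }, character(1))
  catLabSorted <- vapply(categories, function(p)
    paste(sort(p, decreasing = TRUE), collapse = "<->"), character(1))
  nCat <- vapply(catLabSorted, function(l) sum(pairLab == l), integer(1))
  total <- sum(nCat)
  out <- data.frame(category = catLab, n = as.integer(nCat),
                    fraction = if (total > 0) nCat / total else NA_real_,
                    stringsAsFactors = FALSE)
  other <- setdiff(unique(pairLab), catLabSorted)
  if (length(other))
    out <- rbind(out, data.frame(category = other,
                                 n = vapply(other, function(l)
                                   sum(pairLab == l), integer(1)),
                                 fraction = NA_real_))
  rownames(out) <- NULL
  out
}
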