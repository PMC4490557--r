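test_that("bleed-through correction is exact and validated", {
  ts <- TraceSet(data.frame(trace_id = "t", frame = 1:12,
                            donor = rep(100, 12), acceptor = rep(50, 12)))
  out <- correctBleedthrough(ts, 0.13)
  expect_equal(traceData(out)$acceptor, rep(37, 12))
  expect_equal(traceData(out)$donor, rep(100, 12))
  expect_identical(traceData(correctBleedthrough(ts, 0)), traceData(ts))
  expect_error(correctBleedthrough(ts, 1), "beta")
  expect_error(correctBleedthrough(ts, -0.1), "beta")
})

test_that("smoothing is a centered moving average with shrinking edges", {
  expect_equal(smoothSeries(c(0, 3, 6), 3), c(1.5, 3, 4.5))
  expect_equal(smoothSeries(c(0, 3, 6), 1), c(0, 3, 6))
  expect_equal(smoothSeries(rep(2, 10), 3), rep(2, 10))
  expect_error(smoothSeries(1:3, 5), "larger")
  expect_error(smoothSeries(1:10, 2), "odd")
  # mean preserved up to edge handling
  set.seed(1)
  x <- rnorm(200)
  expect_lt(abs(mean(smoothSeries(x, 3)) - mean(x)), 0.01)
})

test_that("bleach-step detection finds constructed steps", {
  set.seed(2)
  n <- 300
  # acceptor bleach at frame 120: acceptor to background, donor rises
  donor <- c(rnorm(119, 500, 20), rnorm(n - 119, 1000, 20))
  acceptor <- c(rnorm(119, 500, 20), rnorm(n - 119, 0, 20))
  st <- detectBleachSteps(donor, acceptor)
  acc <- st[st$channel == "acceptor", ]
  expect_equal(nrow(acc), 1)
  expect_lt(abs(acc$frame - 120), 3)

  # no drop: empty result
  expect_equal(nrow(detectBleachSteps(rnorm(n, 500, 20),
                                      rnorm(n, 500, 20))), 0)

  # two-step donor drop (partial then full): two donor-side entries
  donor2 <- c(rnorm(100, 2000, 20), rnorm(100, 1000, 20), rnorm(100, 0, 20))
  acceptor2 <- rnorm(n, 0, 20)
  st2 <- detectBleachSteps(donor2, acceptor2)
  don2 <- st2[st2$channel == "donor", ]
  expect_equal(nrow(don2), 2)
  expect_false(don2$to_background[1])
  expect_true(don2$to_background[2])
})

test_that("anti-correlation statistic behaves as specified", {
  set.seed(3)
  s <- c(rep(300, 50), rep(700, 50), rep(300, 50))
  expect_equal(checkAnticorrelation(s, 1000 - s), -1)
  r <- checkAnticorrelation(rnorm(200, 500, 50), rnorm(200, 500, 50))
  expect_lt(abs(r), 0.3)
  # constant channels: undefined
  expect_true(is.na(checkAnticorrelation(rep(1, 50), rep(2, 50))))
  # dynamic synthetic trace at renderer defaults is clearly anti-correlated
  xl <- buildPreset("XL"); xl@staticFraction <- 0
  ts <- generateDataset(xl, 6, seed = 8)
  cb <- traceData(correctBleedthrough(ts, 0.13))
  rs <- vapply(split(cb, cb$trace_id), function(d) {
    st <- detectBleachSteps(d$donor, d$acceptor)
    dark <- if (nrow(st)) min(st$frame) else NA
    checkAnticorrelation(d$donor, d$acceptor, dark)
  }, numeric(1))
  expect_true(all(rs < -0.3))
})

test_that("selection truncates at the first bleach and reports every trace", {
  set.seed(4)
  mk <- function(id, nLive, nTotal = 400, static = TRUE) {
    live <- if (static) rep(0.5, nLive) else
      rep(rep(c(0.76, 0.56), each = 10), length.out = nLive)
    E <- c(live, rep(NA, nTotal - nLive))
    donor <- ifelse(is.na(E), 0, 1000 * (1 - E)) + rnorm(nTotal, 0, 30)
    acceptor <- ifelse(is.na(E), 0, 1000 * E) + rnorm(nTotal, 0, 30)
    data.frame(trace_id = id, frame = 1:nTotal, donor = donor,
               acceptor = acceptor)
  }
  ts <- TraceSet(rbind(mk("short", 8), mk("long", 300, static = FALSE)))
  sel <- selectAndTruncate(ts)
  rep_ <- sel$report
  expect_setequal(rep_$trace_id, c("short", "long"))
  expect_false(rep_$accepted[rep_$trace_id == "short"])
  expect_equal(rep_$reason[rep_$trace_id == "short"], "short_lifetime")
  long <- rep_[rep_$trace_id == "long", ]
  expect_true(long$accepted)
  expect_lt(abs(long$truncated_length - 300), 3)
  # all rejections carry a reason; accepted traces are >= 10 frames
  expect_true(all(!is.na(rep_$reason[!rep_$accepted])))
  expect_true(all(rep_$truncated_length[rep_$accepted] >= 10))
})

test_that("noiseless QC acceptance decisions match the ground truth", {
  ts <- generateDataset("PRE", 30, seed = 21,
                        photophysics = noiselessPhysics(0.05, 0.05))
  qc <- runQC(ts, beta = 0.13)
  gt <- groundTruth(ts)
  perTrace <- gt[!duplicated(gt$trace_id), ]
  lastObs <- pmin(ifelse(is.na(perTrace$bleach_frame_donor), Inf,
                         perTrace$bleach_frame_donor),
                  ifelse(is.na(perTrace$bleach_frame_acceptor), Inf,
                         perTrace$bleach_frame_acceptor)) - 1
  expectAccept <- lastObs >= 10
  got <- setNames(qc$report$accepted, qc$report$trace_id)
  expect_equal(unname(got[perTrace$trace_id]), unname(expectAccept))
})

test_that("FRET conversion is the intensity ratio with invalid-frame rules", {
  ts <- TraceSet(data.frame(trace_id = "t", frame = 1:12,
                            donor = c(200, 300, 0, rep(200, 9)),
                            acceptor = c(200, 100, 400, rep(200, 9))))
  fret <- computeFRET(ts)
  e <- traceData(fret)$efficiency
  expect_equal(e[1:3], c(0.5, 0.25, 1.0))
  # > 5% invalid frames: trace rejected
  bad <- TraceSet(data.frame(trace_id = "b", frame = 1:10,
                             donor = c(rep(0, 2), rep(200, 8)),
                             acceptor = c(rep(0, 2), rep(200, 8))))
  fret2 <- computeFRET(bad)
  expect_equal(attr(fret2, "rejected"), "b")
  expect_equal(nrow(traceData(fret2)), 0)
})

test_that("full noiseless QC chain reproduces ground-truth FRET", {
  # window 1 (identity smoothing) isolates the arithmetic chain
  ts <- generateDataset("PRE", 6, seed = 31,
                        photophysics = noiselessPhysics(0.05, 0.05))
  qc <- runQC(ts, beta = 0.13, smoothWindow = 1)
  gt <- groundTruth(ts)
  tr <- traceData(qc$fret)
  expect_gt(length(unique(tr$trace_id)), 0)
  for (id in unique(tr$trace_id)) {
    g <- gt[gt$trace_id == id, ]
    f <- tr[tr$trace_id == id, ]
    common <- f$frame[f$frame <= max(g$frame)]
    # drop the frame containing the bleach event itself (partial signal)
    lastFull <- min(g$bleach_frame_donor[1], g$bleach_frame_acceptor[1],
                    Inf, na.rm = TRUE) - 1
    common <- common[common <= lastFull]
    expect_equal(f$efficiency[match(common, f$frame)],
                 g$fret[match(common, g$frame)], tolerance = 1e-12)
  }
})
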