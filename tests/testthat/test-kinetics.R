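test_that("dwell extraction tiles each trace into complete + censored dwells", {
  idl <- makeIdealized(list(
    a = c(rep(0.56, 10), rep(0.40, 20), rep(0.56, 12))))
  dw <- extractDwells(idl)
  expect_equal(nrow(dw), 3)
  expect_equal(dw$frames, c(10, 20, 12))
  expect_equal(dw$terminated_by, c("transition", "transition", "trace_end"))
  expect_equal(dw$destination_class, c("0.4", "0.6", NA))
  # accounting: dwells tile the trace exactly
  expect_equal(sum(dw$frames), 42)

  # static trace: single censored dwell
  dwS <- extractDwells(makeIdealized(list(s = rep(0.56, 30))))
  expect_equal(nrow(dwS), 1)
  expect_true(is.na(dwS$destination_class))

  # bleach labelling via the QC report
  rep_ <- data.frame(trace_id = "a", accepted = TRUE, reason = NA,
                     bleach_frame = 43, truncated_length = 42, r = -1)
  dwB <- extractDwells(idl, qcReport = rep_)
  expect_equal(dwB$terminated_by[3], "bleach")
})

test_that("noiseless round trip reproduces frame-aligned sojourns exactly", {
  # constructed path with sojourns aligned to frame boundaries: the full
  # noiseless chain (render -> QC -> HMM -> filters) must return exactly the
  # constructed dwells
  sch <- buildPreset("PRE")@scheme
  dt <- 0.033
  runs <- c(12, 5, 20, 3, 9, 30)          # frames per sojourn, all >= 2
  states <- rep(c(1, 2), 3)
  bounds <- c(0, cumsum(runs)) * dt
  path <- data.frame(state = states, entry_time = bounds[-length(bounds)],
                     exit_time = bounds[-1])
  ev <- list(donorBleach = Inf, acceptorBleach = Inf,
             blinks = data.frame(start = numeric(0), end = numeric(0)))
  acq <- acquisitionParams(frameInterval = dt,
                           observationWindow = sum(runs) * dt)
  r <- renderTrace(path, ev, sch, noiselessPhysics(), acq)
  r$trace$trace_id <- "t"
  ts <- TraceSet(r$trace, dt)
  qc <- runQC(ts, smoothWindow = 1)
  ideal <- idealizeTraces(qc$fret, Kmax = 2, seed = 1, nRestarts = 3)
  dw <- extractDwells(ideal, includeFlagged = TRUE)
  expect_equal(dw$frames, runs)
  expect_equal(dw$class, rep(c("0.8", "0.6"), 3))

  # CTMC paths with mid-frame events: dwell counts agree with the
  # majority-state oracle within the one-frame blur ambiguity
  pre <- buildPreset("PRE"); pre@staticFraction <- 0
  sim <- generateDataset(pre, 5, seed = 27,
                         photophysics = noiselessPhysics(0.05, 0.05))
  qc2 <- runQC(sim, smoothWindow = 1)
  ideal2 <- idealizeTraces(qc2$fret, Kmax = 2, seed = 1, nRestarts = 3)
  dw2 <- extractDwells(ideal2, includeFlagged = TRUE)
  gt <- groundTruth(sim)
  for (id in unique(dw2$trace_id)) {
    g <- gt[gt$trace_id == id, ]
    lastObs <- min(g$bleach_frame_donor[1], g$bleach_frame_acceptor[1],
                   Inf, na.rm = TRUE) - 1
    rl <- rle(g$state[g$frame <= lastObs])
    nGt <- sum(rl$lengths >= 2)
    nObs <- sum(dw2$trace_id == id)
    expect_lte(abs(nObs - nGt), max(2, 0.2 * nGt))
  }
})

test_that("exponential dwell fits recover the sampling oracle", {
  set.seed(2)
  d <- rexp(1e4, 1 / 0.25)
  fit <- fitExponential(d, frameInterval = 0.033)
  expect_equal(fit$tau, 0.25, tolerance = 0.10 * 0.25 / 0.25)
  expect_equal(rateFromTau(fit), 4, tolerance = 0.4)

  # frame-quantized fast dwells: within 15% (quantization bias documented)
  dq <- round(rexp(1e4, 1 / 0.125) / 0.033) * 0.033
  fitq <- fitExponential(dq, frameInterval = 0.033)
  expect_equal(fitq$tau, 0.125, tolerance = 0.15)

  # refusal and degeneracy
  few <- fitExponential(rexp(5, 1), 0.033)
  expect_true(few$insufficient)
  expect_true(is.na(few$tau))
  same <- fitExponential(rep(0.33, 50), 0.033)
  expect_true(same$degenerate)
})

test_that("rate = 1/tau including the published scale check", {
  expect_equal(rateFromTau(list(tau = 0.125)), 8)
  expect_equal(rateFromTau(list(tau = 1)), 1)
  expect_equal(rateFromTau(list(tau = 0.127)), 7.9, tolerance = 0.01)
  expect_true(is.na(rateFromTau(list(tau = NA_real_))))
})

test_that("exponential fit agrees with the mean-dwell reciprocal", {
  set.seed(3)
  d <- rexp(800, 3)
  fit <- fitExponential(d, frameInterval = 0.033)
  kFit <- rateFromTau(fit)
  kMean <- 1 / (mean(d[d >= 2 * 0.033]) - 2 * 0.033)
  expect_equal(kFit, kMean, tolerance = 0.10)
})

test_that("photobleaching rates are estimated from censored trace lengths", {
  set.seed(4)
  n <- 1000
  tBleach <- rexp(n, 0.1)
  obs <- pmin(tBleach, 33)
  rep_ <- data.frame(trace_id = sprintf("t%d", 1:n), accepted = TRUE,
                     reason = NA,
                     bleach_frame = ifelse(tBleach < 33,
                                           round(obs / 0.033), NA),
                     truncated_length = round(obs / 0.033), r = -1)
  est <- estimateBleachRates(rep_, 0.033)
  expect_equal(est$global, 0.1, tolerance = 0.10)

  # mean trace length ~10 s implies a global rate of ~0.1/s
  expect_equal(1 / est$global, 10, tolerance = 1)

  none <- rep_; none$bleach_frame <- NA
  expect_error(estimateBleachRates(none, 0.033), "no bleach events")
})

test_that("rate correction removes the photobleaching competing risk", {
  expect_equal(correctRates(5, 0)$k_corr, 5)          # identity at k_b = 0
  expect_equal(correctRates(4.3, 0.3)$k_corr, 4.0)

  # simulation: competing exponentials inflate k_obs by k_bleach
  set.seed(5)
  kTrue <- 4; kB <- 0.3
  tTrans <- rexp(5000, kTrue); tBl <- rexp(5000, kB)
  observedDwell <- tTrans[tTrans < tBl]             # dwells ending in transition
  fit <- fitExponential(observedDwell, 0.033)
  kObs <- rateFromTau(fit)
  expect_equal(kObs, kTrue + kB, tolerance = 0.05 * (kTrue + kB))
  expect_equal(correctRates(kObs, kB)$k_corr, kTrue,
               tolerance = 0.05 * kTrue)

  # small bleach rate: correction is a small relative change
  expect_lt(abs(correctRates(8, 0.1)$k_corr - 8) / 8, 0.03)

  # flooring when k_bleach exceeds k_obs
  fl <- correctRates(0.2, 0.5)
  expect_true(fl$flagged)
  expect_gt(fl$k_corr, 0)

  # static-trace adjustment shrinks rates when statics are counted in
  adj <- correctRates(2, 0, nStatic = 50, nDynamic = 50, Teff = 10,
                      staticAdjust = TRUE)
  expect_lt(adj$k_corr, 2)
})

test_that("reverse rates follow k_forward / K_eq at the published precision", {
  expect_equal(round(backCalculateReverseRate(7.9, 6.7), 1), 1.2)
  expect_equal(round(backCalculateReverseRate(6.9, 15.3), 1), 0.5)
  expect_equal(backCalculateReverseRate(3.3, 1), 3.3)
  expect_error(backCalculateReverseRate(1, 0), "> 0")
})

test_that("the rate table summarizes populations, Keq and both directions", {
  xl <- buildPreset("XL")
  ts <- generateDataset(xl, 60, seed = 29)
  qc <- runQC(ts)
  ideal <- idealizeTraces(qc$fret, Kmax = 3, seed = 1, nRestarts = 3)
  ps <- postsynchronize(ideal)
  kin <- analyzeKinetics(ideal, sync = ps$sync, qcReport = qc$report)
  tab <- summarizeRateTable(list(XL = kin))
  row <- tab[tab$high == "0.6" & tab$low == "0.4", ]
  expect_equal(nrow(row), 1)
  # Table-1-shaped quantities at stochastic tolerance
  expect_equal(row$Keq, 6.7, tolerance = 0.15)
  expect_equal(row$P_low / row$P_high, row$Keq)
  expect_equal(row$dG_kBT, -log(row$Keq))
  # detailed balance: k_down/(k_up * Keq) within 20% of 1
  expect_lt(abs(row$balance - 1), 0.2)

  # POST: single population, no rates
  post <- generateDataset("POST", 25, seed = 31)
  qcP <- runQC(post)
  idealP <- idealizeTraces(qcP$fret, Kmax = 2, seed = 1, nRestarts = 3)
  kinP <- analyzeKinetics(idealP, qcReport = qcP$report)
  tabP <- summarizeRateTable(list(POST = kinP))
  expect_equal(nrow(tabP), 1)
  expect_true(is.na(tabP$Keq))
  expect_equal(tabP$P_high, 1)
})

test_that("dwell accounting tiles the analyzed window of simulated traces", {
  ts <- generateDataset("XL", 10, seed = 33)
  qc <- runQC(ts)
  ideal <- idealizeTraces(qc$fret, Kmax = 3, seed = 1, nRestarts = 3)
  dw <- extractDwells(ideal)
  seg <- idealizedSegments(ideal)
  perTraceDw <- tapply(dw$frames, dw$trace_id, sum)
  perTraceSeg <- tapply(seg$len, seg$trace_id, sum)
  expect_equal(perTraceDw, perTraceSeg)
})
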