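test_that("state-path simulation follows the kinetic scheme", {
  sym <- KineticScheme(c("A", "B"), c(0.8, 0.6), c(0.1, 0.1),
                       matrix(c(0, 3, 3, 0), 2, 2))
  path <- simulateStatePath(sym, duration = 2000, seed = 1)
  occ <- tapply(path$exit_time - path$entry_time, path$state, sum)
  occ <- occ / sum(occ)
  # symmetric scheme: 50/50 within 3 SE (SE ~ 1/sqrt(n sojourns))
  se <- 1 / sqrt(nrow(path))
  expect_lt(abs(occ[1] - 0.5), 3 * se)

  # asymmetric: occupancy ratio = k12/k21 (analytic stationary distribution)
  asym <- KineticScheme(c("hi", "lo"), c(0.6, 0.4), c(0.1, 0.1),
                        matrix(c(0, 1.2, 7.9, 0), 2, 2))
  path <- simulateStatePath(asym, duration = 3000, seed = 2)
  occ <- tapply(path$exit_time - path$entry_time, path$state, sum)
  expect_equal(as.numeric(occ[2] / occ[1]), 7.9 / 1.2,
               tolerance = 3 / sqrt(nrow(path)))

  expect_error(simulateStatePath(sym, duration = 0), "> 0")
  # absorbing scheme yields a single sojourn, not an error
  post <- buildPreset("POST")
  p <- simulateStatePath(post@scheme, 1, seed = 1)
  expect_equal(nrow(p), 1)
  expect_equal(p$exit_time, 1)
  # reproducible under fixed seed
  expect_identical(simulateStatePath(asym, 10, seed = 7),
                   simulateStatePath(asym, 10, seed = 7))
})

test_that("sojourn durations are exponential with the scheme's rate", {
  sch <- KineticScheme(c("A", "B"), c(0.8, 0.6), c(0.1, 0.1),
                       matrix(c(0, 4, 4, 0), 2, 2))
  path <- simulateStatePath(sch, duration = 5000, seed = 3)
  d <- (path$exit_time - path$entry_time)[-nrow(path)]   # drop censored tail
  ks <- suppressWarnings(stats::ks.test(d, "pexp", 4))
  expect_gt(ks$p.value, 0.01)
})

test_that("photophysics draws exponential bleach times", {
  none <- applyPhotophysics(noiselessPhysics(), duration = 33)
  expect_identical(none$donorBleach, Inf)
  expect_identical(none$acceptorBleach, Inf)
  expect_equal(nrow(none$blinks), 0)

  set.seed(4)
  pp <- photophysicsParams(bleachRateDonor = 0.1, bleachRateAcceptor = 0)
  t <- replicate(5000, applyPhotophysics(pp, duration = 1e6)$donorBleach)
  expect_equal(mean(t), 10, tolerance = 3 * 10 / sqrt(5000) / 10)
})

test_that("rendering follows the emission model exactly when noiseless", {
  sch <- KineticScheme("S", 0.5, 0.1, matrix(0, 1, 1))
  acq <- acquisitionParams(frameInterval = 0.033, observationWindow = 0.33)
  path <- data.frame(state = 1, entry_time = 0, exit_time = 0.33)
  ev <- list(donorBleach = Inf, acceptorBleach = Inf,
             blinks = data.frame(start = numeric(0), end = numeric(0)))
  r <- renderTrace(path, ev, sch, noiselessPhysics(beta = 0), acq)
  expect_equal(r$trace$donor, rep(500, 10))
  expect_equal(r$trace$acceptor, rep(500, 10))

  # bleed-through adds exactly beta * donor signal
  r13 <- renderTrace(path, ev, sch, noiselessPhysics(beta = 0.13), acq)
  expect_equal(r13$trace$acceptor, rep(500 + 0.13 * 500, 10))

  # mid-frame state change renders the occupancy-weighted FRET
  sch2 <- KineticScheme(c("hi", "lo"), c(0.8, 0.6), c(0.1, 0.1),
                        matrix(0, 2, 2))
  acq1 <- acquisitionParams(frameInterval = 0.033,
                            observationWindow = 0.033)
  path2 <- data.frame(state = c(1, 2), entry_time = c(0, 0.0165),
                      exit_time = c(0.0165, 0.033))
  r2 <- renderTrace(path2, ev, sch2, noiselessPhysics(beta = 0), acq1)
  E <- r2$trace$acceptor / (r2$trace$donor + r2$trace$acceptor)
  expect_equal(E, 0.7)

  # after acceptor bleach the acceptor falls to background, the donor rises
  ev2 <- list(donorBleach = Inf, acceptorBleach = 0.165,
              blinks = data.frame(start = numeric(0), end = numeric(0)))
  r3 <- renderTrace(path, ev2, sch, noiselessPhysics(beta = 0), acq)
  expect_equal(r3$trace$acceptor[7:10], rep(0, 4))
  expect_equal(r3$trace$donor[7:10], rep(1000, 4))
})

test_that("noiseless rendering inverts exactly through the QC arithmetic", {
  set.seed(5)
  pre <- buildPreset("PRE")
  ts <- generateDataset(pre, 4, seed = 11,
                        photophysics = noiselessPhysics(0.05, 0.05))
  corrected <- correctBleedthrough(ts, 0.13)
  fret <- computeFRET(corrected, maxInvalid = 1)
  gt <- groundTruth(ts)
  tr <- traceData(fret)
  for (id in unique(tr$trace_id)) {
    g <- gt[gt$trace_id == id, ]
    lastObs <- min(g$bleach_frame_donor[1], g$bleach_frame_acceptor[1],
                   Inf, na.rm = TRUE) - 1
    f <- tr[tr$trace_id == id & tr$frame <= lastObs, ]
    expect_equal(f$efficiency, g$fret[g$frame <= lastObs],
                 tolerance = 1e-12)
  }
})

test_that("dataset generation is reproducible and honours static fractions", {
  ts1 <- generateDataset("PRE", 3, seed = 42)
  ts2 <- generateDataset("PRE", 3, seed = 42)
  expect_identical(traceData(ts1), traceData(ts2))
  expect_identical(groundTruth(ts1), groundTruth(ts2))
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  writeTraceSet(ts1, d1); writeTraceSet(ts2, d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "traces.tsv"))),
                   unname(tools::md5sum(file.path(d2, "traces.tsv"))))

  ts <- generateDataset("PRE", 400, seed = 1)
  gt <- groundTruth(ts)
  fracStatic <- mean(tapply(gt$is_static, gt$trace_id, `[`, 1))
  expect_lt(abs(fracStatic - 0.5), 3 * sqrt(0.25 / 400))

  one <- generateDataset("POST", 1, seed = 9)
  expect_equal(length(one), 1)
  expect_error(generateDataset("PRE", 0, seed = 1), ">= 1")
})
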