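test_that("transition filters obey the minimum-change and one-frame rules", {
  # level change below 0.05: not a transition
  id1 <- makeIdealized(list(a = c(rep(0.42, 20), rep(0.38, 20))))
  expect_equal(nrow(extractTransitions(id1)), 0)

  # one-frame dwell merged away: 0.6 (20) / 0.4 (1) / 0.6 (15)
  id2 <- makeIdealized(list(a = c(rep(0.6, 20), 0.4, rep(0.6, 15))))
  expect_equal(nrow(extractTransitions(id2)), 0)

  # a clean two-sided transition is emitted once with its delta
  id3 <- makeIdealized(list(a = c(rep(0.6, 20), rep(0.4, 20))))
  tr3 <- extractTransitions(id3)
  expect_equal(nrow(tr3), 1)
  expect_equal(tr3$delta, -0.2)
  expect_equal(tr3$frame, 21)
  expect_equal(tr3$from_class, "0.6")
  expect_equal(tr3$to_class, "0.4")
})

test_that("one-frame dwells merge into the closer-level neighbour", {
  # 0.8 (10) / 0.6 (1) / 0.4 (10): the 0.6 frame is closer to 0.8 by level
  # distance? no: |0.6-0.8| = |0.6-0.4| = 0.2, tie goes to the earlier dwell
  idT <- makeIdealized(list(a = c(rep(0.8, 10), 0.6, rep(0.4, 10))))
  seg <- idealizedSegments(idT)
  expect_equal(seg$len, c(11, 10))
  # closer level wins: 0.8 (10) / 0.55 (1) / 0.4 (10) -> joins 0.4
  idC <- makeIdealized(list(a = c(rep(0.8, 10), 0.55, rep(0.4, 10))))
  segC <- idealizedSegments(idC)
  expect_equal(segC$len, c(10, 11))
})

test_that("no emitted transition violates the filter invariants", {
  ts <- generateDataset("H91A", 15, seed = 13)
  qc <- runQC(ts)
  ideal <- idealizeTraces(qc$fret, Kmax = 4, seed = 1, nRestarts = 3)
  tr <- extractTransitions(ideal)
  seg <- idealizedSegments(ideal)
  expect_true(all(abs(tr$delta) >= 0.05))
  expect_true(all(seg$len >= 2 | tapply(seg$len, seg$trace_id,
                                        length)[seg$trace_id] == 1))
  # noiseless ground-truth agreement: boundary-aligned constructed path
  lv <- c(rep(0.56, 20), rep(0.40, 30), rep(0.56, 12))
  idN <- makeIdealized(list(gt = lv))
  trN <- extractTransitions(idN)
  expect_equal(trN$frame, c(21, 51))
})

test_that("static/dynamic classification counts filtered transitions", {
  ids <- c("s", "d")
  idl <- makeIdealized(list(s = rep(0.56, 40),
                            d = c(rep(0.56, 20), rep(0.40, 20))))
  tr <- extractTransitions(idl)
  cls <- classifyTraces(tr, ids)
  expect_equal(setNames(cls$label, cls$trace_id),
               c(s = "static", d = "dynamic"))
  expect_equal(cls$n_transitions[cls$trace_id == "d"], 1)
})

test_that("classification recovers the simulated static fraction", {
  ts <- generateDataset("PRE", 150, seed = 17)
  qc <- runQC(ts)
  ideal <- idealizeTraces(qc$fret, Kmax = 3, seed = 1, nRestarts = 3)
  tr <- extractTransitions(ideal)
  ok <- setdiff(traceIDs(ideal),
                modelSummary(ideal)$trace_id[modelSummary(ideal)$flagged])
  cls <- classifyTraces(tr, ok)
  gt <- groundTruth(ts)
  # operational truth: a trace is static when its ground-truth path shows no
  # filter-surviving state change before photobleaching (a dynamic molecule
  # bleaching within its first sojourn, or showing only one-frame
  # excursions, is static by the operational definition)
  opStatic <- vapply(cls$trace_id, function(id) {
    g <- gt[gt$trace_id == id, ]
    lastObs <- min(g$bleach_frame_donor[1], g$bleach_frame_acceptor[1],
                   Inf, na.rm = TRUE) - 1
    r <- rle(g$state[g$frame <= lastObs])
    vals <- r$values[r$lengths >= 2]
    length(unique(vals)) <= 1
  }, logical(1))
  agree <- (cls$label == "static") == opStatic
  # overall: bleach-limited short traces (< ~3 s) cannot resolve the 0.2
  # FRET separation at the printed state SDs, capping overall agreement
  expect_gte(mean(agree), 0.90)
  # for traces long enough to carry information, misclassification <= 5%
  len <- setNames(qc$report$truncated_length,
                  qc$report$trace_id)[cls$trace_id]
  expect_gte(mean(agree[len >= 100]), 0.95)
  fracDyn <- mean(cls$label == "dynamic")
  expect_lt(abs(fracDyn - 0.5), 3 * sqrt(0.25 / nrow(cls)) + 0.11)
})

test_that("post-synchronization aligns at the first high-to-low transition", {
  idl <- makeIdealized(list(
    a = c(0.8, 0.8, rep(0.6, 2), rep(0.4, 6)),
    b = rep(0.8, 12),
    c = c(rep(0.6, 5), rep(0.4, 3), rep(0.6, 4), rep(0.2, 5))))
  ps <- postsynchronize(idl)
  expect_equal(ps$sync$sync_frame[ps$sync$trace_id == "a"], 5)
  expect_true("b" %in% ps$excluded)
  # first qualifying transition, not a later one
  expect_equal(ps$sync$sync_frame[ps$sync$trace_id == "c"], 6)
  # aligned frame 0 is a <= 0.5-class frame for every synced trace
  f0 <- ps$frames[ps$frames$aligned_frame == 0, ]
  expect_true(all(canonicalCenters("lt")[f0$class] <= 0.5))

  # POST preset: single state, every trace excluded
  post <- makeIdealized(list(p1 = rep(0.24, 20), p2 = rep(0.24, 15)))
  psPost <- postsynchronize(post)
  expect_equal(nrow(psPost$sync), 0)
  expect_setequal(psPost$excluded, c("p1", "p2"))

  # idempotence: re-running on the same input gives identical alignment
  ps2 <- postsynchronize(idl)
  expect_identical(ps$sync, ps2$sync)
})

test_that("transition types are tabulated within the dynamic population", {
  idl <- makeIdealized(list(
    a = c(rep(0.4, 10), rep(0.24, 10), rep(0.4, 10)),
    b = c(rep(0.56, 10), rep(0.4, 10))))
  tr <- extractTransitions(idl)
  tt <- countTransitionTypes(tr)
  expect_equal(sum(tt$fraction, na.rm = TRUE), 1)
  expect_equal(tt$n[tt$category == "0.4<->0.2"], 2)
  expect_equal(tt$n[tt$category == "0.6<->0.4"], 1)
  # only one category present: its fraction is 1
  one <- countTransitionTypes(tr[tr$from_class == "0.6", ])
  expect_equal(one$fraction[one$category == "0.6<->0.4"], 1)
  # empty transition list: fractions reported as absent
  none <- countTransitionTypes(tr[0, ])
  expect_true(all(is.na(none$fraction)))
})

test_that("structurally forbidden transitions never appear in the output", {
  ts <- generateDataset("EFG_wt", 40, seed = 19)
  qc <- runQC(ts)
  ideal <- idealizeTraces(qc$fret, Kmax = 4, seed = 1, nRestarts = 3)
  tr <- extractTransitions(ideal)
  # no transitions from 0.2 back to 0.6 or 0.8 (re-entry is forbidden), and
  # none into 0.8 from below
  bad <- (tr$from_class == "0.2" & tr$to_class %in% c("0.6", "0.8")) |
    (tr$from_class %in% c("0.6", "0.4", "0.2") & tr$to_class == "0.8")
  expect_lte(mean(bad, na.rm = TRUE), 0.02)
})
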