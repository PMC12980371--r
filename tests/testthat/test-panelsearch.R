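test_that("confusion-matrix metrics match hand-worked examples", {
  # validation cohort called perfectly: 51 positives, 24 negatives
  m <- computeMetrics(tp = 51, fp = 0, fn = 0, tn = 24)
  expect_equal(m$accuracy, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$youden_j, 1)
  # 6 true positives, 3 false alarms among 75 negatives
  m2 <- computeMetrics(tp = 6, fp = 3, fn = 0, tn = 72)
  expect_equal(m2$sensitivity, 1)
  expect_equal(m2$specificity, 0.96)
  expect_equal(m2$accuracy, 78 / 81)
  expect_equal(m2$youden_j, 0.96)
  # no positives at all: sensitivity undefined, never silently 0
  m3 <- computeMetrics(tp = 0, fp = 0, fn = 0, tn = 104)
  expect_true(is.na(m3$sensitivity))
  expect_true(is.na(m3$youden_j))
  expect_equal(m3$specificity, 1)
  expect_error(computeMetrics(-1, 0, 0, 5), "non-negative")
  expect_error(computeMetrics(0, 0, 0, 0), "all-zero")
})

test_that("rank AUC matches hand enumeration and handles ties", {
  # pos {3, 1}, neg {2, 0}: pairs 3>2, 3>0, 1<2, 1>0 -> 3/4
  expect_equal(rocAUC(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  # perfect separation
  expect_equal(rocAUC(c(5, 4, 1, 0), c(TRUE, TRUE, FALSE, FALSE)), 1)
  # all tied -> 1/2
  expect_equal(rocAUC(rep(1, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  # one class absent
  expect_true(is.na(rocAUC(1:3, c(TRUE, TRUE, TRUE))))
})

test_that("threshold optimization follows the midpoint Youden rule", {
  # pos {0.9, 0.4}, neg {0.6, 0.1}: candidates 0.25, 0.5, 0.75 with
  # J = 1+0.5-1, 0.5+0.5-1... hand: th=0.25 -> sens 1, spec 0.5, J 0.5;
  # th=0.5 -> sens 0.5, spec 0.5, J 0; th=0.75 -> sens 0.5, spec 1, J 0.5;
  # ties go to the smallest threshold
  o <- optimizeThreshold(c(0.9, 0.4, 0.6, 0.1),
                         c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(o$threshold, 0.25)
  expect_equal(o$youden_j, 0.5)
  expect_equal(o$gap, 0.3)       # 0.4 - 0.1
  # complete separation: midpoint of the gap, J = 1
  o2 <- optimizeThreshold(c(0.8, 0.9, 0.1, 0.2),
                          c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(o2$threshold, 0.5)
  expect_equal(o2$youden_j, 1)
  expect_equal(o2$gap, 0.6)
  # all scores identical: documented fallback
  o3 <- optimizeThreshold(rep(0.7, 4), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(o3, list(threshold = 0.5, youden_j = 0, gap = 0))
  expect_error(optimizeThreshold(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("single-transcript screening passes exactly the separating rows", {
  labels <- cohortLabels(13, 71)
  m <- makeSeparatedMatrix(nSig = 2, nNoise = 8, labels, shift = 8, seed = 61L)
  m <- rbind(m, FLAT = rep(3, ncol(m)))
  sc <- screenSingleTranscripts(m, labels, seed = 7L)
  expect_setequal(sc$transcript[sc$pass], c("SIG01", "SIG02"))
  expect_true(sc$degenerate[sc$transcript == "FLAT"])
  expect_true(is.na(sc$accuracy[sc$transcript == "FLAT"]))
  expect_true(all(sc$accuracy[!sc$degenerate] <= 1))
  # relaxed floor admits more
  sc2 <- screenSingleTranscripts(m, labels, accuracyFloor = 0.5, seed = 7L)
  expect_gte(sum(sc2$pass), sum(sc$pass))
  # determinism
  sc3 <- screenSingleTranscripts(m, labels, seed = 7L)
  expect_identical(sc3$accuracy, sc$accuracy)
})

test_that("panel enumeration matches closed-form counts", {
  ids <- sprintf("t%02d", 1:14)
  # C(14,3) = 364, C(14,4) = 1001, C(14,5) = 2002 -> 3367
  pn <- enumeratePanels(ids, 3L, 5L)
  expect_length(pn, choose(14, 3) + choose(14, 4) + choose(14, 5))
  expect_true(all(vapply(pn, length, 0L) %in% 3:5))
  expect_equal(anyDuplicated(vapply(pn, paste, "", collapse = "|")), 0L)
  # exactly size_min ids -> a single panel
  expect_length(enumeratePanels(ids[1:3], 3L, 5L), 1L)
  expect_error(enumeratePanels(ids[1:2], 3L, 5L), "fewer passing")
  expect_error(enumeratePanels(sprintf("x%03d", 1:100), 3L, 5L, cap = 1000),
               "exceeds cap")
})

test_that("panel evaluation is training-frozen with no validation leakage", {
  lab_tr <- cohortLabels(13, 71)
  lab_va <- cohortLabels(6, 75)
  tr <- makeSeparatedMatrix(3, 5, lab_tr, seed = 62L)
  va <- makeSeparatedMatrix(3, 5, lab_va, seed = 63L)
  ev <- evaluatePanel(c("SIG01", "SIG02", "SIG03"), tr, va, lab_tr, lab_va,
                      seed = 5L)
  expect_equal(metricsTrain(ev)$accuracy, 1)
  expect_equal(metricsValid(ev)$accuracy, 1)
  expect_true(ev@threshold > 0 && ev@threshold < 1)
  # perturbing validation data must leave the fitted model, state map and
  # threshold bit-identical
  va2 <- va; va2[, lab_va] <- va2[, lab_va] + rnorm(sum(lab_va) * nrow(va))
  ev2 <- evaluatePanel(c("SIG01", "SIG02", "SIG03"), tr, va2, lab_tr, lab_va,
                       seed = 5L)
  expect_identical(stateMeans(ev2@fit), stateMeans(ev@fit))
  expect_identical(ev2@threshold, ev@threshold)
  expect_identical(ev2@stateToClass, ev@stateToClass)
  expect_identical(metricsTrain(ev2), metricsTrain(ev))
  expect_error(evaluatePanel(c("SIG01", "NOPE"), tr, va, lab_tr, lab_va),
               "absent")
})

test_that("representative selection walks the documented ladder", {
  mkEval <- function(ids, acc_tr, acc_va, gap) {
    p <- list(pi = c(0.5, 0.5), A = matrix(0.5, 2, 2),
              mu = matrix(0, 2, length(ids)),
              sigma2 = matrix(1, 2, length(ids)))
    new("PanelEvaluation", transcripts = ids,
        fit = asFit(p, "per_sample", 10L),
        stateToClass = c("positive", "negative"),
        positiveClass = "positive", threshold = 0.5, thresholdGap = gap,
        metricsTrain = computeMetrics(round(10 * acc_tr), 0,
                                      10 - round(10 * acc_tr), 10),
        metricsValid = computeMetrics(round(10 * acc_va), 0,
                                      10 - round(10 * acc_va), 10),
        youdenJ = 1)
  }
  # criterion 1: min(train, valid) accuracy
  e_lo <- mkEval(c("A", "B", "C"), 1.0, 0.8, 0.9)
  e_hi <- mkEval(c("D", "E", "F"), 0.9, 0.9, 0.1)
  sel <- selectRepresentative(list(e_lo, e_hi))
  expect_equal(panelTranscripts(sel), c("D", "E", "F"))
  # criterion 2: larger gap wins at equal accuracy
  g1 <- mkEval(c("A", "B", "C"), 1, 1, 0.2)
  g2 <- mkEval(c("D", "E", "F"), 1, 1, 0.7)
  expect_equal(panelTranscripts(selectRepresentative(list(g1, g2))),
               c("D", "E", "F"))
  # criterion 3: smaller panel at equal accuracy and gap
  s1 <- mkEval(c("A", "B", "C", "D"), 1, 1, 0.5)
  s2 <- mkEval(c("E", "F", "G"), 1, 1, 0.5)
  expect_length(panelTranscripts(selectRepresentative(list(s1, s2))), 3L)
  # criterion 4: fewer unannotated MSTRG IDs
  m1 <- mkEval(c("MSTRG.1", "ENST1", "ENST2"), 1, 1, 0.5)
  m2 <- mkEval(c("ENST3", "ENST4", "ENST5"), 1, 1, 0.5)
  expect_false(any(startsWith(
    panelTranscripts(selectRepresentative(list(m1, m2))), "MSTRG")))
  # criterion 5: lexicographic tie-break, fully deterministic
  l1 <- mkEval(c("B", "C", "D"), 1, 1, 0.5)
  l2 <- mkEval(c("A", "C", "D"), 1, 1, 0.5)
  expect_equal(panelTranscripts(selectRepresentative(list(l1, l2)))[1], "A")
  expect_equal(panelTranscripts(selectRepresentative(list(l2, l1)))[1], "A")
})

test_that("full search recovers a planted panel on the cohort-sized problem", {
  lab_tr <- cohortLabels(13, 71)   # training cohort shape
  lab_va <- cohortLabels(6, 75)    # validation cohort shape
  tr <- makeSeparatedMatrix(3, 40, lab_tr, seed = 64L)
  va <- makeSeparatedMatrix(3, 40, lab_va, seed = 65L)
  res <- searchPanels(tr, va, lab_tr, lab_va, seed = 9L)
  expect_setequal(res$screen$transcript[res$screen$pass],
                  c("SIG01", "SIG02", "SIG03"))
  expect_length(res$evaluations, 1L)    # only one panel of size >= 3
  rep_panel <- res$representative
  expect_setequal(panelTranscripts(rep_panel), c("SIG01", "SIG02", "SIG03"))
  expect_equal(metricsValid(rep_panel)$accuracy, 1)
  expect_equal(metricsValid(rep_panel)$auc, 1)
})
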