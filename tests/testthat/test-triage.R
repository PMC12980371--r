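triageMeta <- function(diag, onset = NULL, nihss = NULL) {
  n <- length(diag)
  data.frame(diagnosis = factor(diag, levels = DIAGNOSIS_LEVELS),
             onset_hours = if (is.null(onset)) rep(NA_real_, n) else onset,
             nihss = if (is.null(nihss)) rep(NA_integer_, n) else nihss,
             row.names = sprintf("s%03d", seq_len(n)))
}

test_that("task label construction honors cutoffs and eligibility", {
  md <- triageMeta(c("hemorrhagic", "ischemic", "ischemic", "mimic", "TIA"),
                   onset = c(1, 3.5, 6, NA, 2),
                   nihss = c(10L, 4L, 5L, 2L, NA))
  h <- buildLabels(md, taskDefinition("hemorrhage_vs_rest"))
  expect_equal(h$eligible, c(TRUE, TRUE, TRUE, TRUE, FALSE))  # TIA out
  expect_equal(h$labels, c(TRUE, FALSE, FALSE, FALSE))
  i <- buildLabels(md, taskDefinition("ischemic_vs_mimic"))
  expect_equal(sum(i$eligible), 3L)
  expect_equal(i$labels, c(TRUE, TRUE, FALSE))
  # window: ischemic-only, missing onset excluded, 3.5 h inclusive
  w <- buildLabels(md, taskDefinition("window_3p5h"))
  expect_equal(which(w$eligible), c(2L, 3L))
  expect_equal(w$labels, c(TRUE, FALSE))    # onset exactly 3.5 is positive
  # severity: NIHSS 5 is severe, 4 is not; missing excluded; ischemic only
  s <- buildLabels(md, taskDefinition("severity_nihss"))
  expect_equal(which(s$eligible), c(2L, 3L))
  expect_equal(s$labels, c(FALSE, TRUE))
  # ischemic_only = FALSE widens eligibility
  w2 <- buildLabels(md, taskDefinition("window_3p5h", ischemic_only = FALSE))
  expect_equal(which(w2$eligible), c(1L, 2L, 3L, 5L))
  # single-class guard
  md1 <- triageMeta(rep("ischemic", 4), onset = rep(1, 4))
  expect_error(buildLabels(md1, taskDefinition("window_3p5h")), "one class")
  expect_silent(buildLabels(md1, taskDefinition("window_3p5h"),
                            require_both = FALSE))
  expect_error(taskDefinition("nope"))
})

# fit the four frozen panel models on planted training data
fitToyModels <- function(seed = 71L) {
  lab_hem <- cohortLabels(13, 71)
  tr_h <- makeSeparatedMatrix(3, 0, lab_hem, seed = seed, prefix = "HEM")
  lab_isc <- cohortLabels(29, 42)
  tr_i <- makeSeparatedMatrix(3, 0, lab_isc, seed = seed + 1, prefix = "ISC")
  lab_win <- cohortLabels(15, 14)
  tr_w <- makeSeparatedMatrix(3, 0, lab_win, seed = seed + 2, prefix = "WIN")
  lab_sev <- cohortLabels(20, 9)
  tr_s <- makeSeparatedMatrix(3, 0, lab_sev, seed = seed + 3, prefix = "SEV")
  list(
    hemorrhage = evaluatePanel(rownames(tr_h), tr_h, tr_h, lab_hem, lab_hem,
                               seed = seed),
    ischemic = evaluatePanel(rownames(tr_i), tr_i, tr_i, lab_isc, lab_isc,
                             seed = seed + 1),
    window = evaluatePanel(rownames(tr_w), tr_w, tr_w, lab_win, lab_win,
                           seed = seed + 2),
    severity = evaluatePanel(rownames(tr_s), tr_s, tr_s, lab_sev, lab_sev,
                             seed = seed + 3))
}

# assemble a cohort expression matrix whose planted panel rows encode the
# intended truth for every stage
toyCohort <- function(diag, onset, nihss, models, seed = 81L) {
  n <- length(diag)
  shiftRows <- function(prefix, flag) {
    withr::with_seed(seed + match(prefix, c("HEM", "ISC", "WIN", "SEV")), {
      m <- matrix(rnorm(3 * n), 3, n,
                  dimnames = list(sprintf("%s%02d", prefix, 1:3),
                                  sprintf("s%03d", 1:n)))
      m[, flag] <- m[, flag] + 8
      m
    })
  }
  expr <- rbind(shiftRows("HEM", diag == "hemorrhagic"),
                shiftRows("ISC", diag == "ischemic"),
                shiftRows("WIN", !is.na(onset) & onset <= 3.5),
                shiftRows("SEV", !is.na(nihss) & nihss >= 5))
  list(expr = expr, md = triageMeta(diag, onset, nihss))
}

test_that("cascade routes samples through the stages as documented", {
  models <- fitToyModels()
  diag <- c(rep("hemorrhagic", 4), rep("ischemic", 10), rep("mimic", 6))
  onset <- c(rep(NA, 4), c(1, 2, 3, 3.5, 4, 6, 8, 2, 1, 5), rep(NA, 6))
  nihss <- c(rep(NA, 4), c(9, 8, 2, 3, 12, 1, 7, 6, 2, 10), rep(NA, 6))
  co <- toyCohort(diag, onset, nihss, models)
  rep1 <- runCascade(co$expr, models, metadata = co$md)
  s <- rep1$samples
  expect_equal(s$stage1_call, ifelse(diag == "hemorrhagic", "hemorrhagic",
                                     "non-hemorrhagic"))
  # stage 2 only on stage-1 negatives
  expect_true(all(is.na(s$stage2_call[diag == "hemorrhagic"])))
  expect_equal(s$stage2_call[diag != "hemorrhagic"],
               ifelse(diag[diag != "hemorrhagic"] == "ischemic", "ischemic",
                      "mimic"))
  # window/severity only on ischemic-called samples
  expect_true(all(is.na(s$window_call[diag != "ischemic"])))
  expect_equal(s$window_call[diag == "ischemic"],
               ifelse(onset[diag == "ischemic"] <= 3.5, "within_window",
                      "beyond_window"))
  expect_equal(s$severity_call[diag == "ischemic"],
               ifelse(nihss[diag == "ischemic"] >= 5, "severe", "minor"))
  # per-stage metrics are perfect on this separable cohort
  expect_equal(rep1$metrics$stage1$accuracy, 1)
  expect_equal(rep1$metrics$stage2$accuracy, 1)
  expect_equal(rep1$metrics$window$accuracy, 1)
  expect_equal(rep1$metrics$severity$accuracy, 1)
  expect_equal(rep1$metrics$stage2$tp, 10)
  expect_equal(rep1$metrics$stage2$tn, 6)
  # unconditional mode scores window/severity on every sample
  rep2 <- runCascade(co$expr, models, metadata = co$md, conditional = FALSE)
  expect_false(any(is.na(rep2$samples$window_call)))
})

test_that("held-out audit tolerates absent classes and empty cohorts", {
  models <- fitToyModels()
  # all-mimic cohort: stage-1 sensitivity undefined, specificity defined
  diag <- rep("mimic", 8)
  co <- toyCohort(diag, rep(NA, 8), rep(NA, 8), models, seed = 91L)
  aud <- heldOutAudit(co$expr, models, metadata = co$md)
  expect_true(is.na(aud$metrics$stage1$sensitivity))
  expect_equal(aud$metrics$stage1$specificity, 1)
  # empty cohort
  empty <- heldOutAudit(co$expr[, 0, drop = FALSE], models,
                        metadata = co$md[0, ])
  expect_equal(nrow(empty$samples), 0L)
  expect_length(empty$metrics, 0L)
})

test_that("triage reports serialize to TSV + JSON and round-trip", {
  models <- fitToyModels()
  diag <- c(rep("hemorrhagic", 3), rep("ischemic", 5), rep("mimic", 4))
  onset <- c(rep(NA, 3), 1, 2, 5, 6, 3, rep(NA, 4))
  nihss <- c(rep(NA, 3), 9L, 2L, 7L, 1L, 6L, rep(NA, 4))
  co <- toyCohort(diag, onset, nihss, models, seed = 95L)
  rep1 <- runCascade(co$expr, models, metadata = co$md)
  dir <- withr::local_tempdir()
  writeTriageReport(rep1, dir)
  tsv <- read.delim(file.path(dir, "calls.tsv"))
  expect_equal(nrow(tsv), 12L)
  expect_equal(tsv$stage1_call, rep1$samples$stage1_call)
  js <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(js$metrics$stage1$accuracy, rep1$metrics$stage1$accuracy)
  expect_equal(js$provenance[[length(js$provenance)]]$step, "cascade")
})

test_that("missing panel transcripts in the cohort are an explicit error", {
  models <- fitToyModels()
  diag <- c(rep("hemorrhagic", 3), rep("ischemic", 3), rep("mimic", 3))
  co <- toyCohort(diag, rep(NA, 9), rep(NA, 9), models, seed = 97L)
  crippled <- co$expr[rownames(co$expr) != "HEM01", ]
  expect_error(runCascade(crippled, models, metadata = co$md),
               "missing panel transcript")
})
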