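#' Binary task definitions for the triage cascade
#'
#' Four tasks are recognized: `hemorrhage_vs_rest` (positive = hemorrhagic),
#' `ischemic_vs_mimic` (positive = ischemic, hemorrhagic samples ineligible),
#' `window_3p5h` (positive = onset within `time_cutoff_h` hours; samples with
#' missing onset are excluded), and `severity_nihss` (positive = NIHSS at or
#' above `nihss_cutoff`; missing NIHSS excluded). The admission window
#' default of 3.5 h is the 4.5 h thrombolysis guideline minus a 60-minute
#' door-to-needle target; NIHSS 5 is assigned to the severe class.
#'
#' @param name one of the four task names.
#' @param time_cutoff_h window cutoff in hours (default 3.5, inclusive).
#' @param nihss_cutoff severity cutoff (default 5; positive iff NIHSS >= 5).
#' @param ischemic_only restrict window/severity tasks to ischemic samples
#'   (default TRUE, the clinical reading).
#' @return list of class `TaskDefinition`.
#' @export
taskDefinition <- function(name = c("hemorrhage_vs_rest", "ischemic_vs_mimic",
                                    "window_3p5h", "severity_nihss"),
                           time_cutoff_h = 3.5, nihss_cutoff = 5L,
                           ischemic_only = TRUE) {
  name <- match.arg(name)
  stopifnot(time_cutoff_h > 0, nihss_cutoff > 0)
  structure(list(name = name, time_cutoff_h = time_cutoff_h,
                 nihss_cutoff = as.integer(nihss_cutoff),
                 ischemic_only = ischemic_only),
            class = "TaskDefinition")
}

#' Build binary labels and eligibility mask for a task
#'
#' @param metadata sample metadata data.frame with `diagnosis`,
#'   `onset_hours`, `nihss` as needed by the task.
#' @param task a [taskDefinition()].
#' @param require_both error when a class is absent after filtering
#'   (default TRUE; held-out audits set FALSE).
#' @return list with `labels` (logical over eligible samples) and `eligible`
#'   (logical mask over all samples).
#' @export
buildLabels <- function(metadata, task, require_both = TRUE) {
  diag <- as.character(metadata$diagnosis)
  eligible <- switch(task$name,
    hemorrhage_vs_rest = diag %in% c("hemorrhagic", "ischemic", "mimic"),
    ischemic_vs_mimic  = diag %in% c("ischemic", "mimic"),
    window_3p5h = !is.na(metadata$onset_hours) &
      (!task$ischemic_only | diag == "ischemic"),
    severity_nihss = !is.na(metadata$nihss) &
      (!task$ischemic_only | diag == "ischemic"))
  labels <- switch(task$name,
    hemorrhage_vs_rest = diag[eligible] == "hemorrhagic",
    ischemic_vs_mimic  = diag[eligible] == "ischemic",
    window_3p5h = metadata$onset_hours[eligible] <= task$time_cutoff_h,
    severity_nihss = metadata$nihss[eligible] >= task$nihss_cutoff)
  if (require_both && (!any(labels) || all(labels)))
    stop("task ", task$name, ": only one class present after filtering")
  list(labels = labels, eligible = eligible)
}

# posterior + call for one frozen panel model on new samples
.applyPanel <- function(eval, log_expression) {
  miss <- setdiff(eval@transcripts, rownames(log_expression))
  if (length(miss))
    stop("missing panel transcript(s): ", paste(miss, collapse = ", "))
  obs <- t(log_expression[eval@transcripts, , drop = FALSE])
  post <- .positivePosterior(forwardBackward(eval@fit, obs)$gamma,
                             eval@stateToClass, eval@positiveClass)
  list(posterior = post, call = post >= eval@threshold)
}

#' Run the hierarchical triage cascade
#'
#' Stage 1 calls hemorrhagic vs rest on every sample; stage 2 (ischemic vs
#' mimic) runs only on stage-1 negatives; the thrombolysis-window and
#' severity classifiers run only on samples called ischemic (set
#' `conditional = FALSE` to score them on all samples for research use).
#' Per-stage cohort metrics are computed against the metadata labels where
#' available; classes absent from the cohort yield `NA` (flagged) rates.
#'
#' @param normalized a [NormalizedStudy-class] (preprocessed with the
#'   training pipeline) or log-expression matrix with `metadata` supplied.
#' @param models named list of [PanelEvaluation-class] models; recognized
#'   names: `hemorrhage`, `ischemic`, `window`, `severity` (the latter two
#'   optional).
#' @param metadata optional metadata data.frame for matrix input.
#' @param conditional gate window/severity on an ischemic call (default TRUE).
#' @param time_cutoff_h,nihss_cutoff truth cutoffs used for cohort metrics.
#' @return list of class `TriageReport`: `samples` (per-sample posteriors and
#'   calls), `metrics` (per stage), `provenance`.
#' @export
runCascade <- function(normalized, models, metadata = NULL,
                       conditional = TRUE, time_cutoff_h = 3.5,
                       nihss_cutoff = 5L) {
  if (is(normalized, "SummarizedExperiment")) {
    expr <- assay(normalized, "logcpm")
    md <- as.data.frame(colData(normalized))
    prov <- if (is(normalized, "NormalizedStudy"))
      normalized@provenance else list()
  } else {
    expr <- normalized; md <- metadata; prov <- list()
  }
  stopifnot(all(c("hemorrhage", "ischemic") %in% names(models)))
  n <- ncol(expr)
  ids <- colnames(expr)
  s1 <- .applyPanel(models$hemorrhage, expr)
  samples <- data.frame(sample = ids,
                        stage1_posterior = s1$posterior,
                        stage1_call = ifelse(s1$call, "hemorrhagic",
                                             "non-hemorrhagic"),
                        stage2_posterior = NA_real_,
                        stage2_call = NA_character_,
                        window_posterior = NA_real_,
                        window_call = NA_character_,
                        severity_posterior = NA_real_,
                        severity_call = NA_character_,
                        stringsAsFactors = FALSE)
  neg1 <- !s1$call
  if (any(neg1)) {
    s2 <- .applyPanel(models$ischemic, expr[, neg1, drop = FALSE])
    samples$stage2_posterior[neg1] <- s2$posterior
    samples$stage2_call[neg1] <- ifelse(s2$call, "ischemic", "mimic")
  }
  isch_called <- !is.na(samples$stage2_call) & samples$stage2_call == "ischemic"
  downstream <- if (conditional) isch_called else rep(TRUE, n)
  if (!is.null(models$window) && any(downstream)) {
    sw <- .applyPanel(models$window, expr[, downstream, drop = FALSE])
    samples$window_posterior[downstream] <- sw$posterior
    samples$window_call[downstream] <- ifelse(sw$call, "within_window",
                                              "beyond_window")
  }
  if (!is.null(models$severity) && any(downstream)) {
    ss <- .applyPanel(models$severity, expr[, downstream, drop = FALSE])
    samples$severity_posterior[downstream] <- ss$posterior
    samples$severity_call[downstream] <- ifelse(ss$call, "severe", "minor")
  }
  metrics <- list()
  if (!is.null(md$diagnosis)) {
    diag <- as.character(md$diagnosis)
    metrics$stage1 <- .metricsFromCalls(s1$call, diag == "hemorrhagic")
    if (any(neg1)) {
      truth2 <- diag[neg1] == "ischemic"
      eligible2 <- diag[neg1] %in% c("ischemic", "mimic")
      if (any(eligible2))
        metrics$stage2 <- .metricsFromCalls(
          (samples$stage2_call[neg1] == "ischemic")[eligible2],
          truth2[eligible2])
    }
    if (!is.null(models$window) && !is.null(md$onset_hours)) {
      ok <- !is.na(samples$window_call) & !is.na(md$onset_hours)
      if (any(ok))
        metrics$window <- .metricsFromCalls(
          samples$window_call[ok] == "within_window",
          md$onset_hours[ok] <= time_cutoff_h)
    }
    if (!is.null(models$severity) && !is.null(md$nihss)) {
      ok <- !is.na(samples$severity_call) & !is.na(md$nihss)
      if (any(ok))
        metrics$severity <- .metricsFromCalls(
          samples$severity_call[ok] == "severe",
          md$nihss[ok] >= nihss_cutoff)
    }
  }
  structure(list(samples = samples, metrics = metrics,
                 provenance = c(prov, list(list(step = "cascade",
                                                conditional = conditional)))),
            class = "TriageReport")
}

#' Audit frozen models on a held-out cohort
#'
#' Applies the cascade to samples that never entered training or validation.
#' Classes absent from the cohort yield `NA`-flagged sensitivity or
#' specificity rather than errors; an empty cohort returns an empty report.
#'
#' @inheritParams runCascade
#' @return a `TriageReport` (see [runCascade()]).
#' @export
heldOutAudit <- function(normalized, models, metadata = NULL,
                         conditional = TRUE) {
  n <- if (is(normalized, "SummarizedExperiment")) ncol(normalized)
       else ncol(normalized)
  if (n == 0)
    return(structure(list(samples = data.frame(), metrics = list(),
                          provenance = list()), class = "TriageReport"))
  runCascade(normalized, models, metadata = metadata,
             conditional = conditional)
}

#' Serialize a triage report
#'
#' Writes the per-sample calls as a flat TSV and the cohort metrics plus
#' provenance as JSON.
#'
#' @param report a `TriageReport`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeTriageReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$samples, file.path(dir, "calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(metrics = report$metrics,
                            provenance = report$provenance),
                       file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(dir)
}
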