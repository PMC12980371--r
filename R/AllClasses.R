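#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

DIAGNOSIS_LEVELS <- c("hemorrhagic", "ischemic", "mimic", "TIA", "unknown")

#' Container for a whole-blood expression study
#'
#' An `ExpressionStudy` holds a transcripts x samples count matrix together
#' with per-sample clinical metadata (diagnosis, time since last known well,
#' NIHSS, age, sex, batch, read depth). It extends
#' \linkS4class{SummarizedExperiment}; when the study was simulated, the
#' planted-truth record is kept in `metadata(x)$truth`.
#'
#' @slot .Data inherited `SummarizedExperiment` with a `"counts"` assay.
#' @seealso [ExpressionStudy()], [simulateStudy()]
#' @export
setClass("ExpressionStudy", contains = "SummarizedExperiment")

setValidity("ExpressionStudy", function(object) {
  msg <- character()
  if (!"counts" %in% names(assays(object)))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- assay(object, "counts")
    if (anyNA(cts) || any(cts < 0))
      msg <- c(msg, "counts must be non-negative and non-missing")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate transcript IDs")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample IDs")
  cd <- colData(object)
  needed <- c("diagnosis", "onset_hours", "nihss", "age", "sex", "batch")
  miss <- setdiff(needed, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste("missing metadata columns:", paste(miss, collapse = ", ")))
  if ("onset_hours" %in% colnames(cd)) {
    oh <- cd$onset_hours
    if (any(!is.na(oh) & oh < 0)) msg <- c(msg, "onset_hours must be >= 0")
  }
  if ("diagnosis" %in% colnames(cd) &&
      !all(as.character(cd$diagnosis) %in% DIAGNOSIS_LEVELS))
    msg <- c(msg, paste("diagnosis must be one of:",
                        paste(DIAGNOSIS_LEVELS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionStudy
#'
#' @param counts non-negative integer matrix, transcripts in rows, samples in
#'   columns; dimnames are required and must be unique.
#' @param sampleData data.frame (or DataFrame) with one row per sample and at
#'   least the columns `diagnosis` (one of hemorrhagic, ischemic, mimic, TIA,
#'   unknown), `onset_hours` (hours since last known well, `NA` allowed),
#'   `nihss` (integer 0-42, `NA` allowed), `age`, `sex` (0/1), `batch`.
#' @param truth optional list recording planted signature/time/severity
#'   transcripts for simulated studies.
#' @return an [ExpressionStudy-class] object.
#' @examples
#' cfg <- simulationConfig(seed = 1L, n_transcripts = 50L)
#' st <- simulateStudy(cfg)
#' st
#' @export
ExpressionStudy <- function(counts, sampleData, truth = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have transcript and sample dimnames")
  cd <- as(sampleData, "DataFrame")
  if (!"read_depth" %in% colnames(cd)) cd$read_depth <- colSums(counts)
  se <- SummarizedExperiment(assays = list(counts = counts), colData = cd)
  obj <- new("ExpressionStudy", se)
  if (!is.null(truth)) metadata(obj)$truth <- truth
  obj
}

#' Normalized, filtered log2-CPM expression
#'
#' Produced by [normalizeStudy()]: log2 counts-per-million on TMM-normalized
#' effective library sizes, restricted to transcripts passing the
#' low-expression filter. Size factors, the filter mask over the input
#' transcripts, and an append-only provenance list travel with the object.
#'
#' @slot sizeFactors per-sample TMM factors (geometric mean 1).
#' @slot filterMask named logical over the *input* transcripts.
#' @slot provenance ordered list of applied steps with parameters.
#' @export
setClass("NormalizedStudy",
  contains = "SummarizedExperiment",
  representation(sizeFactors = "numeric",
                 filterMask  = "logical",
                 provenance  = "list"))

setValidity("NormalizedStudy", function(object) {
  msg <- character()
  if (!"logcpm" %in% names(assays(object)))
    msg <- c(msg, "assay 'logcpm' is required")
  else if (!all(is.finite(assay(object, "logcpm"))))
    msg <- c(msg, "log expression must be finite everywhere")
  if (any(object@sizeFactors <= 0))
    msg <- c(msg, "size factors must be positive")
  if (length(object@sizeFactors) != ncol(object))
    msg <- c(msg, "one size factor per sample required")
  if (length(msg)) msg else TRUE
})

#' @describeIn NormalizedStudy-class per-sample TMM size factors.
#' @param x a `NormalizedStudy`.
#' @export
sizeFactors <- function(x) x@sizeFactors

#' @describeIn NormalizedStudy-class the log2-CPM matrix (transcripts x samples).
#' @export
logExpression <- function(x) assay(x, "logcpm")

#' @describeIn NormalizedStudy-class low-expression filter mask over the input
#'   transcripts.
#' @export
filterMask <- function(x) x@filterMask

#' @describeIn NormalizedStudy-class ordered list of preprocessing steps applied.
#' @export
provenance <- function(x) x@provenance

#' Fitted Gaussian-emission hidden Markov model
#'
#' Parameters of a K-state HMM with diagonal-Gaussian emissions over D
#' observed features, fitted by EM ([fitGaussianHMM()]). Under
#' `mode = "per_sample"` every sample is a length-1 sequence, so the model is
#' a Gaussian mixture: `pi` doubles as the mixing weights and the transition
#' matrix is frozen uniform (excluded from the parameter count).
#'
#' @slot K,D integers: number of hidden states / observation dimension.
#' @slot mode `"per_sample"` or `"concatenated"`.
#' @slot pi initial-state distribution (length K, sums to 1).
#' @slot A K x K transition matrix (rows sum to 1).
#' @slot mu,sigma2 K x D state means and variances (variance floor 1e-6).
#' @slot logLik,bic fit log-likelihood and -2 logL + p log(n).
#' @slot nObs,nIter,converged,seed fit bookkeeping.
#' @export
setClass("GaussianHMMFit",
  representation(K = "integer", D = "integer", mode = "character",
                 pi = "numeric", A = "matrix", mu = "matrix",
                 sigma2 = "matrix", logLik = "numeric", bic = "numeric",
                 nObs = "integer", converged = "logical", nIter = "integer",
                 seed = "integer"))

setValidity("GaussianHMMFit", function(object) {
  msg <- character()
  if (abs(sum(object@pi) - 1) > 1e-10) msg <- c(msg, "pi must sum to 1")
  if (any(abs(rowSums(object@A) - 1) > 1e-10))
    msg <- c(msg, "transition rows must sum to 1")
  if (any(object@sigma2 <= 0)) msg <- c(msg, "variances must be positive")
  if (!object@mode %in% c("per_sample", "concatenated"))
    msg <- c(msg, "mode must be per_sample or concatenated")
  if (length(msg)) msg else TRUE
})

#' @describeIn GaussianHMMFit-class state means (K x D).
#' @param x a `GaussianHMMFit`.
#' @export
stateMeans <- function(x) x@mu

#' @describeIn GaussianHMMFit-class state variances (K x D).
#' @export
stateVariances <- function(x) x@sigma2

#' @describeIn GaussianHMMFit-class fit log-likelihood.
#' @export
logLikelihood <- function(x) x@logLik

#' @describeIn GaussianHMMFit-class Bayesian Information Criterion of the fit.
#' @export
bicValue <- function(x) x@bic

#' Evaluated transcript panel
#'
#' A 3-5 transcript combination with its training-fitted HMM, the state to
#' class mapping, the Youden-optimal posterior threshold, and confusion
#' metrics on training and validation cohorts. Produced by [evaluatePanel()].
#'
#' @slot transcripts panel transcript IDs.
#' @slot fit the training [GaussianHMMFit-class].
#' @slot stateToClass character vector mapping each hidden state to a class label.
#' @slot positiveClass the label treated as positive.
#' @slot threshold decision threshold on the positive-state posterior, in (0,1).
#' @slot thresholdGap width of the separating posterior gap on training
#'   (threshold stability).
#' @slot metricsTrain,metricsValid named lists from [computeMetrics()] plus `auc`.
#' @slot youdenJ training Youden's J at the chosen threshold.
#' @export
setClass("PanelEvaluation",
  representation(transcripts = "character", fit = "GaussianHMMFit",
                 stateToClass = "character", positiveClass = "character",
                 threshold = "numeric", thresholdGap = "numeric",
                 metricsTrain = "list", metricsValid = "list",
                 youdenJ = "numeric"))

setValidity("PanelEvaluation", function(object) {
  msg <- character()
  if (object@threshold <= 0 || object@threshold >= 1)
    msg <- c(msg, "threshold must lie strictly inside (0,1)")
  if (length(msg)) msg else TRUE
})

#' @describeIn PanelEvaluation-class the panel's transcript IDs.
#' @param x a `PanelEvaluation`.
#' @export
panelTranscripts <- function(x) x@transcripts

#' @describeIn PanelEvaluation-class training metrics list.
#' @export
metricsTrain <- function(x) x@metricsTrain

#' @describeIn PanelEvaluation-class validation metrics list.
#' @export
metricsValid <- function(x) x@metricsValid

setMethod("show", "ExpressionStudy", function(object) {
  cat("ExpressionStudy:", nrow(object), "transcripts x", ncol(object), "samples\n")
  tab <- table(colData(object)$diagnosis)
  cat("  diagnosis:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  if (!is.null(metadata(object)$truth)) cat("  planted truth record present\n")
})

setMethod("show", "NormalizedStudy", function(object) {
  cat("NormalizedStudy:", nrow(object), "transcripts x", ncol(object),
      "samples (log2-CPM)\n")
  cat("  steps:", paste(vapply(object@provenance, `[[`, "", "step"),
                        collapse = " -> "), "\n")
})

setMethod("show", "GaussianHMMFit", function(object) {
  cat(sprintf("GaussianHMMFit: K=%d states, D=%d, mode=%s\n",
              object@K, object@D, object@mode))
  cat(sprintf("  logLik=%.4f  BIC=%.4f  iters=%d  converged=%s\n",
              object@logLik, object@bic, object@nIter, object@converged))
})

setMethod("show", "PanelEvaluation", function(object) {
  cat("PanelEvaluation:", paste(object@transcripts, collapse = " + "), "\n")
  cat(sprintf("  positive=%s threshold=%.4g gap=%.3g\n", object@positiveClass,
              object@threshold, object@thresholdGap))
  cat(sprintf("  train acc=%.3f  valid acc=%.3f  J(train)=%.3f\n",
              object@metricsTrain$accuracy, object@metricsValid$accuracy,
              object@youdenJ))
})
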