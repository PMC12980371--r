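#' Cohort exclusion rules
#'
#' An `ExclusionRuleSet` is an ordered list of predicates over sample
#' metadata. Each rule carries a free-text label and an enabled flag; rules
#' are applied in declared order and every excluded sample is annotated with
#' the *first* rule that matched it.
#'
#' `exclusionRule()` builds one rule; `defaultTrainingExclusions()` mirrors a
#' typical training-cohort policy: drop TIA, unknown diagnoses, samples with
#' missing diagnosis, and low-read-depth libraries.
#'
#' @param label free-text rule label.
#' @param predicate function taking the metadata data.frame and returning a
#'   logical vector (TRUE = exclude).
#' @param enabled logical flag.
#' @return a list of class `ExclusionRule` / `ExclusionRuleSet`.
#' @export
exclusionRule <- function(label, predicate, enabled = TRUE) {
  stopifnot(is.function(predicate))
  structure(list(label = label, predicate = predicate, enabled = enabled),
            class = "ExclusionRule")
}

#' @rdname exclusionRule
#' @param ... `ExclusionRule` objects in application order.
#' @export
exclusionRuleSet <- function(...) {
  rules <- list(...)
  stopifnot(all(vapply(rules, inherits, TRUE, "ExclusionRule")))
  structure(rules, class = "ExclusionRuleSet")
}

#' @rdname exclusionRule
#' @param min_read_depth libraries below this total-count depth are dropped.
#' @export
defaultTrainingExclusions <- function(min_read_depth = 0) {
  exclusionRuleSet(
    exclusionRule("TIA", function(md) as.character(md$diagnosis) == "TIA"),
    exclusionRule("unknown diagnosis",
                  function(md) is.na(md$diagnosis) |
                    as.character(md$diagnosis) == "unknown"),
    exclusionRule("low read depth",
                  function(md) md$read_depth < min_read_depth))
}

#' Apply exclusion rules to a study
#'
#' @param study an [ExpressionStudy-class].
#' @param rules an [exclusionRuleSet()].
#' @return list with `study` (passing samples only) and `log`, a data.frame of
#'   removed samples with the first matching rule.
#' @export
applyExclusions <- function(study, rules) {
  md <- as.data.frame(colData(study))
  assigned <- rep(NA_character_, nrow(md))
  for (rule in rules) {
    if (!isTRUE(rule$enabled)) next
    hit <- rule$predicate(md)
    if (length(hit) != nrow(md))
      stop("rule '", rule$label, "' returned wrong-length predicate")
    hit[is.na(hit)] <- FALSE
    assigned[hit & is.na(assigned)] <- rule$label
  }
  keep <- is.na(assigned)
  if (!any(keep)) stop("empty cohort: all samples excluded")
  log <- data.frame(sample = colnames(study)[!keep],
                    rule = assigned[!keep], stringsAsFactors = FALSE)
  list(study = study[, keep], log = log)
}

#' Low-expression filter
#'
#' Keeps transcripts with counts-per-million (raw library sizes) at or above
#' `min_cpm` in at least `min_samples` samples.
#'
#' @param counts count matrix or an [ExpressionStudy-class].
#' @param min_cpm CPM threshold (default 1).
#' @param min_samples minimum number of samples meeting the threshold;
#'   default 25\% of samples.
#' @return named logical mask over transcripts.
#' @export
filterLowExpression <- function(counts, min_cpm = 1, min_samples = NULL) {
  if (is(counts, "SummarizedExperiment")) counts <- assay(counts, "counts")
  if (is.null(min_samples)) min_samples <- ceiling(0.25 * ncol(counts))
  stopifnot(min_samples <= ncol(counts))
  cpm <- t(t(counts) / colSums(counts)) * 1e6
  mask <- rowSums(cpm >= min_cpm) >= min_samples
  names(mask) <- rownames(counts)
  mask
}

#' TMM size factors
#'
#' Trimmed-mean-of-M-values normalization factors (30\% M-trim, 5\% A-trim,
#' precision-weighted), rescaled to geometric mean 1. Computed with
#' edgeR's TMM implementation.
#'
#' @param counts count matrix (transcripts x samples), >= 2 samples, each
#'   with at least one positive count.
#' @return named numeric vector of size factors.
#' @export
tmmFactors <- function(counts) {
  if (is(counts, "SummarizedExperiment")) counts <- assay(counts, "counts")
  stopifnot(ncol(counts) >= 2)
  if (any(colSums(counts) == 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[colSums(counts) == 0], collapse = ", "))
  f <- edgeR::calcNormFactors(counts, method = "TMM")
  names(f) <- colnames(counts)
  f
}

#' log2 counts-per-million
#'
#' `log2((count + prior) / (effective library size + 2*prior) * 1e6)` where
#' the effective library size is the raw library size times the TMM factor.
#'
#' @param counts count matrix.
#' @param size_factors per-sample factors (default all 1).
#' @param prior_count positive pseudo-count (default 0.5).
#' @return log2-CPM matrix with the same dimnames.
#' @export
logCPM <- function(counts, size_factors = rep(1, ncol(counts)),
                   prior_count = 0.5) {
  stopifnot(prior_count > 0)
  eff <- colSums(counts) * size_factors
  log2(t((t(counts) + prior_count) / (eff + 2 * prior_count)) * 1e6)
}

#' Location-scale batch adjustment
#'
#' Per transcript, each batch is standardized to the transcript's grand mean
#' and pooled within-batch SD: batch means agree to numerical precision
#' afterwards and within-batch rank order is preserved. Intended only within
#' a validation pool; never apply across the train/validation boundary.
#'
#' @param log_expression matrix (transcripts x samples) on the log scale.
#' @param batch factor of batch labels, >= 2 batches with >= 2 samples each.
#' @return adjusted matrix.
#' @export
batchAdjust <- function(log_expression, batch) {
  batch <- droplevels(as.factor(batch))
  stopifnot(length(batch) == ncol(log_expression))
  if (nlevels(batch) < 2) stop("need >= 2 batches")
  if (any(table(batch) < 2)) stop("single-sample batch")
  out <- log_expression
  grand <- rowMeans(log_expression)
  # pooled within-batch SD per transcript
  ss <- 0; df <- 0
  for (b in levels(batch)) {
    cols <- which(batch == b)
    m <- rowMeans(log_expression[, cols, drop = FALSE])
    ss <- ss + rowSums((log_expression[, cols, drop = FALSE] - m)^2)
    df <- df + length(cols) - 1
  }
  pooled_sd <- sqrt(ss / df)
  for (b in levels(batch)) {
    cols <- which(batch == b)
    x <- log_expression[, cols, drop = FALSE]
    m <- rowMeans(x)
    s <- sqrt(rowSums((x - m)^2) / (length(cols) - 1))
    scale <- ifelse(s > 1e-12 & pooled_sd > 1e-12, pooled_sd / s, 1)
    out[, cols] <- (x - m) * scale + grand
  }
  out
}

#' Normalize a study to filtered log2-CPM
#'
#' Chains the low-expression filter, TMM size factors, log2-CPM transform and
#' (optionally) within-pool batch adjustment, recording each step with its
#' parameters in the provenance list.
#'
#' @param study an [ExpressionStudy-class].
#' @inheritParams filterLowExpression
#' @inheritParams logCPM
#' @param batch_adjust apply [batchAdjust()] over the study's `batch` column.
#' @return a [NormalizedStudy-class].
#' @examples
#' st <- simulateStudy(simulationConfig(seed = 2L, n_transcripts = 300L))
#' ns <- normalizeStudy(st)
#' ns
#' @export
normalizeStudy <- function(study, min_cpm = 1, min_samples = NULL,
                           prior_count = 0.5, batch_adjust = FALSE) {
  counts <- assay(study, "counts")
  mask <- filterLowExpression(counts, min_cpm, min_samples)
  prov <- list(list(step = "filter_low_expression", min_cpm = min_cpm,
                    min_samples = if (is.null(min_samples))
                      ceiling(0.25 * ncol(counts)) else min_samples,
                    n_removed = sum(!mask)))
  kept <- counts[mask, , drop = FALSE]
  sf <- tmmFactors(kept)
  prov <- c(prov, list(list(step = "tmm", trim_M = 0.30, trim_A = 0.05)))
  le <- logCPM(kept, sf, prior_count)
  prov <- c(prov, list(list(step = "log_cpm", prior_count = prior_count)))
  if (batch_adjust) {
    le <- batchAdjust(le, colData(study)$batch)
    prov <- c(prov, list(list(step = "batch_adjust",
                              method = "location-scale")))
  }
  se <- SummarizedExperiment(assays = list(logcpm = le),
                             colData = colData(study))
  new("NormalizedStudy", se, sizeFactors = sf, filterMask = mask,
      provenance = prov)
}
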