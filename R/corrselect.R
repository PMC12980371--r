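#' Correlation screening against a continuous clinical target
#'
#' Pearson correlation of each transcript's log2-CPM with a continuous
#' target (time since onset or NIHSS), with p-values from the t-distribution
#' transform of r and Benjamini-Hochberg q-values. Samples with a missing
#' target are dropped (the count is recorded in `metadata()$n_dropped`).
#'
#' @param normalized a [NormalizedStudy-class] or log-expression matrix.
#' @param target name of the metadata column (`"onset_hours"` or `"nihss"`),
#'   or a numeric vector when `normalized` is a matrix.
#' @param r_min selection threshold on |r| (default 0.6).
#' @param q_max FDR threshold (default 0.05).
#' @param samples optional logical/index subset of samples screened.
#' @return [S4Vectors::DataFrame] with columns `transcript`, `r`, `p_value`,
#'   `q_value`, `selected`; the target name, dropped-sample count and the
#'   selected IDs sit in its `metadata()`.
#' @export
correlationScreen <- function(normalized, target = "onset_hours",
                              r_min = 0.6, q_max = 0.05, samples = NULL) {
  if (is(normalized, "SummarizedExperiment")) {
    expr <- assay(normalized, "logcpm")
    tv <- colData(normalized)[[target]]
    target_name <- target
  } else {
    expr <- normalized
    tv <- target
    target_name <- "target"
  }
  if (!is.null(samples)) {
    expr <- expr[, samples, drop = FALSE]
    tv <- tv[samples]
  }
  ok <- !is.na(tv)
  n_dropped <- sum(!ok)
  tv <- as.numeric(tv[ok])
  expr <- expr[, ok, drop = FALSE]
  n <- length(tv)
  if (n < 5) stop("target non-missing in fewer than 5 samples")
  if (stats::sd(tv) == 0) stop("zero-variance target")
  # constant transcripts produce a zero-sd warning and NA; both are handled
  r <- as.numeric(suppressWarnings(stats::cor(t(expr), tv)))
  r[is.na(r)] <- 0
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  q <- stats::p.adjust(p, "BH")
  selected <- abs(r) >= r_min & q < q_max
  res <- DataFrame(transcript = rownames(expr), r = r, p_value = p,
                   q_value = q, selected = selected)
  rownames(res) <- NULL
  metadata(res)$target <- target_name
  metadata(res)$n_dropped <- n_dropped
  metadata(res)$selected <- res$transcript[selected]
  res
}

#' Transcripts replicating across training and validation screens
#'
#' Intersects the training-selected transcripts with those that, in the
#' validation screen, have a sign-concordant correlation of at least
#' `r_min_valid` in magnitude and q below `q_max`.
#'
#' @param train_screen,valid_screen results of [correlationScreen()] over the
#'   same transcript universe.
#' @param r_min_valid validation |r| threshold (default 0.40).
#' @param q_max validation FDR threshold (default 0.05).
#' @return character vector of replicated transcript IDs.
#' @export
replicatedSelection <- function(train_screen, valid_screen,
                                r_min_valid = 0.40, q_max = 0.05) {
  tr_sel <- metadata(train_screen)$selected
  v <- as.data.frame(valid_screen)
  rownames(v) <- v$transcript
  tr <- as.data.frame(train_screen)
  rownames(tr) <- tr$transcript
  keep <- vapply(tr_sel, function(id) {
    if (!id %in% rownames(v)) return(FALSE)
    vr <- v[id, "r"]; vq <- v[id, "q_value"]
    sign(vr) == sign(tr[id, "r"]) && abs(vr) >= r_min_valid && vq < q_max
  }, TRUE)
  tr_sel[keep]
}
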