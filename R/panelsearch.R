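#' Confusion-matrix metrics
#'
#' Accuracy, sensitivity, specificity and Youden's J from confusion counts.
#' Ratios with an empty denominator (e.g. sensitivity with no positive
#' samples) are flagged `NA`, never silently zeroed.
#'
#' @param tp,fp,fn,tn non-negative integer counts, not all zero.
#' @return named list with the counts, `accuracy`, `sensitivity`,
#'   `specificity` and `youden_j`.
#' @examples
#' computeMetrics(tp = 51, fp = 0, fn = 0, tn = 24)$accuracy
#' @export
computeMetrics <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers")
  if (sum(counts) == 0) stop("all-zero confusion matrix")
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       accuracy = (tp + tn) / sum(counts),
       sensitivity = sens, specificity = spec,
       youden_j = if (is.na(sens) || is.na(spec)) NA_real_ else
         sens + spec - 1)
}

.metricsFromCalls <- function(calls, labels) {
  computeMetrics(tp = sum(calls & labels), fp = sum(calls & !labels),
                 fn = sum(!calls & labels), tn = sum(!calls & !labels))
}

#' Rank-based ROC AUC
#'
#' Mann-Whitney estimate of the area under the ROC curve: the probability
#' that a random positive outscores a random negative, ties counting 1/2
#' (midranks).
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels logical (or coercible) positive-class indicator.
#' @return AUC in \[0,1\], or `NA` when one class is absent.
#' @export
rocAUC <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden-optimal posterior threshold
#'
#' Scans the midpoints of adjacent sorted unique scores and returns the
#' threshold maximizing Youden's J (prediction rule: positive iff score >=
#' threshold). Ties go to the smallest such threshold; under complete
#' separation the returned threshold is the midpoint of the separating gap
#' and J = 1. `gap` is the distance between the adjacent scores the winning
#' threshold splits (threshold stability).
#'
#' @param scores positive-state posterior probabilities.
#' @param labels logical positive-class indicator; both classes required.
#' @return list with `threshold`, `youden_j` and `gap`.
#' @export
optimizeThreshold <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    stop("both classes must be present to optimize a threshold")
  u <- sort(unique(scores))
  if (length(u) < 2) {
    return(list(threshold = 0.5, youden_j = 0, gap = 0))
  }
  cand <- (u[-length(u)] + u[-1]) / 2
  js <- vapply(cand, function(th)
    .metricsFromCalls(scores >= th, labels)$youden_j, 0)
  best <- which(js == max(js))[1]         # smallest threshold among ties
  list(threshold = cand[best], youden_j = js[best],
       gap = u[best + 1] - u[best])
}

# map hidden states to class labels by majority vote of hard-assigned
# training samples; a tied state resolves toward the positive (rarer) class
.mapStates <- function(gamma, labels, positiveClass, negativeClass) {
  hard <- max.col(gamma, ties.method = "first")
  vapply(seq_len(ncol(gamma)), function(k) {
    in_k <- hard == k
    n_pos <- sum(in_k & labels); n_neg <- sum(in_k & !labels)
    if (n_pos >= n_neg) positiveClass else negativeClass
  }, "")
}

.positivePosterior <- function(gamma, stateToClass, positiveClass) {
  pos_states <- which(stateToClass == positiveClass)
  if (!length(pos_states)) return(rep(0, nrow(gamma)))
  rowSums(gamma[, pos_states, drop = FALSE])
}

#' Single-transcript HMM screening
#'
#' For every candidate transcript, fits a K-state HMM on that transcript's
#' training expression alone, maps states to classes by majority vote, and
#' classifies at posterior 0.5. A transcript passes when its training
#' accuracy reaches `accuracyFloor` (default 1: the perfect-separation rule).
#' Constant transcripts are flagged degenerate and never pass.
#'
#' @param train log-expression matrix (transcripts x samples).
#' @param labels logical positive-class indicator per sample.
#' @param candidates transcript IDs to screen (default: all rows).
#' @param K hidden states (default 2).
#' @param seed integer seed (per-transcript fit seeds are derived from it).
#' @param accuracyFloor pass threshold on training accuracy (default 1).
#' @param nRestarts,maxIter,tol EM settings; screening defaults are lighter
#'   than [fitGaussianHMM()]'s because the pass rule depends on hard calls,
#'   not on refined likelihoods.
#' @return data.frame of class `ScreenResult` with columns `transcript`,
#'   `accuracy`, `degenerate`, `pass`.
#' @export
screenSingleTranscripts <- function(train, labels, candidates = rownames(train),
                                    K = 2L, seed = 1L, accuracyFloor = 1,
                                    nRestarts = 3L, maxIter = 150L,
                                    tol = 1e-5) {
  labels <- as.logical(labels)
  stopifnot(all(candidates %in% rownames(train)))
  res <- lapply(seq_along(candidates), function(i) {
    id <- candidates[i]
    x <- matrix(train[id, ], ncol = 1)
    if (diff(range(x)) == 0)
      return(data.frame(transcript = id, accuracy = NA_real_,
                        degenerate = TRUE, pass = FALSE))
    fit <- fitGaussianHMM(x, K, "per_sample", nRestarts = nRestarts,
                          maxIter = maxIter, tol = tol, seed = seed + i)
    gamma <- forwardBackward(fit, x)$gamma
    s2c <- .mapStates(gamma, labels, "pos", "neg")
    post <- .positivePosterior(gamma, s2c, "pos")
    acc <- mean((post >= 0.5) == labels)
    data.frame(transcript = id, accuracy = acc, degenerate = FALSE,
               pass = acc >= accuracyFloor)
  })
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(transcript = character(), accuracy = numeric(),
               degenerate = logical(), pass = logical())
  class(out) <- c("ScreenResult", "data.frame")
  out
}

#' Enumerate candidate panels
#'
#' All transcript subsets of sizes `size_min` to `size_max`, in lexicographic
#' order. Refuses (rather than subsamples) when the closed-form count
#' exceeds `cap`.
#'
#' @param passing_ids transcript IDs that passed screening.
#' @param size_min,size_max panel size bounds (defaults 3 and 5).
#' @param cap combinatorial guard (default 250000).
#' @return list of character vectors (the panels).
#' @export
enumeratePanels <- function(passing_ids, size_min = 3L, size_max = 5L,
                            cap = 250000) {
  stopifnot(size_min <= size_max, size_min >= 1)
  n <- length(passing_ids)
  if (n < size_min) stop("fewer passing transcripts (", n,
                         ") than minimum panel size (", size_min, ")")
  sizes <- seq(size_min, min(size_max, n))
  total <- sum(choose(n, sizes))
  if (total > cap)
    stop("panel count ", total, " exceeds cap ", cap,
         "; tighten the single-transcript screening")
  ids <- sort(passing_ids)
  out <- list()
  for (s in sizes) {
    cmb <- utils::combn(ids, s, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Fit and evaluate one panel, training-frozen
#'
#' Fits the HMM on the training observations only, maps states to classes by
#' majority vote of the training labels (ties resolve toward the positive
#' class), optimizes the posterior threshold on training by Youden's J, and
#' only then applies the frozen model and threshold to the validation
#' samples. Validation data can never influence the fit, the state mapping
#' or the threshold.
#'
#' @param panel_ids transcript IDs forming the panel.
#' @param train,valid log-expression matrices (transcripts x samples) on the
#'   same scale, both containing the panel transcripts.
#' @param labels_train,labels_valid logical positive-class indicators.
#' @param K hidden states (default 2).
#' @param seed integer seed for the training fit.
#' @param positiveClass,negativeClass labels used in the state map.
#' @param nRestarts EM restarts.
#' @return a [PanelEvaluation-class].
#' @export
evaluatePanel <- function(panel_ids, train, valid, labels_train, labels_valid,
                          K = 2L, seed = 1L, positiveClass = "positive",
                          negativeClass = "negative", nRestarts = 5L) {
  missing_tr <- setdiff(panel_ids, rownames(train))
  missing_va <- setdiff(panel_ids, rownames(valid))
  if (length(missing_tr) || length(missing_va))
    stop("panel transcript(s) absent: ",
         paste(unique(c(missing_tr, missing_va)), collapse = ", "))
  labels_train <- as.logical(labels_train)
  labels_valid <- as.logical(labels_valid)
  obs_tr <- t(train[panel_ids, , drop = FALSE])
  fit <- fitGaussianHMM(obs_tr, K, "per_sample", nRestarts = nRestarts,
                        seed = seed)
  gamma_tr <- forwardBackward(fit, obs_tr)$gamma
  s2c <- .mapStates(gamma_tr, labels_train, positiveClass, negativeClass)
  post_tr <- .positivePosterior(gamma_tr, s2c, positiveClass)
  opt <- optimizeThreshold(post_tr, labels_train)
  m_tr <- .metricsFromCalls(post_tr >= opt$threshold, labels_train)
  m_tr$auc <- rocAUC(post_tr, labels_train)
  obs_va <- t(valid[panel_ids, , drop = FALSE])
  post_va <- .positivePosterior(forwardBackward(fit, obs_va)$gamma, s2c,
                                positiveClass)
  m_va <- .metricsFromCalls(post_va >= opt$threshold, labels_valid)
  m_va$auc <- rocAUC(post_va, labels_valid)
  th <- min(max(opt$threshold, 1e-9), 1 - 1e-9)
  new("PanelEvaluation", transcripts = panel_ids, fit = fit,
      stateToClass = s2c, positiveClass = positiveClass, threshold = th,
      thresholdGap = opt$gap, metricsTrain = m_tr, metricsValid = m_va,
      youdenJ = opt$youden_j)
}

#' Deterministic representative-panel selection
#'
#' Filters the evaluated panels through a fixed criteria ladder:
#' (1) maximal `min(train accuracy, valid accuracy)`; (2) maximal threshold
#' stability (width of the separating posterior gap on training); (3) fewer
#' transcripts; (4) fewer unannotated `MSTRG` IDs; (5) lexicographically
#' smallest ID tuple. Fully deterministic.
#'
#' @param evaluations non-empty list of [PanelEvaluation-class] objects.
#' @return the selected [PanelEvaluation-class].
#' @export
selectRepresentative <- function(evaluations) {
  stopifnot(length(evaluations) >= 1)
  minacc <- vapply(evaluations, function(e)
    min(e@metricsTrain$accuracy, e@metricsValid$accuracy), 0)
  keep <- which(minacc == max(minacc))
  gaps <- vapply(evaluations[keep], function(e) e@thresholdGap, 0)
  keep <- keep[gaps == max(gaps)]
  sizes <- vapply(evaluations[keep], function(e) length(e@transcripts), 0L)
  keep <- keep[sizes == min(sizes)]
  mstrg <- vapply(evaluations[keep], function(e)
    sum(startsWith(e@transcripts, "MSTRG")), 0L)
  keep <- keep[mstrg == min(mstrg)]
  keys <- vapply(evaluations[keep], function(e)
    paste(e@transcripts, collapse = "\r"), "")
  evaluations[[keep[order(keys)[1]]]]
}

#' Screen, enumerate, evaluate and select in one pass
#'
#' Convenience wrapper chaining [screenSingleTranscripts()],
#' [enumeratePanels()], [evaluatePanel()] and [selectRepresentative()] for
#' one binary task.
#'
#' @inheritParams evaluatePanel
#' @param candidates transcript IDs entering the single-transcript screen.
#' @param size_min,size_max,cap see [enumeratePanels()].
#' @param accuracyFloor screening pass floor (default 1, perfect separation).
#' @param screenK hidden states for screening fits (default `K`).
#' @return list with `screen`, `panels`, `evaluations`, `representative`.
#' @export
searchPanels <- function(train, valid, labels_train, labels_valid,
                         candidates = rownames(train), K = 2L, seed = 1L,
                         size_min = 3L, size_max = 5L, cap = 250000,
                         accuracyFloor = 1, positiveClass = "positive",
                         negativeClass = "negative", nRestarts = 5L,
                         screenK = K) {
  screen <- screenSingleTranscripts(train, labels_train, candidates,
                                    K = screenK, seed = seed,
                                    accuracyFloor = accuracyFloor,
                                    nRestarts = nRestarts)
  passing <- screen$transcript[screen$pass]
  panels <- enumeratePanels(passing, size_min, size_max, cap)
  evals <- lapply(seq_along(panels), function(i)
    evaluatePanel(panels[[i]], train, valid, labels_train, labels_valid,
                  K = K, seed = seed + i, positiveClass = positiveClass,
                  negativeClass = negativeClass, nRestarts = nRestarts))
  list(screen = screen, panels = panels, evaluations = evals,
       representative = selectRepresentative(evals))
}
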