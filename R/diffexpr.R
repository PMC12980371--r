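#' Greedy Mahalanobis full matching
#'
#' Approximate full matching for covariate balance ahead of differential
#' expression. Each minority-group sample claims its nearest majority-group
#' sample by Mahalanobis distance over the chosen covariates; remaining
#' majority samples are then attached to the matched set of their nearest
#' claimed majority sample. Full-matching weights: minority samples get
#' weight 1; majority samples in a set share that set's minority count
#' equally.
#'
#' @param metadata data.frame of sample metadata (rownames = sample IDs).
#' @param group_labels vector with exactly two distinct labels.
#' @param covariates character vector of numeric metadata columns.
#' @return data.frame of class `MatchResult` with columns `sample`, `group`,
#'   `set` and `weight`.
#' @export
mahalanobisMatch <- function(metadata, group_labels,
                             covariates = c("age", "sex", "nihss")) {
  group_labels <- as.character(group_labels)
  stopifnot(length(unique(group_labels)) == 2,
            length(group_labels) == nrow(metadata))
  covariates <- intersect(covariates, colnames(metadata))
  X <- as.matrix(metadata[, covariates, drop = FALSE])
  storage.mode(X) <- "double"
  if (anyNA(X)) {
    # impute column medians so degenerate metadata does not abort matching
    for (j in seq_len(ncol(X)))
      X[is.na(X[, j]), j] <- stats::median(X[, j], na.rm = TRUE)
  }
  S <- stats::cov(X)
  Sinv <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(Sinv))
    Sinv <- tryCatch(solve(S + diag(1e-6, ncol(S))),
                     error = function(e)
                       stop("degenerate-covariance error: covariates carry ",
                            "too little variation"))
  tab <- table(group_labels)
  minority <- names(tab)[which.min(tab)]
  mi <- which(group_labels == minority)
  ma <- which(group_labels != minority)
  d2 <- function(i, j) {
    v <- X[i, ] - X[j, ]
    as.numeric(v %*% Sinv %*% v)
  }
  set_of <- integer(length(group_labels))
  # each minority sample claims its nearest free majority sample
  free <- ma
  for (k in seq_along(mi)) {
    i <- mi[k]
    dd <- vapply(free, function(j) d2(i, j), 0)
    j <- free[which.min(dd)]
    set_of[i] <- k; set_of[j] <- k
    free <- setdiff(free, j)
  }
  # remaining majority samples attach to the set of their nearest matched
  # majority sample
  claimed <- setdiff(ma, free)
  for (j in free) {
    dd <- vapply(claimed, function(m) d2(j, m), 0)
    set_of[j] <- set_of[claimed[which.min(dd)]]
  }
  weight <- numeric(length(group_labels))
  for (k in unique(set_of)) {
    in_set <- which(set_of == k)
    n_min <- sum(group_labels[in_set] == minority)
    n_maj <- sum(group_labels[in_set] != minority)
    weight[in_set] <- ifelse(group_labels[in_set] == minority, 1,
                             n_min / n_maj)
  }
  out <- data.frame(sample = rownames(metadata) %||% seq_along(group_labels),
                    group = group_labels, set = set_of, weight = weight,
                    stringsAsFactors = FALSE)
  class(out) <- c("MatchResult", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Covariate-adjusted pairwise differential expression
#'
#' Per-transcript (optionally weighted) ordinary-least-squares fit of
#' log2-CPM on group plus adjustment covariates. The group coefficient is the
#' log2 fold change (group1 minus group2); p-values are two-sided t-tests on
#' that coefficient; q-values are Benjamini-Hochberg across all tested
#' transcripts.
#'
#' @param normalized a [NormalizedStudy-class] (or log-expression matrix with
#'   `metadata` supplied).
#' @param contrast ordered pair of diagnosis labels, `c(group1, group2)`.
#' @param adjust_for covariate columns entering the design (default age, sex).
#' @param weights optional per-sample non-negative weights (e.g. matching
#'   weights), aligned with the full study's samples or named.
#' @param metadata optional metadata data.frame when `normalized` is a matrix.
#' @return a [S4Vectors::DataFrame] with columns `transcript`, `log2fc`,
#'   `p_value`, `q_value`; the contrast is kept in `metadata()$contrast`.
#' @export
differentialExpression <- function(normalized, contrast,
                                   adjust_for = c("age", "sex"),
                                   weights = NULL, metadata = NULL) {
  if (is(normalized, "SummarizedExperiment")) {
    expr <- assay(normalized, "logcpm")
    md <- as.data.frame(colData(normalized))
  } else {
    expr <- normalized
    md <- metadata
  }
  stopifnot(length(contrast) == 2)
  grp <- as.character(md$diagnosis)
  if (contrast[2] == "rest") {
    # one-vs-rest among the three diagnostic classes
    core <- c("hemorrhagic", "ischemic", "mimic")
    grp[grp %in% setdiff(core, contrast[1])] <- "rest"
  }
  keep <- grp %in% contrast
  if (sum(grp == contrast[1]) < 3 || sum(grp == contrast[2]) < 3)
    stop("both contrast groups need >= 3 samples")
  expr <- expr[, keep, drop = FALSE]
  md <- md[keep, , drop = FALSE]
  g <- as.numeric(grp[keep] == contrast[1])      # 1 = group1, effect = g1 - g2
  X <- cbind(intercept = 1, group = g)
  for (cv in adjust_for) {
    v <- md[[cv]]
    if (is.null(v)) stop("covariate not found: ", cv)
    X <- cbind(X, as.numeric(v))
    colnames(X)[ncol(X)] <- cv
  }
  if (!is.null(weights)) {
    w <- if (!is.null(names(weights))) weights[rownames(md)] else weights[keep]
    stopifnot(all(w >= 0))
    sw <- sqrt(w)
    Xw <- X * sw
    Yw <- sweep(expr, 2, sw, `*`)
  } else {
    Xw <- X; Yw <- expr
  }
  qrX <- qr(Xw)
  if (qrX$rank < ncol(Xw)) {
    drop_cols <- colnames(Xw)[qrX$pivot[(qrX$rank + 1):ncol(Xw)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  XtXinv <- solve(crossprod(Xw))
  B <- Yw %*% Xw %*% XtXinv                       # transcripts x p
  resid <- Yw - B %*% t(Xw)
  dfres <- nrow(Xw) - ncol(Xw)
  s2 <- rowSums(resid^2) / dfres
  se <- sqrt(s2 * XtXinv["group", "group"])
  log2fc <- B[, "group"]
  tstat <- log2fc / se
  p <- 2 * stats::pt(-abs(tstat), dfres)
  # degenerate transcripts: zero residual variance
  flat <- se < 1e-12
  p[flat & abs(log2fc) < 1e-12] <- 1
  p[flat & abs(log2fc) >= 1e-12] <- 0
  res <- DataFrame(transcript = rownames(expr), log2fc = log2fc,
                   p_value = p, q_value = stats::p.adjust(p, "BH"))
  rownames(res) <- NULL
  metadata(res)$contrast <- contrast
  res
}

#' Significant transcripts under the fold-change / p-value filter
#'
#' Retains transcripts with raw p-value below `p_max` and fold change of at
#' least `fc_min` (i.e. |log2FC| >= log2(fc_min)). Raw p, not q, gates the
#' filter; q-values remain available in the `DEResult`.
#'
#' @param de result of [differentialExpression()].
#' @param p_max p-value cutoff (default 0.05).
#' @param fc_min fold-change cutoff on the natural scale (default 1.5).
#' @return character vector of transcript IDs.
#' @export
significantSet <- function(de, p_max = 0.05, fc_min = 1.5) {
  stopifnot(p_max > 0, fc_min > 0)
  de$transcript[de$p_value < p_max & abs(de$log2fc) >= log2(fc_min)]
}

#' Top up- and down-regulated transcripts
#'
#' Among transcripts passing [significantSet()], the `k` largest and `k`
#' most negative log2 fold changes. Ties break by smaller p-value, then
#' lexicographic transcript ID, so selection is deterministic.
#'
#' @inheritParams significantSet
#' @param k list length per direction (default 50).
#' @return list with character vectors `up` and `down` (each length <= k).
#' @export
topUpDown <- function(de, k = 50, p_max = 0.05, fc_min = 1.5) {
  stopifnot(k >= 1)
  sig <- de[de$transcript %in% significantSet(de, p_max, fc_min), , drop = FALSE]
  up <- sig[sig$log2fc > 0, , drop = FALSE]
  dn <- sig[sig$log2fc < 0, , drop = FALSE]
  ord_up <- order(-up$log2fc, up$p_value, up$transcript)
  ord_dn <- order(dn$log2fc, dn$p_value, dn$transcript)
  list(up = as.character(up$transcript[utils::head(ord_up, k)]),
       down = as.character(dn$transcript[utils::head(ord_dn, k)]))
}

#' Condition-unique signature sets
#'
#' Given one transcript set per condition, returns for each condition the
#' transcripts found in that condition's set and in no other's (pairwise
#' disjoint by construction).
#'
#' @param sets named list of character vectors, one per condition (>= 2).
#' @return named list of class `SignatureSets`.
#' @export
uniqueSignatures <- function(sets) {
  stopifnot(length(sets) >= 2, !is.null(names(sets)))
  out <- lapply(names(sets), function(cond) {
    others <- unique(unlist(sets[setdiff(names(sets), cond)]))
    setdiff(sets[[cond]], others)
  })
  names(out) <- names(sets)
  structure(out, class = c("SignatureSets", "list"))
}

#' Per-condition DE signature sets from the three pairwise contrasts
#'
#' Runs the three pairwise contrasts (hemorrhagic vs ischemic, ischemic vs
#' mimic, hemorrhagic vs mimic). A condition's list is the transcripts
#' significant, with sign-concordant fold changes, in *both* contrasts that
#' involve it (oriented condition-first) — i.e. transcripts that set the
#' condition apart from each other group. The condition's top list takes the
#' k largest and k most negative average log2 fold changes across its two
#' contrasts (ties by smaller p, then transcript ID). Condition-unique
#' elements come from [uniqueSignatures()].
#'
#' @inheritParams differentialExpression
#' @param k per-direction top-list size (default 50).
#' @param p_max,fc_min filter thresholds, see [significantSet()].
#' @return list with `de` (three pairwise DEResults), `condition_sets`,
#'   `unique_all`, `unique_top`.
#' @export
signatureSets <- function(normalized, adjust_for = c("age", "sex"),
                          weights = NULL, k = 50, p_max = 0.05, fc_min = 1.5) {
  contrasts <- list(hemorrhagic_vs_ischemic = c("hemorrhagic", "ischemic"),
                    ischemic_vs_mimic       = c("ischemic", "mimic"),
                    hemorrhagic_vs_mimic    = c("hemorrhagic", "mimic"))
  de <- lapply(contrasts, function(ct)
    differentialExpression(normalized, ct, adjust_for, weights))
  conds <- c("hemorrhagic", "ischemic", "mimic")
  # per condition: its two contrasts, oriented condition-minus-other
  oriented <- lapply(conds, function(cond) {
    lapply(which(vapply(contrasts, function(ct) cond %in% ct, TRUE)),
           function(i) {
             d <- as.data.frame(de[[i]])
             if (contrasts[[i]][1] != cond) d$log2fc <- -d$log2fc
             d
           })
  })
  names(oriented) <- conds
  all_sets <- lapply(conds, function(cond) {
    d1 <- oriented[[cond]][[1]]; d2 <- oriented[[cond]][[2]]
    sig1 <- d1$p_value < p_max & abs(d1$log2fc) >= log2(fc_min)
    sig2 <- d2$p_value < p_max & abs(d2$log2fc) >= log2(fc_min)
    keep <- sig1 & sig2 & sign(d1$log2fc) == sign(d2$log2fc)
    d1$transcript[keep]
  })
  top_sets <- lapply(conds, function(cond) {
    d1 <- oriented[[cond]][[1]]; d2 <- oriented[[cond]][[2]]
    ids <- all_sets[[match(cond, conds)]]
    rows <- match(ids, d1$transcript)
    score <- (d1$log2fc[rows] + d2$log2fc[rows]) / 2
    pmin_ <- pmin(d1$p_value[rows], d2$p_value[rows])
    up <- which(score > 0); dn <- which(score < 0)
    take <- function(idx, decreasing) {
      o <- order(if (decreasing) -score[idx] else score[idx], pmin_[idx],
                 ids[idx])
      ids[idx[utils::head(o, k)]]
    }
    unique(c(take(up, TRUE), take(dn, FALSE)))
  })
  names(all_sets) <- names(top_sets) <- conds
  list(de = de, condition_sets = all_sets,
       unique_all = uniqueSignatures(all_sets),
       unique_top = uniqueSignatures(top_sets))
}
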