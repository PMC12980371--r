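suppressPackageStartupMessages({
  library(SummarizedExperiment)
  library(S4Vectors)
})

# log-expression fixture: nSig planted separating transcripts (positive
# samples shifted by `shift` SDs) among nNoise iid-normal transcripts
makeSeparatedMatrix <- function(nSig, nNoise, labels, shift = 8, seed = 1L,
                                prefix = "SIG") {
  n <- length(labels)
  withr::with_seed(seed, {
    m <- matrix(rnorm((nSig + nNoise) * n), nSig + nNoise, n)
    rownames(m) <- c(sprintf("%s%02d", prefix, seq_len(nSig)),
                     sprintf("ENST%011d", seq_len(nNoise)))
    colnames(m) <- sprintf("s%03d", seq_len(n))
    if (nSig > 0) m[seq_len(nSig), labels] <- m[seq_len(nSig), labels] + shift
    m
  })
}

cohortLabels <- function(n_pos, n_neg) rep(c(TRUE, FALSE), c(n_pos, n_neg))

# Benjamini-Hochberg step-up, written directly from the procedure's
# definition: q_(i) = min over j >= i of p_(j) * m / j
bruteForceBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

bruteForcePearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# exhaustive state-path enumeration oracle for the forward-backward
# recursions (concatenated mode, diagonal Gaussian emissions)
bruteForcePosteriors <- function(pi, A, mu, sigma2, obs) {
  Tn <- nrow(obs); K <- length(pi)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  pathProb <- apply(paths, 1, function(s) {
    p <- pi[s[1]] * prod(dnorm(obs[1, ], mu[s[1], ], sqrt(sigma2[s[1], ])))
    if (Tn > 1) for (t in 2:Tn)
      p <- p * A[s[t - 1], s[t]] *
        prod(dnorm(obs[t, ], mu[s[t], ], sqrt(sigma2[s[t], ])))
    p
  })
  lik <- sum(pathProb)
  gamma <- sapply(seq_len(K), function(k)
    sapply(seq_len(Tn), function(t) sum(pathProb[paths[, t] == k]) / lik))
  list(gamma = matrix(gamma, Tn, K), logLik = log(lik))
}

randomHMMParams <- function(K, D) {
  pi <- runif(K); pi <- pi / sum(pi)
  A <- matrix(runif(K * K), K, K); A <- A / rowSums(A)
  list(pi = pi, A = A, mu = matrix(rnorm(K * D, sd = 2), K, D),
       sigma2 = matrix(runif(K * D, 0.3, 2), K, D))
}

# wrap arbitrary HMM parameters in a fit object (for oracle comparisons)
asFit <- function(p, mode = "concatenated", nObs = 10L) {
  new("GaussianHMMFit", K = nrow(p$A), D = ncol(p$mu), mode = mode,
      pi = p$pi, A = p$A, mu = p$mu, sigma2 = p$sigma2, logLik = 0,
      bic = 0, nObs = as.integer(nObs), converged = TRUE, nIter = 0L,
      seed = 0L)
}

# canonical TMM algorithm coded independently from its published definition
# (reference by 75th-percentile rule, 30%/5% two-sided trims on M and A,
# inverse asymptotic-variance weights, geometric-mean-1 rescaling)
bruteForceTMM <- function(counts) {
  lib <- colSums(counts)
  f75 <- apply(counts, 2, function(x) quantile(x, 0.75)) / lib
  ref_i <- which.min(abs(f75 - mean(f75)))
  ref <- counts[, ref_i]; nR <- lib[ref_i]
  f <- vapply(seq_len(ncol(counts)), function(j) {
    obs <- counts[, j]; nO <- lib[j]
    keep0 <- obs > 0 & ref > 0
    o <- obs[keep0]; r <- ref[keep0]
    M <- log2((o / nO) / (r / nR))
    A <- (log2(o / nO) + log2(r / nR)) / 2
    v <- (nO - o) / (nO * o) + (nR - r) / (nR * r)
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * 0.30) + 1; hiM <- n + 1 - loM
    loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
  }, 0)
  f / exp(mean(log(f)))
}
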