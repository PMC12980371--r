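# Gaussian-emission hidden Markov model, fitted by EM.
#
# Two observation regimes:
#   * per_sample   — every sample is its own length-1 sequence. With no
#     transitions to estimate the model is exactly a Gaussian mixture: pi is
#     the mixing distribution and A is frozen uniform and excluded from the
#     BIC parameter count. This is the default for cross-sectional patients.
#   * concatenated — all samples form one sequence in the given row order;
#     classical Baum-Welch with scaled forward-backward recursions.

.logRowSumExp <- function(M) {
  mx <- apply(M, 1, max)
  mx + log(rowSums(exp(M - mx)))
}

# N x K matrix of per-state log emission densities (diagonal Gaussian)
.logEmission <- function(obs, mu, sigma2) {
  N <- nrow(obs); K <- nrow(mu)
  out <- matrix(0, N, K)
  for (k in seq_len(K)) {
    # matrix() guard: vapply drops to a vector when N == 1
    out[, k] <- rowSums(matrix(vapply(seq_len(ncol(obs)), function(d)
      stats::dnorm(obs[, d], mu[k, d], sqrt(sigma2[k, d]), log = TRUE),
      numeric(N)), nrow = N))
  }
  out
}

.freeParams <- function(K, D, mode) {
  if (mode == "per_sample") (K - 1L) + 2L * K * D
  else (K - 1L) + K * (K - 1L) + 2L * K * D
}

# quantile-sliced initialization along the first principal direction
.initParams <- function(obs, K, jitter_sd) {
  D <- ncol(obs)
  ctr <- scale(obs, scale = FALSE)
  v <- svd(ctr, nu = 0, nv = 1)$v[, 1]
  proj <- as.numeric(ctr %*% v)
  grp <- if (K == 1L) rep(1L, nrow(obs)) else
    cut(rank(proj, ties.method = "first"), K, labels = FALSE)
  mu <- do.call(rbind, lapply(seq_len(K), function(k)
    colMeans(obs[grp == k, , drop = FALSE])))
  if (jitter_sd > 0)
    mu <- mu + matrix(stats::rnorm(K * D, 0, jitter_sd), K, D)
  gvar <- pmax(apply(obs, 2, stats::var), 1e-6)
  sigma2 <- matrix(gvar, K, D, byrow = TRUE)
  list(mu = mu, sigma2 = sigma2, pi = rep(1 / K, K),
       A = matrix(0.2 / K, K, K) + diag(0.8, K))
}

.emPerSample <- function(obs, K, init, maxIter, tol, varFloor) {
  N <- nrow(obs); D <- ncol(obs)
  mu <- init$mu; sigma2 <- init$sigma2; pi <- init$pi
  ll_prev <- -Inf; ll <- -Inf; converged <- FALSE; it <- 0L
  for (it in seq_len(maxIter)) {
    lg <- sweep(.logEmission(obs, mu, sigma2), 2, log(pi), `+`)
    lse <- .logRowSumExp(lg)
    ll <- sum(lse)
    if (ll < ll_prev - 1e-8)
      stop("EM log-likelihood decreased: ", ll_prev, " -> ", ll)
    gamma <- exp(lg - lse)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) < tol * (abs(ll_prev) + 1e-12)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    Nk <- pmax(colSums(gamma), 1e-12)
    pi <- Nk / N
    for (k in seq_len(K)) {
      mu[k, ] <- colSums(gamma[, k] * obs) / Nk[k]
      sigma2[k, ] <- pmax(colSums(gamma[, k] *
        sweep(obs, 2, mu[k, ])^2) / Nk[k], varFloor)
    }
  }
  list(pi = pi, A = matrix(1 / K, K, K), mu = mu, sigma2 = sigma2,
       logLik = ll, converged = converged, nIter = it)
}

# scaled forward-backward over one concatenated sequence
.forwardBackwardDense <- function(B, pi, A) {
  Tn <- nrow(B); K <- ncol(B)
  alpha <- matrix(0, Tn, K); beta <- matrix(0, Tn, K); cvec <- numeric(Tn)
  a <- pi * B[1, ]
  cvec[1] <- sum(a); alpha[1, ] <- a / cvec[1]
  if (Tn > 1) for (t in 2:Tn) {
    a <- (alpha[t - 1, ] %*% A) * B[t, ]
    cvec[t] <- sum(a); alpha[t, ] <- a / cvec[t]
  }
  beta[Tn, ] <- 1
  if (Tn > 1) for (t in (Tn - 1):1)
    beta[t, ] <- as.numeric(A %*% (B[t + 1, ] * beta[t + 1, ])) / cvec[t + 1]
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  list(alpha = alpha, beta = beta, gamma = gamma, cvec = cvec,
       logLik = sum(log(cvec)))
}

.emConcatenated <- function(obs, K, init, maxIter, tol, varFloor) {
  N <- nrow(obs); D <- ncol(obs)
  mu <- init$mu; sigma2 <- init$sigma2; pi <- init$pi; A <- init$A
  A <- A / rowSums(A)
  ll_prev <- -Inf; ll <- -Inf; converged <- FALSE; it <- 0L
  for (it in seq_len(maxIter)) {
    B <- exp(.logEmission(obs, mu, sigma2))
    B <- pmax(B, 1e-300)
    fb <- .forwardBackwardDense(B, pi, A)
    ll <- fb$logLik
    if (ll < ll_prev - 1e-8)
      stop("EM log-likelihood decreased: ", ll_prev, " -> ", ll)
    gamma <- fb$gamma
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) < tol * (abs(ll_prev) + 1e-12)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    # transition expectations
    if (N > 1) {
      xi_num <- matrix(0, K, K)
      for (t in seq_len(N - 1)) {
        xi_t <- (fb$alpha[t, ] %o% (B[t + 1, ] * fb$beta[t + 1, ])) * A /
          fb$cvec[t + 1]
        xi_num <- xi_num + xi_t
      }
      denom <- colSums(gamma[seq_len(N - 1), , drop = FALSE])
      A <- xi_num / pmax(denom, 1e-12)
      A <- A / rowSums(A)
    }
    pi <- gamma[1, ]
    pi <- pi / sum(pi)
    Nk <- pmax(colSums(gamma), 1e-12)
    for (k in seq_len(K)) {
      mu[k, ] <- colSums(gamma[, k] * obs) / Nk[k]
      sigma2[k, ] <- pmax(colSums(gamma[, k] *
        sweep(obs, 2, mu[k, ])^2) / Nk[k], varFloor)
    }
  }
  list(pi = pi, A = A, mu = mu, sigma2 = sigma2, logLik = ll,
       converged = converged, nIter = it)
}

#' Fit a Gaussian-emission HMM by EM
#'
#' Baum-Welch under `mode = "concatenated"`; Gaussian-mixture EM under the
#' default `mode = "per_sample"` (length-1 sequences carry no transition
#' information, so the transition matrix is frozen uniform). The best of
#' `nRestarts` quantile-sliced-plus-jitter initializations by final
#' log-likelihood is returned; the log-likelihood is checked to be
#' non-decreasing at every iteration. Variances are floored at `varFloor`.
#'
#' @param observations numeric matrix, samples in rows (N x D), no missing
#'   values; a vector is treated as N x 1.
#' @param K number of hidden states (N >= K required).
#' @param mode `"per_sample"` (default) or `"concatenated"`.
#' @param nRestarts number of EM restarts (default 10; restart 1 unjittered).
#' @param maxIter,tol EM iteration cap and relative log-likelihood tolerance.
#' @param seed integer seed controlling restart jitter; same data + seed
#'   gives a bit-identical fit.
#' @param varFloor variance floor (default 1e-6).
#' @return a [GaussianHMMFit-class].
#' @examples
#' set.seed(1)
#' x <- matrix(c(rnorm(100, 0), rnorm(100, 6)), ncol = 1)
#' fit <- fitGaussianHMM(x, K = 2, seed = 1L)
#' sort(stateMeans(fit)[, 1])
#' @export
fitGaussianHMM <- function(observations, K, mode = c("per_sample",
                                                     "concatenated"),
                           nRestarts = 10L, maxIter = 500L, tol = 1e-6,
                           seed = 1L, varFloor = 1e-6) {
  mode <- match.arg(mode)
  obs <- as.matrix(observations)
  storage.mode(obs) <- "double"
  N <- nrow(obs); D <- ncol(obs)
  if (anyNA(obs)) stop("observations contain missing values")
  if (N < K) stop("N < K: fewer observations than hidden states")
  if (all(apply(obs, 2, function(x) diff(range(x)) == 0)))
    stop("degenerate-fit error: all observations are identical")
  em <- if (mode == "per_sample") .emPerSample else .emConcatenated
  best <- NULL
  withr::with_seed(seed, {
    sds <- apply(obs, 2, stats::sd)
    for (r in seq_len(max(1L, nRestarts))) {
      jit <- if (r == 1L) 0 else 0.5 * mean(sds)
      init <- .initParams(obs, K, jit)
      res <- tryCatch(em(obs, K, init, maxIter, tol, varFloor),
                      error = function(e) NULL)
      if (!is.null(res) && (is.null(best) || res$logLik > best$logLik))
        best <- res
    }
  })
  if (is.null(best)) stop("degenerate-fit error: no EM restart succeeded")
  p_free <- .freeParams(K, D, mode)
  new("GaussianHMMFit", K = as.integer(K), D = as.integer(D), mode = mode,
      pi = best$pi, A = best$A, mu = best$mu, sigma2 = best$sigma2,
      logLik = best$logLik,
      bic = -2 * best$logLik + p_free * log(N),
      nObs = as.integer(N), converged = best$converged,
      nIter = as.integer(best$nIter), seed = as.integer(seed))
}

#' Posterior state probabilities (forward-backward)
#'
#' Scaled forward-backward recursions under `concatenated` mode; under
#' `per_sample` mode each row's posterior is the mixture responsibility
#' `gamma_k(x) = pi_k N(x; mu_k, var_k) / sum_j pi_j N(x; mu_j, var_j)`.
#'
#' @param fit a [GaussianHMMFit-class].
#' @param observations N x D matrix matching the fit's dimension.
#' @return list with `gamma` (N x K, rows sum to 1) and `logLik`.
#' @export
forwardBackward <- function(fit, observations) {
  obs <- as.matrix(observations)
  if (ncol(obs) != fit@D)
    stop("dimension mismatch: fit D=", fit@D, ", observations D=", ncol(obs))
  if (fit@mode == "per_sample") {
    lg <- sweep(.logEmission(obs, fit@mu, fit@sigma2), 2, log(fit@pi), `+`)
    lse <- .logRowSumExp(lg)
    list(gamma = exp(lg - lse), logLik = sum(lse))
  } else {
    B <- pmax(exp(.logEmission(obs, fit@mu, fit@sigma2)), 1e-300)
    fb <- .forwardBackwardDense(B, fit@pi, fit@A)
    list(gamma = fb$gamma, logLik = fb$logLik)
  }
}

#' BIC of a fitted model
#'
#' `-2 logL + p_free log(n_obs)`. Under `per_sample` mode the transition
#' matrix is unidentifiable and excluded from `p_free`; `n_obs` is the number
#' of samples the model was fitted on.
#'
#' @param fit a [GaussianHMMFit-class].
#' @return numeric BIC.
#' @export
bicOf <- function(fit) {
  -2 * fit@logLik + .freeParams(fit@K, fit@D, fit@mode) * log(fit@nObs)
}

#' Select the number of hidden states by BIC
#'
#' Fits each K in `kRange` and returns the fit with minimal BIC; ties go to
#' the smaller K.
#'
#' @inheritParams fitGaussianHMM
#' @param kRange integer vector of candidate state counts within 1..5.
#' @return the winning [GaussianHMMFit-class].
#' @export
selectStates <- function(observations, kRange = 1:5,
                         mode = c("per_sample", "concatenated"),
                         nRestarts = 10L, maxIter = 500L, tol = 1e-6,
                         seed = 1L, varFloor = 1e-6) {
  mode <- match.arg(mode)
  stopifnot(all(kRange >= 1), all(kRange <= 5))
  kRange <- sort(unique(as.integer(kRange)))
  fits <- lapply(kRange, function(k)
    fitGaussianHMM(observations, k, mode, nRestarts, maxIter, tol, seed,
                   varFloor))
  bics <- vapply(fits, bicValue, 0)
  fits[[which.min(bics)]]     # which.min takes the first (smallest K) on ties
}
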