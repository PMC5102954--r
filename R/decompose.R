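#' Laplace-evidence model order for a subjects-by-vertices matrix
#'
#' Estimates how many latent components a metric matrix supports, by Minka's
#' Laplace approximation to the Bayesian evidence of a probabilistic-PCA model
#' evaluated on the eigenspectrum of the subject covariance (vertices act as
#' samples). The returned order maximizes the evidence and is clamped to
#' `[2, n - 1]`.
#'
#' @param X Numeric matrix, `n` subjects by `v` vertices, `n >= 10`.
#' @return Integer model order `k`.
#' @examples
#' X <- matrix(rnorm(50 * 300), 50, 300) +
#'   tcrossprod(rnorm(50), rnorm(300)) * 3
#' estimate_order(X)
#' @export
estimate_order <- function(X) {
  n <- nrow(X)
  if (n < 10) rlang::abort("estimate_order requires at least 10 subjects.")
  Xc <- center_matrix(X)
  N <- ncol(Xc)
  ev <- eigen(tcrossprod(Xc) / N, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  # drop the numerically null tail (centering alone costs one rank)
  ev <- ev[ev > max(ev) * 1e-12]
  d <- length(ev)
  if (d < 2) {
    rlang::abort("Matrix has rank < 2; cannot estimate a model order.")
  }
  kmax <- min(d - 1L, n - 1L)
  ll <- rep(-Inf, kmax)
  small <- .Machine$double.xmin
  for (k in 2:kmax) {
    lam <- ev
    vhat <- sum(lam[(k + 1):d]) / (d - k)
    if (vhat <= 0) { ll[k] <- -Inf; next }
    pu <- -k * log(2)
    ii <- seq_len(k)
    pu <- pu + sum(lgamma((d - ii + 1) / 2) - ((d - ii + 1) / 2) * log(pi))
    pl <- -N / 2 * sum(log(pmax(lam[ii], small)))
    pv <- -N * (d - k) / 2 * log(vhat)
    m <- d * k - k * (k + 1) / 2
    pp <- log(2 * pi) * (m + k) / 2
    lam_hat <- c(lam[ii], rep(vhat, d - k))
    pa <- 0
    for (i in ii) {
      j <- (i + 1):d
      gaps <- (1 / lam_hat[j] - 1 / lam_hat[i]) * (lam[i] - lam[j]) * N
      pa <- pa + sum(log(pmax(gaps, small)))
    }
    ll[k] <- pu + pl + pv + pp - pa / 2 - k / 2 * log(N)
  }
  max(2L, which.max(ll))
}

# remove the per-subject map mean and the cross-subject grand mean per vertex,
# so decompositions reflect cross-subject variability only
center_matrix <- function(X, row_standardize = FALSE) {
  Xc <- X - rowMeans(X)
  if (row_standardize) {
    s <- apply(Xc, 1, sd)
    s[s == 0] <- 1
    Xc <- Xc / s
  }
  sweep(Xc, 2, colMeans(Xc))
}

row_skewness <- function(M) {
  mu <- rowMeans(M)
  D <- M - mu
  m2 <- rowMeans(D^2)
  m3 <- rowMeans(D^3)
  ifelse(m2 > 0, m3 / m2^1.5, 0)
}

# symmetric-decorrelation step: W <- (W W^T)^{-1/2} W
sym_decorrelate <- function(W) {
  e <- eigen(tcrossprod(W), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-300)), nrow(W)) %*%
    t(e$vectors) %*% W
}

fixed_point_ica <- function(Z, k, tol = 1e-6, max_iter = 500L) {
  v <- ncol(Z)
  W <- sym_decorrelate(matrix(rnorm(k * k), k, k))
  best_W <- W
  best_delta <- Inf
  for (iter in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    W1 <- G %*% t(Z) / v - diag(rowMeans(1 - G^2), k) %*% W
    W1 <- sym_decorrelate(W1)
    if (any(!is.finite(W1))) {
      rlang::abort("Fixed-point ICA produced non-finite values.")
    }
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < best_delta) {
      best_delta <- delta
      best_W <- W
    }
    if (delta < tol) {
      return(list(W = W, converged = TRUE, iter = iter, best_delta = delta))
    }
  }
  # most stationary iterate visited; near-Gaussian residual dimensions make
  # the symmetric update wander when k exceeds the non-Gaussian subspace
  list(W = best_W, converged = FALSE, iter = max_iter,
       best_delta = best_delta)
}

#' Spatial ICA decomposition of one metric matrix
#'
#' Decomposes a subjects-by-vertices metric matrix into `k` surface component
#' maps (SCMs) and their subject courses using fixed-point spatial ICA
#' (symmetric FastICA with the tanh negentropy contrast), treating vertices as
#' samples. The matrix is first centered (per-subject map mean and
#' cross-subject grand mean removed, optionally row-standardized), then
#' whitened to `k` principal dimensions.
#'
#' Conventions making results reproducible and comparable downstream:
#' each SCM is scaled to zero mean and unit SD over vertices (a vertex-wise
#' Z-map of relative contribution); the sign of every SCM is flipped, jointly
#' with its course, so SCM skewness is non-negative (focal loadings positive);
#' components are ordered by explained variance, descending. On
#' non-convergence the fixed-point iteration is restarted with a fresh
#' initialization up to 3 times, then errors.
#'
#' @param X Numeric matrix, `n` subjects by `v` vertices.
#' @param k Number of components, `2 <= k < n`; default via
#'   [estimate_order()].
#' @param seed Integer seed for the ICA initialization.
#' @param metric_name Label carried into the result.
#' @param row_standardize Scale each subject's centered map to unit variance
#'   before decomposition (default `TRUE`).
#' @param tol,max_iter Fixed-point convergence controls.
#' @return A `decomposition`: list with `metric`, `scms` (`k x v`), `courses`
#'   (`n x k`), `k`, `order_method`, `seed`, `row_standardize`, `converged`.
#' @examples
#' X <- tcrossprod(rnorm(40), rnorm(300)) +
#'   tcrossprod(rnorm(40), rnorm(300)) + 0.1 * matrix(rnorm(12000), 40, 300)
#' d <- decompose_metric(X, k = 2, seed = 1, metric_name = "thick")
#' dim(d$scms)
#' @export
decompose_metric <- function(X, k = NULL, seed = 1L, metric_name = "metric",
                             row_standardize = TRUE, tol = 1e-6,
                             max_iter = 500L) {
  n <- nrow(X)
  order_method <- if (is.null(k)) "laplace" else "fixed"
  if (is.null(k)) k <- estimate_order(X)
  k <- as.integer(k)
  if (k < 2 || k >= n) rlang::abort("k must satisfy 2 <= k < n.")
  Xc <- center_matrix(X, row_standardize = row_standardize)
  v <- ncol(Xc)

  # whiten to k dims: rows of Z are uncorrelated, unit variance over vertices
  e <- eigen(tcrossprod(Xc) / v, symmetric = TRUE)
  if (e$values[k] <= max(e$values) * 1e-12) {
    rlang::abort("Matrix rank below requested k; cannot whiten.")
  }
  E <- e$vectors[, seq_len(k), drop = FALSE]
  Z <- diag(1 / sqrt(e$values[seq_len(k)]), k) %*% t(E) %*% Xc

  fit <- NULL
  for (attempt in 0:3) {
    att <- withr::with_seed(seed + attempt,
                            fixed_point_ica(Z, k, tol, max_iter))
    if (is.null(fit) || att$converged ||
        (!fit$converged && att$best_delta < fit$best_delta)) fit <- att
    if (fit$converged) break
  }
  if (!fit$converged) {
    rlang::warn(paste0(
      "Spatial ICA for '", metric_name, "' did not reach tol after 4 seeded ",
      "attempts (best delta ", signif(fit$best_delta, 3), "); returning the ",
      "most stationary iterate. Typical when k exceeds the non-Gaussian ",
      "subspace."))
  }
  S <- fit$W %*% Z                       # k x v source maps, zero-mean rows
  courses <- Xc %*% t(S) / v             # n x k (S rows ~ orthonormal in sample)

  s_sd <- sqrt(rowMeans(S^2) - rowMeans(S)^2)
  s_sd[s_sd == 0] <- 1
  scms <- (S - rowMeans(S)) / s_sd
  courses <- sweep(courses, 2, s_sd, `*`)

  flip <- ifelse(row_skewness(scms) < 0, -1, 1)
  scms <- scms * flip
  courses <- sweep(courses, 2, flip, `*`)

  ord <- order(colSums(courses^2), decreasing = TRUE)
  scms <- scms[ord, , drop = FALSE]
  courses <- courses[, ord, drop = FALSE]
  rownames(scms) <- paste0(metric_name, "_", seq_len(k))
  colnames(courses) <- rownames(scms)
  rownames(courses) <- rownames(X)

  structure(list(metric = metric_name, scms = scms, courses = courses,
                 k = k, order_method = order_method, seed = seed,
                 row_standardize = row_standardize,
                 converged = fit$converged, iterations = fit$iter),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat("<decomposition> '", x$metric, "': k = ", x$k, " (",
      x$order_method, "), ", nrow(x$courses), " subjects x ",
      ncol(x$scms), " vertices\n", sep = "")
  invisible(x)
}

#' Decompose every metric of a cohort
#'
#' @param cohort A [cohort_bundle()].
#' @param k `NULL` for per-metric Laplace order selection, or a single integer
#'   / named integer vector of fixed orders.
#' @param seed Base seed; metric `i` uses `seed + 100 * i` so decompositions
#'   are independent but jointly reproducible.
#' @param ... Passed to [decompose_metric()].
#' @return Named list of `decomposition` objects.
#' @export
decompose_cohort <- function(cohort, k = NULL, seed = 1L, ...) {
  stopifnot(inherits(cohort, "cohort_bundle"))
  metrics <- names(cohort$metrics)
  res <- vector("list", length(metrics))
  names(res) <- metrics
  for (i in seq_along(metrics)) {
    m <- metrics[i]
    km <- if (is.null(k)) NULL else if (length(k) == 1L && is.null(names(k)))
      k else k[[m]]
    res[[m]] <- decompose_metric(cohort$metrics[[m]], k = km,
                                 seed = seed + 100L * i,
                                 metric_name = m, ...)
  }
  res
}
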