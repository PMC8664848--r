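# Independent oracles used across the suite.  These deliberately avoid the
# package's own computational paths: brute-force linear algebra, direct
# quadrature, closed forms.

# Tensor-product Gauss-Legendre integration of an M-variate Gaussian density
# over a rectangle; infinite limits are truncated at mean +- 7.5 marginal sd
# (truncated mass ~ 3e-14).  Node counts calibrated against exact cases to
# <= 5e-8 for M <= 5 at the condition numbers random_spd produces.
mvn_rect_prob_quadrature <- function(mean, Sigma, lower, upper,
                                     nodes = NULL) {
  M <- length(mean)
  sds <- sqrt(diag(Sigma))
  lo <- pmax(lower, mean - 7.5 * sds)
  up <- pmin(upper, mean + 7.5 * sds)
  if (any(lo >= up)) return(0)
  if (is.null(nodes)) nodes <- c(64, 48, 48, 40, 32)[min(M, 5)]
  gl <- lapply(seq_len(M), function(j) pracma::gaussLegendre(nodes, lo[j], up[j]))
  Sinv <- solve(Sigma)
  logdet <- determinant(Sigma, logarithm = TRUE)$modulus
  const <- -0.5 * (M * log(2 * pi) + as.numeric(logdet))
  dens <- function(pts) {
    d <- sweep(pts, 2, mean)
    exp(const - 0.5 * rowSums((d %*% Sinv) * d))
  }
  if (M == 1) {
    return(sum(gl[[1]]$w * dens(matrix(gl[[1]]$x, ncol = 1))))
  }
  inner <- as.matrix(expand.grid(lapply(gl[-M], `[[`, "x")))
  w_inner <- Reduce(function(a, b) as.vector(outer(a, b)),
                    lapply(gl[-M], `[[`, "w"))
  total <- 0
  for (k in seq_len(nodes)) {
    pts <- cbind(inner, gl[[M]]$x[k])
    total <- total + gl[[M]]$w[k] * sum(w_inner * dens(pts))
  }
  total
}

# random symmetric positive-definite covariance with unit-scale variances
random_spd <- function(M, scale = 1) {
  A <- matrix(rnorm(M * M), M)
  S <- tcrossprod(A) / M + diag(0.2, M)
  S * scale
}

# Single-task GP predictive distribution, the textbook formulas, written
# without any of the package's multi-task machinery.
st_gp_predict <- function(X, y, Xs, kern, mean_f, noise_var) {
  K <- outer(seq_len(nrow(X)), seq_len(nrow(X)),
             Vectorize(function(i, j) kern(X[i, ], X[j, ])))
  Ks <- outer(seq_len(nrow(X)), seq_len(nrow(Xs)),
              Vectorize(function(i, j) kern(X[i, ], Xs[j, ])))
  Sigma <- K + diag(noise_var, nrow(X))
  Sinv <- solve(Sigma)
  mu_tr <- apply(X, 1, mean_f)
  mu_s <- apply(Xs, 1, mean_f)
  pred_mean <- mu_s + as.numeric(crossprod(Ks, Sinv %*% (y - mu_tr)))
  pred_var <- vapply(seq_len(nrow(Xs)), function(j) {
    kern(Xs[j, ], Xs[j, ]) - as.numeric(crossprod(Ks[, j], Sinv %*% Ks[, j]))
  }, 0)
  list(mean = pred_mean, var = pred_var)
}

# Brute-force negative log marginal likelihood: explicit NM x NM assembly
# with scalar loops and generic solve()/determinant(), no Cholesky reuse.
brute_nll <- function(params, X, Z) {
  N <- nrow(X); M <- ncol(Z)
  Kf <- tcrossprod(params$B) + diag(params$v_task, M)
  kern <- function(a, b) {
    s <- 0
    for (q in seq_along(params$w)) {
      term <- params$w[q]
      for (p in 1:2) {
        tau <- a[p] - b[p]
        term <- term * exp(-2 * pi^2 * tau^2 * params$v[q, p]) *
          cos(2 * pi * tau * params$mu[q, p])
      }
      s <- s + term
    }
    s
  }
  Sigma <- matrix(0, N * M, N * M)
  for (i in 1:M) for (j in 1:M) for (s in 1:N) for (t in 1:N) {
    Sigma[(i - 1) * N + s, (j - 1) * N + t] <-
      Kf[i, j] * kern(X[s, ], X[t, ]) +
      (if (i == j && s == t) params$D[i] else 0)
  }
  Phi <- cbind(1, X[, 1], X[, 2], X[, 1] * X[, 2], X[, 1]^2, X[, 2]^2)
  r <- as.vector(Z - Phi %*% params$C)
  ld <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
  0.5 * as.numeric(crossprod(r, solve(Sigma, r))) + 0.5 * ld +
    N * M / 2 * log(2 * pi)
}

# random valid transformed parameter set for small M
random_mtgp_params <- function(Q, M, r) {
  list(
    w = runif(Q, 0.3, 1.5),
    mu = matrix(runif(2 * Q, 0, 0.8), Q, 2),
    v = matrix(runif(2 * Q, 0.3, 3), Q, 2),
    B = matrix(rnorm(M * r, 0, 0.5), M, r),
    v_task = runif(M, 0.2, 0.8),
    D = runif(M, 0.05, 0.3),
    C = matrix(rnorm(6 * M, 0, 0.3), 6, M)
  )
}
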