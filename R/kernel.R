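#' Spectral mixture kernel and task covariance primitives
#'
#' The spatial covariance is a spectral mixture (SM) kernel: a stationary
#' kernel whose spectral density is a mixture of Q Gaussians,
#' \deqn{k(\tau) = \sum_q w_q \prod_p \exp(-2\pi^2 \tau_p^2 v_p^{(q)})
#'   \cos(2\pi \tau_p \mu_p^{(q)}),}
#' able to approximate any stationary kernel as Q grows.  The inter-parameter
#' (task) covariance is parameterized low-rank as `K^f = B B' + diag(v)` with
#' `B` an M x r matrix, and the spatial trend is a full quadratic polynomial
#' in the two scaled coordinates, one coefficient vector per task.
#'
#' The component "length-scale" used for the over-fitting guard is
#' `l = 1/(2*pi*sqrt(v))` in scaled-coordinate units, i.e. the standard
#' deviation of the Gaussian envelope `exp(-tau^2/(2 l^2))` that the SM term
#' reduces to; the default training box is `l` in \[0.1, 100\].
#'
#' @name sm-kernel
NULL

#' Evaluate the spectral mixture kernel at coordinate differences
#'
#' @param tau Numeric vector of length d, or an n x d matrix of coordinate
#'   differences.
#' @param params List with `w` (length Q, positive), `mu` (Q x d) and `v`
#'   (Q x d, positive) — weights, spectral means and spectral variances.
#' @return Numeric vector of kernel values.
#' @export
sm_kernel <- function(tau, params) {
  tau <- if (is.matrix(tau)) tau else matrix(tau, nrow = 1)
  w <- params$w
  mu <- as.matrix(params$mu); v <- as.matrix(params$v)
  stopifnot(length(w) == nrow(mu), all(dim(mu) == dim(v)), ncol(tau) == ncol(mu))
  out <- numeric(nrow(tau))
  for (q in seq_along(w)) {
    term <- rep(w[q], nrow(tau))
    for (p in seq_len(ncol(tau))) {
      term <- term * exp(-2 * pi^2 * tau[, p]^2 * v[q, p]) *
        cos(2 * pi * tau[, p] * mu[q, p])
    }
    out <- out + term
  }
  out
}

# SM kernel cross-covariance matrix between two point sets (d = 2)
sm_kernel_matrix <- function(X1, X2, params) {
  T1 <- outer(X1[, 1], X2[, 1], "-")
  T2 <- outer(X1[, 2], X2[, 2], "-")
  K <- matrix(0, nrow(X1), nrow(X2))
  for (q in seq_along(params$w)) {
    K <- K + params$w[q] *
      exp(-2 * pi^2 * (T1^2 * params$v[q, 1] + T2^2 * params$v[q, 2])) *
      cos(2 * pi * T1 * params$mu[q, 1]) * cos(2 * pi * T2 * params$mu[q, 2])
  }
  K
}

#' Assemble the low-rank task covariance matrix
#'
#' @param B M x r loading matrix.
#' @param v Length-M positive vector of per-task diagonal offsets.
#' @return The M x M symmetric positive-definite matrix `B B' + diag(v)`.
#' @export
task_covariance <- function(B, v) {
  B <- as.matrix(B)
  stopifnot(nrow(B) == length(v))
  if (any(v <= 0)) stop("task covariance diagonal offsets must be positive",
                        call. = FALSE)
  tcrossprod(B) + diag(v, nrow = length(v))
}

#' Quadratic spatial mean function
#'
#' @param X n x 2 matrix of scaled coordinates.
#' @param C 6 x M coefficient matrix; rows are the intercept, x1, x2, x1*x2,
#'   x1^2 and x2^2 coefficient vectors (one column per task).
#' @return n x M matrix of mean values.
#' @export
quadratic_mean <- function(X, C) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == 2, nrow(C) == 6)
  mean_design(X) %*% C
}

mean_design <- function(X) {
  cbind(1, X[, 1], X[, 2], X[, 1] * X[, 2], X[, 1]^2, X[, 2]^2)
}

#' Task correlation matrix from the optimized task covariance
#'
#' @param Kf M x M symmetric positive-definite task covariance.
#' @return M x M Pearson correlation matrix with unit diagonal.
#' @export
correlation_from_task_cov <- function(Kf) {
  Kf <- as.matrix(Kf)
  d <- diag(Kf)
  if (any(d <= 0)) stop("task covariance has a non-positive diagonal entry",
                        call. = FALSE)
  R <- Kf / sqrt(outer(d, d))
  diag(R) <- 1
  dimnames(R) <- dimnames(Kf)
  R
}

# length-scale <-> spectral variance convention used throughout
lengthscale_to_specvar <- function(ell) 1 / (4 * pi^2 * ell^2)
specvar_to_lengthscale <- function(v) 1 / (2 * pi * sqrt(v))
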