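#' Multi-task Gaussian process regression core
#'
#' The model couples M warped measurement fields through
#' \deqn{\Sigma = K^f \otimes K^x + D \otimes I_N,}
#' with `K^x` the spectral mixture kernel on the N scaled sample locations,
#' `K^f = B B' + diag(v)` the low-rank inter-task covariance, `D` a diagonal
#' per-task noise matrix and a quadratic polynomial trend per task.
#' Hyper-parameters are obtained by maximizing the exact log marginal
#' likelihood with a first-order adaptive optimizer (Adam) over unconstrained
#' raw parameters (softplus for positive quantities, a logistic box map for
#' the component length-scales).
#'
#' Two linear-algebra routes are implemented.  The default route exploits the
#' Kronecker structure through per-factor eigendecompositions after whitening
#' by the task noise, costing `O(N^3 + M^3)` instead of `O(N^3 M^3)`; a naive
#' dense route over the flattened `NM x NM` system is retained for small
#' problems and serves as the internal oracle.
#'
#' @name mtgp
NULL

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
softplus_inv <- function(y) ifelse(y > 30, y, log(expm1(pmax(y, 1e-12))))
dsoftplus <- function(x) stats::plogis(x)

# --- raw parameter vector layout -------------------------------------------

mtgp_param_dims <- function(Q, M, r) {
  Q <- unname(Q); M <- unname(M); r <- unname(r)
  sizes <- c(w = Q, mu = 2 * Q, ell = 2 * Q, B = M * r, v_task = M,
             D = M, C = 6 * M)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  list(sizes = sizes, starts = starts, ends = ends, total = sum(sizes))
}

mtgp_unpack <- function(raw, Q, M, r, box) {
  d <- mtgp_param_dims(Q, M, r)
  seg <- function(nm) raw[d$starts[[nm]]:d$ends[[nm]]]
  ell <- box[1] + (box[2] - box[1]) * stats::plogis(seg("ell"))
  list(
    w = softplus(seg("w")),
    mu = matrix(seg("mu"), Q, 2),
    ell = matrix(ell, Q, 2),
    v = matrix(lengthscale_to_specvar(ell), Q, 2),
    B = matrix(seg("B"), M, r),
    v_task = softplus(seg("v_task")),
    D = softplus(seg("D")),
    C = matrix(seg("C"), 6, M)
  )
}

mtgp_kernel_params <- function(p) list(w = p$w, mu = p$mu, v = p$v)

# --- marginal likelihood ----------------------------------------------------

#' Negative log marginal likelihood of the multi-task GP
#'
#' Returns `-log p(Z | X, theta)` for the flattened `N*M` observation vector.
#' The `"kronecker"` method whitens by the task noise and eigendecomposes the
#' two Kronecker factors; `"dense"` assembles the full `NM x NM` covariance
#' and is intended for small problems and cross-checking.
#'
#' @param params Parameter list with elements `w`, `mu`, `v` (spectral mixture),
#'   `B`, `v_task` (task covariance), `D` (noise variances) and `C` (6 x M
#'   trend coefficients), e.g. the `$params` of a fitted model.
#' @param X N x 2 matrix of scaled coordinates.
#' @param Z N x M matrix of warped observations.
#' @param method `"kronecker"` or `"dense"`.
#' @return Scalar negative log marginal likelihood.
#' @export
neg_log_marginal_likelihood <- function(params, X, Z,
                                        method = c("kronecker", "dense")) {
  method <- match.arg(method)
  X <- as.matrix(X); Z <- as.matrix(Z)
  N <- nrow(X); M <- ncol(Z)
  Kx <- sm_kernel_matrix(X, X, mtgp_kernel_params(params))
  Kf <- task_covariance(params$B, params$v_task)
  R <- Z - quadratic_mean(X, params$C)
  if (method == "dense") {
    Sigma <- kronecker(Kf, Kx) + diag(rep(params$D, each = N))
    L <- chol(Sigma)
    alpha <- backsolve(L, forwardsolve(t(L), as.vector(R)))
    return(0.5 * sum(as.vector(R) * alpha) + sum(log(diag(L))) +
             N * M / 2 * log(2 * pi))
  }
  Dh <- sqrt(params$D)
  Kft <- Kf / outer(Dh, Dh)
  eF <- eigen(Kft, symmetric = TRUE)
  eX <- eigen(Kx, symmetric = TRUE)
  denom <- outer(eX$values, eF$values) + 1
  if (any(denom <= 0)) stop("indefinite whitened covariance", call. = FALSE)
  P <- crossprod(eX$vectors, sweep(R, 2, Dh, "/") %*% eF$vectors)
  0.5 * sum(P^2 / denom) + 0.5 * (sum(log(denom)) + N * sum(log(params$D))) +
    N * M / 2 * log(2 * pi)
}

#' Training objective: value and analytic gradient over raw parameters
#'
#' The objective is the negative log marginal likelihood as a function of the
#' unconstrained raw parameter vector (softplus / logistic-box transforms
#' applied internally).  The gradient is exact (matrix calculus through the
#' dense representation with block-structured contractions) and is what the
#' optimizer consumes; it can be validated against finite differences.
#'
#' @param raw Numeric raw parameter vector (see [mtgp_init()] for the layout).
#' @param X,Z Training coordinates and warped observations.
#' @param Q,r Mixture size and task-covariance rank.
#' @param box Length-scale box `c(min, max)` in scaled units.
#' @param jitter Starting diagonal jitter added on Cholesky failure
#'   (escalating tenfold up to `jitter_max`).
#' @param jitter_max Largest jitter attempted before giving up.
#' @return List with `value`, `grad` (same length as `raw`) and `jitter` (the
#'   jitter actually applied, 0 if none).
#' @export
mtgp_objective <- function(raw, X, Z, Q, r, box = c(0.1, 100),
                           jitter = 1e-6, jitter_max = 1e-2) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  N <- nrow(X); M <- ncol(Z)
  p <- mtgp_unpack(raw, Q, M, r, box)
  d <- mtgp_param_dims(Q, M, r)

  T1 <- outer(X[, 1], X[, 1], "-")
  T2 <- outer(X[, 2], X[, 2], "-")
  T1s <- T1^2; T2s <- T2^2

  comps <- vector("list", Q)
  Kx <- matrix(0, N, N)
  for (q in seq_len(Q)) {
    A1 <- exp(-2 * pi^2 * T1s * p$v[q, 1]); C1 <- cos(2 * pi * T1 * p$mu[q, 1])
    A2 <- exp(-2 * pi^2 * T2s * p$v[q, 2]); C2 <- cos(2 * pi * T2 * p$mu[q, 2])
    E <- A1 * C1 * A2 * C2
    comps[[q]] <- list(A1 = A1, A2 = A2, C1 = C1, C2 = C2, E = E)
    Kx <- Kx + p$w[q] * E
  }
  Kf <- task_covariance(p$B, p$v_task)
  Phi <- mean_design(X)
  R <- Z - Phi %*% p$C
  rvec <- as.vector(R)

  Sigma <- kronecker(Kf, Kx) + diag(rep(p$D, each = N))
  jit_used <- 0
  L <- tryCatch(chol(Sigma), error = function(e) NULL)
  while (is.null(L)) {
    if (jitter > jitter_max) {
      stop(sprintf("covariance ill-conditioned: Cholesky failed at jitter %g",
                   jitter), call. = FALSE)
    }
    jit_used <- jitter
    L <- tryCatch(chol(Sigma + diag(jitter, N * M)), error = function(e) NULL)
    jitter <- jitter * 10
  }
  alpha <- backsolve(L, forwardsolve(t(L), rvec))
  value <- 0.5 * sum(rvec * alpha) + sum(log(diag(L))) + N * M / 2 * log(2 * pi)

  Sinv <- chol2inv(L)
  W <- Sinv - tcrossprod(alpha)
  blk <- function(j) ((j - 1) * N + 1):(j * N)

  # contractions: WK for kernel params, Tm for task-covariance params
  WK <- matrix(0, N, N)
  Tm <- matrix(0, M, M)
  gD <- numeric(M)
  for (i in seq_len(M)) {
    bi <- blk(i)
    for (j in seq_len(M)) {
      Wb <- W[bi, blk(j)]
      WK <- WK + Kf[i, j] * Wb
      Tm[i, j] <- sum(Wb * Kx)
    }
    gD[i] <- 0.5 * sum(diag(W[bi, bi]))
  }

  grad <- numeric(d$total)
  # spectral mixture parameters
  for (q in seq_len(Q)) {
    cm <- comps[[q]]
    grad[d$starts[["w"]] + q - 1] <-
      0.5 * sum(WK * cm$E) * dsoftplus(raw[d$starts[["w"]] + q - 1])
    grad[d$starts[["mu"]] + q - 1] <-
      -pi * p$w[q] * sum(WK * (T1 * sin(2 * pi * T1 * p$mu[q, 1]) *
                                 cm$A1 * cm$A2 * cm$C2))
    grad[d$starts[["mu"]] + Q + q - 1] <-
      -pi * p$w[q] * sum(WK * (T2 * sin(2 * pi * T2 * p$mu[q, 2]) *
                                 cm$A2 * cm$A1 * cm$C1))
    dv1 <- 0.5 * p$w[q] * sum(WK * (-2 * pi^2 * T1s * cm$E))
    dv2 <- 0.5 * p$w[q] * sum(WK * (-2 * pi^2 * T2s * cm$E))
    for (pp in 1:2) {
      i_ell <- d$starts[["ell"]] + (pp - 1) * Q + q - 1
      sig <- stats::plogis(raw[i_ell])
      dell_draw <- (box[2] - box[1]) * sig * (1 - sig)
      dv_dell <- -2 * p$v[q, pp] / p$ell[q, pp]
      grad[i_ell] <- (if (pp == 1) dv1 else dv2) * dv_dell * dell_draw
    }
  }
  # task covariance: d(0.5 tr(W dSigma)) with dSigma = dKf (x) Kx
  gB <- Tm %*% p$B                       # 0.5 * (T + T') B with T symmetric
  grad[d$starts[["B"]]:d$ends[["B"]]] <- as.vector(gB)
  grad[d$starts[["v_task"]]:d$ends[["v_task"]]] <-
    0.5 * diag(Tm) * dsoftplus(raw[d$starts[["v_task"]]:d$ends[["v_task"]]])
  grad[d$starts[["D"]]:d$ends[["D"]]] <-
    gD * dsoftplus(raw[d$starts[["D"]]:d$ends[["D"]]])
  # trend coefficients
  grad[d$starts[["C"]]:d$ends[["C"]]] <-
    as.vector(-crossprod(Phi, matrix(alpha, N, M)))

  list(value = value, grad = grad, jitter = jit_used)
}

# --- initialization ---------------------------------------------------------

#' Seeded raw-parameter initialization
#'
#' Weights start at the total warped-data variance split evenly over the Q
#' components; spectral means are drawn uniformly over low frequencies (up to
#' one cycle per unit domain — starting at the far higher Nyquist frequency
#' of the sample spacing plants oscillatory components that lock onto noise);
#' length-scales start at 0.3 scaled units; the trend starts at the per-task
#' means; noise starts at 10% of the per-task variances.
#'
#' @inheritParams mtgp_objective
#' @param seed Integer seed governing the random draws.
#' @return Numeric raw parameter vector.
#' @export
mtgp_init <- function(X, Z, Q, r, box = c(0.1, 100), seed = 1) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  N <- nrow(X); M <- ncol(Z)
  d <- mtgp_param_dims(Q, M, r)
  raw <- numeric(d$total)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)

  # initial spectral means: random low frequencies up to one cycle per unit
  # domain (the Nyquist frequency of the sample spacing is far higher, but
  # starting there plants high-frequency components that lock onto noise)
  f_init <- 1

  tot_var <- max(stats::var(as.vector(Z)), 1e-8)
  col_var <- pmax(apply(Z, 2, stats::var), 1e-8)

  raw[d$starts[["w"]]:d$ends[["w"]]] <- softplus_inv(rep(tot_var / Q, Q))
  raw[d$starts[["mu"]]:d$ends[["mu"]]] <- stats::runif(2 * Q, 0, f_init)
  raw[d$starts[["ell"]]:d$ends[["ell"]]] <-
    stats::qlogis((0.3 - box[1]) / (box[2] - box[1]))
  raw[d$starts[["B"]]:d$ends[["B"]]] <- stats::rnorm(M * r, 0, sqrt(0.5 / r))
  raw[d$starts[["v_task"]]:d$ends[["v_task"]]] <- softplus_inv(rep(0.5, M))
  raw[d$starts[["D"]]:d$ends[["D"]]] <- softplus_inv(0.1 * col_var)
  C0 <- matrix(0, 6, M); C0[1, ] <- colMeans(Z)
  raw[d$starts[["C"]]:d$ends[["C"]]] <- as.vector(C0)
  raw
}

# --- training ---------------------------------------------------------------

#' Control settings for model fitting
#'
#' @param learning_rate Adam step size.
#' @param iterations Number of optimizer iterations.
#' @param lengthscale_box Allowed component length-scale interval in scaled
#'   coordinate units (over-fitting guard).
#' @param restarts Number of random initializations; the spectral mixture
#'   likelihood is multi-modal, so the run with the best final marginal
#'   likelihood is kept.
#' @param beta1,beta2,adam_eps Adam moment decays and stabilizer.
#' @param jitter,jitter_max Diagonal jitter escalation on Cholesky failure.
#' @return A list of class `psqi_fit_control`.
#' @export
fit_control <- function(learning_rate = 0.1, iterations = 300,
                        lengthscale_box = c(0.1, 100), restarts = 1,
                        beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                        jitter = 1e-6, jitter_max = 1e-2) {
  structure(list(learning_rate = learning_rate, iterations = iterations,
                 lengthscale_box = lengthscale_box, restarts = restarts,
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 jitter = jitter, jitter_max = jitter_max),
            class = "psqi_fit_control")
}

#' Fit the multi-task GP by maximum marginal likelihood
#'
#' @param X N x 2 matrix of scaled coordinates (from [coords_to_model()]).
#' @param Z N x M matrix of warped observations (from [warp_forward()]).
#' @param Q Spectral mixture size.
#' @param r Rank of the low-rank part of the task covariance (`r <= M`).
#' @param control A [fit_control()] list.
#' @param seed Integer seed; two runs with the same seed and data are
#'   bit-for-bit identical.
#' @return A `psqi_mtgp` object holding transformed parameters, the raw
#'   optimizer state, the training data and the loss trace.
#' @export
fit_model <- function(X, Z, Q, r, control = fit_control(), seed = 1) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  N <- nrow(X); M <- ncol(Z)
  Q <- unname(Q); r <- unname(r)
  stopifnot(N >= 10, nrow(Z) == N, Q >= 1, r >= 1, r <= M)
  box <- control$lengthscale_box

  best <- NULL
  for (k in seq_len(max(1, control$restarts))) {
    run_seed <- seed + (k - 1) * 1009
    raw <- mtgp_init(X, Z, Q, r, box = box, seed = run_seed)
    m <- numeric(length(raw)); v2 <- numeric(length(raw))
    trace <- numeric(control$iterations)
    max_jit <- 0
    for (it in seq_len(control$iterations)) {
      ob <- mtgp_objective(raw, X, Z, Q, r, box = box,
                           jitter = control$jitter,
                           jitter_max = control$jitter_max)
      if (!is.finite(ob$value)) {
        stop(sprintf("optimization diverged (non-finite loss) at iteration %d", it),
             call. = FALSE)
      }
      trace[it] <- ob$value
      max_jit <- max(max_jit, ob$jitter)
      m <- control$beta1 * m + (1 - control$beta1) * ob$grad
      v2 <- control$beta2 * v2 + (1 - control$beta2) * ob$grad^2
      mhat <- m / (1 - control$beta1^it)
      vhat <- v2 / (1 - control$beta2^it)
      raw <- raw - control$learning_rate * mhat / (sqrt(vhat) + control$adam_eps)
    }
    final <- mtgp_objective(raw, X, Z, Q, r, box = box,
                            jitter = control$jitter,
                            jitter_max = control$jitter_max)$value
    if (is.null(best) || final < best$final) {
      best <- list(raw = raw, trace = trace, jitter = max_jit,
                   final = final, seed = run_seed)
    }
  }

  p <- mtgp_unpack(best$raw, Q, M, r, box)
  structure(
    list(params = c(p, list(Kf = task_covariance(p$B, p$v_task))),
         raw = best$raw, Q = Q, r = r, M = M, N = N, box = box,
         X = X, Z = Z, parameters = colnames(Z),
         trace = best$trace, seed = seed, restart_seed = best$seed,
         control = control, jitter = best$jitter),
    class = "psqi_mtgp"
  )
}

#' @export
print.psqi_mtgp <- function(x, ...) {
  cat(sprintf("Multi-task GP: N=%d, M=%d, Q=%d, r=%d; final NLL %.4f\n",
              x$N, x$M, x$Q, x$r, x$trace[length(x$trace)]))
  invisible(x)
}

# --- prediction -------------------------------------------------------------

#' Joint predictive distributions at new locations
#'
#' Returns the warped-space M-variate Gaussian predictive distribution of the
#' latent field at each requested location (observation noise `D` is not
#' added).  The default route exploits the Kronecker structure; `"dense"`
#' performs the naive flattened computation (small problems only).
#'
#' @param object A fitted `psqi_mtgp` model.
#' @param X_star n x 2 matrix of scaled coordinates.
#' @param method `"kronecker"` or `"dense"`.
#' @param batch_size Locations processed per block on the Kronecker route.
#' @param ... Unused.
#' @return A `psqi_pred` object: `mean` (n x M) and `cov` (M x M x n) in
#'   warped space, plus the locations.
#' @export
predict.psqi_mtgp <- function(object, X_star, method = c("kronecker", "dense"),
                              batch_size = 1024, ...) {
  method <- match.arg(method)
  X_star <- as.matrix(X_star)
  if (ncol(X_star) != 2) stop("X_star must be n x 2", call. = FALSE)
  p <- object$params
  n <- nrow(X_star)
  M <- object$M
  if (method == "dense") {
    out <- .mtgp_predict_dense(object, X_star)
  } else {
    pre <- .mtgp_kron_prepare(object)
    means <- matrix(NA_real_, n, M)
    covs <- array(NA_real_, c(M, M, n))
    done <- 0
    while (done < n) {
      take <- seq(done + 1, min(done + batch_size, n))
      b <- tryCatch(
        .mtgp_predict_kron(object, pre, X_star[take, , drop = FALSE]),
        error = function(e) stop(sprintf("prediction failed in batch %d-%d: %s",
                                         take[1], take[length(take)],
                                         conditionMessage(e)), call. = FALSE))
      means[take, ] <- b$mean
      covs[, , take] <- b$cov
      done <- take[length(take)]
    }
    out <- list(mean = means, cov = covs)
  }
  colnames(out$mean) <- object$parameters
  structure(list(mean = out$mean, cov = out$cov, locations = X_star,
                 parameters = object$parameters),
            class = "psqi_pred")
}

.mtgp_kron_prepare <- function(object) {
  p <- object$params
  X <- object$X
  N <- object$N
  Kx <- sm_kernel_matrix(X, X, mtgp_kernel_params(p))
  Dh <- sqrt(p$D)
  Kft <- p$Kf / outer(Dh, Dh)
  eF <- eigen(Kft, symmetric = TRUE)
  eX <- eigen(Kx, symmetric = TRUE)
  denom <- outer(eX$values, eF$values) + 1
  R1 <- sweep(object$Z - quadratic_mean(X, p$C), 2, Dh, "/")
  P <- crossprod(eX$vectors, R1 %*% eF$vectors) / denom
  Amat <- sweep(eX$vectors %*% tcrossprod(P, eF$vectors), 2, Dh, "/")
  A2 <- crossprod(eF$vectors, sweep(p$Kf, 1, Dh, "/"))   # M x M
  list(V = eX$vectors, denom = denom, Amat = Amat, A2 = A2,
       k0 = sum(p$w))
}

.mtgp_predict_kron <- function(object, pre, Xs) {
  p <- object$params
  Ks <- sm_kernel_matrix(object$X, Xs, mtgp_kernel_params(p))  # N x n
  n <- nrow(Xs); M <- object$M
  Mean <- quadratic_mean(Xs, p$C) + t(p$Kf %*% crossprod(pre$Amat, Ks))
  Us <- crossprod(pre$V, Ks)                                   # N x n
  Cn <- crossprod(Us^2, 1 / pre$denom)                         # n x M
  covs <- array(NA_real_, c(M, M, n))
  prior <- p$Kf * pre$k0
  for (t in seq_len(n)) {
    Qm <- crossprod(pre$A2, pre$A2 * Cn[t, ])
    S <- prior - (Qm + t(Qm)) / 2
    covs[, , t] <- (S + t(S)) / 2
  }
  list(mean = Mean, cov = covs)
}

.mtgp_predict_dense <- function(object, Xs) {
  p <- object$params
  X <- object$X; N <- object$N; M <- object$M
  Kx <- sm_kernel_matrix(X, X, mtgp_kernel_params(p))
  Sigma <- kronecker(p$Kf, Kx) + diag(rep(p$D, each = N))
  Sinv <- chol2inv(chol(Sigma))
  rvec <- as.vector(object$Z - quadratic_mean(X, p$C))
  k0 <- sum(p$w)
  n <- nrow(Xs)
  means <- matrix(NA_real_, n, M)
  covs <- array(NA_real_, c(M, M, n))
  for (t in seq_len(n)) {
    ks <- sm_kernel_matrix(X, Xs[t, , drop = FALSE], p)       # N x 1
    Kstar <- kronecker(p$Kf, ks)                              # NM x M
    means[t, ] <- as.numeric(quadratic_mean(Xs[t, , drop = FALSE], p$C)) +
      as.numeric(crossprod(Kstar, Sinv %*% rvec))
    S <- p$Kf * k0 - crossprod(Kstar, Sinv %*% Kstar)
    covs[, , t] <- (S + t(S)) / 2
  }
  list(mean = means, cov = covs)
}

#' @export
print.psqi_pred <- function(x, ...) {
  cat(sprintf("Predictive distributions at %d locations, %d parameters (warped space)\n",
              nrow(x$mean), ncol(x$mean)))
  invisible(x)
}
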