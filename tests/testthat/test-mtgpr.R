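test_that("spectral mixture kernel satisfies its algebraic identities", {
  set.seed(2)
  # tau = 0 returns the sum of weights
  p <- list(w = c(0.7, 1.3), mu = matrix(runif(4), 2), v = matrix(runif(4, .1, 2), 2))
  expect_equal(sm_kernel(c(0, 0), p), 2.0)
  # Q = 1, mu = 0, v = 1/(4 pi^2): the unit-length-scale Gaussian kernel
  pg <- list(w = 1, mu = matrix(0, 1, 2), v = matrix(1 / (4 * pi^2), 1, 2))
  taus <- matrix(rnorm(200), 100, 2)
  expect_lt(max(abs(sm_kernel(taus, pg) - exp(-rowSums(taus^2) / 2))), 1e-12)
  # v -> 0: pure cosine product
  pc <- list(w = 1, mu = matrix(c(0.5, 1.25), 1, 2), v = matrix(1e-14, 1, 2))
  expect_equal(sm_kernel(taus, pc),
               cos(2 * pi * taus[, 1] * 0.5) * cos(2 * pi * taus[, 2] * 1.25),
               tolerance = 1e-9)
  # symmetry and stationarity
  expect_equal(sm_kernel(taus, p), sm_kernel(-taus, p))
})

test_that("kernel matrices are symmetric and positive semi-definite", {
  set.seed(3)
  for (k in 1:10) {
    Q <- sample(1:3, 1)
    p <- list(w = runif(Q, .2, 2), mu = matrix(runif(2 * Q, 0, 2), Q),
              v = matrix(runif(2 * Q, .05, 4), Q))
    X <- matrix(runif(2 * 25), 25, 2)
    K <- psqigeo:::sm_kernel_matrix(X, X, p)
    expect_equal(K, t(K))
    expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
})

test_that("task covariance assembles and stays positive definite", {
  expect_equal(task_covariance(matrix(0, 2, 1), c(1, 2)), diag(c(1, 2)))
  K1 <- task_covariance(matrix(c(1, 1), 2, 1), c(1e-6, 1e-6))
  expect_equal(correlation_from_task_cov(K1)[1, 2], 1, tolerance = 1e-5)
  set.seed(4)
  for (k in 1:10) {
    M <- sample(2:6, 1)
    K <- task_covariance(matrix(rnorm(M * 2), M), runif(M, .01, 1))
    expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
  expect_error(task_covariance(matrix(0, 2, 1), c(1, 0)), "positive")
})

test_that("quadratic mean evaluates the polynomial exactly", {
  X <- rbind(c(1, 1), c(0, 0), c(2, -1))
  expect_equal(quadratic_mean(X, matrix(0, 6, 2)), matrix(0, 3, 2))
  C0 <- matrix(0, 6, 2); C0[1, ] <- c(3, -1)
  expect_equal(quadratic_mean(X, C0), rbind(c(3, -1), c(3, -1), c(3, -1)))
  C <- matrix(rnorm(12), 6, 2)
  expect_equal(quadratic_mean(rbind(c(1, 1)), C), rbind(colSums(C)))
})

test_that("task correlation matrix matches the standard conversion", {
  expect_equal(correlation_from_task_cov(diag(c(2, 5, 1))), diag(3))
  expect_equal(correlation_from_task_cov(rbind(c(4, 2), c(2, 1)))[1, 2], 1)
  set.seed(8)
  K <- task_covariance(matrix(rnorm(8), 4), runif(4, .1, 1))
  expect_lt(max(abs(correlation_from_task_cov(K) - stats::cov2cor(K))), 1e-12)
  expect_error(correlation_from_task_cov(diag(c(1, 0))), "non-positive")
})

test_that("marginal likelihood matches closed form and brute force", {
  # N = 1, M = 1, mu = 0, Sigma = 1, y = 0: 0.5 * log(2 pi)
  p1 <- list(w = 1e-14, mu = matrix(0, 1, 2), v = matrix(1, 1, 2),
             B = matrix(0, 1, 1), v_task = 1e-14, D = 1, C = matrix(0, 6, 1))
  expect_equal(
    neg_log_marginal_likelihood(p1, matrix(0.5, 1, 2), matrix(0, 1, 1), "dense"),
    0.5 * log(2 * pi), tolerance = 1e-10)

  set.seed(9)
  for (k in 1:5) {
    N <- sample(5:10, 1); M <- sample(2:3, 1); Q <- sample(1:2, 1)
    X <- matrix(runif(2 * N), N, 2)
    Z <- matrix(rnorm(N * M, 0.5, 0.3), N, M)
    p <- random_mtgp_params(Q, M, r = 2)
    ref <- brute_nll(p, X, Z)
    expect_equal(neg_log_marginal_likelihood(p, X, Z, "dense"), ref,
                 tolerance = 1e-8)
    expect_equal(neg_log_marginal_likelihood(p, X, Z, "kronecker"), ref,
                 tolerance = 1e-8)
  }

  # translation invariance: shifting y and the mean together changes nothing
  N <- 8; M <- 2
  X <- matrix(runif(2 * N), N, 2)
  Z <- matrix(rnorm(N * M), N, M)
  p <- random_mtgp_params(1, M, 2)
  v1 <- neg_log_marginal_likelihood(p, X, Z)
  p2 <- p; p2$C[1, ] <- p$C[1, ] + 3
  v2 <- neg_log_marginal_likelihood(p2, X, Z + 3)
  expect_equal(v1, v2, tolerance = 1e-9)
})

test_that("analytic gradient agrees with central finite differences", {
  set.seed(10)
  N <- 10; M <- 3; Q <- 2; r <- 2
  X <- matrix(runif(2 * N), N, 2)
  Z <- matrix(rnorm(N * M, 0.5, 0.2), N, M)
  raw <- mtgp_init(X, Z, Q, r, seed = 3) + rnorm(psqigeo:::mtgp_param_dims(Q, M, r)$total, 0, 0.05)
  ob <- mtgp_objective(raw, X, Z, Q, r)
  h <- 1e-5
  fd <- vapply(seq_along(raw), function(i) {
    rp <- raw; rp[i] <- rp[i] + h
    rm <- raw; rm[i] <- rm[i] - h
    (mtgp_objective(rp, X, Z, Q, r)$value -
       mtgp_objective(rm, X, Z, Q, r)$value) / (2 * h)
  }, 0)
  expect_lt(max(abs(fd - ob$grad) / pmax(abs(fd), 1e-6)), 1e-4)
})

test_that("fitting is seeded-deterministic and respects the length-scale box", {
  set.seed(12)
  N <- 25; M <- 2
  X <- matrix(runif(2 * N), N, 2)
  Z <- matrix(rnorm(N * M, 0.5, 0.2), N, M)
  ctrl <- fit_control(iterations = 40)
  f1 <- fit_model(X, Z, Q = 2, r = 1, control = ctrl, seed = 7)
  f2 <- fit_model(X, Z, Q = 2, r = 1, control = ctrl, seed = 7)
  expect_identical(f1$raw, f2$raw)
  f3 <- fit_model(X, Z, Q = 2, r = 1, control = ctrl, seed = 8)
  expect_false(identical(f1$raw, f3$raw))
  expect_true(all(f1$params$ell >= 0.1 & f1$params$ell <= 100))
  expect_lt(f1$trace[length(f1$trace)], f1$trace[1])
})

test_that("multi-task predictions reduce to single-task GPR when M = 1", {
  set.seed(13)
  N <- 12
  X <- matrix(runif(2 * N), N, 2)
  y <- rnorm(N, 1, 0.5)
  p <- list(w = c(0.8), mu = matrix(c(0.2, 0.4), 1, 2),
            v = matrix(c(0.5, 1.5), 1, 2), B = matrix(0.6, 1, 1),
            v_task = 0.3, D = 0.05, C = matrix(c(0.4, 0.1, -0.2, 0, 0.05, 0), 6, 1))
  fit <- structure(
    list(params = c(p, list(Kf = task_covariance(p$B, p$v_task))),
         Q = 1, r = 1, M = 1, N = N, box = c(0.1, 100), X = X,
         Z = matrix(y, ncol = 1), parameters = "y", trace = 0, seed = 1,
         control = fit_control(), jitter = 0),
    class = "psqi_mtgp")
  Xs <- matrix(runif(10), 5, 2)
  pr <- predict(fit, Xs)

  Kf_scalar <- 0.6^2 + 0.3
  kern <- function(a, b) Kf_scalar * sm_kernel(rbind(a - b), p)
  mean_f <- function(x) sum(p$C[, 1] * c(1, x[1], x[2], x[1] * x[2], x[1]^2, x[2]^2))
  orac <- st_gp_predict(X, y, Xs, kern, mean_f, noise_var = 0.05)
  expect_equal(as.numeric(pr$mean), orac$mean, tolerance = 1e-8)
  expect_equal(as.numeric(pr$cov[1, 1, ]), orac$var, tolerance = 1e-8)
})

test_that("Kronecker-structured prediction equals the naive dense computation", {
  set.seed(14)
  N <- 15; M <- 3
  X <- matrix(runif(2 * N), N, 2)
  Z <- matrix(rnorm(N * M, 0.5, 0.25), N, M)
  colnames(Z) <- paste0("t", 1:M)
  fit <- fit_model(X, Z, Q = 2, r = 2, control = fit_control(iterations = 40),
                   seed = 3)
  Xs <- matrix(runif(16), 8, 2)
  pk <- predict(fit, Xs, method = "kronecker")
  pd <- predict(fit, Xs, method = "dense")
  expect_lt(max(abs(pk$mean - pd$mean)), 1e-8)
  expect_lt(max(abs(pk$cov - pd$cov)), 1e-8)
  # batching invariance on the Kronecker route
  p1 <- predict(fit, Xs, batch_size = 1)
  expect_lt(max(abs(pk$mean - p1$mean)), 1e-10)
  expect_lt(max(abs(pk$cov - p1$cov)), 1e-10)
})

test_that("prediction interpolates training data as noise vanishes", {
  set.seed(15)
  N <- 20; M <- 2
  X <- matrix(runif(2 * N), N, 2)
  p <- random_mtgp_params(1, M, 1)
  p$D <- rep(1e-10, M)
  Kx <- psqigeo:::sm_kernel_matrix(X, X, p)
  Kf <- task_covariance(p$B, p$v_task)
  Z <- quadratic_mean(X, p$C) +
    t(chol(Kx + diag(1e-10, N))) %*% matrix(rnorm(N * M), N, M) %*% chol(Kf)
  fit <- structure(
    list(params = c(p, list(Kf = Kf)), Q = 1, r = 1, M = M, N = N,
         box = c(0.1, 100), X = X, Z = Z, parameters = paste0("t", 1:M),
         trace = 0, seed = 1, control = fit_control(), jitter = 0),
    class = "psqi_mtgp")
  pr <- predict(fit, X[3:5, , drop = FALSE])
  expect_lt(max(abs(pr$mean - Z[3:5, ])), 1e-4)
  expect_lt(max(abs(pr$cov)), 1e-4)

  # predictive variance never exceeds the prior variance
  Xs <- matrix(runif(40), 20, 2)
  prs <- predict(fit, Xs)
  prior <- diag(Kf) * sum(p$w)
  for (j in 1:M) {
    expect_true(all(prs$cov[j, j, ] <= prior[j] + 1e-8))
    expect_true(all(prs$cov[j, j, ] >= -1e-8))
  }
})

test_that("predictive covariances are symmetric with near-PSD spectra", {
  set.seed(16)
  N <- 18; M <- 3
  X <- matrix(runif(2 * N), N, 2)
  Z <- matrix(rnorm(N * M, 0.5, 0.2), N, M)
  fit <- fit_model(X, Z, Q = 1, r = 2, control = fit_control(iterations = 30),
                   seed = 2)
  pr <- predict(fit, matrix(runif(20), 10, 2))
  for (t in 1:10) {
    S <- pr$cov[, , t]
    expect_lt(max(abs(S - t(S))), 1e-10)
    expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
})
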