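# A hand-built predictive-distribution object (plain list contract)
.mk_pred <- function(mean, cov) {
  n <- nrow(mean)
  M <- ncol(mean)
  cov_arr <- if (length(dim(cov)) == 2) {
    array(rep(cov, n), c(M, M, n))
  } else cov
  structure(list(mean = mean, cov = cov_arr, locations = matrix(0, n, 2),
                 parameters = colnames(mean)),
            class = "psqi_pred")
}

test_that("marginal probability matches univariate Gaussian CDF cases", {
  expect_equal(marginal_probability(0, 1, -1e6, 1e6), 1, tolerance = 1e-12)
  expect_equal(marginal_probability(5, 1, 5 - 1.959964, 5 + 1.959964), 0.95,
               tolerance = 1e-6)
  expect_lt(marginal_probability(10, 0.01, 0, 5), 1e-12)
  # degenerate variance: indicator of the mean lying inside
  expect_equal(marginal_probability(2, 0, 1, 3), 1)
  expect_equal(marginal_probability(4, 0, 1, 3), 0)
})

test_that("closed-form marginals agree with full-density quadrature", {
  set.seed(31)
  worst <- 0
  for (k in 1:30) {
    M <- sample(2:4, 1)
    S <- random_spd(M)
    mu <- rnorm(M, 0, 1)
    i <- sample(M, 1)
    sd_i <- sqrt(S[i, i])
    lo <- rep(-Inf, M); up <- rep(Inf, M)
    lo[i] <- mu[i] - runif(1, 0.2, 2.5) * sd_i
    up[i] <- mu[i] + runif(1, 0.2, 2.5) * sd_i
    closed <- marginal_probability(mu[i], sd_i, lo[i], up[i])
    quad <- mvn_rect_prob_quadrature(mu, S, lo, up)
    worst <- max(worst, abs(closed - quad))
  }
  expect_lt(worst, 1e-6)
})

test_that("softmax weights normalize and clamp negative scores to zero", {
  w <- softmax_weights(c(a = 0.4, b = 0.4, c = 0.4))
  expect_equal(unname(unclass(w)), rep(1 / 3, 3))
  w2 <- softmax_weights(c(a = 1, b = 0))
  expect_equal(unname(unclass(w2)), c(exp(1) / (exp(1) + 1), 1 / (exp(1) + 1)))
  expect_equal(round(unname(unclass(w2)), 3), c(0.731, 0.269))
  w3 <- softmax_weights(c(a = -0.5, b = 0))
  expect_equal(unname(unclass(w3)), c(0.5, 0.5))
  expect_equal(sum(w3), 1, tolerance = 1e-12)
  expect_error(softmax_weights(numeric(0)), "empty")
  # ad-hoc re-weighting renormalizes
  w4 <- reweight(w2, c(b = 3))
  expect_equal(sum(w4), 1, tolerance = 1e-12)
  expect_gt(w4["b"], w2["b"])
})

test_that("fallback substitutes dataset statistics for unreliable parameters", {
  mean <- cbind(a = c(0.2, 0.8), b = c(0.5, 0.6), c = c(0.3, 0.4))
  S <- matrix(c(0.04, 0.02, 0.01,
                0.02, 0.09, 0.03,
                0.01, 0.03, 0.05), 3, 3)
  pred <- .mk_pred(mean, S)
  # all positive R2: untouched
  same <- apply_fallback(pred, c(a = 0.5, b = 0.2, c = 0.1),
                         data_mean = c(), data_var = c())
  expect_identical(same, pred)
  adj <- apply_fallback(pred, c(a = 0.5, b = -0.3, c = 0.1),
                        data_mean = c(b = 0.55), data_var = c(b = 0.2))
  expect_equal(adj$mean[, "b"], c(0.55, 0.55))
  expect_equal(adj$cov[2, 2, 1], 0.2)
  expect_equal(adj$cov[2, 1, 1], 0); expect_equal(adj$cov[3, 2, 2], 0)
  # other entries untouched, result symmetric
  expect_equal(adj$cov[1, 3, 1], S[1, 3])
  expect_equal(adj$cov[, , 1], t(adj$cov[, , 1]))
  # substituted marginals are location-independent
  expect_equal(adj$mean[1, "b"], adj$mean[2, "b"])
})

.psqi_fixture <- function(seed = 33, n_train = 40) {
  set.seed(seed)
  std <- validate_standards(data.frame(
    name = c("pH", "A", "B"), unit = c("-", "mg/L", "mg/L"),
    lower = c(6, NA, NA), upper = c(9, 5, 2), hard_lower = c(0, NA, NA),
    hard_upper = c(14, NA, NA), stringsAsFactors = FALSE
  ))
  Y <- cbind(pH = runif(n_train, 6, 9), A = runif(n_train, 0, 4.5),
             B = runif(n_train, 0, 1.8))
  warp <- fit_warp(Y, std)
  list(std = std, warp = warp, wb = warp_bounds(std, warp))
}

test_that("PSQI is the weighted sum of marginals, bounded and correlation-free", {
  fx <- .psqi_fixture()
  w <- softmax_weights(c(pH = 0.5, A = 0.3, B = 0.1))
  set.seed(34)
  for (k in 1:50) {
    mean <- matrix(runif(3, -0.5, 1.5), 1, dimnames = list(NULL, c("pH", "A", "B")))
    S <- random_spd(3, scale = runif(1, 0.001, 0.3))
    pred <- .mk_pred(mean, S)
    pq <- psqi_values(pred, fx$std, fx$warp, w)
    expect_gte(pq$psqi, 0); expect_lte(pq$psqi, 1)
    expect_gte(pq$confidence, 0); expect_lte(pq$confidence, 1)
    manual <- sum(vapply(seq_along(w), function(i) {
      b <- fx$wb[fx$wb$name == names(w)[i], ]
      w[i] * marginal_probability(mean[1, i], sqrt(S[i, i]), b$lower, b$upper)
    }, 0))
    expect_equal(pq$psqi, manual, tolerance = 1e-10)
    # marginalization: zeroing the correlations changes nothing
    pred_d <- .mk_pred(mean, diag(diag(S)))
    expect_equal(psqi_values(pred_d, fx$std, fx$warp, w)$psqi, pq$psqi,
                 tolerance = 1e-12)
  }
})

test_that("PSQI is monotone under widening of any bound", {
  fx <- .psqi_fixture()
  w <- softmax_weights(c(pH = 0.2, A = 0.2, B = 0.2))
  mean <- matrix(c(0.4, 0.6, 0.5), 1, dimnames = list(NULL, c("pH", "A", "B")))
  pred <- .mk_pred(mean, diag(c(0.05, 0.08, 0.02)))
  base <- psqi_values(pred, fx$std, fx$warp, w)$psqi
  for (nm in c("pH", "A", "B")) {
    std2 <- fx$std
    i <- match(nm, std2$name)
    if (!is.na(std2$lower[i])) std2$lower[i] <- std2$lower[i] - 0.5
    std2$upper[i] <- std2$upper[i] * 1.3
    std2 <- validate_standards(as.data.frame(std2))
    wider <- psqi_values(pred, std2, fx$warp, w)$psqi
    expect_gte(wider, base - 1e-12)
  }
})

test_that("confidence equals PSQI at the midpoints and has the right limits", {
  fx <- .psqi_fixture()
  w <- softmax_weights(c(pH = 0.3, A = 0.3, B = 0.3))
  mids <- (fx$wb$lower + fx$wb$upper) / 2
  mean <- matrix(mids, 1, dimnames = list(NULL, fx$wb$name))
  pred <- .mk_pred(mean, random_spd(3, scale = 0.05))
  pq <- psqi_values(pred, fx$std, fx$warp, w)
  expect_equal(pq$confidence, pq$psqi, tolerance = 1e-12)

  off_mean <- matrix(mids + c(0.3, -0.2, 0.4), 1,
                     dimnames = list(NULL, fx$wb$name))
  tiny <- .mk_pred(off_mean, diag(1e-16, 3))
  expect_equal(psqi_values(tiny, fx$std, fx$warp, w)$confidence, 1,
               tolerance = 1e-9)
  huge <- .mk_pred(off_mean, diag(1e6, 3))
  expect_lt(psqi_values(huge, fx$std, fx$warp, w)$confidence, 1e-2)
})

test_that("fraction in bounds counts regulated parameters only", {
  std <- load_standards()
  reg <- effective_bounds(std)
  good <- as.data.frame(as.list(setNames(
    ifelse(is.na(reg$lower), 1, (reg$lower + reg$upper) / 2), reg$name)))
  expect_equal(fraction_in_bounds(good, std), 1.0)
  bad_ph <- good; bad_ph$pH <- 5.5
  expect_equal(fraction_in_bounds(bad_ph, std), 17 / 18)
  # unregulated calcium cannot move the fraction
  hi_ca <- bad_ph; hi_ca$Ca <- 340
  expect_equal(fraction_in_bounds(hi_ca, std), 17 / 18)
  # missing values are skipped from numerator and denominator with a warning
  na_row <- good; na_row$Zn <- NA
  expect_warning(f <- fraction_in_bounds(na_row, std), "missing")
  expect_equal(f, 17 / 17)
})
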