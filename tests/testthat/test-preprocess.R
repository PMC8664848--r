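# Frozen reference coordinates for UTM zone 37N computed with an independent
# implementation of the classic Snyder series (Map Projections: A Working
# Manual), itself accurate to about a millimetre.
.utm37_reference <- rbind(
  c(37.0, 55.0, 372071.8086, 6096620.7071),
  c(36.5, 55.3, 341291.7902, 6131023.3500),
  c(37.8, 55.6, 424389.4735, 6162215.4845),
  c(37.3, 55.15, 391665.0692, 6112802.5736),
  c(39.0, 54.5, 500000.0000, 6039154.2270)  # central meridian: easting 500 km
)

test_that("UTM projection matches the independent series oracle", {
  en <- utm_forward(.utm37_reference[, 1:2], zone = 37)
  expect_lt(max(abs(en - .utm37_reference[, 3:4])), 5e-3)
})

test_that("projection round-trips to degrees far below 1e-6", {
  set.seed(41)
  ll <- cbind(runif(200, 36.2, 38.8), runif(200, 54.2, 56.5))
  back <- utm_inverse(utm_forward(ll, 37), 37)
  expect_lt(max(abs(back - ll)), 1e-6)
  # also in a southern-hemisphere zone
  ll_s <- cbind(runif(50, 24.2, 26.8), runif(50, -35, -20))
  back_s <- utm_inverse(utm_forward(ll_s, 35, north = FALSE), 35, north = FALSE)
  expect_lt(max(abs(back_s - ll_s)), 1e-6)
})

test_that("coordinate scaler maps the training extent onto the unit square", {
  set.seed(7)
  ll <- cbind(runif(40, 37.0, 37.4), runif(40, 55.0, 55.3))
  sc <- fit_coord_scaler(ll)
  expect_equal(sc$zone, 37L)
  expect_equal(sc$epsg, 32637L)
  xy <- coords_to_model(sc, ll)
  expect_true(all(xy >= -1e-12 & xy <= 1 + 1e-12))
  expect_equal(min(xy[, 1]), 0); expect_equal(max(xy[, 1]), 1)
  expect_equal(min(xy[, 2]), 0); expect_equal(max(xy[, 2]), 1)
  # a held-out point west of all training points extrapolates negative
  far_west <- coords_to_model(sc, cbind(36.5, 55.1))
  expect_lt(far_west[1, 1], 0)
  # round trip through the scaler
  ll2 <- coords_from_model(sc, xy)
  expect_lt(max(abs(ll2 - ll)), 1e-6)
  expect_error(fit_coord_scaler(cbind(c(37, 37), c(55, 55))), "degenerate")
  expect_error(fit_coord_scaler(ll[1, , drop = FALSE]), "at least 2")
})

.toy_standards <- function() {
  validate_standards(data.frame(
    name = c("pH", "A", "B", "U"),
    unit = c("-", "mg/L", "mg/L", "mg/L"),
    lower = c(6, NA, NA, NA), upper = c(9, 5, 5, NA),
    hard_lower = c(0, NA, NA, NA), hard_upper = c(14, NA, NA, NA),
    stringsAsFactors = FALSE
  ))
}

test_that("warp limits follow the 10x rule and the hard pH domain", {
  std <- .toy_standards()
  set.seed(5)
  Y <- cbind(pH = runif(30, 6.3, 8), A = runif(30, 0, 3), B = runif(30, 0, 8),
             U = runif(30, 0, 2))
  w <- fit_warp(Y, std)
  expect_equal(w$upper[w$parameters == "A"], 50)           # 10 * max(3-, 5) = 50
  expect_equal(w$upper[w$parameters == "B"], 10 * max(Y[, "B"]))  # y_max > b_U
  expect_equal(w$upper[w$parameters == "pH"], 14)          # hard domain, no 10x
  expect_equal(w$lower[w$parameters == "pH"], 0)
  expect_equal(w$upper[w$parameters == "U"], 10 * max(Y[, "U"]))  # unregulated
  expect_error(fit_warp(cbind(Y[, 1:3], U = -Y[, 4]), std), "negative")
  Ybad <- Y; Ybad[1, "pH"] <- 14.5
  expect_error(fit_warp(Ybad, std), "hard domain")
})

test_that("warp handles zeros, is strictly monotone and round-trips", {
  std <- .toy_standards()
  set.seed(6)
  Y <- cbind(pH = runif(50, 6, 8.5), A = c(0, 0, runif(48, 0.01, 4)),
             B = runif(50, 0, 7), U = runif(50, 0.1, 2))
  w <- fit_warp(Y, std)
  Z <- warp_forward(Y, w)
  expect_true(all(is.finite(Z)))
  expect_true(all(Z >= 0 & Z <= 1))
  # the median maps strictly inside (0, 1)
  med <- apply(Y, 2, stats::median)
  zm <- warp_forward(matrix(med, 1, dimnames = list(NULL, colnames(Y))), w)
  expect_true(all(zm > 0 & zm < 1))

  # round trip on 1e4 random positive values per parameter
  for (j in 1:4) {
    g <- matrix(stats::runif(1e4, 1e-6 * w$upper[j], 0.099 * w$upper[j]),
                ncol = 1, dimnames = list(NULL, w$parameters[j]))
    grid <- matrix(0, 1e4, 4, dimnames = list(NULL, w$parameters))
    grid[, j] <- g
    grid[, -j] <- rep(apply(Y, 2, stats::median)[-j], each = 1e4)
    back <- warp_inverse(warp_forward(grid, w), w)
    expect_lt(max(abs(back[, j] - grid[, j]) / grid[, j]), 1e-8)
  }

  # strict monotonicity on a sorted grid
  ys <- sort(stats::runif(500, 0, 0.99 * w$upper[2]))
  gm <- matrix(rep(med, each = 500), 500, dimnames = list(NULL, colnames(Y)))
  gm[, 2] <- ys
  zs <- warp_forward(gm, w)[, 2]
  expect_true(all(diff(zs) > 0))

  # inverse of extreme warped values saturates inside the limits
  ext <- matrix(rep(0.5, 8), 2, dimnames = list(NULL, w$parameters))
  ext[1, ] <- -50; ext[2, ] <- 50
  back <- warp_inverse(ext, w)
  expect_true(all(sweep(back, 2, w$lower, ">=")))
  expect_true(all(sweep(back, 2, w$upper, "<=")))
  expect_true(all(diff(back) > 0))
})

test_that("zero measurements warp to the epsilon image, finite everywhere", {
  std <- .toy_standards()
  Y <- cbind(pH = runif(20, 6, 8), A = c(0, runif(19, 0.1, 4)),
             B = runif(20, 1, 6), U = runif(20, 0.5, 2))
  w <- fit_warp(Y, std)
  Z <- warp_forward(Y, w)
  expect_true(all(is.finite(Z)))
  j <- which(w$parameters == "A")
  z0 <- warp_forward(matrix(c(7, 0, 3, 1), 1, dimnames = list(NULL, colnames(Y))), w)
  eps_img <- (stats::qnorm(1e-10) - w$g_min[j]) / (w$g_max[j] - w$g_min[j])
  expect_equal(unname(z0[1, j]), eps_img)
})

test_that("warped bounds preserve interval probabilities (Monte Carlo)", {
  std <- .toy_standards()
  set.seed(11)
  Y <- cbind(pH = runif(60, 6, 8.7), A = runif(60, 0, 4.5),
             B = runif(60, 0, 7), U = runif(60, 0.1, 2))
  w <- fit_warp(Y, std)
  wb <- warp_bounds(std, w)
  expect_true(all(wb$lower < wb$upper))
  expect_setequal(wb$name, c("pH", "A", "B"))   # unregulated U excluded
  # zero lower bound maps exactly like a zero measurement
  jA <- which(w$parameters == "A")
  eps_img <- (stats::qnorm(1e-10) - w$g_min[jA]) / (w$g_max[jA] - w$g_min[jA])
  expect_equal(wb$lower[wb$name == "A"], eps_img)

  n_mc <- 1e5
  for (nm in wb$name) {
    j <- which(w$parameters == nm)
    mu_z <- 0.55; sd_z <- 0.25
    z <- matrix(rep(0.5, 4 * n_mc), n_mc, 4, dimnames = list(NULL, w$parameters))
    z[, j] <- stats::rnorm(n_mc, mu_z, sd_z)
    y <- warp_inverse(z, w)[, j]
    b <- effective_bounds(std, nm)
    emp <- mean(y >= b[1] & y <= b[2])
    gauss <- stats::pnorm(wb$upper[wb$name == nm], mu_z, sd_z) -
      stats::pnorm(wb$lower[wb$name == nm], mu_z, sd_z)
    se <- sqrt(gauss * (1 - gauss) / n_mc)
    expect_lt(abs(emp - gauss), 3 * max(se, 1e-4))
  }
})
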