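#' Warping bounded measurements into Gaussian model space
#'
#' Water-chemistry values live on bounded supports: concentrations are
#' non-negative and pH is confined to \[0, 14\], while a GP's predictive
#' distribution has infinite support.  Measurements are therefore warped into
#' an unbounded space before modelling:
#'
#' 1. a per-parameter upper limit is fixed at `10 * max(column max, normative
#'    upper bound)` — far above anything observable — except for parameters
#'    with a hard physical domain (pH), whose limits are the domain itself;
#' 2. min-max scaling by these limits maps values into \[0, 1\];
#' 3. exact zeros (which sit on the lower limit) are replaced by 1e-10 so the
#'    next step stays finite;
#' 4. the standard-normal inverse CDF maps (0, 1) onto the real line;
#' 5. a second min-max scaling (constants taken from the training data) brings
#'    the result back into \[0, 1\] numerically.
#'
#' The composite map is strictly increasing and invertible, so probabilities
#' of interval events are preserved: the Gaussian mass between warped bounds
#' equals the original-space probability of the measurement lying between the
#' regulatory bounds.  The GP is fitted to the warped values and its
#' predictive distribution is Gaussian only in this warped space.
#'
#' @name warping
NULL

.warp_eps <- 1e-10       # replaces exact zeros on the [0,1] scale
.warp_clamp <- 1e-12     # relative inward clamp for prediction-time values

#' Fit the per-parameter warp transform
#'
#' @param Y N x M numeric matrix of measurements, columns named after the
#'   standards-table parameters.
#' @param standards A `psqi_standards` table covering all columns of `Y`.
#' @return A `psqi_warp` object with per-parameter limits and second-stage
#'   scaling constants.
#' @export
fit_warp <- function(Y, standards) {
  Y <- as.matrix(Y)
  stopifnot(inherits(standards, "psqi_standards"), !is.null(colnames(Y)))
  idx <- match(colnames(Y), standards$name)
  if (anyNA(idx)) {
    stop("measurement column(s) absent from standards table: ",
         paste(colnames(Y)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(Y))) stop("non-finite measurement values", call. = FALSE)

  M <- ncol(Y)
  lower <- numeric(M); upper <- numeric(M)
  g_min <- numeric(M); g_max <- numeric(M)
  for (j in seq_len(M)) {
    i <- idx[j]
    hard <- !is.na(standards$hard_lower[i])
    if (hard) {
      lower[j] <- standards$hard_lower[i]
      upper[j] <- standards$hard_upper[i]
      bad <- Y[, j] < lower[j] | Y[, j] > upper[j]
      if (any(bad)) {
        stop(sprintf("%s values outside hard domain [%g, %g]",
                     colnames(Y)[j], lower[j], upper[j]), call. = FALSE)
      }
    } else {
      if (any(Y[, j] < 0)) {
        stop(sprintf("negative %s measurement", colnames(Y)[j]), call. = FALSE)
      }
      bU <- standards$upper[i]                      # may be NA (unregulated)
      lower[j] <- 0
      upper[j] <- 10 * max(max(Y[, j]), if (is.na(bU)) -Inf else bU)
      if (upper[j] <= 0) {
        stop(sprintf("%s: all-zero column and no normative bound; no warp limit",
                     colnames(Y)[j]), call. = FALSE)
      }
    }
    s <- (Y[, j] - lower[j]) / (upper[j] - lower[j])
    s[s <= 0] <- .warp_eps
    s <- pmin(s, 1 - .warp_clamp)
    g <- stats::qnorm(s)
    g_min[j] <- min(g); g_max[j] <- max(g)
    if (g_max[j] <= g_min[j]) {
      stop(sprintf("%s: constant column, degenerate warp", colnames(Y)[j]),
           call. = FALSE)
    }
  }
  structure(
    list(parameters = colnames(Y), lower = lower, upper = upper,
         g_min = g_min, g_max = g_max, eps = .warp_eps),
    class = "psqi_warp"
  )
}

#' Forward warp: bounded measurements to the GP model scale
#'
#' @param Y N x M matrix in original units (columns in warp order or named).
#' @param warp A fitted [fit_warp()] transform.
#' @return N x M matrix of warped values (training data lands in \[0, 1\]).
#' @export
warp_forward <- function(Y, warp) {
  stopifnot(inherits(warp, "psqi_warp"))
  Y <- .warp_align(Y, warp)
  Z <- Y
  for (j in seq_along(warp$parameters)) {
    s <- (Y[, j] - warp$lower[j]) / (warp$upper[j] - warp$lower[j])
    if (any(s > 1)) {
      stop(sprintf("%s value above warp upper limit %g",
                   warp$parameters[j], warp$upper[j]), call. = FALSE)
    }
    s[s <= 0] <- warp$eps
    # the ICDF diverges at 1; new data equal to the limit is clamped inward
    s <- pmin(s, 1 - .warp_clamp)
    Z[, j] <- (stats::qnorm(s) - warp$g_min[j]) / (warp$g_max[j] - warp$g_min[j])
  }
  Z
}

#' Inverse warp: GP model scale back to original units
#'
#' Any finite input is mapped into the open interval (lower, upper); values
#' beyond the training range of the warped scale saturate towards the limits
#' through the Gaussian CDF.
#'
#' @param Z N x M matrix of warped values.
#' @inheritParams warp_forward
#' @return N x M matrix in original measurement units.
#' @export
warp_inverse <- function(Z, warp) {
  stopifnot(inherits(warp, "psqi_warp"))
  Z <- .warp_align(Z, warp)
  Y <- Z
  for (j in seq_along(warp$parameters)) {
    g <- warp$g_min[j] + Z[, j] * (warp$g_max[j] - warp$g_min[j])
    Y[, j] <- warp$lower[j] +
      stats::pnorm(g) * (warp$upper[j] - warp$lower[j])
  }
  Y
}

#' Regulatory bounds mapped into warped space
#'
#' The PSQI integrals are evaluated in warped space (where the predictive
#' distribution is Gaussian); this maps each regulated parameter's effective
#' bounds through the forward warp.  A zero lower bound maps to the image of
#' the zero-replacement value 1e-10, exactly as a zero measurement would.
#'
#' @inheritParams fit_warp
#' @param warp A fitted [fit_warp()] transform.
#' @return Data frame `name`, `lower`, `upper` (warped scale), regulated
#'   parameters only, ordered as in the warp.
#' @export
warp_bounds <- function(standards, warp) {
  stopifnot(inherits(standards, "psqi_standards"), inherits(warp, "psqi_warp"))
  eb <- effective_bounds(standards)
  keep <- which(!eb$excluded[match(warp$parameters, eb$name)])
  out <- data.frame(name = warp$parameters[keep], lower = NA_real_,
                    upper = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_along(keep)) {
    j <- keep[k]
    b <- eb[match(warp$parameters[j], eb$name), ]
    if (b$upper > warp$upper[j] + 1e-9) {
      stop(sprintf("%s: normative upper bound exceeds warp limit", b$name),
           call. = FALSE)
    }
    bm <- matrix(c(b$lower, b$upper), nrow = 2,
                 dimnames = list(NULL, warp$parameters[j]))
    zb <- .warp_forward_one(bm, warp, j)
    if (!(zb[1] < zb[2])) stop(sprintf("%s: degenerate warped bounds", b$name),
                               call. = FALSE)
    out$lower[k] <- zb[1]; out$upper[k] <- zb[2]
  }
  out
}

# forward warp of a single column j, for internal use on bound vectors
.warp_forward_one <- function(y, warp, j) {
  s <- (as.numeric(y) - warp$lower[j]) / (warp$upper[j] - warp$lower[j])
  s[s <= 0] <- warp$eps
  s <- pmin(s, 1 - .warp_clamp)
  (stats::qnorm(s) - warp$g_min[j]) / (warp$g_max[j] - warp$g_min[j])
}

.warp_align <- function(Y, warp) {
  Y <- as.matrix(Y)
  if (ncol(Y) != length(warp$parameters)) {
    stop("matrix has ", ncol(Y), " columns, warp expects ",
         length(warp$parameters), call. = FALSE)
  }
  if (!is.null(colnames(Y)) && !identical(colnames(Y), warp$parameters)) {
    idx <- match(warp$parameters, colnames(Y))
    if (anyNA(idx)) stop("column names do not match warp parameters", call. = FALSE)
    Y <- Y[, idx, drop = FALSE]
  }
  Y
}
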