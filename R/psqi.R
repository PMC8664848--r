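#' Probabilistic Substance Quality Index
#'
#' At any location the fitted model yields an M-variate Gaussian over the
#' warped measurements.  For each regulated parameter i, let `p_i` be the
#' probability that the i-th component falls between its regulatory bounds
#' with every other component integrated out over the whole real line.  By
#' marginalization this semi-infinite rectangle integral reduces *exactly* to
#' a difference of two univariate Gaussian CDF values of the i-th marginal —
#' the closed form used here (numerical integration of the full density is
#' kept only as a test oracle).  The index is the weighted average
#' \deqn{PSQI(x) = \sum_i w_i p_i(x) \in [0, 1],}
#' with softmax weights built from cross-validated R2 scores so poorly
#' modelled parameters contribute less.  The companion confidence metric is
#' the same computation with the predictive mean re-centred at the bound
#' midpoints: it is high exactly when the predictive spread is small relative
#' to the admissible range, regardless of where the mean sits.
#'
#' Bounds are mapped into warped space before integration (the monotone warp
#' preserves interval probabilities; the predictive distribution is Gaussian
#' only there).
#'
#' @name psqi
NULL

#' Marginal probability of one parameter lying within bounds
#'
#' @param mean,sd Predictive mean and standard deviation of the parameter's
#'   marginal (warped space).
#' @param lower,upper Interval bounds on the same scale.
#' @return Probability in \[0, 1\].  A degenerate (zero) standard deviation
#'   returns the indicator of the mean lying inside the bounds.
#' @export
marginal_probability <- function(mean, sd, lower, upper) {
  stopifnot(upper >= lower)
  if (!is.finite(sd) || sd <= 0) {
    return(as.numeric(mean >= lower & mean <= upper))
  }
  stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd)
}

#' Softmax weights from per-parameter R2 scores
#'
#' `w_i = exp(max(R2_i, 0)) / sum_j exp(max(R2_j, 0))`: negative scores count
#' exactly as zero, weights are positive and sum to one.
#'
#' @param r2 Named numeric vector of per-parameter R2 scores (regulated,
#'   non-excluded parameters).
#' @return Named numeric weight vector of class `psqi_weights`.
#' @export
softmax_weights <- function(r2) {
  if (!length(r2)) stop("empty parameter set for weighting", call. = FALSE)
  e <- exp(pmax(r2, 0))
  structure(e / sum(e), class = "psqi_weights", names = names(r2))
}

#' Re-weight softmax weights with ad-hoc importances
#'
#' Multiplies the weights by user-supplied importances and renormalizes.
#'
#' @param weights A [softmax_weights()] vector.
#' @param importance Named non-negative multipliers (missing names keep 1).
#' @return Renormalized `psqi_weights`.
#' @export
reweight <- function(weights, importance) {
  mult <- rep(1, length(weights)); names(mult) <- names(weights)
  common <- intersect(names(importance), names(weights))
  mult[common] <- importance[common]
  if (any(mult < 0)) stop("importances must be non-negative", call. = FALSE)
  w <- unclass(weights) * mult
  if (sum(w) <= 0) stop("all weights vanished after re-weighting", call. = FALSE)
  structure(w / sum(w), class = "psqi_weights", names = names(weights))
}

#' Fallback substitution for unreliably modelled parameters
#'
#' Parameters whose cross-validated R2 is non-positive are predicted no
#' better than by a constant; their predictive means and variances are
#' replaced by the (warped-space) dataset means and variances and their
#' inter-parameter covariances are zeroed, at every location.
#'
#' @param pred A `psqi_pred` object.
#' @param r2 Named R2 scores for (a subset of) the predicted parameters.
#' @param data_mean,data_var Named warped-space dataset means and variances
#'   for the parameters with `r2 <= 0`.
#' @return The adjusted `psqi_pred`.
#' @export
apply_fallback <- function(pred, r2, data_mean, data_var) {
  stopifnot(inherits(pred, "psqi_pred"))
  bad <- names(r2)[!is.na(r2) & r2 <= 0]
  bad <- intersect(bad, pred$parameters)
  if (!length(bad)) return(pred)
  idx <- match(bad, pred$parameters)
  stopifnot(all(bad %in% names(data_mean)), all(bad %in% names(data_var)))
  for (j in seq_along(idx)) {
    i <- idx[j]
    pred$mean[, i] <- data_mean[[bad[j]]]
    pred$cov[i, , ] <- 0
    pred$cov[, i, ] <- 0
    pred$cov[i, i, ] <- data_var[[bad[j]]]
  }
  pred
}

#' PSQI and confidence at predicted locations
#'
#' @param pred A `psqi_pred` object (after any [apply_fallback()]).
#' @param standards A `psqi_standards` table.
#' @param warp The fitted [fit_warp()] transform behind `pred`.
#' @param weights A [softmax_weights()] vector over regulated parameters.
#' @param space `"warped"` integrates warped bounds against the warped-space
#'   Gaussian (probability-preserving, the default); `"original"` is the
#'   naive variant that pushes the mean and a delta-method standard deviation
#'   into original units and integrates the printed bounds there.
#' @return Data frame with one row per location: `psqi`, `confidence`, and
#'   per-parameter columns `p_<name>` and `q_<name>`.
#' @export
psqi_values <- function(pred, standards, warp, weights,
                        space = c("warped", "original")) {
  space <- match.arg(space)
  stopifnot(inherits(pred, "psqi_pred"), inherits(weights, "psqi_weights"))
  pnames <- names(weights)
  stopifnot(all(pnames %in% pred$parameters))
  idx <- match(pnames, pred$parameters)
  wb <- warp_bounds(standards, warp)
  eb <- effective_bounds(standards)
  n <- nrow(pred$mean)

  P <- matrix(NA_real_, n, length(pnames))
  Qm <- matrix(NA_real_, n, length(pnames))
  for (k in seq_along(pnames)) {
    i <- idx[k]
    mu <- pred$mean[, i]
    sd <- sqrt(pmax(pred$cov[i, i, ], 0))
    if (space == "warped") {
      b <- wb[match(pnames[k], wb$name), ]
      if (anyNA(b)) stop("no warped bounds for ", pnames[k], call. = FALSE)
      lo <- b$lower; up <- b$upper
      mid <- (lo + up) / 2
      P[, k] <- vapply(seq_len(n), function(t)
        marginal_probability(mu[t], sd[t], lo, up), 0)
      Qm[, k] <- vapply(seq_len(n), function(t)
        marginal_probability(mid, sd[t], lo, up), 0)
    } else {
      j <- match(pnames[k], warp$parameters)
      e <- eb[match(pnames[k], eb$name), ]
      ym <- warp_inverse(pred$mean, warp)[, j]
      # delta method: d(inverse warp)/dz at the predictive mean
      g <- warp$g_min[j] + mu * (warp$g_max[j] - warp$g_min[j])
      dydz <- (warp$upper[j] - warp$lower[j]) *
        stats::dnorm(g) * (warp$g_max[j] - warp$g_min[j])
      sdy <- sd * dydz
      mid <- (e$lower + e$upper) / 2
      P[, k] <- vapply(seq_len(n), function(t)
        marginal_probability(ym[t], sdy[t], e$lower, e$upper), 0)
      Qm[, k] <- vapply(seq_len(n), function(t)
        marginal_probability(mid, sdy[t], e$lower, e$upper), 0)
    }
  }
  out <- data.frame(psqi = as.numeric(P %*% weights),
                    confidence = as.numeric(Qm %*% weights))
  for (k in seq_along(pnames)) {
    out[[paste0("p_", pnames[k])]] <- P[, k]
    out[[paste0("q_", pnames[k])]] <- Qm[, k]
  }
  out
}

#' Fraction of regulated parameters within bounds for measured rows
#'
#' The direct, model-free counterpart of PSQI used to validate it: for each
#' measurement row, the share of regulated parameters whose value lies inside
#' its effective bounds.
#'
#' @param samples Data frame (or single row) with parameter columns.
#' @param standards A `psqi_standards` table.
#' @return Numeric vector of fractions in \[0, 1\], one per row.
#' @export
fraction_in_bounds <- function(samples, standards) {
  eb <- effective_bounds(standards)
  reg <- eb$name[!eb$excluded]
  present <- intersect(reg, names(samples))
  if (length(present) < length(reg)) {
    warning("missing regulated parameter(s) skipped: ",
            paste(setdiff(reg, present), collapse = ", "), call. = FALSE)
  }
  n_na <- sum(is.na(as.matrix(samples[, present, drop = FALSE])))
  if (n_na > 0) {
    warning(n_na, " missing regulated value(s) skipped from the fraction",
            call. = FALSE)
  }
  vapply(seq_len(nrow(samples)), function(t) {
    inb <- 0L; tot <- 0L
    for (nm in present) {
      v <- samples[[nm]][t]
      if (is.na(v)) next
      b <- eb[match(nm, eb$name), ]
      tot <- tot + 1L
      if (v >= b$lower && v <= b$upper) inb <- inb + 1L
    }
    if (tot == 0L) NA_real_ else inb / tot
  }, 0)
}
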