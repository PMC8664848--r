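#' Fitted water-quality model bundle
#'
#' [fit_water_model()] wires the full stack together on one dataset: fit the
#' coordinate scaler and warp, train the multi-task GP at a chosen (Q, r),
#' and attach everything PSQI needs (standards, warped-space dataset
#' statistics for the fallback, softmax weights from cross-validated R2).
#'
#' @name model-bundle
NULL

#' Fit the full model bundle on a sample table
#'
#' @param samples Data frame `longitude`, `latitude`, plus parameter columns.
#' @param standards A `psqi_standards` table covering the parameters.
#' @param Q,r Spectral mixture size and task-covariance rank (e.g. the winner
#'   of [mask_and_select()]).
#' @param control A [fit_control()] list.  The default uses three random
#'   restarts: the final model's task covariance feeds the correlation
#'   analysis and PSQI, so it is worth guarding against local optima of the
#'   multi-modal spectral mixture likelihood here (single-start is fine for
#'   the throwaway cross-validation fits).
#' @param seed Integer seed for the fit initialization.
#' @param param_r2 Named per-parameter cross-validated R2 scores (original
#'   space), used for the softmax weights and the fallback; parameters
#'   without a score count as 0.
#' @param importance Optional named multipliers re-weighting the softmax
#'   weights ([reweight()]).
#' @return A `psqi_model` bundle.
#' @export
fit_water_model <- function(samples, standards, Q, r,
                            control = fit_control(restarts = 3), seed = 1,
                            param_r2 = NULL, importance = NULL) {
  params <- setdiff(names(samples), c("longitude", "latitude"))
  stopifnot(all(params %in% standards$name))
  scaler <- fit_coord_scaler(samples[, c("longitude", "latitude")])
  Y <- as.matrix(samples[, params, drop = FALSE])
  warp <- fit_warp(Y, standards)
  X <- coords_to_model(scaler, samples[, c("longitude", "latitude")])
  Z <- warp_forward(Y, warp)
  fit <- fit_model(X, Z, Q = Q, r = r, control = control, seed = seed)

  r2 <- stats::setNames(rep(NA_real_, length(params)), params)
  if (!is.null(param_r2)) {
    common <- intersect(names(param_r2), params)
    r2[common] <- param_r2[common]
  }
  regulated <- standards$name[standards$regulated]
  wr2 <- r2[intersect(params, regulated)]
  wr2[is.na(wr2)] <- 0
  weights <- softmax_weights(wr2)
  if (!is.null(importance)) weights <- reweight(weights, importance)

  structure(
    list(fit = fit, scaler = scaler, warp = warp, standards = standards,
         weights = weights, param_r2 = r2,
         data_mean = colMeans(Z), data_var = apply(Z, 2, stats::var),
         seed = seed),
    class = "psqi_model"
  )
}

#' @export
print.psqi_model <- function(x, ...) {
  cat(sprintf("Water-quality model bundle: %d samples, %d parameters, Q=%d, r=%d (UTM zone %d)\n",
              x$fit$N, x$fit$M, x$fit$Q, x$fit$r, x$scaler$zone))
  invisible(x)
}

# --- serialization ----------------------------------------------------------
# doubles are written as %.17g strings so that save -> load round-trips them
# bit for bit; everything else is plain JSON.

.num_out <- function(x) {
  d <- dim(x)
  list(dim = if (is.null(d)) length(x) else d,
       data = sprintf("%.17g", as.vector(x)))
}
.str2num <- function(x) {
  x <- as.character(x)
  out <- rep(NA_real_, length(x))
  ok <- !(is.na(x) | x %in% c("NA", "nan", ""))
  out[ok] <- as.numeric(x[ok])
  out
}
.num_in <- function(o) {
  v <- .str2num(o$data)
  d <- unlist(o$dim)
  if (length(d) > 1) dim(v) <- d
  v
}

#' Save / load a fitted model bundle
#'
#' The file is self-describing JSON holding every hyper-parameter, the warp
#' constants, the coordinate scaler, the standards table, the training data
#' and a fingerprint; [load_model()] reproduces predictions bit-for-bit.
#'
#' @param model A `psqi_model` bundle.
#' @param path Output / input file path.
#' @return `save_model` returns `path` invisibly; `load_model` the bundle.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "psqi_model"))
  fit <- model$fit
  obj <- list(
    format = "psqigeo-model",
    version = as.character(utils::packageVersion("psqigeo")),
    meta = list(N = fit$N, M = fit$M, Q = fit$Q, r = fit$r, seed = model$seed,
                fingerprint = sprintf("%.17g", sum(fit$X) + sum(fit$Z))),
    control = unclass(fit$control),
    box = fit$box,
    raw = .num_out(fit$raw),
    X = .num_out(fit$X),
    Z = .num_out(fit$Z),
    parameters = fit$parameters,
    fit_seed = fit$seed,
    scaler = list(zone = model$scaler$zone, north = model$scaler$north,
                  epsg = model$scaler$epsg,
                  min_xy = .num_out(model$scaler$min_xy),
                  max_xy = .num_out(model$scaler$max_xy)),
    warp = list(parameters = model$warp$parameters,
                lower = .num_out(model$warp$lower),
                upper = .num_out(model$warp$upper),
                g_min = .num_out(model$warp$g_min),
                g_max = .num_out(model$warp$g_max),
                eps = sprintf("%.17g", model$warp$eps)),
    standards = lapply(seq_len(nrow(model$standards)), function(i)
      lapply(as.list(model$standards[i, c("name", "unit", "lower", "upper",
                                          "hard_lower", "hard_upper")]),
             function(v) if (is.numeric(v)) sprintf("%.17g", v) else v)),
    weights = .num_out(model$weights),
    weight_names = names(model$weights),
    param_r2 = .num_out(model$param_r2),
    data_mean = .num_out(model$data_mean),
    data_var = .num_out(model$data_var)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "psqigeo-model")) {
    stop("not a psqigeo model file: ", path, call. = FALSE)
  }
  std_raw <- obj$standards
  if (!is.data.frame(std_raw)) {
    std_raw <- do.call(rbind, lapply(std_raw, function(r)
      data.frame(name = r$name, unit = r$unit, lower = r$lower,
                 upper = r$upper, hard_lower = r$hard_lower,
                 hard_upper = r$hard_upper, stringsAsFactors = FALSE)))
  }
  std_df <- data.frame(
    name = std_raw$name, unit = std_raw$unit,
    lower = .str2num(std_raw$lower), upper = .str2num(std_raw$upper),
    hard_lower = .str2num(std_raw$hard_lower),
    hard_upper = .str2num(std_raw$hard_upper), stringsAsFactors = FALSE)
  standards <- validate_standards(std_df)

  box <- as.numeric(obj$box)
  raw <- .num_in(obj$raw)
  X <- .num_in(obj$X); Z <- .num_in(obj$Z)
  colnames(Z) <- obj$parameters
  M <- obj$meta$M
  p <- mtgp_unpack(raw, obj$meta$Q, M, obj$meta$r, box)
  control <- do.call(fit_control, lapply(obj$control, unlist))
  fit <- structure(
    list(params = c(p, list(Kf = task_covariance(p$B, p$v_task))),
         raw = raw, Q = obj$meta$Q, r = obj$meta$r, M = M, N = obj$meta$N,
         box = box, X = X, Z = Z, parameters = obj$parameters,
         trace = NA_real_, seed = obj$fit_seed, control = control, jitter = 0),
    class = "psqi_mtgp"
  )
  fp <- sprintf("%.17g", sum(X) + sum(Z))
  if (!identical(fp, obj$meta$fingerprint)) {
    stop("training-data fingerprint mismatch in ", path, call. = FALSE)
  }
  scaler <- structure(
    list(zone = as.integer(obj$scaler$zone), north = obj$scaler$north,
         epsg = as.integer(obj$scaler$epsg),
         min_xy = .num_in(obj$scaler$min_xy),
         max_xy = .num_in(obj$scaler$max_xy)),
    class = "psqi_coord_scaler"
  )
  warp <- structure(
    list(parameters = obj$warp$parameters,
         lower = .num_in(obj$warp$lower), upper = .num_in(obj$warp$upper),
         g_min = .num_in(obj$warp$g_min), g_max = .num_in(obj$warp$g_max),
         eps = as.numeric(obj$warp$eps)),
    class = "psqi_warp"
  )
  weights <- structure(.num_in(obj$weights), class = "psqi_weights",
                       names = obj$weight_names)
  structure(
    list(fit = fit, scaler = scaler, warp = warp, standards = standards,
         weights = weights,
         param_r2 = stats::setNames(.num_in(obj$param_r2), obj$parameters),
         data_mean = stats::setNames(.num_in(obj$data_mean), obj$parameters),
         data_var = stats::setNames(.num_in(obj$data_var), obj$parameters),
         seed = obj$meta$seed),
    class = "psqi_model"
  )
}
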