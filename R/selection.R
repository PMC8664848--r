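#' Cross-validated model selection
#'
#' Candidate models — combinations of the spectral-mixture size Q and the
#' task-covariance rank r — are compared by the coefficient of determination
#' (R2) of held-out predictions, computed per water property in the
#' *original* measurement space (predictions are inverse-warped first, since
#' the non-linear warp makes warped- and original-space R2 differ).  The
#' validation scheme is 5 random 80/20 train/test splits; a disjoint k-fold
#' mode is available behind a flag.  Properties whose split-averaged R2 is
#' negative for *every* candidate are masked out, and the candidate with the
#' highest mean R2 over the kept properties and splits wins (ties towards
#' smaller Q, then smaller r).
#'
#' @name selection
NULL

#' Coefficient of determination in original measurement space
#'
#' `R2 = 1 - MSE / Var(y_true)`: one for a perfect prediction, zero when the
#' prediction error matches the test variance, negative when it is larger.
#'
#' @param y_true,y_pred Numeric vectors in original measurement units.
#' @return Scalar R2, or `NA` when the test values have zero variance (such
#'   cells are excluded from averages, not treated as zero).
#' @export
r2_original_space <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  if (length(y_true) < 2) return(NA_real_)
  v <- mean((y_true - mean(y_true))^2)
  if (v <= 0) return(NA_real_)
  1 - mean((y_true - y_pred)^2) / v
}

#' Cross-validate one (Q, r) candidate
#'
#' Each split refits everything that is data-dependent — the coordinate
#' scaler, the warp and the GP hyper-parameters — on the training fold alone,
#' predicts the held-out locations, inverse-warps the predictive means and
#' scores per-parameter R2 in original units.
#'
#' @param samples Data frame with `longitude`, `latitude` and one column per
#'   measured parameter.
#' @param standards A `psqi_standards` table covering the parameter columns.
#' @param Q,r Candidate spectral mixture size and task-covariance rank.
#' @param seed Integer seed; drives the split indices and the fit
#'   initializations (same seed, same report).
#' @param control A [fit_control()] list.
#' @param n_splits Number of splits (5 in the standard scheme).
#' @param train_frac Training fraction for the `"resample"` mode.
#' @param mode `"resample"` (independent seeded 80/20 resamples, the default)
#'   or `"kfold"` (disjoint folds).
#' @return A `psqi_cv_report`: data frame `split`, `parameter`, `r2` plus
#'   attributes `Q`, `r`, `param_means`, `failed_splits`.
#' @export
cross_validate <- function(samples, standards, Q, r, seed = 1,
                           control = fit_control(), n_splits = 5,
                           train_frac = 0.8, mode = c("resample", "kfold")) {
  mode <- match.arg(mode)
  params <- setdiff(names(samples), c("longitude", "latitude"))
  stopifnot(length(params) >= 1, all(params %in% standards$name))
  N <- nrow(samples)
  splits <- cv_splits(N, n_splits, train_frac, seed, mode)
  if (min(vapply(splits, function(s) length(s$test), 0L)) < 5) {
    stop("test folds too small (< 5 points); increase N", call. = FALSE)
  }

  rows <- list()
  failed <- integer(0)
  for (k in seq_along(splits)) {
    sp <- splits[[k]]
    res <- tryCatch({
      tr <- samples[sp$train, , drop = FALSE]
      te <- samples[sp$test, , drop = FALSE]
      scaler <- fit_coord_scaler(tr[, c("longitude", "latitude")])
      Ytr <- as.matrix(tr[, params, drop = FALSE])
      warp <- fit_warp(Ytr, standards)
      Xtr <- coords_to_model(scaler, tr[, c("longitude", "latitude")])
      Ztr <- warp_forward(Ytr, warp)
      fit <- fit_model(Xtr, Ztr, Q = Q, r = r, control = control,
                       seed = seed + k)
      Xte <- coords_to_model(scaler, te[, c("longitude", "latitude")])
      pred <- predict(fit, Xte)
      Yhat <- warp_inverse(pred$mean, warp)
      Yte <- as.matrix(te[, params, drop = FALSE])
      data.frame(
        split = k, parameter = params,
        r2 = vapply(seq_along(params),
                    function(j) r2_original_space(Yte[, j], Yhat[, j]), 0),
        stringsAsFactors = FALSE
      )
    }, error = function(e) {
      warning(sprintf("split %d failed and is skipped: %s", k,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(res)) failed <- c(failed, k) else rows[[length(rows) + 1]] <- res
  }
  if (!length(rows)) stop("every cross-validation split failed", call. = FALSE)
  rep_df <- do.call(rbind, rows)
  param_means <- tapply(rep_df$r2, factor(rep_df$parameter, levels = params),
                        function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  structure(rep_df, Q = Q, r = r, param_means = param_means,
            failed_splits = failed, splits = splits,
            class = c("psqi_cv_report", "data.frame"))
}

# seeded split indices; resample mode matches "5 random 80/20 splits"
cv_splits <- function(N, n_splits, train_frac, seed, mode) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  if (mode == "kfold") {
    fold <- sample(rep_len(seq_len(n_splits), N))
    lapply(seq_len(n_splits), function(k) {
      list(train = which(fold != k), test = which(fold == k))
    })
  } else {
    n_train <- round(train_frac * N)
    lapply(seq_len(n_splits), function(k) {
      tr <- sort(sample.int(N, n_train))
      list(train = tr, test = setdiff(seq_len(N), tr))
    })
  }
}

#' Mask poorly modelled parameters and pick the best candidate
#'
#' A parameter is dropped iff its split-averaged R2 is negative for every
#' candidate model (its best model cannot beat the constant mean); further
#' parameters can be excluded by name (chronically poor properties).  The
#' best candidate maximizes the mean R2 over kept parameters and splits.
#'
#' @param reports List of [cross_validate()] reports.
#' @param exclude Character vector of parameter names excluded up-front.
#' @return List with `kept` (parameter names), `best` (`c(Q, r)`),
#'   `model_scores` (data frame `Q`, `r`, `mean_r2`), `dropped`, and
#'   `best_param_r2` (per-parameter split-averaged R2 of the winner).
#' @export
mask_and_select <- function(reports, exclude = character()) {
  stopifnot(length(reports) >= 1)
  params <- unique(reports[[1]]$parameter)
  pm <- sapply(reports, function(rp) attr(rp, "param_means")[params])
  pm <- matrix(pm, nrow = length(params),
               dimnames = list(params, NULL))
  best_per_param <- apply(pm, 1, function(v) {
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  })
  dropped <- params[is.na(best_per_param) | best_per_param < 0]
  dropped <- union(dropped, intersect(exclude, params))
  kept <- setdiff(params, dropped)
  if (!length(kept)) stop("all parameters were masked out", call. = FALSE)

  scores <- data.frame(
    Q = vapply(reports, function(rp) attr(rp, "Q"), 0),
    r = vapply(reports, function(rp) attr(rp, "r"), 0),
    mean_r2 = vapply(reports, function(rp) {
      v <- rp$r2[rp$parameter %in% kept]
      mean(v, na.rm = TRUE)
    }, 0)
  )
  # argmax with deterministic ties towards smaller Q, then smaller r
  ord <- order(-scores$mean_r2, scores$Q, scores$r)
  best_i <- ord[1]
  list(kept = kept, dropped = dropped,
       best = c(Q = scores$Q[best_i], r = scores$r[best_i]),
       model_scores = scores,
       best_param_r2 = attr(reports[[best_i]], "param_means"))
}

#' Write a cross-validation grid report to CSV + YAML summary
#'
#' @param reports List of [cross_validate()] reports.
#' @param selection Result of [mask_and_select()] on those reports.
#' @param csv_path,yaml_path Output paths.
#' @return Invisibly, the CSV data frame.
#' @export
write_cv_report <- function(reports, selection, csv_path, yaml_path) {
  long <- do.call(rbind, lapply(reports, function(rp) {
    data.frame(Q = attr(rp, "Q"), r = attr(rp, "r"), split = rp$split,
               parameter = rp$parameter, r2 = rp$r2, stringsAsFactors = FALSE)
  }))
  utils::write.csv(long, csv_path, row.names = FALSE)
  yaml::write_yaml(list(
    kept = as.list(selection$kept),
    dropped = as.list(selection$dropped),
    best = list(Q = unname(selection$best["Q"]), r = unname(selection$best["r"])),
    model_scores = lapply(seq_len(nrow(selection$model_scores)), function(i)
      as.list(selection$model_scores[i, ]))
  ), yaml_path)
  invisible(long)
}
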