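#' Pipeline orchestration
#'
#' [run_pipeline()] drives the four stages of a study as batch commands —
#' `simulate` (synthetic data), `validate` (cross-validated (Q, r) grid
#' search), `fit` (train the selected model on all data) and `map` (grid
#' prediction + PSQI export) — reading one configuration list or YAML file,
#' writing plain-text artifacts plus a manifest (config echo, seeds, package
#' version, input checksums) from which every artifact is reproducible.
#' A thin command-line wrapper around this function ships in
#' `inst/cli/psqi-geo.R`.
#'
#' @name pipeline
NULL

#' Default pipeline configuration
#'
#' @param seed Master seed; every stage derives its randomness from it.
#' @param samples,standards,model Paths of the samples CSV, standards table
#'   (NULL = packaged defaults) and model file.
#' @param q_grid,r_grid Candidate grids for `validate`.
#' @param region,spacing Region (bbox vector or GeoJSON path) and grid
#'   spacing in metres for `map`.
#' @param exclude Parameters excluded from selection up-front.
#' @param psqi_space `"warped"` or `"original"` (see [psqi_values()]).
#' @param cv_mode `"resample"` or `"kfold"`.
#' @param Q,r Model order used by `fit` when no validation summary exists.
#' @param iterations,learning_rate Optimizer settings.
#' @param synth Arguments forwarded to [synth_config()] by `simulate`.
#' @return Configuration list.
#' @export
pipeline_config <- function(seed = 1, samples = NULL, standards = NULL,
                            model = NULL, q_grid = 1:3, r_grid = c(2, 3),
                            region = NULL, spacing = 100,
                            exclude = character(), psqi_space = "warped",
                            cv_mode = "resample", Q = 1, r = 2,
                            iterations = 300, learning_rate = 0.1,
                            synth = list()) {
  list(seed = seed, samples = samples, standards = standards, model = model,
       q_grid = q_grid, r_grid = r_grid, region = region, spacing = spacing,
       exclude = exclude, psqi_space = psqi_space, cv_mode = cv_mode,
       Q = Q, r = r, iterations = iterations, learning_rate = learning_rate,
       synth = synth)
}

#' Run one pipeline command
#'
#' @param config A [pipeline_config()] list or the path of a YAML file with
#'   the same fields.
#' @param command One of `"simulate"`, `"validate"`, `"fit"`, `"map"`.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list of the artifact paths written.
#' @export
run_pipeline <- function(config, command = c("simulate", "validate", "fit", "map"),
                         out_dir = ".") {
  command <- match.arg(command)
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- pipeline_config()
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  control <- fit_control(learning_rate = config$learning_rate,
                         iterations = config$iterations)
  artifacts <- list()

  load_std <- function() {
    if (is.null(config$standards)) {
      if (is.null(config$samples)) synth_standards() else load_standards()
    } else load_standards(config$standards)
  }
  read_samples <- function() {
    if (is.null(config$samples)) {
      stop("config$samples is required for '", command, "'", call. = FALSE)
    }
    utils::read.csv(config$samples, check.names = FALSE)
  }

  if (command == "simulate") {
    cfg <- do.call(synth_config, c(list(seed = config$seed), config$synth))
    gen <- generate_dataset(cfg)
    p_samples <- file.path(out_dir, "samples.csv")
    utils::write.csv(gen$samples, p_samples, row.names = FALSE)
    p_truth <- file.path(out_dir, "truth.yaml")
    tr <- gen$truth
    yaml::write_yaml(list(
      config = unclass(cfg),
      Kf = apply(tr$Kf, 1, as.list),
      correlations = apply(tr$correlations, 1, as.list),
      noise_variances = as.list(tr$D),
      lengthscale = cfg$lengthscale
    ), p_truth)
    artifacts <- list(samples = p_samples, truth = p_truth)
  } else if (command == "validate") {
    samples <- read_samples()
    standards <- load_std()
    grid <- expand.grid(Q = config$q_grid, r = config$r_grid)
    reports <- lapply(seq_len(nrow(grid)), function(i) {
      message(sprintf("cross-validating Q=%d r=%d", grid$Q[i], grid$r[i]))
      cross_validate(samples, standards, Q = grid$Q[i], r = grid$r[i],
                     seed = config$seed, control = control,
                     mode = config$cv_mode)
    })
    sel <- mask_and_select(reports, exclude = config$exclude)
    for (p in sel$dropped) message("parameter masked out: ", p)
    p_csv <- file.path(out_dir, "cv_report.csv")
    p_yaml <- file.path(out_dir, "cv_summary.yaml")
    write_cv_report(reports, sel, p_csv, p_yaml)
    artifacts <- list(cv_report = p_csv, cv_summary = p_yaml)
  } else if (command == "fit") {
    samples <- read_samples()
    standards <- load_std()
    Q <- config$Q; r <- config$r; param_r2 <- NULL
    p_sum <- file.path(out_dir, "cv_summary.yaml")
    if (file.exists(p_sum)) {
      s <- yaml::read_yaml(p_sum)
      Q <- s$best$Q; r <- s$best$r
      p_csv <- file.path(out_dir, "cv_report.csv")
      if (file.exists(p_csv)) {
        long <- utils::read.csv(p_csv)
        best <- long[long$Q == Q & long$r == r, ]
        param_r2 <- tapply(best$r2, best$parameter, mean, na.rm = TRUE)
      }
    }
    final_control <- control
    final_control$restarts <- max(control$restarts, 3)
    model <- fit_water_model(samples, standards, Q = Q, r = r,
                             control = final_control, seed = config$seed,
                             param_r2 = param_r2)
    p_model <- file.path(out_dir, "model.json")
    save_model(model, p_model)
    artifacts <- list(model = p_model)
  } else { # map
    p_model <- if (!is.null(config$model)) config$model else file.path(out_dir, "model.json")
    if (!file.exists(p_model)) {
      stop("model file not found (run 'fit' first or set config$model): ",
           p_model, call. = FALSE)
    }
    model <- load_model(p_model)
    if (is.null(config$region)) {
      stop("config$region (bbox or GeoJSON path) is required for 'map'",
           call. = FALSE)
    }
    grid <- make_grid(config$region, spacing = config$spacing,
                      scaler = model$scaler)
    map_df <- predict_map(model, grid, space = config$psqi_space)
    p_csv <- file.path(out_dir, "map.csv")
    utils::write.csv(map_df, p_csv, row.names = FALSE)
    p_gj <- file.path(out_dir, "map.geojson")
    write_map_geojson(map_df, p_gj)
    artifacts <- list(map_csv = p_csv, map_geojson = p_gj)
  }

  inputs <- Filter(function(p) is.character(p) && length(p) == 1 && file.exists(p),
                   config[c("samples", "standards", "model", "region")])
  manifest <- list(
    command = command,
    seed = config$seed,
    config = config[!vapply(config, is.null, TRUE)],
    package = list(name = "psqigeo",
                   version = as.character(utils::packageVersion("psqigeo"))),
    input_checksums = as.list(vapply(inputs, function(p)
      unname(tools::md5sum(p)), "")),
    artifacts = lapply(artifacts, basename)
  )
  yaml::write_yaml(manifest, file.path(out_dir, paste0("manifest_", command, ".yaml")))
  invisible(artifacts)
}
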