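#' Prediction grids and map products
#'
#' A uniform axis-aligned lattice is laid over the region of interest in
#' projected metres (default spacing 100 m, endpoints inclusive), optionally
#' clipped to a polygon, and the fitted model is evaluated over it in batches
#' to produce per-location predictive summaries, PSQI and confidence.
#'
#' @name mapgrid
NULL

#' Build a uniform prediction grid over a region
#'
#' @param region One of: a length-4 numeric `c(lon1, lat1, lon2, lat2)`
#'   bounding box in degrees; a two-column matrix of polygon vertices
#'   (longitude, latitude, not necessarily closed); or the path of a GeoJSON
#'   file whose first feature is a Polygon.
#' @param spacing Lattice spacing in metres (default 100).
#' @param scaler A fitted [fit_coord_scaler()]; supplies the projection and,
#'   when given, the scaled model coordinates of the grid points.
#' @param bbox_utm Alternative region input: `c(e1, n1, e2, n2)` directly in
#'   projected metres (requires `scaler` for the zone).
#' @return Data frame `longitude`, `latitude`, `easting`, `northing` (+
#'   `x1`, `x2` scaled coordinates when a scaler is given).
#' @export
make_grid <- function(region = NULL, spacing = 100, scaler = NULL,
                      bbox_utm = NULL) {
  stopifnot(spacing > 0)
  poly_en <- NULL
  if (!is.null(bbox_utm)) {
    stopifnot(!is.null(scaler), length(bbox_utm) == 4)
    e_rng <- sort(bbox_utm[c(1, 3)]); n_rng <- sort(bbox_utm[c(2, 4)])
    zone <- scaler$zone; north <- scaler$north
  } else {
    if (is.character(region)) region <- read_geojson_polygon(region)
    if (is.matrix(region) || is.data.frame(region)) {
      poly_ll <- as.matrix(region)
      stopifnot(ncol(poly_ll) == 2)
      zone <- if (!is.null(scaler)) scaler$zone else utm_zone_for(mean(poly_ll[, 1]))
      north <- if (!is.null(scaler)) scaler$north else mean(poly_ll[, 2]) >= 0
      poly_en <- utm_forward(poly_ll, zone, north)
      e_rng <- range(poly_en[, 1]); n_rng <- range(poly_en[, 2])
    } else {
      stopifnot(length(region) == 4)
      lon <- sort(region[c(1, 3)]); lat <- sort(region[c(2, 4)])
      zone <- if (!is.null(scaler)) scaler$zone else utm_zone_for(mean(lon))
      north <- if (!is.null(scaler)) scaler$north else mean(lat) >= 0
      corners <- utm_forward(cbind(lon[c(1, 1, 2, 2)], lat[c(1, 2, 1, 2)]),
                             zone, north)
      e_rng <- range(corners[, 1]); n_rng <- range(corners[, 2])
    }
  }

  es <- seq(e_rng[1], e_rng[2], by = spacing)
  ns <- seq(n_rng[1], n_rng[2], by = spacing)
  # endpoints inclusive: keep the far edge when spacing does not divide the
  # extent (but not when the residual is mere floating-point noise)
  if (e_rng[2] - max(es) > 1e-6 * spacing) es <- c(es, e_rng[2])
  if (n_rng[2] - max(ns) > 1e-6 * spacing) ns <- c(ns, n_rng[2])
  grid_en <- cbind(easting = rep(es, times = length(ns)),
                   northing = rep(ns, each = length(es)))

  if (!is.null(poly_en)) {
    keep <- mgcv::in.out(rbind(poly_en, poly_en[1, ]), grid_en) |
      .on_boundary(poly_en, grid_en)
    grid_en <- grid_en[keep, , drop = FALSE]
  }
  if (nrow(grid_en) == 0) stop("empty grid: region smaller than spacing", call. = FALSE)

  ll <- utm_inverse(grid_en, zone, north)
  out <- data.frame(longitude = ll[, 1], latitude = ll[, 2],
                    easting = grid_en[, 1], northing = grid_en[, 2])
  if (!is.null(scaler)) {
    xy <- cbind(
      (grid_en[, 1] - scaler$min_xy[1]) / (scaler$max_xy[1] - scaler$min_xy[1]),
      (grid_en[, 2] - scaler$min_xy[2]) / (scaler$max_xy[2] - scaler$min_xy[2])
    )
    out$x1 <- xy[, 1]; out$x2 <- xy[, 2]
  }
  out
}

# points lying on a polygon edge (in.out is strict about the boundary);
# tol is relative to the edge length, covering projection round-trip noise
.on_boundary <- function(poly, pts, tol = 1e-8) {
  m <- nrow(poly)
  on <- rep(FALSE, nrow(pts))
  for (i in seq_len(m)) {
    a <- poly[i, ]; b <- poly[if (i == m) 1 else i + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    dx <- pts[, 1] - (a[1] + t * ab[1])
    dy <- pts[, 2] - (a[2] + t * ab[2])
    on <- on | (dx^2 + dy^2 < tol^2 * max(1, len2))
  }
  on
}

read_geojson_polygon <- function(path) {
  if (!file.exists(path)) {
    stop("GeoJSON region file not found: ", path, call. = FALSE)
  }
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feat <- if (identical(gj$type, "FeatureCollection")) gj$features[[1]] else gj
  geom <- if (identical(feat$type, "Feature")) feat$geometry else feat
  if (!identical(geom$type, "Polygon")) {
    stop("GeoJSON region must contain a Polygon", call. = FALSE)
  }
  ring <- geom$coordinates[[1]]
  do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
}

#' Predict the map: per-location summaries, PSQI and confidence
#'
#' For each grid point the model's warped-space predictive distribution is
#' evaluated, poorly modelled parameters are substituted by their dataset
#' statistics ([apply_fallback()]), and PSQI/confidence are computed.  The
#' reported central value per parameter is the inverse warp of the warped
#' predictive mean (a median-type estimate: the original-space distribution
#' is non-Gaussian); the warped-space standard deviation is reported
#' alongside.
#'
#' @param model A fitted model bundle from [fit_water_model()].
#' @param grid A [make_grid()] data frame (scaled coordinates included).
#' @param batch_size Grid points predicted per batch; results are identical
#'   for any batch size.
#' @param space PSQI integration space, see [psqi_values()].
#' @return Data frame: grid columns, `psqi`, `confidence`, per-parameter
#'   `mean_<name>` (original units), `sd_warped_<name>`, `p_<name>`,
#'   `q_<name>`.
#' @export
predict_map <- function(model, grid, batch_size = 1024,
                        space = c("warped", "original")) {
  space <- match.arg(space)
  stopifnot(inherits(model, "psqi_model"))
  if (is.null(grid$x1)) {
    xy <- coords_to_model(model$scaler, grid[, c("longitude", "latitude")])
    grid$x1 <- xy[, 1]; grid$x2 <- xy[, 2]
  }
  pred <- predict(model$fit, as.matrix(grid[, c("x1", "x2")]),
                  batch_size = batch_size)
  pred <- apply_fallback(pred, model$param_r2, model$data_mean, model$data_var)
  pq <- psqi_values(pred, model$standards, model$warp, model$weights,
                    space = space)
  Yhat <- warp_inverse(pred$mean, model$warp)
  out <- cbind(grid, pq[, c("psqi", "confidence")])
  for (k in seq_along(model$fit$parameters)) {
    nm <- model$fit$parameters[k]
    out[[paste0("mean_", nm)]] <- Yhat[, k]
    out[[paste0("sd_warped_", nm)]] <- sqrt(pmax(pred$cov[k, k, ], 0))
  }
  for (nm in names(model$weights)) {
    out[[paste0("p_", nm)]] <- pq[[paste0("p_", nm)]]
    out[[paste0("q_", nm)]] <- pq[[paste0("q_", nm)]]
  }
  out
}

#' Write a predicted map as a GeoJSON FeatureCollection of points
#'
#' @param map_df A [predict_map()] result.
#' @param path Output file.
#' @param properties Column names to attach to each feature (defaults to all
#'   non-coordinate columns).
#' @return Invisibly, `path`.
#' @export
write_map_geojson <- function(map_df, path, properties = NULL) {
  if (is.null(properties)) {
    properties <- setdiff(names(map_df),
                          c("longitude", "latitude", "easting", "northing",
                            "x1", "x2"))
  }
  feats <- lapply(seq_len(nrow(map_df)), function(i) {
    list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(map_df$longitude[i], map_df$latitude[i])),
      properties = as.list(map_df[i, properties, drop = FALSE])
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}
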