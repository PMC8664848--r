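#' Coordinate projection and scaling
#'
#' Sample coordinates arrive as geographic longitude/latitude (EPSG:4326) and
#' are projected to metric UTM coordinates (transverse Mercator on WGS84,
#' e.g. EPSG:32637 = zone 37N for the ~37E longitude band), then min-max
#' scaled into the unit square.  The Gaussian-process length-scales are
#' expressed in these scaled units, so the scaler is fitted once on the
#' training samples and reused unchanged for every prediction grid.
#'
#' The projection itself is the standard Krueger series (order n^4), accurate
#' to well below a millimetre inside a UTM zone; forward/inverse round-trips
#' reproduce coordinates to much better than 1e-6 degrees.
#'
#' @name coords
NULL

# WGS84 / transverse Mercator constants shared by forward and inverse
.utm_const <- local({
  a <- 6378137.0
  f <- 1 / 298.257223563
  n <- f / (2 - f)
  list(
    a = a, f = f, n = n, k0 = 0.9996, fe = 5e5,
    A = a / (1 + n) * (1 + n^2 / 4 + n^4 / 64),
    alpha = c(
      n / 2 - 2 * n^2 / 3 + 5 * n^3 / 16 + 41 * n^4 / 180,
      13 * n^2 / 48 - 3 * n^3 / 5 + 557 * n^4 / 1440,
      61 * n^3 / 240 - 103 * n^4 / 140,
      49561 * n^4 / 161280
    ),
    beta = c(
      n / 2 - 2 * n^2 / 3 + 37 * n^3 / 96 - n^4 / 360,
      n^2 / 48 + n^3 / 15 - 437 * n^4 / 1440,
      17 * n^3 / 480 - 37 * n^4 / 840,
      4397 * n^4 / 161280
    ),
    delta = c(
      2 * n - 2 * n^2 / 3 - 2 * n^3 + 116 * n^4 / 45,
      7 * n^2 / 3 - 8 * n^3 / 5 - 227 * n^4 / 45,
      56 * n^3 / 15 - 136 * n^4 / 35,
      4279 * n^4 / 630
    )
  )
})

#' UTM zone containing a longitude
#' @param lon Longitude in decimal degrees.
#' @return Integer zone number in 1..60.
#' @export
utm_zone_for <- function(lon) {
  z <- floor((lon + 180) / 6) + 1
  as.integer(pmin(pmax(z, 1), 60))
}

#' Project geographic coordinates to UTM metres
#'
#' @param lonlat N x 2 matrix (or data frame) of longitude, latitude in
#'   decimal degrees (EPSG:4326).
#' @param zone UTM zone number (1..60).
#' @param north Logical; northern-hemisphere convention (no false northing).
#' @return N x 2 matrix of easting, northing in metres.
#' @export
utm_forward <- function(lonlat, zone, north = TRUE) {
  lonlat <- as.matrix(lonlat)
  stopifnot(ncol(lonlat) == 2)
  if (any(abs(lonlat[, 1]) > 180) || any(abs(lonlat[, 2]) > 90)) {
    stop("longitude/latitude outside valid ranges", call. = FALSE)
  }
  cc <- .utm_const
  lam0 <- (-183 + 6 * zone) * pi / 180
  phi <- lonlat[, 2] * pi / 180
  lam <- lonlat[, 1] * pi / 180 - lam0

  sn <- 2 * sqrt(cc$n) / (1 + cc$n)
  t <- sinh(atanh(sin(phi)) - sn * atanh(sn * sin(phi)))
  xi <- atan2(t, cos(lam))
  eta <- atanh(sin(lam) / sqrt(1 + t^2))
  xs <- xi; es <- eta
  for (j in 1:4) {
    xs <- xs + cc$alpha[j] * sin(2 * j * xi) * cosh(2 * j * eta)
    es <- es + cc$alpha[j] * cos(2 * j * xi) * sinh(2 * j * eta)
  }
  east <- cc$fe + cc$k0 * cc$A * es
  north_m <- cc$k0 * cc$A * xs + if (north) 0 else 1e7
  cbind(easting = east, northing = north_m)
}

#' Inverse UTM projection back to geographic degrees
#'
#' @param en N x 2 matrix of easting, northing in metres.
#' @inheritParams utm_forward
#' @return N x 2 matrix of longitude, latitude in decimal degrees.
#' @export
utm_inverse <- function(en, zone, north = TRUE) {
  en <- as.matrix(en)
  stopifnot(ncol(en) == 2)
  cc <- .utm_const
  lam0 <- (-183 + 6 * zone) * pi / 180
  xi <- (en[, 2] - if (north) 0 else 1e7) / (cc$k0 * cc$A)
  eta <- (en[, 1] - cc$fe) / (cc$k0 * cc$A)
  xs <- xi; es <- eta
  for (j in 1:4) {
    xs <- xs - cc$beta[j] * sin(2 * j * xi) * cosh(2 * j * eta)
    es <- es - cc$beta[j] * cos(2 * j * xi) * sinh(2 * j * eta)
  }
  chi <- asin(sin(xs) / cosh(es))
  phi <- chi
  for (j in 1:4) phi <- phi + cc$delta[j] * sin(2 * j * chi)
  lam <- atan2(sinh(es), cos(xs))
  cbind(longitude = (lam + lam0) * 180 / pi, latitude = phi * 180 / pi)
}

#' Fit the coordinate scaler on training sample locations
#'
#' @param lonlat N x 2 matrix/data frame of longitude, latitude in degrees.
#' @param zone UTM zone, or `NULL` to take the zone of the data centroid.
#' @return A `psqi_coord_scaler` with the projection id and the min/max of the
#'   projected training coordinates (the unit-square anchors).
#' @export
fit_coord_scaler <- function(lonlat, zone = NULL) {
  lonlat <- as.matrix(lonlat)
  if (nrow(lonlat) < 2) stop("need at least 2 points to fit the scaler", call. = FALSE)
  if (is.null(zone)) zone <- utm_zone_for(mean(lonlat[, 1]))
  north <- mean(lonlat[, 2]) >= 0
  en <- utm_forward(lonlat, zone, north)
  min_xy <- apply(en, 2, min)
  max_xy <- apply(en, 2, max)
  if (any(max_xy - min_xy <= 0)) {
    stop("degenerate spatial extent: all points identical along an axis", call. = FALSE)
  }
  structure(
    list(zone = zone, north = north,
         epsg = if (north) 32600L + zone else 32700L + zone,
         min_xy = unname(min_xy), max_xy = unname(max_xy)),
    class = "psqi_coord_scaler"
  )
}

#' Map geographic coordinates into the scaled model space
#'
#' Training points land inside the unit square by construction; points beyond
#' the training extent extrapolate affinely (coordinates outside \[0,1\] are
#' legitimate).
#'
#' @param scaler A fitted [fit_coord_scaler()] object.
#' @param lonlat N x 2 longitude/latitude degrees.
#' @return N x 2 matrix of scaled coordinates.
#' @export
coords_to_model <- function(scaler, lonlat) {
  stopifnot(inherits(scaler, "psqi_coord_scaler"))
  en <- utm_forward(as.matrix(lonlat), scaler$zone, scaler$north)
  cbind(
    x1 = (en[, 1] - scaler$min_xy[1]) / (scaler$max_xy[1] - scaler$min_xy[1]),
    x2 = (en[, 2] - scaler$min_xy[2]) / (scaler$max_xy[2] - scaler$min_xy[2])
  )
}

#' @rdname coords_to_model
#' @param xy N x 2 scaled model coordinates.
#' @export
coords_from_model <- function(scaler, xy) {
  stopifnot(inherits(scaler, "psqi_coord_scaler"))
  xy <- as.matrix(xy)
  en <- cbind(
    xy[, 1] * (scaler$max_xy[1] - scaler$min_xy[1]) + scaler$min_xy[1],
    xy[, 2] * (scaler$max_xy[2] - scaler$min_xy[2]) + scaler$min_xy[2]
  )
  utm_inverse(en, scaler$zone, scaler$north)
}
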