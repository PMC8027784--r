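# Source-centred polar geometry: coordinate conversion, sector membership,
# and polar prediction grids.

#' @keywords internal
EARTH_RADIUS_KM <- 6371.0088

#' Convert geographic coordinates to source-centred polar coordinates
#'
#' Projects WGS84 longitude/latitude pairs onto a local planar
#' (equirectangular) approximation centred on the source and returns distance
#' and compass bearing. Bearings follow the surveying convention: North = 0,
#' East = 90 degrees, increasing clockwise, reduced to `[0, 360)`.
#'
#' The planar approximation scales longitude differences by the cosine of the
#' origin latitude. Within a few kilometres of the source its error is far
#' below field-sampling position uncertainty; the function refuses points more
#' than 100 km away, where the approximation would degrade.
#'
#' @param lon,lat numeric vectors of WGS84 coordinates, decimal degrees.
#' @param origin_lon,origin_lat scalar coordinates of the source.
#' @return A `data.frame` with columns `r_km` (distance from the source, km)
#'   and `bearing_deg` (degrees in `[0, 360)`).
#' @seealso [from_polar()] for the planar inverse, [make_grid()].
#' @examples
#' to_polar(2.349, 48.862, origin_lon = 2.349, origin_lat = 48.853)
#' @export
to_polar <- function(lon, lat, origin_lon, origin_lat) {
  if (!all(is.finite(lon), is.finite(lat), is.finite(origin_lon),
           is.finite(origin_lat))) {
    stop("coordinates must be finite WGS84 degrees", call. = FALSE)
  }
  rad <- pi / 180
  x <- EARTH_RADIUS_KM * (lon - origin_lon) * rad * cos(origin_lat * rad)
  y <- EARTH_RADIUS_KM * (lat - origin_lat) * rad
  r <- sqrt(x^2 + y^2)
  if (any(r >= 100)) {
    stop("points more than 100 km from the origin are outside the ",
         "planar-approximation regime", call. = FALSE)
  }
  theta <- (atan2(x, y) / rad) %% 360
  theta[r == 0] <- 0
  data.frame(r_km = r, bearing_deg = theta)
}

#' Invert the local planar projection
#'
#' Maps source-centred polar coordinates back to longitude/latitude under the
#' same equirectangular approximation used by [to_polar()].
#'
#' @param r_km,bearing_deg polar coordinates (km; degrees, North = 0 clockwise).
#' @inheritParams to_polar
#' @return A `data.frame` with columns `lon` and `lat`.
#' @export
from_polar <- function(r_km, bearing_deg, origin_lon, origin_lat) {
  rad <- pi / 180
  x <- r_km * sin(bearing_deg * rad)
  y <- r_km * cos(bearing_deg * rad)
  data.frame(
    lon = origin_lon + x / (EARTH_RADIUS_KM * rad * cos(origin_lat * rad)),
    lat = origin_lat + y / (EARTH_RADIUS_KM * rad)
  )
}

#' Define an angular sector
#'
#' A sector is the open wedge of bearings strictly between `theta_min` and
#' `theta_max`. The default, 260--310 degrees, is the downwind wedge fixed a
#' priori from meteorology in the motivating survey; boundary bearings count
#' as outside.
#'
#' @param theta_min,theta_max sector bounds in degrees,
#'   `0 <= theta_min < theta_max <= 360`.
#' @return An object of class `plume_sector`.
#' @seealso [in_sector()]
#' @export
plume_sector <- function(theta_min = 260, theta_max = 310) {
  if (!is.finite(theta_min) || !is.finite(theta_max) ||
      theta_min < 0 || theta_min >= theta_max || theta_max > 360) {
    stop("sector bounds must satisfy 0 <= theta_min < theta_max <= 360",
         call. = FALSE)
  }
  structure(list(theta_min = theta_min, theta_max = theta_max),
            class = "plume_sector")
}

#' @export
print.plume_sector <- function(x, ...) {
  cat(sprintf("<plume_sector> %g deg < theta < %g deg (%.1f%% of the circle)\n",
              x$theta_min, x$theta_max,
              100 * (x$theta_max - x$theta_min) / 360))
  invisible(x)
}

#' Sector membership of a bearing
#'
#' Bearings are reduced modulo 360 before the test, so `theta` and
#' `theta + 360` classify identically. Membership is strict (open interval):
#' a bearing exactly on a sector boundary is outside.
#'
#' @param theta bearing(s) in degrees.
#' @param sector a [plume_sector()].
#' @return Logical vector.
#' @examples
#' in_sector(285, plume_sector())  # TRUE
#' in_sector(260, plume_sector())  # FALSE: open boundary
#' @export
in_sector <- function(theta, sector = plume_sector()) {
  stopifnot(inherits(sector, "plume_sector"))
  th <- theta %% 360
  th > sector$theta_min & th < sector$theta_max
}

#' Minimal angular difference
#'
#' @param a,b bearings in degrees.
#' @return The unsigned minimal difference in `[0, 180]`.
#' @keywords internal
ang_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Polar prediction grid
#'
#' Builds an `n` x `n` grid uniform in polar coordinates: `n` radii equally
#' spaced over `[r_min, r_max]` crossed with `n` bearings equally spaced over
#' `[0, 360)`. The default 30 x 30 grid spans 0.1--1.5 km; the region inside
#' 0.1 km is deliberately excluded because inference there would be pure
#' extrapolation beyond any survey data.
#'
#' @param r_min,r_max radial bounds in km, `0 < r_min < r_max`.
#' @param n points per axis, at least 2.
#' @return A `data.frame` with `n^2` rows and columns `r_km`, `bearing_deg`
#'   (radius varying fastest).
#' @examples
#' g <- make_grid()
#' nrow(g)          # 900
#' range(g$r_km)    # 0.1 1.5
#' @export
make_grid <- function(r_min = 0.1, r_max = 1.5, n = 30) {
  if (!is.finite(r_min) || r_min <= 0) {
    stop("r_min must be positive (the innermost region is excluded)",
         call. = FALSE)
  }
  if (!is.finite(r_max) || r_max <= r_min) stop("need r_min < r_max", call. = FALSE)
  if (n < 2) stop("need n >= 2 grid points per axis", call. = FALSE)
  expand.grid(
    r_km = seq(r_min, r_max, length.out = n),
    bearing_deg = seq(0, 360, length.out = n + 1)[-(n + 1)],
    KEEP.OUT.ATTRS = FALSE
  )
}
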