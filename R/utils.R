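#' Great-circle distance (haversine)
#'
#' Vectorized haversine distance on a sphere of radius `radius_km`
#' (default 6371 km, the mean Earth radius).
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees (recycled).
#' @param radius_km sphere radius in km.
#' @return distances in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2, radius_km = 6371) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  a <- pmin(1, a)
  2 * radius_km * asin(sqrt(a))
}

# unit-sphere mean of lon/lat points, renormalized; avoids longitude-averaging
# artifacts. Returns c(lon, lat).
spherical_centroid <- function(lon, lat) {
  rad <- pi / 180
  x <- mean(cos(lat * rad) * cos(lon * rad))
  y <- mean(cos(lat * rad) * sin(lon * rad))
  z <- mean(sin(lat * rad))
  r <- sqrt(x^2 + y^2 + z^2)
  if (r == 0) stop("degenerate centroid (antipodal cancellation)", call. = FALSE)
  c(lon = atan2(y, x) / rad, lat = asin(z / r) / rad)
}

# parse "2:1" odds strings or numeric fractions into a probability mass
# fraction in (0, 1]: odds a:b -> a / (a + b).
#' Parse an odds-ratio specification
#'
#' Accepts a numeric fraction in `(0, 1]` or a string like `"2:1"`
#' (converted to `a / (a + b)`, so `"2:1"` gives `2/3`).
#'
#' @param x numeric or character scalar.
#' @return numeric fraction in `(0, 1]`.
#' @export
parse_odds <- function(x) {
  if (is.character(x)) {
    parts <- suppressWarnings(as.numeric(strsplit(trimws(x), ":")[[1]]))
    if (length(parts) == 1 && !is.na(parts)) {
      x <- parts
    } else if (length(parts) == 2 && !anyNA(parts) && all(parts > 0)) {
      x <- parts[1] / sum(parts)
    } else stop("cannot parse odds specification: ", x, call. = FALSE)
  }
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0 || x > 1)
    stop("odds fraction must lie in (0, 1]", call. = FALSE)
  x
}
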