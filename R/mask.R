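# Region masks: rectangular extents, polygon sets (lon/lat rings, even-odd
# rule), or boolean grids aligned to a target geometry. Used to limit
# assignment domains to continents or species ranges.

#' Region masks
#'
#' A `region_mask` selects a subset of a grid. Three flavours:
#' * `extent_mask()` — an axis-aligned lon/lat rectangle (bounds inclusive);
#' * `polygon_mask()` — one or more lon/lat rings, interpreted with the
#'   even-odd rule (so holes are rings too); optionally intersected with an
#'   extent;
#' * `grid_mask()` — a boolean [geo_grid()] that must be aligned to the
#'   target geometry (non-zero / `TRUE` cells are inside).
#'
#' Masks are rasterized by testing cell centers.
#'
#' @param lon_min,lon_max,lat_min,lat_max extent bounds in degrees.
#' @param label free-text label (continent, species range, ...).
#' @return an object of class `region_mask`.
#' @export
extent_mask <- function(lon_min, lon_max, lat_min, lat_max, label = "") {
  stopifnot(lon_min <= lon_max, lat_min <= lat_max)
  structure(list(type = "extent",
                 extent = c(lon_min = lon_min, lon_max = lon_max,
                            lat_min = lat_min, lat_max = lat_max),
                 label = label),
            class = "region_mask")
}

#' @rdname extent_mask
#' @param rings a single two-column (lon, lat) matrix or a list of them.
#' @param extent optional `c(lon_min, lon_max, lat_min, lat_max)` intersected
#'   with the polygon (the usual "continent window" construction).
#' @export
polygon_mask <- function(rings, extent = NULL, label = "") {
  if (is.matrix(rings)) rings <- list(rings)
  stopifnot(length(rings) >= 1,
            all(vapply(rings, function(r) is.matrix(r) && ncol(r) == 2 &&
                         nrow(r) >= 3, TRUE)))
  structure(list(type = "polygon", rings = rings, extent = extent,
                 label = label),
            class = "region_mask")
}

#' @rdname extent_mask
#' @param grid a [geo_grid()] whose non-zero, non-`NA` cells are inside.
#' @export
grid_mask <- function(grid, label = "") {
  stopifnot(inherits(grid, "geo_grid"))
  structure(list(type = "grid", grid = grid, label = label),
            class = "region_mask")
}

#' Read a polygon mask from a GeoJSON file
#'
#' Accepts a `Polygon` or `MultiPolygon` geometry, a `Feature`, or a
#' `FeatureCollection` (all features are pooled). All rings, outer and holes,
#' enter the even-odd test.
#'
#' @param path GeoJSON file path.
#' @param label mask label; defaults to the file name.
#' @return a [polygon_mask()].
#' @export
read_geojson_mask <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("GeoJSON file not found: ", path, call. = FALSE)
  x <- jsonlite::read_json(path)
  rings <- list()
  add_geom <- function(geom) {
    ring_mat <- function(ring)
      do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    if (identical(geom$type, "Polygon")) {
      for (ring in geom$coordinates) rings[[length(rings) + 1]] <<- ring_mat(ring)
    } else if (identical(geom$type, "MultiPolygon")) {
      for (poly in geom$coordinates)
        for (ring in poly) rings[[length(rings) + 1]] <<- ring_mat(ring)
    } else stop("unsupported GeoJSON geometry type: ", geom$type, call. = FALSE)
  }
  if (identical(x$type, "FeatureCollection")) {
    for (f in x$features) add_geom(f$geometry)
  } else if (identical(x$type, "Feature")) {
    add_geom(x$geometry)
  } else add_geom(x)
  polygon_mask(rings, label = label)
}

# even-odd (ray casting) point-in-polygon over a set of rings, vectorized
# over points; points exactly on an edge get a deterministic side.
points_in_rings <- function(lon, lat, rings) {
  inside <- rep(FALSE, length(lon))
  for (ring in rings) {
    x <- ring[, 1]; y <- ring[, 2]
    n <- nrow(ring)
    if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1 }
    j <- n
    for (i in seq_len(n)) {
      crosses <- (y[i] > lat) != (y[j] > lat)
      if (any(crosses)) {
        xint <- x[i] + (lat[crosses] - y[i]) * (x[j] - x[i]) / (y[j] - y[i])
        hit <- crosses
        hit[crosses] <- lon[crosses] < xint
        inside <- xor(inside, hit)
      }
      j <- i
    }
  }
  inside
}

#' Rasterize a region mask onto a grid geometry
#'
#' @param mask a `region_mask`, or a list of them (interpreted as the
#'   intersection, e.g. continent extent AND polygon).
#' @param geometry target [grid_geometry()].
#' @return logical matrix of the geometry's shape; `TRUE` = inside.
#' @export
rasterize_mask <- function(mask, geometry) {
  if (is.list(mask) && !inherits(mask, "region_mask")) {
    ms <- lapply(mask, rasterize_mask, geometry = geometry)
    return(Reduce(`&`, ms))
  }
  stopifnot(inherits(mask, "region_mask"))
  latc <- lat_centers(geometry); lonc <- lon_centers(geometry)
  LON <- matrix(lonc, geometry$n_rows, geometry$n_cols, byrow = TRUE)
  LAT <- matrix(latc, geometry$n_rows, geometry$n_cols)
  if (mask$type == "extent") {
    e <- mask$extent
    m <- LON >= e["lon_min"] & LON <= e["lon_max"] &
      LAT >= e["lat_min"] & LAT <= e["lat_max"]
  } else if (mask$type == "polygon") {
    m <- matrix(points_in_rings(as.vector(LON), as.vector(LAT), mask$rings),
                geometry$n_rows, geometry$n_cols)
    if (!is.null(mask$extent)) {
      e <- mask$extent
      m <- m & LON >= e[1] & LON <= e[2] & LAT >= e[3] & LAT <= e[4]
    }
  } else { # grid
    if (!geometry_aligned(mask$grid$geometry, geometry))
      stop("grid mask is not aligned with the target geometry", call. = FALSE)
    m <- !is.na(mask$grid$values) & mask$grid$values != 0
  }
  dimnames(m) <- NULL
  m
}

#' Mask a grid, keeping or dropping the cells a region selects
#'
#' Cells outside (`mode = "keep"`) or inside (`mode = "drop"`) the mask
#' become nodata; the geometry is unchanged. An empty mask raises a warning
#' and returns an all-nodata (`keep`) or unchanged (`drop`) grid.
#'
#' @param grid a [geo_grid()].
#' @param mask a `region_mask` or list of them (intersection).
#' @param mode `"keep"` or `"drop"`.
#' @return a [geo_grid()].
#' @export
mask_grid <- function(grid, mask, mode = c("keep", "drop")) {
  mode <- match.arg(mode)
  m <- rasterize_mask(mask, grid$geometry)
  if (!any(m)) {
    warning("mask rasterizes to no cells on this geometry", call. = FALSE)
    if (mode == "drop") return(grid)
  }
  v <- grid$values
  if (mode == "keep") v[!m] <- NA_real_ else v[m] <- NA_real_
  geo_grid(v, grid$geometry, units = grid$units, name = grid$name)
}
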