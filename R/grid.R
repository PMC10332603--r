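#' Grid geometry for a north-up lat/lon raster
#'
#' Defines a rectangular grid of cells in geographic (longitude/latitude)
#' coordinates. The grid is north-up and values are registered at cell
#' centers. `west` and `north` are the *outer edges* of the top-left cell.
#' A cell owns the half-open footprint
#' `[west_edge, east_edge) x (south_edge, north_edge]`, so every point has a
#' unique owning cell (see [extract_at_point()]).
#'
#' @param n_rows,n_cols positive integers, grid dimensions.
#' @param west longitude of the left (west) edge, in `[-180, 180)`.
#' @param north latitude of the top (north) edge, in `(-90, 90]`.
#' @param cell_width,cell_height cell size in decimal degrees, `> 0`.
#' @return an object of class `grid_geometry`.
#' @export
grid_geometry <- function(n_rows, n_cols, west, north, cell_width, cell_height) {
  check_field <- function(ok, field, what) {
    if (!isTRUE(ok)) stop("invalid grid geometry: ", field, " ", what, call. = FALSE)
  }
  check_field(is.numeric(n_rows) && length(n_rows) == 1 && n_rows >= 1 &&
                n_rows == as.integer(n_rows), "n_rows", "must be a positive integer")
  check_field(is.numeric(n_cols) && length(n_cols) == 1 && n_cols >= 1 &&
                n_cols == as.integer(n_cols), "n_cols", "must be a positive integer")
  check_field(is.numeric(cell_width) && length(cell_width) == 1 && cell_width > 0,
              "cell_width", "must be > 0")
  check_field(is.numeric(cell_height) && length(cell_height) == 1 && cell_height > 0,
              "cell_height", "must be > 0")
  check_field(is.numeric(west) && length(west) == 1 && west >= -180 && west < 180,
              "west", "must lie in [-180, 180)")
  check_field(is.numeric(north) && length(north) == 1 && north > -90 && north <= 90,
              "north", "must lie in (-90, 90]")
  check_field(north - n_rows * cell_height >= -90 - 1e-9,
              "n_rows", "x cell_height extends below -90 latitude")
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         west = as.numeric(west), north = as.numeric(north),
         cell_width = as.numeric(cell_width), cell_height = as.numeric(cell_height)),
    class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("grid_geometry: %d x %d cells, %.6g x %.6g deg\n",
              x$n_rows, x$n_cols, x$cell_width, x$cell_height))
  cat(sprintf("  extent: lon [%.6g, %.6g], lat [%.6g, %.6g]\n",
              x$west, x$west + x$n_cols * x$cell_width,
              x$north - x$n_rows * x$cell_height, x$north))
  invisible(x)
}

#' Test whether two grid geometries are aligned (identical)
#' @param a,b `grid_geometry` objects.
#' @return logical.
#' @export
geometry_aligned <- function(a, b) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    isTRUE(all.equal(c(a$west, a$north, a$cell_width, a$cell_height),
                     c(b$west, b$north, b$cell_width, b$cell_height),
                     tolerance = 1e-12))
}

#' Cell-center coordinates of a grid geometry
#'
#' @param geometry a `grid_geometry`.
#' @return `lat_centers()` gives the `n_rows` center latitudes north to south;
#'   `lon_centers()` the `n_cols` center longitudes west to east.
#' @export
lat_centers <- function(geometry) {
  geometry$north - (seq_len(geometry$n_rows) - 0.5) * geometry$cell_height
}

#' @rdname lat_centers
#' @export
lon_centers <- function(geometry) {
  geometry$west + (seq_len(geometry$n_cols) - 0.5) * geometry$cell_width
}

#' Georeferenced grid of values
#'
#' The package's raster container: a numeric matrix (rows north to south,
#' columns west to east) plus a [grid_geometry()]. Missing cells ("nodata")
#' are `NA`. Every non-`NA` value must be finite; grids with `units =
#' "probability"` must be non-negative.
#'
#' @param values numeric matrix, `n_rows x n_cols`, `NA` = nodata.
#' @param geometry a `grid_geometry` matching `dim(values)`.
#' @param units free-text unit label, e.g. `"permil"`, `"probability"`,
#'   `"count"`, `"km"`.
#' @param name free-text layer name (e.g. an isoscape label).
#' @return an object of class `geo_grid`.
#' @export
geo_grid <- function(values, geometry, units = "", name = "") {
  stopifnot(inherits(geometry, "grid_geometry"))
  values <- as.matrix(values)
  if (!is.numeric(values) && !is.logical(values))
    stop("geo_grid values must be numeric", call. = FALSE)
  storage.mode(values) <- "double"
  if (nrow(values) != geometry$n_rows || ncol(values) != geometry$n_cols)
    stop(sprintf("values are %d x %d but geometry says %d x %d",
                 nrow(values), ncol(values), geometry$n_rows, geometry$n_cols),
         call. = FALSE)
  if (any(is.infinite(values)))
    stop("geo_grid values must be finite or NA", call. = FALSE)
  if (identical(units, "probability") && any(values < 0, na.rm = TRUE))
    stop("probability grids must be non-negative", call. = FALSE)
  structure(list(values = values, geometry = geometry,
                 units = units, name = name),
            class = "geo_grid")
}

#' @export
print.geo_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("geo_grid '%s' [%s]: %d x %d cells (%d nodata)\n",
              x$name, x$units, nrow(v), ncol(v), sum(is.na(v))))
  if (any(!is.na(v)))
    cat(sprintf("  range: [%.6g, %.6g]\n", min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  print(x$geometry)
  invisible(x)
}

# ---- plain-text grid I/O ----------------------------------------------------
# One-line header: n_rows n_cols west north cell_width cell_height nodata
# then n_rows whitespace-separated rows, north to south. The dialect is
# self-contained so fixtures need no binary format support.

#' Read / write the plain-text grid format
#'
#' The on-disk format is a single header line
#' `n_rows n_cols west north cell_width cell_height nodata` followed by the
#' value rows from north to south. Values equal to the `nodata` sentinel map
#' to `NA` in memory and back on write. Values are written with enough digits
#' that a read/write round trip reproduces geometry exactly and values to
#' double precision.
#'
#' @param path file path.
#' @param units,name labels attached to the grid on read (not stored on disk).
#' @return `read_grid()` returns a [geo_grid()]; `write_grid()` returns `path`
#'   invisibly.
#' @export
read_grid <- function(path, units = "", name = "") {
  if (!file.exists(path)) stop("grid file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1) stop("empty grid file: ", path, call. = FALSE)
  hdr_names <- c("n_rows", "n_cols", "west", "north",
                 "cell_width", "cell_height", "nodata")
  toks <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  if (length(toks) != 7)
    stop("malformed grid header: expected 7 fields (",
         paste(hdr_names, collapse = " "), "), got ", length(toks), call. = FALSE)
  hdr <- suppressWarnings(as.numeric(toks))
  bad <- which(is.na(hdr))
  if (length(bad))
    stop("malformed grid header: field ", hdr_names[bad[1]],
         " is not numeric ('", toks[bad[1]], "')", call. = FALSE)
  if (hdr[1] < 1 || hdr[1] != round(hdr[1]))
    stop("malformed grid header: field n_rows must be a positive integer (got ",
         toks[1], ")", call. = FALSE)
  if (hdr[2] < 1 || hdr[2] != round(hdr[2]))
    stop("malformed grid header: field n_cols must be a positive integer (got ",
         toks[2], ")", call. = FALSE)
  geometry <- grid_geometry(hdr[1], hdr[2], hdr[3], hdr[4], hdr[5], hdr[6])
  body <- lines[-1]
  if (length(body) != geometry$n_rows)
    stop(sprintf("grid body has %d rows, header says n_rows=%d",
                 length(body), geometry$n_rows), call. = FALSE)
  rows <- lapply(body, function(l) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
    if (length(v) != geometry$n_cols || anyNA(v))
      stop("malformed grid row (expected ", geometry$n_cols,
           " numeric values): '", substr(l, 1, 60), "'", call. = FALSE)
    v
  })
  values <- do.call(rbind, rows)
  values[values == hdr[7]] <- NA_real_
  geo_grid(values, geometry, units = units, name = name)
}

#' @rdname read_grid
#' @param grid a [geo_grid()] to write.
#' @param nodata numeric sentinel substituted for `NA` cells on disk.
#' @export
write_grid <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "geo_grid"))
  g <- grid$geometry
  v <- grid$values
  if (any(v == nodata, na.rm = TRUE))
    stop("grid contains the nodata sentinel ", nodata,
         " as a real value; choose another sentinel", call. = FALSE)
  v[is.na(v)] <- nodata
  num <- function(x) sprintf("%.17g", x)
  hdr <- paste(g$n_rows, g$n_cols, num(g$west), num(g$north),
               num(g$cell_width), num(g$cell_height), num(nodata))
  body <- apply(v, 1, function(r) paste(num(r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---- tile mosaicking --------------------------------------------------------

#' Mosaic grid tiles that share a common cell lattice
#'
#' Combines tiles (e.g. regional isoscape downloads) into the minimal bounding
#' grid. All tiles must have equal cell sizes and sit on a common lattice
#' (edges coincide up to `tol` cells). Cells covered by no tile are nodata;
#' cells covered by several tiles must agree within `value_tol`.
#'
#' @param tiles list of [geo_grid()] objects.
#' @param tol lattice alignment tolerance, in cells.
#' @param value_tol maximum allowed disagreement on overlapping cells.
#' @return a [geo_grid()]; order of `tiles` does not affect the result.
#' @export
combine_tiles <- function(tiles, tol = 1e-6, value_tol = 1e-6) {
  stopifnot(length(tiles) >= 1, all(vapply(tiles, inherits, TRUE, "geo_grid")))
  ref <- tiles[[1]]$geometry
  cw <- ref$cell_width; ch <- ref$cell_height
  for (t in tiles) {
    g <- t$geometry
    if (abs(g$cell_width - cw) > tol * cw || abs(g$cell_height - ch) > tol * ch)
      stop("tiles have different cell sizes", call. = FALSE)
    off_x <- (g$west - ref$west) / cw
    off_y <- (ref$north - g$north) / ch
    if (abs(off_x - round(off_x)) > tol || abs(off_y - round(off_y)) > tol)
      stop("tile lattices are misaligned (offset of a fractional cell)",
           call. = FALSE)
  }
  wests <- vapply(tiles, function(t) t$geometry$west, 0)
  norths <- vapply(tiles, function(t) t$geometry$north, 0)
  easts <- vapply(tiles, function(t) t$geometry$west +
                    t$geometry$n_cols * t$geometry$cell_width, 0)
  souths <- vapply(tiles, function(t) t$geometry$north -
                     t$geometry$n_rows * t$geometry$cell_height, 0)
  west <- min(wests); north <- max(norths)
  n_cols <- as.integer(round((max(easts) - west) / cw))
  n_rows <- as.integer(round((north - min(souths)) / ch))
  out <- matrix(NA_real_, n_rows, n_cols)
  for (t in tiles) {
    g <- t$geometry
    r0 <- as.integer(round((north - g$north) / ch))
    c0 <- as.integer(round((g$west - west) / cw))
    ri <- r0 + seq_len(g$n_rows)
    ci <- c0 + seq_len(g$n_cols)
    old <- out[ri, ci, drop = FALSE]
    new <- t$values
    both <- !is.na(old) & !is.na(new)
    if (any(both) && any(abs(old[both] - new[both]) > value_tol))
      stop("tiles disagree on overlapping cells (max difference ",
           format(max(abs(old[both] - new[both]))), ")", call. = FALSE)
    keep <- is.na(new) & !is.na(old)
    new[keep] <- old[keep]
    out[ri, ci] <- new
  }
  geo_grid(out, grid_geometry(n_rows, n_cols, west, north, cw, ch),
           units = tiles[[1]]$units, name = tiles[[1]]$name)
}

# ---- bilinear resampling ----------------------------------------------------

#' Resample a grid onto another geometry by bilinear interpolation
#'
#' Each target cell-center value is the bilinear interpolation of the four
#' surrounding source cell centers. Target centers falling outside the source
#' *center* lattice are nodata. The nodata policy is conservative: if any
#' source cell with non-zero interpolation weight is nodata, the target cell
#' is nodata (no partial-weight renormalization, so no values are invented
#' along coastlines). Resampling a grid onto its own geometry reproduces it.
#'
#' @param src a [geo_grid()].
#' @param target a [grid_geometry()] overlapping `src`.
#' @return a [geo_grid()] on `target`.
#' @export
resample_bilinear <- function(src, target) {
  stopifnot(inherits(src, "geo_grid"), inherits(target, "grid_geometry"))
  g <- src$geometry
  eps <- 1e-9
  # fractional row/col position of each target center in the source lattice
  fy <- (lat_centers(g)[1] - lat_centers(target)) / g$cell_height + 1
  fx <- (lon_centers(target) - lon_centers(g)[1]) / g$cell_width + 1
  snap <- function(f, n) {
    ok <- f >= 1 - eps & f <= n + eps
    i0 <- floor(f + eps)
    t <- f - i0
    t[t < eps] <- 0
    t[!ok] <- 0 # out-of-lattice targets become nodata; keep indices in range
    i0[i0 < 1] <- 1L
    i0[i0 > n] <- n
    # t > 0 with i0 == n cannot happen inside the ok range
    list(i0 = i0, t = t, ok = ok)
  }
  sy <- snap(fy, g$n_rows)
  sx <- snap(fx, g$n_cols)
  nI <- target$n_rows; nJ <- target$n_cols
  I0 <- matrix(sy$i0, nI, nJ); TT <- matrix(sy$t, nI, nJ)
  J0 <- matrix(sx$i0, nI, nJ, byrow = TRUE); SS <- matrix(sx$t, nI, nJ, byrow = TRUE)
  OK <- matrix(sy$ok, nI, nJ) & matrix(sx$ok, nI, nJ, byrow = TRUE)
  I1 <- I0 + (TT > 0); J1 <- J0 + (SS > 0)
  V <- src$values
  pick <- function(ri, ci) V[cbind(as.vector(ri), as.vector(ci))]
  v00 <- pick(I0, J0); v01 <- pick(I0, J1)
  v10 <- pick(I1, J0); v11 <- pick(I1, J1)
  t <- as.vector(TT); s <- as.vector(SS)
  w00 <- (1 - t) * (1 - s); w01 <- (1 - t) * s
  w10 <- t * (1 - s);       w11 <- t * s
  term <- function(w, v) ifelse(w > 0, w * v, 0)
  val <- term(w00, v00) + term(w01, v01) + term(w10, v10) + term(w11, v11)
  val[!as.vector(OK)] <- NA_real_
  out <- matrix(val, nI, nJ)
  if (!any(OK))
    stop("target geometry does not overlap the source grid", call. = FALSE)
  geo_grid(out, target, units = src$units, name = src$name)
}

# ---- point extraction -------------------------------------------------------

#' Locate points on a grid (vectorized)
#'
#' Maps lon/lat points to owning cells under the half-open footprint
#' convention: a cell owns `[west_edge, east_edge) x (south_edge, north_edge]`.
#' Points on the grid's east or south outer edge are out of bounds; points on
#' the west or north outer edge are in.
#'
#' @param geometry a [grid_geometry()].
#' @param lon,lat numeric vectors of equal length.
#' @return data.frame with columns `row`, `col` (NA when out of bounds) and
#'   `in_bounds`.
#' @export
locate_cells <- function(geometry, lon, lat) {
  stopifnot(length(lon) == length(lat))
  g <- geometry
  col <- floor((lon - g$west) / g$cell_width) + 1
  row <- floor((g$north - lat) / g$cell_height) + 1
  # north-edge inclusive: a point exactly on an interior horizontal edge
  # belongs to the cell below it, which floor() already gives; the global
  # north edge (lat == north) maps to row 0 + 1 = 1 only via the special case
  row[lat == g$north] <- 1L
  inb <- !is.na(lon) & !is.na(lat) &
    col >= 1 & col <= g$n_cols & row >= 1 & row <= g$n_rows
  row[!inb] <- NA_integer_; col[!inb] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col), in_bounds = inb)
}

#' Extract the grid value at a point
#'
#' Nearest-cell rule (no interpolation): returns the value of the cell whose
#' footprint contains the point. A point over a nodata cell returns `NA`; a
#' point outside the grid bounds raises an error of class
#' `isorigin_out_of_bounds` (a distinct signal, not nodata).
#'
#' @param grid a [geo_grid()].
#' @param lon,lat scalar coordinates in degrees.
#' @return the cell value (possibly `NA` for nodata).
#' @export
extract_at_point <- function(grid, lon, lat) {
  loc <- locate_cells(grid$geometry, lon, lat)
  if (!loc$in_bounds)
    stop(structure(class = c("isorigin_out_of_bounds", "error", "condition"),
                   list(message = sprintf("point (%g, %g) is outside the grid bounds",
                                          lon, lat),
                        call = sys.call(-1))))
  grid$values[loc$row, loc$col]
}

#' Apply a function to grid values, preserving geometry and nodata
#' @param grid a [geo_grid()].
#' @param f vectorized function applied to the value matrix.
#' @param units,name optional new labels.
#' @return a [geo_grid()].
#' @export
map_grid <- function(grid, f, units = grid$units, name = grid$name) {
  geo_grid(f(grid$values), grid$geometry, units = units, name = name)
}
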