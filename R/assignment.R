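# Likelihood-based assignment: per-cell normal densities with combined
# calibration + isoscape error, normalized to a probability-of-origin
# surface, and odds-ratio regions of likely origin.

#' Combined per-cell assignment error
#'
#' The expected SD of a cell combines calibration error (the transfer
#' function's residual SD) and isoscape error (the 1-SD uncertainty surface)
#' in quadrature. Because the calibration maps precipitation space into
#' feather space, the isoscape SD is scaled by `|slope|` before combination
#' (set `scale_by_slope = FALSE` for the unscaled variant):
#' `sigma_c = sqrt(sd_resid^2 + (slope * sigma_iso)^2)`.
#' With no uncertainty surface, `sigma_c` is constant at `sd_resid` (the
#' convention for isoscapes published without an error grid).
#'
#' @param model a [calibration_model()].
#' @param unc an uncertainty [geo_grid()] (1 SD, permil) or `NULL`.
#' @param geometry required when `unc` is `NULL`: the working geometry for
#'   the constant grid.
#' @param scale_by_slope scale the isoscape SD by `|slope|` (default).
#' @return a [geo_grid()] of per-cell SDs, permil.
#' @export
combined_sigma <- function(model, unc = NULL, geometry = NULL,
                           scale_by_slope = TRUE) {
  stopifnot(inherits(model, "calibration_model"))
  if (is.null(unc)) {
    if (is.null(geometry))
      stop("need a geometry when no uncertainty surface is given", call. = FALSE)
    v <- matrix(model$sd_resid, geometry$n_rows, geometry$n_cols)
    return(geo_grid(v, geometry, units = "permil", name = "sigma_c"))
  }
  stopifnot(inherits(unc, "geo_grid"))
  if (any(unc$values < 0, na.rm = TRUE))
    stop("uncertainty surface has negative values", call. = FALSE)
  k <- if (scale_by_slope) abs(model$slope) else 1
  map_grid(unc, function(v) sqrt(model$sd_resid^2 + (k * v)^2),
           units = "permil", name = "sigma_c")
}

#' Probability-of-origin surface for one individual
#'
#' Evaluates the normal density of the measured tissue value at each cell,
#' `dnorm(d2h_f, mean = mu_c, sd = sigma_c)` with `mu_c` the predicted
#' feather value, over the normalization domain (cells that are non-nodata
#' on both grids and inside all masks), then divides by the domain sum so
#' the surface sums to 1. Cells outside the domain are nodata.
#'
#' @param d2h_f measured tissue value, permil.
#' @param feather_grid predicted feather isoscape ([predict_feather_isoscape()]).
#' @param sigma_grid per-cell SDs ([combined_sigma()]), `> 0` on the domain.
#' @param mask optional `region_mask` (or list of masks, intersected)
#'   limiting the domain (continent, species range).
#' @param id individual identifier carried on the surface.
#' @return an object of class `probability_surface`: list with `grid` (a
#'   probability [geo_grid()]) and `id`.
#' @export
probability_surface <- function(d2h_f, feather_grid, sigma_grid, mask = NULL,
                                id = NULL) {
  stopifnot(inherits(feather_grid, "geo_grid"), inherits(sigma_grid, "geo_grid"))
  if (!geometry_aligned(feather_grid$geometry, sigma_grid$geometry))
    stop("feather and sigma grids are not aligned", call. = FALSE)
  mu <- feather_grid$values
  sig <- sigma_grid$values
  domain <- !is.na(mu) & !is.na(sig)
  if (!is.null(mask)) domain <- domain & rasterize_mask(mask, feather_grid$geometry)
  if (!any(domain)) stop("empty normalization domain", call. = FALSE)
  if (any(sig[domain] <= 0))
    stop("sigma must be > 0 on every domain cell", call. = FALSE)
  dens <- matrix(NA_real_, nrow(mu), ncol(mu))
  dens[domain] <- stats::dnorm(d2h_f, mean = mu[domain], sd = sig[domain])
  total <- sum(dens[domain])
  if (total == 0) { # numerically underflowed tails: fall back to log densities
    logd <- stats::dnorm(d2h_f, mean = mu[domain], sd = sig[domain], log = TRUE)
    logd <- logd - max(logd)
    dens[domain] <- exp(logd)
    total <- sum(dens[domain])
  }
  dens[domain] <- dens[domain] / total
  structure(list(grid = geo_grid(dens, feather_grid$geometry,
                                 units = "probability",
                                 name = if (is.null(id)) "p-origin"
                                        else paste0("p-origin-", id)),
                 id = id),
            class = "probability_surface")
}

#' @export
print.probability_surface <- function(x, ...) {
  cat("probability-of-origin surface",
      if (!is.null(x$id)) paste0(" for ", x$id), "\n", sep = "")
  print(x$grid)
  invisible(x)
}

#' Odds-ratio region of likely origin
#'
#' Selects the smallest set of highest-probability cells whose cumulative
#' probability reaches `odds_fraction` (2:1 odds = 2/3): cells are sorted by
#' probability descending, ties broken by row-major cell index, and the
#' minimal qualifying prefix forms the binary region.
#'
#' @param surface a [probability_surface()].
#' @param odds_fraction target cumulative mass in `(0, 1]`; also accepts an
#'   odds string like `"2:1"`.
#' @return an object of class `origin_region`: list with `binary` (logical
#'   matrix, `TRUE` = in region), `geometry`, `odds_fraction`,
#'   `achieved_mass`, `n_cells`, `domain_size` and `id`.
#' @export
odds_region <- function(surface, odds_fraction = 2 / 3) {
  stopifnot(inherits(surface, "probability_surface"))
  odds_fraction <- parse_odds(odds_fraction)
  p <- surface$grid$values
  g <- surface$grid$geometry
  domain <- which(!is.na(p))
  # row-major index for the documented tie order (R matrices are col-major)
  row <- ((domain - 1) %% g$n_rows) + 1
  col <- ((domain - 1) %/% g$n_rows) + 1
  rm_index <- (row - 1) * g$n_cols + col
  o <- order(-p[domain], rm_index)
  cum <- cumsum(p[domain][o])
  k <- if (odds_fraction == 1) length(o) # all domain cells, by definition
       else which(cum >= odds_fraction - 1e-12)[1]
  if (is.na(k)) k <- length(o) # guard against accumulated rounding
  binary <- matrix(FALSE, g$n_rows, g$n_cols)
  binary[domain[o[seq_len(k)]]] <- TRUE
  structure(list(binary = binary, geometry = g,
                 odds_fraction = odds_fraction,
                 achieved_mass = cum[k], n_cells = k,
                 domain_size = length(domain), id = surface$id),
            class = "origin_region")
}

#' @export
print.origin_region <- function(x, ...) {
  cat(sprintf(
    "origin region%s: %d of %d cells (precision %.3g), mass %.4f at odds fraction %.4f\n",
    if (!is.null(x$id)) paste0(" for ", x$id) else "",
    x$n_cells, x$domain_size, x$n_cells / x$domain_size,
    x$achieved_mass, x$odds_fraction))
  invisible(x)
}

#' Stack origin regions into a count grid
#'
#' @param regions list of aligned [odds_region()] results.
#' @return a [geo_grid()] of counts: how many regions include each cell.
#' @export
stack_regions <- function(regions) {
  stopifnot(length(regions) >= 1,
            all(vapply(regions, inherits, TRUE, "origin_region")))
  g <- regions[[1]]$geometry
  for (r in regions)
    if (!geometry_aligned(r$geometry, g))
      stop("regions have mismatched geometries", call. = FALSE)
  counts <- Reduce(`+`, lapply(regions, function(r) r$binary * 1))
  geo_grid(counts, g, units = "count", name = "assigned-individuals")
}

#' Great-circle distance between region centroids
#'
#' Centroid = the mean of the included cell centers taken on the unit sphere
#' and renormalized (avoids longitude-averaging artifacts); distance is
#' haversine with R = 6371 km.
#'
#' @param region_a,region_b non-empty [odds_region()] results.
#' @return distance in km.
#' @export
region_centroid_distance <- function(region_a, region_b) {
  cen <- function(r) {
    idx <- which(r$binary, arr.ind = TRUE)
    if (nrow(idx) == 0) stop("empty region", call. = FALSE)
    spherical_centroid(lon_centers(r$geometry)[idx[, 2]],
                       lat_centers(r$geometry)[idx[, 1]])
  }
  a <- cen(region_a); b <- cen(region_b)
  haversine_km(a["lon"], a["lat"], b["lon"], b["lat"])
}

#' Assign a cohort of unknown-origin individuals
#'
#' Runs [probability_surface()] then [odds_region()] for each individual and
#' stacks the resulting regions, the standard presentation of cohort
#' assignment results. An optional range mask (e.g. a species breeding
#' range) is applied to each surface before normalization.
#'
#' @param d2h_f numeric vector of measured tissue values, or a data.frame
#'   with columns `id` and `d2h_f`.
#' @param feather_grid,sigma_grid aligned working grids.
#' @param range_mask optional `region_mask` (or list).
#' @param odds odds fraction or `"a:b"` string.
#' @param ids individual labels (defaults to the data.frame `id` column or
#'   sequence numbers).
#' @return list with `regions` (per individual), `stack` (count
#'   [geo_grid()]) and `summary` (data.frame: id, d2h_f, n_cells,
#'   achieved_mass, precision).
#' @export
assign_cohort <- function(d2h_f, feather_grid, sigma_grid, range_mask = NULL,
                          odds = 2 / 3, ids = NULL) {
  if (is.data.frame(d2h_f)) {
    if (is.null(ids)) ids <- d2h_f$id
    d2h_f <- d2h_f$d2h_f
  }
  if (is.null(ids)) ids <- as.character(seq_along(d2h_f))
  odds <- parse_odds(odds)
  regions <- vector("list", length(d2h_f))
  for (i in seq_along(d2h_f)) {
    surf <- probability_surface(d2h_f[i], feather_grid, sigma_grid,
                                mask = range_mask, id = ids[i])
    regions[[i]] <- odds_region(surf, odds)
  }
  names(regions) <- ids
  summary <- data.frame(
    id = ids, d2h_f = d2h_f,
    n_cells = vapply(regions, function(r) r$n_cells, 0L),
    achieved_mass = vapply(regions, function(r) r$achieved_mass, 0),
    precision = vapply(regions, function(r) r$n_cells / r$domain_size, 0),
    stringsAsFactors = FALSE, row.names = NULL)
  list(regions = regions, stack = stack_regions(regions), summary = summary)
}
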