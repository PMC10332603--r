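# Split-half cross-validation of a calibration dataset x isoscape pairing:
# refit on a random half, assign the held-out half, and score accuracy
# (region contains the sampling cell), precision (region cells / domain
# cells) and minimum distance (km from an inaccurate bird's sampling point
# to the nearest region cell).

#' Random split-half of a record table
#'
#' Uniform random permutation; the first `ceiling(n / 2)` records form the
#' calibration subset, the rest the validation subset. Disjoint, exhaustive,
#' deterministic given the seed.
#'
#' @param records data.frame with at least 6 rows.
#' @param seed integer seed.
#' @return list with elements `cal` and `val`.
#' @export
split_half <- function(records, seed) {
  n <- nrow(records)
  if (n < 6) stop("need at least 6 records to split, got ", n, call. = FALSE)
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  n_cal <- ceiling(n / 2)
  list(cal = records[perm[seq_len(n_cal)], , drop = FALSE],
       val = records[perm[-seq_len(n_cal)], , drop = FALSE])
}

#' Score one region against a known-origin record
#'
#' `accurate` is whether the binary region includes the cell containing the
#' sampling point; `precision` is the fraction of the working domain's cells
#' the region occupies (smaller = more precise). A sampling point outside
#' the region's domain (masked or nodata cell) yields `accurate = NA`, the
#' signal to skip the record.
#'
#' @param region an [odds_region()].
#' @param lon,lat the record's sampling location, degrees.
#' @return list with `accurate` (logical or NA) and `precision`.
#' @export
region_metrics <- function(region, lon, lat) {
  loc <- locate_cells(region$geometry, lon, lat)
  precision <- region$n_cells / region$domain_size
  if (!loc$in_bounds)
    return(list(accurate = NA, precision = precision))
  list(accurate = region$binary[loc$row, loc$col], precision = precision)
}

#' Minimum distance from a point to a region
#'
#' The minimum over included cells of the great-circle distance (haversine,
#' R = 6371 km) from the sampling point to the cell center. For a point
#' inside the region the nearest included cell is its own, so the distance is
#' 0; cross-validation summaries use this only for inaccurate birds.
#'
#' @param region a non-empty [odds_region()].
#' @param lon,lat point coordinates, degrees.
#' @return distance in km.
#' @export
min_distance_km <- function(region, lon, lat) {
  idx <- which(region$binary, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty region", call. = FALSE)
  min(haversine_km(lon, lat,
                   lon_centers(region$geometry)[idx[, 2]],
                   lat_centers(region$geometry)[idx[, 1]]))
}

#' Repeated split-half cross-validation of a calibration
#'
#' For each iteration `i` (seeded `base_seed + i`): split the records in
#' half, fit the calibration on one half, convert the isoscape to predicted
#' feather space, and assign every validation bird (normal-density surface
#' with the fitted residual SD combined with any isoscape uncertainty,
#' masked to `mask`, odds-ratio region). Iteration summaries: accuracy over
#' validation birds, mean precision over validation birds, and mean minimum
#' distance over *inaccurate* birds only (an all-birds variant, zeros
#' included, is available via `min_dist_all_birds`). Records are expected to
#' be pre-filtered (outliers and excluded sites already removed).
#'
#' A degenerate calibration half (all `d2h_p` equal) is re-drawn with a
#' logged replacement seed so the iteration count stays fixed. Validation
#' birds whose sampling point falls on a masked or nodata working cell are
#' dropped with a logged id rather than counted inaccurate.
#'
#' @param records data.frame with `id`, `lon`, `lat`, `d2h_f`.
#' @param mean_grid precipitation isoscape [geo_grid()] (pre-masked to the
#'   working region, or supply `mask`).
#' @param unc_grid optional aligned uncertainty [geo_grid()] (1 SD); `NULL`
#'   reduces the per-cell SD to the calibration error alone.
#' @param iterations number of split-half repetitions (default 25).
#' @param odds odds fraction or `"a:b"` string (default 2:1 = 2/3).
#' @param base_seed integer; iteration `i` uses seed `base_seed + i`.
#' @param mask optional `region_mask` (or list) limiting the working domain.
#' @param scale_by_slope passed to [combined_sigma()].
#' @param min_dist_all_birds average minimum distance over all validation
#'   birds (inaccurate birds' distances plus zeros) instead of inaccurate
#'   birds only.
#' @return data.frame of class `validation_result`, one row per iteration
#'   (`iteration, seed, n_cal, n_val, accuracy, mean_precision,
#'   mean_min_distance_km, intercept, slope, sd_resid, r2_adj`), with
#'   attributes `grand` (mean and SD across iterations), `dropped_ids` and
#'   `replacement_seeds`.
#' @export
cross_validate <- function(records, mean_grid, unc_grid = NULL,
                           iterations = 25, odds = 2 / 3, base_seed = 1,
                           mask = NULL, scale_by_slope = TRUE,
                           min_dist_all_birds = FALSE) {
  stopifnot(inherits(mean_grid, "geo_grid"))
  odds <- parse_odds(odds)
  work <- if (is.null(mask)) mean_grid else mask_grid(mean_grid, mask, "keep")
  pairs_all <- pair_with_isoscape(records, work)
  dropped <- attr(pairs_all, "excluded_ids")
  usable <- pairs_all[!pairs_all$excluded, , drop = FALSE]
  rows <- vector("list", iterations)
  repl_seeds <- list()
  for (i in seq_len(iterations)) {
    seed <- as.integer(base_seed) + i
    halves <- split_half(usable, seed)
    tries <- 0
    while (stats::var(halves$cal$d2h_p) == 0 && tries < 100) {
      tries <- tries + 1
      new_seed <- as.integer(base_seed) + iterations + 1000L * i + tries
      repl_seeds[[length(repl_seeds) + 1]] <-
        c(iteration = i, seed = new_seed)
      halves <- split_half(usable, new_seed)
      seed <- new_seed
    }
    model <- fit_calibration(halves$cal)
    feather <- predict_feather_isoscape(work, model)
    sigma <- combined_sigma(model, unc = unc_grid,
                            geometry = work$geometry,
                            scale_by_slope = scale_by_slope)
    val <- halves$val
    accurate <- logical(0); precision <- numeric(0); min_d <- numeric(0)
    for (j in seq_len(nrow(val))) {
      surf <- probability_surface(val$d2h_f[j], feather, sigma, mask = NULL,
                                  id = val$id[j])
      reg <- odds_region(surf, odds)
      m <- region_metrics(reg, val$lon[j], val$lat[j])
      if (is.na(m$accurate)) next # masked/nodata sampling cell: skip
      accurate <- c(accurate, m$accurate)
      precision <- c(precision, m$precision)
      if (!m$accurate) min_d <- c(min_d, min_distance_km(reg, val$lon[j], val$lat[j]))
    }
    mean_min <- if (min_dist_all_birds) {
      if (length(accurate)) sum(min_d) / length(accurate) else NA_real_
    } else if (length(min_d)) mean(min_d) else NA_real_
    rows[[i]] <- data.frame(
      iteration = i, seed = seed,
      n_cal = nrow(halves$cal), n_val = length(accurate),
      accuracy = mean(accurate),
      mean_precision = mean(precision),
      mean_min_distance_km = mean_min,
      intercept = model$intercept, slope = model$slope,
      sd_resid = model$sd_resid, r2_adj = model$r2_adj)
  }
  out <- do.call(rbind, rows)
  grand <- list(
    mean_accuracy = mean(out$accuracy),
    sd_accuracy = stats::sd(out$accuracy),
    mean_precision = mean(out$mean_precision),
    sd_precision = stats::sd(out$mean_precision),
    mean_min_distance_km = mean(out$mean_min_distance_km, na.rm = TRUE),
    sd_min_distance_km = stats::sd(out$mean_min_distance_km, na.rm = TRUE))
  structure(out, grand = grand, dropped_ids = dropped,
            replacement_seeds = repl_seeds,
            class = c("validation_result", "data.frame"))
}

#' Write a cross-validation result as CSV
#'
#' One row per iteration plus a final grand-summary row (iteration label
#' `"grand"` with the across-iteration means). Deterministic inputs produce
#' byte-identical files.
#'
#' @param result a [cross_validate()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_validation_csv <- function(result, path) {
  df <- as.data.frame(result)
  grand <- attr(result, "grand")
  grand_row <- df[1, ]
  grand_row[] <- NA
  grand_row$iteration <- "grand"
  grand_row$accuracy <- grand$mean_accuracy
  grand_row$mean_precision <- grand$mean_precision
  grand_row$mean_min_distance_km <- grand$mean_min_distance_km
  df$iteration <- as.character(df$iteration)
  utils::write.csv(rbind(df, grand_row), path, row.names = FALSE)
  invisible(path)
}
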