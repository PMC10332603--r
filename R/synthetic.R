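# Synthetic world: a smooth latitudinal precipitation-delta2H gradient with
# optional spatially smoothed noise and an uncertainty surface, plus
# site-clustered known-origin cohorts generated under the linear calibration
# model the downstream analysis assumes. Everything is seed-deterministic and
# carries enough truth metadata (true site delta2H_p, contamination flags)
# for recovery checks.

#' Synthetic isoscape configuration
#'
#' Describes a synthetic precipitation-isotope world: a linear north-south
#' gradient in cell-center latitude plus optional iid Gaussian noise smoothed
#' by a box filter, and a 1-SD uncertainty surface.
#'
#' Defaults describe a continental window (100 x 100 cells of 0.5 degrees,
#' latitudes 10-60 N) with the gradient running from -160 permil in the north
#' to -20 permil in the south, 6 permil of local noise smoothed over a
#' 2-cell radius, and a constant 8 permil uncertainty surface.
#'
#' @param geometry a [grid_geometry()].
#' @param value_at_north,value_at_south gradient endpoints, permil, attained
#'   at the top and bottom cell-center latitudes.
#' @param spatial_noise_sd SD (permil) of iid cell noise added before
#'   smoothing; 0 disables noise.
#' @param smoothing_radius box-filter radius in cells (0 = no smoothing).
#'   Smoothing shrinks the marginal SD of the noise field.
#' @param isoscape_sd_level uncertainty surface level, permil: a scalar for a
#'   constant surface, or length 2 `c(north, south)` for a latitude-linear one.
#' @param seed integer seed; all randomness flows from it.
#' @return an object of class `world_config`.
#' @export
world_config <- function(geometry = grid_geometry(100, 100, -130, 60, 0.5, 0.5),
                         value_at_north = -160, value_at_south = -20,
                         spatial_noise_sd = 6, smoothing_radius = 2,
                         isoscape_sd_level = 8, seed = 1) {
  stopifnot(inherits(geometry, "grid_geometry"),
            spatial_noise_sd >= 0, smoothing_radius >= 0,
            all(isoscape_sd_level >= 0),
            length(isoscape_sd_level) %in% c(1, 2))
  structure(list(geometry = geometry,
                 value_at_north = value_at_north,
                 value_at_south = value_at_south,
                 spatial_noise_sd = spatial_noise_sd,
                 smoothing_radius = as.integer(smoothing_radius),
                 isoscape_sd_level = isoscape_sd_level,
                 seed = as.integer(seed)),
            class = "world_config")
}

#' Synthetic known-origin cohort configuration
#'
#' Birds are clustered at sites drawn uniformly (without replacement) over
#' the non-nodata isoscape cells; each bird's feather value follows
#' `d2h_f = a + b * d2h_p(site) + site_effect + individual_noise`, with an
#' optional one-sided contamination shift on a random fraction of birds
#' (emulating, e.g., evaporative enrichment at some sites).
#'
#' Default truth is the recommended combined-dabbler transfer function
#' (intercept -69.9 permil, slope 0.7) with a 15 permil residual SD.
#'
#' @param n_sites number of sites.
#' @param birds_per_site scalar or per-site vector of cohort sizes.
#' @param true_intercept,true_slope calibration truth (permil, unitless).
#' @param residual_sd individual residual SD, permil, `> 0` (0 allowed for
#'   noise-free limits).
#' @param site_effect_sd SD of a shared per-site Gaussian shift, permil.
#' @param outlier_fraction probability that a bird is contaminated, `[0, 1)`.
#' @param outlier_shift contamination shift, permil (positive by default:
#'   evaporatively enriched, i.e. less negative, feather values).
#' @param dabbler_fraction probability a bird is labelled `"dabbler"` (others
#'   `"diver"`).
#' @param seed integer seed.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_sites = 200, birds_per_site = 5,
                          true_intercept = -69.9, true_slope = 0.7,
                          residual_sd = 15, site_effect_sd = 0,
                          outlier_fraction = 0, outlier_shift = 60,
                          dabbler_fraction = 1, seed = 1) {
  stopifnot(n_sites >= 1, all(birds_per_site >= 1),
            residual_sd >= 0, site_effect_sd >= 0,
            outlier_fraction >= 0, outlier_fraction < 1,
            dabbler_fraction >= 0, dabbler_fraction <= 1)
  structure(list(n_sites = as.integer(n_sites),
                 birds_per_site = as.integer(birds_per_site),
                 true_intercept = true_intercept, true_slope = true_slope,
                 residual_sd = residual_sd, site_effect_sd = site_effect_sd,
                 outlier_fraction = outlier_fraction,
                 outlier_shift = outlier_shift,
                 dabbler_fraction = dabbler_fraction,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# edge-truncated box filter (moving average over a (2r+1)^2 window)
box_smooth <- function(m, radius) {
  if (radius == 0) return(m)
  n <- nrow(m); p <- ncol(m)
  smooth_1d <- function(x, r) {
    k <- length(x)
    cs <- cumsum(c(0, x))
    lo <- pmax(seq_len(k) - r, 1); hi <- pmin(seq_len(k) + r, k)
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  m <- apply(m, 2, smooth_1d, r = radius)
  t(apply(m, 1, smooth_1d, r = radius))
}

#' Generate a synthetic isoscape and its uncertainty surface
#'
#' The mean grid is the linear latitudinal gradient between
#' `value_at_north` (top-row cell centers) and `value_at_south` (bottom-row
#' cell centers), plus smoothed Gaussian noise. The uncertainty surface is
#' constant or latitude-linear. Deterministic given the config seed.
#'
#' @param config a [world_config()].
#' @return list with elements `mean` and `sd`, both [geo_grid()]s (`sd` is
#'   the 1-SD uncertainty surface, aligned with `mean`).
#' @export
make_synthetic_isoscape <- function(config) {
  stopifnot(inherits(config, "world_config"))
  g <- config$geometry
  latc <- lat_centers(g)
  if (g$n_rows > 1) {
    frac <- (latc[1] - latc) / (latc[1] - latc[g$n_rows])
  } else frac <- 0
  gradient <- config$value_at_north +
    frac * (config$value_at_south - config$value_at_north)
  base <- matrix(gradient, g$n_rows, g$n_cols)
  if (config$spatial_noise_sd > 0) {
    noise <- withr::with_seed(config$seed,
      matrix(stats::rnorm(g$n_rows * g$n_cols, 0, config$spatial_noise_sd),
             g$n_rows, g$n_cols))
    base <- base + box_smooth(noise, config$smoothing_radius)
  }
  lvl <- config$isoscape_sd_level
  sdv <- if (length(lvl) == 1) matrix(lvl, g$n_rows, g$n_cols)
         else matrix(lvl[1] + frac * (lvl[2] - lvl[1]), g$n_rows, g$n_cols)
  list(mean = geo_grid(base, g, units = "permil", name = "synthetic-d2h_p"),
       sd = geo_grid(sdv, g, units = "permil", name = "synthetic-d2h_p-sd"))
}

#' Simulate a known-origin cohort on an isoscape
#'
#' Sites are drawn uniformly without replacement over the non-nodata cells of
#' `isoscape`; each record carries its site's true isoscape value
#' (`truth_d2h_p`) and a contamination flag (`is_outlier`) so truth-based
#' checks never need re-derivation. Deterministic given the cohort seed.
#'
#' @param cohort a [cohort_config()].
#' @param isoscape a [geo_grid()] of precipitation delta-2H.
#' @return data.frame with columns
#'   `id, dataset, species, guild, age, site_id, lon, lat, d2h_f,
#'   truth_d2h_p, is_outlier`.
#' @export
simulate_known_origin <- function(cohort, isoscape) {
  stopifnot(inherits(cohort, "cohort_config"), inherits(isoscape, "geo_grid"))
  g <- isoscape$geometry
  open_cells <- which(!is.na(isoscape$values))
  if (length(open_cells) < cohort$n_sites)
    stop(sprintf("n_sites = %d exceeds the %d non-nodata isoscape cells",
                 cohort$n_sites, length(open_cells)), call. = FALSE)
  per_site <- rep_len(cohort$birds_per_site, cohort$n_sites)
  withr::with_seed(cohort$seed, {
    cells <- sample(open_cells, cohort$n_sites)
    site_eff <- stats::rnorm(cohort$n_sites, 0, cohort$site_effect_sd)
    n_birds <- sum(per_site)
    noise <- stats::rnorm(n_birds, 0, cohort$residual_sd)
    contaminated <- stats::runif(n_birds) < cohort$outlier_fraction
    guild <- ifelse(stats::runif(n_birds) < cohort$dabbler_fraction,
                    "dabbler", "diver")
  })
  row <- ((cells - 1) %% g$n_rows) + 1
  col <- ((cells - 1) %/% g$n_rows) + 1
  site_p <- isoscape$values[cbind(row, col)]
  site_idx <- rep(seq_len(cohort$n_sites), per_site)
  d2h_f <- cohort$true_intercept + cohort$true_slope * site_p[site_idx] +
    site_eff[site_idx] + noise +
    ifelse(contaminated, cohort$outlier_shift, 0)
  data.frame(
    id = sprintf("bird-%04d", seq_len(sum(per_site))),
    dataset = "synthetic",
    species = "synthetic-duck",
    guild = guild,
    age = "HY",
    site_id = sprintf("site-%03d", site_idx),
    lon = lon_centers(g)[col][site_idx],
    lat = lat_centers(g)[row][site_idx],
    d2h_f = d2h_f,
    truth_d2h_p = site_p[site_idx],
    is_outlier = contaminated,
    stringsAsFactors = FALSE)
}

#' Generate-and-refit recovery experiment
#'
#' Runs the full synthetic pipeline — isoscape generation, cohort simulation,
#' pairing records with the isoscape, calibration fit — and reports recovered
#' versus true parameters.
#'
#' @param world a [world_config()].
#' @param cohort a [cohort_config()].
#' @return list with the fitted [fit_calibration()] model, the truth, the
#'   errors `intercept_error` / `slope_error`, their standard errors, and
#'   `sd_resid_error` (estimated minus generative residual SD).
#' @export
recovery_experiment <- function(world, cohort) {
  iso <- make_synthetic_isoscape(world)
  records <- simulate_known_origin(cohort, iso$mean)
  pairs <- pair_with_isoscape(records, iso$mean)
  model <- fit_calibration(pairs)
  list(model = model,
       truth = c(intercept = cohort$true_intercept,
                 slope = cohort$true_slope,
                 residual_sd = cohort$residual_sd),
       intercept_error = model$intercept - cohort$true_intercept,
       slope_error = model$slope - cohort$true_slope,
       intercept_se = model$se_intercept,
       slope_se = model$se_slope,
       sd_resid_error = model$sd_resid - cohort$residual_sd,
       n = model$n)
}

#' Read / write known-origin record tables
#'
#' CSV with the documented header
#' `id,dataset,species,guild,age,site_id,lon,lat,d2h_f` plus the optional
#' truth columns `truth_d2h_p,is_outlier` written by the simulator.
#' `read_records()` validates the schema and reports offending lines.
#'
#' @param records data.frame of records.
#' @param path CSV path.
#' @return `read_records()` returns the validated data.frame.
#' @export
write_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("records file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "site_id", "lon", "lat", "d2h_f")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("records file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (col in c("lon", "lat", "d2h_f")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop("non-numeric ", col, " in records file at data line(s): ",
           paste(utils::head(bad + 1, 5), collapse = ", "), call. = FALSE)
    if (anyNA(v))
      stop("missing ", col, " in records file at data line(s): ",
           paste(utils::head(which(is.na(v)) + 1, 5), collapse = ", "),
           call. = FALSE)
    df[[col]] <- v
  }
  if (any(df$lat < -90 | df$lat > 90))
    stop("latitude outside [-90, 90] in records file", call. = FALSE)
  df
}
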