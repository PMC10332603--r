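# Calibration of tissue delta2H against precipitation delta2H: site-wise
# Tukey-fence outlier screening, pairing of records with isoscape values,
# ordinary least squares transfer functions, and conversion of isoscapes to
# predicted feather space.

#' Flag per-site outliers with Tukey fences
#'
#' Within each site, records with `d2h_f` above `Q3 + 1.5 * IQR` or below
#' `Q1 - 1.5 * IQR` are flagged, with quartiles computed on that site's
#' values by linear-interpolation sample quantiles (R's default type 7).
#' The pass runs once — fences are computed on the full site, not re-derived
#' after removals. Sites on `exclude_sites` (e.g. a site known to be
#' hydrologically compromised) are flagged wholesale with reason
#' `"site-excluded"` instead of the fence rule.
#'
#' Single-valued sites have `IQR = 0` with fences at the value itself, so
#' nothing is flagged there; the flagging is permutation-invariant within a
#' site.
#'
#' @param records data.frame with at least `site_id` and `d2h_f`.
#' @param exclude_sites character vector of site ids excluded wholesale.
#' @return data.frame with columns `id` (if present), `site_id`, `flagged`
#'   (logical) and `reason` (`NA`, `"outlier"` or `"site-excluded"`), one row
#'   per record in input order.
#' @export
flag_site_outliers <- function(records, exclude_sites = character()) {
  stopifnot(all(c("site_id", "d2h_f") %in% names(records)))
  flagged <- logical(nrow(records))
  reason <- rep(NA_character_, nrow(records))
  site_excl <- records$site_id %in% exclude_sites
  flagged[site_excl] <- TRUE
  reason[site_excl] <- "site-excluded"
  for (s in unique(records$site_id[!site_excl])) {
    idx <- which(records$site_id == s & !site_excl)
    q <- stats::quantile(records$d2h_f[idx], c(0.25, 0.75),
                         type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    out <- records$d2h_f[idx] > q[2] + 1.5 * iqr |
           records$d2h_f[idx] < q[1] - 1.5 * iqr
    flagged[idx[out]] <- TRUE
    reason[idx[out]] <- "outlier"
  }
  out <- data.frame(site_id = records$site_id, flagged = flagged,
                    reason = reason, stringsAsFactors = FALSE)
  if (!is.null(records$id)) out <- cbind(id = records$id, out)
  out
}

#' Pair known-origin records with isoscape values
#'
#' Extracts the isoscape value under each record's sampling location
#' (nearest-cell rule, [extract_at_point()]). Records over nodata cells or
#' outside the grid are excluded with reason `"no-isoscape-overlap"`.
#' When several isoscapes are supplied, non-overlap with *any* of them
#' excludes the record from all pairings (global exclusion), matching the
#' usual practice of analyzing a common record set across isoscapes.
#'
#' @param records data.frame with `lon`, `lat`, `d2h_f` (and ideally `id`,
#'   `site_id`).
#' @param grids a [geo_grid()] or a named list of them.
#' @return For a single grid, a data.frame of pairs with columns from
#'   `records` plus `d2h_p`, `excluded`, `reason`; for a list, a named list
#'   of such data.frames. The attribute `"excluded_ids"` lists the ids (or
#'   row numbers) excluded for non-overlap.
#' @export
pair_with_isoscape <- function(records, grids) {
  single <- inherits(grids, "geo_grid")
  if (single) grids <- list(grids)
  stopifnot(length(grids) >= 1, all(vapply(grids, inherits, TRUE, "geo_grid")))
  ids <- if (!is.null(records$id)) records$id else as.character(seq_len(nrow(records)))
  values <- lapply(grids, function(g) {
    loc <- locate_cells(g$geometry, records$lon, records$lat)
    v <- rep(NA_real_, nrow(records))
    v[loc$in_bounds] <- g$values[cbind(loc$row[loc$in_bounds],
                                       loc$col[loc$in_bounds])]
    v
  })
  no_overlap <- Reduce(`|`, lapply(values, is.na))
  excluded_ids <- ids[no_overlap]
  if (length(excluded_ids))
    message("excluding ", length(excluded_ids),
            " record(s) with no isoscape overlap: ",
            paste(utils::head(excluded_ids, 10), collapse = ", "),
            if (length(excluded_ids) > 10) ", ..." else "")
  build <- function(v) {
    pairs <- records
    pairs$d2h_p <- v
    pairs$excluded <- no_overlap
    pairs$reason <- ifelse(no_overlap, "no-isoscape-overlap", NA_character_)
    attr(pairs, "excluded_ids") <- excluded_ids
    pairs
  }
  out <- lapply(values, build)
  if (single) out[[1]] else out
}

#' Fit a linear calibration (transfer function)
#'
#' Ordinary least squares of tissue `d2h_f` on precipitation `d2h_p`.
#' The residual scatter is summarized as `sd_resid`, the sample standard
#' deviation of the residuals (divisor `n - 1`); this is the error term
#' carried into assignment. Model fit is the adjusted r-squared.
#'
#' @param pairs data.frame with `d2h_p`, `d2h_f` and optionally `excluded`
#'   (excluded rows are dropped), as produced by [pair_with_isoscape()];
#'   alternatively pass numeric vectors via `d2h_p` / `d2h_f`.
#' @param d2h_p,d2h_f numeric vectors, used when `pairs` is `NULL`.
#' @param dataset,isoscape labels stored on the model.
#' @return an object of class `calibration_model` with fields `intercept`,
#'   `slope`, `sd_resid`, `r2_adj`, `n`, `se_intercept`, `se_slope`,
#'   `dataset`, `isoscape`.
#' @export
fit_calibration <- function(pairs = NULL, d2h_p = NULL, d2h_f = NULL,
                            dataset = "", isoscape = "") {
  if (!is.null(pairs)) {
    keep <- if (!is.null(pairs$excluded)) !pairs$excluded else TRUE
    d2h_p <- pairs$d2h_p[keep]
    d2h_f <- pairs$d2h_f[keep]
  }
  stopifnot(length(d2h_p) == length(d2h_f))
  ok <- !is.na(d2h_p) & !is.na(d2h_f)
  x <- d2h_p[ok]; y <- d2h_f[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 calibration pairs, got ", n, call. = FALSE)
  if (stats::var(x) == 0)
    stop("degenerate predictor: all d2h_p values are equal", call. = FALSE)
  fit <- stats::lm(y ~ x)
  coefs <- stats::coef(fit)
  sm <- suppressWarnings(summary(fit)) # perfect fits are legal here
  r2 <- sm$r.squared
  calibration_model(
    intercept = unname(coefs[1]), slope = unname(coefs[2]),
    sd_resid = stats::sd(stats::residuals(fit)),
    r2_adj = 1 - (1 - r2) * (n - 1) / (n - 2),
    n = n,
    se_intercept = sm$coefficients[1, 2],
    se_slope = sm$coefficients[2, 2],
    dataset = dataset, isoscape = isoscape)
}

#' Construct a calibration model from known coefficients
#'
#' Use this to apply a published transfer function (e.g. an equation from the
#' literature) without refitting.
#'
#' @param intercept,slope calibration coefficients (permil, unitless).
#' @param sd_resid residual SD, permil, `>= 0`.
#' @param r2_adj,n,se_intercept,se_slope optional fit statistics.
#' @param dataset,isoscape labels.
#' @return an object of class `calibration_model`.
#' @export
calibration_model <- function(intercept, slope, sd_resid, r2_adj = NA_real_,
                              n = NA_integer_, se_intercept = NA_real_,
                              se_slope = NA_real_, dataset = "", isoscape = "") {
  stopifnot(is.numeric(intercept), is.numeric(slope), sd_resid >= 0)
  structure(list(intercept = intercept, slope = slope, sd_resid = sd_resid,
                 r2_adj = r2_adj, n = n, se_intercept = se_intercept,
                 se_slope = se_slope, dataset = dataset, isoscape = isoscape),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("calibration: d2h_f = %.4g + %.4g * d2h_p\n", x$intercept, x$slope))
  cat(sprintf("  sd_resid = %.4g permil, adj r2 = %.3g, n = %s\n",
              x$sd_resid, x$r2_adj, format(x$n)))
  if (nzchar(x$dataset) || nzchar(x$isoscape))
    cat(sprintf("  dataset: %s, isoscape: %s\n", x$dataset, x$isoscape))
  invisible(x)
}

#' Convert an isoscape to predicted tissue (feather) space
#'
#' Applies the calibration cellwise: `intercept + slope * value`. Nodata is
#' preserved and the result is labelled as feather-space.
#'
#' @param grid a [geo_grid()] of precipitation delta-2H, permil.
#' @param model a `calibration_model`.
#' @return a [geo_grid()] of predicted tissue delta-2H.
#' @export
predict_feather_isoscape <- function(grid, model) {
  stopifnot(inherits(grid, "geo_grid"), inherits(model, "calibration_model"))
  map_grid(grid, function(v) model$intercept + model$slope * v,
           units = "permil",
           name = paste0(if (nzchar(grid$name)) paste0(grid$name, "-") else "",
                         "predicted-d2h_f"))
}

#' Calibration table across datasets and isoscapes
#'
#' Convenience wrapper reproducing the usual summary table shape: one row per
#' dataset x isoscape pairing with the fitted coefficients and fit
#' statistics. Outlier flagging (site-wise Tukey fences plus wholesale site
#' exclusions) and non-overlap exclusion are applied before fitting, both
#' computed once on the full record set.
#'
#' @param records data.frame of known-origin records (needs `site_id`,
#'   `d2h_f`, `lon`, `lat` and ideally `dataset`).
#' @param grids named list of [geo_grid()] isoscapes.
#' @param exclude_sites sites excluded wholesale.
#' @param by_dataset split records by their `dataset` column (default) or
#'   fit one pooled calibration per isoscape.
#' @return data.frame with columns `source`, `isoscape`, `intercept`,
#'   `slope`, `n`, `sd_resid`, `r2_adj`; the attribute `"flags"` carries the
#'   outlier report.
#' @export
calibration_table <- function(records, grids, exclude_sites = character(),
                              by_dataset = TRUE) {
  if (inherits(grids, "geo_grid")) grids <- list(isoscape = grids)
  if (is.null(names(grids)) || any(!nzchar(names(grids))))
    names(grids) <- paste0("isoscape", seq_along(grids))
  flags <- flag_site_outliers(records, exclude_sites)
  kept <- records[!flags$flagged, , drop = FALSE]
  pairings <- pair_with_isoscape(kept, grids)
  datasets <- if (by_dataset && !is.null(kept$dataset))
    unique(kept$dataset) else "all"
  rows <- list()
  for (iso in names(grids)) {
    pairs <- pairings[[iso]]
    for (ds in datasets) {
      sub <- if (identical(ds, "all")) pairs
             else pairs[pairs$dataset == ds, , drop = FALSE]
      m <- fit_calibration(sub, dataset = ds, isoscape = iso)
      rows[[length(rows) + 1]] <- data.frame(
        source = ds, isoscape = iso, intercept = m$intercept,
        slope = m$slope, n = m$n, sd_resid = m$sd_resid,
        r2_adj = m$r2_adj, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "flags") <- flags
  out
}
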