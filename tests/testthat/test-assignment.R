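# combined error, probability-of-origin surfaces, odds-ratio regions,
# stacking, centroid distances

test_that("combined sigma follows the quadrature rule", {
  geom <- grid_geometry(3, 3, 0, 3, 1, 1)
  # no uncertainty surface: constant calibration error
  m <- calibration_model(-31.6, 0.93, 12.8)
  s <- combined_sigma(m, geometry = geom)
  expect_true(all(s$values == 12.8))

  unc5 <- make_grid(matrix(5, 3, 3))
  s2 <- combined_sigma(calibration_model(0, 1, 0), unc5)
  expect_true(all(s2$values == 5))

  # 3-4-5: sd_resid 3, slope 0.5, sigma_iso 8 -> sqrt(9 + 16) = 5
  unc8 <- make_grid(matrix(8, 3, 3))
  s3 <- combined_sigma(calibration_model(0, 0.5, 3), unc8)
  expect_true(all(abs(s3$values - 5) < 1e-12))
  # unscaled variant ignores the slope
  s4 <- combined_sigma(calibration_model(0, 0.5, 3), unc8,
                       scale_by_slope = FALSE)
  expect_true(all(abs(s4$values - sqrt(9 + 64)) < 1e-12))
  # sigma_c >= sd_resid everywhere, equality at zero isoscape error
  expect_true(all(s3$values >= 3))
  s0 <- combined_sigma(calibration_model(0, 0.5, 3), make_grid(matrix(0, 3, 3)))
  expect_true(all(s0$values == 3))

  neg <- make_grid(matrix(-1, 3, 3))
  expect_error(combined_sigma(m, neg), "negative")
})

test_that("probability surfaces are normalized normal densities", {
  # constant mu and sigma over K cells: uniform 1/K
  u <- toy_surface(matrix(-100, 4, 5))
  expect_true(all(abs(u$grid$values - 1 / 20) < 1e-15))

  # 3-cell derived example: mu (-80, -100, -120), sigma 10, value -100
  s <- toy_surface(matrix(c(-80, -100, -120), 1, 3), sigma = 10, d2h_f = -100)
  dens <- dnorm(-100, c(-80, -100, -120), 10) # independent hand computation
  expect_equal(as.vector(s$grid$values), dens / sum(dens), tolerance = 1e-12)
  expect_equal(as.vector(s$grid$values), c(0.1065, 0.7870, 0.1065),
               tolerance = 1e-3)

  # masked cells are excluded from the domain and get no probability
  feather <- make_grid(matrix(-100, 4, 6), west = -20, north = 4)
  sigma <- make_grid(matrix(10, 4, 6), west = -20, north = 4)
  west_half <- extent_mask(-20, -17, 0, 4)
  ps <- probability_surface(-100, feather, sigma, mask = west_half)
  expect_true(all(is.na(ps$grid$values[, 4:6])))
  expect_equal(sum(ps$grid$values, na.rm = TRUE), 1, tolerance = 1e-12)

  expect_error(probability_surface(-100, feather, sigma,
                                   mask = extent_mask(50, 60, 0, 4)),
               "empty")
  sigma0 <- make_grid(matrix(0, 4, 6), west = -20, north = 4)
  expect_error(probability_surface(-100, feather, sigma0), "> 0")
})

test_that("surfaces sum to 1 and ignore any positive density scaling", {
  for (seed in 1:25) {
    g <- random_grid(9, 11, seed = seed, mu = -110, sd = 25)
    sig <- make_grid(matrix(withr::with_seed(seed + 100, runif(1, 4, 20)),
                            9, 11))
    d2h <- withr::with_seed(seed + 200, rnorm(1, -110, 30))
    s <- probability_surface(d2h, g, sig)
    expect_lt(abs(sum(s$grid$values) - 1), 1e-9)
    expect_true(all(s$grid$values >= 0))
    # oracle: normalizing unnormalized kernels (any positive scaling) agrees
    kern <- exp(-(d2h - g$values)^2 / (2 * sig$values[1, 1]^2)) * 7.3
    expect_equal(as.vector(s$grid$values), as.vector(kern / sum(kern)),
                 tolerance = 1e-9)
  }
  # extreme tissue values far in the tails still normalize (log fallback)
  far <- probability_surface(500, make_grid(matrix(c(-100, -180), 1, 2)),
                             make_grid(matrix(5, 1, 2)))
  expect_lt(abs(sum(far$grid$values) - 1), 1e-9)
})

test_that("odds regions take the minimal top-probability prefix", {
  # uniform over 10 cells at 2:1 odds: ceiling(20/3) = 7 cells, mass 0.7
  u <- toy_surface(matrix(-100, 2, 5))
  r <- odds_region(u, 2 / 3)
  expect_equal(r$n_cells, 7L)
  expect_equal(r$achieved_mass, 0.7, tolerance = 1e-12)
  # uniform ties resolve by row-major order: first 7 cells of row order
  expect_true(all(r$binary[1, ]))
  expect_identical(as.vector(t(r$binary)), c(rep(TRUE, 7), rep(FALSE, 3)))

  # the 3-cell surface: center cell alone carries 0.787 >= 2/3
  s <- toy_surface(matrix(c(-80, -100, -120), 1, 3), sigma = 10, d2h_f = -100)
  r3 <- odds_region(s, 2 / 3)
  expect_identical(as.vector(r3$binary), c(FALSE, TRUE, FALSE))
  expect_equal(r3$achieved_mass, 0.787, tolerance = 1e-3)

  # odds 1 includes every domain cell; bad odds error
  rall <- odds_region(u, 1)
  expect_equal(rall$n_cells, rall$domain_size)
  expect_error(odds_region(u, 0), "odds")
  expect_error(odds_region(u, 1.2), "odds")
  expect_equal(odds_region(u, "2:1")$n_cells, 7L)
})

test_that("odds regions are minimal, monotone in odds, and match exhaustive search", {
  for (seed in 1:40) {
    nc <- withr::with_seed(seed, sample(6:12, 1))
    s <- toy_surface(matrix(withr::with_seed(seed, rnorm(nc, -100, 30)), 1, nc),
                     sigma = withr::with_seed(seed + 1, runif(1, 5, 25)))
    f <- withr::with_seed(seed + 2, runif(1, 0.3, 0.95))
    r <- odds_region(s, f)
    p <- as.vector(s$grid$values)
    # mass reached, and dropping the smallest included cell loses it
    expect_gte(r$achieved_mass + 1e-12, f)
    expect_lt(r$achieved_mass - min(p[as.vector(r$binary)]), f)
    # exhaustive oracle: smallest subset cardinality reaching the mass
    best <- Inf
    for (bits in 0:(2^nc - 1)) {
      sel <- as.logical(intToBits(bits)[1:nc])
      if (sum(p[sel]) >= f - 1e-12) best <- min(best, sum(sel))
    }
    expect_equal(r$n_cells, best)
    # nesting: a larger odds fraction only adds cells
    r2 <- odds_region(s, min(1, f + 0.2))
    expect_true(all(r2$binary[r$binary]))
  }
})

test_that("inflating sigma flattens the surface", {
  g <- random_grid(8, 8, seed = 5, mu = -110, sd = 25)
  peaks <- vapply(c(1, 2, 4, 8), function(k) {
    sig <- make_grid(matrix(10 * k, 8, 8))
    max(probability_surface(-100, g, sig)$grid$values)
  }, 0)
  expect_true(all(diff(peaks) <= 1e-12))
})

test_that("stacking counts region membership per cell", {
  s <- toy_surface(matrix(c(-80, -100, -120, -140), 1, 4),
                   sigma = 8, d2h_f = -100)
  r <- odds_region(s, 2 / 3)
  expect_equal(stack_regions(list(r))$values, r$binary * 1)
  s2 <- toy_surface(matrix(c(-80, -100, -120, -140), 1, 4),
                    sigma = 8, d2h_f = -140)
  r2 <- odds_region(s2, 0.5)
  stk <- stack_regions(list(r, r2))
  expect_equal(stk$values, r$binary + r2$binary)
  expect_identical(stk$units, "count")
  many <- stack_regions(rep(list(r), 5))
  expect_true(all(many$values %in% c(0, 5)))
  r_alien <- odds_region(toy_surface(matrix(-100, 2, 2)), 0.5)
  expect_error(stack_regions(list(r, r_alien)), "mismatch")
})

test_that("centroid distances use spherical means and haversine", {
  mk_region <- function(binary, west, north, cell = 1) {
    g <- grid_geometry(nrow(binary), ncol(binary), west, north, cell, cell)
    structure(list(binary = binary, geometry = g, odds_fraction = 0.5,
                   achieved_mass = 1, n_cells = sum(binary),
                   domain_size = length(binary), id = NULL),
              class = "origin_region")
  }
  a <- mk_region(matrix(TRUE, 1, 1), west = -0.5, north = 0.5) # center (0, 0)
  b <- mk_region(matrix(TRUE, 1, 1), west = 0.5, north = 0.5)  # center (1, 0)
  expect_equal(region_centroid_distance(a, a), 0)
  expect_equal(region_centroid_distance(a, b), 111.19, tolerance = 1e-4)
  # centroid of a region symmetric about the 0 meridian lies on it:
  # equidistant from mirrored targets
  sym <- mk_region(matrix(TRUE, 1, 3), west = -1.5, north = 10.5) # centers -1,0,1
  east <- mk_region(matrix(TRUE, 1, 1), west = 4.5, north = 20.5)
  west <- mk_region(matrix(TRUE, 1, 1), west = -5.5, north = 20.5)
  expect_equal(region_centroid_distance(sym, east),
               region_centroid_distance(sym, west), tolerance = 1e-9)
  empty <- mk_region(matrix(FALSE, 1, 1), 0, 1)
  expect_error(region_centroid_distance(empty, a), "empty")
})

test_that("assign_cohort runs surface -> region per bird and stacks", {
  iso <- make_synthetic_isoscape(small_world(seed = 4))
  model <- calibration_model(-69.9, 0.7, 12)
  feather <- predict_feather_isoscape(iso$mean, model)
  sigma <- combined_sigma(model, geometry = feather$geometry)

  one <- assign_cohort(-130, feather, sigma)
  expect_equal(one$stack$values, one$regions[[1]]$binary * 1)
  expect_equal(one$summary$achieved_mass, one$regions[[1]]$achieved_mass)

  two <- assign_cohort(c(a = -130, b = -130), feather, sigma,
                       ids = c("a", "b"))
  expect_identical(two$regions$a$binary, two$regions$b$binary)
  expect_true(all(two$stack$values %in% c(0, 2)))

  # a +-6.8 permil measurement shift moves the region a finite distance
  base <- assign_cohort(-130, feather, sigma)$regions[[1]]
  up <- assign_cohort(-130 + 6.8, feather, sigma)$regions[[1]]
  dn <- assign_cohort(-130 - 6.8, feather, sigma)$regions[[1]]
  d_up <- region_centroid_distance(base, up)
  d_dn <- region_centroid_distance(base, dn)
  expect_gt(d_up, 0); expect_gt(d_dn, 0)
  expect_lt(d_up, 2000); expect_lt(d_dn, 2000)

  # range mask limits the domain before normalization
  rng <- extent_mask(-100, -95, 35, 55)
  masked <- assign_cohort(-130, feather, sigma, range_mask = rng)
  expect_true(all(is.na(masked$regions[[1]]$binary[
    matrix(lon_centers(feather$geometry), 20, 20, byrow = TRUE) > -95]) |
    !masked$regions[[1]]$binary[
      matrix(lon_centers(feather$geometry), 20, 20, byrow = TRUE) > -95]))
  expect_lt(masked$regions[[1]]$domain_size, length(feather$values))
})
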