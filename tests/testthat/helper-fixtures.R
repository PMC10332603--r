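# Small in-code fixtures shared across test files.

# grid with explicit values; geometry defaults to 1-degree cells with the
# north-west corner at (west, north)
make_grid <- function(values, west = 0, north = nrow(as.matrix(values)),
                      cell = 1, units = "permil", name = "fixture") {
  values <- as.matrix(values)
  geo_grid(values,
           grid_geometry(nrow(values), ncol(values), west, north, cell, cell),
           units = units, name = name)
}

# n_rows x n_cols grid of iid N(mu, sd) values, seed-deterministic
random_grid <- function(n_rows, n_cols, seed, mu = -100, sd = 30, ...) {
  vals <- withr::with_seed(seed,
    matrix(rnorm(n_rows * n_cols, mu, sd), n_rows, n_cols))
  make_grid(vals, ...)
}

# a probability surface over a small working grid for one tissue value
toy_surface <- function(mu_values, sigma = 10, d2h_f = -100, ...) {
  feather <- make_grid(mu_values, ...)
  sig <- make_grid(matrix(sigma, nrow(feather$values), ncol(feather$values)), ...)
  probability_surface(d2h_f, feather, sig)
}

# small synthetic world used where the full 100x100 default would be slow
small_world <- function(seed = 1, noise = 0, radius = 0)
  world_config(geometry = grid_geometry(20, 20, -100, 55, 1, 1),
               spatial_noise_sd = noise, smoothing_radius = radius,
               seed = seed)
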