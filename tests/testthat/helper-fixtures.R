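# shared fixture builders; everything is generated in code at test time

make_series <- function(values, parameter = "temperature", regular = TRUE) {
  sensor_series(parameter, seq_along(values) - 1, values, regular = regular)
}

# sum of Gaussians on the canonical grid
gaussian_profile <- function(mu, sigma, amp = rep(1, length(mu)),
                             n = 1501L, t_max = 20) {
  tm <- chrom_grid(n, t_max)
  y <- rep(0, n)
  for (j in seq_along(mu)) {
    y <- y + amp[j] * exp(-(tm - mu[j])^2 / (2 * sigma[j]^2))
  }
  list(time = tm, values = y)
}

# a point-event peak set: each peak occupies one grid cell only; with
# sigma = delta/4 the n = 1 tolerance (sigma + sigma') = delta/2 never
# reaches a neighbouring cell
point_peaks <- function(cells, n_grid = 1501L, t_max = 20,
                        source = "test") {
  dt <- t_max / (n_grid - 1)
  peak_set(location = (cells - 1) * dt, sigma = rep(dt / 4, length(cells)),
           n_grid = n_grid, delta_t = dt, source = source)
}

write_sensor_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(c("timestamp,value", lines), f)
  f
}

# the 12 well-separated test peak cells used by the MCC anchor checks
anchor_test_cells <- function(n_grid = 1501L, j = 12L) {
  round(seq(80, n_grid - 80, length.out = j))
}
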