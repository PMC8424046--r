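test_that("williams_r follows the trailing-window formula", {
  s <- make_series(c(1, 2, 3, 4))
  w <- williams_r(s, 2)
  expect_equal(w$values, c(0.5, 0, 0, 0)) # x_t is the window max from t=2
  s <- make_series(c(4, 3, 2, 1))
  expect_equal(williams_r(s, 2)$values, c(0.5, 1, 1, 1))
  expect_equal(williams_r(make_series(rep(3, 6)), 3)$values, rep(0.5, 6))
})

test_that("stochastic oscillator %K and %D behave as stated", {
  s <- make_series(c(1, 2, 3, 4, 5))
  k <- stochastic_oscillator(s, 2, return_k = TRUE)
  expect_equal(k$values, c(0.5, 1, 1, 1, 1))
  d <- stochastic_oscillator(s, 2, d = 2)
  expect_equal(d$values, c(0.5, 0.75, 1, 1, 1))
  expect_equal(stochastic_oscillator(make_series(rep(2, 5)), 3, 2)$values,
               rep(0.5, 5))
})

test_that("williams_r and %K are complements on non-flat windows", {
  set.seed(31)
  s <- make_series(cumsum(rnorm(500)))
  for (k in c(3, 20, 77)) {
    w <- williams_r(s, k)$values
    kk <- stochastic_oscillator(s, k, return_k = TRUE)$values
    expect_equal(w + kk, rep(1, 500), tolerance = 1e-12)
  }
})

test_that("indicators are invariant to positive affine input transforms", {
  set.seed(32)
  x <- cumsum(rnorm(300))
  a <- williams_r(make_series(x), 25)$values
  b <- williams_r(make_series(3.7 * x + 11), 25)$values
  expect_equal(a, b, tolerance = 1e-9)
  ka <- stochastic_oscillator(make_series(x), 25, return_k = TRUE)$values
  kb <- stochastic_oscillator(make_series(0.2 * x - 5), 25, return_k = TRUE)$values
  expect_equal(ka, kb, tolerance = 1e-9)
})

test_that("missing cells poison every window that touches them", {
  v <- c(1, 2, NA, 4, 5, 6, 7)
  s <- structure(list(parameter = "temperature", time = 0:6, values = v,
                      missing = is.na(v), origin = NULL, regular = TRUE),
                 class = "sensor_series")
  w <- williams_r(s, 3)$values
  expect_true(all(is.na(w[3:5])))
  expect_false(anyNA(w[c(1, 2, 6, 7)]))
})

test_that("paa_resample averages near-equal segments", {
  x <- runif(256)
  p <- paa_resample(x, 128)
  expect_equal(p, colMeans(matrix(x, 2)))
  expect_equal(paa_resample(rep(0.5, 1000), 128), rep(0.5, 128))
  expect_error(paa_resample(runif(100), 128), "shorter")

  # month-long series: segments of 337 or 338 minutes (~6 h per pixel)
  n <- 43200
  sizes <- diff(c(0, floor(seq_len(128) * (n / 128) + 1e-9)))
  expect_true(all(sizes %in% c(337L, 338L)))
  expect_equal(sum(sizes), n)
})

test_that("paa_resample is the identity when n equals m", {
  x <- runif(128)
  expect_equal(paa_resample(x, 128), x)
})

test_that("gasf and gadf match their closed forms", {
  g <- gasf(c(1, 0))
  expect_equal(g$matrix, rbind(c(1, 0), c(0, -1)), tolerance = 1e-12)
  expect_equal(gadf(c(1, 0))$matrix, rbind(c(0, -1), c(1, 0)), tolerance = 1e-12)
  expect_equal(gasf(rep(1, 5))$matrix, matrix(1, 5, 5))

  set.seed(33)
  for (i in 1:50) {
    v <- runif(128)
    A <- gasf(v)$matrix
    expect_equal(A, outer(v, v) - outer(sqrt(1 - v^2), sqrt(1 - v^2)),
                 tolerance = 1e-12)
    expect_equal(A, t(A))                        # symmetric
    expect_equal(diag(A), 2 * v^2 - 1, tolerance = 1e-12)
    D <- gadf(v)$matrix
    expect_equal(D, outer(sqrt(1 - v^2), v) - outer(v, sqrt(1 - v^2)),
                 tolerance = 1e-12)
    expect_equal(D + t(D), matrix(0, 128, 128))  # antisymmetric
    expect_true(all(abs(A) <= 1 + 1e-12) && all(abs(D) <= 1 + 1e-12))
  }
  expect_error(gasf(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("NA pixels become zeros in the image", {
  v <- c(0.2, NA, 0.8)
  m <- gasf(v)$matrix
  expect_equal(m[2, ], rep(0, 3))
  expect_equal(m[, 2], rep(0, 3))
  expect_false(anyNA(m))
})

test_that("augment emits one image per retained grid combination", {
  set.seed(34)
  s <- make_series(runif(1500))
  a <- augment(s, indicators = "stochastic_D", k_grid = c(5, 20, 30, 60, 90, 120, 240, 480),
               d_grid = c(30, 60, 90), m = 128)
  expect_length(a, 24L)
  a <- augment(s, indicators = "williams_r", k_grid = c(5, 20, 30, 60, 90, 120, 240, 480),
               d_grid = c(30, 60, 90), m = 128)
  expect_length(a, 8L) # d grid ignored
  a <- augment(s, indicators = "stochastic_D", k_grid = 30, d_grid = 60, m = 128)
  expect_length(a, 1L)
  expect_error(augment(s, k_grid = numeric(0)), "empty")
  expect_warning(augment(s, indicators = "williams_r", k_grid = c(5, 1400),
                         d_grid = 30, warn_kmax = TRUE), "ceiling")
})

test_that("assemble_input lays out channels in the fixed order", {
  consts <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  imgs <- Map(function(p, v) gasf(rep(v, 8), parameter = p,
                                  config = list(indicator = "williams_r", k = 5, d = NA)),
              chromcast:::SENSOR_PARAMETERS, consts)
  # shuffle: assemble must reorder to the canonical channel order
  t5 <- assemble_input(unname(imgs[c(3, 1, 5, 2, 4)]), "stacked_5d")
  expect_equal(dim(t5), c(8, 8, 5))
  for (i in 1:5) expect_equal(t5[, , i], imgs[[i]]$matrix)
  t1 <- assemble_input(unname(imgs), "concat_1d")
  expect_equal(dim(t1), c(40, 8, 1))
  expect_equal(t1[9:16, , 1], imgs[[2]]$matrix)

  expect_error(assemble_input(unname(imgs[1:4]), "stacked_5d"), "5 images")
  bad <- imgs
  bad[[2]] <- gasf(rep(0.3, 8), parameter = "humidity",
                   config = list(indicator = "williams_r", k = 99, d = NA))
  expect_error(assemble_input(unname(bad), "stacked_5d"), "mismatched")
})
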