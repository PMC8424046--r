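test_that("gen_environment produces the stated channel structure", {
  env <- gen_environment(days = 3, seed = 5, missing_rate = 0)
  expect_length(env, 5L)
  expect_equal(vapply(env, function(s) s$parameter, character(1)),
               chromcast:::SENSOR_PARAMETERS)
  expect_false(any(vapply(env, function(s) any(s$missing), logical(1))))

  env2 <- gen_environment(days = 3, seed = 5, missing_rate = 0)
  expect_identical(env, env2) # seeded determinism

  # diurnal periodicity: temperature autocorrelation at lag 1440 min
  temp <- env[[1L]]$values
  n <- length(temp)
  ac <- cor(temp[1:(n - 1440)], temp[1441:n])
  expect_gt(ac, 0.5)

  hum <- env[[2L]]$values
  expect_true(all(hum >= 0 & hum <= 100))
  expect_lt(cor(temp, hum), 0) # anti-phase with temperature
  expect_true(all(env[[3L]]$values >= 0))
  expect_true(all(env[[5L]]$values >= 4 & env[[5L]]$values <= 9))
})

test_that("outage masking hits the requested rate with seeded placement", {
  env <- gen_environment(days = 5, seed = 6, missing_rate = 0.1)
  rates <- vapply(env, function(s) mean(s$missing), numeric(1))
  expect_true(all(rates >= 0.08 & rates <= 0.25))
  g <- detect_gaps(env[[1L]])
  expect_true(all(g[, 2L] - g[, 1L] >= 1))
})

test_that("the amplitude map is zero for a null truth and monotone in W.z", {
  truth <- synthetic_truth(n_grid = 501, noise_sd = 0, rt_jitter_sd = 0,
                           replicate_cv = 0,
                           baseline = list(b0 = 0, b1 = 0, b2 = 0,
                                           period = 13, phase = 0))
  null_truth <- truth
  null_truth$W[] <- 0
  null_truth$w0 <- rep(-40, nrow(truth$peaks)) # softplus(-40) ~ 0
  env <- gen_environment(days = 2, seed = 7, missing_rate = 0)
  ch <- gen_chromatogram(env, null_truth, "E1", seed = 1)
  expect_lt(max(abs(ch$absorbance)), 1e-12)

  z <- env_features(env)
  a1 <- amplitudes_for(truth, z)
  a2 <- amplitudes_for(truth, 2 * z)
  drive <- as.numeric(truth$W %*% z)
  expect_true(all((a2 > a1) == (drive > 0)))
  expect_true(all(a1 >= 0))
})

test_that("noiseless chromatograms return the truth peak table", {
  truth <- synthetic_truth(noise_sd = 0, rt_jitter_sd = 0, replicate_cv = 0,
                           baseline = list(b0 = 0, b1 = 0, b2 = 0,
                                           period = 13, phase = 0))
  env <- gen_environment(days = 2, seed = 8, missing_rate = 0)
  ch <- gen_chromatogram(env, truth, "E1", seed = 2)
  expect_true(all(ch$absorbance >= 0))
  pk <- detect_peaks(ch$absorbance, prominence = 0.02, time = ch$time)
  expect_length(pk$location, nrow(truth$peaks))
  expect_true(all(abs(pk$location - truth$peaks$mu) <= 20 / 1500 + 1e-9))
  expect_true(all(abs(pk$sigma - truth$peaks$sigma) / truth$peaks$sigma <= 0.1))

  # unit area after the concentration transform
  p <- to_concentration(ch)
  expect_lt(abs(sum(p$values) - 1), 1e-9)
})

test_that("gen_dataset has the full factorial cardinality and is reproducible", {
  truth <- synthetic_truth(n_grid = 301)
  ds <- gen_dataset(10, truth = truth, seed = 3, days = 2, replicates = 6,
                    missing_rate = 0)
  expect_length(ds$chromatograms, 10L * 3L * 6L)
  ds2 <- gen_dataset(10, truth = truth, seed = 3, days = 2, replicates = 6,
                     missing_rate = 0)
  expect_identical(ds, ds2)
  solv <- vapply(ds$chromatograms, function(ch) ch$meta$solvent, character(1))
  expect_equal(unname(table(solv)[c("E1", "E2", "E3")]),
               rep(60L, 3L), ignore_attr = TRUE)
})

test_that("detected amplitudes track the hidden weight map across plants", {
  truth <- synthetic_truth(noise_sd = 0, rt_jitter_sd = 0, replicate_cv = 0,
                           baseline = list(b0 = 0, b1 = 0, b2 = 0,
                                           period = 13, phase = 0))
  heights <- NULL
  expected <- NULL
  for (p in 1:8) {
    env <- gen_environment(days = 2, seed = 100 + p, missing_rate = 0)
    z <- env_features(env)
    ch <- gen_chromatogram(env, truth, "E1", seed = p)
    pk <- detect_peaks(ch$absorbance, prominence = 0.01, time = ch$time)
    # heights at the known locations
    h <- vapply(truth$peaks$mu, function(mu) {
      i <- which.min(abs(pk$location - mu))
      pk$height[i]
    }, numeric(1))
    heights <- rbind(heights, h)
    expected <- rbind(expected, amplitudes_for(truth, z))
  }
  # per-peak correlation across plants between hidden and detected amplitude
  cors <- vapply(seq_len(ncol(heights)), function(j) {
    cor(heights[, j], expected[, j])
  }, numeric(1))
  expect_gt(median(cors), 0.95)
})

test_that("build_training_pairs assembles aligned tensors and targets", {
  truth <- synthetic_truth(n_grid = 301)
  ds <- gen_dataset(3, truth = truth, seed = 9, days = 2,
                    solvents = c("E1", "E2"), replicates = 2,
                    missing_rate = 0.03)
  pairs <- suppressWarnings(
    build_training_pairs(ds, indicators = "williams_r", k_grid = c(30, 240),
                         layout = "stacked_5d", imputed = TRUE, seed = 4))
  expect_s3_class(pairs, "pair_dataset")
  expect_equal(dim(pairs$tensors), c(128, 128, 5, 6)) # 3 plants x 2 combos
  expect_equal(ncol(pairs$targets), 12L)              # x 2 solvents
  expect_equal(nrow(pairs$targets), 301L)
  expect_false(anyNA(pairs$tensors))
  # every pair points at a tensor of its own plant
  tensor_plant <- rep(vapply(ds$plants, `[[`, character(1), "id"), each = 2)
  expect_equal(tensor_plant[pairs$pair_tensor], pairs$plant)

  # non-imputed pairs carry zeroed pixels instead of NAs
  pairs_n <- suppressWarnings(
    build_training_pairs(ds, indicators = "williams_r", k_grid = c(30, 240),
                         layout = "stacked_5d", imputed = FALSE, seed = 4))
  expect_false(anyNA(pairs_n$tensors))
  expect_gt(mean(pairs_n$tensors == 0), mean(pairs$tensors == 0))
})
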