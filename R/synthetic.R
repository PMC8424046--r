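#' Ground truth for the synthetic paired dataset
#'
#' The generator's hidden state: a table of Gaussian peaks (retention time
#' `mu`, width `sigma`), per-solvent multiplicative amplitude factors, and
#' the weight matrix mapping standardized environment summary features
#' (per-channel mean and standard deviation) to peak amplitudes through a
#' softplus link. The default table ships with the package so results are
#' stable across installations; pass `seed` to draw a fresh random truth
#' with the same structure.
#'
#' @param n_grid chromatogram grid size, default 1501 (0-20 min).
#' @param seed if not `NULL`, draw a random truth instead of the packaged one.
#' @param noise_sd additive detector noise, absorbance units.
#' @param rt_jitter_sd per-chromatogram retention-time shift (run-to-run
#'   drift), minutes.
#' @param replicate_cv coefficient of variation of the multiplicative
#'   log-normal replicate noise on peak amplitudes.
#' @param baseline coefficients of the drift added to every chromatogram:
#'   `b0 + b1 t + b2 sin(2 pi t / period + phase)`.
#' @return an object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(n_grid = 1501L, seed = NULL, noise_sd = 0.01,
                            rt_jitter_sd = 0.15, replicate_cv = 0.05,
                            baseline = list(b0 = 0.05, b1 = 0.015, b2 = 0.15,
                                            period = 13, phase = 0.7)) {
  if (is.null(seed)) {
    path <- system.file("extdata", "synthetic_truth.csv", package = "chromcast")
    tab <- read.csv(path, check.names = FALSE)
  } else {
    tab <- with_seed(seed, {
      J <- 12L
      mu <- 1.5 + (0:(J - 1L)) * (17 / 11) + runif(J, -0.3, 0.3)
      data.frame(peak = 1:J, mu = mu, sigma = runif(J, 0.08, 0.20),
                 f_E1 = 1, f_E2 = runif(J, 0.5, 1), f_E3 = runif(J, 0.3, 0.9),
                 w0 = runif(J, 0.2, 1.4),
                 matrix(rnorm(J * 10L, sd = 0.35), J, 10L,
                        dimnames = list(NULL, paste0("w_", feature_names()))),
                 check.names = FALSE)
    })
  }
  W <- as.matrix(tab[, paste0("w_", feature_names())])
  structure(list(peaks = tab[, c("peak", "mu", "sigma")],
                 solvent_factors = as.matrix(tab[, c("f_E1", "f_E2", "f_E3")]),
                 w0 = tab$w0, W = W,
                 n_grid = as.integer(n_grid), t_max = 20,
                 noise_sd = noise_sd, rt_jitter_sd = rt_jitter_sd,
                 replicate_cv = replicate_cv, baseline = baseline),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d peaks on %d points, noise sd %.3g, RT jitter %.2f min\n",
              nrow(x$peaks), x$n_grid, x$noise_sd, x$rt_jitter_sd))
  invisible(x)
}

feature_names <- function() {
  as.vector(t(outer(SENSOR_PARAMETERS, c("mean", "sd"), paste, sep = "_")))
}

# standardization constants for the summary features; chosen once to match
# the generator's typical channel statistics so z is roughly unit scale
FEATURE_CENTER <- c(temperature_mean = 25, temperature_sd = 3.5,
                    humidity_mean = 70, humidity_sd = 7,
                    light_mean = 12000, light_sd = 15000,
                    soil_moisture_mean = 0.4, soil_moisture_sd = 0.08,
                    soil_ph_mean = 6.5, soil_ph_sd = 0.08)
FEATURE_SCALE <- c(temperature_mean = 2, temperature_sd = 1,
                   humidity_mean = 5, humidity_sd = 3,
                   light_mean = 4000, light_sd = 5000,
                   soil_moisture_mean = 0.12, soil_moisture_sd = 0.04,
                   soil_ph_mean = 0.6, soil_ph_sd = 0.05)

#' Standardized environment summary features
#'
#' Per-channel mean and standard deviation of the five fully observed
#' sensor channels, standardized by fixed package constants.
#'
#' @param env list of five fully observed [sensor_series()] (canonical
#'   channel order not required; channels are matched by parameter).
#' @return named numeric vector of 10 features.
#' @export
env_features <- function(env) {
  params <- vapply(env, function(s) s$parameter, character(1))
  if (!setequal(params, SENSOR_PARAMETERS)) {
    stop_chromcast("env must hold the 5 sensor parameters exactly")
  }
  env <- env[match(SENSOR_PARAMETERS, params)]
  raw <- unlist(lapply(env, function(s) {
    if (any(s$missing)) stop_chromcast("channel '%s' has missing minutes; impute first", s$parameter)
    c(mean(s$values), sd(s$values))
  }))
  names(raw) <- feature_names()
  (raw - FEATURE_CENTER[names(raw)]) / FEATURE_SCALE[names(raw)]
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' Peak amplitudes implied by a feature vector
#'
#' `a_j = softplus(w0_j + W_j . z) * solvent_factor_j`.
#'
#' @param truth a [synthetic_truth()].
#' @param z standardized feature vector from [env_features()].
#' @param solvent `"E1"`, `"E2"` or `"E3"`.
#' @export
amplitudes_for <- function(truth, z, solvent = "E1") {
  solvent <- match.arg(solvent, c("E1", "E2", "E3"))
  fac <- truth$solvent_factors[, paste0("f_", solvent)]
  as.numeric(softplus(truth$w0 + truth$W %*% z) * fac)
}

ar1 <- function(n, phi, innov_sd) {
  as.numeric(stats::filter(rnorm(n, 0, innov_sd), phi, method = "recursive"))
}

#' Generate a month of synthetic greenhouse sensor channels
#'
#' Per-minute channels with the structure of a tropical greenhouse record:
#' temperature as a diurnal sinusoid plus AR(1) weather noise, relative
#' humidity in anti-phase (clipped to \[0, 100\]), light as a half-rectified
#' diurnal arc modulated by slow cloud noise, soil moisture as a daily
#' watering sawtooth with exponential decay, and soil pH as a slow random
#' walk clipped to \[4, 9\]. Missing blocks (logger outages of 30 min to
#' 12 h) are inserted to the requested rate with seeded placement.
#'
#' @param days study length, days (>= 2).
#' @param seed integer seed.
#' @param missing_rate target fraction of minutes lost to outages.
#' @return list of five regular [sensor_series()] in canonical order.
#' @export
gen_environment <- function(days = 30L, seed = 1L, missing_rate = 0.05) {
  if (days < 2) stop_chromcast("need at least 2 days")
  n <- as.integer(days) * MINUTES_PER_DAY
  t <- 0:(n - 1L)
  diurnal <- sin(2 * pi * (t - 8.5 * 60) / MINUTES_PER_DAY) # peak ~14:30

  temp <- with_seed(child_seed(seed, "temperature"), {
    base <- runif(1, 22, 28)
    amp <- runif(1, 3, 7)
    base + amp * diurnal + ar1(n, 0.98, 0.1)
  })
  hum <- with_seed(child_seed(seed, "humidity"), {
    base <- runif(1, 60, 80)
    pmin(pmax(base - 1.2 * (temp - mean(temp)) + ar1(n, 0.98, 0.3), 0), 100)
  })
  light <- with_seed(child_seed(seed, "light"), {
    lmax <- runif(1, 2e4, 6e4)
    cloud <- pmin(pmax(1 - abs(ar1(n, 0.997, 0.05)), 0.15), 1)
    lmax * pmax(diurnal, 0)^1.2 * cloud
  })
  moist <- with_seed(child_seed(seed, "soil_moisture"), {
    target <- runif(1, 0.35, 0.7)
    k <- runif(1, 7e-5, 4.8e-4) # per-minute decay
    since <- (t - 7 * 60) %% MINUTES_PER_DAY # watered daily at 07:00
    lvl <- target * exp(-k * since)
    pmin(pmax(lvl + rnorm(n, 0, 0.005), 0), 1)
  })
  ph <- with_seed(child_seed(seed, "soil_ph"), {
    start <- runif(1, 5.5, 7.5)
    pmin(pmax(start + cumsum(rnorm(n, 0, 0.0015)), 4), 9)
  })

  env <- list(
    sensor_series("temperature", t, temp, regular = TRUE),
    sensor_series("humidity", t, hum, regular = TRUE),
    sensor_series("light", t, light, regular = TRUE),
    sensor_series("soil_moisture", t, moist, regular = TRUE),
    sensor_series("soil_ph", t, ph, regular = TRUE)
  )
  if (missing_rate > 0) env <- apply_outages(env, missing_rate, seed)
  env
}

#' Insert seeded logger outages into a set of channels
#'
#' @param env list of regular [sensor_series()].
#' @param rate target fraction of minutes masked per channel.
#' @param seed integer seed.
#' @export
apply_outages <- function(env, rate, seed = 1L) {
  lapply(env, function(s) {
    n <- n_points(s)
    mask <- with_seed(child_seed(seed, paste0("outage_", s$parameter)), {
      m <- rep(FALSE, n)
      want <- rate * n
      guard <- 0L
      while (sum(m) < want && guard < 1000L) {
        len <- as.integer(runif(1, 30, 720))
        at <- as.integer(runif(1, 1, max(1, n - len)))
        m[at:min(n, at + len - 1L)] <- TRUE
        guard <- guard + 1L
      }
      m
    })
    s$values[mask] <- NA_real_
    s$missing <- mask
    s
  })
}

#' Synthesize one chromatogram from an environment realization
#'
#' Summary features of the (fully observed) channels set the peak
#' amplitudes through the truth's softplus weight map and solvent factors;
#' the trace is a sum of Gaussians on the canonical grid plus a drifting
#' baseline, detector noise, a per-run retention-time shift, and
#' multiplicative log-normal replicate noise on the amplitudes.
#'
#' @param env list of five fully observed [sensor_series()].
#' @param truth a [synthetic_truth()].
#' @param solvent extraction solvent `"E1"`, `"E2"`, `"E3"`.
#' @param seed integer seed for the stochastic parts.
#' @param meta extra metadata stored on the chromatogram.
#' @export
gen_chromatogram <- function(env, truth, solvent = "E1", seed = 1L,
                             meta = list()) {
  z <- env_features(env)
  a <- amplitudes_for(truth, z, solvent)
  tm <- chrom_grid(truth$n_grid, truth$t_max)
  with_seed(seed, {
    if (truth$replicate_cv > 0) a <- a * exp(rnorm(length(a), 0, truth$replicate_cv))
    shift <- if (truth$rt_jitter_sd > 0) rnorm(1, 0, truth$rt_jitter_sd) else 0
    sig <- rep(0, length(tm))
    for (j in seq_along(a)) {
      sig <- sig + a[j] * exp(-(tm - truth$peaks$mu[j] - shift)^2 /
                                (2 * truth$peaks$sigma[j]^2))
    }
    bl <- truth$baseline
    base <- bl$b0 + bl$b1 * tm + bl$b2 * sin(2 * pi * tm / bl$period + bl$phase)
    noise <- if (truth$noise_sd > 0) rnorm(length(tm), 0, truth$noise_sd) else 0
    meta$solvent <- solvent
    meta$rt_shift <- shift
    chromatogram(tm, sig + base + noise, meta)
  })
}

#' Generate a paired environment/chromatogram dataset
#'
#' One environment realization per plant; for each configured solvent,
#' `replicates` chromatogram acquisitions with replicate-level noise. The
#' complete (pre-outage) channels used to synthesize the chromatograms are
#' retained alongside the gappy observed channels, so imputed and
#' non-imputed processing can be compared on identical targets.
#'
#' @param n_plants number of plants (>= 2).
#' @param truth a [synthetic_truth()].
#' @param seed integer seed.
#' @param days environment length per plant, days.
#' @param solvents subset of `c("E1","E2","E3")`.
#' @param replicates extraction replicates per (plant, solvent).
#' @param missing_rate sensor outage rate.
#' @return a `synthetic_dataset`: `plants` (per plant, `observed` and
#'   `complete` channel lists), `chromatograms` (with plant/solvent/
#'   replicate metadata), and the `truth`.
#' @export
gen_dataset <- function(n_plants, truth = synthetic_truth(), seed = 1L,
                        days = 30L, solvents = c("E1", "E2", "E3"),
                        replicates = 6L, missing_rate = 0.05) {
  if (n_plants < 2) stop_chromcast("need at least 2 plants")
  solvents <- match.arg(solvents, c("E1", "E2", "E3"), several.ok = TRUE)
  plants <- vector("list", n_plants)
  chroms <- list()
  for (p in seq_len(n_plants)) {
    pseed <- child_seed(seed, paste0("plant", p))
    complete <- gen_environment(days, pseed, missing_rate = 0)
    observed <- if (missing_rate > 0) {
      apply_outages(complete, missing_rate, child_seed(pseed, "outages"))
    } else complete
    plants[[p]] <- list(id = paste0("plant", p), complete = complete,
                        observed = observed)
    for (sv in solvents) {
      for (r in seq_len(replicates)) {
        cs <- child_seed(pseed, paste0(sv, "_rep", r))
        chroms[[length(chroms) + 1L]] <-
          gen_chromatogram(complete, truth, sv, cs,
                           meta = list(plant = paste0("plant", p), replicate = r))
      }
    }
  }
  structure(list(plants = plants, chromatograms = chroms, truth = truth,
                 solvents = solvents, replicates = as.integer(replicates),
                 days = as.integer(days), seed = as.integer(seed)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d plants x %d solvent(s) x %d replicate(s) = %d chromatograms\n",
              length(x$plants), length(x$solvents), x$replicates,
              length(x$chromatograms)))
  invisible(x)
}
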