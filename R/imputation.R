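#' Fit a stochastic regression imputation model
#'
#' Ordinary least squares of the observed minutes on an intercept, a linear
#' trend, and sine/cosine pairs at the configured periods (by default the
#' diurnal 1440-minute cycle and its 720-minute harmonic). The residual
#' standard deviation of the fit is retained so that imputed values can carry
#' realistic noise rather than lying exactly on the regression surface.
#' Harmonic terms are dropped when the observed span covers fewer than two
#' diurnal periods, where their amplitudes are not identifiable.
#'
#' @param s a regularized [sensor_series()].
#' @param periods harmonic periods in minutes.
#' @param long_gap_warn warn when the longest gap exceeds this fraction of
#'   the series length.
#' @return an object of class `imputation_model` with elements `parameter`,
#'   `coef`, `periods`, `residual_sd`, and `fit_window`.
#' @export
fit_stochastic_model <- function(s, periods = c(1440, 720),
                                 long_gap_warn = 0.5) {
  stopifnot(inherits(s, "sensor_series"))
  if (!s$regular) stop_chromcast("fit_stochastic_model() needs a regularized series")
  obs <- !s$missing
  if (mean(obs) < 0.10) {
    stop_chromcast("fewer than 10%% of minutes observed (%.1f%%)", 100 * mean(obs))
  }
  gaps <- detect_gaps(s)
  if (nrow(gaps)) {
    longest <- max(gaps[, 2L] - gaps[, 1L])
    if (longest > long_gap_warn * n_points(s)) {
      warning(sprintf("longest gap (%d min) exceeds %d%% of the series",
                      longest, round(100 * long_gap_warn)), call. = FALSE)
    }
  }
  t_obs <- s$time[obs]
  span_obs <- diff(range(t_obs))
  keep_harmonics <- span_obs >= 2 * max(periods, MINUTES_PER_DAY)
  periods_used <- if (keep_harmonics) periods else numeric(0)

  X <- design_matrix(t_obs, periods_used)
  fit <- lm.fit(X, s$values[obs])
  res <- fit$residuals
  rsd <- if (length(res) > length(fit$coefficients)) {
    sqrt(sum(res^2) / (length(res) - 1L))
  } else 0
  structure(
    list(parameter = s$parameter,
         coef = fit$coefficients,
         periods = periods_used,
         residual_sd = rsd,
         fit_window = range(t_obs)),
    class = "imputation_model")
}

design_matrix <- function(t, periods) {
  cols <- list(intercept = rep(1, length(t)), trend = t)
  for (p in periods) {
    w <- 2 * pi * t / p
    cols[[paste0("sin", p)]] <- sin(w)
    cols[[paste0("cos", p)]] <- cos(w)
  }
  do.call(cbind, cols)
}

#' @export
print.imputation_model <- function(x, ...) {
  cat(sprintf("<imputation_model> %s: trend + %d harmonic(s), residual sd %.4g\n",
              x$parameter, length(x$periods), x$residual_sd))
  invisible(x)
}

#' Harmonic amplitude of a fitted imputation model
#'
#' @param m an `imputation_model`.
#' @param period the harmonic period, minutes.
#' @return the amplitude `sqrt(a^2 + b^2)` of the sine/cosine pair.
#' @export
harmonic_amplitude <- function(m, period) {
  a <- m$coef[paste0("sin", period)]
  b <- m$coef[paste0("cos", period)]
  if (anyNA(c(a, b))) return(NA_real_)
  unname(sqrt(a^2 + b^2))
}

model_fitted <- function(m, t) {
  as.numeric(design_matrix(t, m$periods) %*% m$coef)
}

#' Impute missing minutes with stochastic regression draws
#'
#' Observed values are never altered. Each missing minute receives the
#' regression fit plus a Gaussian draw with the model's residual standard
#' deviation, then is clipped to the physical bounds of the parameter
#' (e.g. relative humidity to \[0, 100\], pH to \[0, 14\], light to be
#' nonnegative). The result carries an `imputed` mask recording provenance.
#'
#' @param s a regularized [sensor_series()].
#' @param m the [fit_stochastic_model()] output for the same parameter.
#' @param seed integer seed controlling the Gaussian draws.
#' @return a fully observed `sensor_series` with an `imputed` logical field.
#' @export
impute <- function(s, m, seed = 1L) {
  stopifnot(inherits(s, "sensor_series"), inherits(m, "imputation_model"))
  if (!identical(s$parameter, m$parameter)) {
    stop_chromcast("model was fitted on '%s', series is '%s'", m$parameter, s$parameter)
  }
  out <- s
  miss <- s$missing
  if (any(miss)) {
    fitted <- model_fitted(m, s$time[miss])
    noise <- with_seed(seed, rnorm(sum(miss), mean = 0, sd = m$residual_sd))
    b <- SENSOR_BOUNDS[[s$parameter]]
    out$values[miss] <- pmin(pmax(fitted + noise, b[1L]), b[2L])
  }
  out$missing <- rep(FALSE, n_points(s))
  out$imputed <- miss
  out
}
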