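#' Chromatogram container
#'
#' Absorbance versus elution time on a uniform grid, by default 1,501
#' points over 0-20 min (UV detection at 285 nm).
#'
#' @param time minutes, uniform and increasing.
#' @param absorbance detector response, arbitrary units.
#' @param meta list of sample metadata (`sample_id`, `solvent` in
#'   `E1`/`E2`/`E3`, `replicate`, `wavelength_nm`, ...).
#' @return an object of class `chromatogram`.
#' @export
chromatogram <- function(time, absorbance, meta = list()) {
  if (length(time) != length(absorbance)) stop_chromcast("time/absorbance length mismatch")
  if (length(time) < 3L) stop_chromcast("a chromatogram needs at least 3 points")
  dt <- diff(time)
  if (any(dt <= 0)) stop_chromcast("time axis must be strictly increasing")
  if (max(abs(dt - dt[1L])) > 1e-6 * dt[1L]) {
    stop_chromcast("time grid is not uniform (relative tolerance 1e-6)")
  }
  meta$wavelength_nm <- meta$wavelength_nm %||% 285
  structure(list(time = as.numeric(time), absorbance = as.numeric(absorbance),
                 meta = meta), class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("<chromatogram> %d points, %.2f-%.2f min, solvent %s\n",
              length(x$time), min(x$time), max(x$time),
              x$meta$solvent %||% "?"))
  invisible(x)
}

#' The canonical 0-20 min elution grid
#' @param n number of points, default 1501.
#' @param t_max end of the acquisition window, minutes.
#' @export
chrom_grid <- function(n = 1501L, t_max = 20) seq(0, t_max, length.out = n)

#' Read a chromatogram CSV
#'
#' Expects columns `time_min,absorbance`. Optionally resamples by linear
#' interpolation onto a canonical uniform grid spanning the same range
#' (endpoints are preserved exactly).
#'
#' @param path CSV file path.
#' @param resample_n if not `NULL`, interpolate to this many points.
#' @param meta metadata list passed to [chromatogram()].
#' @export
read_chromatogram <- function(path, resample_n = NULL, meta = list()) {
  df <- read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L) stop_chromcast("expected two columns 'time_min,absorbance' in %s", path)
  tm <- as.numeric(df[[1L]])
  ab <- as.numeric(df[[2L]])
  if (anyNA(tm) || anyNA(ab)) stop_chromcast("non-numeric entries in %s", path)
  if (any(diff(tm) <= 0)) stop_chromcast("non-monotone time axis in %s", path)
  if (!is.null(resample_n)) {
    grid <- seq(min(tm), max(tm), length.out = resample_n)
    ab <- approx(tm, ab, xout = grid, rule = 2)$y
    tm <- grid
  }
  chromatogram(tm, ab, meta)
}

# Zero-phase banded high-pass filter pair (A, B) such that H = B A^{-1} is
# the high-pass used by the sparsity-assisted baseline model: order-d
# difference numerator, cutoff fc in cycles/sample.
beads_filters <- function(d, fc, n) {
  b1 <- c(1, -1)
  if (d > 1) for (i in seq_len(d - 1)) b1 <- convolve(b1, rev(c(-1, 2, -1)), type = "open")
  b <- convolve(b1, rev(c(-1, 1)), type = "open")
  omc <- 2 * pi * fc
  t_fac <- ((1 - cos(omc)) / (1 + cos(omc)))^d
  a <- 1
  for (i in seq_len(d)) a <- convolve(a, rev(c(1, 2, 1)), type = "open")
  a <- b + t_fac * a
  offs <- -d:d
  A <- Matrix::bandSparse(n, n, k = offs,
                          diagonals = lapply(seq_along(offs), function(i) rep(a[i], n)))
  B <- Matrix::bandSparse(n, n, k = offs,
                          diagonals = lapply(seq_along(offs), function(i) rep(b[i], n)))
  list(A = A, B = B)
}

#' Sparsity-assisted baseline correction (BEADS)
#'
#' Models the measured trace as sparse nonnegative peaks plus a low-pass
#' baseline plus noise, and estimates the peaks by majorization-minimization
#' of a cost with an asymmetric penalty on the signal (weight `r` on
#' negative excursions) and smoothed L1 penalties on its first two
#' differences. The filter pair is an order-`d` zero-phase high-pass with
#' cutoff `fc` cycles/sample. Regularization defaults scale with the signal
#' amplitude since absorbance units are arbitrary.
#'
#' The signal is extended by point-symmetric reflection at both ends before
#' the solve and trimmed afterwards, suppressing the boundary artifacts the
#' plain estimator exhibits.
#'
#' @param c a [chromatogram()].
#' @param d filter order (1 or 2).
#' @param fc cutoff frequency, cycles/sample (0 < fc < 0.5).
#' @param r asymmetry ratio penalizing negative peaks.
#' @param lam0,lam1,lam2 regularization weights; defaults are
#'   `c(0.4, 2, 2) * amp` with `amp = 0.005 * max(abs(absorbance))`.
#' @param max_iter maximum majorization-minimization iterations.
#' @param tol relative cost-change convergence tolerance.
#' @param pad reflection padding length, samples (capped at `n - 1`).
#' @return list with `corrected` and `baseline` chromatograms, the `cost`
#'   trace, and the iteration count.
#' @export
beads_correct <- function(c, d = 1L, fc = 0.005, r = 6,
                          lam0 = NULL, lam1 = NULL, lam2 = NULL,
                          max_iter = 80L, tol = 1e-4, pad = 300L) {
  stopifnot(inherits(c, "chromatogram"))
  y0 <- c$absorbance
  n0 <- length(y0)
  if (n0 < 50L) stop_chromcast("baseline correction needs at least 50 points")
  L <- max(0L, min(as.integer(pad), n0 - 1L))
  y <- if (L > 0L) {
    c(2 * y0[1L] - rev(y0[2:(L + 1L)]), y0, 2 * y0[n0] - rev(y0[(n0 - L):(n0 - 1L)]))
  } else y0
  n <- length(y)
  amp <- 0.005 * max(abs(y0))
  if (amp == 0) { # an all-zero trace has a zero baseline
    zero <- chromatogram(c$time, rep(0, n0), c$meta)
    return(list(corrected = zero, baseline = zero, cost = numeric(0), iterations = 0L))
  }
  lam0 <- lam0 %||% (0.4 * amp)
  lam1 <- lam1 %||% (2.0 * amp)
  lam2 <- lam2 %||% (2.0 * amp)

  eps0 <- 1e-6
  eps1 <- 1e-6
  phi <- function(x) sqrt(x^2 + eps1)
  wfun <- function(x) x / sqrt(x^2 + eps1)

  fl <- beads_filters(d, fc, n)
  A <- fl$A
  B <- fl$B
  H <- function(x) as.numeric(B %*% Matrix::solve(A, x))

  e <- rep(1, n - 1L)
  D1 <- Matrix::bandSparse(n - 1L, n, k = c(0L, 1L), diagonals = list(-e, e))
  e2 <- rep(1, n - 2L)
  D2 <- Matrix::bandSparse(n - 2L, n, k = c(0L, 1L, 2L),
                           diagonals = list(e2, -2 * e2, e2))
  D <- rbind(D1, D2)
  BTB <- Matrix::crossprod(B)
  w <- c(lam1 * rep(1, n - 1L), lam2 * rep(1, n - 2L))
  b_lin <- rep((1 - r) / 2, n)
  d_vec <- as.numeric(BTB %*% Matrix::solve(A, y)) - lam0 * as.numeric(Matrix::crossprod(A, b_lin))

  theta <- function(x) sum(x * (1 - r) / 2 + abs(x) * (1 + r) / 2)
  cost_of <- function(x) {
    0.5 * sum(H(y - x)^2) + lam0 * theta(x) +
      lam1 * sum(phi(diff(x))) + lam2 * sum(phi(diff(x, differences = 2)))
  }

  x <- y
  cost <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lam_diag <- w * wfun(as.numeric(D %*% x))
    Lam <- Matrix::Diagonal(x = lam_diag)
    gam <- ifelse(abs(x) > eps0, (1 + r) / (4 * abs(x)), (1 + r) / (4 * eps0))
    Gam <- Matrix::Diagonal(x = gam)
    M <- 2 * lam0 * Gam + Matrix::crossprod(D, Lam %*% D)
    Q <- BTB + Matrix::crossprod(A, M %*% A)
    x <- as.numeric(A %*% Matrix::solve(Q, d_vec))
    cost <- c(cost, cost_of(x))
    if (it > 1L) {
      rel <- abs(cost[it] - cost[it - 1L]) / (abs(cost[it - 1L]) + .Machine$double.eps)
      if (rel < tol) { converged <- TRUE; break }
    }
  }
  if (!converged) {
    e <- simpleError(sprintf("baseline correction did not converge in %d iterations", max_iter))
    e$cost_trace <- cost
    stop(e)
  }
  baseline <- (y - x - H(y - x))[(L + 1L):(L + n0)]
  list(corrected = chromatogram(c$time, y0 - baseline, c$meta),
       baseline = chromatogram(c$time, baseline, c$meta),
       cost = cost, iterations = length(cost))
}

#' Relative concentration profile
#'
#' Clips negative post-correction absorbances to zero and rescales to unit
#' sum, giving the per-point relative contribution of each elution time to
#' the total detected metabolite content. Values are interpreted on a
#' naringenin-equivalent scale (mg per 100 mg dried leaves) when an external
#' standard response factor is supplied; the factor is carried in the
#' metadata but never applied to the network target.
#'
#' @param c a baseline-corrected [chromatogram()].
#' @param response_factor optional external-standard response factor.
#' @return a `concentration_profile` with unit-sum `values`.
#' @export
to_concentration <- function(c, response_factor = NULL) {
  stopifnot(inherits(c, "chromatogram"))
  a <- pmax(c$absorbance, 0)
  total <- sum(a)
  if (total <= 0) stop_chromcast("all-zero chromatogram cannot be normalized")
  meta <- c$meta
  meta$response_factor <- response_factor
  structure(list(time = c$time, values = a / total, unit_area = TRUE,
                 meta = meta), class = "concentration_profile")
}

#' Invertible log transform of a concentration profile
#'
#' Unit-area relative concentrations sit around 1e-4 to 1e-3, which starves
#' gradient-based training. `y*(t) = -log10(C(t) + eps) / s` rescales them
#' to order 1e-1 while remaining strictly decreasing in `C`, so the exact
#' inverse `C = 10^(-s y*) - eps` recovers the profile.
#'
#' @param p a `concentration_profile`.
#' @param s scale divisor, default 10.
#' @param eps additive floor keeping zero concentrations finite.
#' @return a `log_profile`.
#' @export
log_transform <- function(p, s = 10, eps = 1e-12) {
  stopifnot(inherits(p, "concentration_profile"))
  structure(list(time = p$time, values = -log10(p$values + eps) / s,
                 scale = s, floor = eps, meta = p$meta),
            class = "log_profile")
}

#' @rdname log_transform
#' @param l a `log_profile`.
#' @export
inverse_log <- function(l) {
  stopifnot(inherits(l, "log_profile"))
  v <- 10^(-l$scale * l$values) - l$floor
  structure(list(time = l$time, values = pmax(v, 0), unit_area = FALSE,
                 meta = l$meta), class = "concentration_profile")
}
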