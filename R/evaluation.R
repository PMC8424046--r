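profile_values <- function(p) {
  if (inherits(p, c("concentration_profile", "log_profile"))) p$values
  else as.numeric(p)
}

#' Lag-tolerant cross-correlation between two profiles
#'
#' The maximum over lags `|l| <= max_lag` of the Pearson correlation of the
#' overlapping segments. Lag tolerance absorbs small retention-time shifts
#' between acquisition runs.
#'
#' @param a,b equal-length profiles (or numeric vectors).
#' @param max_lag largest lag searched; default a tenth of the length.
#' @return correlation in \[-1, 1\].
#' @export
cross_correlation <- function(a, b, max_lag = NULL) {
  x <- profile_values(a)
  y <- profile_values(b)
  if (length(x) != length(y)) stop_chromcast("profiles have different lengths")
  if (sd(x) == 0 || sd(y) == 0) stop_chromcast("cross-correlation of a constant profile is undefined")
  n <- length(x)
  max_lag <- as.integer(max_lag %||% round(n / 10))
  best <- -Inf
  for (l in (-max_lag):max_lag) {
    if (l >= 0) { xs <- x[(1 + l):n]; ys <- y[1:(n - l)] }
    else { xs <- x[1:(n + l)]; ys <- y[(1 - l):n] }
    if (length(xs) < 3L || sd(xs) == 0 || sd(ys) == 0) next
    best <- max(best, cor(xs, ys))
  }
  if (!is.finite(best)) stop_chromcast("no lag produced a defined correlation")
  best
}

#' Coefficient of determination of test on predicted values
#'
#' The R-squared of the test profile regressed on the predicted profile
#' (the squared Pearson correlation), matching a predicted-vs-test
#' scatterplot with a fitted line. A constant prediction explains nothing
#' and scores 0; a constant test profile is an error.
#'
#' @param pred,test equal-length profiles.
#' @export
r_squared <- function(pred, test) {
  x <- profile_values(pred)
  y <- profile_values(test)
  if (length(x) != length(y)) stop_chromcast("profiles have different lengths")
  if (sd(y) == 0) stop_chromcast("R-squared against a constant test profile is undefined")
  if (sd(x) == 0) return(0)
  cor(x, y)^2
}

#' Construct a peak set
#'
#' @param location peak apex positions, minutes.
#' @param height apex heights.
#' @param sigma Gaussian width estimates, minutes (positive).
#' @param n_grid number of grid points of the source profile.
#' @param delta_t grid spacing, minutes.
#' @param source `"test"` or `"predicted"`.
#' @export
peak_set <- function(location, height = rep(NA_real_, length(location)),
                     sigma, n_grid, delta_t,
                     source = c("test", "predicted")) {
  source <- match.arg(source)
  if (any(sigma <= 0)) stop_chromcast("peak widths must be positive")
  ord <- order(location)
  structure(list(location = as.numeric(location)[ord],
                 height = as.numeric(height)[ord],
                 sigma = as.numeric(sigma)[ord],
                 n_grid = as.integer(n_grid),
                 delta_t = as.numeric(delta_t),
                 source = source),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d %s peak(s) on %d grid points\n",
              length(x$location), x$source, x$n_grid))
  invisible(x)
}

#' Detect chromatographic peaks by the first-derivative test
#'
#' Local maxima are located by a sign change of the first difference,
#' filtered by topographic prominence, and assigned a Gaussian width from
#' the full width at half prominence via `sigma = FWHM / (2 sqrt(2 ln 2))`.
#' Peaks whose width cannot be measured get the grid spacing as a floor.
#'
#' @param p a profile (concentration scale) or numeric vector.
#' @param prominence minimum prominence; interpreted as an absolute height
#'   unless `relative = TRUE`, in which case as a fraction of the profile
#'   maximum.
#' @param time optional time axis when `p` is a plain vector.
#' @param relative treat `prominence` as a fraction of `max(p)`.
#' @param source label for the returned [peak_set()].
#' @export
detect_peaks <- function(p, prominence = 0.05, time = NULL, relative = TRUE,
                         source = "predicted") {
  x <- profile_values(p)
  tm <- if (!is.null(time)) time else if (is.list(p)) p$time else seq_along(x) - 1
  n <- length(x)
  if (n < 3L) stop_chromcast("profile too short for peak detection")
  dt <- tm[2L] - tm[1L]
  thr <- if (relative) prominence * max(x) else prominence

  d <- diff(x)
  # apex: rise immediately before, fall at the next nonzero difference
  cand <- integer(0)
  for (i in 2:(n - 1L)) {
    if (x[i] > x[i - 1L] && x[i] >= x[i + 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L
      if (j == n || x[j + 1L] < x[j]) cand <- c(cand, i)
    }
  }
  if (!length(cand)) {
    return(peak_set(numeric(0), numeric(0), numeric(0), n, dt, source))
  }

  prom <- vapply(cand, function(i) peak_prominence(x, i), numeric(1))
  keep <- prom >= thr
  cand <- cand[keep]
  prom <- prom[keep]
  if (!length(cand)) {
    return(peak_set(numeric(0), numeric(0), numeric(0), n, dt, source))
  }
  sig <- vapply(seq_along(cand), function(q) {
    w <- peak_halfprom_width(x, cand[q], prom[q]) * dt
    max(w / (2 * sqrt(2 * log(2))), dt)
  }, numeric(1))
  peak_set(tm[cand], x[cand], sig, n, dt, source)
}

# topographic prominence: drop to the highest of the two key saddles
peak_prominence <- function(x, i) {
  n <- length(x)
  left_min <- x[i]
  j <- i
  while (j > 1L && x[j - 1L] <= x[i]) { j <- j - 1L; left_min <- min(left_min, x[j]) }
  if (j == 1L) left_min <- min(x[1:i])
  right_min <- x[i]
  j <- i
  while (j < n && x[j + 1L] <= x[i]) { j <- j + 1L; right_min <- min(right_min, x[j]) }
  if (j == n) right_min <- min(x[i:n])
  x[i] - max(left_min, right_min)
}

# interpolated width (in grid steps) at height = apex - prom/2
peak_halfprom_width <- function(x, i, prom) {
  n <- length(x)
  level <- x[i] - prom / 2
  l <- i
  while (l > 1L && x[l - 1L] > level) l <- l - 1L
  lpos <- if (l == 1L) 1 else (l - 1) + (x[l - 1L] - level) / (x[l - 1L] - x[l])
  r <- i
  while (r < n && x[r + 1L] > level) r <- r + 1L
  rpos <- if (r == n) n else r + (x[r] - level) / (x[r] - x[r + 1L])
  rpos - lpos
}

#' Match predicted against test peaks within an n-sigma tolerance
#'
#' A predicted peak is a true positive when it lies within `n` combined
#' widths of an unconsumed test peak, `|p' - p| <= n (sigma + sigma')`;
#' pairs are matched greedily in increasing distance, one-to-one. Remaining
#' predicted peaks are false positives, remaining test peaks false
#' negatives, and every other grid point a true negative
#' (`TN = N - TP - FP - FN`).
#'
#' With `literal_rule = TRUE` the one-sided inequality
#' `p - n sigma <= p' + n sigma' <= p + n sigma` is used instead of the
#' symmetric interval-overlap reading.
#'
#' @param pred,test [peak_set()] objects on the same grid.
#' @param n tolerance multiplier (>= 1).
#' @param n_grid grid size N; defaults to the peak sets' grid.
#' @param literal_rule use the one-sided published inequality.
#' @return a `match_result` with counts `tp`, `fp`, `fn`, `tn` and `mcc`.
#' @export
match_peaks <- function(pred, test, n = 1L, n_grid = NULL, literal_rule = FALSE) {
  stopifnot(inherits(pred, "peak_set"), inherits(test, "peak_set"))
  if (n < 1) stop_chromcast("tolerance multiplier n must be >= 1")
  N <- as.integer(n_grid %||% test$n_grid)
  np <- length(pred$location)
  nt <- length(test$location)
  matched_p <- rep(FALSE, np)
  matched_t <- rep(FALSE, nt)
  if (np && nt) {
    dist <- abs(outer(pred$location, test$location, `-`))
    ok <- if (literal_rule) {
      upper <- outer(pred$location + n * pred$sigma,
                     test$location + n * test$sigma, `-`) <= 0
      lower <- outer(pred$location + n * pred$sigma,
                     test$location - n * test$sigma, `-`) >= 0
      upper & lower
    } else {
      dist <= n * outer(pred$sigma, test$sigma, `+`)
    }
    cand <- which(ok, arr.ind = TRUE)
    if (nrow(cand)) {
      cand <- cand[order(dist[ok]), , drop = FALSE]
      for (q in seq_len(nrow(cand))) {
        i <- cand[q, 1L]; j <- cand[q, 2L]
        if (!matched_p[i] && !matched_t[j]) {
          matched_p[i] <- TRUE
          matched_t[j] <- TRUE
        }
      }
    }
  }
  tp <- sum(matched_p)
  fp <- np - tp
  fn <- nt - sum(matched_t)
  tn <- N - tp - fp - fn
  if (tn < 0) stop_chromcast("grid oversaturated: TP + FP + FN exceeds N = %d", N)
  res <- structure(list(n = n, tp = tp, fp = fp, fn = fn, tn = tn, N = N),
                   class = "match_result")
  res$mcc <- mcc(res)
  res
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> n=%s TP=%d FP=%d FN=%d TN=%d MCC=%.4f\n",
              format(x$n), x$tp, x$fp, x$fn, x$tn, x$mcc))
  invisible(x)
}

#' Matthews correlation coefficient of a peak contingency
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with the
#' convention that any zero factor in the denominator gives 0. +1 is a
#' perfect predictor, 0 matches random guessing, -1 a perfectly wrong
#' predictor; the statistic is robust to the heavy peak/non-peak imbalance
#' of a chromatogram grid.
#'
#' @param m a `match_result`, or the TP count when the four counts are
#'   given separately.
#' @param fp,tn,fn counts when calling with scalars.
#' @export
mcc <- function(m, fp = NULL, tn = NULL, fn = NULL) {
  if (inherits(m, "match_result")) {
    tp <- m$tp; fp <- m$fp; tn <- m$tn; fn <- m$fn
  } else {
    tp <- m
    if (is.null(fp) || is.null(tn) || is.null(fn)) {
      stop_chromcast("supply fp, tn and fn alongside tp")
    }
  }
  if (any(c(tp, fp, tn, fn) < 0)) stop_chromcast("negative contingency count")
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Select the tolerance multiplier from a hand-held f(n) curve
#'
#' Given `f(n) = mu_MCC(n) / sigma_MCC(n)` evaluated on a grid of `n`
#' values, computes forward differences `f'(n)` and returns the smallest
#' `n` whose rate of change has fallen to `tau` or below (further widening
#' of the tolerance no longer buys significant accuracy).
#'
#' @param f_values values of `f(n)`.
#' @param n_values the scanned tolerance multipliers.
#' @param tau rate-of-change threshold, default 1e-3.
#' @return list with `n_star`, `fprime`, and a `saturated` flag (`FALSE`
#'   when no scanned `n` met the threshold and the largest was returned).
#' @export
select_tolerance <- function(f_values, n_values = seq_along(f_values), tau = 1e-3) {
  if (length(f_values) < 2L) stop_chromcast("need at least two f(n) values")
  fp <- diff(f_values) / diff(n_values)
  hit <- which(fp <= tau)
  if (!length(hit)) {
    warning("f'(n) never fell below tau; returning the largest scanned n", call. = FALSE)
    return(list(n_star = n_values[length(n_values)], fprime = fp, saturated = FALSE))
  }
  list(n_star = n_values[hit[1L]], fprime = fp, saturated = TRUE)
}

#' Scan the peak-matching tolerance and pick n*
#'
#' Computes `MCC(n)` for every sample and every scanned `n`, forms
#' `f(n) = mu_MCC / sigma_MCC`, and selects the smallest `n` at which the
#' forward difference of `f` drops to `tau` (diminishing returns). Values
#' of `n` where the MCC spread is zero leave `f` undefined and are skipped
#' with a warning.
#'
#' @param samples list of `list(pred = peak_set, test = peak_set)` pairs.
#' @param n_range tolerance multipliers to scan.
#' @param tau threshold on `f'(n)`.
#' @param literal_rule passed to [match_peaks()].
#' @return a `tolerance_scan`: the MCC matrix (samples x n), `mu`, `sigma`,
#'   `f`, `fprime`, `n_star`, `tau`.
#' @export
scan_tolerance <- function(samples, n_range = 1:10, tau = 1e-3,
                           literal_rule = FALSE) {
  if (length(samples) < 2L) stop_chromcast("need at least 2 samples to scan the tolerance")
  mccs <- vapply(n_range, function(n) {
    vapply(samples, function(s) {
      match_peaks(s$pred, s$test, n = n, literal_rule = literal_rule)$mcc
    }, numeric(1))
  }, numeric(length(samples)))
  mccs <- matrix(mccs, nrow = length(samples))
  mu <- colMeans(mccs)
  sig <- apply(mccs, 2L, sd)
  f <- mu / sig
  usable <- is.finite(f)
  if (!all(usable)) {
    warning("f(n) undefined where the MCC spread is zero; those n were skipped",
            call. = FALSE)
  }
  if (sum(usable) < 2L) {
    return(structure(list(mcc = mccs, n_values = n_range, mu = mu, sigma = sig,
                          f = f, fprime = numeric(0),
                          n_star = n_range[which.max(mu)], tau = tau),
                     class = "tolerance_scan"))
  }
  sel <- select_tolerance(f[usable], n_range[usable], tau)
  structure(list(mcc = mccs, n_values = n_range, mu = mu, sigma = sig, f = f,
                 fprime = sel$fprime, n_star = sel$n_star, tau = tau),
            class = "tolerance_scan")
}

#' @export
print.tolerance_scan <- function(x, ...) {
  cat(sprintf("<tolerance_scan> n in [%s..%s], n* = %s (tau = %g)\n",
              min(x$n_values), max(x$n_values), x$n_star, x$tau))
  invisible(x)
}

#' Precision-recall area under the curve for peak classification
#'
#' Sweeps the peak-detection prominence threshold over `threshold_grid` on
#' the predicted profiles, matches against the fixed test peaks at
#' tolerance `n`, pools TP/FP/FN across samples, and integrates precision
#' over recall by the trapezoid rule with the `(recall 0, precision 1)`
#' anchor prepended.
#'
#' @param samples list of `list(pred_profile = , test = peak_set)` entries;
#'   `pred_profile` is a concentration-scale profile.
#' @param n tolerance multiplier used for matching.
#' @param threshold_grid prominence fractions to sweep.
#' @param literal_rule passed to [match_peaks()].
#' @return list with `auc` and the swept `curve` data frame.
#' @export
pr_auc <- function(samples, n = 6L,
                   threshold_grid = seq(0.01, 0.6, by = 0.02),
                   literal_rule = FALSE) {
  if (length(threshold_grid) < 2L) stop_chromcast("need at least 2 thresholds")
  rows <- lapply(sort(threshold_grid), function(thr) {
    tp <- fp <- fn <- 0
    any_peak <- FALSE
    for (s in samples) {
      pk <- detect_peaks(s$pred_profile, prominence = thr, relative = TRUE)
      any_peak <- any_peak || length(pk$location) > 0
      m <- match_peaks(pk, s$test, n = n, literal_rule = literal_rule)
      tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
    }
    data.frame(threshold = thr, tp = tp, fp = fp, fn = fn,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               any_peak = any_peak)
  })
  curve <- do.call(rbind, rows)
  if (!any(curve$any_peak)) stop_chromcast("no peaks detected at any threshold")
  pts <- curve[!is.na(curve$precision) & !is.na(curve$recall), ]
  pts <- pts[order(pts$recall), ]
  rec <- c(0, pts$recall)
  prec <- c(1, pts$precision)
  auc <- sum(diff(rec) * (head(prec, -1L) + tail(prec, -1L)) / 2)
  list(auc = auc, curve = curve)
}
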