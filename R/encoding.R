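#' @name indicators
#' @title Trailing-window indicator normalization
#'
#' @description
#' Technical chart indicators rescale a sensor series into \[0, 1\] while
#' preserving seasonal and autoregressive structure. Windows are trailing
#' (causal) and truncated at the series start; a flat window (max = min)
#' maps to the midpoint 0.5. On a window basis `williams_r()` and the
#' stochastic `%K` are complements: they sum to 1 wherever the window is
#' not flat.
#'
#' Missing values (a non-imputed series) propagate: any window touching a
#' missing minute yields `NA`, which downstream image encoding renders as
#' zeroed pixels.
#' @param s a regularized [sensor_series()], normally fully imputed.
#' @param k lookback window, minutes.
#' @param d smoothing window for the stochastic `%D`, minutes.
#' @return a `normalized_series`: values in \[0, 1\] plus the indicator
#'   configuration.
NULL

new_normalized <- function(values, s, indicator, k, d = NA_integer_) {
  structure(list(values = values, parameter = s$parameter,
                 config = list(indicator = indicator, k = as.integer(k),
                               d = as.integer(d))),
            class = "normalized_series")
}

# mask of positions whose trailing k-window touches an NA
na_window_mask <- function(x, k) {
  isna <- cumsum(is.na(x))
  lag <- c(rep(0, k), head(isna, -k))
  (isna - lag) > 0
}

window_scale <- function(x, k) {
  hi <- cpp_run_max(x, as.integer(k))
  lo <- cpp_run_min(x, as.integer(k))
  mask <- na_window_mask(x, as.integer(k))
  hi[mask] <- NA_real_
  lo[mask] <- NA_real_
  list(hi = hi, lo = lo, flat = !mask & !is.na(hi) & (hi - lo) <= 0)
}

#' @rdname indicators
#' @export
williams_r <- function(s, k) {
  stopifnot(inherits(s, "sensor_series"), k >= 1)
  ws <- window_scale(s$values, k)
  v <- (ws$hi - s$values) / (ws$hi - ws$lo)
  v[ws$flat] <- 0.5
  new_normalized(v, s, "williams_r", k)
}

#' @rdname indicators
#' @param return_k return the raw `%K` line instead of the smoothed `%D`.
#' @export
stochastic_oscillator <- function(s, k, d = 1440, return_k = FALSE) {
  stopifnot(inherits(s, "sensor_series"), k >= 1, d >= 1)
  ws <- window_scale(s$values, k)
  kline <- (s$values - ws$lo) / (ws$hi - ws$lo)
  kline[ws$flat] <- 0.5
  if (return_k) return(new_normalized(kline, s, "stochastic_K", k))
  dline <- cpp_run_mean(kline, as.integer(d))
  new_normalized(dline, s, "stochastic_D", k, d)
}

#' Piecewise aggregate approximation
#'
#' Partitions the `n` minutes of a normalized series into `m` near-equal
#' contiguous segments and returns each segment's mean, reducing a
#' month-long per-minute record to an image-sized vector (each of the 128
#' default segments then spans roughly six hours).
#'
#' @param ns a `normalized_series` (or plain numeric vector in \[0, 1\]).
#' @param m output length, default 128.
#' @return numeric vector of length `m`.
#' @export
paa_resample <- function(ns, m = 128L) {
  x <- if (inherits(ns, "normalized_series")) ns$values else as.numeric(ns)
  n <- length(x)
  if (n < m) stop_chromcast("series length %d is shorter than m = %d", n, m)
  bounds <- floor(seq_len(m) * (n / m) + 1e-9)
  starts <- c(0L, head(bounds, -1L)) + 1L
  vapply(seq_len(m), function(i) {
    seg <- x[starts[i]:bounds[i]]
    sum(seg) / length(seg) # NA propagates by design
  }, numeric(1))
}

new_gramian <- function(mat, kind, parameter = NA_character_, config = NULL) {
  structure(list(matrix = mat, field_kind = kind, parameter = parameter,
                 config = config), class = "gramian_image")
}

#' @export
print.gramian_image <- function(x, ...) {
  cat(sprintf("<gramian_image> %s %dx%d (%s, k=%s, d=%s)\n", x$field_kind,
              nrow(x$matrix), ncol(x$matrix), x$parameter %||% "?",
              x$config$k %||% "?", x$config$d %||% "?"))
  invisible(x)
}

check_unit_interval <- function(v) {
  finite <- !is.na(v)
  if (any(v[finite] < -1e-9 | v[finite] > 1 + 1e-9)) {
    stop_chromcast("input vector has entries outside [0, 1]")
  }
  pmin(pmax(v, 0), 1)
}

#' Gramian angular fields
#'
#' Maps a \[0, 1\] vector to polar angles `phi = acos(v)` and forms the
#' summation field `GASF[i, j] = cos(phi_i + phi_j)` or the difference
#' field `GADF[i, j] = sin(phi_i - phi_j)`. GASF is symmetric with diagonal
#' `2 v^2 - 1`; GADF is antisymmetric with a zero diagonal. `NA` entries
#' (non-imputed inputs) produce zeroed pixels.
#'
#' @param v numeric vector with entries in \[0, 1\] (typically length 128
#'   from [paa_resample()]).
#' @param parameter,config optional provenance attached to the image.
#' @return a `gramian_image`.
#' @export
gasf <- function(v, parameter = NA_character_, config = NULL) {
  v <- check_unit_interval(v)
  phi <- acos(v)
  m <- cos(outer(phi, phi, `+`))
  m[is.na(m)] <- 0
  new_gramian(m, "GASF", parameter, config)
}

#' @rdname gasf
#' @export
gadf <- function(v, parameter = NA_character_, config = NULL) {
  v <- check_unit_interval(v)
  phi <- acos(v)
  m <- sin(outer(phi, phi, `-`))
  m[is.na(m)] <- 0
  new_gramian(m, "GADF", parameter, config)
}

#' Augment one sensor series into a set of Gramian images
#'
#' Emits one image per retained (indicator, k, d) combination: `williams_r`
#' and the stochastic `%K` vary over `k_grid` only, the stochastic `%D`
#' over the full `k_grid` x `d_grid`. Every image is tagged with its
#' configuration so augmented copies of a plant can be grouped later.
#'
#' @param s a regularized (normally imputed) [sensor_series()].
#' @param indicators subset of
#'   `c("williams_r", "stochastic_K", "stochastic_D")`.
#' @param k_grid lookback windows, minutes.
#' @param d_grid smoothing windows for `%D`, minutes.
#' @param field_kind `"GASF"` or `"GADF"`.
#' @param m image edge, default 128.
#' @param warn_kmax warn about k values exceeding `ceiling(n / m)`, the
#'   window beyond which one lookback covers more than one image pixel.
#' @return list of `gramian_image` objects.
#' @export
augment <- function(s, indicators = c("williams_r", "stochastic_D"),
                    k_grid = c(5, 20, 30, 60, 720, 1440, 4320, 7200),
                    d_grid = c(720, 1440, 4320),
                    field_kind = c("GASF", "GADF"), m = 128L,
                    warn_kmax = FALSE) {
  stopifnot(inherits(s, "sensor_series"))
  field_kind <- match.arg(field_kind)
  indicators <- match.arg(indicators,
                          c("williams_r", "stochastic_K", "stochastic_D"),
                          several.ok = TRUE)
  if (!length(k_grid)) stop_chromcast("empty k grid")
  k_max <- ceiling(n_points(s) / m)
  if (warn_kmax && any(k_grid > k_max)) {
    warning(sprintf("k values beyond ceiling(n/%d) = %d: %s", m, k_max,
                    paste(k_grid[k_grid > k_max], collapse = ", ")),
            call. = FALSE)
  }
  enc <- function(ns) {
    v <- paa_resample(ns, m)
    if (field_kind == "GASF") gasf(v, s$parameter, ns$config)
    else gadf(v, s$parameter, ns$config)
  }
  out <- list()
  for (ind in indicators) {
    if (ind == "stochastic_D") {
      if (!length(d_grid)) stop_chromcast("empty d grid for stochastic_D")
      for (k in k_grid) for (d in d_grid) {
        out[[length(out) + 1L]] <- enc(stochastic_oscillator(s, k, d))
      }
    } else {
      for (k in k_grid) {
        ns <- if (ind == "williams_r") williams_r(s, k)
              else stochastic_oscillator(s, k, return_k = TRUE)
        out[[length(out) + 1L]] <- enc(ns)
      }
    }
  }
  out
}

#' Assemble a CNN input tensor from five per-parameter images
#'
#' The five channels follow the fixed order temperature, humidity, light,
#' soil moisture, soil pH. `concat_1d` concatenates the images along the
#' first axis into a 640 x 128 x 1 array; `stacked_5d` stacks them into
#' 128 x 128 x 5.
#'
#' @param images list of five `gramian_image` objects, one per parameter,
#'   sharing the same field kind and indicator configuration.
#' @param layout `"stacked_5d"` or `"concat_1d"`.
#' @return numeric array with a `layout` attribute.
#' @export
assemble_input <- function(images, layout = c("stacked_5d", "concat_1d")) {
  layout <- match.arg(layout)
  if (length(images) != 5L) {
    stop_chromcast("need exactly 5 images (one per parameter), got %d", length(images))
  }
  params <- vapply(images, function(im) im$parameter, character(1))
  if (!setequal(params, SENSOR_PARAMETERS)) {
    stop_chromcast("images must cover the 5 sensor parameters exactly")
  }
  images <- images[match(SENSOR_PARAMETERS, params)]
  kinds <- unique(vapply(images, function(im) im$field_kind, character(1)))
  cfgs <- unique(vapply(images, function(im)
    paste(im$config$indicator %||% "", im$config$k %||% "", im$config$d %||% ""),
    character(1)))
  if (length(kinds) != 1L || length(cfgs) != 1L) {
    stop_chromcast("images have mismatched field kinds or indicator configs")
  }
  mside <- nrow(images[[1L]]$matrix)
  if (layout == "stacked_5d") {
    arr <- array(0, dim = c(mside, mside, 5L))
    for (i in 1:5) arr[, , i] <- images[[i]]$matrix
  } else {
    arr <- array(0, dim = c(5L * mside, mside, 1L))
    for (i in 1:5) arr[((i - 1L) * mside + 1L):(i * mside), , 1L] <- images[[i]]$matrix
  }
  attr(arr, "layout") <- layout
  attr(arr, "field_kind") <- kinds
  arr
}
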