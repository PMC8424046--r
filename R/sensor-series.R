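#' Construct a sensor time series
#'
#' A `sensor_series` holds one environmental parameter sampled over time:
#' timestamps in minutes since the series start, values, and an explicit
#' missingness mask. After [resample_to_minutes()] the series sits on an
#' exact 1-minute integer grid.
#'
#' @param parameter one of `"temperature"`, `"humidity"`, `"light"`,
#'   `"soil_moisture"`, `"soil_ph"`.
#' @param time numeric, minutes since the first observation (0-based),
#'   strictly increasing.
#' @param values numeric readings; `NA` exactly where `missing` is `TRUE`.
#' @param missing logical mask of absent readings.
#' @param origin optional calendar timestamp (`POSIXct`) of minute 0.
#' @param regular logical; `TRUE` once the series is on the 1-minute grid.
#' @return an object of class `sensor_series`.
#' @export
sensor_series <- function(parameter, time, values, missing = is.na(values),
                          origin = NULL, regular = FALSE) {
  parameter <- match.arg(parameter, SENSOR_PARAMETERS)
  if (length(time) != length(values) || length(values) != length(missing)) {
    stop_chromcast("time, values and missing must have equal length")
  }
  if (length(values) < 2L) stop_chromcast("a sensor series needs at least 2 points")
  if (any(diff(time) <= 0)) stop_chromcast("timestamps must be strictly increasing")
  if (any(missing != is.na(values))) {
    stop_chromcast("missing mask must be TRUE exactly where the value is absent")
  }
  structure(
    list(parameter = parameter, time = as.numeric(time),
         values = as.numeric(values), missing = as.logical(missing),
         origin = origin, regular = isTRUE(regular)),
    class = "sensor_series")
}

#' @export
print.sensor_series <- function(x, ...) {
  cat(sprintf("<sensor_series> %s: %d points over %.1f min, %d missing%s\n",
              x$parameter, length(x$values), diff(range(x$time)),
              sum(x$missing), if (x$regular) " [1-min grid]" else ""))
  invisible(x)
}

n_points <- function(s) length(s$values)

#' Read a raw sensor log
#'
#' Parses a two-column CSV (`timestamp,value`) as produced by a greenhouse
#' monitoring logger. Timestamps may be ISO-8601 strings or numeric epoch
#' seconds; values may be empty (a missing reading). Rows are sorted by time
#' and duplicated timestamps are resolved by keeping the last record. No
#' regularization is performed.
#'
#' @param path CSV file path.
#' @param parameter which environmental parameter the file holds.
#' @return a [sensor_series()] with `time` in fractional minutes since the
#'   first reading and the calendar origin retained.
#' @export
read_sensor_log <- function(path, parameter) {
  parameter <- match.arg(parameter, SENSOR_PARAMETERS)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop_chromcast("empty sensor log: %s", path)
  header <- tolower(gsub("\\s", "", lines[1L]))
  if (!identical(header, "timestamp,value")) {
    stop_chromcast("expected header 'timestamp,value' in %s", path)
  }
  body <- lines[-1L]
  parts <- strsplit(body, ",", fixed = TRUE)
  ts_raw <- vapply(parts, function(p) trimws(p[1L] %||% ""), character(1))
  val_raw <- vapply(parts, function(p) trimws(if (length(p) >= 2L) p[2L] else ""), character(1))

  ts_num <- suppressWarnings(as.numeric(ts_raw))
  origin <- NULL
  if (all(!is.na(ts_num))) {
    secs <- ts_num
  } else {
    tt <- as.POSIXct(ts_raw, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                    "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
    bad <- which(is.na(tt))
    if (length(bad)) {
      stop_chromcast("unparseable timestamp on line %d of %s", bad[1L] + 1L, path)
    }
    secs <- as.numeric(tt)
    origin <- tt[1L]
  }
  empty <- !nzchar(val_raw) | toupper(val_raw) %in% c("NA", "NAN")
  vals <- suppressWarnings(as.numeric(val_raw))
  bad <- which(is.na(vals) & !empty)
  if (length(bad)) {
    stop_chromcast("non-numeric value on line %d of %s", bad[1L] + 1L, path)
  }
  vals[empty] <- NA_real_

  ord <- order(secs)
  secs <- secs[ord]; vals <- vals[ord]
  keep <- !duplicated(secs, fromLast = TRUE) # keep the last record
  secs <- secs[keep]; vals <- vals[keep]
  if (length(secs) < 2L) stop_chromcast("fewer than 2 distinct timestamps in %s", path)

  sensor_series(parameter, time = (secs - secs[1L]) / 60, values = vals,
                origin = origin)
}

#' Read a multichannel sensor manifest
#'
#' A manifest maps each environmental parameter to its log file, e.g.
#' `{"temperature": "temp.csv", "humidity": "rh.csv", ...}` (JSON, or YAML
#' when the yaml package is installed). Relative paths resolve against the
#' manifest's directory.
#'
#' @param path manifest file (`.json`, `.yaml`, `.yml`).
#' @param regularize also place each channel on the 1-minute grid.
#' @return named list of [sensor_series()], in canonical channel order.
#' @export
read_sensor_manifest <- function(path, regularize = TRUE) {
  mapping <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_chromcast("the yaml package is needed to read YAML manifests")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(mapping), SENSOR_PARAMETERS)
  if (length(unknown)) {
    stop_chromcast("unknown parameter(s) in manifest: %s",
                   paste(unknown, collapse = ", "))
  }
  present <- intersect(SENSOR_PARAMETERS, names(mapping))
  out <- lapply(present, function(p) {
    f <- mapping[[p]]
    if (!file.exists(f)) f <- file.path(dirname(path), mapping[[p]])
    s <- read_sensor_log(f, p)
    if (regularize) resample_to_minutes(s) else s
  })
  stats::setNames(out, present)
}

#' Regularize a sensor series onto the 1-minute grid
#'
#' Each grid cell `[j, j+1)` minutes takes the arithmetic mean of the raw
#' readings that fall in it; cells with no reading are flagged missing.
#' Already-regular series pass through unchanged (the operation is
#' idempotent and preserves observed values bit-exactly).
#'
#' @param s a [sensor_series()].
#' @param span optional total span in minutes to pad the grid to (must be
#'   at least the observed span).
#' @return a regular `sensor_series` with integer minute timestamps.
#' @export
resample_to_minutes <- function(s, span = NULL) {
  stopifnot(inherits(s, "sensor_series"))
  if (s$regular) return(s)
  last <- max(s$time)
  n_cells <- floor(last) + 1L
  if (!is.null(span)) {
    if (span < last) stop_chromcast("span (%s) shorter than the observed series", span)
    n_cells <- max(n_cells, as.integer(ceiling(span)))
  }
  if (n_cells < 2L) {
    stop_chromcast("series spans less than 2 minutes; pass span= to pad the grid")
  }
  idx <- pmin(floor(s$time), n_cells - 1L)
  obs <- !s$missing
  vals <- rep(NA_real_, n_cells)
  if (any(obs)) {
    iobs <- idx[obs]
    vobs <- s$values[obs]
    counts <- tabulate(iobs + 1L, nbins = n_cells)
    rs <- rowsum(vobs, iobs) # rows sorted by cell index
    present <- as.integer(rownames(rs)) + 1L
    sums <- rep(0, n_cells)
    sums[present] <- rs[, 1L]
    filled <- counts > 0L
    vals[filled] <- sums[filled] / counts[filled]
    # a cell with exactly one reading keeps it bit-exactly
    one <- which(counts == 1L)
    if (length(one)) {
      vals[one] <- vobs[match(one - 1L, iobs)]
    }
  }
  sensor_series(s$parameter, time = 0:(n_cells - 1L), values = vals,
                origin = s$origin, regular = TRUE)
}

#' Locate runs of missing minutes
#'
#' @param s a regularized [sensor_series()].
#' @return a two-column matrix of half-open minute intervals
#'   `[start_min, end_min)`, one row per maximal missing run, sorted.
#' @export
detect_gaps <- function(s) {
  stopifnot(inherits(s, "sensor_series"))
  if (!s$regular) stop_chromcast("detect_gaps() needs a regularized series")
  r <- rle(s$missing)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  out <- cbind(start_min = starts[r$values], end_min = ends[r$values])
  out[order(out[, 1L]), , drop = FALSE]
}
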