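#' Quality-flagged scalar time series on (or destined for) a regular grid
#'
#' A `gridded_series` is a data frame with columns `time` (POSIXct, strictly
#' increasing), `value` (numeric) and `flag` (one of `"ok"`, `"interpolated"`,
#' `"missing"`, `"discarded"`), with the measurement unit attached as an
#' attribute. Samples flagged `missing` or `discarded` are never consumed by
#' downstream statistics; use [series_values()] to obtain values with those
#' samples masked to `NA`.
#'
#' @param time POSIXct vector, strictly increasing.
#' @param value numeric vector, same length as `time`.
#' @param flag character vector of per-sample quality codes; recycled if
#'   length 1.
#' @param unit unit string carried as metadata (e.g. `"um"`, `"MPa"`).
#' @return A `gridded_series` object.
#' @export
gridded_series <- function(time, value, flag = "ok", unit = NA_character_) {
  if (length(flag) == 1L) flag <- rep(flag, length(time))
  s <- data.frame(time = time, value = as.numeric(value),
                  flag = as.character(flag), stringsAsFactors = FALSE)
  attr(s, "unit") <- unit
  class(s) <- c("gridded_series", "data.frame")
  validate_gridded_series(s)
  s
}

series_flags <- c("ok", "interpolated", "missing", "discarded")

validate_gridded_series <- function(s) {
  stopifnot(inherits(s$time, "POSIXct"))
  if (nrow(s) == 0L) stop("empty series", call. = FALSE)
  if (length(s$value) != length(s$time) || length(s$flag) != length(s$time))
    stop("time, value and flag must have equal length", call. = FALSE)
  if (!all(s$flag %in% series_flags))
    stop("invalid quality flag(s): ",
         paste(setdiff(unique(s$flag), series_flags), collapse = ", "),
         call. = FALSE)
  dt <- diff(as.numeric(s$time))
  if (any(dt <= 0))
    stop("ordering error: timestamps must be strictly increasing", call. = FALSE)
  invisible(s)
}

#' @export
print.gridded_series <- function(x, ...) {
  cat(sprintf("<gridded_series> %d samples, unit: %s, %s .. %s\n",
              nrow(x), series_unit(x),
              format(x$time[1]), format(x$time[nrow(x)])))
  cat(sprintf("  flags: %s\n",
              paste(sprintf("%s=%d", names(table(x$flag)), table(x$flag)),
                    collapse = " ")))
  invisible(x)
}

#' Unit metadata of a series
#' @param s a `gridded_series`.
#' @return The unit string.
#' @export
series_unit <- function(s) attr(s, "unit")

#' Values with unusable samples masked
#'
#' Returns the numeric values of a series with every sample flagged
#' `missing` or `discarded` replaced by `NA`. All downstream statistics go
#' through this mask, so poisoned sentinel values in excluded samples can
#' never leak into results.
#'
#' @param s a `gridded_series`.
#' @return Numeric vector.
#' @export
series_values <- function(s) {
  v <- s$value
  v[!(s$flag %in% c("ok", "interpolated"))] <- NA_real_
  v
}

#' Is the series on an exact regular grid?
#' @param s a `gridded_series`.
#' @param interval grid spacing in seconds.
#' @return Logical.
#' @export
is_regular <- function(s, interval = 600) {
  dt <- diff(as.numeric(s$time))
  length(dt) == 0L || all(dt == interval)
}

parse_iso_times <- function(x) {
  as.POSIXct(x, tz = "UTC",
             tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                            "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d"))
}

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a sensor series from delimited text
#'
#' Reads a comma- or tab-delimited file with a header row, an ISO-8601
#' timestamp column and one value column. Rows whose value cell cannot be
#' parsed as a number are kept on the time axis but flagged `missing`.
#'
#' @param path file path.
#' @param value_col name of the value column.
#' @param time_col name of the timestamp column (default `"time"`).
#' @param unit unit string attached to the series.
#' @param sep field separator; auto-detected from the header when `NULL`.
#' @return A `gridded_series` on the file's native sampling.
#' @export
read_series <- function(path, value_col, time_col = "time",
                        unit = NA_character_, sep = NULL) {
  if (is.null(sep)) sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          na.strings = c("NA", ""), strip.white = TRUE)
  if (!time_col %in% names(df))
    stop("format error: no timestamp column '", time_col, "' in ", path,
         call. = FALSE)
  if (!value_col %in% names(df))
    stop("format error: no value column '", value_col, "' in ", path,
         call. = FALSE)
  tm <- parse_iso_times(df[[time_col]])
  if (anyNA(tm))
    stop("format error: unparseable timestamp(s) in ", path, call. = FALSE)
  if (any(diff(as.numeric(tm)) <= 0))
    stop("ordering error: timestamps not strictly increasing in ", path,
         call. = FALSE)
  v <- suppressWarnings(as.numeric(df[[value_col]]))
  flag <- ifelse(is.finite(v), "ok", "missing")
  if ("flag" %in% names(df)) flag <- df[["flag"]]
  s <- gridded_series(tm, v, flag, unit = unit)
  if ("unit" %in% names(df) && is.na(unit)) attr(s, "unit") <- df$unit[1]
  s
}

#' Write a series to delimited text (lossless round trip)
#'
#' Values are written with 17 significant digits so that
#' `read_series(write_series(s))` reproduces `s` bit-exactly, including
#' flags and unit metadata.
#'
#' @param s a `gridded_series`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_series <- function(s, path) {
  df <- data.frame(
    time = format(s$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    value = ifelse(is.na(s$value), "NA", sprintf("%.17g", s$value)),
    flag = s$flag,
    unit = series_unit(s),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resample a series onto an exact regular grid
#'
#' Places the series on a grid with the given spacing. Grid points that
#' coincide with an observed sample keep its value and flag. Interior grid
#' points inside an observation gap no longer than `max_gap` seconds are
#' linearly interpolated between the neighbouring valid samples and flagged
#' `interpolated`; points inside longer gaps (and before the first or after
#' the last valid sample) are flagged `missing`. Already-gridded input is
#' returned unchanged, so the operation is idempotent.
#'
#' @param s a `gridded_series`.
#' @param interval grid spacing in seconds (default 600 s, the measurement
#'   cadence all model equations assume).
#' @param max_gap longest observation gap (seconds, end minus start of the
#'   bracketing valid samples) that is still bridged by interpolation.
#' @return A `gridded_series` on the exact grid.
#' @export
regularize <- function(s, interval = 600, max_gap = 1800) {
  validate_gridded_series(s)
  tn <- as.numeric(s$time)
  t0 <- ceiling(tn[1] / interval) * interval
  t1 <- floor(tn[length(tn)] / interval) * interval
  if (t1 < t0) stop("empty-input error: no grid point inside series span",
                    call. = FALSE)
  grid <- seq(t0, t1, by = interval)

  usable <- s$flag %in% c("ok", "interpolated") & is.finite(s$value)
  out_v <- rep(NA_real_, length(grid))
  out_f <- rep("missing", length(grid))

  # exact hits keep their sample (any flag, including discarded)
  hit <- match(grid, tn)
  has <- !is.na(hit)
  out_v[has] <- s$value[hit[has]]
  out_f[has] <- s$flag[hit[has]]

  # fill holes between valid observations
  tv <- tn[usable]
  vv <- s$value[usable]
  if (length(tv) >= 2L) {
    fill <- which(!has | !(out_f %in% c("ok", "interpolated")))
    fill <- fill[!(has[fill] & out_f[fill] == "discarded")]
    for (i in fill) {
      g <- grid[i]
      j <- findInterval(g, tv)
      if (j >= 1L && j < length(tv)) {
        gap <- tv[j + 1L] - tv[j]
        if (gap <= max_gap) {
          w <- (g - tv[j]) / gap
          out_v[i] <- (1 - w) * vv[j] + w * vv[j + 1L]
          out_f[i] <- if (g == tv[j] || g == tv[j + 1L]) "ok" else "interpolated"
        }
      }
    }
  }
  # off-grid samples that landed exactly on a grid point via interpolation
  # weight 0/1 keep flag ok above; everything else already labelled.
  g <- gridded_series(as.POSIXct(grid, tz = "UTC", origin = "1970-01-01"),
                      out_v, out_f, unit = series_unit(s))
  g
}

#' Flag an interval as discarded
#'
#' Marks every sample with `start <= time < end` as `discarded`, excluding it
#' from all downstream statistics. The reason is appended to the series'
#' discard log (attribute `"discards"`), which the pipeline copies into its
#' run manifest.
#'
#' @param s a `gridded_series`.
#' @param start,end POSIXct (or coercible) interval bounds, `start < end`.
#' @param reason short free-text reason recorded in the log.
#' @return The flagged series.
#' @export
discard_interval <- function(s, start, end, reason = "unreliable") {
  start <- parse_iso_times(start); end <- parse_iso_times(end)
  if (!(start < end)) stop("start must precede end", call. = FALSE)
  idx <- s$time >= start & s$time < end
  s$flag[idx] <- "discarded"
  log <- attr(s, "discards")
  attr(s, "discards") <- rbind(log, data.frame(
    start = format(start, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    end = format(end, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    n = sum(idx), reason = reason, stringsAsFactors = FALSE))
  s
}

#' Extract one calendar day of a series
#' @param s a `gridded_series`.
#' @param date a `Date` (or coercible).
#' @return A `gridded_series` restricted to `[00:00, 24:00)` of `date`.
#' @export
series_day <- function(s, date) {
  date <- as.Date(date)
  d0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  idx <- s$time >= d0 & s$time < d0 + 86400
  if (!any(idx)) stop("no samples on ", format(date), call. = FALSE)
  out <- s[idx, , drop = FALSE]
  attr(out, "unit") <- series_unit(s)
  class(out) <- class(s)
  out
}

#' Calendar dates covered by a series
#' @param s a `gridded_series`.
#' @return Vector of `Date`.
#' @export
series_dates <- function(s) unique(as.Date(s$time, tz = "UTC"))
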