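#' Daily maximum/minimum thickness and diurnal amplitude
#'
#' The daily maximum is searched within `[00:00, 24:00)` of the date. The
#' minimum is searched forward from the time of the maximum over a 24-h
#' window (`[t_max, t_max + 24 h)`, truncated to the available data), so a
#' minimum that falls after midnight is reported at its true post-midnight
#' time rather than clipped to the end of the calendar day. Amplitude is
#' `thickness(t_max) - thickness(t_min)`. Ties are broken to the earliest
#' time. Amplitude is invariant under any additive offset of the series.
#'
#' @param detrended detrended thickness `gridded_series` (um).
#' @param date calendar date (`Date` or coercible).
#' @param min_valid_frac minimum fraction of usable samples within the day
#'   for the day to be valid (default 0.8).
#' @return One-row data frame: `date`, `amplitude` (um), `t_max`, `t_min`
#'   (POSIXct), `valid`.
#' @export
daily_extrema <- function(detrended, date, min_valid_frac = 0.8) {
  date <- as.Date(date)
  d0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  day_idx <- detrended$time >= d0 & detrended$time < d0 + 86400
  n_expected <- 144L
  v <- series_values(detrended)
  v_day <- v[day_idx]
  invalid <- data.frame(date = date, amplitude = NA_real_,
                        t_max = as.POSIXct(NA), t_min = as.POSIXct(NA),
                        valid = FALSE)
  if (sum(is.finite(v_day)) < min_valid_frac * n_expected) return(invalid)
  t_day <- detrended$time[day_idx]
  i_max <- which.max(v_day)                     # first max on ties
  t_max <- t_day[i_max]
  win <- detrended$time >= t_max & detrended$time < t_max + 86400
  v_win <- v[win]
  t_win <- detrended$time[win]
  if (!any(is.finite(v_win))) return(invalid)
  i_min <- which.min(v_win)                     # first min on ties
  data.frame(date = date,
             amplitude = v_day[i_max] - v_win[i_min],
             t_max = t_max, t_min = t_win[i_min], valid = TRUE)
}

#' Daily metrics table over all covered dates
#'
#' @param detrended detrended thickness `gridded_series`.
#' @param dates dates to evaluate (default: all dates covered).
#' @param min_valid_frac passed to [daily_extrema()].
#' @return Data frame with one row per date.
#' @export
daily_metrics <- function(detrended, dates = series_dates(detrended),
                          min_valid_frac = 0.8) {
  do.call(rbind, lapply(dates, daily_extrema, detrended = detrended,
                        min_valid_frac = min_valid_frac))
}

#' Lag of thickness behind xylem water potential by cross-correlation
#'
#' Both day series are mean-centred and the Pearson correlation is computed
#' over the overlapping samples for every candidate lag (multiples of the
#' grid step up to `max_lag_min`). The reported lag maximizes the signed
#' correlation (not its absolute value): a thickness series that mirrors
#' psi_X upside-down therefore reports its most positive correlation, and
#' the expected physiological sign (positive peak correlation, thickness
#' tracks psi) is exposed through `peak_correlation` for QC. Negative lag
#' means thickness lags behind psi_X (e.g. thickness(t) = psi(t - 120 min)
#' gives lag -120). Ties are broken toward the smallest `|lag|`, then toward
#' the more negative lag.
#'
#' @param thickness_day,psi_day `gridded_series` for one day on one grid.
#' @param max_lag_min search half-window in minutes (default 720).
#' @return One-row data frame: `lag_minutes`, `peak_correlation`,
#'   `sign_expected` (QC flag, TRUE when peak correlation is positive).
#' @export
xcorr_lag <- function(thickness_day, psi_day, max_lag_min = 720) {
  if (nrow(thickness_day) != nrow(psi_day) ||
      any(thickness_day$time != psi_day$time))
    stop("alignment error: day series are not on one grid", call. = FALSE)
  x <- series_values(thickness_day)
  y <- series_values(psi_day)
  if (stats::sd(x, na.rm = TRUE) == 0 || stats::sd(y, na.rm = TRUE) == 0 ||
      all(is.na(x)) || all(is.na(y)))
    stop("undefined-correlation error: zero-variance input", call. = FALSE)
  x <- x - mean(x, na.rm = TRUE)
  y <- y - mean(y, na.rm = TRUE)
  step_min <- as.numeric(diff(thickness_day$time[1:2]), units = "mins")
  k_max <- floor(max_lag_min / step_min)
  ks <- seq(-k_max, k_max)
  ks <- ks[order(abs(ks), ks)]          # tie-break order: |lag|, then value
  n <- length(x)
  r <- vapply(ks, function(k) {
    if (k >= 0) { xi <- x[seq_len(n - k)]; yi <- y[seq_len(n - k) + k] }
    else        { xi <- x[seq_len(n + k) - k]; yi <- y[seq_len(n + k)] }
    keep <- is.finite(xi) & is.finite(yi)
    if (sum(keep) < 3 || stats::sd(xi[keep]) == 0 || stats::sd(yi[keep]) == 0)
      return(-Inf)
    stats::cor(xi[keep], yi[keep])
  }, numeric(1))
  best <- which.max(r)
  data.frame(lag_minutes = ks[best] * step_min,
             peak_correlation = r[best],
             sign_expected = r[best] > 0)
}

#' Apparent Q10 from an exponential rate
#'
#' Multiplicative change of a response per 10 degrees C, `exp(10 k)` for an
#' exponential rate `k` per degree C.
#'
#' @param k exponential rate (per degree C).
#' @return Dimensionless Q10.
#' @export
q10_from_rate <- function(k) exp(10 * k)

#' Fit a climate response of the diurnal amplitude
#'
#' Fits the relationship between daily amplitude and one daily climate
#' predictor, matching form to predictor as in the field convention:
#' linear for global radiation, quadratic for VPD, exponential for air
#' temperature (overridable). The exponential form is fitted as
#' `amplitude = A exp(k T_A)` by log-linearization; non-positive amplitudes
#' are dropped with a warning. When the merged table has a `tree` column and
#' `scope = "pooled"`, per-tree fixed intercept offsets are included; with
#' `scope = "by_tree"` a separate fit is returned per tree.
#'
#' @param daily daily metrics table (columns `date`, `amplitude`, optionally
#'   `tree`).
#' @param climate_daily daily climate table (columns `date` and the
#'   predictor).
#' @param predictor one of `"R_G"`, `"VPD"`, `"T_A"`.
#' @param form one of `"linear"`, `"quadratic"`, `"exponential"`; default
#'   matched to the predictor.
#' @param scope `"pooled"` or `"by_tree"`.
#' @param min_days minimum number of valid merged days (default 10).
#' @return A `climate_response_fit` (or a list of them for `"by_tree"`):
#'   coefficients, `r_squared`, `n`, and for the exponential form `k` and
#'   `q10 = exp(10 k)`.
#' @export
fit_climate_response <- function(daily, climate_daily,
                                 predictor = c("R_G", "VPD", "T_A"),
                                 form = NULL, scope = c("pooled", "by_tree"),
                                 min_days = 10) {
  predictor <- match.arg(predictor)
  scope <- match.arg(scope)
  if (is.null(form))
    form <- switch(predictor, R_G = "linear", VPD = "quadratic",
                   T_A = "exponential")
  form <- match.arg(form, c("linear", "quadratic", "exponential"))
  d <- merge(daily[!is.na(daily$amplitude), , drop = FALSE], climate_daily,
             by = "date")
  if (scope == "by_tree" && "tree" %in% names(d)) {
    fits <- lapply(split(d, d$tree), function(di) {
      di$tree <- NULL
      fit_climate_response(di, climate_daily, predictor, form, "pooled",
                           min_days)
    })
    return(fits)
  }
  x <- d[[predictor]]
  amp <- d$amplitude
  has_tree <- "tree" %in% names(d) && length(unique(d$tree)) > 1
  if (form == "exponential") {
    keep <- amp > 0
    if (!all(keep))
      warning(sum(!keep), " day(s) with non-positive amplitude dropped from ",
              "exponential fit")
    d <- d[keep, , drop = FALSE]; x <- x[keep]; amp <- amp[keep]
  }
  if (nrow(d) < min_days)
    stop("need at least ", min_days, " valid days, got ", nrow(d),
         call. = FALSE)
  md <- data.frame(x = x, amp = amp)
  if (has_tree) md$tree <- factor(d$tree)
  fml <- switch(form,
    linear      = amp ~ x,
    quadratic   = amp ~ x + I(x^2),
    exponential = log(amp) ~ x)
  if (has_tree) fml <- stats::update(fml, . ~ . + tree)
  model <- stats::lm(fml, data = md)
  cf <- stats::coef(model)
  resp <- stats::model.response(stats::model.frame(model))
  tss <- sum((resp - mean(resp))^2)
  r2 <- if (tss == 0) NA_real_ else 1 - sum(stats::resid(model)^2) / tss
  out <- list(predictor = predictor, form = form, scope = scope,
              coefficients = cf, n = nrow(md),
              r_squared = r2, model = model)
  if (form == "exponential") {
    out$k <- unname(cf[["x"]])
    out$amplitude_at_zero <- unname(exp(cf[[1]]))
    out$q10 <- q10_from_rate(out$k)
  }
  if (form == "quadratic") {
    # abscissa of the vertex: where the amplitude response saturates
    out$vertex <- unname(-cf[["x"]] / (2 * cf[["I(x^2)"]]))
  }
  class(out) <- "climate_response_fit"
  out
}

#' @export
print.climate_response_fit <- function(x, ...) {
  cat(sprintf("<climate_response_fit> %s ~ %s (%s), n = %d, R2 = %.3f\n",
              "amplitude", x$predictor, x$form, x$n, x$r_squared))
  if (!is.null(x$q10)) cat(sprintf("  k = %.5f /degC, Q10 = %.3f\n",
                                   x$k, x$q10))
  if (!is.null(x$vertex)) cat(sprintf("  vertex at %s = %.3f\n",
                                      x$predictor, x$vertex))
  invisible(x)
}

#' Aggregate a 10-min climate table to daily values
#'
#' Radiation is integrated to MJ m-2 per day from W m-2 samples; VPD and
#' temperature are summarized as daily maximum and mean; rainfall is summed.
#'
#' @param climate data frame with columns `time`, `R_G` (W m-2), `T_A`,
#'   `RH`, `rainfall` (mm per sample) and optionally `VPD`.
#' @return Data frame: `date`, `R_G` (MJ m-2 d-1), `T_A` (mean, degC),
#'   `T_A_min`, `T_A_max`, `VPD` (daily max, kPa), `rainfall` (mm d-1).
#' @export
aggregate_climate_daily <- function(climate) {
  if (!"VPD" %in% names(climate))
    climate$VPD <- vpd_from_t_rh(climate$T_A, climate$RH)
  step_s <- as.numeric(diff(climate$time[1:2]), units = "secs")
  date <- as.Date(climate$time, tz = "UTC")
  agg <- function(x, f) as.numeric(tapply(x, date, f))
  data.frame(date = as.Date(names(tapply(climate$R_G, date, sum))),
             R_G = agg(climate$R_G, sum) * step_s / 1e6,
             T_A = agg(climate$T_A, mean),
             T_A_min = agg(climate$T_A, min),
             T_A_max = agg(climate$T_A, max),
             VPD = agg(climate$VPD, max),
             rainfall = agg(climate$rainfall, sum))
}
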