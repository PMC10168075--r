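#' Inner bark thickness from a dual-dendrometer pair
#'
#' The inner bark thickness is the pointwise difference between the trunk
#' (over-bark) radius and the xylem radius measured by the paired
#' dendrometers. Because both sensors share one frame, any thermal expansion
#' of the frame cancels in the difference and no temperature correction is
#' applied. A sample is unusable whenever either input is unusable.
#'
#' @param trunk_radius,xylem_radius `gridded_series` (um, relative) on one
#'   common grid.
#' @return A `gridded_series` of thickness (um, relative).
#' @export
bark_thickness <- function(trunk_radius, xylem_radius) {
  if (nrow(trunk_radius) != nrow(xylem_radius) ||
      any(trunk_radius$time != xylem_radius$time))
    stop("alignment error: trunk and xylem series are not on one grid",
         call. = FALSE)
  rank <- c(ok = 1L, interpolated = 2L, missing = 3L, discarded = 4L)
  flag <- names(rank)[pmax(rank[trunk_radius$flag], rank[xylem_radius$flag])]
  gridded_series(trunk_radius$time, trunk_radius$value - xylem_radius$value,
                 flag, unit = "um")
}

#' Remove the seasonal growth trend from a thickness series
#'
#' Seasonal-trend decomposition by loess (`stats::stl`) with a daily period
#' separates the slow trunk-growth trend from the diurnal cycle. The
#' detrended component returned is `raw - trend` (i.e. seasonal + remainder),
#' so the decomposition is exact at every usable sample: `raw = trend +
#' detrended`. Gaps are bridged by linear interpolation for the decomposition
#' only; the original flags are preserved and bridged samples stay masked.
#'
#' @param thickness a `gridded_series` (um) on the 600 s grid.
#' @param period samples per day (default 144 at 10-min cadence).
#' @param trend_window_days loess trend window in days (default 7); wide
#'   enough to leave the diurnal cycle untouched while tracking growth of a
#'   few um per day.
#' @param robust use robust loess fitting (default TRUE).
#' @return A `bark_decomposition`: list with `raw`, `trend` and `detrended`
#'   `gridded_series`.
#' @export
detrend_seasonal <- function(thickness, period = 144, trend_window_days = 7,
                             robust = TRUE) {
  v <- series_values(thickness)
  if (sum(is.finite(v)) < 3 * period)
    stop("length error: need at least 3 full periods of usable data",
         call. = FALSE)
  vfill <- zoo::na.approx(v, na.rm = FALSE)
  vfill <- zoo::na.fill(vfill, "extend")
  tw <- trend_window_days * period
  if (tw %% 2 == 0) tw <- tw + 1  # loess windows must be odd
  dec <- stats::stl(stats::ts(vfill, frequency = period),
                    s.window = "periodic", t.window = tw, robust = robust)
  trend <- as.numeric(dec$time.series[, "trend"])
  detr <- v - trend
  structure(list(
    raw = thickness,
    trend = gridded_series(thickness$time, trend, thickness$flag, unit = "um"),
    detrended = gridded_series(thickness$time, detr, thickness$flag,
                               unit = "um")),
    class = "bark_decomposition")
}

#' @export
print.bark_decomposition <- function(x, ...) {
  cat(sprintf("<bark_decomposition> %d samples, trend %.2f .. %.2f um\n",
              nrow(x$raw), min(x$trend$value, na.rm = TRUE),
              max(x$trend$value, na.rm = TRUE)))
  invisible(x)
}

#' Saturation vapour pressure of water
#'
#' Buck-type formulation, `e_s(T) = 0.61365 exp(17.502 T / (240.97 + T))`
#' kPa with `T` in degrees Celsius. The constants are fixed so results are
#' bit-reproducible.
#'
#' @param t_a air temperature (degrees C).
#' @return Saturation vapour pressure (kPa).
#' @export
saturation_vapour_pressure <- function(t_a) {
  0.61365 * exp(17.502 * t_a / (240.97 + t_a))
}

#' Vapour pressure deficit from temperature and relative humidity
#'
#' `VPD = e_s(T_A) (1 - RH/100)`, in kPa.
#'
#' @param t_a air temperature (degrees C).
#' @param rh relative humidity (percent, in `[0, 100]`).
#' @return VPD (kPa), same length as the inputs.
#' @export
vpd_from_t_rh <- function(t_a, rh) {
  if (any(rh < 0 | rh > 100, na.rm = TRUE))
    stop("domain error: RH must be within [0, 100]", call. = FALSE)
  saturation_vapour_pressure(t_a) * (1 - rh / 100)
}
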