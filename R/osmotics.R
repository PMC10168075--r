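#' Phloem hydrostatic pressure from osmolality and xylem water potential
#'
#' Van 't Hoff estimate: `P_H = psi_X + C_S R T`, with the sap osmolality
#' `C_S` (mol/kg) taken as the osmotic concentration in mol/L (no density
#' correction), `R = 0.008314` L MPa mol-1 K-1, and `T` in Kelvin. The
#' default `T = 298.15` K matches osmometer operation at 25 degrees C.
#'
#' @param psi_x xylem water potential at sampling (MPa, <= 0).
#' @param osmolality sap osmolality (mol/kg), > 0.
#' @param temperature temperature (K), default 298.15.
#' @param gas_constant L MPa mol-1 K-1, default 0.008314.
#' @return Data frame with `psi_term`, `osmotic_term` and `P_H` (MPa).
#' @export
hydrostatic_pressure <- function(psi_x, osmolality, temperature = 298.15,
                                 gas_constant = 0.008314) {
  if (any(temperature <= 0)) stop("domain error: temperature must be > 0 K",
                                  call. = FALSE)
  osm <- osmolality * gas_constant * temperature
  data.frame(psi_term = psi_x, osmotic_term = osm, P_H = psi_x + osm)
}

#' Axial gradient between trunk positions
#'
#' Difference of a matched pair of values measured at the upper and lower
#' trunk positions, sign convention upper minus lower (positive = downward-
#' driving gradient).
#'
#' @param upper,lower values at the two positions (same unit).
#' @return `upper - lower`.
#' @export
axial_gradient <- function(upper, lower) {
  if (length(upper) != length(lower))
    stop("pairing error: upper and lower are not matched", call. = FALSE)
  upper - lower
}

#' Linear regression of hydrostatic pressure on xylem water potential
#'
#' Ordinary least squares of `P_H` on `psi_X` with the coefficient of
#' determination.
#'
#' @param psi_x xylem water potential (MPa).
#' @param p_h hydrostatic pressure (MPa).
#' @return List with `slope`, `intercept`, `r_squared`, `n` and the `lm`
#'   object.
#' @export
fit_ph_vs_psi <- function(psi_x, p_h) {
  keep <- is.finite(psi_x) & is.finite(p_h)
  psi_x <- psi_x[keep]; p_h <- p_h[keep]
  if (length(psi_x) < 3)
    stop("need at least 3 points", call. = FALSE)
  if (stats::sd(psi_x) == 0)
    stop("singular error: all psi_x identical", call. = FALSE)
  m <- stats::lm(p_h ~ psi_x)
  cf <- stats::coef(m)
  tss <- sum((p_h - mean(p_h))^2)
  r2 <- if (tss == 0) NA_real_ else 1 - sum(stats::resid(m)^2) / tss
  list(slope = unname(cf[2]), intercept = unname(cf[1]),
       r_squared = r2, n = length(psi_x), model = m)
}

#' Xylem water potential at which phloem pressure vanishes
#'
#' Zero crossing of the fitted line `P_H = intercept + slope psi_X`:
#' `psi = -intercept / slope`.
#'
#' @param slope,intercept regression coefficients (`slope != 0`).
#' @return Xylem water potential (MPa) at zero turgor.
#' @export
zero_turgor_psi <- function(slope, intercept) {
  if (slope == 0) stop("domain error: zero slope", call. = FALSE)
  -intercept / slope
}

#' Volume-equivalent radius change across stem diameters
#'
#' For a thin annulus, the water volume per unit stem length corresponding
#' to a radius change scales as diameter times the change, so a change
#' `delta_r` at diameter `d_source` is volume-equivalent to
#' `delta_r d_source / d_target` at diameter `d_target`.
#'
#' @param delta_r radius change (um).
#' @param d_source,d_target stem diameters (cm), > 0.
#' @return Equivalent radius change (um) at `d_target`.
#' @export
equivalent_radius_change <- function(delta_r, d_source, d_target) {
  if (any(d_source <= 0) || any(d_target <= 0))
    stop("domain error: diameters must be positive", call. = FALSE)
  delta_r * d_source / d_target
}

#' Bulk elastic modulus implied by a water-potential drop
#'
#' If a diurnal water-potential drop `delta_psi` accompanies a relative
#' change in tissue water content `w`, the implied bulk elastic modulus is
#' `|delta_psi| / w` (e.g. a 0.6 MPa drop at a 4 percent water change gives
#' 15 MPa).
#'
#' @param delta_psi water-potential drop (MPa, sign ignored).
#' @param relative_water_change fractional water change, > 0.
#' @return Modulus (MPa).
#' @export
bulk_elastic_modulus <- function(delta_psi, relative_water_change) {
  if (any(relative_water_change <= 0))
    stop("domain error: relative water change must be positive",
         call. = FALSE)
  abs(delta_psi) / relative_water_change
}

#' Read an osmotic-sample table from delimited text
#'
#' Expects columns `tree`, `date`, `time_class` (`dawn` or
#' `early_afternoon`), `position` (`upper` or `lower`), `osmolality`
#' (mol/kg), `water_content` (g/g) and `psi_x` (MPa at sampling).
#'
#' @param path file path (comma- or tab-delimited, header row).
#' @return Data frame of samples.
#' @export
read_osmotic_samples <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                          stringsAsFactors = FALSE)
  need <- c("tree", "date", "time_class", "position", "osmolality",
            "water_content", "psi_x")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("format error: missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$date <- as.Date(df$date)
  stopifnot(all(df$time_class %in% c("dawn", "early_afternoon")),
            all(df$position %in% c("upper", "lower")),
            all(df$osmolality > 0))
  df
}

#' Summarize osmotic samples by date, time of day and position
#'
#' Cell means and standard deviations of water content, osmolality and the
#' hydrostatic pressure; pressure is computed per sample from that sample's
#' concurrent xylem water potential, then averaged.
#'
#' @param samples data frame as returned by [read_osmotic_samples()] or
#'   [simulate_osmotic_samples()].
#' @param temperature temperature (K) for the van 't Hoff term.
#' @return Data frame with one row per date x time_class x position cell.
#' @export
summarize_osmotics <- function(samples, temperature = 298.15) {
  samples$P_H <- hydrostatic_pressure(samples$psi_x, samples$osmolality,
                                      temperature)$P_H
  key <- interaction(samples$date, samples$time_class, samples$position,
                     drop = TRUE)
  cells <- split(samples, key)
  out <- do.call(rbind, lapply(cells, function(d) {
    sd_or_na <- function(x) if (length(x) > 1) stats::sd(x) else NA_real_
    data.frame(date = d$date[1], time_class = d$time_class[1],
               position = d$position[1], n = nrow(d),
               water_content_mean = mean(d$water_content),
               water_content_sd = sd_or_na(d$water_content),
               osmolality_mean = mean(d$osmolality),
               osmolality_sd = sd_or_na(d$osmolality),
               pressure_mean = mean(d$P_H),
               pressure_sd = sd_or_na(d$P_H),
               single_sample = nrow(d) == 1L)
  }))
  rownames(out) <- NULL
  out[order(out$date, out$time_class, out$position), , drop = FALSE]
}

#' Axial gradients from an osmotics summary
#'
#' Upper-minus-lower differences of mean osmolality and mean hydrostatic
#' pressure for every date x time-of-day cell present at both positions.
#'
#' @param summary data frame from [summarize_osmotics()] (or the reference
#'   survey, [osmolality_reference()]).
#' @return Data frame: `date`, `time_class`, `osmolality_gradient`
#'   (mol/kg), `pressure_gradient` (MPa).
#' @export
osmotic_gradients <- function(summary) {
  up <- summary[summary$position == "upper", , drop = FALSE]
  lo <- summary[summary$position == "lower", , drop = FALSE]
  m <- merge(up, lo, by = c("date", "time_class"),
             suffixes = c("_upper", "_lower"))
  data.frame(date = m$date, time_class = m$time_class,
             osmolality_gradient = axial_gradient(m$osmolality_mean_upper,
                                                  m$osmolality_mean_lower),
             pressure_gradient = axial_gradient(m$pressure_mean_upper,
                                                m$pressure_mean_lower))
}

#' Reference inner-bark osmotic survey (hinoki cypress)
#'
#' Published summary of a field survey on three mature hinoki cypress
#' (*Chamaecyparis obtusa*) trunks: inner-bark water content, sap osmolality
#' and derived hydrostatic pressure (cell means with standard deviations of
#' two samples on three trees) by sampling date, time of day (dawn / early
#' afternoon) and trunk position (upper / lower), together with the day's
#' local climate. Shipped as plain text under `extdata`.
#'
#' @return Data frame with one row per date x time x position cell.
#' @export
osmolality_reference <- function() {
  path <- system.file("extdata", "hinoki_osmotic_survey.csv",
                      package = "innerbark", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$date <- as.Date(df$date)
  df
}
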