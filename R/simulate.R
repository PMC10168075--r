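#' Derive a substream seed
#'
#' One global seed fans out to per-stream seeds so adding a stream never
#' perturbs the others. All generators are pure functions of
#' (parameters, seed).
#'
#' @param seed integer master seed.
#' @param id integer stream identifier.
#' @return Integer seed below 2^31.
#' @export
stream_seed <- function(seed, id) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(id)
}

day_hours <- function(time) {
  as.numeric(difftime(time, trunc(time, "days"), units = "hours"))
}

#' Simulate a climate record on the 10-min grid
#'
#' Emulates warm-season field conditions: a truncated-sinusoid clear-sky
#' radiation course scaled by a per-day cloudiness multiplier, air
#' temperature lagging radiation (daily peak at 14:00), relative humidity in
#' anti-phase with temperature, occasional rain days, and VPD derived from
#' temperature and humidity. Clear days integrate to roughly 25 MJ m-2 d-1
#' and produce afternoon VPD up to about 3 kPa.
#'
#' @param days number of days (>= 1).
#' @param seed integer seed; output is bit-identical per seed.
#' @param start_date first day (default `"2019-08-01"`).
#' @param weather list of knobs: `p_rain`, `p_cloud` (day-type
#'   probabilities), `s_max` (clear-sky peak, W m-2), `t_base` (seasonal
#'   mean temperature, degC), `rh_night` (nocturnal RH, percent).
#' @return Data frame: `time`, `R_G` (W m-2), `T_A` (degC), `RH` (percent),
#'   `rainfall` (mm per 10 min), `VPD` (kPa); day states in attribute
#'   `"day_state"`.
#' @export
simulate_climate <- function(days, seed, start_date = "2019-08-01",
                             weather = list()) {
  stopifnot(days >= 1)
  w <- utils::modifyList(list(p_rain = 0.15, p_cloud = 0.25, s_max = 900,
                              t_base = 24, rh_night = 95), weather)
  set.seed(stream_seed(seed, 1L))
  t0 <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC")
  time <- t0 + seq(0, days * 86400 - 600, by = 600)
  h <- day_hours(time)
  day <- rep(seq_len(days), each = 144)

  u <- stats::runif(days)
  rain <- u < w$p_rain
  cloudy <- !rain & u < w$p_rain + w$p_cloud
  m <- ifelse(rain, stats::runif(days, 0.05, 0.2),
              ifelse(cloudy, stats::runif(days, 0.3, 0.7),
                     stats::runif(days, 0.85, 1)))
  t_anom <- as.numeric(stats::filter(stats::rnorm(days, 0, 1.5), 0.7,
                                     method = "recursive"))
  t_mean <- w$t_base - 4 * (1 - m) + t_anom
  t_amp <- 3 + 5 * m
  rh_min <- pmin(98, pmax(20, w$rh_night - 62 * m + stats::rnorm(days, 0, 4)))
  rain_mm <- ifelse(rain, stats::runif(days, 2, 30), 0)

  r_g <- m[day] * w$s_max * pmax(0, sin(pi * (h - 6) / 12))
  t_a <- t_mean[day] + t_amp[day] * cos(2 * pi * (h - 14) / 24)
  # RH tracks temperature in anti-phase between its nocturnal and daily
  # minimum levels
  frac <- (1 - cos(2 * pi * (h - 14) / 24)) / 2   # 1 at 02:00, 0 at 14:00
  rh <- rh_min[day] + (w$rh_night - rh_min[day]) * frac
  rh <- pmin(100, pmax(0, rh + stats::rnorm(length(rh), 0, 1)))

  rainfall <- numeric(length(time))
  for (d in which(rain)) {
    slots <- sample(which(day == d), size = sample(3:12, 1))
    rainfall[slots] <- rainfall[slots] + rain_mm[d] / length(slots)
  }
  out <- data.frame(time = time, R_G = r_g, T_A = t_a, RH = rh,
                    rainfall = rainfall,
                    VPD = vpd_from_t_rh(t_a, rh))
  attr(out, "day_state") <- data.frame(day = seq_len(days), rain = rain,
                                       cloudy = cloudy, cloud_mult = m,
                                       rain_mm = rain_mm)
  out
}

#' Simulate xylem water potential from climate
#'
#' Transpiration demand pulls the xylem water potential toward a target
#' `-min(0.95, a_d (VPD/3) sqrt(R_G / s_max))` through a first-order lag
#' (relaxing back toward 0 at night when the target vanishes), with a
#' per-day lognormal gain `a_d` representing day-to-day variation in
#' stomatal behaviour, plus small Gaussian measurement noise. Values are
#' clipped to `[-1, 0]` MPa: daily minima never drop below -1 MPa and daily
#' maxima stay close to 0.
#'
#' @param climate data frame from [simulate_climate()].
#' @param coupling list of knobs: `gain` (mean demand gain), `day_sd`
#'   (lognormal sd of the per-day gain), `tau_min` (lag time constant,
#'   minutes), `noise_sd` (MPa), `s_max` (W m-2).
#' @param seed integer seed.
#' @return A `gridded_series` (MPa) on the climate grid.
#' @export
simulate_psi <- function(climate, coupling = list(), seed = 1) {
  k <- utils::modifyList(list(gain = 0.9, day_sd = 0.25, tau_min = 60,
                              noise_sd = 0.01, s_max = 900), coupling)
  set.seed(stream_seed(seed, 2L))
  n <- nrow(climate)
  day <- rep(seq_len(ceiling(n / 144)), each = 144)[seq_len(n)]
  a_d <- k$gain * exp(stats::rnorm(max(day), 0, k$day_sd))
  target <- -pmin(0.95, a_d[day] * (climate$VPD / 3) *
                    sqrt(pmax(0, climate$R_G) / k$s_max))
  lambda <- 10 / k$tau_min                 # per 10-min step
  psi <- numeric(n)
  for (t in seq_len(n - 1L))
    psi[t + 1L] <- psi[t] + lambda * (target[t] - psi[t])
  psi <- psi + stats::rnorm(n, 0, k$noise_sd)
  psi <- pmin(0, pmax(-1, psi))
  s <- gridded_series(climate$time, psi, unit = "MPa")
  attr(s, "day_gain") <- a_d
  s
}

#' Diurnal turgor waveform
#'
#' Daily-periodic waveform of the injected turgor contribution to inner
#' bark thickness, normalized to `[0, amplitude]` (so the daily amplitude
#' max - min equals `amplitude`). The default `night_rise` shape increases
#' from 19:00 through the night to a maximum at 09:30, fluctuates mildly
#' around the plateau during the day, and declines in the late afternoon.
#'
#' @param hours clock hours in `[0, 24)`.
#' @param amplitude waveform amplitude (um).
#' @param shape `"night_rise"`, `"sinusoid"` or `"ramp_plateau"`.
#' @return Numeric vector, same length as `hours`.
#' @export
turgor_waveform <- function(hours, amplitude,
                            shape = c("night_rise", "sinusoid",
                                      "ramp_plateau")) {
  shape <- match.arg(shape)
  h <- hours %% 24
  w <- switch(shape,
    night_rise = {
      out <- numeric(length(h))
      rise <- h >= 19 | h < 9.5
      u <- ifelse(h[rise] >= 19, h[rise] - 19, h[rise] + 5) / 14.5
      out[rise] <- 0.5 * (1 - cos(pi * u))
      plateau <- h >= 9.5 & h < 16
      u2 <- (h[plateau] - 9.5) / 6.5
      out[plateau] <- 1 - 0.05 * (1 - cos(2 * pi * u2))
      fall <- h >= 16 & h < 19
      u3 <- (h[fall] - 16) / 3
      out[fall] <- 0.5 * (1 + cos(pi * u3))
      out
    },
    sinusoid = 0.5 * (1 + cos(2 * pi * (h - 9.5) / 24)),
    ramp_plateau = {
      out <- numeric(length(h))
      rise <- h >= 20 | h < 10
      out[rise] <- ifelse(h[rise] >= 20, h[rise] - 20, h[rise] + 4) / 14
      plateau <- h >= 10 & h < 17
      out[plateau] <- 1
      fall <- h >= 17 & h < 20
      out[fall] <- 1 - (h[fall] - 17) / 3
      out
    })
  amplitude * w
}

#' Ground-truth parameters for a simulated sensor pair
#'
#' Defaults reproduce the study conditions: radial conductance alpha*beta of
#' 4.8 um MPa-1 step-1 at the upper position and 1.8 at the lower (8e-9 and
#' 3e-9 m MPa-1 s-1 in SI units), turgor-waveform amplitudes of 38 um
#' (upper) and 18 um (lower), trunk growth of a few um per day, AR(1)
#' observation noise at the 0.022 um sensor resolution floor.
#'
#' @param position `"upper"` or `"lower"`.
#' @param ... overrides for any truth field.
#' @return List of truth parameters.
#' @export
simulation_truth <- function(position = c("upper", "lower"), ...) {
  position <- match.arg(position)
  base <- if (position == "upper")
    list(alpha = 0.08, beta = 60, turgor_amplitude = 38, growth_um_day = 5)
  else
    list(alpha = 0.06, beta = 30, turgor_amplitude = 18, growth_um_day = 3)
  truth <- utils::modifyList(c(base, list(
    gamma = 0, phi = 0.6, sigma = 0.022,
    turgor_shape = "night_rise",
    baseline_um = 3000,
    xylem_coef_um_mpa = 12, xylem_sigma = 0.15, xylem_phi = 0.3,
    position = position)), list(...))
  truth$alpha_beta <- truth$alpha * truth$beta
  truth
}

ar1_noise <- function(n, phi, sigma) {
  if (sigma == 0) return(numeric(n))
  innov_sd <- sigma * sqrt(1 - phi^2)
  as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), phi,
                           method = "recursive"))
}

#' Simulate a dual-dendrometer pair from xylem water potential
#'
#' Integrates the capacitor recursion
#' `h(t+1) = h(t) + alpha (beta psi(t) - h(t))` to obtain the water-exchange
#' component of inner bark thickness, adds the daily turgor waveform, a
#' linear growth ramp and AR(1) observation noise; the xylem radius carries
#' its own small diurnal signal proportional to psi plus noise; the trunk
#' radius is their sum.
#'
#' @param psi a `gridded_series` of xylem water potential (MPa).
#' @param truth truth list from [simulation_truth()].
#' @param seed integer seed.
#' @return List: `trunk`, `xylem` (`gridded_series`, um), `psi`, `truth`,
#'   and the injected components `thickness_capacitor`, `turgor_true`
#'   (numeric vectors).
#' @export
simulate_dendrometer_pair <- function(psi, truth, seed = 1) {
  set.seed(stream_seed(seed, 3L))
  p <- series_values(psi)
  n <- length(p)
  h <- numeric(n)
  for (t in seq_len(n - 1L))
    h[t + 1L] <- h[t] + truth$alpha * (truth$beta * p[t] - h[t]) +
      truth$gamma
  s <- turgor_waveform(day_hours(psi$time), truth$turgor_amplitude,
                       truth$turgor_shape)
  t_days <- as.numeric(difftime(psi$time, psi$time[1], units = "days"))
  growth <- truth$growth_um_day * t_days
  noise <- ar1_noise(n, truth$phi, truth$sigma)
  thickness <- truth$baseline_um + h + s + growth + noise

  xylem <- truth$xylem_coef_um_mpa * p +
    ar1_noise(n, truth$xylem_phi, truth$xylem_sigma)
  trunk <- xylem + thickness
  list(trunk = gridded_series(psi$time, trunk, unit = "um"),
       xylem = gridded_series(psi$time, xylem, unit = "um"),
       psi = psi, truth = truth,
       thickness_capacitor = h, turgor_true = s)
}

#' Simulate an osmotic-sample campaign
#'
#' Draws inner-bark sap osmolality around position- and season-specific
#' means (upper above lower; winter above summer), with the concurrent
#' xylem water potential read off the simulated psi series at the sampling
#' time (dawn 05:30 or early afternoon 14:00), two replicates per tree.
#'
#' @param psi_by_position list with `upper` and `lower` psi
#'   `gridded_series`.
#' @param dates sampling dates (within the simulated span).
#' @param seed integer seed.
#' @param profile list of osmolality means: `upper_summer`, `lower_summer`,
#'   `winter_boost_upper`, `winter_boost_lower` (mol/kg).
#' @param replicate_sd replicate-level osmolality sd (mol/kg).
#' @param trees tree identifiers.
#' @return Data frame of samples (columns as [read_osmotic_samples()]).
#' @export
simulate_osmotic_samples <- function(psi_by_position, dates, seed = 1,
                                     profile = list(), replicate_sd = 0.04,
                                     trees = 1:3) {
  pr <- utils::modifyList(list(upper_summer = 0.46, lower_summer = 0.39,
                               winter_boost_upper = 0.14,
                               winter_boost_lower = 0.08), profile)
  set.seed(stream_seed(seed, 4L))
  dates <- as.Date(dates)
  grid <- expand.grid(rep = 1:2, tree = trees,
                      position = c("upper", "lower"),
                      time_class = c("dawn", "early_afternoon"),
                      date = dates, stringsAsFactors = FALSE)
  clock <- ifelse(grid$time_class == "dawn", "05:30:00", "14:00:00")
  when <- as.POSIXct(paste(grid$date, clock), tz = "UTC")
  psi_at <- function(pos, tm) {
    s <- psi_by_position[[pos]]
    idx <- match(tm, s$time)
    if (anyNA(idx))
      stop("sampling date outside the simulated span", call. = FALSE)
    series_values(s)[idx]
  }
  winter <- as.integer(format(grid$date, "%m")) %in% c(11, 12, 1, 2)
  mu <- ifelse(grid$position == "upper",
               pr$upper_summer + winter * pr$winter_boost_upper,
               pr$lower_summer + winter * pr$winter_boost_lower)
  osm <- stats::rnorm(nrow(grid), mu, replicate_sd)
  osm <- pmax(osm, 0.05)
  psi_x <- vapply(seq_len(nrow(grid)),
                  function(i) psi_at(grid$position[i], when[i]), numeric(1))
  data.frame(tree = grid$tree, date = grid$date,
             time_class = grid$time_class, position = grid$position,
             osmolality = osm,
             water_content = pmax(0.5, stats::rnorm(nrow(grid), 1.4, 0.15)),
             psi_x = psi_x)
}

format_precise <- function(df) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && !inherits(df[[nm]], c("Date", "POSIXct")))
      df[[nm]] <- ifelse(is.na(df[[nm]]), "NA", sprintf("%.17g", df[[nm]]))
    if (inherits(df[[nm]], "POSIXct"))
      df[[nm]] <- format(df[[nm]], "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  }
  df
}

write_table_precise <- function(df, path) {
  utils::write.table(format_precise(df), path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a complete synthetic field-campaign fixture
#'
#' Generates and writes the full input file set for the pipeline — climate,
#' per-sensor-pair trunk/xylem/psi series, osmotic samples — together with
#' a JSON truth manifest. Deterministic per seed. Kinds:
#' \describe{
#'   \item{`tiny`}{4 days, 1 tree, 2 positions — the smallest bundle the
#'     full pipeline (whose decomposition needs 3 daily periods) can run.}
#'   \item{`campaign`}{9 days, 3 trees, 2 positions.}
#'   \item{`stress`}{16 days, 2 trees, 2 positions, rain-heavy weather,
#'     sensor dropouts and a discarded interval.}
#' }
#'
#' @param kind fixture kind.
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @return Invisibly, a list with `files`, `truth` and `dir`.
#' @export
make_fixture <- function(kind = c("tiny", "campaign", "stress"),
                         seed = 1, dir = tempfile("fixture")) {
  kind <- match.arg(kind)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- switch(kind,
    tiny = list(days = 4, trees = 1, weather = list()),
    campaign = list(days = 9, trees = 1:3, weather = list()),
    stress = list(days = 16, trees = 1:2,
                  weather = list(p_rain = 0.45, p_cloud = 0.35)))
  climate <- simulate_climate(spec$days, seed, weather = spec$weather)
  files <- list(climate = file.path(dir, "climate.csv"))
  write_table_precise(climate, files$climate)

  truth <- list(seed = seed, kind = kind, days = spec$days, pairs = list())
  pair_id <- 0L
  for (tree in spec$trees) {
    for (pos in c("upper", "lower")) {
      pair_id <- pair_id + 1L
      psi <- simulate_psi(climate, seed = stream_seed(seed, 10L + pair_id))
      tr <- simulation_truth(pos)
      pair <- simulate_dendrometer_pair(
        psi, tr, seed = stream_seed(seed, 50L + pair_id))
      trunk <- pair$trunk; xylem <- pair$xylem; psi_out <- psi
      if (kind == "stress") {
        # sensor dropout: delete a block of rows from the raw files
        set.seed(stream_seed(seed, 90L + pair_id))
        i0 <- sample(seq_len(nrow(trunk) - 160L), 1)
        drop <- seq(i0, i0 + sample(6:144, 1))
        trunk <- trunk[-drop, , drop = FALSE]
        class(trunk) <- c("gridded_series", "data.frame")
        attr(trunk, "unit") <- "um"
      }
      base <- sprintf("tree%d_%s", tree, pos)
      f <- list(trunk = file.path(dir, paste0(base, "_trunk.csv")),
                xylem = file.path(dir, paste0(base, "_xylem.csv")),
                psi = file.path(dir, paste0(base, "_psi.csv")))
      write_series(trunk, f$trunk)
      write_series(xylem, f$xylem)
      write_series(psi_out, f$psi)
      files[[base]] <- f
      truth$pairs[[base]] <- c(tr[c("alpha", "beta", "gamma", "phi",
                                    "sigma", "alpha_beta",
                                    "turgor_amplitude", "growth_um_day")],
                               list(tree = tree, position = pos))
    }
  }
  dates <- series_dates(
    gridded_series(climate$time, climate$T_A, unit = "degC"))
  samp_dates <- dates[c(2, length(dates) - 1)]
  psi_ref <- list(
    upper = simulate_psi(climate, seed = stream_seed(seed, 11L)),
    lower = simulate_psi(climate, seed = stream_seed(seed, 12L)))
  samples <- simulate_osmotic_samples(psi_ref, samp_dates,
                                      seed = stream_seed(seed, 5L),
                                      trees = spec$trees)
  files$osmotics <- file.path(dir, "osmotic_samples.csv")
  write_table_precise(samples, files$osmotics)

  files$truth <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, files$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(files = files, truth = truth, dir = dir))
}
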