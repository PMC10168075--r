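#' Default pipeline configuration
#'
#' Every knob of every stage with its documented default: grid cadence and
#' gap rule, decomposition windows, daily-metric validity threshold and lag
#' search window, fit minimum length, rainy-day pre-filter and rejection
#' thresholds, and the van 't Hoff temperature. A configuration passed to
#' [run_pipeline()] may override any subset; unknown keys are rejected
#' before any computation.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    input = list(dir = NULL),
    output = list(dir = NULL),
    seed = 1,
    grid = list(interval_s = 600, max_gap_s = 1800),
    stl = list(period = 144, trend_window_days = 7, robust = TRUE),
    metrics = list(min_valid_frac = 0.8, max_lag_min = 720),
    fit = list(min_steps = 48, rain_mm_threshold = 1,
               reject = default_fit_criteria()),
    osmotics = list(temperature_k = 298.15))
}

check_config_keys <- function(cfg, ref, path = "") {
  extra <- setdiff(names(cfg), names(ref))
  if (length(extra))
    stop("validation error: unknown config key(s): ",
         paste0(path, extra, collapse = ", "), call. = FALSE)
  for (nm in names(cfg))
    if (is.list(cfg[[nm]]) && is.list(ref[[nm]]))
      check_config_keys(cfg[[nm]], ref[[nm]], paste0(path, nm, "."))
  invisible(TRUE)
}

#' Validate and complete a pipeline configuration
#'
#' @param config partial configuration list (or path to a YAML file).
#' @return Full configuration merged over [default_config()].
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  ref <- default_config()
  check_config_keys(config, ref)
  utils::modifyList(ref, config)
}

read_fixture_climate <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$time <- parse_iso_times(df$time)
  if (!"VPD" %in% names(df)) df$VPD <- vpd_from_t_rh(df$T_A, df$RH)
  df
}

day_slice_complete <- function(s, date, n = 144L) {
  d0 <- as.POSIXct(paste(as.Date(date), "00:00:00"), tz = "UTC")
  idx <- s$time >= d0 & s$time < d0 + 86400
  sum(idx) == n && !anyNA(series_values(s)[idx])
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline on a fixture directory
#'
#' Executes regularize, thickness derivation, seasonal detrending, daily
#' metrics and lag extraction, rainy-day filtering, per-day exchange-model
#' fits with acceptance rules and turgor-signal extraction, and the osmotics
#' summary, over every sensor pair found in the input directory (layout as
#' written by [make_fixture()]). All tabular outputs plus a JSON run
#' manifest (config, input file hashes, per-stage counts) are written to the
#' output directory; reruns with identical config and inputs are
#' byte-identical.
#'
#' @param config configuration list or YAML path; must set `input$dir`
#'   (and optionally `output$dir`).
#' @return Invisibly, the result bundle: `daily_metrics`, `lags`, `fits`,
#'   `turgor`, `osmotic_summary`, `osmotic_gradients`, `climate_daily`,
#'   `config`, `manifest`.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  in_dir <- cfg$input$dir
  if (is.null(in_dir) || !dir.exists(in_dir))
    stop("validation error: input$dir does not exist", call. = FALSE)
  out_dir <- cfg$output$dir
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  climate <- stage("climate", read_fixture_climate(
    file.path(in_dir, "climate.csv")))
  climate_daily <- stage("climate", aggregate_climate_daily(climate))
  rainy_dates <- climate_daily$date[
    climate_daily$rainfall > cfg$fit$rain_mm_threshold]

  pair_files <- list.files(in_dir, pattern = "^tree[0-9]+_(upper|lower)_trunk\\.csv$")
  if (!length(pair_files))
    stop("validation error: no sensor-pair files in ", in_dir, call. = FALSE)
  pairs <- sub("_trunk\\.csv$", "", pair_files)

  metrics_all <- list(); lags_all <- list(); fits_all <- list()
  turgor_all <- list()
  for (pb in pairs) {
    tree <- as.integer(sub("^tree([0-9]+)_.*$", "\\1", pb))
    pos <- sub("^tree[0-9]+_", "", pb)
    trunk <- stage(paste0(pb, "/read"), regularize(
      read_series(file.path(in_dir, paste0(pb, "_trunk.csv")), "value",
                  unit = "um"),
      cfg$grid$interval_s, cfg$grid$max_gap_s))
    xylem <- stage(paste0(pb, "/read"), regularize(
      read_series(file.path(in_dir, paste0(pb, "_xylem.csv")), "value",
                  unit = "um"),
      cfg$grid$interval_s, cfg$grid$max_gap_s))
    psi <- stage(paste0(pb, "/read"), regularize(
      read_series(file.path(in_dir, paste0(pb, "_psi.csv")), "value",
                  unit = "MPa"),
      cfg$grid$interval_s, cfg$grid$max_gap_s))
    # align on the intersection grid
    t_common <- Reduce(intersect, list(as.numeric(trunk$time),
                                       as.numeric(xylem$time),
                                       as.numeric(psi$time)))
    keep_gs <- function(s) {
      out <- s[as.numeric(s$time) %in% t_common, , drop = FALSE]
      attr(out, "unit") <- series_unit(s)
      class(out) <- c("gridded_series", "data.frame")
      out
    }
    trunk <- keep_gs(trunk); xylem <- keep_gs(xylem); psi <- keep_gs(psi)
    th <- stage(paste0(pb, "/thickness"), bark_thickness(trunk, xylem))
    dec <- stage(paste0(pb, "/detrend"), detrend_seasonal(
      th, cfg$stl$period, cfg$stl$trend_window_days, cfg$stl$robust))
    det <- dec$detrended

    dm <- stage(paste0(pb, "/metrics"), daily_metrics(
      det, min_valid_frac = cfg$metrics$min_valid_frac))
    dm$tree <- tree; dm$position <- pos
    metrics_all[[pb]] <- dm

    for (d in as.list(series_dates(det))) {
      if (!day_slice_complete(det, d) || !day_slice_complete(psi, d)) next
      lg <- stage(paste0(pb, "/lag"), xcorr_lag(
        series_day(det, d), series_day(psi, d), cfg$metrics$max_lag_min))
      lg <- cbind(data.frame(tree = tree, position = pos, date = as.Date(d)),
                  lg)
      lags_all[[paste(pb, d)]] <- lg

      if (as.Date(d) %in% rainy_dates) {
        fits_all[[paste(pb, d)]] <- data.frame(
          tree = tree, position = pos, date = as.Date(d),
          alpha = NA_real_, beta = NA_real_, gamma = NA_real_,
          phi = NA_real_, alpha_beta = NA_real_, alpha_beta_si = NA_real_,
          accepted = FALSE, reason = "rainy day",
          prediction_r2 = NA_real_, turgor_amplitude = NA_real_)
        next
      }
      res <- stage(paste0(pb, "/fit ", format(as.Date(d))), fit_exchange_day(
        series_day(det, d), series_day(psi, d),
        criteria = cfg$fit$reject, min_steps = cfg$fit$min_steps))
      fits_all[[paste(pb, d)]] <- data.frame(
        tree = tree, position = pos, date = as.Date(d),
        alpha = res$fit$alpha, beta = res$fit$beta, gamma = res$fit$gamma,
        phi = res$fit$phi, alpha_beta = res$fit$alpha_beta,
        alpha_beta_si = radial_conductance_si(res$fit$alpha_beta),
        accepted = res$accepted, reason = res$reason,
        prediction_r2 = res$prediction_r2,
        turgor_amplitude = if (res$accepted) res$turgor$amplitude
                           else NA_real_)
      if (res$accepted)
        turgor_all[[paste(pb, d)]] <- data.frame(
          tree = tree, position = pos, date = as.Date(d),
          time = res$turgor$time, turgor_um = res$turgor$series)
    }
  }

  osm_path <- file.path(in_dir, "osmotic_samples.csv")
  osmotic_summary <- NULL; osmotic_grad <- NULL
  if (file.exists(osm_path)) {
    samples <- stage("osmotics", read_osmotic_samples(osm_path))
    osmotic_summary <- stage("osmotics", summarize_osmotics(
      samples, cfg$osmotics$temperature_k))
    osmotic_grad <- stage("osmotics", osmotic_gradients(osmotic_summary))
  }

  bundle <- list(
    daily_metrics = do.call(rbind, metrics_all),
    lags = do.call(rbind, lags_all),
    fits = do.call(rbind, fits_all),
    turgor = do.call(rbind, turgor_all),
    osmotic_summary = osmotic_summary,
    osmotic_gradients = osmotic_grad,
    climate_daily = climate_daily,
    config = cfg)
  for (nm in c("daily_metrics", "lags", "fits", "turgor"))
    if (!is.null(bundle[[nm]])) rownames(bundle[[nm]]) <- NULL

  inputs <- list.files(in_dir, full.names = TRUE)
  # manifest must be reproducible across runs regardless of where the
  # bundle lands: identify inputs by content hash, not by path
  cfg_manifest <- cfg
  cfg_manifest$input$dir <- NULL
  cfg_manifest$output$dir <- NULL
  bundle$manifest <- list(
    config = cfg_manifest,
    inputs = stats::setNames(as.vector(tools::md5sum(inputs)),
                             basename(inputs)),
    counts = list(
      pairs = length(pairs),
      days_with_metrics = sum(bundle$daily_metrics$valid, na.rm = TRUE),
      fits_total = if (is.null(bundle$fits)) 0L else nrow(bundle$fits),
      fits_accepted = if (is.null(bundle$fits)) 0L
                      else sum(bundle$fits$accepted),
      rejections = if (is.null(bundle$fits)) character(0)
                   else table(bundle$fits$reason[!bundle$fits$accepted])))

  if (!is.null(out_dir)) {
    for (nm in c("daily_metrics", "lags", "fits", "turgor",
                 "osmotic_summary", "osmotic_gradients", "climate_daily"))
      if (!is.null(bundle[[nm]]))
        write_table_precise(bundle[[nm]], file.path(out_dir,
                                                    paste0(nm, ".csv")))
    jsonlite::write_json(bundle$manifest,
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  invisible(bundle)
}

fmt_or_na <- function(x, fmt = "%.2f") {
  if (length(x) == 0 || all(is.na(x))) "n/a" else sprintf(fmt, x)
}

#' Human-readable summary of a pipeline result bundle
#'
#' One markdown report with the per-position amplitude medians, the median
#' lag, accepted-fit counts and rejection reasons, radial-conductance
#' medians in SI units, turgor-signal amplitude medians, and the osmotics
#' summary with axial gradients. Regenerating the report from the same
#' bundle yields identical text.
#'
#' @param bundle result of [run_pipeline()].
#' @return Character vector of report lines.
#' @export
report_summary <- function(bundle) {
  lines <- c("# Inner bark diurnal dynamics: run summary", "")
  dm <- bundle$daily_metrics
  lines <- c(lines, "## Diurnal amplitude (um) by position")
  for (pos in c("upper", "lower")) {
    a <- dm$amplitude[dm$position == pos & dm$valid]
    lines <- c(lines, sprintf("- %s: median %s (n = %d)", pos,
                              fmt_or_na(stats::median(a, na.rm = TRUE)),
                              sum(is.finite(a))))
  }
  lg <- bundle$lags
  lines <- c(lines, "", "## Lag of thickness behind xylem water potential",
             sprintf("- median lag: %s min over %d days",
                     fmt_or_na(if (is.null(lg)) NA_real_
                               else stats::median(lg$lag_minutes), "%.0f"),
                     if (is.null(lg)) 0L else nrow(lg)))
  ft <- bundle$fits
  n_acc <- if (is.null(ft)) 0L else sum(ft$accepted)
  lines <- c(lines, "", "## Water-exchange model fits",
             sprintf("- accepted %d of %d daily fits", n_acc,
                     if (is.null(ft)) 0L else nrow(ft)))
  if (n_acc > 0) {
    for (pos in c("upper", "lower")) {
      g <- ft$alpha_beta_si[ft$accepted & ft$position == pos]
      tg <- ft$turgor_amplitude[ft$accepted & ft$position == pos]
      lines <- c(lines, sprintf(
        "- %s: median conductance %s m MPa-1 s-1; median turgor amplitude %s um",
        pos, fmt_or_na(stats::median(g, na.rm = TRUE), "%.3g"),
        fmt_or_na(stats::median(tg, na.rm = TRUE), "%.1f")))
    }
  } else {
    lines <- c(lines, "- zero accepted fits")
  }
  if (!is.null(ft) && any(!ft$accepted)) {
    tab <- table(ft$reason[!ft$accepted])
    lines <- c(lines, paste0("- rejections: ",
                             paste(sprintf("%s (%d)", names(tab), tab),
                                   collapse = ", ")))
  }
  os <- bundle$osmotic_summary
  if (!is.null(os)) {
    lines <- c(lines, "", "## Osmotics summary",
               "date | time | position | osmolality (mol/kg) | P_H (MPa)")
    lines <- c(lines, sprintf("%s | %s | %s | %.3f | %.3f",
                              format(os$date), os$time_class, os$position,
                              os$osmolality_mean, os$pressure_mean))
    gr <- bundle$osmotic_gradients
    lines <- c(lines, "", "### Axial gradients (upper - lower)",
               sprintf("%s %s: osmolality %+.3f mol/kg, pressure %+.3f MPa",
                       format(gr$date), gr$time_class,
                       gr$osmolality_gradient, gr$pressure_gradient))
  }
  lines
}
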