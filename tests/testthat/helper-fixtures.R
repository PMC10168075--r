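# Small in-code fixtures shared across test files.

day_start <- function(date = "2019-08-01") {
  as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
}

# one calendar day on the 10-min grid
day_grid <- function(date = "2019-08-01", n = 144) {
  day_start(date) + 600 * (seq_len(n) - 1)
}

make_series <- function(values, start = day_start(), unit = "um",
                        flag = "ok") {
  gridded_series(start + 600 * (seq_along(values) - 1), values,
                 flag = flag, unit = unit)
}

# sinusoidal day series with given peak hour and amplitude (max - min)
sine_day <- function(date = "2019-08-01", peak_hour = 9, amplitude = 40,
                     unit = "um") {
  tm <- day_grid(date)
  h <- as.numeric(difftime(tm, day_start(date), units = "hours"))
  gridded_series(tm, (amplitude / 2) * cos(2 * pi * (h - peak_hour) / 24),
                 unit = unit)
}

# multi-day thickness built from the capacitor recursion, optionally with
# noise and turgor; psi is a truncated-sine daytime depression
capacitor_days <- function(days = 3, alpha = 0.1, beta = 100, gamma = 0,
                           psi_min = -0.6, date = "2019-08-01") {
  n <- days * 144
  tm <- day_start(date) + 600 * (seq_len(n) - 1)
  h <- as.numeric(difftime(tm, tm[1], units = "hours")) %% 24
  psi <- psi_min * pmax(0, sin(pi * (h - 6) / 12))
  th <- numeric(n)
  for (t in seq_len(n - 1))
    th[t + 1] <- th[t] + alpha * (beta * psi[t] - th[t]) + gamma
  list(thickness = gridded_series(tm, th, unit = "um"),
       psi = gridded_series(tm, psi, unit = "MPa"))
}

write_tmp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
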