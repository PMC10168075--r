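test_that("daily extrema of a sinusoid match the analytic peak and trough", {
  day <- sine_day(peak_hour = 9, amplitude = 40)
  m <- daily_extrema(day, "2019-08-01")
  expect_true(m$valid)
  expect_equal(format(m$t_max, "%H:%M", tz = "UTC"), "09:00")
  expect_equal(format(m$t_min, "%H:%M", tz = "UTC"), "21:00")
  expect_equal(m$amplitude, 40, tolerance = 1e-6)
})

test_that("a trough after midnight is reported at its true time", {
  # two days; maximum at 10:00 of day 1, monotone decline into 01:30 of
  # day 2, then recovery
  tm <- day_grid(n = 288)
  h <- as.numeric(difftime(tm, tm[1], units = "hours"))
  v <- numeric(288)
  v[h <= 10] <- 10 * (h[h <= 10] / 10)
  decl <- h > 10 & h <= 25.5
  v[decl] <- 10 - 30 * (h[decl] - 10) / 15.5
  v[h > 25.5] <- -20 + 10 * (h[h > 25.5] - 25.5) / 10
  s <- gridded_series(tm, v, unit = "um")
  m <- daily_extrema(s, "2019-08-01")
  expect_equal(format(m$t_min, "%Y-%m-%d %H:%M", tz = "UTC"),
               "2019-08-02 01:30")
  expect_equal(m$amplitude, 30, tolerance = 1e-6)
})

test_that("constant day has zero amplitude with first-sample tie-break", {
  s <- make_series(rep(5, 144))
  m <- daily_extrema(s, "2019-08-01")
  expect_equal(m$amplitude, 0)
  expect_equal(m$t_max, s$time[1])
  expect_equal(m$t_min, s$time[1])
})

test_that("amplitude is invariant under additive offsets", {
  day <- sine_day()
  m0 <- daily_extrema(day, "2019-08-01")
  day$value <- day$value + 123.4
  m1 <- daily_extrema(day, "2019-08-01")
  expect_equal(m0$amplitude, m1$amplitude)
})

test_that("days with too many missing samples are invalid", {
  day <- sine_day()
  day$flag[1:40] <- "missing"
  m <- daily_extrema(day, "2019-08-01")
  expect_false(m$valid)
})

test_that("cross-correlation recovers identity, shifts and sign", {
  psi <- sine_day(peak_hour = 5, amplitude = 1, unit = "MPa")
  th <- psi
  r <- xcorr_lag(th, psi)
  expect_equal(r$lag_minutes, 0)
  expect_equal(r$peak_correlation, 1, tolerance = 1e-12)

  # thickness = psi delayed by 120 min -> lag -120
  v <- psi$value
  th2 <- gridded_series(psi$time, c(rep(v[1], 12), v[1:(144 - 12)]),
                        unit = "um")
  # use a periodic construction so the delayed copy stays exact in-window
  h <- as.numeric(difftime(psi$time, psi$time[1], units = "hours"))
  th2$value <- 0.5 * cos(2 * pi * (h - 2 - 5) / 24)
  r2 <- xcorr_lag(th2, psi)
  expect_equal(r2$lag_minutes, -120)

  # mirrored signal: maximization is over signed correlation, so the best
  # signed correlation sits a half-period away and the QC flag trips
  th3 <- psi; th3$value <- -psi$value
  r3 <- xcorr_lag(th3, psi)
  expect_equal(abs(r3$lag_minutes), 720)
  idx0 <- which.min(abs(as.numeric(th3$time - th3$time[1])))
  expect_equal(cor(th3$value, psi$value), -1)
})

test_that("lag recovery is exact for periodic shifts up to the window", {
  psi <- sine_day(peak_hour = 5, amplitude = 1, unit = "MPa")
  h <- as.numeric(difftime(psi$time, psi$time[1], units = "hours"))
  for (s_min in c(-360, -120, -10, 10, 240, 600)) {
    th <- psi
    th$value <- 0.5 * cos(2 * pi * (h - s_min / 60 - 5) / 24)
    r <- xcorr_lag(th, psi)
    expect_equal(r$lag_minutes, -s_min)
  }
})

test_that("zero-variance input raises an undefined-correlation error", {
  psi <- sine_day(unit = "MPa")
  flat <- make_series(rep(1, 144))
  expect_error(xcorr_lag(flat, psi), "undefined-correlation")
})

test_that("exact linear amplitude-radiation response is recovered", {
  daily <- data.frame(date = as.Date("2019-08-01") + 0:11,
                      amplitude = 3 * (5 + (0:11)))
  clim <- data.frame(date = daily$date, R_G = 5 + (0:11))
  f <- fit_climate_response(daily, clim, "R_G")
  expect_equal(unname(f$coefficients["x"]), 3, tolerance = 1e-10)
  expect_equal(unname(f$coefficients[1]), 0, tolerance = 1e-8)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
})

test_that("exponential fits return exact Q10 on noise-free amplitudes", {
  t_a <- seq(8, 30, length.out = 15)
  daily <- data.frame(date = as.Date("2019-08-01") + 0:14,
                      amplitude = 10 * exp(0.07885 * t_a))
  clim <- data.frame(date = daily$date, T_A = t_a)
  f <- fit_climate_response(daily, clim, "T_A")
  expect_equal(f$k, 0.07885, tolerance = 1e-10)
  expect_equal(f$q10, exp(0.7885), tolerance = 1e-10)
  expect_equal(f$q10, 2.2, tolerance = 1e-3)

  daily$amplitude <- 10 * exp((log(3) / 10) * t_a)
  f3 <- fit_climate_response(daily, clim, "T_A")
  expect_equal(f3$q10, 3, tolerance = 1e-10)
})

test_that("q10_from_rate obeys its identities", {
  expect_equal(q10_from_rate(0), 1)
  expect_equal(q10_from_rate(log(2.2) / 10), 2.2)
  expect_equal(q10_from_rate(log(2) / 10), 2)
  for (k1 in c(-0.05, 0.02, 0.1)) for (k2 in c(0.01, 0.07))
    expect_equal(q10_from_rate(k1 + k2),
                 q10_from_rate(k1) * q10_from_rate(k2))
})

test_that("quadratic VPD fit recovers a known saturation point", {
  # generator: amplitude saturates at VPD = 3 kPa (vertex of the parabola)
  vpd <- seq(0.3, 3.4, length.out = 20)
  amp <- 60 * (1 - ((vpd - 3) / 3)^2)
  daily <- data.frame(date = as.Date("2019-08-01") + 0:19, amplitude = amp)
  clim <- data.frame(date = daily$date, VPD = vpd)
  f <- fit_climate_response(daily, clim, "VPD")
  expect_equal(f$vertex, 3, tolerance = 0.1 * 3)
})

test_that("non-positive amplitudes are dropped from exponential fits", {
  t_a <- seq(5, 30, length.out = 12)
  daily <- data.frame(date = as.Date("2019-08-01") + 0:11,
                      amplitude = c(-1, 10 * exp(0.05 * t_a[-1])))
  clim <- data.frame(date = daily$date, T_A = t_a)
  expect_warning(f <- fit_climate_response(daily, clim, "T_A",
                                           min_days = 10),
                 "non-positive")
  expect_equal(f$n, 11)
})
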