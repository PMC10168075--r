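test_that("build_design anchors deltas at midnight and differences thickness", {
  th <- make_series(seq(0, 143))          # ramp 1 um/step
  psi <- make_series(rep(-0.2, 144), unit = "MPa")
  psi$value <- psi$value + 0.1 * sin(seq_len(144) / 10)
  d <- build_design(th, psi)
  expect_equal(d$d_thickness, rep(1, 143))
  expect_equal(d$delta_th, 0:142)
  expect_equal(d$delta_psi[1], 0)
  expect_equal(d$n_steps, 143)

  const <- build_design(make_series(rep(2, 144)),
                        make_series(rep(-0.1, 144), unit = "MPa"))
  expect_true(all(const$d_thickness == 0))
  expect_true(all(const$delta_psi == 0))
})

test_that("a missing midnight anchor raises an anchor error", {
  th <- make_series(rnorm(144)); psi <- make_series(rnorm(144), unit = "MPa")
  th$flag[1] <- "missing"
  expect_error(build_design(th, psi), "anchor error")
  # day not starting at midnight
  th2 <- gridded_series(day_start() + 3600 + 600 * (0:143), rnorm(144))
  psi2 <- gridded_series(day_start() + 3600 + 600 * (0:143), rnorm(144))
  expect_error(build_design(th2, psi2), "anchor error")
})

test_that("noise-free capacitor data is recovered to numerical precision", {
  cd <- capacitor_days(1, alpha = 0.1, beta = 100, gamma = 0)
  d <- build_design(cd$thickness, cd$psi)
  f <- fit_gls_ar1(d)
  expect_equal(f$coefficients[["c1"]], 10, tolerance = 1e-8)
  expect_equal(f$coefficients[["c2"]], -0.1, tolerance = 1e-8)
  expect_equal(f$alpha, 0.1, tolerance = 1e-7)
  expect_equal(f$beta, 100, tolerance = 1e-6)
  expect_equal(f$alpha_beta, f$alpha * f$beta, tolerance = 1e-10)
})

test_that("GLS with phi = 0 coincides with ordinary least squares", {
  set.seed(11)
  cd <- capacitor_days(1, alpha = 0.08, beta = 60)
  th <- cd$thickness
  th$value <- th$value + rnorm(144, 0, 0.5)
  d <- build_design(th, cd$psi)
  f0 <- fit_gls_ar1(d, phi = 0)
  ols <- lm(d$d_thickness ~ d$delta_psi + d$delta_th)
  expect_equal(unname(f0$coefficients[c("c1", "c2")]),
               unname(coef(ols)[2:3]), tolerance = 1e-8)
  expect_equal(f0$coefficients[["gamma"]], unname(coef(ols)[1]),
               tolerance = 1e-8)
})

test_that("fit agrees with nlme::gls under an AR(1) correlation structure", {
  skip_if_not_installed("nlme")
  set.seed(21)
  cd <- capacitor_days(1, alpha = 0.08, beta = 60)
  th <- cd$thickness
  ar <- as.numeric(stats::filter(rnorm(144, 0, 0.3 * sqrt(1 - 0.36)), 0.6,
                                 method = "recursive"))
  th$value <- th$value + ar
  d <- build_design(th, cd$psi)
  f <- fit_gls_ar1(d)
  df <- data.frame(y = d$d_thickness, x1 = d$delta_psi, x2 = d$delta_th)
  g <- nlme::gls(y ~ x1 + x2, data = df,
                 correlation = nlme::corAR1(form = ~1), method = "ML")
  expect_equal(f$coefficients[["c1"]], unname(coef(g)["x1"]),
               tolerance = 0.02)
  expect_equal(f$coefficients[["c2"]], unname(coef(g)["x2"]),
               tolerance = 0.05)
  phi_nlme <- as.numeric(coef(g$modelStruct$corStruct,
                              unconstrained = FALSE))
  expect_equal(f$phi, phi_nlme, tolerance = 0.02)
})

test_that("mean recovery under AR(1) noise stays within 10 percent", {
  set.seed(31)
  alphas <- betas <- numeric(50)
  for (i in 1:50) {
    cd <- capacitor_days(1, alpha = 0.1, beta = 100,
                         psi_min = -0.7)
    th <- cd$thickness
    ar <- as.numeric(stats::filter(rnorm(144, 0, 0.2 * sqrt(1 - 0.36)),
                                   0.6, method = "recursive"))
    th$value <- th$value + ar
    f <- fit_gls_ar1(build_design(th, cd$psi))
    alphas[i] <- f$alpha; betas[i] <- f$beta
  }
  expect_lt(abs(mean(alphas) - 0.1) / 0.1, 0.1)
  expect_lt(abs(mean(betas) - 100) / 100, 0.1)
})

test_that("confidence intervals for the conductance have near-nominal coverage", {
  # AR(1) innovations enter the thickness dynamics themselves, so the
  # fitted regression with AR(1) errors is exactly specified and the
  # 95% interval for c1 should cover at close to its nominal rate
  set.seed(41)
  tm <- day_grid()
  h <- as.numeric(difftime(tm, tm[1], units = "hours"))
  psi_v <- -0.7 * pmax(0, sin(pi * (h - 6) / 12))
  psi <- gridded_series(tm, psi_v, unit = "MPa")
  hits <- logical(200)
  for (i in 1:200) {
    a <- runif(1, 0.05, 0.3); b <- runif(1, 30, 150)
    phi <- runif(1, 0, 0.8)
    e <- as.numeric(stats::filter(rnorm(144, 0, 0.1 * sqrt(1 - phi^2)),
                                  phi, method = "recursive"))
    th_v <- numeric(144)
    for (t in 1:143)
      th_v[t + 1] <- th_v[t] + a * (b * psi_v[t] - th_v[t]) + e[t]
    f <- fit_gls_ar1(build_design(gridded_series(tm, th_v, unit = "um"),
                                  psi))
    ci <- f$coefficients[["c1"]] + c(-1.96, 1.96) * f$se[["c1"]]
    hits[i] <- ci[1] <= a * b && a * b <= ci[2]
  }
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 0.99)
})

test_that("a constant psi day raises a collinearity error", {
  th <- make_series(rnorm(144))
  psi <- make_series(rep(-0.3, 144), unit = "MPa")
  expect_error(fit_gls_ar1(build_design(th, psi)), "collinearity")
})

test_that("prediction matches the geometric-series step response", {
  fit <- list(alpha = 0.1, beta = 100, gamma = 0)
  pred <- predict_thickness(fit, rep(-0.5, 11))
  expect_equal(pred[11], -50 * (1 - 0.9^10), tolerance = 1e-14)
  expect_equal(pred[11], -32.566, tolerance = 1e-4)
  # limit is beta * delta_psi
  long <- predict_thickness(fit, rep(-0.5, 500))
  expect_equal(long[500], -50, tolerance = 1e-8)

  # fixed point gamma / alpha under zero forcing
  fit2 <- list(alpha = 0.1, beta = 100, gamma = 1)
  p2 <- predict_thickness(fit2, rep(0, 300))
  expect_equal(p2[300], 10, tolerance = 1e-8)

  expect_equal(predict_thickness(fit, rep(0, 10)), rep(0, 10))
})

test_that("prediction is a contraction for bounded forcing", {
  set.seed(5)
  for (i in 1:10) {
    a <- runif(1, 0.02, 0.9); b <- runif(1, 10, 200)
    g <- runif(1, -1, 1)
    dpsi <- runif(288, -1, 0)
    p <- predict_thickness(list(alpha = a, beta = b, gamma = g), dpsi)
    expect_true(all(abs(p) <= b * max(abs(dpsi)) + abs(g) / a + 1e-9))
  }
})

test_that("turgor signal is the observed-minus-predicted residual", {
  obs <- c(0, cumsum(rnorm(100)))
  ts0 <- turgor_signal(obs, obs)
  expect_true(all(ts0$series == 0))
  expect_equal(ts0$amplitude, 0)

  step <- c(rep(0, 50), rep(7, 51))
  ts1 <- turgor_signal(obs + step, obs)
  expect_equal(ts1$series, step)
  expect_equal(ts1$amplitude, 7)
})

test_that("an injected sinusoidal turgor waveform is recovered (r > 0.9)", {
  # waveform in quadrature with the daytime psi depression (peak 21:00),
  # so the capacitor fit cannot absorb it; collinear phases are partially
  # soaked up by the model and recover with lower correlation
  cd <- capacitor_days(1, alpha = 0.1, beta = 60, psi_min = -0.7)
  h <- as.numeric(difftime(cd$thickness$time, cd$thickness$time[1],
                           units = "hours"))
  wave <- 10 * sin(2 * pi * (h - 15) / 24)
  for (sd_seed in 1:3) {
    set.seed(sd_seed)
    noise <- as.numeric(stats::filter(rnorm(144, 0, 0.1 * 0.8), 0.6,
                                      method = "recursive"))
    th <- cd$thickness
    th$value <- th$value + wave + noise
    res <- fit_exchange_day(th, cd$psi)
    expect_true(res$accepted)
    expect_gt(cor(res$turgor$series, wave), 0.9)
  }
})

test_that("acceptance rules flag unrealistic fits with a reason", {
  f_bad <- list(alpha = -0.05, beta = 50, gamma = 0, phi = 0.2,
                alpha_beta = -2.5, coefficients = c(c1 = -2.5, c2 = 0.05,
                                                    gamma = 0),
                se = c(c1 = 0.1, c2 = 0.01, gamma = 0.01),
                design = build_design(capacitor_days(1)$thickness,
                                      capacitor_days(1)$psi))
  a <- accept_fit(f_bad)
  expect_false(a$accepted)
  expect_equal(a$reason, "negative rate")

  cd <- capacitor_days(1, alpha = 0.1, beta = 100)
  good <- fit_gls_ar1(build_design(cd$thickness, cd$psi))
  expect_true(accept_fit(good)$accepted)

  # a fit predicting worse than the zero model is rejected
  anti <- good
  anti$beta <- -good$beta; anti$alpha <- good$alpha
  anti$coefficients[["c1"]] <- -good$coefficients[["c1"]]
  a2 <- accept_fit(anti)
  expect_false(a2$accepted)
})

test_that("conductance converts to SI units by 1e-6/600", {
  expect_equal(radial_conductance_si(4.8), 8.0e-9)
  expect_equal(radial_conductance_si(1.8), 3.0e-9)
  expect_equal(radial_conductance_si(0), 0)
})

test_that("turgor pressure amplitude scales by modulus over thickness", {
  expect_equal(turgor_pressure_amplitude(50, 20, 5000), 0.2)
  expect_equal(turgor_pressure_amplitude(100, 15, 7500), 0.2)
  expect_equal(turgor_pressure_amplitude(0, 20, 5000), 0)
  expect_error(turgor_pressure_amplitude(50, 20, 0), "domain error")
})
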