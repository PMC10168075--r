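#' Build the per-day design for the radial water-exchange model
#'
#' The capacitor model treats the inner bark as a water reservoir exchanging
#' radially with the xylem: over each 10-min step,
#' `dTh/dt = alpha (beta dPsi_X - dTh) + gamma`,
#' where `dPsi_X` and `dTh` are the differences of xylem water potential and
#' inner bark thickness relative to the first measurement at midnight. The
#' design holds the forward difference of thickness per step (response) and
#' the two anchored regressors.
#'
#' @param thickness_day detrended thickness `gridded_series` for one full
#'   calendar day starting at midnight, all samples usable.
#' @param psi_day xylem water potential `gridded_series`, same grid.
#' @return An `exchange_design`: list with `d_thickness` (um/step, length
#'   n-1), `delta_psi` (MPa) and `delta_th` (um) at the step origins,
#'   `n_steps`, and `time`.
#' @export
build_design <- function(thickness_day, psi_day) {
  if (nrow(thickness_day) != nrow(psi_day) ||
      any(thickness_day$time != psi_day$time))
    stop("alignment error: day series are not on one grid", call. = FALSE)
  t0 <- thickness_day$time[1]
  if (format(t0, "%H:%M", tz = "UTC") != "00:00")
    stop("anchor error: day does not start at midnight", call. = FALSE)
  th <- series_values(thickness_day)
  psi <- series_values(psi_day)
  if (!is.finite(th[1]) || !is.finite(psi[1]))
    stop("anchor error: first midnight sample is missing", call. = FALSE)
  if (anyNA(th) || anyNA(psi))
    stop("day contains unusable samples; exclude it before fitting",
         call. = FALSE)
  n <- length(th)
  structure(list(
    d_thickness = diff(th),
    delta_psi = (psi - psi[1])[-n],
    delta_th = (th - th[1])[-n],
    n_steps = n - 1L,
    time = thickness_day$time[-n]),
    class = "exchange_design")
}

# Exact AR(1) whitening of a column: first row scaled by sqrt(1 - phi^2),
# later rows x_t - phi x_{t-1}.
ar1_whiten <- function(m, phi) {
  n <- nrow(m)
  w <- m - phi * rbind(0, m[-n, , drop = FALSE])
  w[1, ] <- sqrt(1 - phi^2) * m[1, ]
  w
}

gls_at_phi <- function(X, y, phi) {
  Xw <- ar1_whiten(X, phi)
  yw <- ar1_whiten(matrix(y, ncol = 1), phi)[, 1]
  fit <- .lm.fit(Xw, yw)
  rss <- sum(fit$residuals^2)
  n <- length(y)
  # profile Gaussian log-likelihood (additive constants dropped);
  # log|V|^{-1/2} contributes 0.5 log(1 - phi^2)
  ll <- if (rss <= 0) Inf else -n / 2 * log(rss / n) + 0.5 * log(1 - phi^2)
  list(coef = fit$coefficients, rss = rss, loglik = ll, Xw = Xw)
}

#' Fit the water-exchange model by AR(1) generalized least squares
#'
#' Fits `dTh/dt = c1 dPsi_X + c2 dTh + gamma` with AR(1) errors, then maps
#' to the parenthesized capacitor form `dTh/dt = alpha (beta dPsi_X - dTh) +
#' gamma` via `alpha = -c2`, `beta = c1 / alpha`, so that the product
#' `alpha beta = c1` is the radial hydraulic conductance in native units
#' (um MPa-1 per 10-min step). The AR(1) coefficient is estimated by profile
#' likelihood over a phi grid with exact GLS whitening at each phi: a coarse
#' pass (step 0.05) followed by a step-0.01 refinement around its optimum,
#' which is deterministic and free of iterative-convergence ambiguity. Ties
#' (e.g. exact data with zero residuals at every phi) resolve to the
#' smallest `|phi|`.
#'
#' @param design an `exchange_design` from [build_design()].
#' @param phi fix the AR(1) coefficient instead of profiling (e.g. `phi = 0`
#'   reduces the fit to ordinary least squares).
#' @param min_steps minimum number of steps required (default 48).
#' @return An `exchange_fit`: `alpha`, `beta`, `gamma`, `phi`, `alpha_beta`,
#'   coefficient vector `c(c1, c2, gamma)`, standard errors, `sigma`,
#'   `loglik`, `n`, and the design (for prediction and acceptance checks).
#' @export
fit_gls_ar1 <- function(design, phi = NULL, min_steps = 48) {
  stopifnot(inherits(design, "exchange_design"))
  n <- design$n_steps
  if (n < min_steps)
    stop("need at least ", min_steps, " steps, got ", n, call. = FALSE)
  if (stats::sd(design$delta_psi) == 0)
    stop("collinearity error: delta_psi is constant over the day",
         call. = FALSE)
  X <- cbind(dpsi = design$delta_psi, dth = design$delta_th, const = 1)
  if (qr(X)$rank < 3L)
    stop("collinearity error: singular design", call. = FALSE)
  y <- design$d_thickness

  if (is.null(phi)) {
    coarse <- round(seq(-0.95, 0.95, by = 0.05), 2)
    coarse <- coarse[order(abs(coarse), coarse)]
    ll_c <- vapply(coarse, function(p) gls_at_phi(X, y, p)$loglik, numeric(1))
    p0 <- coarse[which.max(ll_c)]
    fine <- round(seq(max(-0.99, p0 - 0.05), min(0.99, p0 + 0.05),
                      by = 0.01), 2)
    fine <- fine[order(abs(fine), fine)]
    ll_f <- vapply(fine, function(p) gls_at_phi(X, y, p)$loglik, numeric(1))
    phi_hat <- fine[which.max(ll_f)]
  } else phi_hat <- phi

  g <- gls_at_phi(X, y, phi_hat)
  cf <- g$coef
  sigma2 <- g$rss / (n - 3)
  xtx <- crossprod(g$Xw)
  cov <- tryCatch(sigma2 * chol2inv(chol(xtx)),
                  error = function(e) matrix(NA_real_, 3, 3))
  se <- sqrt(diag(cov))
  alpha <- -cf[2]
  structure(list(
    alpha = unname(alpha),
    beta = unname(cf[1] / alpha),
    gamma = unname(cf[3]),
    phi = phi_hat,
    alpha_beta = unname(cf[1]),
    coefficients = c(c1 = unname(cf[1]), c2 = unname(cf[2]),
                     gamma = unname(cf[3])),
    se = c(c1 = se[1], c2 = se[2], gamma = se[3]),
    sigma = sqrt(sigma2),
    loglik = g$loglik,
    n = n,
    design = design),
    class = "exchange_fit")
}

#' @export
print.exchange_fit <- function(x, ...) {
  cat(sprintf(paste0("<exchange_fit> alpha = %.4f /step, beta = %.2f um/MPa,",
                     " gamma = %.3f um/step\n  alpha*beta = %.3f um MPa-1",
                     " step-1 (%.3g m MPa-1 s-1), phi = %.2f, n = %d\n"),
              x$alpha, x$beta, x$gamma, x$alpha_beta,
              radial_conductance_si(x$alpha_beta), x$phi, x$n))
  invisible(x)
}

#' Predict thickness change from xylem water potential
#'
#' Runs the fitted capacitor recursion at the 10-min step:
#' `dTh(t+1) = dTh(t) + alpha (beta dPsi_X(t) - dTh(t)) + gamma`, starting
#' from `dTh(0) = 0`. For `0 < alpha < 1` the recursion is a contraction, so
#' bounded forcing gives bounded predictions
#' (`|dTh| <= beta max|dPsi| + |gamma|/alpha`).
#'
#' @param fit an `exchange_fit` (or any list with `alpha`, `beta`, `gamma`).
#' @param delta_psi xylem potential differences relative to midnight (MPa).
#' @return Predicted thickness change (um), same length as `delta_psi`,
#'   first element 0.
#' @export
predict_thickness <- function(fit, delta_psi) {
  n <- length(delta_psi)
  out <- numeric(n)
  a <- fit$alpha; b <- fit$beta; g <- fit$gamma
  for (t in seq_len(n - 1L))
    out[t + 1L] <- out[t] + a * (b * delta_psi[t] - out[t]) + g
  out
}

#' Extract the turgor-related signal
#'
#' The observed-minus-predicted thickness change: the part of the diurnal
#' thickness variation that the constant-osmoticum capacitor model cannot
#' explain, attributed to varying solute content of the phloem.
#'
#' @param observed observed thickness change relative to midnight (um).
#' @param predicted predicted change from [predict_thickness()] (um).
#' @param time optional POSIXct vector for the returned series.
#' @return A `turgor_signal`: list with `series` (um), `amplitude`
#'   (max - min, um) and `time`.
#' @export
turgor_signal <- function(observed, predicted, time = NULL) {
  if (length(observed) != length(predicted))
    stop("alignment error: observed and predicted differ in length",
         call. = FALSE)
  s <- observed - predicted
  structure(list(series = s, amplitude = max(s) - min(s), time = time),
            class = "turgor_signal")
}

#' @export
print.turgor_signal <- function(x, ...) {
  cat(sprintf("<turgor_signal> %d samples, amplitude %.2f um\n",
              length(x$series), x$amplitude))
  invisible(x)
}

#' Default fit-acceptance criteria
#'
#' Thresholds used to rule out unrealistic daily adjustments (typically on
#' rainy, very cloudy or late-fall days): non-positive rate or capacitance,
#' residual autocorrelation at the grid edge, an uninformative conductance
#' (relative standard error above 100 percent), or a prediction that
#' explains the observed day worse than a flat zero model.
#'
#' @return Named list of thresholds.
#' @export
default_fit_criteria <- function() {
  list(max_abs_phi = 0.99, max_rel_se_c1 = 1, min_prediction_r2 = 0)
}

#' Accept or reject a daily model fit
#'
#' @param fit an `exchange_fit`.
#' @param criteria list of thresholds, see [default_fit_criteria()].
#' @return List with `accepted` (logical) and `reason` (string, `""` when
#'   accepted).
#' @export
accept_fit <- function(fit, criteria = default_fit_criteria()) {
  reason <- ""
  obs <- c(0, cumsum(fit$design$d_thickness))
  pred <- predict_thickness(fit, c(fit$design$delta_psi, NA)[seq_along(obs)])
  ss_tot <- sum((obs - mean(obs))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - sum((obs - pred)^2) / ss_tot
  rel_se <- abs(fit$se[["c1"]] / fit$coefficients[["c1"]])
  if (!is.finite(fit$alpha) || fit$alpha <= 0) reason <- "negative rate"
  else if (!is.finite(fit$beta) || fit$beta <= 0) reason <- "negative capacitance"
  else if (abs(fit$phi) >= criteria$max_abs_phi) reason <- "residual autocorrelation at bound"
  else if (!is.finite(rel_se) || rel_se > criteria$max_rel_se_c1)
    reason <- "uninformative conductance"
  else if (is.finite(r2) && r2 < criteria$min_prediction_r2)
    reason <- "prediction worse than zero model"
  list(accepted = reason == "", reason = reason,
       prediction_r2 = r2, rel_se_c1 = unname(rel_se))
}

#' Radial hydraulic conductance in SI units
#'
#' Converts the fitted product `alpha beta` from its native units
#' (um MPa-1 per 10-min step) to m MPa-1 s-1: multiply by 1e-6 / 600.
#'
#' @param alpha_beta conductance in um MPa-1 step-1.
#' @param step_s step length in seconds (default 600).
#' @return Conductance in m MPa-1 s-1.
#' @export
radial_conductance_si <- function(alpha_beta, step_s = 600) {
  alpha_beta * 1e-6 / step_s
}

#' Turgor pressure amplitude from a thickness signal
#'
#' Scales the turgor-signal thickness amplitude by the bulk elastic modulus
#' of the inner bark: `dP = modulus * (signal_amplitude / bark_thickness)`.
#'
#' @param signal_amplitude turgor-signal amplitude (um).
#' @param modulus bulk elastic modulus of the inner bark (MPa).
#' @param bark_thickness absolute inner bark thickness (um), > 0.
#' @return Pressure amplitude (MPa).
#' @export
turgor_pressure_amplitude <- function(signal_amplitude, modulus,
                                      bark_thickness) {
  if (any(bark_thickness <= 0))
    stop("domain error: bark thickness must be positive", call. = FALSE)
  modulus * signal_amplitude / bark_thickness
}

#' Fit one day end to end and extract its turgor signal
#'
#' Convenience wrapper: builds the design, fits the AR(1) GLS, applies the
#' acceptance rules, and (for accepted fits) extracts the turgor signal.
#'
#' @param thickness_day,psi_day one full day on a common grid.
#' @param criteria acceptance thresholds.
#' @param ... passed to [fit_gls_ar1()].
#' @return List: `fit`, `accepted`, `reason`, `prediction_r2`, `turgor`
#'   (`turgor_signal` or `NULL`).
#' @export
fit_exchange_day <- function(thickness_day, psi_day,
                             criteria = default_fit_criteria(), ...) {
  design <- build_design(thickness_day, psi_day)
  fit <- fit_gls_ar1(design, ...)
  acc <- accept_fit(fit, criteria)
  turgor <- NULL
  if (acc$accepted) {
    obs <- c(0, cumsum(design$d_thickness))
    dpsi_full <- c(design$delta_psi,
                   design$delta_psi[design$n_steps])  # pad to day length
    pred <- predict_thickness(fit, dpsi_full)
    turgor <- turgor_signal(obs, pred,
                            time = c(design$time,
                                     design$time[design$n_steps] + 600))
  }
  c(list(fit = fit, turgor = turgor), acc)
}
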