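# The four curve families of routine voltage-clamp analysis.  All fitters
# are data-frame-first, return an `iks_fit` object with broom-style tidy()
# and glance() methods, and flag (rather than throw on) non-convergence.

new_iks_fit <- function(family, estimate, std_error, rss, converged,
                        data, predict_fn, tag = NULL, n = NA_integer_) {
  structure(
    list(family = family,
         estimate = estimate,
         std_error = std_error,
         rss = rss,
         converged = converged,
         tag = tag,
         n = n,
         data = data,
         predict_fn = predict_fn),
    class = "iks_fit")
}

#' @export
print.iks_fit <- function(x, digits = 6, ...) {
  cat(sprintf("<iks_fit> family '%s'%s, %s (n = %d, RSS = %.4g)\n",
              x$family,
              if (!is.null(x$tag)) paste0(" [", x$tag, "]") else "",
              if (isTRUE(x$converged)) "converged" else "NOT converged",
              x$n, x$rss))
  print(tidy(x), digits = digits)
  invisible(x)
}

#' Coefficients of a fitted curve
#' @param object An `iks_fit`.
#' @param ... Unused.
#' @return Named numeric vector of parameter estimates.
#' @export
coef.iks_fit <- function(object, ...) object$estimate

#' Predict from a fitted curve
#' @param object An `iks_fit`.
#' @param newdata Numeric vector of predictor values on the fit's natural
#'   scale (concentration in M for Hill, voltage in mV for Boltzmann,
#'   time in s for exponential, concentration in M for log-linear).
#' @param ... Unused.
#' @return Predicted responses.
#' @export
predict.iks_fit <- function(object, newdata, ...) object$predict_fn(newdata)

flagged_fit <- function(family, params, data, predict_fn, n, tag = NULL) {
  new_iks_fit(family,
              estimate = params,
              std_error = setNames(rep(NA_real_, length(params)), names(params)),
              rss = NA_real_, converged = FALSE, data = data,
              predict_fn = predict_fn, tag = tag, n = n)
}

# Restarted bounded Levenberg-Marquardt least squares.  `starts` is a list
# of named start vectors tried in order until one converges.
nls_restart <- function(formula, data, starts, lower, upper) {
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = st,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) return(fit)
  }
  NULL
}

hill_response <- function(conc, ic50, h) 1 / (1 + (conc / ic50)^h)

#' Fit the Hill concentration-response equation
#'
#' Fits the fractional response `I_drug / I_max = 1 / (1 + (C / IC50)^H)`
#' to a dose-response table.  `IC50` is searched in log10 space (default
#' bounds 1e-11 to 1e-3 M) and the Hill coefficient `H` is bounded to
#' \[0.2, 5\] (or fixed via `fix_H`).  By construction the fitted response
#' at `C = IC50` is 0.5.  The `IC50` standard error is obtained from the
#' log-space error by the delta method.
#'
#' @param data Data frame with columns `concentration_M` (> 0) and
#'   `response` (fractional current, dimensionless); replicate rows are
#'   allowed.
#' @param fix_H Optional fixed Hill coefficient; default `NULL` fits H
#'   freely.
#' @param ic50_bounds_M Length-2 search interval for IC50 (M).
#'
#' @return An `iks_fit` with parameters `IC50` (M) and `H`.  A fit that
#'   fails to converge is returned with `converged = FALSE`, not thrown.
#' @examples
#' tbl <- synth_dose_response(78.4e-9, 1, sigma_rel = 0, seed = 1)
#' hill_fit(tbl)
#' @export
hill_fit <- function(data, fix_H = NULL, ic50_bounds_M = c(1e-11, 1e-3)) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("concentration_M", "response") %in% names(data)))
  if (any(data$concentration_M <= 0) || any(!is.finite(data$concentration_M))) {
    abort("Concentrations must be strictly positive.",
          class = "iksim_invalid_input")
  }
  if (dplyr::n_distinct(data$concentration_M) < 3) {
    abort("Hill fit needs at least 3 distinct concentrations.",
          class = "iksim_invalid_input")
  }
  df <- data.frame(lc = log10(data$concentration_M), y = data$response)
  # start IC50 where the mean response is closest to 0.5
  means <- stats::aggregate(y ~ lc, df, mean)
  lc0 <- means$lc[which.min(abs(means$y - 0.5))]
  lower <- c(lic50 = log10(ic50_bounds_M[1]))
  upper <- c(lic50 = log10(ic50_bounds_M[2]))
  if (is.null(fix_H)) {
    form <- y ~ 1 / (1 + 10^(h * (lc - lic50)))
    starts <- list(c(lic50 = lc0, h = 1),
                   c(lic50 = mean(range(df$lc)), h = 1),
                   c(lic50 = lc0, h = 2))
    lower <- c(lower, h = 0.2); upper <- c(upper, h = 5)
  } else {
    h_fixed <- fix_H
    form <- y ~ 1 / (1 + 10^(h_fixed * (lc - lic50)))
    starts <- list(c(lic50 = lc0), c(lic50 = mean(range(df$lc))))
  }
  fit <- nls_restart(form, df, starts, lower, upper)
  params0 <- c(IC50 = 10^lc0, H = if (is.null(fix_H)) 1 else fix_H)
  if (is.null(fit)) {
    return(flagged_fit("hill", params0, data,
                       function(x) hill_response(x, params0[["IC50"]],
                                                 params0[["H"]]),
                       n = nrow(df), tag = "non-convergence"))
  }
  cf <- coef(fit)
  se <- tryCatch(suppressWarnings(summary(fit))$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, length(cf)),
                                              names(cf)))
  ic50 <- 10^cf[["lic50"]]
  h <- if (is.null(fix_H)) cf[["h"]] else fix_H
  est <- c(IC50 = ic50, H = h)
  ses <- c(IC50 = ic50 * log(10) * unname(se["lic50"]),
           H = if (is.null(fix_H)) unname(se["h"]) else 0)
  new_iks_fit("hill", est, ses,
              rss = sum(stats::resid(fit)^2), converged = TRUE,
              data = data,
              predict_fn = function(x) hill_response(x, ic50, h),
              tag = if (is.null(fix_H)) "free H" else "fixed H",
              n = nrow(df))
}

boltzmann_response <- function(v, v_half, k, a_max, a_min) {
  a_min + (a_max - a_min) / (1 + exp((v_half - v) / k))
}

#' Fit a Boltzmann activation curve
#'
#' Fits `A(V) = A_min + (A_max - A_min) / (1 + exp((V1/2 - V) / k))` to
#' normalized tail amplitudes versus test potential.  `V1/2` is the
#' half-activation voltage and `k` the slope factor (both mV); the fitted
#' value at `V = V1/2` is `(A_max + A_min) / 2`.
#'
#' @param data Data frame with columns `voltage_mV` and `response`
#'   (normalized amplitude); at least 5 voltage points.
#' @param bounds Named list overriding the box constraints; defaults:
#'   `v_half` in \[-200, 200\] mV, `k` in \[0.5, 50\] mV, `a_max` in
#'   \[0.2, 2\], `a_min` in \[-0.5, 0.5\].
#'
#' @return An `iks_fit` with parameters `v_half`, `k`, `a_max`, `a_min`.
#' @export
boltzmann_fit <- function(data, bounds = list()) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("voltage_mV", "response") %in% names(data)))
  if (dplyr::n_distinct(data$voltage_mV) < 5) {
    abort("Boltzmann fit needs at least 5 voltage points.",
          class = "iksim_invalid_input")
  }
  if (any(!is.finite(data$response))) {
    abort("Amplitudes must be finite.", class = "iksim_invalid_input")
  }
  b <- modifyList(list(v_half = c(-200, 200), k = c(0.5, 50),
                       a_max = c(0.2, 2), a_min = c(-0.5, 0.5)), bounds)
  df <- data.frame(v = data$voltage_mV, y = data$response)
  a_max0 <- max(df$y); a_min0 <- min(df$y)
  vh0 <- df$v[which.min(abs(df$y - (a_max0 + a_min0) / 2))]
  clamp <- function(x, lim) pmin(pmax(x, lim[1]), lim[2])
  starts <- list(
    c(v_half = clamp(vh0, b$v_half), k = 12,
      a_max = clamp(a_max0, b$a_max), a_min = clamp(a_min0, b$a_min)),
    c(v_half = clamp(mean(range(df$v)), b$v_half), k = 20,
      a_max = clamp(a_max0, b$a_max), a_min = clamp(a_min0, b$a_min)),
    c(v_half = clamp(vh0 + 20, b$v_half), k = 8,
      a_max = 1, a_min = 0))
  fit <- nls_restart(y ~ a_min + (a_max - a_min) / (1 + exp((v_half - v) / k)),
                     df, starts,
                     lower = c(v_half = b$v_half[1], k = b$k[1],
                               a_max = b$a_max[1], a_min = b$a_min[1]),
                     upper = c(v_half = b$v_half[2], k = b$k[2],
                               a_max = b$a_max[2], a_min = b$a_min[2]))
  if (is.null(fit)) {
    p0 <- starts[[1]]
    return(flagged_fit("boltzmann", p0, data,
                       function(x) boltzmann_response(x, p0[["v_half"]],
                                                      p0[["k"]], p0[["a_max"]],
                                                      p0[["a_min"]]),
                       n = nrow(df), tag = "non-convergence"))
  }
  cf <- coef(fit)
  se <- tryCatch(suppressWarnings(summary(fit))$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 4), names(cf)))
  new_iks_fit("boltzmann", cf, se[names(cf)],
              rss = sum(stats::resid(fit)^2), converged = TRUE, data = data,
              predict_fn = function(x) {
                boltzmann_response(x, cf[["v_half"]], cf[["k"]],
                                   cf[["a_max"]], cf[["a_min"]])
              },
              n = nrow(df))
}

#' Fit a single-exponential relaxation
#'
#' Fits `y(t) = A0 + A * exp(-t / tau)` to a current trace, the standard
#' description of (de)activation kinetics.  Time is measured from the
#' start of the fit window.  For sigmoidally delayed activation the
#' default analysis excludes the first 200 ms of a test pulse (see
#' [activation_kinetics()]); this function fits exactly the rows given.
#'
#' @param data Data frame with columns `time_s` and `signal` (at least 10
#'   rows); or use `window` to restrict to `time_s` within
#'   `[window[1], window[2]]`.
#' @param window Optional length-2 numeric window on `time_s` (s).
#' @param tag Optional label (e.g. `"tau_activation"`,
#'   `"tau_deactivation"`) recorded on the result.
#'
#' @return An `iks_fit` with parameters `A0`, `A`, `tau` (s, > 0).  A
#'   trace too flat to constrain `tau` yields `converged = FALSE`.
#' @export
exp_fit <- function(data, window = NULL, tag = NULL) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("time_s", "signal") %in% names(data)))
  if (!is.null(window)) {
    data <- dplyr::filter(data, .data$time_s >= window[1],
                          .data$time_s <= window[2])
  }
  if (nrow(data) < 10) {
    abort("Exponential fit needs at least 10 samples in the window.",
          class = "iksim_invalid_input")
  }
  t0 <- min(data$time_s)
  df <- data.frame(t = data$time_s - t0, y = data$signal)
  span <- diff(range(df$y))
  scale_y <- max(abs(df$y), span)
  if (span <= 1e-12 * max(scale_y, 1)) {
    p0 <- c(A0 = mean(df$y), A = 0, tau = NA_real_)
    return(flagged_fit("exponential", p0, data,
                       function(x) rep(mean(df$y), length(x)),
                       n = nrow(df), tag = "flat trace"))
  }
  y_first <- df$y[which.min(df$t)]; y_last <- df$y[which.max(df$t)]
  t_span <- diff(range(df$t))
  starts <- list(
    c(A0 = y_last, A = y_first - y_last, tau = t_span / 5),
    c(A0 = y_last, A = y_first - y_last, tau = t_span / 2),
    c(A0 = y_last + 0.5 * (y_first - y_last), A = y_first - y_last,
      tau = t_span * 2))
  big <- 10 * max(abs(df$y), 1)
  fit <- nls_restart(y ~ A0 + A * exp(-t / tau), df, starts,
                     lower = c(A0 = -big, A = -big, tau = t_span * 1e-6),
                     upper = c(A0 = big, A = big, tau = t_span * 1e4))
  if (is.null(fit)) {
    p0 <- starts[[1]]
    return(flagged_fit("exponential", p0, data,
                       function(x) p0[["A0"]] +
                         p0[["A"]] * exp(-(x - t0) / p0[["tau"]]),
                       n = nrow(df), tag = "non-convergence"))
  }
  cf <- coef(fit)
  se <- tryCatch(suppressWarnings(summary(fit))$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 3), names(cf)))
  new_iks_fit("exponential", cf, se[names(cf)],
              rss = sum(stats::resid(fit)^2), converged = TRUE, data = data,
              predict_fn = function(x) {
                cf[["A0"]] + cf[["A"]] * exp(-(x - t0) / cf[["tau"]])
              },
              tag = tag, n = nrow(df))
}

#' Log-log linear fit of wash-in time constants versus concentration
#'
#' Ordinary least squares of `log10(tau)` on `log10(C)`:
#' `log10(tau) = m * log10(C) + b`.  For pseudo-first-order drug binding
#' (`tau ~ 1 / (kon C + koff)`) the slope `m` approaches -1 when
#' `C >> Kd`.
#'
#' @param data Data frame with columns `concentration_M` (> 0) and
#'   `tau_s` (> 0); at least 3 points.
#'
#' @return An `iks_fit` with parameters `m` (slope) and `b` (intercept).
#' @export
linear_log_fit <- function(data) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("concentration_M", "tau_s") %in% names(data)))
  if (nrow(data) < 3) {
    abort("Log-linear fit needs at least 3 points.",
          class = "iksim_invalid_input")
  }
  if (any(data$concentration_M <= 0) || any(data$tau_s <= 0)) {
    abort("Concentrations and time constants must be positive.",
          class = "iksim_invalid_input")
  }
  df <- data.frame(x = log10(data$concentration_M), y = log10(data$tau_s))
  fit <- stats::lm(y ~ x, df)
  cf <- coef(fit)
  se <- suppressWarnings(summary(fit))$coefficients[, "Std. Error"]
  est <- c(m = unname(cf[["x"]]), b = unname(cf[["(Intercept)"]]))
  ses <- c(m = unname(se[["x"]]), b = unname(se[["(Intercept)"]]))
  new_iks_fit("linear_log", est, ses,
              rss = sum(stats::resid(fit)^2), converged = TRUE, data = data,
              predict_fn = function(x) {
                10^(est[["m"]] * log10(x) + est[["b"]])
              },
              n = nrow(df))
}
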