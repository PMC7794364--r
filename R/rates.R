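#' Fit a Gompertz growth model to a cell-count time course
#'
#' Uses the standard three-parameter Gompertz form
#' `N(t) = K * exp(log(N0 / K) * exp(-mu * t))`
#' with `N0` the inoculum, `K` the carrying capacity and `mu` the growth
#' rate constant (1/h); an optional lag shifts time by `lambda`:
#' `N(t) = K * exp(log(N0/K) * exp(-mu * (t - lambda)))`. Parameters are
#' estimated by Levenberg-Marquardt least squares with a deterministic
#' initialization (N0 = first count, K = 1.05 * max count, mu from the
#' log-count slope over the first half of the series), so repeated fits of
#' the same data are identical. When every count is positive the residuals
#' are taken on the log scale, matching the multiplicative error of cell
#' counting; otherwise on the natural scale.
#'
#' @param data Data frame with the time course.
#' @param time,count Column names (strings) holding hours and viable counts.
#' @param fit_lag Estimate the lag parameter too (default `FALSE`, lag 0).
#' @return A `gompertz_fit`: `n0`, `carrying_capacity`, `mu_max`, `lag`,
#'   `rss`, plus the data for prediction. Errors on non-convergence carry
#'   the final residual.
#' @export
fit_gompertz <- function(data, time = "time_h", count = "count", fit_lag = FALSE) {
  t <- data[[time]]; n <- data[[count]]
  if (is.null(t) || is.null(n)) abort("fit_gompertz: time/count columns not found")
  if (length(t) < 4) abort("fit_gompertz needs at least 4 time points")
  if (any(diff(t) <= 0)) abort("times must be strictly increasing")
  if (any(n < 0)) abort("counts must be non-negative")
  # degenerate flat series: any mu fits equally; report mu 0
  if (max(n) - min(n) <= 1e-10 * max(n, 1)) {
    return(new_gompertz_fit(n0 = mean(n), K = mean(n), mu = 0, lag = 0,
                            rss = 0, data = tibble(time_h = t, count = n)))
  }
  n0_init <- max(n[1], 1e-6 * max(n))
  k_init <- 1.05 * max(n)
  half <- t <= stats::median(t)
  mu_init <- tryCatch({
    s <- stats::coef(stats::lm(log(pmax(n[half], 1e-9)) ~ t[half]))[2]
    max(min(unname(s) * 2, 1), 1e-4)
  }, error = function(e) 0.02)
  # counting noise is multiplicative, so fit in log space when possible
  log_space <- all(n > 0)
  df <- data.frame(t = t, n = n, ln = if (log_space) log(n) else n)
  form <- if (log_space) {
    if (fit_lag) ln ~ log(K) + log(n0 / K) * exp(-mu * (t - lag))
    else ln ~ log(K) + log(n0 / K) * exp(-mu * t)
  } else {
    if (fit_lag) n ~ K * exp(log(n0 / K) * exp(-mu * (t - lag)))
    else n ~ K * exp(log(n0 / K) * exp(-mu * t))
  }
  start <- list(K = k_init, n0 = n0_init, mu = mu_init)
  if (fit_lag) start$lag <- 0
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = df, start = start,
                      lower = c(K = 1e-9, n0 = 1e-9, mu = 0,
                                if (fit_lag) c(lag = -max(t)) else NULL),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) {
      abort(sprintf("Gompertz fit failed to converge: %s (start K=%.3g n0=%.3g mu=%.3g)",
                    conditionMessage(e), k_init, n0_init, mu_init))
    })
  cf <- stats::coef(fit)
  obj <- new_gompertz_fit(n0 = unname(cf["n0"]), K = unname(cf["K"]),
                          mu = unname(cf["mu"]),
                          lag = if (fit_lag) unname(cf["lag"]) else 0,
                          rss = 0, data = tibble(time_h = t, count = n))
  obj$rss <- sum((n - predict(obj, t))^2)   # reported on the count scale
  obj
}

new_gompertz_fit <- function(n0, K, mu, lag, rss, data) {
  structure(list(n0 = n0, carrying_capacity = K, mu_max = mu, lag = lag,
                 rss = rss, data = data),
            class = "gompertz_fit")
}

#' @export
print.gompertz_fit <- function(x, ...) {
  cat(sprintf("<gompertz_fit> mu = %.4g /h, N0 = %.4g, K = %.4g, RSS = %.4g\n",
              x$mu_max, x$n0, x$carrying_capacity, x$rss))
  invisible(x)
}

#' @export
predict.gompertz_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$data$time_h
  if (object$mu_max == 0) return(rep(object$n0, length(times)))
  object$carrying_capacity *
    exp(log(object$n0 / object$carrying_capacity) *
          exp(-object$mu_max * (times - object$lag)))
}

#' @export
tidy.gompertz_fit <- function(x, ...) {
  tibble(term = c("n0", "carrying_capacity", "mu_max", "lag"),
         estimate = c(x$n0, x$carrying_capacity, x$mu_max, x$lag))
}

#' @export
glance.gompertz_fit <- function(x, ...) {
  tibble(rss = x$rss, n = nrow(x$data), mu_max = x$mu_max)
}

#' Consumption-and-release (CORE) value of a metabolite
#'
#' Signed concentration change `C(t1) - C(t0)` over the culture period:
#' negative = net consumption, positive = net release.
#'
#' @param series Data frame with columns `time_h` and `concentration` (mM).
#' @param t0,t1 Window endpoints in hours (defaults 0 and 96).
#' @param interpolate Allow linear interpolation when the endpoints are not
#'   sampled exactly.
#' @return Signed concentration difference (mM).
#' @export
core_value <- function(series, t0 = 0, t1 = 96, interpolate = FALSE) {
  tt <- series$time_h; cc <- series$concentration
  if (is.null(tt) || is.null(cc)) abort("series needs time_h and concentration columns")
  conc_at <- function(tq) {
    i <- which(abs(tt - tq) < 1e-9)
    if (length(i) >= 1) return(cc[i[1]])
    if (!interpolate) {
      abort(sprintf("time %g h not in series (set interpolate = TRUE to allow it)", tq))
    }
    if (tq < min(tt) || tq > max(tt)) abort(sprintf("time %g h outside series range", tq))
    stats::approx(tt, cc, xout = tq)$y
  }
  conc_at(t1) - conc_at(t0)
}

#' Specific exchange rate from a concentration time course
#'
#' Converts a net extracellular concentration change into a biomass-specific
#' exchange rate: `rate = dC * V / integral(X(t) dt)` over `[t0, t1]`, with
#' `dC` the CORE value (mM = mmol/L), `V` the culture volume (L) and
#' `X(t) = N(t) * dry_weight_per_cell` the biomass (gDW) from the Gompertz
#' fit. Signs follow the exchange convention: consumed metabolites get
#' negative rates.
#'
#' @param series Concentration series (see [core_value()]).
#' @param fit A [fit_gompertz()] result for the same culture.
#' @param culture_volume Culture volume in liters.
#' @param dry_weight_per_cell Dry mass per cell in gDW (default 400 pg, a
#'   typical adherent mammalian-cell dry weight).
#' @param t0,t1 Window in hours.
#' @param interpolate Passed to [core_value()].
#' @return Specific rate in mmol/gDW/h.
#' @export
specific_exchange_rate <- function(series, fit, culture_volume,
                                   dry_weight_per_cell = 4e-10,
                                   t0 = 0, t1 = 96, interpolate = FALSE) {
  stopifnot(culture_volume > 0, dry_weight_per_cell > 0)
  dC <- core_value(series, t0 = t0, t1 = t1, interpolate = interpolate)
  biomass_integral <- stats::integrate(function(tt) predict(fit, tt),
                                       lower = t0, upper = t1,
                                       rel.tol = 1e-9)$value * dry_weight_per_cell
  if (biomass_integral <= 0) abort("biomass integral is zero; cannot normalize the rate")
  dC * culture_volume / biomass_integral
}

#' Exchange-rate table from tidy growth and concentration data
#'
#' Convenience wrapper chaining [fit_gompertz()], [core_value()] and
#' [specific_exchange_rate()] over every metabolite in a tidy concentration
#' table, producing the table [apply_exchange_constraints()] consumes.
#'
#' @param growth Data frame `time_h`, `count`.
#' @param concentrations Data frame `metabolite`, `time_h`, `concentration`.
#' @param culture_volume Liters.
#' @param dry_weight_per_cell gDW per cell.
#' @param t0,t1 Window in hours.
#' @return Tibble `metabolite`, `rate` (mmol/gDW/h), `core_mM`.
#' @export
exchange_rate_table <- function(growth, concentrations, culture_volume,
                                dry_weight_per_cell = 4e-10, t0 = 0, t1 = 96) {
  fit <- fit_gompertz(growth)
  concentrations |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::group_modify(function(d, key) {
      tibble(rate = specific_exchange_rate(d, fit, culture_volume,
                                           dry_weight_per_cell, t0, t1),
             core_mM = core_value(d, t0, t1))
    }) |>
    dplyr::ungroup()
}
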