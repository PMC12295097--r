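#' Configuration for automatic ARIMA order selection
#'
#' @param max_p,max_q maximal AR and MA orders searched (exhaustive grid).
#' @param max_d maximal differencing order.
#' @param criterion information criterion minimised over the grid.
#' @param kpss_alpha significance level of the KPSS level-stationarity test
#'   driving the choice of `d`; one of 0.01, 0.025, 0.05, 0.10.
#' @return An `arima_config` object.
#' @export
arima_config <- function(max_p = 5L, max_q = 5L, max_d = 2L,
                         criterion = c("AICc", "AIC", "BIC"),
                         kpss_alpha = 0.05) {
  criterion <- match.arg(criterion)
  if (min(max_p, max_q, max_d) < 0) stop_value("order maxima must be >= 0")
  if (kpss_alpha <= 0 || kpss_alpha >= 1)
    stop_value("kpss_alpha must be in (0, 1)")
  structure(list(max_p = as.integer(max_p), max_q = as.integer(max_q),
                 max_d = as.integer(max_d), criterion = criterion,
                 kpss_alpha = kpss_alpha),
            class = "arima_config")
}

#' KPSS test for level stationarity
#'
#' Computes the KPSS statistic \eqn{\sum_t S_t^2 / (n^2 \hat\sigma^2_l)} where
#' \eqn{S_t} are partial sums of the demeaned series and
#' \eqn{\hat\sigma^2_l} is the Bartlett-weighted long-run variance with lag
#' truncation \eqn{l = \lfloor 4 (n/100)^{1/4} \rfloor}. The null hypothesis
#' is level stationarity; large statistics reject.
#'
#' @param x numeric series.
#' @param lags lag truncation; default `NULL` uses the rule above.
#' @return A list with `statistic`, `lags` and the `crit` table
#'   (1%, 2.5%, 5%, 10% critical values).
#' @export
kpss_statistic <- function(x, lags = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4L) stop_value("KPSS needs at least 4 observations")
  if (is.null(lags)) lags <- floor(4 * (n / 100)^0.25)
  e <- x - mean(x)
  s2 <- sum(e^2) / n
  if (lags > 0) {
    for (l in seq_len(lags)) {
      w <- 1 - l / (lags + 1)
      s2 <- s2 + 2 * w * sum(e[(l + 1):n] * e[1:(n - l)]) / n
    }
  }
  S <- cumsum(e)
  stat <- if (s2 <= 0) Inf else sum(S^2) / (n^2 * s2)
  list(statistic = stat, lags = lags,
       crit = c(`0.1` = 0.347, `0.05` = 0.463, `0.025` = 0.574, `0.01` = 0.739))
}

# Smallest differencing order (<= max_d) whose KPSS statistic fails to reject
# level stationarity at `alpha`. A (near-)constant series counts as
# stationary immediately.
kpss_ndiffs <- function(x, max_d = 2L, alpha = 0.05) {
  crit_tab <- c(`0.1` = 0.347, `0.05` = 0.463, `0.025` = 0.574, `0.01` = 0.739)
  key <- as.character(alpha)
  if (!key %in% names(crit_tab))
    stop_value("kpss_alpha must be one of %s", paste(names(crit_tab), collapse = ", "))
  crit <- crit_tab[[key]]
  d <- 0L
  y <- as.numeric(x)
  while (d < max_d) {
    if (stats::sd(y) < 1e-12) return(d)
    if (kpss_statistic(y)$statistic < crit) return(d)
    y <- diff(y)
    d <- d + 1L
  }
  d
}

# Information criterion for a fitted stats::arima model.
arima_criterion <- function(fit, n_eff, criterion) {
  k <- length(fit$coef) + 1          # + innovation variance
  switch(criterion,
         AIC = fit$aic,
         AICc = {
           den <- n_eff - k - 1
           if (den <= 0) Inf else fit$aic + 2 * k * (k + 1) / den
         },
         BIC = fit$aic + k * (log(n_eff) - 2))
}

fit_arima_quiet <- function(series, order, include_mean, drift = FALSE) {
  tryCatch(suppressWarnings({
    if (drift) {
      xreg <- matrix(seq_along(series), dimnames = list(NULL, "drift"))
      stats::arima(series, order = order, include.mean = include_mean,
                   xreg = xreg, method = "CSS-ML")
    } else {
      stats::arima(series, order = order, include.mean = include_mean,
                   method = "CSS-ML")
    }
  }), error = function(e) NULL)
}

#' Automatic ARIMA order selection
#'
#' Chooses the differencing order `d` as the smallest order at which the KPSS
#' test no longer rejects level stationarity, then minimises the information
#' criterion over the exhaustive `(p, q)` grid `[0..max_p] x [0..max_q]` on
#' the `d`-differenced series. Ties go to the smaller `p + q`, then the
#' smaller `p`. Models include a mean term when `d = 0`; when `d = 1` the
#' grid additionally tries a drift term (the usual auto-selection
#' convention — trend-dominated series would otherwise be forecast flat),
#' and the winner's drift choice is returned as the `"drift"` attribute.
#'
#' A series whose `d`-th difference is (numerically) constant is a pure
#' degree-`d` polynomial trend; selection short-circuits to `(0, d, 0)` with
#' drift, which [fit_forecast_arima()] continues in closed form.
#'
#' @param series numeric series, length at least 10.
#' @param config an [arima_config()].
#' @return Integer vector `c(p, d, q)`, with logical attribute `drift`.
#' @export
select_arima_order <- function(series, config = arima_config()) {
  stopifnot(inherits(config, "arima_config"))
  series <- as.numeric(series)
  n <- length(series)
  if (n < 10L) stop_value("series too short for order selection (n = %d < 10)", n)
  named_order <- function(p, d, q, drift = FALSE) {
    out <- as.integer(c(p, d, q))
    names(out) <- c("p", "d", "q")
    attr(out, "drift") <- drift
    out
  }
  if (stats::sd(series) < 1e-12) return(named_order(0, 0, 0))
  d <- kpss_ndiffs(series, config$max_d, config$kpss_alpha)
  if (d > 0 && stats::sd(diff(series, differences = d)) < 1e-12)
    return(named_order(0, d, 0, drift = TRUE))
  n_eff <- n - d
  grid <- expand.grid(p = 0:config$max_p, q = 0:config$max_q)
  grid <- grid[order(grid$p + grid$q, grid$p, grid$q), , drop = FALSE]
  best <- NULL; best_crit <- Inf
  for (i in seq_len(nrow(grid))) {
    p <- grid$p[i]; q <- grid$q[i]
    if (p + q + 2 >= n_eff) next      # not enough data to estimate
    for (drift in if (d == 1L) c(FALSE, TRUE) else FALSE) {
      fit <- fit_arima_quiet(series, c(p, d, q), include_mean = d == 0L,
                             drift = drift)
      if (is.null(fit)) next
      crit <- arima_criterion(fit, n_eff, config$criterion)
      if (is.finite(crit) && crit < best_crit - 1e-10) {
        best_crit <- crit
        best <- named_order(p, d, q, drift)
      }
    }
  }
  if (is.null(best))
    stop_estimation("no ARIMA model could be fitted over the (p, q) grid")
  best
}

#' Fit an ARIMA model and forecast
#'
#' Fits `stats::arima` with the given order (CSS-ML; mean term iff `d = 0`;
#' optional drift regressor when `d = 1`) and returns the `h`-step mean
#' forecasts with their standard errors. Degenerate series short-circuit to
#' closed forms: a zero-variance series forecasts its constant, and a series
#' whose `d`-th difference is constant continues the polynomial trend
#' exactly.
#'
#' @param series numeric series.
#' @param order integer `c(p, d, q)`, e.g. from [select_arima_order()].
#' @param h forecast horizon, `>= 1`.
#' @param component optional component label carried into the result.
#' @param drift include a drift regressor (only meaningful for `d = 1`);
#'   defaults to the order's `"drift"` attribute.
#' @return A `score_forecast`: list with `point` (length `h`), `se`,
#'   `method = "ARIMA"`, `order`, `h`, `component`.
#' @export
fit_forecast_arima <- function(series, order, h, component = NA_integer_,
                               drift = isTRUE(attr(order, "drift"))) {
  series <- as.numeric(series)
  force(drift)                 # before the attribute is stripped below
  if (h < 1L) stop_value("h must be >= 1")
  d <- as.integer(order[2L])
  order <- as.integer(order)
  if (length(order) != 3L || any(order < 0L)) stop_value("order must be (p, d, q) >= 0")
  if (stats::sd(series) < 1e-12) {
    return(score_forecast(rep(series[length(series)], h), method = "ARIMA",
                          component = component, se = rep(0, h), order = order))
  }
  if (d > 0 && stats::sd(diff(series, differences = d)) < 1e-12) {
    # exact polynomial trend: extend by keeping the d-th difference constant
    vals <- series
    for (i in seq_len(h)) {
      n <- length(vals)
      nxt <- diff(vals, differences = d)[n - d]   # the constant
      for (k in seq_len(d))
        nxt <- nxt + (-1)^(k + 1) * choose(d, k) * vals[n + 1L - k]
      vals <- c(vals, nxt)
    }
    return(score_forecast(vals[length(series) + seq_len(h)], method = "ARIMA",
                          component = component, se = rep(0, h), order = order))
  }
  fit <- fit_arima_quiet(series, order, include_mean = d == 0L, drift = drift)
  if (is.null(fit))
    stop_estimation("ARIMA(%d,%d,%d) fit failed", order[1L], order[2L], order[3L])
  n <- length(series)
  pr <- if (drift) {
    # predict.Arima re-evaluates the symbol `xreg` from the fitting call in
    # this frame, so it must exist here under that name
    xreg <- matrix(seq_along(series), dimnames = list(NULL, "drift"))
    stats::predict(fit, n.ahead = h,
                   newxreg = matrix(n + seq_len(h), dimnames = list(NULL, "drift")))
  } else {
    stats::predict(fit, n.ahead = h)
  }
  score_forecast(as.numeric(pr$pred), method = "ARIMA", component = component,
                 se = as.numeric(pr$se), order = order)
}

#' Construct a score forecast record
#'
#' @param point numeric vector of `h` point forecasts.
#' @param method `"ARIMA"` or `"LSTM"`.
#' @param component component index the forecast belongs to.
#' @param se optional standard errors (ARIMA only).
#' @param order optional `(p, d, q)` (ARIMA only).
#' @return A `score_forecast` object.
#' @export
score_forecast <- function(point, method, component = NA_integer_,
                           se = NULL, order = NULL) {
  structure(list(point = as.numeric(point), h = length(point),
                 method = method, component = component,
                 se = se, order = order),
            class = "score_forecast")
}
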