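#' Final multi-year forecast with uncertainty
#'
#' Fits the decomposition on the full log panel and forecasts each score
#' series to `horizon_end_year`. With `method = "lstm"`, uncertainty is
#' quantified by Monte-Carlo dropout: each of `n_passes` forward passes
#' forecasts the score paths recursively with dropout active, the paths are
#' reconstructed to counts per pass, and the point forecast / interval bounds
#' are the mean / 2.5 and 97.5 percentiles over passes on the count scale.
#' Propagating uncertainty at the score level keeps the regional forecasts
#' coherent through the shared basis. With `method = "arima"`, point
#' forecasts come from the mean forecasts and intervals are analytic normal
#' intervals on the log scale (independent components), exponentiated.
#'
#' @param panel a [region_year_panel()].
#' @param horizon_end_year last forecast year (`> max(panel$years)`).
#' @param method `"lstm"` (default) or `"arima"`.
#' @param lstm_config an [lstm_config()] (LSTM method).
#' @param arima_config an [arima_config()] (ARIMA method).
#' @param J retained components.
#' @param n_passes MC-dropout forward passes (LSTM method).
#' @param point `"mean"` (default) or `"median"` over MC passes.
#' @param seed base seed for training and the MC mask streams.
#' @return A `forecast_result`: `years`, `point`, `lower95`, `upper95`
#'   (R x h count matrices), `n_passes`, `method`, plus the fitted `model`
#'   and the per-component `score_forecasts` (score-scale point paths).
#' @export
final_forecast <- function(panel, horizon_end_year, method = c("lstm", "arima"),
                           lstm_config = fpcaforecast::lstm_config(),
                           arima_config = fpcaforecast::arima_config(),
                           J = 3L, n_passes = 100L,
                           point = c("mean", "median"), seed = 1L) {
  method <- match.arg(method)
  point <- match.arg(point)
  stopifnot(inherits(panel, "region_year_panel"))
  last_year <- max(panel$years)
  if (horizon_end_year <= last_year)
    stop_value("horizon_end_year must exceed the last panel year (%d)", last_year)
  h <- as.integer(horizon_end_year - last_year)
  years <- seq(last_year + 1L, horizon_end_year)
  model <- fit_fpca(log_transform(panel), J = J)
  K <- model$scores
  R <- length(panel$regions)

  if (method == "lstm") {
    if (n_passes < 2L) stop_value("n_passes must be >= 2 for intervals")
    # per-component MC sample stacks: list of n_passes x h matrices
    samples <- lapply(seq_len(J), function(j) {
      cfg <- lstm_config
      cfg$seed <- derive_seed(seed, 31L, j)
      fc <- train_lstm(K[, j], cfg, component = j)
      mc_dropout_samples(fc, K[, j], h, n_passes = n_passes,
                         seed = derive_seed(seed, 67L, j))
    })
    # reconstruct per pass; counts: n_passes x R x h
    stack <- array(NA_real_, c(n_passes, R, h))
    for (p in seq_len(n_passes)) {
      khat <- vapply(samples, function(s) s[p, ], numeric(h))  # h x J
      stack[p, , ] <- reconstruct(model, matrix(khat, nrow = h))
    }
    point_mat <- apply(stack, c(2L, 3L), if (point == "mean") mean else stats::median)
    lower <- apply(stack, c(2L, 3L), stats::quantile, probs = 0.025, names = FALSE)
    upper <- apply(stack, c(2L, 3L), stats::quantile, probs = 0.975, names = FALSE)
    score_fc <- lapply(seq_len(J), function(j)
      score_forecast(colMeans(samples[[j]]), "LSTM", component = j))
  } else {
    score_fc <- lapply(seq_len(J), function(j) {
      order <- select_arima_order(K[, j], arima_config)
      fit_forecast_arima(K[, j], order, h, component = j)
    })
    khat <- vapply(score_fc, `[[`, numeric(h), "point")        # h x J
    kse <- vapply(score_fc, `[[`, numeric(h), "se")
    log_point <- model$mu + model$basis %*% t(matrix(khat, nrow = h))
    # independent score components: log-scale forecast sd per region/year
    log_sd <- sqrt(model$basis^2 %*% t(matrix(kse, nrow = h)^2))
    point_mat <- exp(log_point)
    lower <- exp(log_point - 1.959964 * log_sd)
    upper <- exp(log_point + 1.959964 * log_sd)
    n_passes <- NA_integer_
  }
  dimnames(point_mat) <- dimnames(lower) <- dimnames(upper) <-
    list(panel$regions, years)
  structure(list(years = years, point = point_mat,
                 lower95 = lower, upper95 = upper,
                 n_passes = n_passes, method = toupper(method),
                 model = model, score_forecasts = score_fc),
            class = "forecast_result")
}

#' @export
print.forecast_result <- function(x, ...) {
  cat(sprintf("forecast_result (%s): %d regions x %d years (%d-%d)%s\n",
              x$method, nrow(x$point), length(x$years),
              min(x$years), max(x$years),
              if (is.na(x$n_passes)) "" else sprintf(", %d MC passes", x$n_passes)))
  invisible(x)
}

#' Write a forecast result to CSV
#'
#' Writes three wide CSVs (point, lower95, upper95; one row per region,
#' columns = forecast years) plus a single long CSV with columns
#' `region,year,point,lower95,upper95`.
#'
#' @param result a [final_forecast()] result.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_forecast_result <- function(result, dir, prefix = "forecast") {
  stopifnot(inherits(result, "forecast_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (part in c("point", "lower95", "upper95")) {
    df <- data.frame(region = rownames(result[[part]]),
                     result[[part]], check.names = FALSE)
    p <- file.path(dir, sprintf("%s_%s.csv", prefix, part))
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  long <- data.frame(
    region = rep(rownames(result$point), times = length(result$years)),
    year = rep(result$years, each = nrow(result$point)),
    point = as.vector(result$point),
    lower95 = as.vector(result$lower95),
    upper95 = as.vector(result$upper95))
  p <- file.path(dir, sprintf("%s_long.csv", prefix))
  utils::write.csv(long, p, row.names = FALSE, quote = FALSE)
  invisible(c(paths, p))
}

#' Average annual growth implied by two endpoint counts
#'
#' Convenience for headline reporting: the straight-line annual growth rate
#' `(last - first) / n_years` between two observed counts.
#'
#' @param first,last endpoint counts.
#' @param n_years number of elapsed years between them.
#' @return Growth per year, same units as the counts.
#' @examples
#' annual_growth_rate(2198, 10540, 24)
#' @export
annual_growth_rate <- function(first, last, n_years) {
  if (n_years <= 0) stop_value("n_years must be positive")
  (last - first) / n_years
}
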