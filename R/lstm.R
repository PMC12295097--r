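#' Configuration of the LSTM score forecaster
#'
#' One univariate network per score component: a single LSTM layer, a dropout
#' layer on its output, and a dense linear head; trained with Adam on mean
#' squared error. Series are min-max scaled to `[0, 1]` before training and
#' forecasts are inverse-scaled, which keeps gradients bounded for the
#' small-magnitude score series.
#'
#' @param units LSTM hidden units.
#' @param dropout_rate dropout fraction on the LSTM output, in `[0, 1)`; also
#'   the rate used for Monte-Carlo-dropout inference.
#' @param lookback length of the input window in years.
#' @param learning_rate Adam step size.
#' @param epochs training epochs (no early stopping).
#' @param batch_size minibatch size; batches are drawn from a seeded
#'   per-epoch shuffle.
#' @param seed integer seed controlling initialisation, shuffling, dropout
#'   masks and MC-dropout passes. Identical seeds give bit-identical weights
#'   and forecasts.
#' @return An `lstm_config` object.
#' @export
lstm_config <- function(units = 50L, dropout_rate = 0.2, lookback = 3L,
                        learning_rate = 0.001, epochs = 200L, batch_size = 4L,
                        seed = 1L) {
  if (units < 1L) stop_value("units must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop_value("dropout_rate must be in [0, 1)")
  if (lookback < 1L) stop_value("lookback must be >= 1")
  if (learning_rate <= 0) stop_value("learning_rate must be positive")
  structure(list(units = as.integer(units), dropout_rate = dropout_rate,
                 lookback = as.integer(lookback),
                 learning_rate = learning_rate, loss = "MSE",
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "lstm_config")
}

#' Build overlapping supervised windows from a series
#'
#' Window `t .. t+lookback-1` predicts element `t+lookback`; windows overlap,
#' giving exactly `length(series) - lookback` pairs.
#'
#' @param series numeric series.
#' @param lookback window length; must be `< length(series)`.
#' @return A list with `x` (n x lookback matrix) and `y` (length-n targets).
#' @examples
#' make_supervised(1:5, 3)
#' @export
make_supervised <- function(series, lookback) {
  series <- as.numeric(series)
  n <- length(series)
  if (n <= lookback)
    stop_value("series length (%d) must exceed lookback (%d)", n, lookback)
  m <- n - lookback
  x <- t(vapply(seq_len(m), function(i) series[i:(i + lookback - 1L)],
                numeric(lookback)))
  list(x = matrix(x, nrow = m), y = series[(lookback + 1L):n])
}

# Min-max scaling helpers shared by training and forecasting.
scale_params <- function(series) {
  lo <- min(series); hi <- max(series)
  list(lo = lo, span = if (hi > lo) hi - lo else 1)
}
scale_series <- function(series, sp) (series - sp$lo) / sp$span
unscale_series <- function(scaled, sp) scaled * sp$span + sp$lo

#' Train an LSTM forecaster on a score series
#'
#' @param series numeric score series (training window).
#' @param config an [lstm_config()].
#' @param component optional component label carried into forecasts.
#' @return An `lstm_forecaster`: trained weights, the scaling parameters, and
#'   the config.
#' @export
train_lstm <- function(series, config = lstm_config(), component = NA_integer_) {
  stopifnot(inherits(config, "lstm_config"))
  series <- as.numeric(series)
  if (length(series) <= config$lookback + 1L)
    stop_value("series too short (%d) for lookback %d: need at least 2 pairs",
               length(series), config$lookback)
  sp <- scale_params(series)
  sup <- make_supervised(scale_series(series, sp), config$lookback)
  weights <- cpp_lstm_train(sup$x, sup$y, config$units, config$dropout_rate,
                            config$learning_rate, config$epochs,
                            config$batch_size, as.double(config$seed))
  structure(list(weights = weights, scaling = sp, config = config,
                 component = component),
            class = "lstm_forecaster")
}

#' Forecast with a trained LSTM
#'
#' One step ahead uses the last look-back window; longer horizons are
#' recursive, feeding each prediction back into the window. Dropout is
#' disabled (deterministic forecast); see [mc_dropout_samples()] for
#' uncertainty.
#'
#' @param forecaster a trained [train_lstm()] forecaster.
#' @param series the series to forecast from (at least `lookback` long);
#'   typically the training series itself.
#' @param h horizon, `>= 1`.
#' @return A [score_forecast()] with `method = "LSTM"`.
#' @export
forecast_lstm <- function(forecaster, series, h) {
  stopifnot(inherits(forecaster, "lstm_forecaster"))
  if (h < 1L) stop_value("h must be >= 1")
  cfg <- forecaster$config
  series <- as.numeric(series)
  if (length(series) < cfg$lookback)
    stop_value("series shorter than lookback window")
  win <- scale_series(utils::tail(series, cfg$lookback), forecaster$scaling)
  out <- cpp_lstm_forecast(forecaster$weights, win, as.integer(h),
                           cfg$dropout_rate, FALSE, 1L, as.double(cfg$seed))
  score_forecast(unscale_series(out[1L, ], forecaster$scaling),
                 method = "LSTM", component = forecaster$component)
}

#' Monte-Carlo-dropout forecast samples
#'
#' Runs the recursive `h`-step forecast `n_passes` times with dropout active
#' at inference, drawing an independent seeded mask stream per pass. The
#' spread across passes is the model's predictive uncertainty (approximate
#' Bayesian inference over dropout sub-networks). With `dropout_rate = 0` all
#' passes are identical.
#'
#' @param forecaster a trained [train_lstm()] forecaster.
#' @param series series to forecast from.
#' @param h horizon.
#' @param n_passes number of stochastic forward passes.
#' @param seed seed for the mask stream (independent of the training seed).
#' @return An `n_passes` x `h` matrix of forecasts on the score scale.
#' @export
mc_dropout_samples <- function(forecaster, series, h, n_passes = 100L,
                               seed = forecaster$config$seed) {
  stopifnot(inherits(forecaster, "lstm_forecaster"))
  if (n_passes < 1L) stop_value("n_passes must be >= 1")
  if (h < 1L) stop_value("h must be >= 1")
  cfg <- forecaster$config
  series <- as.numeric(series)
  if (length(series) < cfg$lookback)
    stop_value("series shorter than lookback window")
  win <- scale_series(utils::tail(series, cfg$lookback), forecaster$scaling)
  out <- cpp_lstm_forecast(forecaster$weights, win, as.integer(h),
                           cfg$dropout_rate, TRUE, as.integer(n_passes),
                           as.double(seed))
  unscale_series(out, forecaster$scaling)
}
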