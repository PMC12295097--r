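#' Absolute percentage error
#'
#' @param actual positive actual value(s).
#' @param forecast forecast value(s).
#' @return `|actual - forecast| / actual * 100`, elementwise.
#' @examples
#' ape(100, 103)
#' @export
ape <- function(actual, forecast) {
  if (any(actual <= 0)) stop_value("APE needs strictly positive actuals")
  abs(actual - forecast) / actual * 100
}

# One fold of score forecasting: returns the length-J vector of 1-step (or
# h-step) score forecasts for the fitted model's score matrix K.
forecast_scores <- function(K, method, method_config, h, seed_base, fold) {
  J <- ncol(K)
  vapply(seq_len(J), function(j) {
    series <- K[, j]
    if (method == "arima") {
      cfg <- method_config %||% arima_config()
      order <- select_arima_order(series, cfg)
      fit_forecast_arima(series, order, h, component = j)$point
    } else {
      cfg <- method_config %||% lstm_config()
      cfg$seed <- derive_seed(seed_base, fold, j)
      fc <- train_lstm(series, cfg, component = j)
      forecast_lstm(fc, series, h)$point
    }
  }, numeric(h))
}

#' Rolling-origin expanding-window cross-validation
#'
#' Fold `k` trains on years `start .. first_train_end + k - 1` and forecasts
#' the following year; folds advance until the final panel year has been
#' tested, so the training window expands one year at a time and no training
#' window ever contains its test year. Within each fold the decomposition is
#' refit on the fold's log training matrix, each score series is forecast one
#' step by the chosen method, the forecast year-curve is reconstructed and
#' exponentiated, and per-region absolute percentage errors are recorded
#' against the held-out year. On a 25-year panel with the default
#' `first_train_end` 16 years in, this yields 9 folds.
#'
#' Fold failures raise: aggregates are never silently computed on a subset.
#'
#' @param panel a [region_year_panel()].
#' @param method `"arima"` or `"lstm"`.
#' @param method_config an [arima_config()] or [lstm_config()]; defaults per
#'   method.
#' @param J retained components per fold.
#' @param first_train_end last year of the first training window; default 16
#'   years after the panel start (e.g. 2015 on a 2000-start panel).
#' @param seed base seed for per-fold, per-component forecaster seeds (LSTM).
#' @param .score_permuter internal: optional `function(K, fold)` applied to
#'   the fold's training score matrix before forecaster training (used by
#'   [permutation_test()]).
#' @return A `cv_report`: `folds` (data frame of train_end/test years),
#'   `ape` (region x fold matrix of APE percentages), `mape_by_region`,
#'   `mape_by_year`, `mape_overall`, `method`.
#' @export
rolling_origin_cv <- function(panel, method = c("arima", "lstm"),
                              method_config = NULL, J = 3L,
                              first_train_end = min(panel$years) + 15L,
                              seed = 1L, .score_permuter = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(panel, "region_year_panel"))
  if (first_train_end < min(panel$years) + 3L)
    stop_value("first_train_end must leave at least 4 training years")
  if (first_train_end >= max(panel$years))
    stop_value("no test years remain after first_train_end = %d", first_train_end)
  test_years <- (first_train_end + 1L):max(panel$years)
  R <- length(panel$regions)
  ape_mat <- matrix(NA_real_, R, length(test_years),
                    dimnames = list(panel$regions, test_years))
  for (k in seq_along(test_years)) {
    train_end <- test_years[k] - 1L
    train <- window_panel(panel, end_year = train_end)
    model <- fit_fpca(log_transform(train), J = J)
    K <- model$scores
    if (!is.null(.score_permuter)) K <- .score_permuter(K, k)
    khat <- forecast_scores(K, method, method_config, h = 1L,
                            seed_base = seed, fold = k)
    yhat <- reconstruct(model, matrix(khat, nrow = 1L))[, 1L]
    actual <- panel$counts[, match(test_years[k], panel$years)]
    ape_mat[, k] <- ape(actual, yhat)
  }
  new_cv_report(ape_mat, test_years, method)
}

new_cv_report <- function(ape_mat, test_years, method) {
  structure(list(
    folds = data.frame(train_end_year = test_years - 1L, test_year = test_years),
    ape = ape_mat,
    mape_by_region = rowMeans(ape_mat),
    mape_by_year = colMeans(ape_mat),
    mape_overall = mean(ape_mat),
    method = method), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report (%s): %d folds (test years %d-%d)\n", x$method,
              nrow(x$folds), min(x$folds$test_year), max(x$folds$test_year)))
  cat(sprintf("  overall MAPE %.2f%% | by region %.2f-%.2f%% | by year %.2f-%.2f%%\n",
              x$mape_overall, min(x$mape_by_region), max(x$mape_by_region),
              min(x$mape_by_year), max(x$mape_by_year)))
  invisible(x)
}

#' MAPE aggregates of a CV report
#'
#' Recomputes the arithmetic means over the APE grid: per region (over
#' folds), per test year (over regions), and overall (over all cells).
#'
#' @param report a `cv_report` (or any object with an `ape` matrix).
#' @return List with `by_region`, `by_year`, `overall`.
#' @export
aggregate_mape <- function(report) {
  ape_mat <- report$ape
  if (is.null(ape_mat) || !length(ape_mat)) stop_value("report has no APE grid")
  list(by_region = rowMeans(ape_mat),
       by_year = colMeans(ape_mat),
       overall = mean(ape_mat))
}

#' In-sample fitting accuracy
#'
#' Fits the decomposition on the whole given panel, reconstructs the same
#' window from the fitted scores, and reports APE/MAPE of the reconstruction
#' against the observed counts. Pass a [window_panel()] of the training
#' timeframe to evaluate fit quality on a sub-span.
#'
#' @param panel a [region_year_panel()].
#' @param J retained components.
#' @return List with `ape` (region x year matrix), `by_region`, `by_year`,
#'   `overall`.
#' @export
fitting_mape <- function(panel, J = 3L) {
  stopifnot(inherits(panel, "region_year_panel"))
  model <- fit_fpca(log_transform(panel), J = J)
  fitted <- reconstruct(model)
  ape_mat <- ape(panel$counts, fitted)
  dimnames(ape_mat) <- dimnames(panel$counts)
  list(ape = ape_mat, by_region = rowMeans(ape_mat),
       by_year = colMeans(ape_mat), overall = mean(ape_mat))
}

#' Score-permutation significance test of the LSTM pipeline
#'
#' Compares the observed rolling-origin CV MAPE of the LSTM pipeline against
#' a null distribution obtained by destroying the temporal order of the
#' scores: in each of `B` iterations, one random row permutation is applied
#' to every fold's training score matrix (jointly across components, so
#' cross-component alignment is kept) before the supervised windows are built
#' and the LSTM retrained; the decomposition itself is left intact. The
#' p-value is the fraction of permuted MAPEs at or below the observed MAPE
#' (count/B; anti-conservative — with finite B a true null would still report
#' 0 occasionally).
#'
#' @param panel a [region_year_panel()].
#' @param B number of permutation iterations.
#' @param seed base seed (observed run and permutation streams).
#' @param lstm_config an [lstm_config()].
#' @param first_train_end see [rolling_origin_cv()].
#' @param J retained components.
#' @param joint permute rows jointly across components (default) or
#'   independently per component.
#' @return A `permutation_test_result`: `n_iterations`, `observed_mape`,
#'   `permuted_mapes`, `mean_permuted`, `ci95`, `p_value`.
#' @export
permutation_test <- function(panel, B = 50L, seed = 1L,
                             lstm_config = fpcaforecast::lstm_config(),
                             first_train_end = min(panel$years) + 15L,
                             J = 3L, joint = TRUE) {
  if (B < 1L) stop_value("B must be >= 1")
  observed <- rolling_origin_cv(panel, "lstm", lstm_config, J = J,
                                first_train_end = first_train_end, seed = seed)
  permuted <- vapply(seq_len(B), function(b) {
    permuter <- function(K, fold) {
      with_seed(derive_seed(seed, 7919L, b, fold), {
        if (joint) {
          K[sample.int(nrow(K)), , drop = FALSE]
        } else {
          apply(K, 2L, function(col) col[sample.int(length(col))])
        }
      })
    }
    rep <- rolling_origin_cv(panel, "lstm", lstm_config, J = J,
                             first_train_end = first_train_end, seed = seed,
                             .score_permuter = permuter)
    rep$mape_overall
  }, numeric(1L))
  ci <- stats::quantile(permuted, c(0.025, 0.975), names = FALSE)
  structure(list(n_iterations = as.integer(B),
                 observed_mape = observed$mape_overall,
                 permuted_mapes = permuted,
                 mean_permuted = mean(permuted),
                 ci95 = ci,
                 p_value = mean(permuted <= observed$mape_overall)),
            class = "permutation_test_result")
}

#' @export
print.permutation_test_result <- function(x, ...) {
  cat(sprintf(paste0("permutation test (B = %d): observed MAPE %.2f%%, ",
                     "permuted mean %.2f%% [%.2f, %.2f], p = %.3f\n"),
              x$n_iterations, x$observed_mape, x$mean_permuted,
              x$ci95[1L], x$ci95[2L], x$p_value))
  invisible(x)
}

#' Write a CV report to JSON and a long CSV
#'
#' The CSV has columns `region,year,method,ape` (one row per cell), the shape
#' heatmap plotters expect.
#'
#' @param report a `cv_report`.
#' @param json_path,csv_path output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_cv_report <- function(report, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(report, "cv_report"))
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      method = report$method, folds = report$folds, ape = report$ape,
      mape_by_region = report$mape_by_region,
      mape_by_year = report$mape_by_year,
      mape_overall = report$mape_overall,
      regions = rownames(report$ape)), json_path, digits = NA, auto_unbox = TRUE)
  }
  if (!is.null(csv_path)) {
    long <- data.frame(
      region = rep(rownames(report$ape), times = ncol(report$ape)),
      year = rep(report$folds$test_year, each = nrow(report$ape)),
      method = report$method,
      ape = as.vector(report$ape))
    utils::write.csv(long, csv_path, row.names = FALSE, quote = FALSE)
  }
  invisible(c(json_path, csv_path))
}

#' Write a permutation-test result to JSON
#'
#' @param result a `permutation_test_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_permutation_result <- function(result, path) {
  stopifnot(inherits(result, "permutation_test_result"))
  jsonlite::write_json(unclass(result), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
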