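test_that("LSTM final forecast has the right shape and ordered positive intervals", {
  sim <- generate_panel(synthetic_spec(n_regions = 6, n_years = 14, seed = 19,
                                       variance_shares = c(0.9, 0.05)))
  res <- final_forecast(sim$panel, 2017, method = "lstm",
                        lstm_config = small_lstm(seed = 2), J = 2,
                        n_passes = 60, seed = 8)
  expect_identical(res$years, 2014:2017)
  expect_identical(dim(res$point), c(6L, 4L))
  expect_true(all(res$point > 0))
  expect_true(all(res$lower95 > 0))
  expect_true(all(res$lower95 < res$upper95))
  expect_true(all(res$lower95 <= res$point * (1 + 1e-12)))
  # median point option sits inside the percentile bounds by construction
  med <- final_forecast(sim$panel, 2016, method = "lstm",
                        lstm_config = small_lstm(seed = 2), J = 2,
                        n_passes = 40, point = "median", seed = 8)
  expect_true(all(med$lower95 <= med$point & med$point <= med$upper95))
  expect_error(final_forecast(sim$panel, 2013), class = "fpca_value_error")
})

test_that("zero dropout gives zero-width intervals equal to the point path", {
  sim <- generate_panel(synthetic_spec(n_regions = 5, n_years = 12, seed = 3,
                                       variance_shares = c(0.9, 0.05)))
  res <- final_forecast(sim$panel, 2014, method = "lstm",
                        lstm_config = small_lstm(seed = 1, dropout_rate = 0),
                        J = 2, n_passes = 30, seed = 5)
  expect_equal(res$lower95, res$point, tolerance = 1e-12)
  expect_equal(res$upper95, res$point, tolerance = 1e-12)
})

test_that("noiseless exponential trends are extended within 5%", {
  sim <- linear_panel(n_regions = 6, n_years = 25)
  tr <- sim$truth
  res <- final_forecast(sim$panel, 2027, method = "lstm",
                        lstm_config = lstm_config(dropout_rate = 0, seed = 4),
                        J = 1, n_passes = 2, seed = 4)
  # truth: scores continue linearly at the same slope
  slope <- diff(tr$scores[1:2, 1])
  k_future <- tr$scores[25, 1] + slope * (1:3)
  truth_counts <- exp(tr$mu + tr$basis %*% t(matrix(k_future, 3, 1)))
  expect_lt(max(abs(res$point - truth_counts) / truth_counts), 0.05)
  # ARIMA recognises the polynomial trend and extends it almost exactly
  res_a <- final_forecast(sim$panel, 2027, method = "arima", J = 1)
  expect_lt(max(abs(res_a$point - truth_counts) / truth_counts), 1e-6)
})

test_that("ARIMA final forecasts carry analytic intervals", {
  sim <- generate_panel(synthetic_spec(n_regions = 6, n_years = 16, seed = 29,
                                       variance_shares = c(0.92, 0.05)))
  res <- final_forecast(sim$panel, 2019, method = "arima", J = 2,
                        arima_config = arima_config(max_p = 2, max_q = 2))
  expect_identical(res$method, "ARIMA")
  expect_true(is.na(res$n_passes))
  expect_true(all(res$lower95 < res$point & res$point < res$upper95))
  # interval width grows with horizon on average over regions
  w <- res$upper95 - res$lower95
  expect_gt(mean(w[, ncol(w)] / res$point[, ncol(w)]),
            mean(w[, 1] / res$point[, 1]))
})

test_that("MC interval width is non-decreasing in horizon on average", {
  widen <- vapply(1:5, function(seed) {
    sim <- generate_panel(synthetic_spec(n_regions = 5, n_years = 12,
                                         seed = seed,
                                         variance_shares = c(0.9, 0.05)))
    res <- final_forecast(sim$panel, 2015, method = "lstm",
                          lstm_config = small_lstm(seed = seed), J = 2,
                          n_passes = 60, seed = seed)
    rel_w <- (res$upper95 - res$lower95) / res$point
    mean(rel_w[, 4]) >= mean(rel_w[, 1])
  }, logical(1))
  expect_gte(mean(widen), 0.8)   # widening generically, tolerate single flips
})

test_that("two independent MC runs agree within Monte-Carlo error", {
  sim <- generate_panel(synthetic_spec(n_regions = 6, n_years = 14, seed = 5,
                                       variance_shares = c(0.9, 0.05)))
  np <- 100
  f1 <- final_forecast(sim$panel, 2017, lstm_config = small_lstm(seed = 3),
                       J = 2, n_passes = np, seed = 101)
  f2 <- final_forecast(sim$panel, 2017, lstm_config = small_lstm(seed = 3),
                       J = 2, n_passes = np, seed = 202)
  # pass sd from the percentile width; difference of two MC means should be
  # within ~5 combined standard errors everywhere
  sd_hat <- (f1$upper95 - f1$lower95) / (2 * 1.959964)
  z <- abs(f1$point - f2$point) / (sd_hat * sqrt(2 / np))
  expect_lt(max(z), 5)
})

test_that("forecast results serialise to wide and long CSV", {
  sim <- generate_panel(synthetic_spec(n_regions = 5, n_years = 12, seed = 7,
                                       variance_shares = c(0.9, 0.05)))
  res <- final_forecast(sim$panel, 2014, lstm_config = small_lstm(seed = 2),
                        J = 2, n_passes = 20, seed = 3)
  d <- tempfile()
  paths <- write_forecast_result(res, d)
  expect_true(all(file.exists(paths)))
  wide <- read.csv(file.path(d, "forecast_point.csv"), check.names = FALSE)
  expect_identical(dim(wide), c(5L, 4L))   # region column + 3 years
  long <- read.csv(file.path(d, "forecast_long.csv"))
  expect_identical(nrow(long), 15L)
  expect_equal(long$point, as.vector(res$point), tolerance = 1e-12)
})

test_that("annual growth rate matches straight-line arithmetic", {
  expect_equal(annual_growth_rate(2198, 10540, 24), 347.5833, tolerance = 1e-4)
  expect_equal(annual_growth_rate(100, 100, 10), 0)
  expect_error(annual_growth_rate(1, 2, 0), class = "fpca_value_error")
})
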