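test_that("noiseless generation is exactly recovered by the decomposition", {
  spec <- synthetic_spec(variance_shares = c(0.95, 0.03, 0.02), noise_sd = 0,
                         seed = 3)
  sim <- generate_panel(spec)
  model <- fit_fpca(log_transform(sim$panel), J = 3)
  expect_lt(max(abs(explained_variance(model) - spec$variance_shares)), 1e-6)
  # basis recovered up to sign
  dots <- abs(colSums(model$basis * sim$truth$basis))
  expect_true(all(dots > 1 - 1e-9))
  # scores recovered up to the same sign, relative error 1e-6
  for (j in 1:3) {
    s <- sign(sum(model$basis[, j] * sim$truth$basis[, j]))
    rel <- max(abs(model$scores[, j] * s - sim$truth$scores[, j])) /
      max(abs(sim$truth$scores[, j]))
    expect_lt(rel, 1e-6)
  }
  # mu identified as the time-mean
  expect_equal(unname(model$mu), sim$truth$mu, tolerance = 1e-10)
})

test_that("degenerate spec with all-zero scores gives a flat panel", {
  spec <- synthetic_spec(n_regions = 5, n_years = 6,
                         variance_shares = 0.9,
                         score_models = list(list(slope = 0, ar_coef = 0,
                                                  innovation_sd = 0)),
                         noise_sd = 0, seed = 1)
  sim <- generate_panel(spec)
  expect_equal(sim$panel$counts, matrix(exp(spec$mean_function), 5, 6,
                                        dimnames = dimnames(sim$panel$counts)),
               tolerance = 1e-12)
  expect_error(fit_fpca(log_transform(sim$panel), J = 2),
               class = "fpca_degenerate_error")
})

test_that("generation is deterministic in the seed and positive everywhere", {
  spec <- synthetic_spec(seed = 11)
  a <- generate_panel(spec)
  b <- generate_panel(spec)
  expect_identical(a$panel$counts, b$panel$counts)
  expect_identical(a$truth$scores, b$truth$scores)
  c_ <- generate_panel(synthetic_spec(seed = 12))
  expect_false(identical(a$panel$counts, c_$panel$counts))
  expect_true(all(a$panel$counts > 0))
  # generator does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(generate_panel(spec)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("invalid specs are rejected", {
  expect_error(synthetic_spec(variance_shares = c(0.8, 0.3)),
               class = "fpca_value_error")
  expect_error(synthetic_spec(n_years = 3), class = "fpca_value_error")
  expect_error(synthetic_spec(noise_sd = -1), class = "fpca_value_error")
  expect_error(synthetic_spec(loading_signs = rep(2, 16)),
               class = "fpca_value_error")
})

test_that("recovered leading share is consistent with its design value under noise", {
  # The sample eigen-share slightly exceeds the design share because each
  # retained direction also absorbs the noise projected onto it; compare the
  # Monte-Carlo mean against the first-order expectation that accounts for
  # this leakage.
  n_rep <- 100
  got <- numeric(n_rep); expected <- numeric(n_rep)
  for (s in seq_len(n_rep)) {
    sim <- generate_panel(synthetic_spec(seed = s))
    tr <- sim$truth
    ssj <- colSums(tr$scores^2)
    sig2 <- tr$noise_sd^2
    Tn <- ncol(tr$log_panel); R <- nrow(tr$log_panel)
    expected[s] <- (ssj[1] + sig2 * (Tn - 1)) /
      (sum(ssj) + sig2 * R * (Tn - 1))
    got[s] <- explained_variance(fit_fpca(log_transform(sim$panel), 3))[1]
  }
  mc_se <- sd(got - expected) / sqrt(n_rep)
  expect_lt(abs(mean(got - expected)), 3 * mc_se)
  # and each replicate sits near the nominal design value
  expect_true(all(abs(got - 0.947) < 0.02))
})

test_that("anomaly injection matches its definitions and touches nothing else", {
  p <- tiny_panel(R = 3, T_ = 8, seed = 5)
  before <- p$counts
  sp <- inject_anomalies(p, list(list(region = "R2", year = 2004,
                                      kind = "spike", magnitude = 0.15)))
  expect_equal(unname(sp$counts["R2", "2004"]),
               unname(before["R2", "2004"]) * 1.15)
  untouched <- sp$counts; untouched["R2", "2004"] <- before["R2", "2004"]
  expect_identical(untouched, before)

  expect_identical(inject_anomalies(p, list())$counts, before)

  # dip-and-rebound on a monotone upward panel: dip below previous year,
  # rebound above the dipped year
  mono <- linear_panel(n_regions = 4, n_years = 10)$panel
  dr <- inject_anomalies(mono, list(list(region = "R1", year = 2004,
                                         kind = "dip_rebound", magnitude = 0.1)))
  yi <- match(2004, dr$years)
  expect_lt(dr$counts["R1", yi], dr$counts["R1", yi - 1])
  expect_gt(dr$counts["R1", yi + 1], dr$counts["R1", yi])

  expect_error(inject_anomalies(p, list(list(region = "R1", year = 2007,
                                             kind = "dip_rebound",
                                             magnitude = 0.1))),
               class = "fpca_value_error")   # final year has no rebound year
  expect_error(inject_anomalies(p, list(list(region = "R1", year = 2004,
                                             kind = "meteor", magnitude = 1))),
               class = "fpca_value_error")
})

test_that("synthetic specs serialise and reload", {
  spec <- synthetic_spec(n_regions = 6, n_years = 10, seed = 21,
                         variance_shares = c(0.9, 0.1), noise_sd = 0.05,
                         score_models = list(
                           list(slope = 0.1, ar_coef = 0.5, innovation_sd = 0.02),
                           list(slope = 0, ar_coef = 0.6, innovation_sd = 1)))
  f <- tempfile(fileext = ".json")
  write_synthetic_spec(spec, f)
  spec2 <- read_synthetic_spec(f)
  expect_equal(spec2$variance_shares, spec$variance_shares)
  # decimal serialisation is not bit-exact, but the panels agree to 1e-12
  expect_equal(generate_panel(spec2)$panel$counts,
               generate_panel(spec)$panel$counts, tolerance = 1e-12)
})
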