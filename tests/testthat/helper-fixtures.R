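# Shared fixtures and independent oracles. Everything is generated in code;
# no data files.

# A small positive panel with mild structure, deterministic in `seed`.
tiny_panel <- function(R = 4, T_ = 8, seed = 1, start_year = 2000) {
  set.seed(seed)
  base <- exp(seq(log(500), log(5000), length.out = R))
  trend <- seq(0, 0.4, length.out = T_)
  counts <- outer(base, exp(trend)) * exp(matrix(rnorm(R * T_, 0, 0.02), R, T_))
  region_year_panel(counts, years = seq(start_year, length.out = T_),
                    regions = paste0("R", seq_len(R)))
}

# A noiseless panel whose single score series is exactly linear in time.
linear_panel <- function(n_regions = 8, n_years = 25, seed = 9) {
  generate_panel(synthetic_spec(
    n_regions = n_regions, n_years = n_years,
    variance_shares = 1,
    score_models = list(list(slope = 0.12, ar_coef = 0, innovation_sd = 0)),
    noise_sd = 0, seed = seed))
}

# Reduced LSTM configuration for fast unit tests (the full 50-unit default is
# exercised in the acceptance suite).
small_lstm <- function(seed = 1, units = 20L, epochs = 60L, ...) {
  lstm_config(units = units, epochs = epochs, seed = seed, ...)
}

# Independent brute-force FPCA oracle: explicit covariance eigendecomposition
# (divisor T), scores by projection. Kept deliberately separate from the
# package's SVD path.
eigen_oracle <- function(X, J) {
  mu <- rowMeans(X)
  C <- X - mu
  S <- C %*% t(C) / ncol(X)
  eg <- eigen(S, symmetric = TRUE)
  vals <- eg$values[seq_len(J)]
  vecs <- eg$vectors[, seq_len(J), drop = FALSE]
  list(mu = mu,
       shares = eg$values[seq_len(J)] / sum(eg$values),
       basis = vecs,
       scores = t(C) %*% vecs,
       eigenvalues = vals)
}

# Independent KPSS implementation (level stationarity), written from the
# autocovariance form of the Newey-West long-run variance.
kpss_oracle <- function(x, lags) {
  n <- length(x)
  e <- x - mean(x)
  gamma0 <- mean(e^2)
  lrv <- gamma0
  if (lags > 0) {
    for (l in seq_len(lags)) {
      gl <- mean(e[seq_len(n - l)] * e[seq_len(n - l) + l]) * (n - l) / n
      lrv <- lrv + 2 * (1 - l / (lags + 1)) * gl
    }
  }
  sum(cumsum(e)^2) / (n^2 * lrv)
}

# Exhaustive-grid ARIMA selection oracle: plain loops, AICc recomputed from
# scratch, ties resolved by iteration order over increasing (p+q, p).
arima_grid_oracle <- function(series, max_p, max_q, d) {
  n_eff <- length(series) - d
  best <- NULL; best_crit <- Inf
  for (sum_pq in 0:(max_p + max_q)) {
    for (p in 0:max_p) {
      q <- sum_pq - p
      if (q < 0 || q > max_q) next
      if (p + q + 2 >= n_eff) next
      for (drift in if (d == 1) c(FALSE, TRUE) else FALSE) {
        fit <- tryCatch(suppressWarnings({
          if (drift) {
            xreg <- matrix(seq_along(series), dimnames = list(NULL, "drift"))
            arima(series, order = c(p, d, q), xreg = xreg, method = "CSS-ML")
          } else {
            arima(series, order = c(p, d, q), include.mean = d == 0,
                  method = "CSS-ML")
          }
        }), error = function(e) NULL)
        if (is.null(fit)) next
        k <- length(fit$coef) + 1
        crit <- if (n_eff - k - 1 <= 0) Inf else
          fit$aic + 2 * k * (k + 1) / (n_eff - k - 1)
        if (is.finite(crit) && crit < best_crit - 1e-10) {
          best_crit <- crit
          best <- list(order = c(p, d, q), drift = drift, crit = crit)
        }
      }
    }
  }
  best
}
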