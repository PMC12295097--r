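#' Specification for a synthetic region-by-year panel
#'
#' Describes the generative model used for testing the decomposition and
#' forecasting pipeline end to end with known ground truth. Log counts follow
#' a low-rank factor structure,
#' \deqn{\log y_t(x) = \mu(x) + \sum_j \beta_j(x)\,\kappa_j(t) + \varepsilon_t(x),}
#' with orthonormal regional loadings \eqn{\beta_j}, mutually orthogonal
#' mean-centred score series \eqn{\kappa_j(t)} whose energies match the
#' requested variance shares, and i.i.d. Gaussian log-scale noise. Counts are
#' the exponential of the log panel, hence strictly positive by construction.
#'
#' The defaults emulate a national workforce panel: 16 regions over 25 years,
#' one dominant near-linear upward trend component carrying ~94.7% of the
#' structured variance with positive loadings everywhere except one
#' counter-trend region (region 8), plus two weak contrast components with
#' sign-changing trajectories.
#'
#' @param n_regions,n_years,start_year panel dimensions and first year.
#' @param mean_function optional length-`n_regions` vector of log-scale region
#'   means; default decreases log-linearly from ~12000 down to ~1500 counts,
#'   mimicking regions ranked by decreasing size.
#' @param variance_shares positive fractions of the structured (noise-free)
#'   variance carried by each component; must sum to at most 1 (any remainder
#'   is interpreted as unstructured, i.e. left to the noise term).
#' @param score_models list (one per component) of
#'   `list(slope =, ar_coef =, innovation_sd =)`: each score series is a linear
#'   trend in time plus an AR(1) deviation. Component 1's slope sets the
#'   absolute scale; later components are rescaled to the share ratios.
#' @param loading_signs optional length-`n_regions` vector of +/-1 sign
#'   constraints for the first component's loadings; default all +1 with
#'   region 8 (when present) negative.
#' @param noise_sd log-scale observation noise standard deviation. The default
#'   `NULL` calibrates it so the expected noise energy equals the unstructured
#'   remainder `1 - sum(variance_shares)` of the total centred log variance;
#'   the shares then are shares of the total variance, in expectation, which
#'   is what the decomposition measures. Set `0` for a noise-free panel.
#' @param anomalies list of anomaly records, see [inject_anomalies()].
#' @param seed integer seed; identical specs give bit-identical panels.
#' @return A `synthetic_spec` object.
#' @seealso [generate_panel()]
#' @export
synthetic_spec <- function(n_regions = 16L, n_years = 25L, start_year = 2000L,
                           mean_function = NULL,
                           variance_shares = c(0.947, 0.02, 0.013),
                           score_models = NULL,
                           loading_signs = NULL,
                           noise_sd = NULL,
                           anomalies = list(),
                           seed = 1L) {
  n_regions <- as.integer(n_regions); n_years <- as.integer(n_years)
  if (n_years < 4L) stop_value("n_years must be at least 4")
  if (n_regions < 2L) stop_value("n_regions must be at least 2")
  if (any(variance_shares <= 0)) stop_value("variance_shares must be positive")
  if (sum(variance_shares) > 1 + 1e-12)
    stop_value("variance_shares must sum to at most 1 (got %.3f)",
               sum(variance_shares))
  if (!is.null(noise_sd) && noise_sd < 0) stop_value("noise_sd must be non-negative")
  J <- length(variance_shares)
  if (J > min(n_regions, n_years - 1L))
    stop_value("too many components for a %dx%d panel", n_regions, n_years)
  if (is.null(mean_function))
    mean_function <- seq(log(12000), log(1500), length.out = n_regions)
  if (length(mean_function) != n_regions)
    stop_value("mean_function must have length n_regions")
  if (is.null(score_models)) {
    # component 1: steady upward trend (~0.03/yr on the log scale => roughly
    # a doubling over 25 years after loading by ~1/sqrt(R)); contrast
    # components are pure AR(1) wandering so their trajectories change sign.
    score_models <- c(list(list(slope = 0.12, ar_coef = 0.6, innovation_sd = 0.05)),
                      rep(list(list(slope = 0, ar_coef = 0.6, innovation_sd = 1)),
                          J - 1L))
  }
  if (length(score_models) != J)
    stop_value("score_models must have one entry per variance share")
  if (is.null(loading_signs)) {
    loading_signs <- rep(1, n_regions)
    if (n_regions >= 8L) loading_signs[8L] <- -1
  }
  if (length(loading_signs) != n_regions || any(abs(loading_signs) != 1))
    stop_value("loading_signs must be +/-1 of length n_regions")
  structure(list(n_regions = n_regions, n_years = n_years,
                 start_year = as.integer(start_year),
                 mean_function = mean_function,
                 variance_shares = variance_shares,
                 score_models = score_models,
                 loading_signs = loading_signs,
                 noise_sd = noise_sd, anomalies = anomalies,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic panel with ground truth
#'
#' Draws loadings and score series per the spec, orthonormalises the loadings
#' (Gram-Schmidt, first column respecting the sign constraints), mean-centres
#' and orthogonalises the score series over time, rescales score energies to
#' the requested variance shares, adds Gaussian log-scale noise, exponentiates,
#' and finally injects any anomalies.
#'
#' @param spec a [synthetic_spec()].
#' @return A list with components `panel` (a [region_year_panel()]) and
#'   `truth` (class `synthetic_truth`: the generating `mu`, `basis`, `scores`,
#'   the noise-free `log_panel`, and the `spec`).
#' @examples
#' sim <- generate_panel(synthetic_spec(n_regions = 5, n_years = 12, seed = 7))
#' sim$panel
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  R <- spec$n_regions; T_ <- spec$n_years; J <- length(spec$variance_shares)
  with_seed(spec$seed, {
    # --- loadings: seeded random vectors, first constrained in sign ---------
    M <- matrix(stats::rnorm(R * J), R, J)
    M[, 1L] <- spec$loading_signs * abs(stats::rnorm(R, mean = 1, sd = 0.25))
    basis <- gram_schmidt(M)
    # re-impose signs on column 1 (orthonormalisation preserves them only up
    # to the global sign)
    if (sum(sign(basis[, 1L]) == spec$loading_signs) < R / 2)
      basis[, 1L] <- -basis[, 1L]
    # --- scores: trend + AR(1), centred, orthogonalised, share-scaled -------
    tt <- seq_len(T_) - (T_ + 1) / 2
    K <- sapply(spec$score_models, function(m) {
      dev <- numeric(T_)
      if (m$innovation_sd > 0) {
        e <- stats::rnorm(T_, sd = m$innovation_sd)
        for (t in seq_len(T_)) dev[t] <- if (t == 1) e[t] else m$ar_coef * dev[t - 1] + e[t]
      }
      m$slope * tt + dev
    })
    K <- matrix(K, T_, J)
    K <- sweep(K, 2L, colMeans(K))           # identifies mu as the time-mean
    K <- gram_schmidt_cols(K)                # orthogonal, not normalised
    ss <- colSums(K^2)
    if (ss[1L] > 0) {
      target <- ss[1L] * spec$variance_shares / spec$variance_shares[1L]
      for (j in seq_len(J)[-1L])
        K[, j] <- if (ss[j] > 0) K[, j] * sqrt(target[j] / ss[j]) else K[, j]
    }
    log_true <- spec$mean_function + basis %*% t(K)
    noise_sd <- spec$noise_sd
    if (is.null(noise_sd)) {
      s <- sum(spec$variance_shares)
      structured_ss <- sum(K^2)     # basis is orthonormal
      noise_sd <- if (s < 1 && structured_ss > 0) {
        sqrt(structured_ss * (1 - s) / s / (R * (T_ - 1)))
      } else 0
    }
    noise <- matrix(stats::rnorm(R * T_, sd = noise_sd), R, T_)
    counts <- exp(log_true + noise)
    years <- seq(spec$start_year, length.out = T_)
    regions <- paste0("R", seq_len(R))
    panel <- region_year_panel(counts, years = years, regions = regions)
    if (length(spec$anomalies))
      panel <- inject_anomalies(panel, spec$anomalies)
    truth <- structure(list(mu = spec$mean_function, basis = basis, scores = K,
                            log_panel = log_true, noise_sd = noise_sd,
                            spec = spec),
                       class = "synthetic_truth")
    list(panel = panel, truth = truth)
  })
}

# Gram-Schmidt with normalisation (orthonormal columns).
gram_schmidt <- function(M) {
  Q <- gram_schmidt_cols(M)
  sweep(Q, 2L, sqrt(colSums(Q^2)), "/")
}

# Gram-Schmidt without normalisation; zero columns stay zero.
gram_schmidt_cols <- function(M) {
  Q <- M
  for (j in seq_len(ncol(M))) {
    v <- M[, j]
    if (j > 1L) for (k in seq_len(j - 1L)) {
      qk <- Q[, k]; nk <- sum(qk^2)
      if (nk > 0) v <- v - qk * (sum(qk * v) / nk)
    }
    Q[, j] <- v
  }
  Q
}

#' Inject anomalies into a panel
#'
#' Two anomaly kinds reproduce patterns seen in real workforce series:
#' `dip_rebound` multiplies the target year by `1 - magnitude` and the
#' following year by `1 + magnitude` (a reporting dip corrected the year
#' after); `spike` multiplies a single year by `1 + magnitude` (an abrupt
#' local hiring event). All other cells are untouched.
#'
#' @param panel a [region_year_panel()].
#' @param anomalies list of records `list(region =, year =, kind =, magnitude =)`.
#' @param seed reserved for stochastic anomaly kinds; the current kinds are
#'   deterministic and ignore it.
#' @return A new [region_year_panel()].
#' @export
inject_anomalies <- function(panel, anomalies, seed = NULL) {
  stopifnot(inherits(panel, "region_year_panel"))
  counts <- panel$counts
  for (a in anomalies) {
    r <- match(as.character(a$region), panel$regions)
    if (is.na(r)) stop_value("unknown region in anomaly: %s", a$region)
    ti <- match(as.integer(a$year), panel$years)
    if (is.na(ti)) stop_value("anomaly year %s not in panel", a$year)
    if (!a$kind %in% c("dip_rebound", "spike"))
      stop_value("unknown anomaly kind: %s", a$kind)
    if (a$kind == "dip_rebound") {
      if (ti == length(panel$years))
        stop_value("dip_rebound needs a year after %d", a$year)
      counts[r, ti] <- counts[r, ti] * (1 - a$magnitude)
      counts[r, ti + 1L] <- counts[r, ti + 1L] * (1 + a$magnitude)
    } else {
      counts[r, ti] <- counts[r, ti] * (1 + a$magnitude)
    }
  }
  region_year_panel(counts, years = panel$years, regions = panel$regions)
}

#' Serialise / deserialise a synthetic spec
#'
#' @param spec a [synthetic_spec()]; `path` a `.yaml`/`.yml` or `.json` file.
#' @return `read_synthetic_spec()` returns a [synthetic_spec()];
#'   `write_synthetic_spec()` returns `path` invisibly.
#' @rdname synthetic_spec_io
#' @export
read_synthetic_spec <- function(path) {
  if (!file.exists(path)) stop_value("file not found: %s", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  raw$variance_shares <- as.numeric(unlist(raw$variance_shares))
  if (!is.null(raw$mean_function))
    raw$mean_function <- as.numeric(unlist(raw$mean_function))
  if (!is.null(raw$loading_signs))
    raw$loading_signs <- as.numeric(unlist(raw$loading_signs))
  do.call(synthetic_spec, raw)
}

#' @param path output path.
#' @rdname synthetic_spec_io
#' @export
write_synthetic_spec <- function(spec, path) {
  stopifnot(inherits(spec, "synthetic_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
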