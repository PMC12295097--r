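#' Log-transform a panel
#'
#' The decomposition and all forecasting operate on natural-log counts; counts
#' are strictly positive by panel invariant, so the transform is always
#' defined. Returns the bare matrix so downstream code can window it freely.
#'
#' @param panel a [region_year_panel()] (or a positive numeric matrix).
#' @return A region-by-year matrix of natural logs.
#' @export
log_transform <- function(panel) {
  m <- if (inherits(panel, "region_year_panel")) panel$counts else as.matrix(panel)
  if (any(m <= 0)) stop_value("log_transform needs strictly positive counts")
  log(m)
}

#' Functional principal component decomposition of a log panel
#'
#' Treats each year as a discrete "curve" over regions and decomposes the
#' panel as
#' \deqn{\log y_t(x) = \mu(x) + \sum_{j=1}^{J} \beta_j(x)\,\kappa_j(t) + e_t(x),}
#' where \eqn{\mu(x)} is the per-region mean over years, the \eqn{\beta_j} are
#' the leading orthonormal eigenvectors of the regional covariance of the
#' centred year-curves (equivalently the leading left singular vectors of the
#' centred matrix), and \eqn{\kappa_j(t)} is the projection of year `t`'s
#' centred curve onto \eqn{\beta_j}. Because regions are an unordered discrete
#' index, no smoothing is applied: the basis is extracted directly from the
#' data (empirical orthogonal functions).
#'
#' Sign convention: each basis column is flipped so that its entry of largest
#' magnitude is positive (the matching score column is flipped with it). This
#' fixes the inherent sign indeterminacy and keeps score series comparable
#' across cross-validation folds.
#'
#' @param log_matrix region-by-year numeric matrix (see [log_transform()]).
#' @param J number of components to retain; must satisfy
#'   `1 <= J <= min(R, T - 1)`.
#' @param share_threshold optional cumulative explained-variance threshold in
#'   (0, 1]; when given, `J` is reduced to the smallest component count whose
#'   cumulative share reaches it (never increased above `J`).
#' @return An object of class `fpca_model` with fields `mu` (length R),
#'   `basis` (R x J, orthonormal columns), `scores` (T x J, columns sum to 0),
#'   `explained_variance_shares` (length J), `eigenvalues` (length J,
#'   covariance divisor T), `residuals` (R x T), `years`, `regions`, `J`.
#' @examples
#' sim <- generate_panel(synthetic_spec(n_regions = 6, n_years = 12,
#'                                      variance_shares = c(0.9, 0.1),
#'                                      noise_sd = 0, seed = 2))
#' m <- fit_fpca(log_transform(sim$panel), J = 2)
#' explained_variance(m)
#' @export
fit_fpca <- function(log_matrix, J = 3L, share_threshold = NULL) {
  X <- as.matrix(log_matrix)
  R <- nrow(X); T_ <- ncol(X)
  if (T_ < 4L) stop_value("need at least 4 years to fit (got %d)", T_)
  J <- as.integer(J)
  if (J < 1L || J > min(R, T_ - 1L))
    stop_value("J must be in [1, %d] (got %d)", min(R, T_ - 1L), J)
  mu <- rowMeans(X)
  C <- X - mu
  total <- sum(C^2)
  if (total < 1e-14)
    stop(errorCondition("panel has zero centred variance; nothing to decompose",
                        class = c("fpca_degenerate_error", "fpca_estimation_error",
                                  "fpca_error")))
  sv <- svd(C)
  shares_all <- sv$d^2 / total
  if (!is.null(share_threshold)) {
    if (share_threshold <= 0 || share_threshold > 1)
      stop_value("share_threshold must be in (0, 1]")
    J <- min(J, max(1L, which(cumsum(shares_all) >= share_threshold - 1e-12)[1L]))
  }
  basis <- sv$u[, seq_len(J), drop = FALSE]
  scores <- sv$v[, seq_len(J), drop = FALSE] %*% diag(sv$d[seq_len(J)], J, J)
  # sign convention: largest-magnitude basis entry positive
  for (j in seq_len(J)) {
    i <- which.max(abs(basis[, j]))
    if (basis[i, j] < 0) {
      basis[, j] <- -basis[, j]
      scores[, j] <- -scores[, j]
    }
  }
  resid <- C - basis %*% t(scores)
  yrs <- suppressWarnings(as.integer(colnames(X)))
  structure(list(mu = mu,
                 basis = basis,
                 scores = scores,
                 explained_variance_shares = shares_all[seq_len(J)],
                 eigenvalues = sv$d[seq_len(J)]^2 / T_,
                 residuals = resid,
                 years = if (anyNA(yrs)) seq_len(T_) else yrs,
                 regions = rownames(X) %||% paste0("R", seq_len(R)),
                 J = J),
            class = "fpca_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fpca_model <- function(x, ...) {
  cat(sprintf("fpca_model: %d regions, %d years, J = %d\n",
              nrow(x$basis), nrow(x$scores), x$J))
  cat("  explained variance shares:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance_shares), collapse = ", "),
      "\n")
  invisible(x)
}

#' Reconstruct counts from scores
#'
#' Applies the inverse map \eqn{\hat y_t(x) = \exp\{\mu(x) + \sum_j
#' \beta_j(x)\,\kappa_j(t)\}} to any score matrix — the fitted scores (giving
#' fitted counts) or forecast scores (giving count forecasts).
#'
#' @param model an [fit_fpca()] model.
#' @param scores T' x J matrix (or length-J vector for a single year).
#' @return R x T' matrix of strictly positive counts.
#' @export
reconstruct <- function(model, scores = model$scores) {
  stopifnot(inherits(model, "fpca_model"))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  if (ncol(scores) != model$J)
    stop_value("scores must have %d columns (got %d)", model$J, ncol(scores))
  exp(model$mu + model$basis %*% t(scores))
}

#' Per-component contribution to the log panel
#'
#' Entry (x, t) is \eqn{\beta_j(x)\,\kappa_j(t)}: component `j`'s additive
#' contribution on the log scale. Summing contributions over all retained
#' components and adding `mu` recovers the fitted log panel (the centred
#' matrix minus residuals, plus mean).
#'
#' @param model an [fit_fpca()] model.
#' @param j component index in `1..J`.
#' @return R x T matrix on the log scale.
#' @export
component_contribution <- function(model, j) {
  stopifnot(inherits(model, "fpca_model"))
  j <- as.integer(j)
  if (j < 1L || j > model$J) stop_value("j must be in [1, %d]", model$J)
  outer(model$basis[, j], model$scores[, j])
}

#' Explained-variance shares
#'
#' @param model an [fit_fpca()] model.
#' @return Length-J vector: eigenvalue of each retained component divided by
#'   the total centred variance; non-increasing.
#' @export
explained_variance <- function(model) {
  stopifnot(inherits(model, "fpca_model"))
  model$explained_variance_shares
}

#' Serialise / deserialise an FPCA model as JSON
#'
#' @param model an [fit_fpca()] model; `path` a file path.
#' @return `read_fpca_model()` returns an `fpca_model`;
#'   `write_fpca_model()` returns `path` invisibly.
#' @rdname fpca_model_io
#' @export
write_fpca_model <- function(model, path) {
  stopifnot(inherits(model, "fpca_model"))
  doc <- list(mu = model$mu, basis = model$basis, scores = model$scores,
              explained_variance_shares = model$explained_variance_shares,
              eigenvalues = model$eigenvalues,
              residuals = model$residuals,
              years = model$years, regions = model$regions, J = model$J)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @param path file path.
#' @rdname fpca_model_io
#' @export
read_fpca_model <- function(path) {
  if (!file.exists(path)) stop_value("file not found: %s", path)
  doc <- jsonlite::fromJSON(path)
  structure(list(mu = as.numeric(doc$mu),
                 basis = as.matrix(doc$basis),
                 scores = as.matrix(doc$scores),
                 explained_variance_shares = as.numeric(doc$explained_variance_shares),
                 eigenvalues = as.numeric(doc$eigenvalues),
                 residuals = as.matrix(doc$residuals),
                 years = as.integer(doc$years),
                 regions = as.character(doc$regions),
                 J = as.integer(doc$J)),
            class = "fpca_model")
}
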