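# Functional PCA of the 400-bin profiles.
#
# The profiles are densely and regularly observed, so the mean and
# covariance are estimated cross-sectionally and the Karhunen-Loeve
# basis comes from a plain eigendecomposition of the 400 x 400 sample
# covariance; no smoothing step is applied. Grid spacing is treated as 1,
# so inner products are ordinary dot products and eigenfunctions have
# unit Euclidean norm.

#' Fit a functional PCA model to log-scale profiles
#'
#' Decomposes centered profiles as
#' \eqn{y_i(t) = \mu(t) + \sum_j C_{ij} \psi_j(t)} with orthonormal
#' eigenfunctions \eqn{\psi_j} and uncorrelated scores \eqn{C_j}. The
#' number of retained components `q` is the smallest number whose
#' cumulative fraction of variance explained (FVE) reaches
#' `fve_threshold`, unless `q_override` is given.
#'
#' Each eigenfunction's sign is fixed so that its largest-magnitude
#' element is positive, making the fit deterministic.
#'
#' @param pm A log-scale `profile_matrix` (or plain matrix on the log
#'   scale), n >= 2 rows.
#' @param fve_threshold Target cumulative FVE in (0, 1] (default 0.90).
#' @param q_override Optional fixed number of components.
#' @return An object of class `fpca_model` with elements `mu` (mean
#'   function), `psi` (grid-length x q eigenfunction matrix), `lambda`
#'   (eigenvalues), `fve` (cumulative FVE over all components), `q`,
#'   `scores` (n x q), and `total_var`.
#' @export
fit_fpca <- function(pm, fve_threshold = 0.90, q_override = NULL) {
  if (inherits(pm, "profile_matrix") && transform_state(pm) != "log")
    stop("fit_fpca() expects log-scale profiles; call log_transform() first")
  x <- unclass(pm)
  n <- nrow(x)
  if (is.null(n) || n < 2L) stop("need at least 2 profiles to fit FPCA")
  if (anyNA(x)) stop("profiles contain missing values")
  if (fve_threshold <= 0 || fve_threshold > 1)
    stop("`fve_threshold` must be in (0, 1]")
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  S <- crossprod(xc) / (n - 1)
  eg <- eigen(S, symmetric = TRUE)
  lambda <- pmax(eg$values, 0)
  total_var <- sum(lambda)
  psi <- eg$vectors
  # deterministic sign: largest-magnitude element of each psi_j positive
  for (j in seq_len(ncol(psi))) {
    peak <- which.max(abs(psi[, j]))
    if (psi[peak, j] < 0) psi[, j] <- -psi[, j]
  }
  fve <- if (total_var > 0) cumsum(lambda) / total_var else
    rep(1, length(lambda))
  q <- if (!is.null(q_override)) {
    if (q_override < 1L || q_override > length(lambda))
      stop("`q_override` out of range")
    as.integer(q_override)
  } else {
    # tolerance guards against cumsum rounding at exact-threshold spectra
    which(fve >= fve_threshold - 1e-9)[1]
  }
  psi <- psi[, seq_len(q), drop = FALSE]
  scores <- xc %*% psi
  rownames(scores) <- rownames(x)
  structure(
    list(mu = mu, psi = psi, lambda = lambda[seq_len(q)],
         lambda_all = lambda, fve = fve, q = q, scores = scores,
         total_var = total_var, n = n),
    class = "fpca_model")
}

#' @export
print.fpca_model <- function(x, ...) {
  cat(sprintf("fpca_model: %d profiles, grid %d, q = %d (FVE %.1f%%)\n",
              x$n, length(x$mu), x$q, 100 * x$fve[x$q]))
  invisible(x)
}

#' Project profiles onto a fitted FPCA basis
#'
#' Computes scores \eqn{C_j = \langle y - \mu, \psi_j \rangle} for new
#' log-scale profiles.
#'
#' @param model An `fpca_model`.
#' @param y A log-scale profile vector of grid length, or a matrix with
#'   one profile per row.
#' @return Score vector of length `q` (or an n x q matrix).
#' @export
project <- function(model, y) {
  stopifnot(inherits(model, "fpca_model"))
  if (is.null(dim(y))) {
    if (length(y) != length(model$mu))
      stop("profile length ", length(y), " != grid length ",
           length(model$mu))
    drop(crossprod(model$psi, y - model$mu))
  } else {
    if (ncol(y) != length(model$mu))
      stop("profile length ", ncol(y), " != grid length ",
           length(model$mu))
    sweep(unclass(y), 2L, model$mu) %*% model$psi
  }
}

#' Reconstruct a profile from FPCA scores
#'
#' Returns \eqn{\mu(t) + \sum_{j=1}^{q} C_j \psi_j(t)} on the log scale.
#'
#' @param model An `fpca_model`.
#' @param scores Score vector of length `q`.
#' @return Numeric vector of grid length.
#' @export
reconstruct <- function(model, scores) {
  stopifnot(inherits(model, "fpca_model"))
  if (length(scores) != model$q)
    stop("scores length ", length(scores), " != q = ", model$q)
  drop(model$mu + model$psi %*% scores)
}
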