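# EM clustering of FPCA scores.
#
# The mixture density is a weighted sum over K components of products of
# univariate Gaussians, one per score dimension:
#   f(C) = sum_k pi_k * prod_j N(C_j; mu_jk, var_jk)
# i.e. a diagonal-covariance Gaussian mixture, exploiting the
# decorrelation of the FPCA scores. Full covariances are deliberately
# not offered.

logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# n x K matrix of log(pi_k) + sum_j log N(x_j; mu_jk, var_jk)
.log_component_density <- function(x, pi, mu, var) {
  n <- nrow(x); K <- length(pi)
  ld <- matrix(0, n, K)
  for (k in seq_len(K)) {
    ld[, k] <- log(pi[k]) - 0.5 * sum(log(2 * pi_const * var[, k])) -
      0.5 * colSums((t(x) - mu[, k])^2 / var[, k])
  }
  ld
}
pi_const <- base::pi

.em_run <- function(x, K, init_labels, tol, max_iter, var_floor) {
  n <- nrow(x); q <- ncol(x)
  # init from hard labels
  pi <- tabulate(init_labels, K) / n
  if (any(pi == 0)) return(NULL)
  mu <- matrix(0, q, K); var <- matrix(1, q, K)
  for (k in seq_len(K)) {
    xk <- x[init_labels == k, , drop = FALSE]
    mu[, k] <- colMeans(xk)
    var[, k] <- pmax(colMeans(sweep(xk, 2L, mu[, k])^2), var_floor)
  }
  ll_old <- -Inf
  ll_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    ld <- .log_component_density(x, pi, mu, var)
    row_ll <- logsumexp_rows(ld)
    ll <- sum(row_ll)
    if (ll < ll_old - 1e-8 * (abs(ll_old) + 1))
      stop("EM log-likelihood decreased; numerical failure")
    ll_trace <- c(ll_trace, ll)
    resp <- exp(ld - row_ll)
    nk <- colSums(resp)
    if (any(nk < 1e-8 * n)) return(NULL)  # degenerate component
    converged <- is.finite(ll_old) &&
      abs(ll - ll_old) < tol * (abs(ll_old) + 1e-12)
    pi <- nk / n
    mu <- t(crossprod(resp, x) / nk)
    var <- t(crossprod(resp, x^2) / nk) - mu^2
    var <- pmax(var, var_floor)
    if (converged) break
    ll_old <- ll
  }
  # final E-step so responsibilities match returned parameters
  ld <- .log_component_density(x, pi, mu, var)
  row_ll <- logsumexp_rows(ld)
  resp <- exp(ld - row_ll)
  list(pi = pi, mu = mu, var = var, resp = resp, loglik = sum(row_ll),
       n_iter = length(ll_trace), ll_trace = ll_trace,
       converged = isTRUE(converged))
}

#' Fit a diagonal-covariance Gaussian mixture to FPCA scores by EM
#'
#' Runs EM from `n_restarts` k-means initializations (each with its own
#' sub-seed derived from `seed`) and keeps the solution with the highest
#' log-likelihood. Restarts that collapse a component are discarded; if
#' all restarts degenerate, an error is raised. The log-likelihood is
#' checked to be non-decreasing at every iteration.
#'
#' @param scores n x q score matrix (n > K).
#' @param K Number of mixture components.
#' @param seed Integer seed controlling all initializations.
#' @param n_restarts Number of k-means warm starts (default 10).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per restart.
#' @param var_floor Lower bound on component variances, preventing
#'   degenerate spikes.
#' @return An object of class `mixture_model` with elements `K`, `pi`,
#'   `mu` (q x K), `var` (q x K), `resp` (n x K responsibilities),
#'   `labels` (argmax of responsibilities), `loglik`, `ll_trace`,
#'   `n_iter`, `converged`.
#' @export
fit_em <- function(scores, K, seed = 1L, n_restarts = 10L, tol = 1e-6,
                   max_iter = 500L, var_floor = 1e-8) {
  x <- as.matrix(unclass(scores))
  n <- nrow(x)
  if (!(n > K && K >= 1L)) stop("need n > K >= 1")
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_restarts)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(sub_seeds[r])
    init <- if (K == 1L) rep(1L, n) else
      stats::kmeans(x, centers = K, nstart = 1L,
                    iter.max = 50L)$cluster
    fit <- tryCatch(.em_run(x, K, init, tol, max_iter, var_floor),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik))
      best <- fit
  }
  if (is.null(best)) stop("all EM restarts degenerated; reduce K")
  labels <- max.col(best$resp, ties.method = "first")
  structure(
    c(best, list(K = as.integer(K), labels = labels, n = n, q = ncol(x),
                 seed = seed)),
    class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf(
    "mixture_model: K = %d on %d profiles (q = %d), loglik = %.2f\n",
    x$K, x$n, x$q, x$loglik))
  cat("cluster sizes:", paste(tabulate(x$labels, x$K), collapse = ", "),
      "\n")
  invisible(x)
}

#' Number of free parameters of a diagonal Gaussian mixture
#' @noRd
.gmm_n_params <- function(K, q) (K - 1L) + 2L * K * q

#' Fit a range of K and report selection diagnostics
#'
#' Fits each K in `K_range`, reports the Bayesian information criterion
#' (BIC; smaller is better) and cluster sizes, and optionally writes a
#' per-K heatmap of the profiles (z-scored log counts, rows sorted by
#' cluster) so the homogeneity of each clustering can be judged by eye.
#' The BIC minimum is reported as a suggestion only; the final choice of
#' K is the user's.
#'
#' @param scores n x q score matrix.
#' @param K_range Integer vector of K values to fit (e.g. `2:6`).
#' @param seed Seed passed to [fit_em()].
#' @param pm Optional log-scale `profile_matrix` used for the heatmaps.
#' @param out_dir Optional directory for `heatmap_K<k>.png` files; no
#'   images are written when `NULL`.
#' @param ... Further arguments to [fit_em()].
#' @return A list of class `K_selection`: `table` (one row per K with
#'   loglik, BIC, cluster sizes), `fits` (the `mixture_model`s), and
#'   `suggested_K` (BIC minimum).
#' @export
select_K <- function(scores, K_range = 2:6, seed = 1L, pm = NULL,
                     out_dir = NULL, ...) {
  if (!length(K_range)) stop("`K_range` must be non-empty")
  n <- nrow(scores); q <- ncol(scores)
  fits <- list(); rows <- list()
  for (K in K_range) {
    fit <- fit_em(scores, K, seed = seed, ...)
    fits[[as.character(K)]] <- fit
    sizes <- tabulate(fit$labels, K)
    bic <- -2 * fit$loglik + .gmm_n_params(K, q) * log(n)
    rows[[as.character(K)]] <- data.frame(
      K = K, loglik = fit$loglik, BIC = bic,
      min_size = min(sizes), max_size = max(sizes))
    if (!is.null(out_dir) && !is.null(pm))
      .write_cluster_heatmap(pm, fit$labels,
                             file.path(out_dir,
                                       sprintf("heatmap_K%d.png", K)))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits,
                 suggested_K = tab$K[which.min(tab$BIC)]),
            class = "K_selection")
}

#' @export
print.K_selection <- function(x, ...) {
  print(x$table)
  cat("suggested K (BIC minimum):", x$suggested_K, "\n")
  invisible(x)
}

.write_cluster_heatmap <- function(pm, labels, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  x <- unclass(pm)
  if (transform_state(pm) == "raw") x <- log1p(x)
  z <- scale(x)
  z[!is.finite(z)] <- 0
  ord <- order(labels)
  grDevices::png(path, width = 800, height = 600)
  on.exit(grDevices::dev.off())
  graphics::image(t(z[ord, , drop = FALSE]), axes = FALSE, useRaster = TRUE,
                  col = grDevices::hcl.colors(64, "Blue-Red 2"),
                  xlab = "bin", ylab = "profiles (sorted by cluster)")
  invisible(path)
}

#' Characteristic histone-modification pattern of each cluster
#'
#' The characteristic pattern of a cluster is the elementwise mean of
#' all member profiles, reported on both the raw-count scale and the
#' `log(1 + y)` scale (the mean of members' log profiles, which is the
#' scale the genome scan correlates against).
#'
#' @param pm A raw-scale `profile_matrix`.
#' @param labels Integer cluster label per profile (1..K).
#' @return An object of class `characteristic_patterns`: `raw` and `log`
#'   K x 400 matrices and `n_members`.
#' @export
characteristic_patterns <- function(pm, labels) {
  if (transform_state(pm) != "raw")
    stop("characteristic_patterns() expects raw-scale profiles")
  x <- unclass(pm)
  if (length(labels) != nrow(x))
    stop("labels length must match profile count")
  K <- max(labels)
  sizes <- tabulate(labels, K)
  if (any(sizes == 0))
    stop("empty cluster: ", paste(which(sizes == 0), collapse = ", "))
  raw <- matrix(0, K, ncol(x))
  lg <- matrix(0, K, ncol(x))
  for (k in seq_len(K)) {
    xk <- x[labels == k, , drop = FALSE]
    raw[k, ] <- colMeans(xk)
    lg[k, ] <- colMeans(log1p(xk))
  }
  rownames(raw) <- rownames(lg) <- paste0("cluster_", seq_len(K))
  structure(list(raw = raw, log = lg, n_members = sizes, K = K),
            class = "characteristic_patterns")
}

#' @export
print.characteristic_patterns <- function(x, ...) {
  cat(sprintf("characteristic_patterns: %d clusters (sizes %s)\n", x$K,
              paste(x$n_members, collapse = ", ")))
  invisible(x)
}

#' Renumber mixture clusters by descending mean total signal
#'
#' Makes cluster numbering canonical across runs: cluster 1 has the
#' highest mean total raw intensity, and the last cluster (the flattest,
#' typically inactive promoters) the lowest.
#'
#' @param model A `mixture_model`.
#' @param pm The raw-scale `profile_matrix` the scores came from.
#' @return The `mixture_model` with components, responsibilities and
#'   labels permuted into canonical order.
#' @export
canonicalize_clusters <- function(model, pm) {
  stopifnot(inherits(model, "mixture_model"))
  x <- unclass(pm)
  if (transform_state(pm) != "raw")
    stop("canonicalize_clusters() expects raw-scale profiles")
  totals <- vapply(seq_len(model$K), function(k)
    mean(rowSums(x[model$labels == k, , drop = FALSE])), numeric(1))
  ord <- order(totals, decreasing = TRUE)
  inv <- match(seq_len(model$K), ord)
  model$pi <- model$pi[ord]
  model$mu <- model$mu[, ord, drop = FALSE]
  model$var <- model$var[, ord, drop = FALSE]
  model$resp <- model$resp[, ord, drop = FALSE]
  model$labels <- inv[model$labels]
  model
}
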