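# High-level two-step pipeline: QC -> log -> FPCA -> EM clustering ->
# characteristic patterns -> correlation thresholds; then genome scan.

#' Train the two-step promoter-pattern model
#'
#' Runs the full training pipeline on raw promoter profiles: QC filter
#' (max count >= `threshold`), log transform, FPCA with FVE-based
#' component selection, EM mixture clustering of the scores, canonical
#' renumbering of clusters by descending mean total signal (so the last
#' cluster is the flattest/inactive one), characteristic patterns, and
#' the per-cluster `100 * alpha` percentile correlation thresholds.
#'
#' @param pm Raw-scale `profile_matrix` of promoter profiles.
#' @param K Number of clusters (default 4; use [select_K()] to choose).
#' @param alpha Percentile level for the scan thresholds (default 0.4).
#' @param fve_threshold FVE target for FPCA component selection.
#' @param q_override Optional fixed number of FPCA components.
#' @param threshold QC maximum-intensity cutoff (default 7).
#' @param seed Integer seed for the EM restarts.
#' @param ... Further arguments to [fit_em()].
#' @return An object of class `promoter_model`: `profiles` (QC-passing
#'   raw profiles), `fpca`, `mixture`, `labels`, `patterns`,
#'   `thresholds`, and the settings used.
#' @export
fit_promoter_model <- function(pm, K = 4L, alpha = 0.4,
                               fve_threshold = 0.90, q_override = NULL,
                               threshold = 7, seed = 1L, ...) {
  qc <- filter_low_signal(pm, threshold = threshold, mode = "promoter")
  if (nrow(qc) <= K)
    stop("only ", nrow(qc), " profiles pass QC; cannot fit K = ", K)
  lg <- log_transform(qc)
  fpca <- fit_fpca(lg, fve_threshold = fve_threshold,
                   q_override = q_override)
  em <- fit_em(fpca$scores, K = K, seed = seed, ...)
  em <- canonicalize_clusters(em, qc)
  patterns <- characteristic_patterns(qc, em$labels)
  thresholds <- correlation_thresholds(qc, patterns, em$labels,
                                       alpha = alpha)
  structure(list(profiles = qc, fpca = fpca, mixture = em,
                 labels = em$labels, patterns = patterns,
                 thresholds = thresholds,
                 settings = list(K = K, alpha = alpha,
                                 fve_threshold = fve_threshold,
                                 threshold = threshold, seed = seed)),
            class = "promoter_model")
}

#' @export
print.promoter_model <- function(x, ...) {
  cat(sprintf(
    "promoter_model: %d profiles, q = %d components, K = %d clusters\n",
    nrow(x$profiles), x$fpca$q, x$mixture$K))
  cat("cluster sizes:", paste(x$patterns$n_members, collapse = ", "),
      "\n")
  cat(sprintf("alpha = %.2f thresholds: %s\n", x$thresholds$alpha,
              paste(round(x$thresholds$thresholds, 3), collapse = ", ")))
  invisible(x)
}

#' Predict putative promoters on a genome track
#'
#' Scans the track with the model's characteristic patterns (by default
#' all clusters except the last, flattest one, which marks inactive
#' promoters), merges significance windows into regions, optionally
#' drops thin regions, groups regions across clusters into putative
#' promoters, and optionally shortens them.
#'
#' @param track A [genome_track()] (or list of them, one per
#'   chromosome).
#' @param model A [fit_promoter_model()] result.
#' @param known_promoters Optional data frame of known 10 kb promoter
#'   windows (`chrom`, `start`, `end`) to exclude from the scan.
#' @param scan_clusters Clusters to scan with; default `1:(K-1)`.
#' @param stride_bins Window stride in bins.
#' @param max_count Scan maximum-intensity cutoff (strictly-greater
#'   rule; default 7).
#' @param min_windows Minimum significance windows per region (default
#'   1 = no filtering).
#' @param shorten Shortening mode for the final promoters (`"none"`,
#'   `"first"`, `"last"`, `"both"`).
#' @return List with `windows`, `regions`, and `promoters` data frames.
#' @export
predict_promoters <- function(track, model, known_promoters = NULL,
                              scan_clusters = NULL, stride_bins = 1L,
                              max_count = 7, min_windows = 1L,
                              shorten = "none") {
  stopifnot(inherits(model, "promoter_model"))
  if (is.null(scan_clusters))
    scan_clusters <- seq_len(max(model$mixture$K - 1L, 1L))
  tracks <- if (inherits(track, "genome_track")) list(track) else track
  windows <- do.call(rbind, lapply(tracks, function(tr)
    scan_genome(tr, model$patterns, model$thresholds,
                known_promoters = known_promoters,
                clusters = scan_clusters, stride_bins = stride_bins,
                max_count = max_count)))
  rownames(windows) <- NULL
  regions <- filter_regions(merge_windows(windows), min_windows)
  promoters <- shorten_region(group_and_assign(regions), mode = shorten)
  list(windows = windows, regions = regions, promoters = promoters)
}
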