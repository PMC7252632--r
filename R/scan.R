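# Genome-wide promoter scan: percentile thresholds from the training
# clusters, sliding-window correlation, merging of significance windows
# into regions, cross-cluster grouping and optional shortening.
#
# All correlations are computed on the log(1 + y) scale, the same scale
# the characteristic patterns are trained on (Pearson r is not invariant
# to the log map, so train and scan scales must agree).

#' Pearson correlation between a window profile and a pattern
#'
#' Thin wrapper over [stats::cor()] that treats a constant vector as
#' non-significant: the correlation is undefined, so `NA` is returned
#' with a message rather than an error.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Pearson's r, or `NA_real_` for constant input.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    message("constant vector: correlation undefined, treated as NA")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Per-cluster correlation thresholds at the 100*alpha percentile
#'
#' For each cluster, computes the Pearson correlation of every member's
#' log profile with the cluster's characteristic pattern (log scale) and
#' takes the lower empirical `100 * alpha` percentile — the smallest
#' member correlation whose empirical CDF reaches `alpha` (inverse ECDF,
#' `quantile(type = 1)`). Profiles whose contribution to the pattern is
#' minimal have small correlations, so this threshold calibrates how
#' pattern-like a scanned window must be.
#'
#' @param pm Raw-scale `profile_matrix` of training promoters.
#' @param patterns A [characteristic_patterns()] object.
#' @param labels Cluster label per profile.
#' @param alpha Percentile level in (0, 1); default 0.4, a compromise
#'   between sensitivity and confidence.
#' @return An object of class `threshold_set`: `alpha`, `thresholds`
#'   (named per cluster), and the per-cluster training correlations.
#' @export
correlation_thresholds <- function(pm, patterns, labels, alpha = 0.4) {
  if (alpha <= 0 || alpha > 1) stop("`alpha` must be in (0, 1]")
  lg <- if (transform_state(pm) == "raw") log1p(unclass(pm)) else unclass(pm)
  K <- patterns$K
  thr <- numeric(K)
  cors <- vector("list", K)
  for (k in seq_len(K)) {
    idx <- which(labels == k)
    if (length(idx) < 2L)
      stop("cluster ", k, " has fewer than 2 members")
    r <- apply(lg[idx, , drop = FALSE], 1L, pearson,
               y = patterns$log[k, ])
    cors[[k]] <- r
    thr[k] <- unname(stats::quantile(r, alpha, type = 1, na.rm = TRUE))
  }
  names(thr) <- paste0("cluster_", seq_len(K))
  structure(list(alpha = alpha, thresholds = thr, correlations = cors),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("threshold_set: alpha = %.2f\n", x$alpha))
  print(round(x$thresholds, 4))
  invisible(x)
}

# rowwise max of a matrix without apply()
.row_max <- function(m) do.call(pmax, lapply(seq_len(ncol(m)),
                                             function(j) m[, j]))

#' Sliding-window scan of a genome track for pattern matches
#'
#' Slides a 10 kb window one bin (`stride_bins`) at a time across the
#' track, skipping windows that overlap a known promoter window or whose
#' maximum raw intensity count is not greater than `max_count`. Each
#' remaining window's concatenated log profile is correlated with every
#' requested characteristic pattern, and one significance window is
#' emitted per cluster whose threshold is strictly exceeded.
#'
#' @param track A [genome_track()] (all four marks).
#' @param patterns A [characteristic_patterns()] object.
#' @param thresholds A [correlation_thresholds()] object.
#' @param known_promoters Optional data frame with `chrom`, `start`,
#'   `end` of known 10 kb promoter windows to exclude.
#' @param clusters Clusters to scan with; defaults to all clusters in
#'   `thresholds`. Typically the flat/inactive cluster is left out.
#' @param stride_bins Window stride in bins (default 1 = 100 bp).
#' @param max_count Raw maximum-intensity cutoff; windows with max count
#'   not greater than this are not tested (default 7).
#' @param flank_bins Half-window size in bins (default 50, i.e. 10 kb).
#' @return Data frame of significance windows: `chrom`, `start`, `end`
#'   (1-based inclusive, width 10 kb), `cluster_id`, `r`.
#' @export
scan_genome <- function(track, patterns, thresholds,
                        known_promoters = NULL, clusters = NULL,
                        stride_bins = 1L, max_count = 7,
                        flank_bins = 50L) {
  stopifnot(inherits(track, "genome_track"),
            inherits(patterns, "characteristic_patterns"),
            inherits(thresholds, "threshold_set"))
  if (is.null(clusters)) clusters <- seq_along(thresholds$thresholds)
  W <- 2L * flank_bins
  nb <- n_bins(track)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), cluster_id = integer(0),
                      r = numeric(0))
  if (nb < W) return(empty)
  pos <- seq.int(1L, nb - W + 1L, by = stride_bins)
  starts <- track$offset + (pos - 1L) * track$bin_size
  ends <- starts + W * track$bin_size - 1L
  keep <- rep(TRUE, length(pos))
  if (!is.null(known_promoters) && nrow(known_promoters)) {
    wgr <- GenomicRanges::GRanges(track$chrom,
                                  IRanges::IRanges(starts, ends))
    kgr <- GenomicRanges::GRanges(known_promoters$chrom,
                                  IRanges::IRanges(known_promoters$start,
                                                   known_promoters$end))
    keep <- !IRanges::overlapsAny(wgr, kgr)
  }
  pos <- pos[keep]; starts <- starts[keep]; ends <- ends[keep]
  if (!length(pos)) return(empty)
  # assemble the window x 400 profile matrix (raw), mark by mark
  idx <- outer(pos, 0:(W - 1L), `+`)
  raw <- do.call(cbind, lapply(MARK_ORDER, function(m)
    matrix(track$counts[[m]][idx], nrow = length(pos))))
  mx <- .row_max(raw)
  ok <- mx > max_count
  if (!any(ok)) return(empty)
  raw <- raw[ok, , drop = FALSE]
  starts <- starts[ok]; ends <- ends[ok]
  lg <- log1p(raw)
  # rowwise Pearson r against each pattern via standardized cross-products
  ctr <- lg - rowMeans(lg)
  denom <- sqrt(rowSums(ctr^2))
  out <- list()
  for (k in clusters) {
    p <- patterns$log[k, ]
    pc <- p - mean(p)
    r <- as.vector(ctr %*% pc) / (denom * sqrt(sum(pc^2)))
    r[!is.finite(r)] <- NA_real_
    hit <- which(!is.na(r) & r > thresholds$thresholds[k])
    if (length(hit))
      out[[as.character(k)]] <- data.frame(
        chrom = track$chrom, start = starts[hit], end = ends[hit],
        cluster_id = k, r = r[hit])
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$cluster_id, res$start), , drop = FALSE]
}

#' Merge overlapping significance windows into significance regions
#'
#' Consecutive sliding windows share 99 of their 100 bins, so their
#' correlations are themselves highly correlated; maximal runs of
#' mutually overlapping same-cluster windows are therefore collapsed
#' into a single region spanning from the first window's start to the
#' last window's end.
#'
#' @param windows Significance-window data frame from [scan_genome()]
#'   (any mix of clusters/chromosomes; grouped internally).
#' @return Data frame of regions: `chrom`, `start`, `end`, `cluster_id`,
#'   `max_r`, `n_windows`, and the extreme contributing windows
#'   (`first_start`, `first_end`, `last_start`, `last_end`).
#' @export
merge_windows <- function(windows) {
  cols <- data.frame(chrom = character(0), start = integer(0),
                     end = integer(0), cluster_id = integer(0),
                     max_r = numeric(0), n_windows = integer(0),
                     first_start = integer(0), first_end = integer(0),
                     last_start = integer(0), last_end = integer(0))
  if (!nrow(windows)) return(cols)
  parts <- split(windows,
                 list(windows$cluster_id, windows$chrom), drop = TRUE)
  out <- lapply(parts, function(w) {
    w <- w[order(w$start), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(w$start[-1] >
                                     cummax(w$end)[-nrow(w)] )))
    do.call(rbind, lapply(split(w, grp), function(g) data.frame(
      chrom = g$chrom[1], start = min(g$start), end = max(g$end),
      cluster_id = g$cluster_id[1], max_r = max(g$r),
      n_windows = nrow(g),
      first_start = g$start[1], first_end = g$end[1],
      last_start = g$start[nrow(g)], last_end = g$end[nrow(g)])))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$chrom, res$start, res$cluster_id), , drop = FALSE]
}

#' Drop regions supported by too few significance windows
#'
#' A region whose peak rests on a single (or a couple of) significance
#' windows may be a spike and a potential false positive; this optional
#' filter requires a minimum number of contributing windows ("width" in
#' addition to "height"). The default 1 leaves all regions in place.
#'
#' @param regions Region data frame from [merge_windows()].
#' @param min_windows Minimum `n_windows` to keep.
#' @return The filtered region data frame.
#' @export
filter_regions <- function(regions, min_windows = 1L) {
  regions[regions$n_windows >= min_windows, , drop = FALSE]
}

#' Group overlapping regions across clusters into putative promoters
#'
#' Transitively overlapping significance regions from all clusters form
#' one set; the putative promoter is the union interval of the set, and
#' its cluster is the member cluster with the largest `max_r` (ties go
#' to the lowest cluster index).
#'
#' @param regions Region data frame from [merge_windows()] (all
#'   clusters together).
#' @return Data frame of putative promoters: `chrom`, `start`, `end`,
#'   `cluster_id`, `max_r`, `n_regions`, extreme-window columns
#'   (earliest `first_*`, latest `last_*` over the member regions), and
#'   an `evidence` list-column holding each promoter's member regions.
#' @export
group_and_assign <- function(regions) {
  cols <- data.frame(chrom = character(0), start = integer(0),
                     end = integer(0), cluster_id = integer(0),
                     max_r = numeric(0), n_regions = integer(0),
                     first_start = integer(0), first_end = integer(0),
                     last_start = integer(0), last_end = integer(0))
  cols$evidence <- list()
  if (!nrow(regions)) return(cols)
  out <- lapply(split(regions, regions$chrom), function(rg) {
    rg <- rg[order(rg$start, rg$cluster_id), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(rg$start[-1] >
                                     cummax(rg$end)[-nrow(rg)])))
    sets <- split(rg, grp)
    res <- do.call(rbind, lapply(sets, function(g) {
      win <- which(g$max_r == max(g$max_r))
      win <- win[which.min(g$cluster_id[win])]
      fi <- which.min(g$first_start)
      la <- which.max(g$last_end)
      data.frame(chrom = g$chrom[1], start = min(g$start),
                 end = max(g$end), cluster_id = g$cluster_id[win],
                 max_r = g$max_r[win], n_regions = nrow(g),
                 first_start = g$first_start[fi],
                 first_end = g$first_end[fi],
                 last_start = g$last_start[la],
                 last_end = g$last_end[la])
    }))
    res$evidence <- unname(sets)
    res
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Shorten a significance region or putative promoter
#'
#' Large regions arise from long chains of overlapping windows; if a
#' shorter interval is desired, the first and/or last contributing
#' significance window can be shortened by half: mode `"first"` raises
#' the start by half the first window's width, `"last"` lowers the end
#' by half the last window's width, `"both"` does both. If shortening
#' would invert the interval (single-window regions), the row is
#' returned unchanged with a warning.
#'
#' @param x Region or promoter data frame (with `first_*`/`last_*`
#'   columns); all rows are shortened.
#' @param mode One of `"none"`, `"first"`, `"last"`, `"both"`.
#' @return `x` with adjusted `start`/`end`.
#' @export
shorten_region <- function(x, mode = c("none", "first", "last", "both")) {
  mode <- match.arg(mode)
  if (mode == "none" || !nrow(x)) return(x)
  start <- x$start; end <- x$end
  if (mode %in% c("first", "both"))
    start <- x$start + (x$first_end - x$first_start + 1L) %/% 2L
  if (mode %in% c("last", "both"))
    end <- x$end - (x$last_end - x$last_start + 1L) %/% 2L
  bad <- start > end
  if (any(bad)) {
    warning(sum(bad), " region(s) would invert when shortened; ",
            "left unchanged")
    start[bad] <- x$start[bad]; end[bad] <- x$end[bad]
  }
  x$start <- as.integer(start); x$end <- as.integer(end)
  x
}
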