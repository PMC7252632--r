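# Promoter profile construction and QC filtering.
#
# Coordinates are 1-based inclusive throughout the package; BED/bedGraph
# readers convert from 0-based half-open at the boundary.

#' Construct a genome coverage track
#'
#' A `genome_track` holds binned intensity counts for all four histone
#' marks over one chromosome, on a shared grid of consecutive,
#' non-overlapping `bin_size` bp bins starting at genomic coordinate
#' `offset` (1-based).
#'
#' @param chrom Chromosome name.
#' @param counts Named list of four equal-length numeric vectors of
#'   non-negative bin counts; names must be `MARK_ORDER`.
#' @param bin_size Bin width in bp (default 100).
#' @param offset 1-based genomic coordinate of the first bin's start.
#' @return An object of class `genome_track`.
#' @seealso [bin_coverage()], [build_profiles()]
#' @export
genome_track <- function(chrom, counts, bin_size = 100L, offset = 1L) {
  if (!is.list(counts) || length(counts) != 4L)
    stop("`counts` must be a list of 4 vectors, one per mark")
  if (is.null(names(counts))) names(counts) <- MARK_ORDER
  if (!identical(names(counts), MARK_ORDER))
    stop("`counts` must be named, in order: ", paste(MARK_ORDER, collapse = ", "))
  lens <- lengths(counts)
  if (length(unique(lens)) != 1L)
    stop("all four mark vectors must have equal length")
  if (any(vapply(counts, function(v) any(v < 0), logical(1))))
    stop("bin counts must be non-negative")
  if (bin_size <= 0) stop("`bin_size` must be positive")
  structure(
    list(chrom = as.character(chrom),
         counts = lapply(counts, as.numeric),
         bin_size = as.integer(bin_size),
         offset = as.integer(offset)),
    class = "genome_track"
  )
}

#' @export
print.genome_track <- function(x, ...) {
  n <- length(x$counts[[1]])
  cat(sprintf("genome_track: %s, %d bins of %d bp (span %d-%d)\n",
              x$chrom, n, x$bin_size, x$offset,
              x$offset + n * x$bin_size - 1L))
  invisible(x)
}

n_bins <- function(track) length(track$counts[[1]])

#' Bin per-base coverage intervals into a genome track
#'
#' Each bin's intensity count is the sum over its bases of the per-base
#' value of the covering intervals, i.e. interval value times the number
#' of overlapping bases. Intervals are 1-based inclusive (use
#' [read_bedgraph()] to convert from bedGraph).
#'
#' @param intervals Named list with elements from `MARK_ORDER`, each a
#'   data frame with columns `chrom`, `start`, `end`, `value`
#'   (non-overlapping within a mark). Marks absent from the list get
#'   all-zero bins.
#' @param bin_size Bin width in bp.
#' @param chrom Chromosome name; taken from the intervals if `NULL`.
#' @param span Total genomic span (bp) to tile, starting at `offset`;
#'   defaults to the largest interval end, rounded up to a bin boundary.
#' @param offset 1-based start coordinate of the first bin.
#' @return A [genome_track()].
#' @export
bin_coverage <- function(intervals, bin_size = 100L, chrom = NULL,
                         span = NULL, offset = 1L) {
  if (is.data.frame(intervals)) stop(
    "`intervals` must be a named list of per-mark data frames; got a bare ",
    "data frame (wrap it, e.g. list(H3K4me2 = x))")
  if (!all(names(intervals) %in% MARK_ORDER))
    stop("interval list names must be among: ", paste(MARK_ORDER, collapse = ", "))
  for (m in names(intervals)) {
    df <- intervals[[m]]
    need <- c("chrom", "start", "end", "value")
    if (!all(need %in% names(df)))
      stop("mark ", m, ": intervals need columns chrom, start, end, value")
    bad <- which(df$value < 0 | df$start > df$end | df$start < offset)
    if (length(bad))
      stop("mark ", m, ": malformed or negative-value interval at line ", bad[1])
  }
  if (is.null(chrom)) {
    ch <- unique(unlist(lapply(intervals, function(d) unique(d$chrom))))
    if (length(ch) > 1L) stop("intervals span multiple chromosomes: ",
                              paste(ch, collapse = ", "))
    chrom <- if (length(ch)) ch else "chr1"
  }
  if (is.null(span)) {
    ends <- unlist(lapply(intervals, function(d) d$end))
    span <- if (length(ends)) max(ends) - offset + 1L else bin_size
  }
  nb <- as.integer(ceiling(span / bin_size))
  counts <- stats::setNames(vector("list", 4L), MARK_ORDER)
  for (m in MARK_ORDER) {
    v <- numeric(nb)
    df <- intervals[[m]]
    if (!is.null(df) && nrow(df)) {
      rs <- df$start - offset + 1L  # relative 1-based
      re <- pmin(df$end - offset + 1L, nb * bin_size)
      for (i in seq_len(nrow(df))) {
        if (re[i] < rs[i]) next
        b0 <- (rs[i] - 1L) %/% bin_size + 1L
        b1 <- (re[i] - 1L) %/% bin_size + 1L
        val <- df$value[i]
        if (b0 == b1) {
          v[b0] <- v[b0] + (re[i] - rs[i] + 1L) * val
        } else {
          v[b0] <- v[b0] + (b0 * bin_size - rs[i] + 1L) * val
          v[b1] <- v[b1] + (re[i] - (b1 - 1L) * bin_size) * val
          if (b1 > b0 + 1L)
            v[(b0 + 1L):(b1 - 1L)] <- v[(b0 + 1L):(b1 - 1L)] + bin_size * val
        }
      }
    }
    counts[[m]] <- v
  }
  genome_track(chrom, counts, bin_size = bin_size, offset = offset)
}

# 10 kb promoter window anchored at a TSS: [tss - 5000 + 1, tss + 5000]
# for flank_bins = 50 and 100 bp bins (50 bins end at the TSS, 50 follow).
tss_window <- function(tss, flank_bins = 50L, bin_size = 100L) {
  half <- flank_bins * bin_size
  cbind(start = tss - half + 1L, end = tss + half)
}

#' Extract one mark's oriented promoter window from a track
#'
#' Returns the `2 * flank_bins` bins covering the 10 kb window anchored at
#' the TSS (50 bins ending at the TSS, 50 bins after it, for the
#' defaults). Minus-strand windows are reversed so index 1 is always the
#' most upstream bin.
#'
#' @param track A [genome_track()].
#' @param tss 1-based TSS position.
#' @param strand `"+"` or `"-"`.
#' @param mark Mark name or index in `MARK_ORDER`.
#' @param flank_bins Bins on each side of the TSS (default 50).
#' @return Numeric vector of length `2 * flank_bins`, or `NULL` (with a
#'   warning) when the window exceeds the track span.
#' @export
extract_window <- function(track, tss, strand = "+", mark = 1L,
                           flank_bins = 50L) {
  stopifnot(inherits(track, "genome_track"))
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  w <- tss_window(tss, flank_bins, track$bin_size)
  b0 <- (w[1, "start"] - track$offset) %/% track$bin_size + 1L
  b1 <- b0 + 2L * flank_bins - 1L
  if (b0 < 1L || b1 > n_bins(track)) {
    warning(sprintf("window [%d,%d] exceeds track span; record skipped",
                    w[1, "start"], w[1, "end"]))
    return(NULL)
  }
  v <- track$counts[[mark]][b0:b1]
  if (strand == "-") v <- rev(v)
  v
}

profile_matrix <- function(x, transform_state = c("raw", "log"),
                           windows = NULL) {
  transform_state <- match.arg(transform_state)
  x <- as.matrix(x)
  structure(x, class = c("profile_matrix", class(x)),
            transform_state = transform_state, windows = windows)
}

transform_state <- function(pm) {
  st <- attr(pm, "transform_state")
  if (is.null(st)) "raw" else st
}

pm_subset <- function(pm, idx) {
  profile_matrix(unclass(pm)[idx, , drop = FALSE],
                 transform_state = transform_state(pm),
                 windows = attr(pm, "windows")[idx, , drop = FALSE])
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("profile_matrix: %d profiles x %d bins (%s scale)\n",
              nrow(x), ncol(x), transform_state(x)))
  invisible(x)
}

#' Build concatenated promoter profiles from coverage tracks
#'
#' For each TSS, extracts the oriented 100-bin window of every mark and
#' concatenates them in the fixed order `MARK_ORDER` into one 400-bin
#' profile. TSSs whose window falls outside the track span, or whose
#' chromosome has no track, are skipped with a warning.
#'
#' @param tracks A [genome_track()] or a list of them (one per
#'   chromosome).
#' @param tss_list Data frame with columns `chrom`, `tss`, `strand`,
#'   `gene_id` (see [read_tss_bed()]).
#' @param flank_bins Bins on each side of the TSS.
#' @return A `profile_matrix` (raw scale) with one row per retained TSS,
#'   `gene_id` rownames, and a `windows` attribute recording each
#'   profile's 10 kb interval.
#' @export
build_profiles <- function(tracks, tss_list, flank_bins = 50L) {
  if (inherits(tracks, "genome_track")) {
    tracks <- stats::setNames(list(tracks), tracks$chrom)
  }
  if (is.null(names(tracks)))
    names(tracks) <- vapply(tracks, `[[`, character(1), "chrom")
  stopifnot(all(c("chrom", "tss", "strand", "gene_id") %in% names(tss_list)))
  ncols <- 8L * flank_bins
  rows <- vector("list", nrow(tss_list))
  kept <- logical(nrow(tss_list))
  for (i in seq_len(nrow(tss_list))) {
    tr <- tracks[[tss_list$chrom[i]]]
    if (is.null(tr)) {
      warning("no track for chromosome ", tss_list$chrom[i], "; record skipped")
      next
    }
    segs <- lapply(MARK_ORDER, function(m)
      extract_window(tr, tss_list$tss[i], tss_list$strand[i], m, flank_bins))
    if (any(vapply(segs, is.null, logical(1)))) next
    rows[[i]] <- unlist(segs, use.names = FALSE)
    kept[i] <- TRUE
  }
  mat <- do.call(rbind, rows[kept])
  if (is.null(mat)) mat <- matrix(numeric(0), nrow = 0, ncol = ncols)
  rownames(mat) <- tss_list$gene_id[kept]
  w <- tss_window(tss_list$tss[kept], flank_bins)
  windows <- data.frame(gene_id = tss_list$gene_id[kept],
                        chrom = tss_list$chrom[kept],
                        start = as.integer(w[, "start"]),
                        end = as.integer(w[, "end"]),
                        stringsAsFactors = FALSE)
  profile_matrix(mat, "raw", windows = windows)
}

#' QC-filter profiles by their maximum intensity count
#'
#' Two modes mirror the two filtering rules used in training and
#' scanning: `"promoter"` keeps profiles whose maximum count is at least
#' `threshold` (training promoters are dropped when the maximum is *less
#' than* the threshold), while `"scan"` keeps profiles whose maximum is
#' *strictly greater than* the threshold.
#'
#' @param pm A raw-scale `profile_matrix`.
#' @param threshold Maximum-intensity cutoff (default 7).
#' @param mode `"promoter"` or `"scan"`.
#' @return The filtered `profile_matrix`.
#' @export
filter_low_signal <- function(pm, threshold = 7,
                              mode = c("promoter", "scan")) {
  mode <- match.arg(mode)
  if (transform_state(pm) != "raw")
    stop("filter_low_signal() requires raw-scale profiles")
  mx <- apply(unclass(pm), 1L, max)
  keep <- if (mode == "promoter") mx >= threshold else mx > threshold
  pm_subset(pm, keep)
}

#' Drop TSSs whose 10 kb windows overlap
#'
#' Any TSS whose promoter window shares at least one bp with another
#' TSS's window is removed; both members of an overlapping pair are
#' dropped, since the contribution of each gene to the shared counts is
#' ambiguous.
#'
#' @param tss_list Data frame with columns `chrom`, `tss` (and any
#'   others, preserved).
#' @param window_bp Promoter window width (default 10000).
#' @return The subset of `tss_list` with pairwise-disjoint windows.
#' @export
remove_overlapping_promoters <- function(tss_list, window_bp = 10000L) {
  if (!nrow(tss_list)) return(tss_list)
  half <- window_bp %/% 2L
  gr <- GenomicRanges::GRanges(
    tss_list$chrom,
    IRanges::IRanges(start = tss_list$tss - half + 1L,
                     end = tss_list$tss + half))
  keep <- GenomicRanges::countOverlaps(gr, gr) == 1L  # self only
  tss_list[keep, , drop = FALSE]
}

#' Log-transform a profile matrix
#'
#' Elementwise `log(1 + y)`; the offset accommodates the zero counts
#' that raw bins contain. Applying it twice is an error.
#'
#' @param pm A raw-scale `profile_matrix`.
#' @return The `profile_matrix` on the log scale.
#' @export
log_transform <- function(pm) {
  if (transform_state(pm) != "raw")
    stop("profiles are already log-transformed")
  profile_matrix(log1p(unclass(pm)), "log", windows = attr(pm, "windows"))
}

#' Split a concatenated profile back into its four mark segments
#'
#' @param y Numeric vector whose length is a multiple of 4 (400 for the
#'   default 100-bin windows).
#' @return Named list of four equal-length segments in `MARK_ORDER`.
#' @export
split_profile <- function(y) {
  if (length(y) %% 4L != 0L) stop("profile length must be a multiple of 4")
  seg <- length(y) %/% 4L
  stats::setNames(
    lapply(seq_len(4L), function(k) y[((k - 1L) * seg + 1L):(k * seg)]),
    MARK_ORDER)
}
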