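# Overlap of putative promoters with annotation interval sets
# (ESTs, CpG islands, common SNPs): Venn-cell counts and percentages.

#' Load an annotation interval set from a BED file
#'
#' BED's 0-based half-open records are converted to the package's
#' 1-based inclusive convention (so a SNP record of width 1 becomes a
#' 1 bp interval) and sorted.
#'
#' @param path Path to a BED3+ file.
#' @param name Annotation name; defaults to the file name.
#' @return An object of class `annotation_set` wrapping a sorted
#'   `GRanges`.
#' @export
load_bed <- function(path, name = NULL) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "bed"),
    error = function(e) stop("failed to read BED '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  gr <- GenomicRanges::sort(gr)
  structure(list(name = name %||% sub("\\.bed$", "", basename(path)),
                 ranges = gr),
            class = "annotation_set")
}

#' Build an annotation set from a data frame
#'
#' Convenience constructor for in-memory intervals (1-based inclusive).
#'
#' @param df Data frame with `chrom`, `start`, `end`.
#' @param name Annotation name.
#' @return An `annotation_set`.
#' @export
annotation_set <- function(df, name) {
  if (nrow(df) && any(df$start > df$end)) stop("invalid interval: start > end")
  gr <- GenomicRanges::sort(GenomicRanges::GRanges(
    if (nrow(df)) df$chrom else character(0),
    IRanges::IRanges(start = df$start, end = df$end)))
  structure(list(name = name, ranges = gr), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set '%s': %d intervals\n", x$name,
              length(x$ranges)))
  invisible(x)
}

.venn_cells <- function(m) {
  # m: logical n x 3 membership matrix; returns the 7 cells + none
  key <- paste0(as.integer(m[, 1]), as.integer(m[, 2]), as.integer(m[, 3]))
  cells <- c("100", "010", "001", "110", "101", "011", "111", "000")
  counts <- vapply(cells, function(cl) sum(key == cl), integer(1))
  names(counts) <- cells
  counts
}

#' Summarize promoter overlaps with three annotation sets
#'
#' A promoter overlaps an annotation iff it shares at least one bp with
#' any interval of that set. Counts are reported per Venn cell (which
#' combination of the three annotations a promoter hits), per cluster
#' and overall, together with the percentage of promoters overlapping at
#' least one annotation.
#'
#' @param promoters Promoter data frame (from [group_and_assign()]) with
#'   `chrom`, `start`, `end`, `cluster_id`.
#' @param annotations List of three [annotation_set]s.
#' @return An object of class `overlap_summary`: `cells` (data frame of
#'   Venn-cell counts, one row per cluster plus `overall`),
#'   `pct_any` (named percentage overlapping >= 1 annotation), and
#'   `membership` (the logical matrix).
#' @export
overlap_summary <- function(promoters, annotations) {
  if (length(annotations) != 3L)
    stop("exactly three annotation sets are expected")
  nms <- vapply(annotations, `[[`, character(1), "name")
  n <- nrow(promoters)
  pgr <- GenomicRanges::GRanges(
    if (n) promoters$chrom else character(0),
    IRanges::IRanges(start = promoters$start, end = promoters$end))
  m <- vapply(annotations, function(a)
    IRanges::overlapsAny(pgr, a$ranges), logical(n))
  m <- matrix(m, nrow = n, dimnames = list(NULL, nms))
  groups <- c(list(overall = seq_len(n)),
              split(seq_len(n), paste0("cluster_", promoters$cluster_id)))
  cells <- do.call(rbind, lapply(groups, function(idx)
    as.data.frame(t(.venn_cells(m[idx, , drop = FALSE])))))
  cells <- cbind(group = names(groups), n = lengths(groups), cells)
  rownames(cells) <- NULL
  any_hit <- rowSums(m) >= 1
  pct <- vapply(groups, function(idx)
    if (length(idx)) 100 * mean(any_hit[idx]) else 0, numeric(1))
  structure(list(cells = cells, pct_any = pct, membership = m,
                 annotation_names = nms),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat("overlap with annotations:",
      paste(x$annotation_names, collapse = ", "), "\n")
  print(x$cells)
  cat("percent overlapping >= 1 annotation:\n")
  print(round(x$pct_any, 2))
  invisible(x)
}

#' Write an overlap summary as TSV
#'
#' @param summary An [overlap_summary()] result.
#' @param path Output path.
#' @export
write_overlap_tsv <- function(summary, path) {
  df <- summary$cells
  df$pct_any <- round(summary$pct_any[df$group], 4)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
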