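# Readers/writers for the plain-text formats the pipeline consumes:
# bedGraph coverage, BED6 TSS lists, BED3+ annotations, profile TSVs.

#' Read a bedGraph coverage file for one mark
#'
#' @param path Path to a 4-column bedGraph file.
#' @return Data frame with columns `chrom`, `start`, `end`, `value` in
#'   1-based inclusive coordinates.
#' @export
read_bedgraph <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "bedGraph"),
    error = function(e) stop("failed to read bedGraph '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             value = gr$score,
             stringsAsFactors = FALSE)
}

#' Read a TSS list from a BED6 file
#'
#' The TSS is the 5' end of each record: the interval start for `+`
#' records, the interval end for `-` records.
#'
#' @param path Path to a BED6 file (name column = gene id).
#' @return Data frame with columns `chrom`, `tss`, `strand`, `gene_id`.
#' @export
read_tss_bed <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "bed"),
    error = function(e) stop("failed to read BED '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "+"
  tss <- ifelse(strand == "-", GenomicRanges::end(gr),
                GenomicRanges::start(gr))
  nm <- if (!is.null(gr$name)) gr$name else paste0("tss_", seq_along(gr))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             tss = as.integer(tss), strand = strand, gene_id = nm,
             stringsAsFactors = FALSE)
}

#' Read a binned profile matrix from TSV
#'
#' Expects the format written by [write_profiles()]: a `gene_id` column
#' followed by 400 bin columns named by mark segment.
#'
#' @param path Path to the TSV.
#' @return A raw-scale `profile_matrix`.
#' @export
read_profiles <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!"gene_id" %in% names(df)) stop("profile TSV must have a gene_id column")
  mat <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- df$gene_id
  profile_matrix(mat, "raw")
}

#' Write a profile matrix as TSV
#'
#' Columns are named `<mark>_<bin>` so the four concatenated segments are
#' self-describing.
#'
#' @param pm A `profile_matrix`.
#' @param path Output path.
#' @export
write_profiles <- function(pm, path) {
  seg <- ncol(pm) %/% 4L
  cn <- unlist(lapply(MARK_ORDER, function(m) paste0(m, "_", seq_len(seg))))
  df <- data.frame(gene_id = rownames(pm) %||% seq_len(nrow(pm)),
                   unclass(pm), check.names = FALSE)
  names(df) <- c("gene_id", cn)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write putative promoters as BED6
#'
#' Name is the winning cluster (`cluster_<k>`), score is
#' `round(1000 * max_r)` clipped to \[0, 1000\].
#'
#' @param promoters Promoter data frame from [group_and_assign()].
#' @param path Output path.
#' @export
write_promoters_bed <- function(promoters, path) {
  if (!nrow(promoters)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  bed <- data.frame(chrom = promoters$chrom,
                    start = promoters$start - 1L,  # to 0-based half-open
                    end = promoters$end,
                    name = paste0("cluster_", promoters$cluster_id),
                    score = pmax(0L, pmin(1000L,
                                          round(1000 * promoters$max_r))),
                    strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a genome track as four bedGraph files
#'
#' bedGraph values are per-base signal, so each bin is written as
#' `count / bin_size`; re-binning with [bin_coverage()] recovers the
#' original counts exactly.
#'
#' @param track A [genome_track()].
#' @param dir Output directory; one `<mark>.bedGraph` file per mark.
#' @return Paths of the files written.
#' @export
write_track_bedgraph <- function(track, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nb <- n_bins(track)
  start0 <- track$offset - 1L + (seq_len(nb) - 1L) * track$bin_size
  paths <- character(0)
  for (m in MARK_ORDER) {
    v <- track$counts[[m]]
    keep <- v != 0
    df <- data.frame(chrom = track$chrom, start = start0[keep],
                     end = start0[keep] + track$bin_size,
                     value = v[keep] / track$bin_size)
    p <- file.path(dir, paste0(m, ".bedGraph"))
    utils::write.table(df, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
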