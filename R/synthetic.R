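# Synthetic-data generators.
#
# The generators emulate the statistical structure the method assumes:
# four cluster-specific mean shapes on the log scale (pre-TSS ramp,
# post-TSS ramp, unimodal peak at the TSS, flat baseline; the H4K20me1
# segment stays at baseline in all four), additive Gaussian noise on the
# log scale, and integer counts obtained by exponentiating and rounding.
# Defaults put the active-profile maximum near 30 raw counts (well above
# the QC threshold of 7) and the flat cluster near enough to baseline
# that a fraction of its profiles fail QC, exercising the filter.

#' The four canonical log-scale cluster patterns
#'
#' Returns a 4 x 400 matrix of log-scale mean profiles: cluster 1 ramps
#' down to baseline at the TSS (signal upstream), cluster 2 mirrors it
#' (signal downstream), cluster 3 has a symmetric unimodal peak centered
#' on the TSS, cluster 4 is flat. Signal is present in the first three
#' mark segments only; the fourth segment (H4K20me1) is baseline in all
#' clusters.
#'
#' @param amplitude Peak height of the active patterns above baseline,
#'   on the log(1 + count) scale (default 2.2, i.e. a raw maximum of
#'   about 30 counts over baseline 1.2).
#' @param baseline Baseline log level (default 1.2, about 2.3 raw
#'   counts).
#' @param peak_sd Width (in bins) of the Gaussian bump of cluster 3.
#' @param seg_bins Bins per mark segment (default 100).
#' @return 4 x (4 * seg_bins) numeric matrix, rows named by cluster.
#' @export
make_patterns <- function(amplitude = 2.2, baseline = 1.2, peak_sd = 12,
                          seg_bins = 100L) {
  if (amplitude <= 0) stop("`amplitude` must be positive")
  t <- seq_len(seg_bins)
  half <- seg_bins %/% 2L
  ramp_down <- ifelse(t <= half, (half - t) / (half - 1L), 0)
  ramp_up <- ifelse(t > half, (t - half - 1L) / (half - 1L), 0)
  peak <- exp(-((t - (half + 0.5))^2) / (2 * peak_sd^2))
  flat <- rep(0, seg_bins)
  shapes <- rbind(ramp_down, ramp_up, peak, flat)
  pat <- matrix(baseline, 4L, 4L * seg_bins)
  for (s in 1:3)  # active segments; segment 4 (H4K20me1) stays flat
    pat[, ((s - 1L) * seg_bins + 1L):(s * seg_bins)] <-
      baseline + amplitude * shapes
  rownames(pat) <- paste0("cluster_", 1:4)
  pat
}

#' Simulate labelled promoter profiles from the four patterns
#'
#' Profile i in cluster k is
#' `round(exp(pattern_k + eps) - 1)` clamped at zero, with
#' `eps ~ N(0, noise_sd^2)` iid per bin — Gaussian noise on the log
#' scale, matching the mixture step's Gaussian-after-log assumption.
#'
#' @param n_per_cluster Integer vector of 4 cluster sizes (default 100
#'   each).
#' @param noise_sd Log-scale noise standard deviation (default 0.3,
#'   moderate within-cluster variability).
#' @param amplitude,baseline,peak_sd Passed to [make_patterns()].
#' @param seed Integer seed; the output is deterministic given it.
#' @return List with `profiles` (raw-scale `profile_matrix`), `labels`
#'   (true cluster per row), and `patterns` (the generating log-scale
#'   matrix).
#' @export
simulate_profiles <- function(n_per_cluster = c(100L, 100L, 100L, 100L),
                              noise_sd = 0.3, amplitude = 2.2,
                              baseline = 1.2, peak_sd = 12, seed = 1L) {
  if (length(n_per_cluster) != 4L || any(n_per_cluster < 0))
    stop("`n_per_cluster` must be 4 non-negative integers")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  pat <- make_patterns(amplitude, baseline, peak_sd)
  set.seed(seed)
  labels <- rep(1:4, times = n_per_cluster)
  n <- length(labels)
  logp <- pat[labels, , drop = FALSE] +
    matrix(stats::rnorm(n * ncol(pat), sd = noise_sd), n, ncol(pat))
  raw <- pmax(round(exp(logp) - 1), 0)
  rownames(raw) <- sprintf("sim_gene_%04d", seq_len(n))
  list(profiles = profile_matrix(raw, "raw"), labels = labels,
       patterns = pat)
}

#' Simulate a genome track with embedded promoter signatures
#'
#' Generates four-mark background coverage (iid Poisson bins at
#' `background_level`) over one synthetic chromosome and embeds
#' `n_sites` full 10 kb four-mark signatures of randomly chosen active
#' clusters (1-3), each written as `round(exp(pattern + eps) - 1)` with
#' log-scale noise `noise_sd`. Sites are placed on the bin grid, one per
#' equal-sized genome block with at least 20 kb between site windows so
#' embedded signatures cannot merge.
#'
#' @param n_sites Number of embedded signatures (default 20).
#' @param genome_length Chromosome length in bp (default 2e6); must be
#'   at least `40000 * n_sites`.
#' @param background_level Mean background count per bin (default 1).
#' @param noise_sd Log-scale noise on the embedded signatures (default
#'   0.1, so a site's window correlates > 0.9 with its pattern).
#' @param amplitude,baseline,peak_sd Passed to [make_patterns()].
#' @param chrom Chromosome name of the synthetic track.
#' @param seed Integer seed.
#' @return List with `track` (a [genome_track()]), `truth` (data frame
#'   `chrom`, `start`, `end`, `cluster` of the embedded windows), and
#'   `patterns`.
#' @export
simulate_genome <- function(n_sites = 20L, genome_length = 2e6,
                            background_level = 1, noise_sd = 0.1,
                            amplitude = 2.2, baseline = 1.2,
                            peak_sd = 12, chrom = "chrS", seed = 1L) {
  bin <- 100L
  win_bp <- 10000L
  block <- floor(genome_length / max(n_sites, 1L))
  if (n_sites > 0 && block < 4L * win_bp)
    stop("genome too short for ", n_sites,
         " sites with 20 kb spacing; need >= ", 4L * win_bp * n_sites,
         " bp")
  nb <- as.integer(genome_length %/% bin)
  pat <- make_patterns(amplitude, baseline, peak_sd)
  set.seed(seed)
  counts <- stats::setNames(lapply(1:4, function(m)
    as.numeric(stats::rpois(nb, background_level))), MARK_ORDER)
  truth <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), cluster = integer(0))
  if (n_sites > 0) {
    margin <- 15000L
    # one site per block, uniform on the bin grid inside the block margins
    lo <- (seq_len(n_sites) - 1L) * block + margin
    hi <- seq_len(n_sites) * block - margin - win_bp
    start0 <- vapply(seq_len(n_sites), function(i)
      sample(seq.int(lo[i], hi[i], by = bin), 1L), numeric(1))
    site_cluster <- sample(1:3, n_sites, replace = TRUE)
    for (i in seq_len(n_sites)) {
      b0 <- as.integer(start0[i] %/% bin) + 1L   # first bin of the window
      eps <- stats::rnorm(ncol(pat), sd = noise_sd)
      sig <- pmax(round(exp(pat[site_cluster[i], ] + eps) - 1), 0)
      for (m in seq_len(4L)) {
        seg <- sig[((m - 1L) * 100L + 1L):(m * 100L)]
        counts[[m]][b0:(b0 + 99L)] <- seg
      }
    }
    truth <- data.frame(chrom = chrom,
                        start = as.integer(start0 + 1L),
                        end = as.integer(start0 + win_bp),
                        cluster = site_cluster)
  }
  list(track = genome_track(chrom, counts, bin_size = bin, offset = 1L),
       truth = truth, patterns = pat)
}

#' Write a truth BED of embedded sites
#'
#' @param truth Truth data frame from [simulate_genome()].
#' @param path Output path.
#' @export
write_truth_bed <- function(truth, path) {
  bed <- data.frame(chrom = truth$chrom, start = truth$start - 1L,
                    end = truth$end,
                    name = paste0("cluster_", truth$cluster))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
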