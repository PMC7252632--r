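# Shared fixtures built in code.

# constant-count track: each mark m has every bin equal to levels[m]
constant_track <- function(levels = c(1, 2, 3, 4), nb = 300L,
                           chrom = "chr1") {
  genome_track(chrom,
               stats::setNames(lapply(levels, rep, times = nb),
                               MARK_ORDER))
}

# bare characteristic_patterns object from a log-scale pattern matrix
patterns_from_log <- function(log_mat) {
  structure(list(raw = expm1(log_mat), log = log_mat,
                 n_members = rep(1L, nrow(log_mat)), K = nrow(log_mat)),
            class = "characteristic_patterns")
}

threshold_set_fixture <- function(thresholds, alpha = 0.4) {
  names(thresholds) <- paste0("cluster_", seq_along(thresholds))
  structure(list(alpha = alpha, thresholds = thresholds,
                 correlations = NULL),
            class = "threshold_set")
}

# significance-window data frame at the given starts (width 10 kb)
windows_at <- function(starts, cluster_id = 1L, r = 0.9,
                       chrom = "chr1") {
  data.frame(chrom = chrom, start = as.integer(starts),
             end = as.integer(starts + 9999L), cluster_id = cluster_id,
             r = r)
}

# clustering accuracy maximized over label permutations (K small)
perm_accuracy <- function(labels, truth, K = max(truth)) {
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  best <- 0
  for (p in perms(seq_len(K)))
    best <- max(best, mean(p[labels] == truth))
  best
}

# a vector with an exact prescribed correlation r to pattern p
vector_with_cor <- function(p, r, z) {
  ps <- as.vector(scale(p))
  zo <- z - mean(z)
  zo <- zo - ps * sum(zo * ps) / sum(ps^2)  # orthogonal to centered p
  zs <- as.vector(scale(zo))
  r * ps + sqrt(1 - r^2) * zs
}
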