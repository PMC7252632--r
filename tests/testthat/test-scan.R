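# Thresholds, sliding-window scan, region merging, promoter assignment.

test_that("pearson matches the closed form and handles constants", {
  x <- rnorm(400)
  expect_equal(pearson(x, x), 1)
  expect_equal(pearson(x, -x), -1)
  expect_equal(pearson(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_message(r <- pearson(rep(1, 400), x), "constant")
  expect_true(is.na(r))
  expect_error(pearson(1:3, 1:4), "equal length")
})

test_that("thresholds use the lower empirical percentile", {
  p <- log1p(seq(0, 20, length.out = 400))
  set.seed(70)
  z <- rnorm(400)
  want <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  x <- t(sapply(want, function(r) vector_with_cor(p, r, z)))
  pm <- profile_matrix(x, "log")
  pat <- patterns_from_log(rbind(p))
  thr <- correlation_thresholds(pm, pat, labels = rep(1, 5), alpha = 0.4)
  # ECDF reaches 0.4 at the 2nd of 5 order statistics
  expect_equal(unname(thr$thresholds), 0.2, tolerance = 1e-10)
  # alpha = 1 gives the maximum member correlation
  thr1 <- correlation_thresholds(pm, pat, rep(1, 5), alpha = 1)
  expect_equal(unname(thr1$thresholds), 0.5, tolerance = 1e-10)
  # all member correlations equal c -> threshold c
  xc <- t(sapply(rep(0.3, 4), function(r) vector_with_cor(p, r, z)))
  thrc <- correlation_thresholds(profile_matrix(xc, "log"), pat,
                                 rep(1, 4), alpha = 0.4)
  expect_equal(unname(thrc$thresholds), 0.3, tolerance = 1e-10)
  expect_error(correlation_thresholds(pm, pat, c(1, 2, 2, 2, 2)),
               "fewer than 2")
  expect_error(correlation_thresholds(pm, pat, rep(1, 5), alpha = 0))
})

test_that("chained overlapping windows merge into exact regions", {
  # chain of 100 bp-stepped windows: 9701..22301 -> one 9701-32300 region
  w1 <- windows_at(seq(9701, 22301, by = 100))
  r1 <- merge_windows(w1)
  expect_equal(nrow(r1), 1L)
  expect_equal(c(r1$start, r1$end), c(9701L, 32300L))
  expect_equal(r1$n_windows, 127L)
  expect_equal(c(r1$first_start, r1$first_end), c(9701L, 19700L))
  expect_equal(c(r1$last_start, r1$last_end), c(22301L, 32300L))
  # second chain: 66301 plus windows up to start 67801 -> 66301-77800
  r2 <- merge_windows(windows_at(seq(66301, 67801, by = 100)))
  expect_equal(c(r2$start, r2$end), c(66301L, 77800L))
  # two windows 20 kb apart stay two regions equal to the windows
  r3 <- merge_windows(windows_at(c(10001, 30001)))
  expect_equal(nrow(r3), 2L)
  expect_equal(r3$start, c(10001L, 30001L))
  expect_equal(r3$end, c(20000L, 40000L))
  # max_r is the largest member correlation
  w4 <- windows_at(c(10001, 10101), r = c(0.85, 0.95))
  expect_equal(merge_windows(w4)$max_r, 0.95)
})

test_that("merged regions respect cluster and chromosome boundaries", {
  w <- rbind(windows_at(seq(10001, 11001, 100), cluster_id = 1),
             windows_at(seq(10501, 11501, 100), cluster_id = 2),
             windows_at(10001, cluster_id = 1, chrom = "chr2"))
  rg <- merge_windows(w)
  expect_equal(nrow(rg), 3L)
  # within a cluster, regions are pairwise disjoint
  for (k in unique(rg$cluster_id)) {
    g <- rg[rg$cluster_id == k & rg$chrom == "chr1", ]
    if (nrow(g) > 1) expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  }
  # every region boundary coincides with a member window boundary
  expect_equal(rg$start, rg$first_start)
  expect_equal(rg$end, rg$last_end)
})

test_that("cross-cluster grouping unions regions and picks the best cluster", {
  regions <- rbind(
    data.frame(chrom = "chr1", start = 9701L, end = 32300L,
               cluster_id = 1L, max_r = 0.9, n_windows = 127L,
               first_start = 9701L, first_end = 19700L,
               last_start = 22301L, last_end = 32300L),
    data.frame(chrom = "chr1", start = 22101L, end = 36300L,
               cluster_id = 2L, max_r = 0.8, n_windows = 43L,
               first_start = 22101L, first_end = 32100L,
               last_start = 26301L, last_end = 36300L),
    data.frame(chrom = "chr1", start = 25801L, end = 40000L,
               cluster_id = 3L, max_r = 0.7, n_windows = 43L,
               first_start = 25801L, first_end = 35800L,
               last_start = 30001L, last_end = 40000L))
  pp <- group_and_assign(regions)
  expect_equal(nrow(pp), 1L)
  expect_equal(c(pp$start, pp$end), c(9701L, 40000L))
  expect_equal(pp$cluster_id, 1L)
  expect_equal(pp$max_r, 0.9)
  expect_equal(nrow(pp$evidence[[1]]), 3L)
  # a lone region maps to an identical promoter of the same cluster
  lone <- group_and_assign(regions[3, ])
  expect_equal(c(lone$start, lone$end, lone$cluster_id),
               c(25801L, 40000L, 3L))
  # equal max_r ties break to the lowest cluster index
  tie <- regions[1:2, ]
  tie$max_r <- c(0.8, 0.8)
  expect_equal(group_and_assign(tie)$cluster_id, 1L)
})

test_that("promoters from a grouped scan are pairwise disjoint", {
  set.seed(80)
  starts <- sort(sample(seq(1, 2e5, by = 100), 40))
  w <- rbind(windows_at(starts, cluster_id = 1, r = runif(40, 0.5, 1)),
             windows_at(starts + 300, cluster_id = 2,
                        r = runif(40, 0.5, 1)))
  pp <- group_and_assign(merge_windows(w))
  if (nrow(pp) > 1)
    expect_true(all(pp$start[-1] > pp$end[-nrow(pp)]))
})

test_that("shortening halves the first/last windows with an inversion guard", {
  rg <- merge_windows(windows_at(seq(9701, 22301, by = 100)))
  both <- shorten_region(rg, "both")
  expect_equal(c(both$start, both$end), c(14701L, 27300L))
  expect_equal(shorten_region(rg, "first")$start, 14701L)
  expect_equal(shorten_region(rg, "last")$end, 27300L)
  expect_equal(shorten_region(rg, "none"), rg)
  # promoter spanning 9701-40000 with last window 30001-40000
  pp <- group_and_assign(rbind(
    merge_windows(windows_at(seq(9701, 22301, 100), r = 0.9)),
    merge_windows(windows_at(seq(26301, 30001, 100), cluster_id = 3,
                             r = 0.7))))
  short <- shorten_region(pp, "both")
  expect_equal(c(short$start, short$end), c(14701L, 35000L))
  # single-window region would invert: returned unchanged with warning
  one <- merge_windows(windows_at(9701))
  expect_warning(kept <- shorten_region(one, "both"), "invert")
  expect_equal(c(kept$start, kept$end), c(9701L, 19700L))
})

test_that("the scan finds embedded patterns and honors the exclusions", {
  pat_log <- make_patterns()[1:3, ]
  patterns <- patterns_from_log(pat_log)
  thr <- threshold_set_fixture(c(0.8, 0.8, 0.8))
  nb <- 400L
  counts <- stats::setNames(lapply(1:4, function(m) rep(1, nb)),
                            MARK_ORDER)
  # embed the exact raw rendering of pattern 2 at bins 151-250
  sig <- pmax(round(expm1(pat_log[2, ])), 0)
  for (m in 1:4)
    counts[[m]][151:250] <- sig[((m - 1) * 100 + 1):(m * 100)]
  tr <- genome_track("chr1", counts)
  hits <- scan_genome(tr, patterns, thr)
  expect_true(nrow(hits) >= 1)
  expect_true(all(hits$end - hits$start + 1L == 10000L))
  # the exactly covering window is a cluster-2 hit with r ~ 1, and no
  # other cluster beats it anywhere (shifted windows may still clear
  # other clusters' thresholds at lower r; grouping resolves those)
  exact <- hits[hits$start == 15001 & hits$cluster_id == 2L, ]
  expect_equal(nrow(exact), 1L)
  expect_gt(exact$r, 0.99)
  expect_equal(hits$cluster_id[which.max(hits$r)], 2L)
  pp <- group_and_assign(merge_windows(hits))
  expect_equal(pp$cluster_id, 2L)
  # a window overlapping a known promoter is never emitted
  known <- data.frame(chrom = "chr1", start = 14001L, end = 24000L)
  hits2 <- scan_genome(tr, patterns, thr, known_promoters = known)
  expect_equal(nrow(hits2), 0L)
  # flat track: the max-count rule leaves nothing to test
  flat <- genome_track("chr1", stats::setNames(
    lapply(1:4, function(m) rep(2, nb)), MARK_ORDER))
  expect_equal(nrow(scan_genome(flat, patterns, thr)), 0L)
  # max exactly at the cutoff is excluded by the strictly-greater rule
  seven <- genome_track("chr1", stats::setNames(
    lapply(1:4, function(m) rep(7, nb)), MARK_ORDER))
  expect_equal(nrow(scan_genome(seven, patterns, thr)), 0L)
})

test_that("thin regions can be filtered by window support", {
  w <- rbind(windows_at(seq(10001, 11001, 100)), windows_at(50001))
  rg <- merge_windows(w)
  expect_equal(nrow(filter_regions(rg, 1)), 2L)
  expect_equal(nrow(filter_regions(rg, 2)), 1L)
})
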