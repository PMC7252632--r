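# Profile construction, orientation, QC filtering.

test_that("bin_coverage sums per-base values into 100 bp bins", {
  iv <- list(H3K4me2 = data.frame(chrom = "chr1", start = 1, end = 250,
                                  value = 1))
  tr <- bin_coverage(iv, bin_size = 100, span = 300)
  expect_equal(tr$counts$H3K4me2, c(100, 100, 50))
  expect_equal(tr$counts$H3K9ac, c(0, 0, 0))  # absent marks are zero

  # interval exactly one bin wide, value v -> single bin = 100 * v
  iv2 <- list(H3K4me3 = data.frame(chrom = "chr1", start = 101, end = 200,
                                   value = 2.5))
  tr2 <- bin_coverage(iv2, span = 300)
  expect_equal(tr2$counts$H3K4me3, c(0, 250, 0))

  # empty interval list -> all-zero bins over the declared span
  tr0 <- bin_coverage(stats::setNames(list(), character(0)), span = 500)
  expect_true(all(unlist(tr0$counts) == 0))
  expect_length(tr0$counts$H3K4me2, 5L)
})

test_that("bin_coverage rejects malformed input naming the line", {
  iv <- list(H3K4me2 = data.frame(chrom = "chr1",
                                  start = c(1, 300), end = c(100, 350),
                                  value = c(1, -2)))
  expect_error(bin_coverage(iv), "line 2")
  iv2 <- list(H3K4me2 = data.frame(chrom = "chr1", start = 50, end = 10,
                                   value = 1))
  expect_error(bin_coverage(iv2), "line 1")
})

test_that("extract_window orients by strand and respects bounds", {
  nb <- 200L
  tr <- genome_track("chr1",
                     stats::setNames(lapply(1:4, function(m)
                       as.numeric(seq_len(nb))), MARK_ORDER))
  plus <- extract_window(tr, tss = 10000, strand = "+", mark = 1)
  expect_length(plus, 100L)
  # + strand keeps genomic order; - strand is the exact reversal
  minus <- extract_window(tr, tss = 10000, strand = "-", mark = 1)
  expect_equal(minus, rev(plus))
  # tss at 5000 with track starting at 1 -> first bin of track included
  left <- extract_window(tr, tss = 5000, strand = "+", mark = 1)
  expect_equal(left[1], 1)
  # window past the chromosome end is skipped with a warning
  expect_warning(out <- extract_window(tr, tss = 19999, strand = "+"),
                 "skipped")
  expect_null(out)
})

test_that("build_profiles concatenates the four marks in fixed order", {
  tr <- constant_track(c(1, 2, 3, 4))
  tss <- data.frame(chrom = "chr1", tss = 15000, strand = "+",
                    gene_id = "g1")
  pm <- build_profiles(tr, tss)
  expect_equal(dim(pm), c(1L, 400L))
  expect_equal(as.vector(unclass(pm)),
               rep(c(1, 2, 3, 4), each = 100))
  # constant 1 across marks -> 400 ones
  pm1 <- build_profiles(constant_track(rep(1, 4)), tss)
  expect_equal(as.vector(unclass(pm1)), rep(1, 400))
  # no TSS records -> empty matrix, no error
  pm0 <- build_profiles(tr, tss[0, ])
  expect_equal(nrow(pm0), 0L)
})

test_that("profiles round-trip into the four extracted windows", {
  nb <- 300L
  set.seed(42)
  tr <- genome_track("chr1",
                     stats::setNames(lapply(1:4, function(m)
                       as.numeric(rpois(nb, 5))), MARK_ORDER))
  tss <- data.frame(chrom = "chr1", tss = 15000, strand = "-",
                    gene_id = "g1")
  pm <- build_profiles(tr, tss)
  segs <- split_profile(unclass(pm)[1, ])
  for (m in MARK_ORDER)
    expect_equal(segs[[m]],
                 extract_window(tr, 15000, "-", m),
                 ignore_attr = TRUE)
  # window metadata: 10 kb, 1-based inclusive
  w <- attr(pm, "windows")
  expect_equal(w$end - w$start + 1L, 10000L)
})

test_that("filter_low_signal applies the two max-count rules", {
  mk <- function(mx) c(rep(0, 399), mx)
  pm <- profile_matrix(rbind(mk(6), mk(7), mk(8), rep(0, 400)), "raw")
  # promoter mode keeps max >= 7 (max 6 removed, max 7 kept)
  prom <- filter_low_signal(pm, 7, "promoter")
  expect_equal(apply(unclass(prom), 1, max), c(7, 8))
  # scan mode keeps max > 7 (max 7 removed)
  scn <- filter_low_signal(pm, 7, "scan")
  expect_equal(apply(unclass(scn), 1, max), 8)
  # all-zero profile removed in both modes
  expect_false(any(apply(unclass(prom), 1, max) == 0))
  expect_false(any(apply(unclass(scn), 1, max) == 0))
  # idempotent, never increases row count
  expect_equal(unclass(filter_low_signal(prom, 7, "promoter")),
               unclass(prom))
  expect_lte(nrow(prom), nrow(pm))
  # refuses log-scale input
  expect_error(filter_low_signal(log_transform(pm)), "raw-scale")
})

test_that("overlapping promoter windows are removed pairwise", {
  tss <- data.frame(chrom = "chr1",
                    tss = c(30000, 50000),
                    strand = "+", gene_id = c("a", "b"))
  expect_equal(nrow(remove_overlapping_promoters(tss)), 2L)
  tss2 <- transform(tss, tss = c(30000, 35000))
  expect_equal(nrow(remove_overlapping_promoters(tss2)), 0L)
  expect_equal(nrow(remove_overlapping_promoters(tss[1, ])), 1L)
})

test_that("surviving promoter windows are pairwise disjoint", {
  set.seed(11)
  tss <- data.frame(chrom = sample(c("chr1", "chr2"), 60, TRUE),
                    tss = sample(10000:500000, 60),
                    strand = "+", gene_id = paste0("g", 1:60))
  kept <- remove_overlapping_promoters(tss)
  for (ch in unique(kept$chrom)) {
    t <- sort(kept$tss[kept$chrom == ch])
    if (length(t) > 1) expect_true(all(diff(t) >= 10000))
  }
})

test_that("log transform is ln(1+y), monotone, and stateful", {
  pm <- profile_matrix(matrix(c(0, exp(1) - 1, 5, 2), 1), "raw")
  lg <- log_transform(pm)
  expect_equal(unclass(lg)[1, 1:2], c(0, 1), ignore_attr = TRUE)
  # monotone input stays monotone
  mono <- profile_matrix(matrix(sort(runif(400, 0, 50)), 1), "raw")
  expect_false(is.unsorted(unclass(log_transform(mono))[1, ]))
  # double transform is a state error
  expect_error(log_transform(lg), "already")
})
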