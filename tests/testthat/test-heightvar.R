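test_that("coding/non-coding locus split follows protein-coding overlap and
           a brute-force oracle", {
  sz <- chrom_sizes(c(chr1 = 100000))
  genes <- gi("chr1", c(10000, 50000), c(12000, 52000), strand = "+",
              sizes = sz)
  genes$is_protein_coding <- c(TRUE, FALSE)
  loci <- gi("chr1", c(9000, 49000, 80000), c(11000, 53000, 85000),
             sizes = sz)
  loci$variance_explained <- c(0.1, 0.2, 0.3)
  sp <- split_coding(loci, genes)
  expect_equal(length(sp$coding), 1)      # only the protein-coding overlap
  expect_equal(length(sp$non_coding), 2)  # non-coding gene does not count
  set.seed(41)
  for (rep_i in 1:10) {
    g <- random_intervals(5, toy_sizes())
    g$is_protein_coding <- TRUE
    l <- random_intervals(10, toy_sizes())
    l$variance_explained <- stats::runif(10)
    sp2 <- split_coding(l, g)
    want <- oracle_overlaps_any(l, g)
    expect_equal(length(sp2$coding), sum(want))
    expect_equal(length(sp2$non_coding), sum(!want))
  }
})

mk_calls <- function(chrom, start0, fc_limb, fc_trunk, sz) {
  g <- gi(chrom, start0, start0 + 400, sizes = sz)
  g$fc_limb <- fc_limb
  g$fc_trunk <- fc_trunk
  g
}

test_that("top-k selection filters to autosomes, ranks by max fold change
           and flags short sets", {
  sz <- chrom_sizes(c(chr1 = 100000, chrX = 100000))
  calls <- c(mk_calls("chr1", 1000, 10, 1, sz),
             mk_calls("chr1", 5000, 2, 6, sz),
             mk_calls("chr1", 9000, 8, 3, sz),
             mk_calls("chrX", 2000, 50, 50, sz))
  top2 <- top_k_enhancers(calls, k = 2, sizes = sz)
  expect_equal(BiocGenerics::start(top2) - 1L, c(1000, 9000))
  expect_false(attr(top2, "short"))
  # chrX never selected even with the highest fold change
  expect_false("chrX" %in% as.character(GenomeInfoDb::seqnames(
    top_k_enhancers(calls, k = 10, sizes = sz))))
  all_flagged <- top_k_enhancers(calls, k = 10, sizes = sz)
  expect_true(attr(all_flagged, "short"))
  expect_length(all_flagged, 3)
})

test_that("the cumulative curve walks loci by decreasing variance and
           counts a locus once", {
  sz <- chrom_sizes(c(chr1 = 100000))
  loci <- gi("chr1", c(10000, 40000, 70000), c(12000, 42000, 72000),
             sizes = sz)
  loci$variance_explained <- c(0.5, 0.3, 0.2)
  enh <- gi("chr1", c(10500, 70500, 70700), c(10900, 70600, 70900),
            sizes = sz)
  cc <- cumulative_curve(loci, enh)
  expect_equal(cc$curve$x, c(0.5, 0.8, 1.0))
  expect_equal(cc$curve$y, c(0.5, 0.5, 0.7))  # two enhancers, one locus
  expect_equal(cc$y_total, 0.7)
  none <- cumulative_curve(loci, enh[0])
  expect_true(all(none$curve$y == 0))
  bad <- gi("chr1", c(0, 500), c(1000, 1500), sizes = sz)
  bad$variance_explained <- c(1, 1)
  expect_error(cumulative_curve(bad, enh), "non-overlapping")
})

test_that("cumulative curves match a prefix-sum oracle and satisfy the
           monotone envelope on random fixtures", {
  set.seed(77)
  sz <- chrom_sizes(c(chr1 = 1000000))
  for (rep_i in 1:10) {
    starts <- sort(sample.int(990000, 30)) ; starts <- starts[c(TRUE, diff(starts) > 600)]
    loci <- gi("chr1", starts, starts + 500, sizes = sz)
    loci$variance_explained <- stats::runif(length(loci))
    enh <- random_intervals(12, chrom_sizes(c(chr1 = 1000000)), max_len = 300)
    cc <- cumulative_curve(loci, enh)
    or <- oracle_curve(loci, enh)
    expect_equal(cc$curve$x, or$x)
    expect_equal(cc$curve$y, or$y)
    expect_true(all(cc$curve$y <= cc$curve$x + 1e-12))
    expect_true(all(diff(cc$curve$x) >= 0))
    expect_true(all(diff(cc$curve$y) >= 0))
    expect_equal(cc$y_total, sum(loci$variance_explained[
      oracle_overlaps_any(loci, enh)]))
    # adding an enhancer never decreases y anywhere
    cc2 <- cumulative_curve(loci, c(enh, loci[1]))
    expect_true(all(cc2$curve$y >= cc$curve$y - 1e-12))
  }
})

test_that("set comparisons respect superset monotonicity and identical
           sets give identical rows", {
  set.seed(55)
  sz <- chrom_sizes(c(chr1 = 1000000))
  starts <- seq(1000, 900000, by = 50000)
  loci <- gi("chr1", starts, starts + 1000, sizes = sz)
  loci$variance_explained <- rev(sort(stats::runif(length(loci))))
  big <- random_intervals(20, sz, max_len = 2000)
  small <- big[1:8]
  comp <- compare_sets(loci, list(A = big, B = small, B2 = small))
  expect_gte(comp$y_total[comp$set == "A"], comp$y_total[comp$set == "B"])
  expect_equal(comp[comp$set == "B", -1], comp[comp$set == "B2", -1],
               ignore_attr = TRUE)
})

test_that("enhancers placed independently of variance recover the null
           expectation for the explained-variance share", {
  set.seed(101)
  sz <- chrom_sizes(c(chr1 = 10000000))
  starts <- seq(0, 9990000, by = 10000)
  loci <- gi("chr1", starts, starts + 2000, sizes = sz)
  loci$variance_explained <- 1e-4 * stats::runif(length(loci))^(-1 / 3)
  pick <- stats::runif(length(loci)) < 0.3
  enh <- GenomicRanges::shift(loci[pick], 500)  # inside their loci
  cc <- cumulative_curve(loci, enh)
  # independent placement: variance share ~ fraction of loci overlapped
  expect_equal(cc$ratio, mean(pick), tolerance = 0.25)
})
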