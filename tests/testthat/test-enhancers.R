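test_that("ATAC consensus keeps reproducible peaks, merges the union and
           extends by the flank", {
  sz <- toy_sizes()
  p <- calling_params()
  r1 <- gi("chr1", 1000, 1300, sizes = sz)
  r2 <- gi("chr1", 1250, 1400, sizes = sz)
  cons <- consensus_atac(r1, r2, p)
  expect_equal(c(BiocGenerics::start(cons) - 1L, BiocGenerics::end(cons)),
               c(850, 1550))
  expect_length(consensus_atac(r1, gi("chr1", 2000, 2100, sizes = sz), p), 0)
  ident <- consensus_atac(r1, r1, p)
  expect_equal(granges_to_df(ident), granges_to_df(extend_intervals(r1, 150)))
  expect_warning(consensus_atac(r1[0], r2, p), "empty")
})

test_that("candidate regions require ATAC overlap and exclude any promoter
           touch, matching a brute-force set difference", {
  sz <- toy_sizes()
  k27 <- gi("chr1", c(1000, 3000, 5000), c(1400, 3400, 5400), sizes = sz)
  atac <- gi("chr1", c(900, 2900, 4900), c(1500, 3500, 5500), sizes = sz)
  prom <- gi("chr1", 5399, 6000, sizes = sz)  # touches third peak by 1 bp
  out <- candidate_regions(k27, atac, prom)
  expect_equal(BiocGenerics::start(out) - 1L, c(1000, 3000))
  # no ATAC support -> dropped
  expect_length(candidate_regions(k27, atac[1], prom), 1)
  set.seed(31)
  for (rep_i in 1:10) {
    k <- random_intervals(10, sz)
    a <- random_intervals(6, sz)
    pr <- random_intervals(4, sz)
    got <- candidate_regions(k, a, pr)
    want <- k[oracle_overlaps_any(k, a) & !oracle_overlaps_any(k, pr)]
    expect_identical(granges_to_df(got), granges_to_df(want))
  }
})

test_that("differential calling applies the joint fold-change and floor
           rule in both directions", {
  sz <- toy_sizes()
  cand <- gi("chr1", c(1000, 3000, 5000), c(1500, 3500, 5500), sizes = sz)
  calls <- call_differential(cand, cov_pos = c(2.0, 0.4, 0.1),
                             cov_neg = c(0.4, 0.05, 2.0),
                             tissue = "limb")
  # 2.0/0.4 = 5x with floor met -> chondrogenic
  # 0.4 fails the 0.5 floor despite 8x -> no call
  # 0.1 vs 2.0: mirrored rule, floor 2.0 -> non-chondrogenic (20x)
  expect_equal(calls$activity, c("chondrogenic", "non_chondrogenic"))
  expect_equal(calls$fold_change, c(5, 20))
  expect_equal(calls$tissue_of_call, c("limb", "limb"))
  expect_error(call_differential(cand, c(1, 1, -1), c(0, 0, 0)), "negative")
})

test_that("calls within the merge gap collapse per class with max coverage
           and recomputed fold change", {
  sz <- toy_sizes()
  cand <- gi("chr1", c(1000, 1600, 4000), c(1400, 1900, 4400), sizes = sz)
  calls <- call_differential(cand, cov_pos = c(2, 4, 3),
                             cov_neg = c(0.4, 0.5, 0.1), tissue = "limb")
  # first two are 200 bp apart -> one merged call
  expect_length(calls, 2)
  expect_equal(calls$cov_pos[1], 4)
  expect_equal(calls$cov_neg[1], 0.5)
  expect_equal(calls$fold_change[1], 8)
})

test_that("raising the fold-change threshold never increases calls", {
  sz <- toy_sizes()
  set.seed(17)
  cand <- gi("chr1", seq(0, 9500, by = 950)[1:10] + 10,
             seq(0, 9500, by = 950)[1:10] + 500, sizes = sz)
  cov_pos <- stats::rexp(10, 1 / 2)
  cov_neg <- stats::rexp(10, 1 / 0.5)
  prev <- Inf
  for (fc in c(2, 4, 8, 16)) {
    n <- length(call_differential(cand, cov_pos, cov_neg,
                                  calling_params(fc_threshold = fc)))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("tissue classification uses the 2-fold between-tissue rule with
           a pseudocount floor", {
  sz <- toy_sizes(len = 10000L, chroms = "chr1")
  regions0 <- data.frame(start = c(1000, 3000, 5000),
                         end = c(1600, 3600, 5600))
  limb_vals <- c(1.0, 1.0, 0.0)
  trunk_vals <- c(0.4, 0.6, 0.6)
  regs <- gi("chr1", regions0$start, regions0$end, sizes = sz)
  tracks <- list(limb_pos = flat_track(regs, limb_vals, sz),
                 limb_neg = flat_track(regs, limb_vals / 10, sz),
                 trunk_pos = flat_track(regs, trunk_vals, sz),
                 trunk_neg = flat_track(regs, trunk_vals / 10, sz))
  calls <- regs
  calls$activity <- "chondrogenic"
  out <- classify_tissue(calls, calls[0], tracks)
  # 2.5x -> limb; 1.67x -> pan; 0 vs 0.6 -> 0.6/0.01 = 60x -> trunk
  expect_equal(out$tissue_class,
               c("limb_enriched", "pan", "trunk_enriched"))
  expect_equal(out$cov_limb, limb_vals)
  expect_equal(out$cov_trunk, trunk_vals)
})

test_that("marker-gene classification uses strict thresholds and partitions
           markers into limb/trunk/shared", {
  de_l <- data.frame(gene = c("a", "b", "c", "d", "e"),
                     log2FC = c(2.0, 2.0, 1.5, -2.5, 0.1),
                     padj = c(0.01, 0.01, 0.01, 0.001, 0.9))
  de_t <- data.frame(gene = c("a", "b", "c", "d"),
                     log2FC = c(1.9, 0.3, 2.5, -1.8),
                     padj = c(0.04, 0.9, 0.04, 0.01))
  gc <- classify_genes(de_l, de_t)
  expect_equal(gc$chondro_class[match(c("a", "b", "c"), gc$gene)],
               c("shared", "limb_specific", "trunk_specific"))
  # log2FC == 1.5 is not a marker (strict inequality)
  expect_equal(gc$marker_limb[gc$gene == "c"], "none")
  expect_equal(gc$marker_limb[gc$gene == "d"], "egfp_neg_marker")
  # gene absent from the trunk table is a non-marker there, flagged
  expect_equal(gc$missing_in[gc$gene == "e"], "trunk")
  expect_true(is.na(gc$chondro_class[gc$gene == "e"]))
})

test_that("landscape summaries reproduce printed-precision percentages", {
  expect_equal(percent_of(2003, 2704), 74)
  expect_equal(percent_of(483, 2704), 18)
  expect_equal(percent_of(218, 2704), 8)
  expect_equal(percent_of(2704, 3583), 75)
  sz <- chrom_sizes(c(chr1 = 1e7))
  n <- c(pan = 2003, limb_enriched = 483, trunk_enriched = 218)
  cls <- gi("chr1", seq_len(sum(n)) * 1000, seq_len(sum(n)) * 1000 + 100,
            sizes = sz)
  cls$tissue_class <- rep(names(n), n)
  nc <- gi("chr1", 1:879 * 10 + 3e6, 1:879 * 10 + 3e6 + 5, sizes = sz)
  s <- summarize_landscape(cls, nc)
  expect_equal(c(s$pct_pan, s$pct_limb, s$pct_trunk), c(74, 18, 8))
  expect_equal(s$pct_chondrogenic, 75)
  expect_equal(s$n_pan + s$n_limb + s$n_trunk, s$n_chondrogenic)
  single <- summarize_landscape(cls[1], nc[0])
  expect_equal(single$pct_chondrogenic, 100)
})
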