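toy_tads <- function(sz = toy_sizes(len = 10000L, chroms = "chr1")) {
  gi("chr1", c(0, 4000, 8000), c(4000, 8000, 10000), sizes = sz)
}

test_that("enhancers assign only when overlapping exactly one TAD", {
  sz <- toy_sizes(len = 10000L, chroms = "chr1")
  tads <- toy_tads(sz)
  enh <- gi("chr1", c(1000, 3900, 4200, 9000), c(1200, 4100, 4400, 9100),
            sizes = sz)
  out <- assign_to_tads(enh, tads)
  expect_equal(out$tad, c(1L, NA, 2L, 3L))  # boundary-straddler unassigned
  # inter-TAD gap
  tads2 <- gi("chr1", c(0, 5000), c(4000, 10000), sizes = sz)
  out2 <- assign_to_tads(gi("chr1", 4200, 4400, sizes = sz), tads2)
  expect_true(is.na(out2$tad))
  expect_error(assign_to_tads(enh, gi("chr1", c(0, 3000), c(4000, 6000),
                                      sizes = sz)), "non-overlapping")
})

test_that("TAD categories follow the enhancer/gene invariant and partition
           all TADs", {
  sz <- toy_sizes(len = 10000L, chroms = "chr1")
  tads <- toy_tads(sz)
  enh <- gi("chr1", c(1000, 1500, 2000, 4200, 4500),
            c(1100, 1600, 2100, 4300, 4600), sizes = sz)
  enh <- assign_to_tads(enh, tads)
  genes <- gi("chr1", c(3000, 5000, 8100), c(3500, 5500, 8600),
              strand = "+", sizes = sz)
  genes$name <- c("g1", "g2", "g3")
  genes$biotype <- c("protein_coding", "lincRNA", "protein_coding")
  genes$is_protein_coding <- genes$biotype == "protein_coding"
  gc <- data.frame(gene = c("g1", "g2", "g3"),
                   chondro_class = c("shared", "shared", "shared"))
  recs <- categorize_tads(tads, enh, genes, gc)
  # TAD1: 3 enh + protein-coding chondro gene -> chondroTAD
  # TAD2: 2 enh + only a non-coding marker -> chondroEnhTAD
  # TAD3: gene but no enhancer -> other
  expect_equal(recs$category, c("chondroTAD", "chondroEnhTAD", "other"))
  expect_equal(recs$n_enhancers, c(3L, 2L, 0L))
  expect_equal(sum(table(recs$category)), length(tads))
  expect_equal(sum(recs$n_enhancers), sum(!is.na(enh$tad)))
})

test_that("per-TAD statistics reproduce printed means", {
  expect_equal(round(1363 / 357, 1), 3.8)
  expect_equal(round(1315 / 661, 1), 2.0)
  sz <- toy_sizes(len = 10000L, chroms = "chr1")
  tads <- toy_tads(sz)
  tads$n_enhancers <- c(5L, 0L, 0L)
  tads$category <- c("chondroTAD", "other", "other")
  tads$chondro_genes <- c("g", "", "")
  st <- per_tad_stats(tads)
  row <- st[st$category == "chondroTAD", ]
  expect_equal(row$mean_enhancers, 5)
  expect_equal(row$median_enhancers, 5)
  expect_true(is.na(st$mean_enhancers[st$category == "chondroEnhTAD"]))
})

test_that("rank-sum exact branch enumerates the tied permutation
           distribution", {
  rs <- rank_sum_test(c(3, 3, 4), c(1, 1, 2))
  expect_equal(rs$U, 9)
  expect_equal(rs$p, 0.1)
  expect_equal(rs$method, "exact")
  same <- rank_sum_test(c(2, 5, 5, 7), c(5, 7, 2, 5))
  expect_equal(same$p, 1)
  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("rank-sum approximation is sound for large shifted samples and
           agrees with the reference implementation", {
  set.seed(12)
  x <- stats::rnorm(50, 10); y <- stats::rnorm(50, 0)
  rs <- rank_sum_test(x, y)
  expect_equal(rs$method, "approx")
  expect_lt(rs$p, 1e-10)
  for (rep_i in 1:10) {
    a <- sample(0:8, 25, replace = TRUE)
    b <- sample(0:10, 30, replace = TRUE)
    got <- rank_sum_test(a, b, method = "approx")
    ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                               correct = TRUE))
    expect_equal(got$p, ref$p.value, tolerance = 1e-8)
    expect_equal(got$U, unname(ref$statistic))
  }
})

test_that("rank-sum exact and approximate branches agree at moderate n and
           the exact branch matches a pair-count oracle", {
  set.seed(8)
  for (rep_i in 1:10) {
    x <- sample(0:6, 6, replace = TRUE)
    y <- sample(0:6, 6, replace = TRUE)
    ex <- rank_sum_test(x, y, method = "exact")
    expect_equal(ex$p, oracle_rank_sum_exact(x, y))
  }
  for (rep_i in 1:5) {
    x <- sample(0:20, 12, replace = TRUE)
    y <- sample(0:20, 12, replace = TRUE)
    pe <- rank_sum_test(x, y, method = "exact")$p
    pa <- rank_sum_test(x, y, method = "approx")$p
    # relative agreement is meaningful away from the extreme tail, where
    # an absolute bound is the honest comparison
    if (pe >= 0.05) expect_lt(abs(pa - pe) / pe, 0.10)
    else expect_lt(abs(pa - pe), 0.005)
  }
})

test_that("concordance table tabulates gene class against enhancer content
           and excludes mixed-gene TADs", {
  sz <- chrom_sizes(c(chr1 = 60000))
  tads <- gi("chr1", (0:5) * 10000, (1:6) * 10000, sizes = sz)
  tads$category <- rep("chondroTAD", 6)
  tads$chondro_genes <- c("gL", "gT", "gS", "gS2", "gL2,gT2", "gS3")
  tads$n_enhancers <- rep(1L, 6)
  enh <- gi("chr1", (0:5) * 10000 + 500, (0:5) * 10000 + 900, sizes = sz)
  enh$tad <- 1:6
  enh$tissue_class <- c("limb_enriched", "trunk_enriched", "pan", "pan",
                        "pan", "limb_enriched")
  extra <- gi("chr1", 3 * 10000 + 2000, 3 * 10000 + 2400, sizes = sz)
  extra$tad <- 4L
  extra$tissue_class <- "limb_enriched"
  enh <- c(enh, extra)
  gc <- data.frame(gene = c("gL", "gT", "gS", "gS2", "gL2", "gT2", "gS3"),
                   chondro_class = c("limb_specific", "trunk_specific",
                                     "shared", "shared", "limb_specific",
                                     "trunk_specific", "shared"))
  out <- concordance_table(tads, enh, gc)
  expect_equal(out$n_excluded, 1L)
  expect_equal(out$table["limb", "limb"], 1L)
  expect_equal(out$table["trunk", "trunk"], 1L)
  expect_equal(out$table["pan", "pan"], 1L)
  expect_equal(out$table["pan", "mixed"], 1L)
  expect_equal(out$table["pan", "limb"], 1L)
  expect_equal(sum(out$table), 5L)
})
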