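toy_pcm <- function(consensus = "ACGT", strong = 85, weak = 5) {
  bases <- c("A", "C", "G", "T")
  m <- vapply(strsplit(consensus, "")[[1]], function(b) {
    v <- rep(weak, 4); v[match(b, bases)] <- strong; v
  }, numeric(4))
  rownames(m) <- bases
  m
}

test_that("PCM files round-trip in the plain-text layout", {
  pcms <- list(M1 = toy_pcm("ACGTA"), M2 = toy_pcm("TTTTT"))
  f <- withr::local_tempfile(fileext = ".pcm")
  write_pcm(pcms, f)
  back <- read_pcm(f)
  expect_equal(names(back), names(pcms))
  expect_equal(unname(back$M1), unname(pcms$M1))
  writeLines(c(">short", "1 2 3 4", "1 2 3 4"), f)
  expect_error(read_pcm(f), "length")
})

test_that("region centering trims or grows symmetrically with clipping", {
  sz <- toy_sizes(len = 10000L, chroms = "chr1")
  wide <- center_regions(gi("chr1", 1000, 1600, sizes = sz), 500)
  expect_equal(c(BiocGenerics::start(wide) - 1L, BiocGenerics::end(wide)),
               c(1050, 1550))
  narrow <- center_regions(gi("chr1", 1000, 1100, sizes = sz), 500)
  expect_equal(c(BiocGenerics::start(narrow) - 1L, BiocGenerics::end(narrow)),
               c(800, 1300))
  edge <- center_regions(gi("chr1", 50, 150, sizes = sz), 500)
  expect_equal(BiocGenerics::start(edge) - 1L, 0)
  expect_true(edge$clipped)
  expect_false(wide$clipped)
})

test_that("threshold calibration matches exhaustive enumeration for a
           length-4 motif", {
  pcm <- toy_pcm("ACGT")
  sm <- chondromap:::score_matrix(pcm)
  kmers <- expand.grid(1:4, 1:4, 1:4, 1:4)
  kscores <- apply(kmers, 1, function(idx) sum(sm$k[cbind(idx, 1:4)]))
  for (alpha in c(0.001, 0.01, 0.05)) {
    thr <- calibrate_threshold(pcm, alpha = alpha)
    t_int <- round(thr / sm$grid)
    # brute force over all 256 4-mers under the uniform background: the
    # threshold is the smallest grid score whose tail is within alpha
    expect_lte(mean(kscores >= t_int), alpha)
    expect_gt(mean(kscores >= t_int - 1), alpha)
  }
})

test_that("degenerate and boundary calibrations behave as defined", {
  uni <- matrix(25, 4, 16, dimnames = list(c("A", "C", "G", "T"), NULL))
  thr <- calibrate_threshold(uni, alpha = 0.001)
  # all log-odds are zero: the threshold is unattainable and nothing hits
  hits <- count_hits(random_dna(5, 100), uni, thr)
  expect_equal(hits$hits, 0)
  expect_gt(thr, 0)
  # alpha = 1: minimal score, every scanned window is a hit
  pcm <- toy_pcm("ACGTAC")
  thr1 <- calibrate_threshold(pcm, alpha = 1)
  set.seed(2)
  seqs <- random_dna(3, 50)
  h1 <- count_hits(seqs, pcm, thr1)
  expect_equal(h1$hits, h1$positions)
  expect_equal(h1$positions, 2 * 3 * (50 - 6 + 1))
  expect_error(calibrate_threshold(pcm, alpha = 0), "alpha")
})

test_that("hit counting finds the consensus, is strand-symmetric, skips N
           windows, and matches a naive scanner", {
  pcm <- toy_pcm("ACGTACGTAC")
  thr <- calibrate_threshold(pcm, alpha = 0.001)
  expect_gte(count_hits("ACGTACGTAC", pcm, thr)$hits, 1)
  rc <- "GTACGTACGT"  # reverse complement of the consensus
  expect_equal(count_hits(rc, pcm, thr)$hits,
               count_hits("ACGTACGTAC", pcm, thr)$hits)
  # windows containing N are excluded from scanned positions; here every
  # window on both strands touches the N
  withN <- count_hits("ACGTNACGTACGTA", pcm, thr)
  expect_equal(withN$positions, 0)
  # an N outside every window leaves counts unchanged
  clean <- count_hits("ACGTACGTACGTN", pcm, thr)
  expect_equal(clean$positions, 2 * (13 - 10 + 1) - 2)
  short <- count_hits("ACGT", pcm, thr)
  expect_equal(short$positions, 0)
  set.seed(19)
  seqs <- random_dna(20, 120)
  planted <- sample(20, 6)
  for (i in planted)
    substr(seqs[i], 30, 39) <- "ACGTACGTAC"
  got <- count_hits(seqs, pcm, thr)
  want <- oracle_count_hits(seqs, pcm, thr)
  expect_equal(got$hits, want$hits)
  expect_gte(got$hits, 6)
  expect_equal(got$positions, want$positions)
})

test_that("hit counts are invariant under reverse-complementing every
           sequence and monotone in the threshold", {
  set.seed(29)
  pcm <- toy_pcm("ACGGTTCA", strong = 60, weak = 10)
  seqs <- random_dna(10, 200)
  rc <- vapply(seqs, function(s)
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = "")),
    character(1), USE.NAMES = FALSE)
  thr <- calibrate_threshold(pcm, alpha = 0.01)
  expect_equal(count_hits(seqs, pcm, thr)$hits,
               count_hits(rc, pcm, thr)$hits)
  hits_at <- vapply(c(thr - 1, thr, thr + 1), function(t)
    count_hits(seqs, pcm, t)$hits, numeric(1))
  expect_true(all(diff(hits_at) <= 0))
})

test_that("enrichment follows the pseudocounted closed form", {
  expect_equal(motif_enrichment(10, 1000, 10, 1000)$log2_fold_change, 0)
  # 4x the background rate approaches log2FC = 2 for large counts
  big <- motif_enrichment(4000, 1e6, 1000, 1e6)$log2_fold_change
  expect_equal(big, 2, tolerance = 0.01)
  zero <- motif_enrichment(0, 1000, 0, 1000)$log2_fold_change
  expect_equal(zero, 0)
  expect_error(motif_enrichment(1, 0, 1, 10), "zero")
  exact <- motif_enrichment(7, 500, 2, 800)$log2_fold_change
  expect_equal(exact, log2((7.5 / 500) / (2.5 / 800)))
})

test_that("a planted motif outranks decoys when target density is 5x the
           background", {
  set.seed(67)
  consensus <- "TGACGTCATT"
  pcm <- toy_pcm(consensus)
  decoys <- lapply(1:20, function(i)
    toy_pcm(paste(sample(c("A", "C", "G", "T"), 10, replace = TRUE),
                  collapse = "")))
  names(decoys) <- sprintf("decoy%02d", 1:20)
  plant <- function(n, density) {
    vapply(seq_len(n), function(i) {
      s <- sample(c("A", "C", "G", "T"), 300, replace = TRUE)
      if (stats::runif(1) < density) {
        st <- sample(290, 1)
        s[st:(st + 9)] <- strsplit(consensus, "")[[1]]
      }
      paste(s, collapse = "")
    }, character(1))
  }
  targ <- plant(40, 1.0)
  bg <- plant(40, 0.2)
  res <- scan_enrichment(targ, bg, c(list(planted = pcm), decoys))
  expect_lte(match("planted", res$motif), 3)
})
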