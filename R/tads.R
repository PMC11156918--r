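#' Assign enhancers to TADs
#'
#' An enhancer is unambiguously assigned when it overlaps exactly one TAD;
#' enhancers overlapping zero TADs (inter-TAD gaps) or two or more TADs
#' (boundary-straddling) are reported unassigned. Overlapping TADs are an
#' input error.
#'
#' @param enhancers `GRanges` of enhancer calls.
#' @param tads Disjoint `GRanges` of TADs.
#' @return The enhancers with an integer `tad` column (index into `tads`,
#'   `NA` when unassigned).
#' @export
assign_to_tads <- function(enhancers, tads) {
  if (!IRanges::isDisjoint(tads))
    stop("TADs must be non-overlapping")
  n <- GenomicRanges::countOverlaps(enhancers, tads, ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(enhancers, tads, ignore.strand = TRUE)
  tad <- rep(NA_integer_, length(enhancers))
  one <- which(n == 1L)
  tad[one] <- S4Vectors::subjectHits(hits)[match(one, S4Vectors::queryHits(hits))]
  enhancers$tad <- tad
  enhancers
}

#' Categorize TADs by chondrogenic content
#'
#' A chondroTAD contains at least one assigned chondrogenic enhancer and at
#' least one protein-coding chondrogenic gene; a chondroEnhTAD contains
#' chondrogenic enhancers but no chondrogenic gene; everything else is
#' "other". Genes attach to TADs by any overlap of the gene body (a
#' boundary-spanning gene may belong to two TADs).
#'
#' @param tads Disjoint `GRanges` of TADs.
#' @param enhancers Output of [assign_to_tads()] (chondrogenic calls).
#' @param genes Gene `GRanges` (see [read_gene_table()]).
#' @param gene_classes Output of [classify_genes()]; a chondrogenic gene is
#'   a protein-coding gene with non-`NA` `chondro_class`.
#' @return `tads` with columns `n_enhancers`, `n_chondro_genes`,
#'   `chondro_genes` (comma-separated names), `category`.
#' @export
categorize_tads <- function(tads, enhancers, genes, gene_classes) {
  stopifnot("tad" %in% names(S4Vectors::mcols(enhancers)))
  if (!IRanges::isDisjoint(tads)) stop("TADs must be non-overlapping")
  n_enh <- tabulate(enhancers$tad, nbins = length(tads))
  chondro_names <- gene_classes$gene[!is.na(gene_classes$chondro_class)]
  cg <- genes[genes$is_protein_coding & genes$name %in% chondro_names]
  hits <- GenomicRanges::findOverlaps(cg, tads, ignore.strand = TRUE)
  gene_lists <- split(cg$name[S4Vectors::queryHits(hits)],
                      factor(S4Vectors::subjectHits(hits),
                             levels = seq_along(tads)))
  n_cg <- unname(lengths(gene_lists))
  tads$n_enhancers <- n_enh
  tads$n_chondro_genes <- unname(n_cg)
  tads$chondro_genes <- unname(vapply(gene_lists, paste, character(1),
                                      collapse = ","))
  tads$category <- ifelse(n_enh >= 1 & n_cg >= 1, "chondroTAD",
                   ifelse(n_enh >= 1, "chondroEnhTAD", "other"))
  tads
}

#' Per-category TAD statistics
#'
#' Enhancer-count distribution per TAD category: number of TADs, total
#' enhancers, mean (reported to one decimal, as printed) and median.
#' Categories without TADs report `NA`.
#'
#' @param tad_records Output of [categorize_tads()].
#' @return Data frame, one row per category.
#' @export
per_tad_stats <- function(tad_records) {
  cats <- c("chondroTAD", "chondroEnhTAD", "other")
  rows <- lapply(cats, function(cat) {
    n <- tad_records$n_enhancers[tad_records$category == cat]
    data.frame(category = cat, n_tads = length(n),
               n_enhancers = sum(n),
               mean_enhancers = if (length(n)) round(mean(n), 1) else NA_real_,
               median_enhancers = if (length(n)) stats::median(n) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Two-tailed Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' Exact enumeration of the permutation distribution when the smaller
#' sample has at most 8 observations (valid with ties), otherwise a
#' tie-corrected normal approximation with continuity correction. The
#' two-tailed exact p-value is the permutation probability of a U at least
#' as far from its null mean as observed.
#'
#' @param x,y Non-empty numeric samples (typically per-TAD counts).
#' @param method `"auto"` (default), `"exact"` or `"approx"`.
#' @return List with `U` (statistic for `x`), `p`, and the `method` used.
#' @export
rank_sum_test <- function(x, y, method = c("auto", "exact", "approx")) {
  method <- match.arg(method)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  z <- c(x, y)
  r <- rank(z)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (method == "auto") {
    method <- if (min(n1, n2) <= 8) "exact" else "approx"
  }
  mu <- n1 * n2 / 2
  if (method == "exact") {
    # permutation distribution of U by counting subsets per rank-sum
    # (dynamic programme over doubled ranks, exact under ties)
    k <- min(n1, n2)
    d <- as.integer(round(2 * r))
    maxs <- sum(d)
    dp <- matrix(0, k + 1, maxs + 1)   # dp[j+1, s+1]: subsets of size j, sum s
    dp[1, 1] <- 1
    for (x in d) {
      for (j in k:1) {
        dp[j + 1, (x + 1):(maxs + 1)] <-
          dp[j + 1, (x + 1):(maxs + 1)] + dp[j, 1:(maxs - x + 1)]
      }
    }
    counts <- dp[k + 1, ]
    Us <- (seq_along(counts) - 1) / 2 - k * (k + 1) / 2
    # U for the smaller sample; the null is symmetric around mu either way
    obs <- if (n1 <= n2) U else n1 * n2 - U
    keep <- abs(Us - mu) >= abs(obs - mu) - 1e-9
    p <- sum(counts[keep]) / choose(N, k)
  } else {
    ties <- table(r)
    sigma2 <- (n1 * n2 / 12) *
      ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    d <- U - mu
    d <- d - sign(d) * 0.5  # continuity correction
    zstat <- d / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(zstat)))
  }
  list(U = U, p = p, method = method)
}

#' Gene-class vs enhancer-content concordance within chondroTADs
#'
#' For chondroTADs whose chondrogenic genes all share one specificity class
#' (limb / trunk / pan, where "pan" is the shared class), the enhancer
#' content is the set of distinct tissue classes of the TAD's assigned
#' chondrogenic enhancers ("mixed" when more than one). chondroTADs with
#' genes of several classes are excluded and counted separately.
#'
#' @param tad_records Output of [categorize_tads()].
#' @param enhancers Output of [assign_to_tads()] on tissue-classified
#'   chondrogenic enhancers (needs `tad` and `tissue_class` columns).
#' @param gene_classes Output of [classify_genes()].
#' @return List with `table` (gene class x enhancer content contingency
#'   counts) and `n_excluded` (mixed-gene chondroTADs).
#' @export
concordance_table <- function(tad_records, enhancers, gene_classes) {
  stopifnot(all(c("tad", "tissue_class") %in%
                  names(S4Vectors::mcols(enhancers))))
  gene_cls <- c(limb_specific = "limb", trunk_specific = "trunk",
                shared = "pan")
  enh_cls <- c(limb_enriched = "limb", trunk_enriched = "trunk", pan = "pan")
  idx <- which(tad_records$category == "chondroTAD")
  gene_levels <- c("limb", "trunk", "pan")
  enh_levels <- c("limb", "trunk", "pan", "mixed")
  tab <- matrix(0L, length(gene_levels), length(enh_levels),
                dimnames = list(gene = gene_levels, enhancers = enh_levels))
  n_excluded <- 0L
  cls_of_gene <- stats::setNames(gene_cls[gene_classes$chondro_class],
                                 gene_classes$gene)
  for (i in idx) {
    gnames <- strsplit(tad_records$chondro_genes[i], ",", fixed = TRUE)[[1]]
    gcl <- unique(stats::na.omit(cls_of_gene[gnames]))
    if (length(gcl) != 1L) { n_excluded <- n_excluded + 1L; next }
    ecl <- unique(enh_cls[enhancers$tissue_class[
      !is.na(enhancers$tad) & enhancers$tad == i]])
    content <- if (length(ecl) == 1L) ecl else "mixed"
    tab[gcl, content] <- tab[gcl, content] + 1L
  }
  list(table = tab, n_excluded = n_excluded)
}
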