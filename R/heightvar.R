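#' Read a table of genome-wide-significant (GWS) height loci
#'
#' Tab-separated with header: chrom, start, end, variance_explained
#' (BED-style coordinates; variance as a fraction of phenotypic variance).
#'
#' @param path File path.
#' @param sizes A [chrom_sizes()] object.
#' @return `GRanges` with a `variance_explained` column.
#' @export
read_gws_loci <- function(path, sizes) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end", "variance_explained") %in%
                  names(tab)))
  gr <- gi(tab$chrom, tab$start, tab$end, sizes = sizes)
  gr$variance_explained <- tab$variance_explained
  if (any(gr$variance_explained < 0)) stop("negative variance_explained")
  gr
}

#' Split GWS loci by protein-coding gene overlap
#'
#' A locus is "coding" when it overlaps at least one protein-coding gene
#' body, "non-coding" otherwise.
#'
#' @param loci GWS locus `GRanges`.
#' @param genes Gene `GRanges` with an `is_protein_coding` column.
#' @return List with elements `coding` and `non_coding`.
#' @export
split_coding <- function(loci, genes) {
  pc <- genes[genes$is_protein_coding]
  flag <- overlaps_any(loci, pc)
  list(coding = loci[flag], non_coding = loci[!flag])
}

#' Size-matched top-k enhancer selection
#'
#' Enhancer sets compared on the variance curve are matched in size by
#' keeping autosomal enhancers only and ranking them by the maximum over
#' tissues of the EGFP+/EGFP- H3K27ac fold change (default), or by the
#' maximum absolute coverage difference (`metric = "coverage_diff"`).
#' Ties break by (chrom, start) for determinism. When fewer than `k`
#' candidates exist the whole set is returned with attribute
#' `short = TRUE`.
#'
#' @param calls Tissue-classified enhancer `GRanges` (needs `fc_limb`,
#'   `fc_trunk` and, for the coverage metric, `cov_limb`, `cov_trunk`).
#' @param k Set size (877 in the published analysis).
#' @param sizes A [chrom_sizes()] object carrying autosome flags.
#' @param metric Ranking statistic.
#' @return `GRanges` subset of `calls`.
#' @export
top_k_enhancers <- function(calls, k = 877, sizes,
                            metric = c("fold_change", "coverage_diff")) {
  metric <- match.arg(metric)
  stopifnot(inherits(sizes, "ChromSizes"))
  auto_chroms <- names(sizes$autosome)[sizes$autosome]
  calls <- calls[as.character(GenomeInfoDb::seqnames(calls)) %in% auto_chroms]
  val <- if (metric == "fold_change") {
    pmax(calls$fc_limb, calls$fc_trunk)
  } else {
    pmax(abs(calls$cov_limb), abs(calls$cov_trunk))
  }
  ord <- order(-val, as.character(GenomeInfoDb::seqnames(calls)),
               BiocGenerics::start(calls))
  short <- length(calls) < k
  out <- calls[ord[seq_len(min(k, length(calls)))]]
  attr(out, "short") <- short
  out
}

#' Cumulative height-variance attribution curve
#'
#' Walking GWS loci from highest to lowest variance explained (ties stable
#' by coordinates), the x coordinate accumulates every locus's variance
#' while the y coordinate accumulates a locus's variance iff at least one
#' enhancer of the set overlaps it — once per locus, regardless of how
#' many enhancers overlap, so that y <= x everywhere.
#'
#' @param loci Non-overlapping GWS locus `GRanges` with
#'   `variance_explained`.
#' @param enhancers Enhancer `GRanges`.
#' @return List: `curve` (data frame x, y, overlapped per walked locus),
#'   `n_overlapped`, `pct_loci`, `y_total`, `x_total`, `ratio`
#'   (= y_total / x_total).
#' @export
cumulative_curve <- function(loci, enhancers) {
  if (!IRanges::isDisjoint(loci)) stop("GWS loci must be non-overlapping")
  ord <- order(-loci$variance_explained,
               as.character(GenomeInfoDb::seqnames(loci)),
               BiocGenerics::start(loci))
  loci <- loci[ord]
  flag <- overlaps_any(loci, enhancers)
  v <- loci$variance_explained
  x <- cumsum(v)
  y <- cumsum(v * flag)
  list(curve = data.frame(x = x, y = y, overlapped = flag),
       n_overlapped = sum(flag),
       pct_loci = percent_of(sum(flag), length(loci), 1),
       y_total = sum(v[flag]),
       x_total = sum(v),
       ratio = if (sum(v) > 0) sum(v[flag]) / sum(v) else NA_real_)
}

#' Compare the variance explained by several enhancer sets
#'
#' One curve per named set over the same loci; sets should be size-matched
#' via [top_k_enhancers()] beforehand.
#'
#' @param loci Non-overlapping GWS locus `GRanges`.
#' @param sets Named list of enhancer `GRanges`.
#' @return Data frame with one row per set: `set`, `n_enhancers`,
#'   `n_overlapped`, `pct_loci`, `y_total`, `ratio`.
#' @export
compare_sets <- function(loci, sets) {
  stopifnot(length(names(sets)) == length(sets))
  rows <- lapply(names(sets), function(nm) {
    cc <- cumulative_curve(loci, sets[[nm]])
    data.frame(set = nm, n_enhancers = length(sets[[nm]]),
               n_overlapped = cc$n_overlapped, pct_loci = cc$pct_loci,
               y_total = cc$y_total, ratio = cc$ratio,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
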