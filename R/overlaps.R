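#' Merged inactive-chromatin control set
#'
#' Accessible regions lacking H3K27ac in every condition, merged when
#' closer than 500 bp, form the control universe for TF-binding overlap.
#'
#' @param inactive_regions `GRanges` of accessible-but-inactive regions.
#' @param merge_gap Merge distance in bp.
#' @return Merged `GRanges`.
#' @export
prepare_control <- function(inactive_regions, merge_gap = 500) {
  merge_within(inactive_regions, merge_gap)
}

#' TF-binding overlap of enhancers versus an inactive control
#'
#' Any-overlap (>= 1 bp) counting of query enhancers and control regions
#' against a set of TF ChIP peaks (peaks are expected pre-merged within
#' 500 bp). Percentages are reported at printed precision: integer for the
#' query, one decimal for the control.
#'
#' @param enhancers Query `GRanges`.
#' @param tf_peaks TF ChIP peak `GRanges`.
#' @param control Output of [prepare_control()].
#' @return List: `n_query`, `n_overlapping`, `fraction` (percent),
#'   `control_n`, `control_overlapping`, `control_fraction`.
#' @export
tf_overlap <- function(enhancers, tf_peaks, control) {
  if (length(enhancers) == 0L) stop("empty enhancer query")
  n_q <- length(enhancers)
  n_ov <- sum(overlaps_any(enhancers, tf_peaks))
  n_c <- length(control)
  n_cov <- if (n_c) sum(overlaps_any(control, tf_peaks)) else 0L
  list(n_query = n_q, n_overlapping = n_ov,
       fraction = percent_of(n_ov, n_q),
       control_n = n_c, control_overlapping = n_cov,
       control_fraction = if (n_c) percent_of(n_cov, n_c, 1) else NA_real_)
}

#' Enhancer and gene content of large named loci
#'
#' Per named locus: the number of chondrogenic and non-chondrogenic
#' enhancers it overlaps and the chondrogenic gene names it contains.
#' Totals deduplicate enhancers that fall in several (possibly
#' overlapping) loci, and report the percentage of each enhancer universe,
#' to one decimal.
#'
#' @param loci Named `GRanges` of large intervals (e.g. selected TAD
#'   spans); a `name` metadata column is used when present.
#' @param chondro,non_chondro Enhancer `GRanges`.
#' @param genes Optional chondrogenic gene `GRanges` with a `name` column.
#' @return List with `per_locus` (data frame) and `totals`.
#' @export
locus_overlap_counts <- function(loci, chondro, non_chondro, genes = NULL) {
  nm <- if ("name" %in% names(S4Vectors::mcols(loci))) loci$name
        else paste0("locus_", seq_along(loci))
  per <- lapply(seq_along(loci), function(i) {
    l <- loci[i]
    gn <- if (!is.null(genes)) paste(genes$name[overlaps_any(genes, l)],
                                     collapse = ",") else ""
    data.frame(locus = nm[i],
               n_chondro = sum(overlaps_any(chondro, l)),
               n_non_chondro = sum(overlaps_any(non_chondro, l)),
               chondro_genes = gn, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  tot_ch <- sum(overlaps_any(chondro, loci))
  tot_nc <- sum(overlaps_any(non_chondro, loci))
  totals <- list(
    n_chondro = tot_ch,
    pct_chondro = percent_of(tot_ch, length(chondro), 1),
    n_non_chondro = tot_nc,
    pct_non_chondro = percent_of(tot_nc, length(non_chondro), 1),
    n_genes = if (!is.null(genes)) sum(overlaps_any(genes, loci)) else NA_integer_
  )
  list(per_locus = per, totals = totals)
}
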