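#' Enhancer-calling parameters
#'
#' Defaults reproduce the published calling rule: replicated ATAC peaks
#' extended by 150 bp, promoters excluded over a -2 kb/+500 b TSS window,
#' a differential H3K27ac call requiring a >= 4-fold ratio between sorted
#' fractions together with an absolute coverage floor of 0.5 in the high
#' fraction, calls merged within 500 bp, and a 2-fold between-tissue ratio
#' for tissue specificity. All thresholds are inclusive (>=). The
#' pseudocount floors ratio denominators near zero.
#'
#' @param atac_flank bp added to each side of consensus ATAC peaks.
#' @param promoter_up,promoter_down Promoter window extent around the TSS.
#' @param fc_threshold Fold-change threshold between fractions.
#' @param min_pos_cov Coverage floor (signal units) in the high fraction.
#' @param merge_gap Merge distance for surviving calls, bp.
#' @param tissue_fc Between-tissue enrichment threshold.
#' @param pseudocount Denominator floor, signal units.
#' @return A `CallingParams` list.
#' @export
calling_params <- function(atac_flank = 150, promoter_up = 2000,
                           promoter_down = 500, fc_threshold = 4,
                           min_pos_cov = 0.5, merge_gap = 500,
                           tissue_fc = 2, pseudocount = 0.01) {
  p <- list(atac_flank = atac_flank, promoter_up = promoter_up,
            promoter_down = promoter_down, fc_threshold = fc_threshold,
            min_pos_cov = min_pos_cov, merge_gap = merge_gap,
            tissue_fc = tissue_fc, pseudocount = pseudocount)
  if (any(vapply(p, function(v) length(v) != 1L || is.na(v) || v <= 0,
                 logical(1)) & names(p) != "atac_flank"))
    stop("all calling parameters must be positive scalars")
  if (atac_flank < 0) stop("atac_flank must be >= 0")
  structure(p, class = "CallingParams")
}

#' Reproducible ATAC consensus peaks
#'
#' A peak is reproducible when it overlaps (>= 1 bp) a peak of the other
#' replicate; the consensus is the merged union of reproducible peaks from
#' either replicate, extended by `atac_flank` on each side. The union is
#' kept (rather than either replicate's footprint) so the result is
#' symmetric under replicate relabeling.
#'
#' @param rep1,rep2 `GRanges` of replicate peaks for one condition.
#' @param params A [calling_params()].
#' @return Consensus `GRanges`.
#' @export
consensus_atac <- function(rep1, rep2, params = calling_params()) {
  if (length(rep1) == 0L || length(rep2) == 0L) {
    warning("empty ATAC replicate: consensus is empty")
    return(GenomicRanges::granges(rep1[0]))
  }
  keep1 <- rep1[overlaps_any(rep1, rep2)]
  keep2 <- rep2[overlaps_any(rep2, rep1)]
  un <- merge_within(c(GenomicRanges::granges(keep1),
                       GenomicRanges::granges(keep2)), 0)
  extend_intervals(un, params$atac_flank)
}

#' Candidate enhancer regions
#'
#' H3K27ac peaks that overlap (>= 1 bp) the ATAC consensus and overlap no
#' promoter window (any-overlap exclusion).
#'
#' @param h3k27ac_peaks `GRanges` of H3K27ac peaks in the high fraction.
#' @param atac_consensus Output of [consensus_atac()].
#' @param promoters Output of [promoter_windows()].
#' @return Filtered `GRanges` (same metadata as the input peaks).
#' @export
candidate_regions <- function(h3k27ac_peaks, atac_consensus, promoters) {
  keep <- overlaps_any(h3k27ac_peaks, atac_consensus) &
    !overlaps_any(h3k27ac_peaks, promoters)
  h3k27ac_peaks[keep]
}

#' Call differential enhancers between sorted fractions
#'
#' A candidate is chondrogenic when its high-fraction (EGFP+) coverage is
#' at least `min_pos_cov` and the EGFP+/EGFP- ratio is at least
#' `fc_threshold`; non-chondrogenic by the mirrored rule. Ratio
#' denominators are floored at `pseudocount`. Surviving calls of each class
#' are merged within `merge_gap` separately; a merged call carries the
#' per-fraction maximum coverage over its members with the fold change
#' recomputed from those (deterministic and order-independent).
#'
#' @param candidates `GRanges` from [candidate_regions()].
#' @param cov_pos,cov_neg Mean normalized H3K27ac coverage per candidate in
#'   the EGFP+ and EGFP- fractions.
#' @param params A [calling_params()].
#' @param tissue Label stored on the calls (`"limb"` or `"trunk"`).
#' @return `GRanges` with columns `activity`, `cov_pos`, `cov_neg`,
#'   `fold_change`, `tissue_of_call`.
#' @export
call_differential <- function(candidates, cov_pos, cov_neg,
                              params = calling_params(), tissue = NA_character_) {
  stopifnot(length(cov_pos) == length(candidates),
            length(cov_neg) == length(candidates))
  if (any(cov_pos < 0) || any(cov_neg < 0))
    stop("negative coverage value")
  pc <- params$pseudocount
  fc_pos <- cov_pos / pmax(cov_neg, pc)
  fc_neg <- cov_neg / pmax(cov_pos, pc)
  is_ch <- cov_pos >= params$min_pos_cov & fc_pos >= params$fc_threshold
  is_nc <- cov_neg >= params$min_pos_cov & fc_neg >= params$fc_threshold
  stopifnot(!any(is_ch & is_nc))  # rules are mutually exclusive
  merge_class <- function(idx, activity) {
    if (!length(idx)) {
      out <- GenomicRanges::granges(candidates[0])
    } else {
      g <- GenomicRanges::granges(candidates[idx])
      red <- GenomicRanges::reduce(g, min.gapwidth = params$merge_gap + 1L,
                                   ignore.strand = TRUE, with.revmap = TRUE)
      out <- GenomicRanges::granges(red)
      cp <- vapply(red$revmap, function(i) max(cov_pos[idx][i]), numeric(1))
      cn <- vapply(red$revmap, function(i) max(cov_neg[idx][i]), numeric(1))
      out$cov_pos <- cp
      out$cov_neg <- cn
      out$fold_change <- if (activity == "chondrogenic")
        cp / pmax(cn, pc) else cn / pmax(cp, pc)
    }
    if (!length(idx)) {
      out$cov_pos <- numeric(0); out$cov_neg <- numeric(0)
      out$fold_change <- numeric(0)
    }
    out$activity <- rep(activity, length(out))
    out$tissue_of_call <- rep(tissue, length(out))
    out
  }
  calls <- c(merge_class(which(is_ch), "chondrogenic"),
             merge_class(which(is_nc), "non_chondrogenic"))
  sort(calls, ignore.strand = TRUE)
}

#' Classify tissue specificity of chondrogenic enhancers
#'
#' Chondrogenic calls from both tissues are aggregated (overlapping calls
#' merged), the EGFP+ H3K27ac coverage of each aggregated region is
#' quantified in each tissue, and the region is limb-enriched when
#' limb/trunk >= `tissue_fc`, trunk-enriched when trunk/limb >=
#' `tissue_fc`, else pan-chondrogenic. Denominators are floored at the
#' pseudocount. Per-tissue EGFP+/EGFP- fold changes are also recorded (the
#' ranking statistic of [top_k_enhancers()]).
#'
#' @param limb_calls,trunk_calls Chondrogenic calls from
#'   [call_differential()] (non-chondrogenic rows are ignored).
#' @param tracks Named list of [coverage_track()]s with elements
#'   `limb_pos`, `limb_neg`, `trunk_pos`, `trunk_neg`.
#' @param params A [calling_params()].
#' @return Aggregated `GRanges` with columns `cov_limb`, `cov_trunk`,
#'   `fc_limb`, `fc_trunk`, `tissue_class`.
#' @export
classify_tissue <- function(limb_calls, trunk_calls, tracks,
                            params = calling_params()) {
  need <- c("limb_pos", "limb_neg", "trunk_pos", "trunk_neg")
  stopifnot(all(need %in% names(tracks)))
  ch <- c(GenomicRanges::granges(limb_calls[limb_calls$activity == "chondrogenic"]),
          GenomicRanges::granges(trunk_calls[trunk_calls$activity == "chondrogenic"]))
  agg <- merge_within(ch, 0)
  if (length(agg) == 0L) {
    agg$cov_limb <- numeric(0); agg$cov_trunk <- numeric(0)
    agg$fc_limb <- numeric(0); agg$fc_trunk <- numeric(0)
    agg$tissue_class <- character(0)
    return(agg)
  }
  pc <- params$pseudocount
  limb <- quantify(agg, tracks$limb_pos)
  trunk <- quantify(agg, tracks$trunk_pos)
  limb_neg <- quantify(agg, tracks$limb_neg)
  trunk_neg <- quantify(agg, tracks$trunk_neg)
  agg$cov_limb <- limb
  agg$cov_trunk <- trunk
  agg$fc_limb <- limb / pmax(limb_neg, pc)
  agg$fc_trunk <- trunk / pmax(trunk_neg, pc)
  ratio_l <- limb / pmax(trunk, pc)
  ratio_t <- trunk / pmax(limb, pc)
  agg$tissue_class <- ifelse(ratio_l >= params$tissue_fc, "limb_enriched",
                      ifelse(ratio_t >= params$tissue_fc, "trunk_enriched",
                             "pan"))
  agg
}

#' Classify marker genes from differential-expression tables
#'
#' A gene is an EGFP+ marker in a tissue when `log2FC > 1.5` and
#' `padj < 0.05` (strict inequalities), an EGFP- marker by the mirrored
#' rule. Genes that are EGFP+ markers in at least one tissue are
#' partitioned into limb-specific, trunk-specific and shared. A gene
#' missing from one tissue's table is treated as a non-marker there and
#' flagged.
#'
#' @param de_limb,de_trunk Data frames with columns `gene`, `log2FC`,
#'   `padj` (EGFP+ vs EGFP- contrasts).
#' @param lfc_threshold,alpha Marker thresholds.
#' @return Data frame with one row per gene seen in either table: columns
#'   `gene`, `marker_limb`, `marker_trunk` (egfp_pos_marker /
#'   egfp_neg_marker / none), `chondro_class` (limb_specific /
#'   trunk_specific / shared / NA), `missing_in`.
#' @export
classify_genes <- function(de_limb, de_trunk, lfc_threshold = 1.5,
                           alpha = 0.05) {
  check_de <- function(d) {
    stopifnot(all(c("gene", "log2FC", "padj") %in% names(d)))
    d
  }
  de_limb <- check_de(de_limb); de_trunk <- check_de(de_trunk)
  genes <- union(de_limb$gene, de_trunk$gene)
  status <- function(d) {
    i <- match(genes, d$gene)
    lfc <- d$log2FC[i]; p <- d$padj[i]
    s <- rep("none", length(genes))
    s[!is.na(i) & lfc > lfc_threshold & p < alpha] <- "egfp_pos_marker"
    s[!is.na(i) & lfc < -lfc_threshold & p < alpha] <- "egfp_neg_marker"
    list(status = s, missing = is.na(i))
  }
  sl <- status(de_limb); st <- status(de_trunk)
  pos_l <- sl$status == "egfp_pos_marker"
  pos_t <- st$status == "egfp_pos_marker"
  cls <- rep(NA_character_, length(genes))
  cls[pos_l & pos_t] <- "shared"
  cls[pos_l & !pos_t] <- "limb_specific"
  cls[!pos_l & pos_t] <- "trunk_specific"
  missing_in <- ifelse(sl$missing & st$missing, "both",
                ifelse(sl$missing, "limb",
                ifelse(st$missing, "trunk", "")))
  data.frame(gene = genes, marker_limb = sl$status, marker_trunk = st$status,
             chondro_class = cls, missing_in = missing_in,
             stringsAsFactors = FALSE)
}

#' Round a share to a printed percentage
#'
#' @param n Numerator count.
#' @param total Denominator count.
#' @param digits Decimal digits of the printed value (0 for class shares,
#'   1 where one decimal is printed).
#' @return `round(100 * n / total, digits)`.
#' @export
percent_of <- function(n, total, digits = 0) {
  round(100 * n / total, digits)
}

#' Summarize the enhancer landscape
#'
#' Counts and printed-precision percentages per activity class and, among
#' chondrogenic enhancers, per tissue class.
#'
#' @param classified Output of [classify_tissue()] (chondrogenic,
#'   aggregated, with `tissue_class`).
#' @param non_chondro `GRanges` of non-chondrogenic enhancers (aggregated
#'   across tissues).
#' @param gene_classes Optional output of [classify_genes()].
#' @return A list of counts and percentages.
#' @export
summarize_landscape <- function(classified, non_chondro, gene_classes = NULL) {
  n_ch <- length(classified)
  n_nc <- length(non_chondro)
  total <- n_ch + n_nc
  tc <- table(factor(classified$tissue_class,
                     levels = c("pan", "limb_enriched", "trunk_enriched")))
  out <- list(
    n_enhancers = total,
    n_chondrogenic = n_ch,
    n_non_chondrogenic = n_nc,
    pct_chondrogenic = percent_of(n_ch, total),
    pct_non_chondrogenic = percent_of(n_nc, total),
    n_pan = unname(tc[["pan"]]),
    n_limb = unname(tc[["limb_enriched"]]),
    n_trunk = unname(tc[["trunk_enriched"]]),
    pct_pan = percent_of(tc[["pan"]], n_ch),
    pct_limb = percent_of(tc[["limb_enriched"]], n_ch),
    pct_trunk = percent_of(tc[["trunk_enriched"]], n_ch)
  )
  if (!is.null(gene_classes)) {
    gc <- gene_classes$chondro_class
    n_marker <- sum(!is.na(gc))
    out$n_chondro_genes <- n_marker
    out$n_genes_shared <- sum(gc == "shared", na.rm = TRUE)
    out$n_genes_limb <- sum(gc == "limb_specific", na.rm = TRUE)
    out$n_genes_trunk <- sum(gc == "trunk_specific", na.rm = TRUE)
    out$pct_genes_shared <- percent_of(out$n_genes_shared, n_marker)
    out$pct_genes_limb <- percent_of(out$n_genes_limb, n_marker)
    out$pct_genes_trunk <- percent_of(out$n_genes_trunk, n_marker)
  }
  out
}
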