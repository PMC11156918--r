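#' Run the full enhancer-landscape analysis on a bundle
#'
#' Orchestrates every stage over a bundle directory laid out by
#' [synth_generate()] (real data may be supplied in the same layout via
#' its `manifest.json`): per-tissue enhancer calling (ATAC consensus,
#' candidate filtering, differential H3K27ac calls), tissue
#' classification, marker-gene classification, TAD assignment and
#' categorization with the rank-sum comparison, TF-binding overlap against
#' the merged inactive control, discrete-locus overlap counting,
#' height-variance attribution over size-matched enhancer sets, and
#' (optionally) motif enrichment. Analysis stages are deterministic;
#' reruns on the same bundle produce byte-identical summary JSON.
#'
#' @param bundle_dir Directory containing `manifest.json` and the bundle
#'   files.
#' @param out_dir Output directory for per-stage tables and
#'   `landscape_summary.json`.
#' @param params A [calling_params()].
#' @param top_k Size-matching cap for the variance comparison; reduced to
#'   the smallest compared set when needed.
#' @param run_motifs Whether to run the motif stage.
#' @return Invisibly, the summary list (also written as JSON).
#' @export
run_landscape <- function(bundle_dir, out_dir, params = calling_params(),
                          top_k = 877, run_motifs = TRUE) {
  man <- jsonlite::read_json(file.path(bundle_dir, "manifest.json"))
  p <- function(f) {
    path <- file.path(bundle_dir, f)
    if (!file.exists(path)) stop("missing bundle file: ", f)
    path
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", sQuote(name), " failed: ", conditionMessage(e),
           call. = FALSE))
  }

  sizes <- stage("inputs", read_chrom_sizes(p(man$files$chrom_sizes)))
  genes <- stage("inputs", read_gene_table(p(man$files$genes), sizes))
  tracks <- stage("inputs", {
    trs <- lapply(man$files$h3k27ac_cov, function(f)
      read_bedgraph(p(f), sizes))
    names(trs) <- names(man$files$h3k27ac_cov)
    trs
  })

  ## enhancer calling per tissue -------------------------------------------
  promoters <- promoter_windows(genes, params$promoter_up,
                                params$promoter_down)
  consensus <- list()
  calls <- list()
  for (tissue in c("limb", "trunk")) {
    res <- stage(paste0("enhancers_", tissue), {
      pos <- paste0(tissue, "_pos")
      rep1 <- read_narrowpeak(p(man$files$atac[[pos]][[1]]), sizes)
      rep2 <- read_narrowpeak(p(man$files$atac[[pos]][[2]]), sizes)
      cons <- consensus_atac(rep1, rep2, params)
      k27 <- read_bed(p(man$files$h3k27ac_peaks[[tissue]]), sizes)
      cand <- candidate_regions(k27, cons, promoters)
      cov_pos <- quantify(cand, tracks[[paste0(tissue, "_pos")]])
      cov_neg <- quantify(cand, tracks[[paste0(tissue, "_neg")]])
      list(consensus = cons,
           calls = call_differential(cand, cov_pos, cov_neg, params,
                                     tissue = tissue))
    })
    consensus[[tissue]] <- res$consensus
    calls[[tissue]] <- res$calls
  }

  classified <- stage("classify_tissue",
                      classify_tissue(calls$limb, calls$trunk, tracks, params))
  non_chondro <- stage("aggregate_non_chondro", {
    nc <- c(GenomicRanges::granges(
              calls$limb[calls$limb$activity == "non_chondrogenic"]),
            GenomicRanges::granges(
              calls$trunk[calls$trunk$activity == "non_chondrogenic"]))
    agg <- merge_within(nc, 0)
    pc <- params$pseudocount
    agg$cov_limb <- quantify(agg, tracks$limb_neg)
    agg$cov_trunk <- quantify(agg, tracks$trunk_neg)
    agg$fc_limb <- agg$cov_limb / pmax(quantify(agg, tracks$limb_pos), pc)
    agg$fc_trunk <- agg$cov_trunk / pmax(quantify(agg, tracks$trunk_pos), pc)
    agg
  })

  gene_classes <- stage("classify_genes", {
    de_limb <- utils::read.table(p(man$files$de$limb), header = TRUE,
                                 sep = "\t", stringsAsFactors = FALSE)
    de_trunk <- utils::read.table(p(man$files$de$trunk), header = TRUE,
                                  sep = "\t", stringsAsFactors = FALSE)
    classify_genes(de_limb, de_trunk)
  })

  landscape <- summarize_landscape(classified, non_chondro, gene_classes)

  ## TADs --------------------------------------------------------------------
  tad_res <- stage("tads", {
    tads <- read_bed(p(man$files$tads), sizes)
    enh <- assign_to_tads(classified, tads)
    recs <- categorize_tads(tads, enh, genes, gene_classes)
    stats_tab <- per_tad_stats(recs)
    ct <- recs$n_enhancers[recs$category == "chondroTAD"]
    cet <- recs$n_enhancers[recs$category == "chondroEnhTAD"]
    rs <- if (length(ct) && length(cet)) rank_sum_test(ct, cet) else NULL
    conc <- concordance_table(recs, enh, gene_classes)
    list(records = recs, enh = enh, stats = stats_tab, rank_sum = rs,
         concordance = conc)
  })

  ## TF overlap over the inactive control ------------------------------------
  tf_res <- stage("overlaps_tf", {
    tf_peaks <- read_bed(p(man$files$tf_peaks), sizes)
    cons_all <- merge_within(c(consensus$limb, consensus$trunk), 0)
    k27_all <- merge_within(
      c(read_bed(p(man$files$h3k27ac_peaks$limb), sizes),
        read_bed(p(man$files$h3k27ac_peaks$trunk), sizes)), 0)
    inactive <- cons_all[!overlaps_any(cons_all, k27_all)]
    control <- prepare_control(inactive, 500)
    query <- classified[classified$tissue_class %in%
                          c("pan", "limb_enriched")]
    list(report = tf_overlap(query, tf_peaks, control),
         control = control)
  })

  ## discrete named loci ------------------------------------------------------
  loci_res <- if (!is.null(man$files$size_loci)) stage("overlaps_loci", {
    sl <- read_bed(p(man$files$size_loci), sizes)
    chondro_gene_set <- genes[genes$is_protein_coding &
                                genes$name %in% gene_classes$gene[
                                  !is.na(gene_classes$chondro_class)]]
    locus_overlap_counts(sl, classified, non_chondro, chondro_gene_set)
  }) else NULL

  ## height-variance attribution ----------------------------------------------
  hv <- stage("heightvar", {
    loci <- read_gws_loci(p(man$files$gws_loci), sizes)
    parts <- split_coding(loci, genes)
    in_cat <- function(cat) {
      tad_ids <- which(tad_res$records$category == cat)
      tad_res$enh[!is.na(tad_res$enh$tad) & tad_res$enh$tad %in% tad_ids]
    }
    sets_full <- list(chondroTAD = in_cat("chondroTAD"),
                      chondroEnhTAD = in_cat("chondroEnhTAD"),
                      non_chondrogenic = non_chondro)
    auto <- function(x) x[as.character(GenomeInfoDb::seqnames(x)) %in%
                            names(sizes$autosome)[sizes$autosome]]
    k <- min(top_k, min(vapply(sets_full, function(s) length(auto(s)),
                               numeric(1))))
    sets <- lapply(sets_full, top_k_enhancers, k = k, sizes = sizes)
    comp <- compare_sets(parts$non_coding, sets)
    all_curve <- cumulative_curve(loci, classified)
    nc_curve <- cumulative_curve(parts$non_coding, classified)
    list(k = k, comparison = comp, all_curve = all_curve,
         nc_curve = nc_curve,
         n_loci = length(loci), n_non_coding = length(parts$non_coding))
  })

  ## motifs --------------------------------------------------------------------
  motif_res <- if (run_motifs && !is.null(man$files$motifs))
    stage("motifs", {
      pcms <- read_pcm(p(man$files$motifs))
      targ <- Biostrings::readDNAStringSet(p(man$files$sequences$target))
      bg <- Biostrings::readDNAStringSet(p(man$files$sequences$background))
      scan_enrichment(targ, bg, pcms)
    }) else NULL

  ## outputs --------------------------------------------------------------------
  o <- function(f) file.path(out_dir, f)
  cls_bed <- classified
  cls_bed$name <- cls_bed$tissue_class
  cls_bed$score <- pmax(cls_bed$fc_limb, cls_bed$fc_trunk)
  write_bed(cls_bed, o("chondrogenic_enhancers.bed"))
  write_bed(non_chondro, o("non_chondrogenic_enhancers.bed"))
  tad_tab <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(tad_res$records)),
    start = BiocGenerics::start(tad_res$records) - 1L,
    end = BiocGenerics::end(tad_res$records),
    category = tad_res$records$category,
    n_enhancers = tad_res$records$n_enhancers,
    chondro_genes = tad_res$records$chondro_genes)
  utils::write.table(tad_tab, o("tads_categorized.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(motif_res))
    utils::write.table(motif_res, o("motif_enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  utils::write.table(hv$nc_curve$curve, o("variance_curve_noncoding.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  summary <- list(
    landscape = landscape,
    tads = list(
      stats = tad_res$stats,
      rank_sum_p = if (!is.null(tad_res$rank_sum)) tad_res$rank_sum$p else NA,
      n_assigned = sum(!is.na(tad_res$enh$tad)),
      n_unassigned = sum(is.na(tad_res$enh$tad)),
      pct_assigned = percent_of(sum(!is.na(tad_res$enh$tad)),
                                length(tad_res$enh)),
      concordance_excluded = tad_res$concordance$n_excluded
    ),
    tf_overlap = tf_res$report,
    locus_overlap = if (!is.null(loci_res)) loci_res$totals else NULL,
    heightvar = list(
      k = hv$k,
      n_loci = hv$n_loci, n_non_coding = hv$n_non_coding,
      pct_loci_overlapped = hv$all_curve$pct_loci,
      pct_variance_overlapped = round(100 * hv$all_curve$ratio, 1),
      nc_pct_loci_overlapped = hv$nc_curve$pct_loci,
      nc_pct_variance_overlapped = round(100 * hv$nc_curve$ratio, 1),
      comparison = hv$comparison
    ),
    motifs = if (!is.null(motif_res)) list(
      top_motif = motif_res$motif[1],
      planted_rank = match("planted", motif_res$motif),
      planted_log2fc = motif_res$log2_fold_change[
        motif_res$motif == "planted"]
    ) else NULL
  )
  jsonlite::write_json(summary, o("landscape_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10,
                       dataframe = "columns", na = "null")
  invisible(summary)
}
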