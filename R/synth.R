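#' Configuration of the synthetic landscape generator
#'
#' The generator emits a complete, internally consistent file bundle with
#' ground-truth labels for every pipeline stage: two tissues (limb, trunk)
#' by two sorted fractions (EGFP+, EGFP-), replicated ATAC peaks with edge
#' jitter, per-condition H3K27ac coverage with planted fold changes (both
#' above and below the calling threshold), TADs tiling each chromosome
#' with planted chondrogenic genes and enhancers, TF peaks co-located with
#' a set fraction of planted enhancers, GWS loci with heavy-tailed
#' variance weights, and sequences with planted motif occurrences.
#'
#' Class proportions default to the published landscape: pan / limb /
#' trunk chondrogenic enhancers near 74/18/8 percent, chondrogenic share
#' near 75 percent, marker genes near 84/9/7 shared/limb/trunk, chondroTAD
#' and chondroEnhTAD enhancer loads averaging 3.8 and 2.0 per TAD.
#'
#' @param seed Integer seed; the bundle is a pure function of the config.
#' @param n_autosomes,autosome_length,chrx_length Genome geometry (bp).
#' @param tad_size TAD tile size (bp).
#' @param n_pan,n_limb,n_trunk Autosomal planted chondrogenic enhancers
#'   per tissue class.
#' @param n_pan_chrx Pan-chondrogenic enhancers planted on chrX.
#' @param n_straddle Pan enhancers planted across TAD boundaries.
#' @param n_non_chondro,n_subthreshold,n_inactive Other planted region
#'   classes (sub-threshold regions carry a 2-fold change only).
#' @param n_marker_shared,n_marker_limb,n_marker_trunk EGFP+ marker genes.
#' @param n_marker_neg EGFP- marker genes.
#' @param n_background_genes,n_noncoding_genes Non-marker protein-coding
#'   genes and non-coding genes (3 non-coding genes carry marker-level
#'   differential expression to exercise the protein-coding filter).
#' @param noise_cv Coefficient of variation of multiplicative log-normal
#'   region-level coverage noise.
#' @param jitter Uniform jitter (bp) applied to replicate ATAC peak edges.
#' @param fc_high_range,fc_low_range,fc_high_share Planted fold-change
#'   mixture for differential regions.
#' @param tf_cofraction,tf_inactive_fraction Fractions of planted
#'   chondrogenic enhancers / inactive regions carrying a TF peak.
#' @param n_gws_coding,n_gws_enhancer,n_gws_empty GWS loci anchored on
#'   protein-coding genes, on planted enhancers, and on empty ground.
#' @param pareto_alpha,pareto_scale Pareto tail index and scale of the
#'   locus variance weights.
#' @param n_size_loci Large named multi-TAD loci for discrete-locus
#'   overlap counting.
#' @param n_decoys,motif_length,n_target_seqs,n_background_seqs,seq_length
#'   Motif-stage fixture sizes.
#' @param target_density,background_density Planted consensus occurrences
#'   per sequence in target and background sets (5x enrichment default).
#' @param baseline Background H3K27ac coverage level (signal units).
#' @return A `SynthConfig` list.
#' @export
synth_config <- function(seed = 42L,
                         n_autosomes = 5L, autosome_length = 1200000L,
                         chrx_length = 600000L, tad_size = 100000L,
                         n_pan = 111L, n_limb = 27L, n_trunk = 12L,
                         n_pan_chrx = 6L, n_straddle = 2L,
                         n_non_chondro = 50L, n_subthreshold = 40L,
                         n_inactive = 250L,
                         n_marker_shared = 42L, n_marker_limb = 4L,
                         n_marker_trunk = 4L, n_marker_neg = 20L,
                         n_background_genes = 150L, n_noncoding_genes = 30L,
                         noise_cv = 0.1, jitter = 50L,
                         fc_high_range = c(8, 25), fc_low_range = c(4.3, 6),
                         fc_high_share = 0.7,
                         tf_cofraction = 0.4, tf_inactive_fraction = 0.03,
                         n_gws_coding = 40L, n_gws_enhancer = 40L,
                         n_gws_empty = 40L,
                         pareto_alpha = 1.5, pareto_scale = 1e-4,
                         n_size_loci = 4L,
                         n_decoys = 20L, motif_length = 10L,
                         n_target_seqs = 60L, n_background_seqs = 60L,
                         seq_length = 500L,
                         target_density = 1.0, background_density = 0.2,
                         baseline = 0.05) {
  cfg <- as.list(environment())
  counts <- cfg[grepl("^n_", names(cfg))]
  if (any(unlist(counts) < 0)) stop("counts must be >= 0")
  if (noise_cv < 0 || jitter < 0) stop("noise_cv and jitter must be >= 0")
  stopifnot(tf_cofraction >= 0, tf_cofraction <= 1,
            tf_inactive_fraction >= 0, tf_inactive_fraction <= 1)
  structure(cfg, class = "SynthConfig")
}

# Pareto quantile sampler for locus variance weights.
rpareto <- function(n, alpha, scale) scale * stats::runif(n)^(-1 / alpha)

# Build a CoverageTrack from disjoint planted regions with flat levels
# over a constant baseline.
build_track <- function(regions, values, baseline, sizes, label) {
  cov <- list()
  sn <- as.character(GenomeInfoDb::seqnames(regions))
  for (chrom in names(sizes$lengths)) {
    len <- sizes$lengths[[chrom]]
    idx <- which(sn == chrom)
    if (!length(idx)) {
      cov[[chrom]] <- S4Vectors::Rle(baseline, len)
      next
    }
    o <- idx[order(BiocGenerics::start(regions)[idx])]
    s <- BiocGenerics::start(regions)[o]
    e <- BiocGenerics::end(regions)[o]
    v <- values[o]
    if (length(o) > 1 && any(s[-1] <= e[-length(e)]))
      stop("planted regions must be disjoint")
    run_len <- integer(0); run_val <- numeric(0)
    pos <- 1L
    for (i in seq_along(o)) {
      if (s[i] > pos) {
        run_len <- c(run_len, s[i] - pos); run_val <- c(run_val, baseline)
      }
      run_len <- c(run_len, e[i] - s[i] + 1L); run_val <- c(run_val, v[i])
      pos <- e[i] + 1L
    }
    if (pos <= len) {
      run_len <- c(run_len, len - pos + 1L); run_val <- c(run_val, baseline)
    }
    cov[[chrom]] <- S4Vectors::Rle(run_val, run_len)
  }
  coverage_track(IRanges::RleList(cov, compress = FALSE), sizes, label = label)
}

#' Generate a synthetic bundle with ground truth
#'
#' Writes the full file bundle under `out_dir` and returns the truth
#' tables. Deterministic: the same config yields a byte-identical bundle.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the truth tables (`regions`, `genes`,
#'   `loci`, `tads`), the `ChromSizes`, and the manifest.
#' @export
synth_generate <- function(config = synth_config(), out_dir) {
  stopifnot(inherits(config, "SynthConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  cfg <- config

  ## genome and TAD tiling -------------------------------------------------
  chroms <- c(paste0("chr", seq_len(cfg$n_autosomes)), "chrX")
  lens <- c(rep(cfg$autosome_length, cfg$n_autosomes), cfg$chrx_length)
  names(lens) <- chroms
  sizes <- chrom_sizes(lens)
  tad_list <- lapply(chroms, function(ch) {
    n <- lens[[ch]] %/% cfg$tad_size
    data.frame(chrom = ch, start = (seq_len(n) - 1L) * cfg$tad_size,
               end = seq_len(n) * cfg$tad_size)
  })
  tads <- do.call(rbind, tad_list)
  n_tads <- nrow(tads)
  tads$is_x <- tads$chrom == "chrX"

  ## slot bookkeeping: a 4-kb lattice inside each TAD keeps promoters,
  ## enhancers and merge windows from interacting by construction
  slot_offsets <- seq(8000L, cfg$tad_size - 8000L, by = 4000L)
  n_slots <- length(slot_offsets)
  slot_order <- lapply(seq_len(n_tads), function(i) sample(n_slots))
  slot_next <- rep(1L, n_tads)
  take_slot <- function(tad_i) {
    j <- slot_next[tad_i]
    if (j > n_slots) stop("infeasible packing: TAD ", tad_i, " is full")
    slot_next[tad_i] <<- j + 1L
    tads$start[tad_i] + slot_offsets[slot_order[[tad_i]][j]] +
      sample.int(601L, 1L) - 301L
  }
  free_tads <- function() which(slot_next <= n_slots)

  ## TAD category plan ----------------------------------------------------
  auto_tads <- which(!tads$is_x)
  x_tads <- which(tads$is_x)
  # roughly half the chondrogenic enhancers sit in gene-bearing TADs, at
  # mean loads of ~3.8 (chondroTADs) and ~2.0 (chondroEnhTADs) per TAD,
  # echoing the published per-TAD distribution; counts are built by
  # capacity-capped preferential attachment (skewed, median below mean)
  alloc_counts <- function(n_items, n_groups, cap = 10L) {
    counts <- rep(1L, n_groups)
    extra <- n_items - n_groups
    if (extra < 0) stop("infeasible packing: fewer enhancers than TAD groups")
    for (i in seq_len(extra)) {
      w <- counts * (counts < cap)
      if (all(w == 0)) stop("infeasible packing: TAD load cap exceeded")
      g <- sample.int(n_groups, 1L, prob = w)
      counts[g] <- counts[g] + 1L
    }
    counts
  }
  n_auto_chondro <- cfg$n_pan + cfg$n_limb + cfg$n_trunk
  n_ct_enh <- round(n_auto_chondro * 76 / 150)
  n_cet_enh <- n_auto_chondro - n_ct_enh
  n_ct <- max(1L, round(n_ct_enh / 3.8))
  n_cet <- max(1L, round(n_cet_enh / 2.0))
  counts_ct <- alloc_counts(n_ct_enh, n_ct)
  counts_cet <- alloc_counts(n_cet_enh, n_cet)
  need <- length(counts_ct) + length(counts_cet)
  if (need > length(auto_tads))
    stop("infeasible packing: not enough autosomal TADs for the category plan")
  picked <- sample(auto_tads, need)
  ct_tads <- picked[seq_along(counts_ct)]
  cet_tads <- picked[length(counts_ct) + seq_along(counts_cet)]
  x_enh_tads <- if (cfg$n_pan_chrx > 0) {
    utils::head(sample(x_tads), max(1L, min(2L, length(x_tads))))
  } else integer(0)

  ## planted fold changes and coverage levels ------------------------------
  draw_fc <- function(n) {
    hi <- stats::runif(n) < cfg$fc_high_share
    ifelse(hi,
           stats::runif(n, cfg$fc_high_range[1], cfg$fc_high_range[2]),
           stats::runif(n, cfg$fc_low_range[1], cfg$fc_low_range[2]))
  }

  regions <- list()
  add_region <- function(tad_i, class, width = sample(400:800, 1L)) {
    pos <- take_slot(tad_i)
    list(chrom = tads$chrom[tad_i], start = pos, end = pos + width,
         class = class, tad = tad_i)
  }

  # chondrogenic enhancers inside planned TADs
  class_pool <- sample(c(rep("pan", cfg$n_pan), rep("limb", cfg$n_limb),
                         rep("trunk", cfg$n_trunk)))
  stopifnot(length(class_pool) == sum(counts_ct) + sum(counts_cet))
  k <- 1L
  for (i in seq_along(counts_ct)) for (j in seq_len(counts_ct[i])) {
    regions[[length(regions) + 1L]] <- add_region(ct_tads[i], class_pool[k])
    k <- k + 1L
  }
  for (i in seq_along(counts_cet)) for (j in seq_len(counts_cet[i])) {
    regions[[length(regions) + 1L]] <- add_region(cet_tads[i], class_pool[k])
    k <- k + 1L
  }
  # chrX pan enhancers
  if (cfg$n_pan_chrx > 0) {
    xt <- rep(x_enh_tads, length.out = cfg$n_pan_chrx)
    for (i in seq_len(cfg$n_pan_chrx))
      regions[[length(regions) + 1L]] <- add_region(xt[i], "pan")
  }
  # boundary-straddling pan enhancers (internal boundaries, autosomes)
  if (cfg$n_straddle > 0) {
    for (i in seq_len(cfg$n_straddle)) {
      ch <- chroms[i]
      b <- (lens[[ch]] %/% cfg$tad_size %/% 2L) * cfg$tad_size
      regions[[length(regions) + 1L]] <-
        list(chrom = ch, start = b - 300L, end = b + 300L,
             class = "pan", tad = NA_integer_)
    }
  }
  ## genes (placed before filler regions so marker genes always fit in
  ## their planned chondroTADs) ---------------------------------------------
  gene_specs <- c(rep("shared", cfg$n_marker_shared),
                  rep("limb_specific", cfg$n_marker_limb),
                  rep("trunk_specific", cfg$n_marker_trunk),
                  rep("neg", cfg$n_marker_neg),
                  rep("none", cfg$n_background_genes),
                  rep("noncoding", cfg$n_noncoding_genes))
  n_gene <- length(gene_specs)
  marker_idx <- which(gene_specs %in% c("shared", "limb_specific",
                                        "trunk_specific"))
  genes <- vector("list", n_gene)
  # each chondroTAD gets at least one marker gene; the rest spread out
  marker_tads <- c(ct_tads,
                   if (length(marker_idx) > length(ct_tads))
                     sample(ct_tads, length(marker_idx) - length(ct_tads),
                            replace = TRUE) else integer(0))
  place_gene <- function(tad_i, name, biotype, spec) {
    pos <- take_slot(tad_i)
    len <- sample(800:1200, 1L)
    list(chrom = tads$chrom[tad_i], start = pos, end = pos + len,
         strand = sample(c("+", "-"), 1L), name = name, biotype = biotype,
         spec = spec, tad = tad_i)
  }
  for (i in seq_along(marker_idx)) {
    genes[[marker_idx[i]]] <- place_gene(marker_tads[i],
                                         sprintf("G%04d", marker_idx[i]),
                                         "protein_coding",
                                         gene_specs[marker_idx[i]])
  }
  other_idx <- setdiff(seq_len(n_gene), marker_idx)
  nc_marker <- utils::tail(which(gene_specs == "noncoding"), 3L)
  for (i in other_idx) {
    spec <- gene_specs[i]
    tad_i <- if (i %in% nc_marker && length(cet_tads)) {
      # non-coding genes with marker-level expression go to chondroEnhTADs:
      # they must not promote those TADs (protein-coding filter)
      cet_free <- intersect(cet_tads, free_tads())
      if (length(cet_free)) cet_free[sample.int(length(cet_free), 1L)]
      else free_tads()[sample.int(length(free_tads()), 1L)]
    } else {
      ft <- free_tads()
      ft[sample.int(length(ft), 1L, prob = n_slots - slot_next[ft] + 1L)]
    }
    genes[[i]] <- place_gene(tad_i, sprintf("G%04d", i),
                             if (spec == "noncoding") "lincRNA"
                             else "protein_coding",
                             if (i %in% nc_marker) "shared" else spec)
  }
  gene_tab <- do.call(rbind, lapply(genes, as.data.frame))
  gene_tab$is_noncoding <- gene_tab$biotype != "protein_coding"

  # filler classes distributed over TADs with free slots
  fillers <- c(rep("non_chondro", cfg$n_non_chondro),
               rep("subthreshold", cfg$n_subthreshold),
               rep("inactive", cfg$n_inactive))
  for (cl in fillers) {
    ft <- free_tads()
    if (!length(ft)) stop("infeasible packing: no free slots left")
    w <- (n_slots - slot_next[ft] + 1L)
    tad_i <- ft[sample.int(length(ft), 1L, prob = w)]
    regions[[length(regions) + 1L]] <- add_region(tad_i, cl)
  }

  reg <- do.call(rbind, lapply(regions, as.data.frame))
  reg$id <- sprintf("R%04d", seq_len(nrow(reg)))
  reg$chondro <- reg$class %in% c("pan", "limb", "trunk")

  # per-region coverage levels per condition
  n_reg <- nrow(reg)
  L <- stats::runif(n_reg, 1, 4)
  fc <- draw_fc(n_reg)
  ratio <- stats::runif(n_reg, 2.2, 4)      # tissue enrichment when enriched
  pan_ratio <- stats::runif(n_reg, 0.8, 1.25)
  bl <- cfg$baseline
  lv <- matrix(bl, n_reg, 4,
               dimnames = list(NULL, c("limb_pos", "limb_neg",
                                       "trunk_pos", "trunk_neg")))
  for (i in seq_len(n_reg)) {
    cl <- reg$class[i]
    if (cl == "pan") {
      lv[i, ] <- c(L[i], L[i] / fc[i],
                   L[i] * pan_ratio[i], L[i] * pan_ratio[i] / fc[i])
    } else if (cl == "limb") {
      lv[i, ] <- c(L[i], L[i] / fc[i],
                   L[i] / ratio[i], L[i] / ratio[i] / fc[i])
    } else if (cl == "trunk") {
      lv[i, ] <- c(L[i] / ratio[i], L[i] / ratio[i] / fc[i],
                   L[i], L[i] / fc[i])
    } else if (cl == "non_chondro") {
      lv[i, ] <- c(L[i] / fc[i], L[i], L[i] / fc[i], L[i])
    } else if (cl == "subthreshold") {
      p <- stats::runif(1, 0.8, 1.5)
      lv[i, ] <- c(p, p / 2, p, p / 2)
    }                                        # inactive: baseline everywhere
  }
  reg$fc_limb <- ifelse(reg$class %in% c("pan", "limb", "trunk"),
                        lv[, "limb_pos"] / lv[, "limb_neg"],
                        ifelse(reg$class == "subthreshold", 2, NA))
  reg$fc_trunk <- ifelse(reg$class %in% c("pan", "limb", "trunk"),
                         lv[, "trunk_pos"] / lv[, "trunk_neg"],
                         ifelse(reg$class == "subthreshold", 2, NA))
  reg$fc_max <- pmax(reg$fc_limb, reg$fc_trunk)
  reg$on_autosome <- reg$chrom != "chrX"
  reg$straddles <- is.na(reg$tad)

  # multiplicative log-normal noise, region x condition
  sdlog <- sqrt(log(1 + cfg$noise_cv^2))
  noise <- if (cfg$noise_cv > 0) {
    matrix(stats::rlnorm(n_reg * 4, meanlog = -sdlog^2 / 2, sdlog = sdlog),
           n_reg, 4)
  } else matrix(1, n_reg, 4)
  lv_obs <- lv * noise
  lv_obs[reg$class == "inactive", ] <- bl   # inactive stays at baseline

  ## DE tables ---------------------------------------------------------------
  de_val <- function(kind) {
    switch(kind,
           pos = c(stats::runif(1, 1.8, 4), 0.001),
           neg = c(-stats::runif(1, 1.8, 4), 0.001),
           none = c(stats::runif(1, -1.2, 1.2), 0.5))
  }
  de_rows <- function(tissue) {
    rows <- lapply(seq_len(n_gene), function(i) {
      spec <- gene_tab$spec[i]
      kind <- if (spec == "shared") "pos"
        else if (spec == "limb_specific") ifelse(tissue == "limb", "pos", "none")
        else if (spec == "trunk_specific") ifelse(tissue == "trunk", "pos", "none")
        else if (spec == "neg") "neg"
        else "none"
      v <- de_val(kind)
      data.frame(gene = gene_tab$name[i], log2FC = v[1], padj = v[2])
    })
    do.call(rbind, rows)
  }
  de_limb <- de_rows("limb")
  de_trunk <- de_rows("trunk")
  # two background genes are absent from the trunk table (missing-gene path)
  drop2 <- utils::head(gene_tab$name[gene_tab$spec == "none" &
                                       !gene_tab$is_noncoding], 2L)
  de_trunk <- de_trunk[!de_trunk$gene %in% drop2, ]

  ## TF peaks ----------------------------------------------------------------
  ch_idx <- which(reg$chondro)
  n_tf <- round(cfg$tf_cofraction * length(ch_idx))
  tf_on <- sample(ch_idx, n_tf)
  in_idx <- which(reg$class == "inactive")
  n_tf_in <- round(cfg$tf_inactive_fraction * length(in_idx))
  tf_in <- if (n_tf_in > 0) sample(in_idx, n_tf_in) else integer(0)
  reg$has_tf <- seq_len(n_reg) %in% c(tf_on, tf_in)
  tf_idx <- sort(c(tf_on, tf_in))
  mid <- (reg$start + reg$end) %/% 2L
  tf_tab <- data.frame(chrom = reg$chrom[tf_idx], start = mid[tf_idx] - 100L,
                       end = mid[tf_idx] + 100L,
                       name = sprintf("TF%03d", seq_along(tf_idx)))

  ## GWS loci ----------------------------------------------------------------
  pc_gene_rows <- which(!gene_tab$is_noncoding)
  gws <- list()
  anchors_g <- sample(pc_gene_rows, min(cfg$n_gws_coding, length(pc_gene_rows)))
  for (i in anchors_g)
    gws[[length(gws) + 1L]] <- data.frame(
      chrom = gene_tab$chrom[i], start = gene_tab$start[i] - 1000L,
      end = gene_tab$end[i] + 1000L, coding = TRUE, overlaps_chondro = FALSE)
  anchors_e <- sample(which(reg$chondro & !reg$straddles),
                      min(cfg$n_gws_enhancer, sum(reg$chondro & !reg$straddles)))
  for (i in anchors_e)
    gws[[length(gws) + 1L]] <- data.frame(
      chrom = reg$chrom[i], start = reg$start[i] - 1000L,
      end = reg$end[i] + 1000L, coding = FALSE, overlaps_chondro = TRUE)
  empty_tads <- sample(seq_len(n_tads), min(cfg$n_gws_empty, n_tads))
  for (i in empty_tads)
    gws[[length(gws) + 1L]] <- data.frame(
      chrom = tads$chrom[i], start = tads$start[i] + 1000L,
      end = tads$start[i] + 3000L, coding = FALSE, overlaps_chondro = FALSE)
  gws <- do.call(rbind, gws)
  gws$variance_explained <- rpareto(nrow(gws), cfg$pareto_alpha,
                                    cfg$pareto_scale)
  gws$id <- sprintf("GWS%03d", seq_len(nrow(gws)))

  ## named multi-TAD size loci (two consecutive TADs each) -------------------
  size_loci <- NULL
  if (cfg$n_size_loci > 0) {
    sl_chroms <- rep(chroms[seq_len(cfg$n_autosomes)],
                     length.out = cfg$n_size_loci)
    size_loci <- do.call(rbind, lapply(seq_len(cfg$n_size_loci), function(i) {
      ch <- sl_chroms[i]
      tads_ch <- which(tads$chrom == ch)
      first <- tads_ch[sample.int(length(tads_ch) - 1L, 1L)]
      data.frame(chrom = ch, start = tads$start[first],
                 end = tads$end[first + 1L], name = sprintf("L%d", i))
    }))
  }

  ## write the bundle ---------------------------------------------------------
  paths <- list()
  p <- function(f) file.path(out_dir, f)
  write_chrom_sizes(sizes, p("chrom_sizes.tsv"))
  paths$chrom_sizes <- "chrom_sizes.tsv"

  utils::write.table(
    data.frame(chrom = tads$chrom, start = tads$start, end = tads$end),
    p("tads.bed"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  paths$tads <- "tads.bed"

  # ATAC narrowPeak, two jittered replicates per condition
  conds <- c("limb_pos", "limb_neg", "trunk_pos", "trunk_neg")
  paths$atac <- list()
  for (cond in conds) {
    paths$atac[[cond]] <- character(2)
    for (rep_i in 1:2) {
      j1 <- if (cfg$jitter > 0)
        sample.int(2L * cfg$jitter + 1L, n_reg, replace = TRUE) -
          cfg$jitter - 1L else rep(0L, n_reg)
      j2 <- if (cfg$jitter > 0)
        sample.int(2L * cfg$jitter + 1L, n_reg, replace = TRUE) -
          cfg$jitter - 1L else rep(0L, n_reg)
      s <- pmax(reg$start + j1, 0L)
      e <- pmin(reg$end + j2, lens[reg$chrom])
      tab <- data.frame(chrom = reg$chrom, start = s, end = e,
                        name = reg$id, score = 0L, strand = ".",
                        signalValue = sprintf("%.6g", lv_obs[, 1] + 1),
                        pValue = -1, qValue = -1,
                        peak = (e - s) %/% 2L)
      f <- sprintf("atac_%s_rep%d.narrowPeak", cond, rep_i)
      utils::write.table(tab, p(f), sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      paths$atac[[cond]][rep_i] <- f
    }
  }

  # H3K27ac peak files (candidate universe) per tissue: every planted
  # region active in either fraction of that tissue
  active <- reg$class %in% c("pan", "limb", "trunk", "non_chondro",
                             "subthreshold")
  paths$h3k27ac_peaks <- list()
  for (tissue in c("limb", "trunk")) {
    tab <- data.frame(chrom = reg$chrom[active], start = reg$start[active],
                      end = reg$end[active], name = reg$id[active],
                      score = 0L, strand = ".")
    f <- sprintf("h3k27ac_%s_peaks.bed", tissue)
    utils::write.table(tab, p(f), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths$h3k27ac_peaks[[tissue]] <- f
  }

  # H3K27ac coverage per condition
  reg_gr <- gi(reg$chrom, reg$start, reg$end, sizes = sizes)
  paths$h3k27ac_cov <- list()
  for (ci in seq_along(conds)) {
    tr <- build_track(reg_gr, lv_obs[, ci], bl, sizes,
                      label = paste0(conds[ci], "_H3K27ac"))
    f <- sprintf("h3k27ac_%s.bedGraph", conds[ci])
    write_bedgraph(tr, p(f))
    paths$h3k27ac_cov[[conds[ci]]] <- f
  }

  # genes and DE tables
  gg <- gi(gene_tab$chrom, gene_tab$start, gene_tab$end,
           strand = gene_tab$strand, sizes = sizes)
  gg$name <- gene_tab$name; gg$biotype <- gene_tab$biotype
  write_gene_table(gg, p("genes.tsv"))
  paths$genes <- "genes.tsv"
  fmt_de <- function(d) data.frame(gene = d$gene,
                                   log2FC = sprintf("%.6g", d$log2FC),
                                   padj = sprintf("%.6g", d$padj))
  utils::write.table(fmt_de(de_limb), p("de_limb.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fmt_de(de_trunk), p("de_trunk.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths$de <- list(limb = "de_limb.tsv", trunk = "de_trunk.tsv")

  utils::write.table(tf_tab, p("tf_peaks.bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  paths$tf_peaks <- "tf_peaks.bed"

  utils::write.table(
    data.frame(chrom = gws$chrom, start = gws$start, end = gws$end,
               variance_explained = sprintf("%.6g", gws$variance_explained)),
    p("gws_loci.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  paths$gws_loci <- "gws_loci.tsv"

  if (!is.null(size_loci)) {
    utils::write.table(size_loci[, c("chrom", "start", "end", "name")],
                       p("size_loci.bed"), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths$size_loci <- "size_loci.bed"
  }

  ## motif fixture ------------------------------------------------------------
  bases <- c("A", "C", "G", "T")
  consensus <- paste(sample(bases, cfg$motif_length, replace = TRUE),
                     collapse = "")
  true_pcm <- vapply(strsplit(consensus, "")[[1]], function(b) {
    counts <- rep(5, 4); counts[match(b, bases)] <- 85; counts
  }, numeric(4))
  rownames(true_pcm) <- bases
  pcms <- list(planted = true_pcm)
  for (d in seq_len(cfg$n_decoys)) {
    m <- vapply(seq_len(cfg$motif_length), function(j) {
      as.numeric(stats::rmultinom(1, 100, prob = stats::runif(4, 0.1, 1)))
    }, numeric(4))
    rownames(m) <- bases
    pcms[[sprintf("decoy_%02d", d)]] <- m
  }
  write_pcm(pcms, p("motifs.pcm"))
  paths$motifs <- "motifs.pcm"

  make_seqs <- function(n, density, prefix) {
    vapply(seq_len(n), function(i) {
      s <- sample(bases, cfg$seq_length, replace = TRUE)
      n_occ <- stats::rpois(1, density)
      if (n_occ > 0) {
        starts <- sample.int(cfg$seq_length - cfg$motif_length + 1L, n_occ)
        for (st in starts)
          s[st:(st + cfg$motif_length - 1L)] <- strsplit(consensus, "")[[1]]
      }
      paste(s, collapse = "")
    }, character(1))
  }
  tseq <- make_seqs(cfg$n_target_seqs, cfg$target_density, "enh")
  bseq <- make_seqs(cfg$n_background_seqs, cfg$background_density, "inact")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(
      tseq, sprintf("enh_%03d", seq_along(tseq)))),
    p("target_sequences.fa"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(
      bseq, sprintf("inactive_%03d", seq_along(bseq)))),
    p("inactive_sequences.fa"))
  paths$sequences <- list(target = "target_sequences.fa",
                          background = "inactive_sequences.fa")

  ## truth tables --------------------------------------------------------------
  truth_regions <- cbind(reg[, c("id", "chrom", "start", "end", "class",
                                 "chondro", "fc_limb", "fc_trunk", "fc_max",
                                 "tad", "has_tf", "straddles",
                                 "on_autosome")],
                         as.data.frame(lv))
  utils::write.table(truth_regions, p("truth_regions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth_genes <- gene_tab[, c("name", "chrom", "start", "end", "strand",
                              "biotype", "spec", "tad")]
  utils::write.table(truth_genes, p("truth_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth_loci <- gws[, c("id", "chrom", "start", "end", "coding",
                        "overlaps_chondro", "variance_explained")]
  utils::write.table(truth_loci, p("truth_loci.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tad_cat <- rep("other", n_tads)
  tad_cat[ct_tads] <- "chondroTAD"
  tad_cat[cet_tads] <- "chondroEnhTAD"
  tad_cat[x_enh_tads] <- "chondroEnhTAD"
  truth_tads <- data.frame(tad = seq_len(n_tads), chrom = tads$chrom,
                           start = tads$start, end = tads$end,
                           category = tad_cat)
  utils::write.table(truth_tads, p("truth_tads.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths$truth <- list(regions = "truth_regions.tsv",
                      genes = "truth_genes.tsv",
                      loci = "truth_loci.tsv", tads = "truth_tads.tsv")

  manifest <- list(seed = cfg$seed, planted_motif = consensus,
                   files = paths)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(regions = truth_regions, genes = truth_genes,
                 loci = truth_loci, tads = truth_tads, sizes = sizes,
                 manifest = manifest, dir = out_dir))
}

#' Consistency checks on a generated bundle
#'
#' Parses every file of the bundle and verifies the structural invariants:
#' coverage files parse with no overlapping intervals, planted truth
#' coordinates lie on their chromosomes, planted regions are disjoint, and
#' sequences parse. Violations are collected, not thrown.
#'
#' @param dir Bundle directory (containing `manifest.json`).
#' @return Data frame of violations (zero rows when the bundle is
#'   consistent).
#' @export
validate_bundle <- function(dir) {
  viol <- list()
  note <- function(what, msg)
    viol[[length(viol) + 1L]] <<- data.frame(check = what, message = msg)
  man <- tryCatch(jsonlite::read_json(file.path(dir, "manifest.json")),
                  error = function(e) {
                    note("manifest", conditionMessage(e)); NULL
                  })
  if (is.null(man))
    return(do.call(rbind, viol))
  p <- function(f) file.path(dir, f)
  sizes <- tryCatch(read_chrom_sizes(p(man$files$chrom_sizes)),
                    error = function(e) {
                      note("chrom_sizes", conditionMessage(e)); NULL
                    })
  if (is.null(sizes)) return(do.call(rbind, viol))
  for (f in unlist(man$files$h3k27ac_cov)) {
    tryCatch(read_bedgraph(p(f), sizes),
             error = function(e) note(f, conditionMessage(e)))
  }
  tr <- tryCatch(utils::read.table(p(man$files$truth$regions), header = TRUE,
                                   sep = "\t"),
                 error = function(e) {
                   note("truth_regions", conditionMessage(e)); NULL
                 })
  if (!is.null(tr)) {
    bad <- tr$end > sizes$lengths[tr$chrom] | tr$start < 0
    if (any(bad)) note("truth_regions",
                       paste(sum(bad), "regions off chromosome"))
    gr <- gi(tr$chrom, tr$start, tr$end)
    if (!IRanges::isDisjoint(gr))
      note("truth_regions", "planted regions overlap")
  }
  for (f in unlist(man$files$sequences)) {
    tryCatch(Biostrings::readDNAStringSet(p(f)),
             error = function(e) note(f, conditionMessage(e)))
  }
  out <- if (length(viol)) do.call(rbind, viol)
    else data.frame(check = character(0), message = character(0))
  out
}
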