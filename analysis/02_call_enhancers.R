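#!/usr/bin/env Rscript
# Call chondrogenic / non-chondrogenic enhancers per tissue from the
# bundle (ATAC consensus -> candidate regions -> differential H3K27ac)
# and classify tissue specificity; classify marker genes from the
# differential-expression tables. This is the core of the landscape.
#
# Reads results/bundle, writes enhancer BED/TSV under results/landscape.

suppressPackageStartupMessages(library(chondromap))

s <- run_landscape("results/bundle", "results/landscape")

L <- s$landscape
cat(sprintf("Differential calls: %d (%d chondrogenic = %d%%, %d non-chondrogenic)\n",
            L$n_enhancers, L$n_chondrogenic, L$pct_chondrogenic,
            L$n_non_chondrogenic))
cat(sprintf("Tissue classes: pan %d (%d%%), limb %d (%d%%), trunk %d (%d%%)\n",
            L$n_pan, L$pct_pan, L$n_limb, L$pct_limb, L$n_trunk,
            L$pct_trunk))
cat(sprintf("Marker genes: %d (%d%% shared, %d%% limb, %d%% trunk)\n",
            L$n_chondro_genes, L$pct_genes_shared, L$pct_genes_limb,
            L$pct_genes_trunk))
cat("Per-stage outputs and landscape_summary.json in results/landscape\n")
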