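#!/usr/bin/env Rscript
# Height-variance attribution: cumulative variance of GWS loci explained
# by overlapping enhancers, compared across size-matched enhancer sets
# (chondroTAD, chondroEnhTAD, non-chondrogenic).

suppressPackageStartupMessages(library(chondromap))

summary <- jsonlite::read_json("results/landscape/landscape_summary.json",
                               simplifyVector = TRUE)
hv <- summary$heightvar

cat(sprintf("GWS loci: %d total, %d non-coding\n", hv$n_loci,
            hv$n_non_coding))
cat(sprintf("All loci: %.1f%% overlapped, %.1f%% of variance attributable\n",
            hv$pct_loci_overlapped, hv$pct_variance_overlapped))
cat(sprintf("Non-coding loci: %.1f%% overlapped, %.1f%% of variance attributable\n",
            hv$nc_pct_loci_overlapped, hv$nc_pct_variance_overlapped))
comparison <- as.data.frame(hv$comparison)
cat(sprintf("Size-matched comparison (k = %d per set):\n", hv$k))
print(comparison)

write.table(comparison, "results/variance_comparison.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Comparison table written to results/variance_comparison.tsv;",
    "full curve in results/landscape/variance_curve_noncoding.tsv\n")
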