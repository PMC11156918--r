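#!/usr/bin/env Rscript
# TF-binding overlap of chondrogenic enhancers versus the merged inactive
# control, and enhancer content of the large named size-associated loci.

suppressPackageStartupMessages(library(chondromap))

summary <- jsonlite::read_json("results/landscape/landscape_summary.json",
                               simplifyVector = TRUE)

tf <- summary$tf_overlap
cat(sprintf("TF overlap: %d of %d enhancers (%d%%) vs %d of %d inactive controls (%.1f%%)\n",
            tf$n_overlapping, tf$n_query, tf$fraction,
            tf$control_overlapping, tf$control_n, tf$control_fraction))

lo <- summary$locus_overlap
cat(sprintf("Size loci: %d chondrogenic enhancers (%.1f%% of all), %d non-chondrogenic (%.1f%%), %d chondrogenic genes\n",
            lo$n_chondro, lo$pct_chondro, lo$n_non_chondro,
            lo$pct_non_chondro, lo$n_genes))

write.table(data.frame(measure = c("tf_pct", "tf_control_pct",
                                   "loci_pct_chondro",
                                   "loci_pct_non_chondro"),
                       value = c(tf$fraction, tf$control_fraction,
                                 lo$pct_chondro, lo$pct_non_chondro)),
            "results/overlap_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Overlap summary written to results/overlap_summary.tsv\n")
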