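#!/usr/bin/env Rscript
# Summarize the TAD view of the landscape produced by 02_call_enhancers.R:
# chondroTADs (enhancers + chondrogenic genes) versus chondroEnhTADs
# (enhancers only), their per-TAD enhancer loads and the rank-sum
# comparison, plus the gene-class/enhancer-content concordance.

suppressPackageStartupMessages(library(chondromap))

summary <- jsonlite::read_json("results/landscape/landscape_summary.json",
                               simplifyVector = TRUE)
tads <- read.table("results/landscape/tads_categorized.tsv", header = TRUE,
                   sep = "\t")

st <- as.data.frame(summary$tads$stats)
cat("TAD categories:\n")
print(st)
cat(sprintf("Assigned enhancers: %d (%d%%); unassigned (boundary/gap): %d\n",
            summary$tads$n_assigned, summary$tads$pct_assigned,
            summary$tads$n_unassigned))
cat(sprintf("chondroTAD vs chondroEnhTAD enhancer load: %.1f vs %.1f per TAD, rank-sum p = %.3g\n",
            st$mean_enhancers[st$category == "chondroTAD"],
            st$mean_enhancers[st$category == "chondroEnhTAD"],
            summary$tads$rank_sum_p))

counts <- table(tads$category)
write.table(as.data.frame(counts), "results/tad_category_counts.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Category counts written to results/tad_category_counts.tsv\n")
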