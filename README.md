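# chondromap

Differential-activity enhancer calling and downstream landscape analysis
for sorted chondrocyte populations.

Chondrocytes build the fetal cartilage that becomes bone, and the distal
enhancers active in them are a mechanistic route from non-coding genetic
variation to skeletal phenotypes such as adult height. Profiling a whole
embryonic limb or trunk mixes chondrocytes with many other cell types, so
chondrocyte-specific enhancers have to be called from *sorted* fractions:
a reporter-positive (EGFP+, chondrocyte) and a reporter-negative (EGFP-)
population per tissue. `chondromap` implements that analysis for
researchers in regulatory genomics: it starts from per-replicate ATAC-seq
peaks, H3K27ac peak sets and normalized coverage tracks, and produces a
classified enhancer landscape plus the analyses that interpret it —
TAD-level categorization, transcription-factor binding overlap, and
cumulative height-variance attribution.

## The calling rule

For each tissue, with EGFP+ ATAC replicate peak sets $A_1, A_2$, EGFP+
H3K27ac peaks $K$, and mean normalized H3K27ac coverage $c^+(r)$,
$c^-(r)$ of a region $r$ in the two fractions:

1. **Consensus accessibility**: peaks of $A_1 \cup A_2$ that overlap the
   other replicate (≥ 1 bp), merged, extended ±150 bp.
2. **Candidates**: $r \in K$ overlapping the consensus and no promoter
   window (TSS −2 kb/+500 b, strand-aware, protein-coding genes).
3. **Differential call**: $r$ is *chondrogenic* iff

   $$c^+(r) \ge 0.5 \quad\text{and}\quad \frac{c^+(r)}{c^-(r)} \ge 4,$$

   *non-chondrogenic* by the mirrored rule; calls of each class are then
   merged within 500 bp.
4. **Tissue class**: chondrogenic calls from limb and trunk are
   aggregated; a region is limb- or trunk-enriched iff the
   between-tissue EGFP+ coverage ratio is ≥ 2, otherwise
   *pan*-chondrogenic.

Downstream, TADs holding ≥ 1 chondrogenic enhancer are *chondroTADs*
(also ≥ 1 protein-coding chondrogenic marker gene) or *chondroEnhTADs*
(no such gene); per-TAD enhancer loads are compared with a two-tailed
Wilcoxon rank-sum test (exact under ties for small samples). GWS height
loci, walked from highest to lowest variance explained, accumulate
variance into the curve $y(x) \le x$ whenever an enhancer of a
size-matched set (top-$k$ autosomal calls by max EGFP+/EGFP- fold
change) overlaps the locus.

A deterministic synthetic-data generator (`synth_config()` /
`synth_generate()`) emits a complete bundle — jittered replicate ATAC
peaks, H3K27ac coverage with planted fold changes above and below
threshold, TADs with planted marker genes, TF peaks on a set fraction of
enhancers, Pareto-weighted GWS loci, motif sequences — together with
ground-truth tables, so every stage is testable end to end.

## Worked example

The `analysis/` directory holds numbered drivers that run the whole
study on the synthetic landscape (seed 42):

```sh
Rscript analysis/01_simulate.R         # generate results/bundle
Rscript analysis/02_call_enhancers.R   # call + classify the landscape
Rscript analysis/03_tad_categories.R
Rscript analysis/04_tf_and_loci_overlap.R
Rscript analysis/05_height_variance.R
Rscript analysis/06_motif_enrichment.R
```

`02_call_enhancers.R` prints:

```
Differential calls: 208 (158 chondrogenic = 76%, 50 non-chondrogenic)
Tissue classes: pan 121 (77%), limb 25 (16%), trunk 12 (8%)
Marker genes: 53 (85% shared, 8% limb, 8% trunk)
```

i.e. of 208 differential calls, 76% are chondrogenic (stronger H3K27ac
in the sorted chondrocytes), and three quarters of those are active in
both tissues — the planted shares, recovered through the full calling
chain under coverage noise. `03_tad_categories.R` then reports the TAD
view:

```
       category n_tads n_enhancers mean_enhancers median_enhancers
1    chondroTAD     20          76            3.8              3.5
2 chondroEnhTAD     39          80            2.1              1.0
3         other      7           0            0.0              0.0
Assigned enhancers: 156 (99%); unassigned (boundary/gap): 2
```

gene-bearing chondroTADs carry about twice the enhancer load of
chondroEnhTADs (rank-sum p = 6.1e-4 on this small landscape), and
`04`/`05` report 40% TF-peak overlap of chondrogenic enhancers versus
3.2% of inactive controls, and the variance-attribution comparison in
which chondrogenic enhancer sets explain height variance while the
size-matched non-chondrogenic set explains none.

Equivalent programmatic entry point:

```r
library(chondromap)
truth <- synth_generate(synth_config(seed = 42), "results/bundle")
summary <- run_landscape("results/bundle", "results/landscape")
summary$landscape$pct_pan
#> [1] 77
```

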