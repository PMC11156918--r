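---
title: "Mapping a chondrogenic enhancer landscape: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a chondrogenic enhancer landscape: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chondromap)
```

## The problem

Chondrocytes — the cells that build fetal cartilage and, through the
growth plate, determine bone length and stature — rely on distal
enhancers to drive their gene programs. Bulk chromatin profiles of a
developing limb or trunk mix chondrocytes with muscle, dermis, tendon and
other lineages, so cell-type-specific enhancers are invisible without
sorting. The analysis implemented here starts *after* sorting and peak
calling: given ATAC-seq peaks and normalized H3K27ac coverage for
reporter-positive (chondrocyte, "EGFP+") and reporter-negative ("EGFP-")
fractions of two tissues (limb and trunk), it reconstructs the
chondrogenic enhancer landscape and asks what that landscape explains —
which TADs concentrate chondrogenic regulation, how often a chondrogenic
transcription factor binds these elements, and how much human height
variance the orthologous loci account for.

`chondromap` packages every step as a tested function, and ships a
synthetic-data generator that emits a complete, internally consistent
bundle with ground-truth labels, so the whole pipeline runs and is
validated without any sequencing data.

## Enhancer calling

The calling rule, applied per tissue:

1. **Reproducible accessibility.** EGFP+ ATAC peaks present in both
   replicates (reciprocal ≥ 1 bp overlap; the merged union of
   reproducible peaks is kept so the result is symmetric under replicate
   relabeling), extended by 150 bp per side (`atac_flank`).
2. **Candidate regions.** EGFP+ H3K27ac peaks overlapping the ATAC
   consensus and overlapping no promoter window. Promoter windows span
   2 kb upstream to 500 b downstream of each protein-coding TSS,
   strand-aware; exclusion is by any overlap, the stricter of the
   plausible readings.
3. **Differential activity.** Mean normalized H3K27ac coverage is
   quantified per candidate in both fractions. A candidate is
   *chondrogenic* when EGFP+ coverage ≥ 0.5 (`min_pos_cov`) **and**
   EGFP+/EGFP- ≥ 4 (`fc_threshold`); *non-chondrogenic* by the mirrored
   rule on the same candidate universe. Both thresholds are inclusive.
   Ratio denominators are floored at a pseudocount (0.01 signal units);
   the absolute-coverage floor is what actually guards near-zero
   denominators, so the pseudocount choice is immaterial in practice.
4. **Merging.** Surviving calls of each class are merged within 500 bp,
   separately per class. A merged call carries the per-fraction *maximum*
   coverage of its members and a fold change recomputed from those —
   deterministic and independent of member order.
5. **Tissue specificity.** Chondrogenic calls from both tissues are
   aggregated (overlap-merged); a region is limb- or trunk-enriched when
   the between-tissue EGFP+ coverage ratio is ≥ 2 (`tissue_fc`), else
   pan-chondrogenic.

Marker genes come from per-tissue differential-expression tables:
a gene is an EGFP+ marker when log2FC > 1.5 and BH-adjusted p < 0.05
(strict inequalities, matching how the thresholds are stated), and
markers partition into limb-specific, trunk-specific and shared.

## TADs, TF overlap, height variance, motifs

**TAD categorization.** An enhancer is *unambiguously assigned* when it
overlaps exactly one TAD; boundary-straddlers and gap dwellers are
reported unassigned. A *chondroTAD* holds ≥ 1 chondrogenic enhancer and
≥ 1 protein-coding chondrogenic gene (gene bodies attach by any overlap);
a *chondroEnhTAD* holds enhancers but no such gene. Per-TAD enhancer
loads are compared with a two-tailed Wilcoxon rank-sum test: exact by
enumeration of the permutation distribution (a subset-count dynamic
programme, valid under ties) when the smaller sample has ≤ 8
observations, otherwise a tie-corrected normal approximation with
continuity correction. `stats::wilcox.test` is used in the test suite as
an independent cross-check, not as the implementation, because it
refuses exact p-values under ties.

**TF overlap.** Any-overlap counting of enhancers against pre-merged TF
ChIP peaks, with accessible-but-inactive regions (merged within 500 bp)
as the control universe. Fractions are reported at printed precision:
integer percent for the query, one decimal for the control.

**Height variance.** GWS loci (non-overlapping genomic segments with a
known fraction of height variance) are split into coding and non-coding
by protein-coding gene overlap. Enhancer sets are size-matched by
keeping autosomal calls ranked by the maximum over tissues of the
EGFP+/EGFP- fold change — the ranking statistic is a genuine design
choice, since "highest differential coverage" and "maximum enrichment"
diverge; fold change is the default and an absolute coverage-difference
metric is available behind `metric = "coverage_diff"`. Walking loci from
highest to lowest variance, the x coordinate accumulates every locus's
variance and y accumulates it iff ≥ 1 enhancer overlaps — once per
locus, never once per enhancer, because double counting would break the
defining envelope y ≤ x.

**Motifs.** Position count matrices are converted to log-odds with a
0.8-per-cell pseudocount against a zero-order background, scores are
discretized to a 0.01-bit grid, and the hit threshold at false-positive
level α = 0.001 is computed by exact convolution of the per-position
score distributions. Both strands are scanned; windows containing N are
skipped and excluded from the scanned-position count; overlapping hits
are not collapsed. Enrichment is the pseudocounted log2 ratio of hit
rates between target and background sequence sets. This deliberately
substitutes a zero-order background and a rate ratio for the published
order-1 Markov background with a compound-Poisson test: it reproduces
the *ranking* semantics at desk scale, and its absolute values are not
comparable to the published ones. The calibration and the scanner share
one discretized score matrix, so threshold semantics are exactly
consistent between the two.

## The synthetic landscape

`synth_config()` defaults define the study conditions the generator
emulates; they are fixed once, not tuned:

* **Geometry.** Five 1.2-Mb autosomes plus a 0.6-Mb chrX, tiled by
  100-kb TADs. Elements occupy a 4-kb lattice inside each TAD with ±300
  bp placement jitter — spacing chosen so promoter windows, merge
  distances (500 bp), ATAC flanks (150 bp) and replicate jitter (±50 bp)
  can never make distinct planted elements interact, which is what makes
  exact truth recovery a well-defined target.
* **Classes.** 111/27/12 autosomal pan/limb/trunk enhancers plus 6 chrX
  pan enhancers and 2 TAD-boundary straddlers (~75/17/8 percent shares),
  50 non-chondrogenic, 40 sub-threshold (exact 2-fold) and 250 inactive
  regions — echoing the published 74/18/8 tissue shares, the 75/25
  chondrogenic split, and the existence of unassignable enhancers.
* **Signal.** Baseline coverage 0.05; planted EGFP+ levels uniform on
  [1, 4]; planted fold changes a 70/30 mixture of uniform [8, 25] and
  [4.3, 6], so the landscape contains both comfortable and
  near-threshold calls. Tissue-enriched classes carry a [2.2, 4]
  between-tissue ratio, pan classes [0.8, 1.25]. Noise is multiplicative
  log-normal per region and condition at CV 0.1 (the simplest strictly
  positive model); replicate ATAC peak edges jitter uniformly ±50 bp.
* **TADs and genes.** Roughly half the chondrogenic enhancers go to
  gene-bearing TADs at a mean load of ~3.8, the rest to gene-free TADs
  at ~2.0 per TAD (capacity-capped preferential attachment, so the count
  distribution is right-skewed with median below mean, as in real TAD
  maps). 50 marker genes (84/8/8 percent shared/limb/trunk), EGFP-
  markers, background genes, and three non-coding genes with
  marker-level expression that must *not* promote their TADs — an
  explicit trap for the protein-coding filter.
* **Downstream fixtures.** TF peaks on exactly 40% of planted
  chondrogenic enhancers and 3% of inactive regions; 120 GWS loci
  (40 gene-anchored, 40 enhancer-anchored, 40 empty) with Pareto
  (α = 1.5, scale 1e-4) variance weights; four named two-TAD size loci;
  a planted consensus motif at 1 occurrence/sequence in targets versus
  0.2 in background (5× density) among 20 random decoy PCMs.
* **Candidate universe.** The generator emits per-tissue H3K27ac peak
  files covering every planted region that is active in either fraction.
  This is required for the mirrored non-chondrogenic rule to see its
  targets on the same candidate universe, and mirrors how a peak caller
  behaves on the EGFP- fraction signal.

What the generator does **not** emulate: read-level noise and mapping
artifacts, copy-number and GC biases, overlapping or nested regulatory
elements, correlated noise across conditions, peak-width variation of
real MACS2 output, and realistic inter-gene distances. Passing the
planted-truth tests therefore demonstrates the correctness of the
interval arithmetic, thresholds and bookkeeping under the stated noise
model — not robustness to everything real chromatin data can do.

## Numerical choices and degenerate inputs

* Coordinates are BED-convention 0-based half-open on disk and standard
  Bioconductor 1-based `GRanges` in memory; conversion happens only in
  the readers/writers. Chromosome-name dialects are normalized to the
  `ChromSizes` spelling at load. Intervals beyond a chromosome are
  errors, never silently clipped — except for deliberate `extend` and
  `center` operations, which clip.
* Coverage values serialize with 6 significant digits; round-trip tests
  compare at 1e-5, in-memory identities at numerical precision.
* Merged calls break no ties: output order is (chrom, start), merged
  scores are member maxima.
* Empty inputs: empty ATAC replicates yield an empty consensus with a
  warning; empty TAD categories report `NA` means; a zero-position
  motif scan is an error (rates undefined).
* Percentages destined for comparison with printed values go through one
  helper (`percent_of`) that rounds at the printed precision — integer
  for class shares, one decimal where one decimal is printed.

## Problem sizes

The default synthetic landscape (≈ 500 planted regions, 250 genes, 66
TADs, 120 loci, 21 motifs over 120 sequences of 500 bp) was chosen so a
full generate-and-analyze cycle completes in seconds while every count
that matters (class shares, per-TAD means, overlap fractions) is large
enough to be stable at the reported precision. The test suite's oracle
checks run on deliberately tiny instances (≤ 10 kb chromosomes, ≤ 15
intervals, ≤ 6-observation rank-sum samples) where brute force is exact
and fast.

## Known limitations

* The pipeline starts from peaks and normalized coverage; peak calling,
  read alignment and normalization constants are upstream of its
  contract, and the exact normalization of any real dataset is not
  reproducible from these inputs alone (the factor actually applied is
  recorded on each track instead).
* The motif stage is a simplified enrichment (see above) suitable for
  ranking, not for absolute enrichment statistics.
* Enhancer-gene assignment is TAD-colocalization, not contact data;
  boundary-straddling elements are deliberately dropped rather than
  arbitrated.
* Liftover between assemblies is out of scope; all inputs must share one
  assembly.
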