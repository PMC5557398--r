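---
title: "Fusion transcripts and methylation-expression signatures in pediatric ALL: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusion transcripts and methylation-expression signatures in pediatric ALL: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leukfuse)
library(dplyr)
```

# The problem

Expressed fusion genes are a hallmark of pediatric acute lymphoblastic
leukemia (ALL) and the basis of its clinical subtyping: t(12;21)
*ETV6-RUNX1*, t(9;22) *BCR-ABL1*, 11q23/*KMT2A* rearrangements, and the
more recently described *DUX4-IGH* and *ZNF384*-rearranged subgroups.
Detecting them from RNA-seq raises two complementary problems:

1. **Candidate filtering.** De novo fusion callers emit thousands of
   candidate chimeric transcripts per cohort, most of them artifacts of
   sequence homology, library chimeras, or transcriptional read-through.
   A cascade of removal rules — blacklists, multi-mapping evidence,
   promiscuous partners, minimum unique support, subtraction of calls
   seen in normal B/T cells — reduces these to a high-confidence set.
2. **Targeted screening.** Clinically established fusions deserve a
   directed search: build the expected junction sequence and count the
   read pairs that match it *uniquely*, i.e. better than they match any
   normal transcript.

Around the fusion calls, the package integrates the two molecular layers
that give the emerging subgroups their identity: genome-wide DNA
methylation (450k-style beta values) and gene expression (FPKM), plus
copy-number segments and driver-gene mutations.

Because the patient-level sequencing data behind this design is not
publicly depositable, every analysis here is exercised on synthetic data
with planted ground truth; the generators are first-class, tested code.

# Pipeline stages and their models

## Candidate filter cascade (`apply_filter_cascade()`)

Rules fire in a fixed order; the order affects only which rule is
*recorded* in the audit trail, not the kept set, because a candidate is
removed if any rule fires (this is verified as a property in the test
suite):

1. `blacklist` — unordered pair match first, then single-gene match.
2. `normal_subtraction` — the unordered pair was also called in normal
   B/T reference samples. Orientation of artifacts in normals is
   unstable, so matching is orientation-free.
3. `common_mapping` — a candidate is removed when its multi-mapping
   ("common mapping") supporting reads reach or exceed its uniquely
   aligned support (`n_common_mapping >= n_unique_spanning > 0`).
   Uniqueness is the currency of evidence; homology-driven artifacts are
   dominated by multi-mapping reads.
4. `promiscuity` — a gene fused to more than `promiscuity_threshold`
   distinct partners (default 5) across the cohort marks all its
   candidates. The index is computed on the post-blacklist candidate
   set, pooling 5'/3' roles, so blacklist noise cannot inflate partner
   counts. No published threshold exists for this rule; 5 was chosen
   once as a value that tolerates genuine ALL hub genes (which have up
   to five described partners) while catching promiscuous artifacts,
   and it is configurable.
5. `low_support` — fewer than `min_unique_reads` (default 3) uniquely
   aligned supporting read *pairs*. Whether "reads" means reads or
   pairs is ambiguous in common usage; pairs was chosen because the
   simulator and screen count fragments, and the setting is explicit in
   `filter_config()`.

Genes with described ALL fusion involvement (`known_all_genes`) are
exempt from every rule: a canonical fusion with two supporting reads is
still reported. Blacklists ship empty — they are caller- and
annotation-specific and must be user-supplied.

## Targeted junction screen (`targeted_screen()`)

A junction assay concatenates the last `flank` bases of the 5' partner
before its breakpoint with the first `flank` bases of the 3' partner
(default 40 bp each, sized so a 50 bp read can span with 10 bp anchors).
A read supports the assay iff:

* it matches the contig ungapped at some offset, on either strand, with
  at most `max_mismatches` (default 2) mismatches;
* the match covers at least `anchor_min` (default 10) bases on each side
  of the junction; and
* (uniqueness, default on) no single reference transcript matches the
  read with as few or fewer mismatches — a single-best-hit notion of
  "uniquely aligned", evaluated in transcript space because the whole
  artifact works in transcript space.

Both mates are tested and a pair counts once. Matching is ungapped by
design: at 50 bp read length an indel-tolerant matcher buys little and
costs the exactness that the brute-force oracle tests rely on. Assays
with at least `min_support` (default 3, mirroring the de novo rule —
the targeted threshold is not separately established) become targeted
candidates; the rest are reported in a sub-threshold log so that
near-miss cases (a canonical fusion with two supporting reads in a
shallow library) stay visible instead of silently disappearing.

The screen cannot detect fusions with inserted sequence between the
partners (the junction no longer matches the contig); that failure mode
is documented, not worked around.

## Fusion-partner graph (`build_fusion_graph()` and friends)

Genes are nodes; an undirected edge joins genes observed fused in a
patient, with multiplicity counting distinct patients (a patient
carrying both A→B and B→A counts once). Promiscuous genes are nodes
with ≥ 2 distinct partners, partitioned into exactly-two and
three-or-more classes; *node groups* are connected components containing
at least one promiscuous gene. Reciprocal pairing is strictly
per-sample: A→B in one patient and B→A in another are two singletons.
Event classification calls locality from chromosome labels, measures
intra-chromosomal distance between gene-body midpoints (nearest-edge
distance is available as an option) with a 1 Mbp "far apart" flag, and
classifies reading frame by CDS-phase arithmetic — the event is in
frame when the coding length retained 5' of the junction is congruent
mod 3 with the 3' partner's CDS phase at its breakpoint. Calls without
breakpoints or CDS information report `unknown` rather than a guess.

## Differentially methylated CpGs (`call_dmcs()`)

A CpG is a DMC for a target subgroup when, against *each* of three
reference populations (remission bone marrow, CD19+ B cells, CD34+
progenitor cells):

* the signed mean beta difference Δβ has a consistent sign,
* |Δβ| ≥ `delta_min` (default 0.2), and
* a per-CpG two-sample test is significant at `q_max` (default 0.01)
  after Benjamini-Hochberg adjustment across CpGs within the comparison.

The per-CpG test is an exact two-sided Wilcoxon rank-sum test,
implemented vectorised with average ranks on ties; the exact null is
computed with `pwilcox`. A rank-sum test was chosen as a
distribution-free default on bounded beta values, and the test is the
one deliberately pluggable piece of the DMC caller. Subgroup
*specificity* is an exclusion: CpGs that would also be called, in the
same direction, with any of the `specificity_groups` as the target are
dropped.

**A sample-size floor worth knowing about:** the exact rank-sum p-value
cannot fall below `2 / choose(n1 + n2, n1)`. With a 6-sample subgroup
against 5-sample references that floor is 0.0043, and after BH
adjustment over a realistically sparse DMC fraction, q ≤ 0.01 is
unattainable — no DMC can be called at all. The default q of 0.01 is
therefore only meaningful for subgroups of about 8 samples and up (the
floor at 8 vs 5 is 0.0016); for smaller subgroups either the q
threshold or the test engine must be revisited. This is an honest
property of the rank-sum substitute, not of the underlying biology.

## Genomic-context enrichment (`context_enrichment()`)

For each annotation category (CpG-island context, gene region, chromatin
state) and direction, a 2×2 two-sided Fisher's exact test compares the
DMC set against *all* array probes (the background includes the DMCs —
this makes the identity case, DMC set = array, exactly null). Two-sided
means the sum of all table probabilities not exceeding the observed
one — stated explicitly because two-sided conventions differ; the test
suite pins it to an independent hypergeometric enumeration. A category
is flagged only when both conditions hold: Bonferroni-corrected p < 0.01
(corrected over all categories tested in the run) *and* an absolute
difference in proportion above 10 percentage points. Unannotated probes
count as "out of category" in denominators.

## Consensus differential expression (`consensus_de()`)

Pairwise comparisons of the target subgroup against each comparator use
Welch's t-test on log2(FPKM + 1); the testing engine is pluggable in
principle and deliberately simple — the analysis's substance is the
consensus rule, which is engine-agnostic. Genes with mean FPKM below 5
(over the samples involved) are excluded before testing; fold change is
the ratio of group mean FPKMs with a symmetric 0.1 pseudo-count so that
equal means give fold exactly 1 and empty denominators are safe. A gene
is a consensus subgroup signature when it passes — q < 0.1 and at least
twofold — in at least `min_passing_comparisons` (default 3)
comparisons, **all in the same direction**. Direction consistency is a
design choice: a signature gene should deviate the same way from every
comparator; genes passing in both directions are never called. It is
configurable for users who disagree.

## Integration

* `overlap_dmc_de()` intersects differentially methylated genes with
  consensus DE genes and classifies each shared gene as *inverse*
  (hypo+up or hyper+down), *concordant*, or *ambiguous* (mixed-direction
  methylation). The three relations partition the overlap; the inverse
  fraction is reported over all overlap genes. Genes with
  mixed-direction DMCs are never forced into inverse/concordant — a
  known divergence risk versus analyses that resolve mixed genes by
  majority.
* `cna_corroborate()` flags a fusion call when a same-sample
  copy-number segment overlaps either partner's gene body extended by
  `window` (default 100 kb, half-open intervals) — "within or in close
  proximity". Monotone in the window by construction.
* `cooccurrence_table()` aggregates driver mutations by hotspot
  (gene + residue prefix, so p.G12D and p.G12S pool as p.G12) and
  copy-number flags per fusion family. Samples without targeted
  sequencing are excluded from mutation denominators but kept in CNA
  denominators; inconclusive copy-number profiles leave the CNA
  denominator.
* `cluster_profiles()` ranks features by variance on the clustering
  scale (raw beta for methylation, log2(FPKM+1) for expression), keeps
  the top 1000 by default, and reports a centered PCA (variance
  fractions per component) plus average-linkage hierarchical clustering
  on 1 − Pearson correlation, with ties broken by input order so the
  leaf order is deterministic.

# The synthetic-data generators

The generators define the conditions every recovery claim is made
under; their defaults are fixed once and mirror the study design the
package models.

* `simulate_cohort()` — 18 t(12;21), 6 t(9;22), 7 11q23/MLL, 42
  high-hyperdiploid, 42 BCP-ALL "other", 18 T-ALL, and 5 + 5 normal
  B/T references, with canonical fusions planted per subtype and the
  recurrent *DUX4-IGH* / *ZNF384* / *PAX5* events in the "other" group.
  Normal samples never carry truth fusions.
* `simulate_transcriptome()` / `simulate_fusion_reads()` — a toy
  spliced reference (multi-exon gene models, optional high-identity
  paralog pairs) and 50 bp paired-end reads in transcript space.
  Exactly `n_support` pairs per fusion have one mate spanning the
  junction with ≥ 10 bp anchors; truth labels ride in read names so
  support counting is auditable without alignment. Sequencing errors
  (uniform substitutions) are applied *after* truth labelling: truth
  records origin, and the screen is allowed to miss errored reads.
* `simulate_methylation()` — beta values as planted group means plus
  truncated-normal noise (Gaussian, clipped to [0, 1]; planted means
  stay in [0.05, 0.95] so clipping is negligible). Defaults: 5000 CpGs,
  1000 planted DMCs at Δ = 0.3, noise SD 0.05, 8 target vs 5+5+5
  reference samples, 88% of planted DMCs hypomethylated. The noise
  model is a declared stand-in — nothing is inferred about the real
  array noise. Probe annotations (island context, gene region,
  chromatin state, gene symbol) are drawn with configurable marginals.
* `simulate_expression()` — gamma-Poisson (negative binomial) counts
  per gene with FPKM derived back from the counts, so both matrices are
  consistent and heavy-tailed as the FPKM < 5 filter assumes. Defaults
  mirror the expression comparison groups (8/6/18/6/7/42/5); planted DE
  genes shift fourfold in the target group; 10% of genes are planted
  below FPKM 5 to exercise the exclusion.
* `simulate_integrated()` — couples the two: 100 overlap genes carry
  both planted DMCs (3 CpGs each, single direction) and a planted
  expression shift, with exactly 85% of the genes coupled inversely.
  The methylation matrix uses 1500 CpGs here: with the rank-sum floor
  of 0.0016 at 8-vs-5, BH over m CpGs with k planted passes q ≤ 0.01
  only when k/m ≳ 0.16, and 300/1500 leaves comfortable margin.

What the generators do *not* emulate — and what passing tests therefore
do not show about real data: genomic (intron-containing) reads and
splice-aware alignment, base-quality structure, array normalisation
artifacts, batch effects, correlated CpGs within islands, and
library-size variation. The recovery rates are statements about the
pipeline's logic under its stated model, not about clinical sensitivity.

# Numerical choices

* Rank-sum p-values are exact (`pwilcox`) with average ranks on ties;
  ties essentially only arise from beta clipping at 0/1.
* Welch's t statistic with zero pooled variance (identical constant
  groups) is defined as 0 with p = 1 rather than NaN.
* Fold changes use the symmetric 0.1 FPKM pseudo-count described above.
* BH adjustment is always within one pairwise comparison, never pooled
  across comparisons; Bonferroni for enrichment is over all
  category-direction tests in one run.
* Feature selection for clustering breaks variance ties by row order;
  hierarchical clustering inherits `hclust`'s deterministic merge order
  on 1 − r distances.
* Interval logic (CNA corroboration, probe coordinates) is 0-based
  half-open throughout; breakpoint positions in files are 1-based and
  converted on read.
* Seeded functions save and restore the caller's RNG state, so
  `simulate_*` calls are reproducible without clobbering a session's
  randomness.

# Problem sizes used by the tests

The test suite and the acceptance script run entirely on generated
data, sized for exactness rather than scale: 200 random candidate
cohorts (≤ 50 candidates each) for the filter-cascade oracle; 20 seeded
libraries of ~150–200 read pairs for the targeted screen's exact
recovery; the 5000-CpG / 1000-DMC recovery run plus a 1000-CpG
permutation null (100 label permutations); a 2000-gene expression
cohort at the study group sizes; and the 100-overlap-gene integrated
run. All of it completes in a few minutes on one CPU.

# Known limitations

* The rank-sum DMC engine has the small-sample floor described above;
  subgroups of fewer than ~8 samples need a different engine or a
  relaxed q threshold, and the package makes no attempt to hide this.
* The targeted screen is ungapped and transcript-space: fusions with
  novel inserted sequence or unknown partners are out of reach by
  design.
* Mixed-direction methylation genes are classified `ambiguous`, which
  can depress the inverse fraction relative to majority-vote
  conventions.
* The bundled alteration table is a small compiled case series; its
  counts are reproduced exactly but carry no statistical weight.
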