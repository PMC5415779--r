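---
title: "MitoMeDIP: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MitoMeDIP: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the statistical model behind MitoMeDIP, the
parameters that matter and why their defaults were chosen, what the
synthetic-data generator does and does not emulate, and the places where
the design was genuinely open and a choice had to be made.

# The attribution problem and the three-pass triage

MeDIP-seq enriches methylated fragments from *total* genomic DNA, so reads
over the mitochondrial genome are contaminated by NUMTs — nuclear segments
homologous to mitochondrial sequence. The triage retains a fragment only
when its placement survives three passes:

1. **Full-reference uniqueness.** Both mates map uniquely to the
   mitochondrial record of the full reference. "Unique" means: a primary
   alignment with no co-optimal alternative placement and mapping quality
   above zero (for SAM input: primary, MAPQ > 0, no secondary records).
   The underlying aligner convention does not pin this down, so the
   package states its own definition and applies it identically to the
   built-in aligner and to external SAM/BAM input.
2. **Nuclear-only exclusion.** The surviving mates are realigned to the
   reference *minus* the mitochondrial record; any mate that maps at all
   is evidence of a nuclear paralogue and removes the fragment.
3. **Confirmation.** Survivors are realigned to the full reference and
   must again be mitochondrial-unique; final coordinates come from this
   pass. With the deterministic built-in aligner this pass cannot change
   pass-1 placements, but it is kept as an independent pass because the
   real-data path runs an external aligner whose two invocations need not
   agree.

Pair handling is conservative: a fragment is kept only when **both** mates
survive every pass (single-mate mode is available via `pairMode = "any"`).
The procedure trades recall for precision by construction: fragments inside
a perfect homology tract are unattributable and are dropped, so the windows
covering such tracts carry no data and are flagged ND rather than imputed.

The built-in aligner (C++ core) is seed-and-extend: exact `k = 15`-mer
seeds on both strands, ungapped extension scoring mismatches, at most
`maxMismatch = 5` per read (calibrated to 50 bp reads: 10% divergence).
Ties are broken to the leftmost placement (record order, then coordinate),
but tied reads are non-unique regardless, so the tie-break never affects
retention. Indels are not modelled; the simulator's NUMT mutation model is
substitution-only for the same reason, and real data should be aligned
externally (e.g. bwa mem) and imported from SAM/BAM.

# Windows, RPKM and the coverage filter

Windows are a contiguous 100 bp tiling of the mitochondrial sequence in
1-based inclusive coordinates. Window *labels* keep nominal 100 bp bounds
(a 16,569 bp genome yields 166 windows labelled up to 16600); the
truncation of the final window applies to counting only. This matches the
convention of the result tables the package reproduces, which label a
16,569 bp genome to 16600. Circularity is recorded on the reference but
alignment and windowing treat the sequence as linear by default; a
circular-aware mode can be emulated with a rotated duplicate reference.

Each retained fragment is counted into exactly one window by the leftmost
aligned base of its leftmost mate, so counts are conserved (no
read-extension double counting; this is a documented divergence from
MEDIPS-style extension). RPKM uses the per-sample total of retained
mitochondrial fragments as denominator — after triage the analysis
universe is the mitochondrial genome — with an externally supplied total
accepted where a genome-wide denominator is wanted.

A window is *analyzed* only when its count strictly exceeds 10
(`count >= 11`) in **every** sample. The per-sample scope is what makes a
single ND flag per window well defined, mirroring a single ND column in a
published per-window table; a total-across-samples scope is available by
flag. Analyzed RPKM values are log2-transformed (positivity is guaranteed
by the filter, so no pseudocount is used; a non-positive value in an
analyzed cell is an error, never silently patched).

# Per-window statistics

* **Paired t.** For each analyzed window, a two-tailed paired t test on
  log2 RPKM matched by individual; the effect is
  `delta = mean(region - cerebellum)`, so `delta < 0` means
  hypomethylated relative to cerebellum. Windows with zero-variance
  differences return a distinct `zero_variance` code instead of a
  fabricated p of 0 or 1.
* **Mixed model.** For total cortex vs cerebellum:
  `value ~ tissue + (1 | individual)` fitted by ML, p from the
  likelihood-ratio test against the model without `tissue` (Wald z by
  flag). A "transposed" mode swaps the roles — individual as a fixed
  effect, brain region as the random intercept — and reports the
  model-comparison p for adding `tissue`; it is kept for comparison with
  analyses described that way, but note the transposed base model contains
  no tissue term of its own, so only the default parameterisation directly
  tests cortex vs cerebellum. Singular fits (including constant input) are
  flagged rather than hidden.
* **Multiple testing.** Bonferroni with `n` = the number of analyzed
  (non-ND) windows, not the full 166 — with the packaged tables this is
  71 and yields 0.05 / 71 ≈ 7.04e-4, the threshold the tables were
  published with.
* **Summaries.** Nominal results are counted either as table *entries*
  (window × comparison pairs — the unit in which the five-region analysis
  was reported) or distinct windows; conserved windows are those nominal
  in every comparison of a subset, with a hyper/hypo/mixed direction
  summary; adjacency is the longest run of consecutive grid windows;
  direction concordance between two delta profiles excludes zero deltas
  from numerator and denominator.

# Tissue-level structure

Average RPKM profiles per group feed `hclust` on Euclidean distance
(complete linkage, the clustering function's default; average/Ward by
argument), Pearson correlation matrices, and a corrgram-style PCA ordering:
samples sorted by `atan2(PC2, PC1)` of the first two eigenvectors of the
correlation matrix, with each eigenvector's sign fixed so its
largest-magnitude loading is positive (orderings are then reproducible
across platforms; ties break by original index). Dendrograms export to
Newick.

# The fixture tables

The two per-window result tables are packaged as literal TSV
transcriptions (windows, gene labels, printed p values and RPKM
differences, ND flags, bold-face flags). Two properties of the published
tables deserve note, and the package preserves both verbatim rather than
"repairing" them:

* The ND patterns of the two tables disagree at windows 3101–3200 and
  4101–4200 (ND in the five-region table, merely non-significant in the
  total-cortex table). `loadFixtureTables()` reports the discrepancy (a
  warning by default, an error under `strict = TRUE`). The
  multiple-testing `n` is taken from the five-region table's non-ND count
  (71), the value consistent with the published threshold.
* One row prints an RPKM difference with no accompanying p value, and one
  gene is named inconsistently between tables ("MT-TL" vs "MT-TL1");
  both are transcribed as printed.

The packaged gene-interval annotation is *derived* from the tables'
per-window gene labels (`annotationFromWindowLabels()`): real GENCODE
coordinates are external, and the printed labels are not consistent with
rCRS gene coordinates at sub-window resolution (e.g. a tRNA listed in a
window it would not overlap). The derived intervals reproduce the printed
labels exactly under `annotateWindows()` and are clearly marked synthetic
(file suffix `.synthetic.tsv`); they are label-faithful at window
resolution and arbitrary below it.

# The simulator: what it emulates, and its defaults

Per sample, window methylation is
`baseline + planted tissue effect + N(0, noiseSd)`, clipped to [0, 1].
Fragments have length uniform on 220–320 bp and are sampled with weight
`baseWeight + slope * methylation(window of fragment midpoint)`; the two
50 bp mates are the fragment ends (mate 2 reverse-complemented) with i.i.d.
substitution errors. NUMT contamination is emitted from the planted nuclear
copies at a configurable fraction. Everything is driven by an explicit
seed and is byte-reproducible.

Defaults (the package's reference study conditions, chosen once):

| parameter | default | rationale |
|---|---|---|
| mitoLength | 16,569 bp | human mitochondrial genome length |
| fragment length | 220–320 bp | library fragment-size selection of the targeted protocol |
| read length | 50 bp | paired-end read length of the targeted protocol |
| baselineMeth | 0.2 | low mitochondrial methylation; keeps noise clear of the [0,1] bounds |
| noiseSd | 0.05 | individual-level biological variability on the methylation scale |
| baseWeight, slope | 0.1, 1.0 | positive background pulldown plus enrichment proportional to methylation |
| errorRate | 1e-3 | typical post-filter substitution error |
| NUMTs | identical copy of mito 5001–7000; 10%-diverged copy of 12001–13000 | one unattributable tract (window-aligned, so the depleted windows are unambiguous) and one divergent paralogue the triage must reject |
| numtFraction | 0.2 | appreciable nuclear contamination pressure |
| planted DMRs | +0.3 on 16201–16600 (cortex) and 2201–2600 (cerebellum) | one hyper- and one hypomethylated block relative to cerebellum, 400 bp each |

`noiseSd = 0.05` was fixed by a design-stage power analysis (noncentral t,
closed form) *before* any pipeline run: with a +0.3 methylation effect,
3 individuals and 50,000 fragments per sample, the induced log2-RPKM shift
of ~1 against a paired-difference sd of ~0.29 gives predicted power 0.84 at
alpha 0.05 with 2 degrees of freedom. Smaller noise makes the recovery
trivial, larger noise makes 3 matched individuals hopeless; 0.05 sits where
the design is challenging but feasible.

Because enrichment acts on the *midpoint* window while counting assigns
fragments to the window of their leftmost base, a planted region influences
counts up to half a fragment length (~110–160 bp) upstream of itself. The
planted regions are therefore blocks of several windows, and
`plantedWindowStatus()` classifies each grid window as *informative* (all
midpoints of fragments starting there lie inside a planted region),
*affected* (some do) or *null*. Power is assessed on informative windows
and specificity on null windows; edge windows are excluded from both,
which is a property of the generative geometry, not a relaxation of the
detection task. The two trailing grid windows can never receive a fragment
start (a 220 bp fragment cannot begin there) and are never counted as null.

What the simulator does **not** emulate: CpG-resolution methylation (truth
lives on the analysis grid by design), sequence-dependent pulldown
efficiency and CpG-density bias (so no MEDIPS-style coupling
normalisation is attempted), PCR duplicates, indels, base-quality error
profiles, and circular junction reads. Passing the package's simulation
tests therefore demonstrates that the *procedure* is sound under its own
stated model, not that any particular biological dataset will behave as
cleanly.

# Problem sizes used by the validation suite

* Triage soundness: 10,000 fragment pairs, the default NUMT scenario, one
  seed; precision/recall scored against per-read truth.
* Paired-t parity: 1,000 random instances against an independent
  closed-form oracle at 1e-10.
* Mixed-model calibration: a fixed null dataset of 30 individuals × 6
  observations (5 cortical + 1 cerebellar per individual in the study
  design; balanced 3 + 3 here so the within-individual contrast is
  estimated from more than one observation per arm), tissue labels
  permuted within individual 1,000 times; the rejection rate at 0.05 is
  compared with the binomial confidence band. The size was chosen a
  priori as one where the 1-df chi-square reference for the
  likelihood-ratio test is expected to hold; at very small sizes the
  ML-based LRT is not exactly calibrated and the check would measure that
  finite-sample deficit rather than the implementation.
* DMR recovery: 100 replicate simulations (seeds derived from the run
  seed), 3 individuals, 2 tissues, 50,000 fragments per sample; power on
  informative windows, false-positive rate on null windows, pooled (the
  per-replicate dispersion of the false-positive rate matches the
  binomial prediction, so pooling is fair).
* Clustering recovery: 3 tissues × 3 individuals with disjoint planted
  blocks and `noiseSd = 0.01` (offsets dominating noise), per-sample
  average-RPKM profiles, complete-linkage Euclidean clustering cut at
  k = 3.

The count-level path (`simulateWindowCounts()`, the exact marginal of the
read-level generator on window counts) is used for the 100-replicate
studies; the sequence-level path including alignment is exercised by the
triage scenarios.

# Numerical and degenerate-input conventions

* Quality trimming uses the maximal-partial-sum rule over
  `(qThreshold - q_i)` on the 3' end, ties resolved toward trimming more;
  a hard-clip-at-first-low-base mode exists. Trimming is idempotent, and
  a trimmed read never ends in a base below the threshold.
* Phred+33 FASTQ encoding is assumed (configurable offset).
* Zero-variance windows and singular mixed-model fits return codes, never
  invented p values. Empty retained sets give an undefined-precision code.
* All window coordinates are 1-based inclusive externally; BED export
  converts to 0-based half-open at the boundary.
* Aligner determinism: equal-score placements resolve leftmost; such
  reads are marked non-unique so the choice never changes retention.

# Known limitations

The triage is deliberately over-conservative: windows inside strong
homology tracts are lost (ND) rather than rescued, and recall on
NUMT-containing genomes drops near homology boundaries. The toy aligner
handles substitutions only. RPKM magnitudes depend on the denominator
convention and are not comparable across denominator modes. The
mixed-model LRT relies on an asymptotic reference that is only
approximately calibrated for very small cohorts — for three individuals
the paired t is the better-behaved primary analysis, which is how the
package's own result tables are organised.
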