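# MitoMeDIP

Window-based analysis of mitochondrial DNA (mtDNA) methylation from
MeDIP-seq data, with explicit control for nuclear-mitochondrial pseudogenes
(NUMTs).

## The problem

MeDIP-seq (methylated-DNA immunoprecipitation sequencing) libraries are
made from total genomic DNA, so reads attributable to the ~16.6 kb circular
mitochondrial genome are mixed with reads from NUMTs — nuclear loci highly
homologous to mitochondrial sequence. Naive mapping therefore conflates
nuclear and mitochondrial methylation signal, and most pipelines simply
discard chrM reads. MitoMeDIP instead retains mtDNA reads that can be
attributed to the mitochondrial genome with confidence, then quantifies and
tests methylation in 100 bp windows. It is aimed at anyone re-analysing
existing whole-genome MeDIP-seq data (e.g. matched brain-region/blood
cohorts) for mitochondrial methylation.

## The method

**Three-pass triage.** Reads are (1) aligned to the full reference and kept
only if uniquely mapped to the mitochondrial record; (2) realigned to a
custom nuclear-only reference (the full reference minus chrM) and kept only
if they fail to map there; (3) realigned to the full reference and
confirmed mitochondrial-unique. Fragments survive only if both mates
survive. This is deliberately conservative: reads inside perfect
mitochondria–nucleus homology tracts are unattributable and are dropped,
leaving those windows flagged ND (not determined).

**Quantification.** Retained fragments are counted into non-overlapping
100 bp windows by the leftmost base of the leftmost mate, converted to
RPKM,

```
RPKM_w = count_w / ( (len_w / 1000) * (total_retained / 1e6) )
```

filtered (a window is analyzed only when its count exceeds 10 in every
sample), and log2-transformed for testing.

**Statistics.** Per window: two-tailed paired t tests between each cortical
region and cerebellum (matched by individual), and a mixed-effects model
`log2RPKM ~ tissue + (1 | individual)` with a likelihood-ratio test for the
total-cortex vs cerebellum contrast. Multiple testing is controlled by
Bonferroni over the analyzed windows (alpha / n_analyzed). Tissue-level
structure is summarised by Euclidean hierarchical clustering of average
RPKM profiles, Pearson correlation matrices, and corrgram-style PCA
ordering.

**Simulator.** A fully seeded generator produces a random mitochondrial
genome, a nuclear decoy with planted NUMTs of controlled divergence,
per-tissue/per-individual window methylomes with planted DMRs, and
MeDIP-like 220–320 bp fragments sequenced as 50 bp paired-end reads whose
sampling weight is `baseWeight + slope * methylation` of the fragment
midpoint's window. Per-read truth labels let every pipeline stage be scored
without any external data.

## Worked example

```r
library(MitoMeDIP)

cfg  <- simulationConfig()                      # default study conditions
refs <- simulateReference(cfg, seed = 1)        # mito + NUMT-bearing decoy
meth <- simulateMethylomes(cfg, seed = 2)
rd   <- simulateMedipReads(refs, meth$meth[, "CER", 1], cfg,
                           nFragments = 10000, seed = 3)

out <- runTriage(rd$mate1, rd$mate2, refs$full, refs$nuclear)
triageCounts(out$report)
#>                  input      pass1_mito_unique pass2_nuclear_unmapped
#>                  10000                   6968                   6591
#>        pass3_confirmed
#>                   6591
evaluateTriage(rd$truth, out$retained)$precision
#> [1] 1
```

Of 10,000 simulated fragment pairs (~20% of them NUMT contamination),
pass 1 removes non-mitochondrial and ambiguous pairs, pass 2 removes pairs
that still map to the nuclear-only reference, and every retained fragment
is truly mitochondrial (precision 1). Windows inside the planted
identical-NUMT homology tract end up with zero coverage and are ND.

The packaged transcriptions of the published per-window result tables
reproduce every printed summary:

```r
str(reproducePublishedCounts())
#> List of 10
#>  $ nominal_entries_five_region    : int 74
#>  $ conserved_prefrontal_windows   : int 7
#>  $ conserved_hypomethylated       : int 3
#>  $ conserved_hypermethylated      : int 4
#>  $ conserved_longest_adjacent_run : int 4
#>  $ nominal_windows_total_cortex   : int 48
#>  $ analyzed_windows               : int 71
#>  $ bonferroni_threshold           : num 0.000704
#>  $ bonferroni_significant_windows : int 8
#>  $ bonferroni_longest_adjacent_run: int 3
```

74 window-by-region entries are nominally significant across the five
cortical-region comparisons; 7 windows are significant in all three
prefrontal regions (3 hypo-, 4 hypermethylated relative to cerebellum, 4 of
them adjacent in the D-Loop); the total-cortex mixed model yields 48
nominal windows of which 8 pass the Bonferroni threshold
0.05 / 71 ≈ 7.04e-4 (3 adjacent).

A command-line wrapper with `simulate`, `triage`, `quantify`, `dmr`,
`cluster`, `reproduce-tables` and `pipeline` subcommands is installed at
`inst/scripts/mitomedip` (see `?mitomedipCLI`).

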