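---
title: "Discovering synthetic-viability candidates in BRCA-deficient tumors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering synthetic-viability candidates in BRCA-deficient tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synviab)
```

## The problem

Bi-allelic inactivation of *BRCA1* or *BRCA2* (bBRCA1/2) cripples
homologous-recombination repair. Tumor cells that nonetheless thrive with
this defect often carry *secondary* alterations that rescue the fitness
cost — synthetic viability, the mirror image of synthetic lethality. The
canonical example is loss of 53BP1 restoring viability in *BRCA1*-null
cells. Because such rescuing losses are frequently swept along inside
large recurrent copy-number deletions, they can be discovered
computationally by asking three questions of a tumor cohort:

1. **Which cytobands are deleted more often in bBRCA1/2 tumors than in
   HR-proficient controls?** (copy-number evidence)
2. **Which genes inside those bands are actually expressed less when the
   band is deleted?** (transcriptional evidence)
3. **Which of those genes, when knocked out, increase proliferation in a
   BRCA-knockout background relative to wild type?** (functional
   evidence, from isogenic CRISPR screens)

`synviab` implements this three-stream discovery procedure as a tested
pipeline, plus a synthetic-cohort generator with planted ground truth so
every stage has a parameter-recovery test that runs at desk scale.

## Cohort definition

Tumors are partitioned by `classify_group()`:

* **case** — bi-allelic *BRCA1* or *BRCA2* inactivation (`bBRCA1`,
  `bBRCA2`); allelic status is an input, not inferred here;
* **control** — *BRCA1/2* wild type (no mono-allelic alteration) *and*
  little evidence of HRD: SBS signature 3 is not the dominant signature
  and the large-scale state transition count satisfies LST < 12;
* **excluded** — everything else (mono-allelic carriers, HRD-like wild
  types).

"Non-dominant signature 3" is operationalised as a boolean input flag:
dominance means signature 3 has the largest exposure among the tumor's
decomposed signatures. The control rule applies the signature condition
and the LST condition as two independent filters. A related helper,
`brcaness_flag()`, labels tumors LST-high with > 20% signature-3
contribution (strict inequality) as BRCAness for mutation-enrichment
analyses such as `lof_enrichment_test()`.

## Cytoband copy-number calls

Absolute copy-number segments (FACETS-style SEG input, 1-based inclusive,
converted on read to the internal 0-based half-open convention) are
intersected with cytobands. A band's integer copy number is the copy
number whose segments contribute the greatest overlapped length within
the band; the call is made only when segments cover **strictly more than
50%** of the band's length, otherwise the cell is missing. Two numerical
choices are deliberate:

* the 50% rule is applied to the *fraction of the band covered*, since
  the quantity being assigned belongs to the band;
* exact length ties between copy numbers resolve to the **lower** copy
  number, a conservative choice for a deletion-focused analysis
  (configurable via `assign_cytoband_cn()` if a different rule is ever
  needed).

Status is called relative to the tumor's *average ploidy*, used as a real
number without rounding: **deleted** when `cn <= ploidy - 1`,
**amplified** when `cn >= ploidy + 3`, neutral otherwise. With ploidy
3.2, a copy number of 2 is deleted (2 ≤ 2.2). Missing cells are excluded
from both numerator and denominator of every downstream frequency —
absence of evidence, not neutrality. The package ships the standard UCSC
hg19 cytoband table (`hg19_cytobands()`), which yields 851 bands after
excluding chromosome Y; chromosome Y, the mitochondrial contig and
unplaced scaffolds are dropped at ingestion.

## Enrichment testing and the fixed-margin permutation null

For each band and direction, `fisher_cytoband_enrichment()` builds the
2×2 table of altered/unaltered by group and computes the two-sided
Fisher exact p (sum of hypergeometric probabilities of tables no more
probable than the one observed), followed by Benjamini–Hochberg
adjustment over all bands of that direction. Deletions and
amplifications are corrected as separate families because they are
reported separately. A band is **enriched** when both `q < alpha`
(default 0.05) *and* the case frequency exceeds the control frequency —
the test is two-sided but the scientific question is directional.

bBRCA1/2 tumors are genomically unstable, so more of everything is
deleted. To show that the *count* of enriched bands is not explained by
sample- and band-level instability alone, `permutation_empirical_p()`
permutes the binarised alteration matrix while keeping **all row sums
(per-band alteration counts) and column sums (per-tumor alteration
burdens) fixed**, re-runs the full Fisher + BH procedure in each
iteration, and reports the add-one empirical p-value
`(1 + #{perm >= obs}) / (1 + n_perm)`. Implementation notes:

* the sampler is the sequential checkerboard-swap Markov chain (vegan's
  `"swap"` null model), with burn-in 10·nnz swaps and thinning nnz swaps
  between samples by default, where nnz is the number of 1-cells; a
  matrix with no checkerboard submatrix (e.g. all ones) is the unique
  matrix with its margins and is returned unchanged;
* missing cells binarise to 0 before permutation (they contribute no
  alteration);
* because margins are preserved, every band's 2×2 margins are constant
  across permutations, so per-band p-values come from a precomputed
  margin-conditional lookup table — this makes desk-scale permutation
  counts (hundreds to thousands) cheap; re-using the observed BH
  threshold instead of re-running BH per iteration is available via
  `recompute_bh = FALSE`.

## Transcriptional consistency score (TCS)

Differential expression averaged over a whole cohort underestimates
genes whose deletion is present in only a subset of tumors. The TCS
conditions on the deletion: expression of each gene is dichotomised at
its median over **all** tumors (regardless of group or copy-number
status; "low" is *strictly below* the median, so median ties are "high"
— conservative toward claiming downregulation), and

* **TCS** = proportion of deletion-bearing case tumors with low
  expression, evaluated only when at least 5 case tumors carry the
  deletion (so 4 low of 5 deleted gives TCS = 0.8);
* **control TCS** = the analogous proportion among *control* tumors
  *without* the deletion (the control group only, per the procedure's
  definition of the reference);
* **normalized TCS** = TCS / control TCS; a zero control TCS with a
  positive TCS yields an infinity sentinel.

A gene passes when TCS > 0.7 **and** normalized TCS > 1.5 (both strict).
A gene inherits the deletion call of the cytoband containing its
interval midpoint, keeping gene- and band-level analyses consistent.

## Relative proliferation score (RPS)

BAGEL-style Bayes factors (BF — the log odds that a gene is essential)
from a wild-type screen and an isogenic BRCA-knockout screen are
combined per gene as

`RPS = BF_KO − BF_WT`.

Negative RPS means the knockout background tolerates (or favours) loss
of the gene — the synthetic-viability signature. Genes are also
categorised per screen: among genes with BF < 0 the lowest-scoring half
(ceiling) are *non-essential*; among genes with BF > 0 the
highest-scoring half (ceiling) are *essential*; the remainder (including
BF = 0 exactly) are *neutral*. Ties break by gene symbol for
determinism. Proliferation-gain candidates are genes whose category
drops (essential → neutral/non-essential, or neutral → non-essential)
**intersected with** the top half (ceiling) of negative-RPS genes. An
optional DepMap filter (`depmap_proliferation_filter()`) keeps genes
whose mean gene-effect across selected BRCA-deficient cell lines exceeds
−0.5 (strict).

## Integration

`integrate_candidates()` intersects the three evidence streams; a final
candidate must lie in an enriched deletion locus, pass the TCS filter,
and gain proliferation in the screen. Per-gene evidence booleans are
kept for the whole union so near-misses are visible.
`combine_tracks()` unions candidate lists across cohorts (e.g. ovarian
and ER+ breast) with provenance. BRCA1 and BRCA2 tracks are run
independently (separate case groups and BF pairs); TCS membership is
evaluated in the track-specific cohort. `run_pipeline()` chains all
stages and returns a classed object with `print()`, `summary()` and
`plot()` methods; stages whose optional inputs are absent (BF tables,
gene effects) are skipped with a recorded reason rather than failing.

```{r example, eval = FALSE}
sim <- simulate_dataset(sim_config(seed = 3))
res <- run_pipeline(sim$bundle, sv_config(n_perm = 200))
res
setdiff(sim$truth$viable_genes, res$candidates$gene[res$candidates$candidate])
```

## What the synthetic cohort emulates — and what it does not

`simulate_dataset()` generates a toy genome of 1-Mb cytobands tiled over
four chromosomes; each case tumor deletes each enriched band with
probability 0.6 and every other band with probability 0.15, controls use
the background rate everywhere, and deletions are realised as segments
at one copy below the tumor's ploidy (sampled from {2, 3, 4} to exercise
the ploidy-relative thresholds). Default scales are 90 cases vs 140
controls with 20 enriched of 200 bands — the cohort proportions the
recovery tests are specified at. A `ragged = TRUE` mode jitters segment
boundaries by up to 20% of the band width to exercise the > 50% overlap
rule without changing the planted calls.

Expression is log-normal around a per-gene baseline (uniform 3–8 in
log2-FPKM, noise SD 0.5); 70% of genes in enriched bands are "coupled":
shifted down by 2 log2-units in tumors whose covering band is deleted —
a deliberately strong planted dosage signal. Bayes factors place planted
essential genes in [5, 15], non-essential in [−15, −5], neutral in
[−1, 1], plus Gaussian noise (SD 0.5); 30 switch genes are essential in
WT and non-essential in KO, with roughly half drawn from the coupled
genes so the three evidence streams genuinely intersect. The remaining
genes split 20% essential / 20% non-essential / 60% neutral so that the
planted ranges fill their ceiling-half categories with margin. Mutations
arrive at a uniform 3% per gene per sample — a null for co-mutation
calibration.

What this does **not** emulate: realistic segmentation noise and focal
events, signature decomposition from trinucleotide spectra, sgRNA-level
screen noise, purity/ploidy estimation error, or expression
heteroskedasticity across dynamic range. Passing recovery tests
therefore demonstrates the *procedure's* correctness and calibration
under its stated assumptions, not performance on real cohorts, where
thresholds interact with caller behaviour.

## Numerical choices and degenerate inputs

* Fisher p-values use the standard minimum-likelihood two-sided rule
  with a 1 + 1e−7 relative tolerance (matching `stats::fisher.test`),
  clipped at 1; enrichment odds ratios are the sample cross-product
  ratio (infinite when a zero cell makes them so), while the small-table
  `lof_enrichment_test()` applies the Haldane–Anscombe 0.5 correction
  when any cell is zero.
* BH adjustment is `stats::p.adjust(method = "BH")` behind a validated
  wrapper; inputs outside [0, 1] are fatal.
* A band covered exactly 50% is missing (strict rule); a sample with no
  segments becomes an all-missing column with a warning; an empty group
  is fatal for the enrichment and co-mutation tests.
* The empirical p-value uses the add-one estimator, so it can never be
  zero; its resolution is 1/(n_perm + 1). Production-scale counts
  (10^5) are supported but desk-scale analyses use hundreds to
  thousands.
* All randomness (simulation, permutation chain) is seed-controlled;
  identical seeds give byte-identical outputs, including written
  tables.

## Problem sizes used by the test suite

Unit tests run a reduced cohort (40 vs 60 samples, 60 bands, 120 genes);
recovery and calibration suites use the full default conditions (90 vs
140, 200 bands) with 20–40 seeds and 200 permutations per seed — sizes
chosen so the entire suite completes in minutes on a laptop while
keeping the binomial error of every rate being checked well inside the
asserted bounds.

## Known limitations

* Bi-allelic status, signature exposures and LST counts are inputs; the
  package neither calls variants nor fits signatures.
* BAGEL Bayes factors are inputs; sgRNA counting and BF computation are
  out of scope.
* The permutation null conditions on the binarised matrix of one
  direction at a time; joint deletion/amplification nulls are not
  implemented.
* Cytoband annotation is hg19; other assemblies can be supplied as BED
  but are not bundled.
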