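---
title: "Designing and applying diagnostic SNP panels for lamprey ecotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and applying diagnostic SNP panels for lamprey ecotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lampid)
```

## The problem

Western Brook Lamprey (WBL) and Western River Lamprey (WRL) are sympatric
*Lampetra* that very likely represent alternate life histories — resident and
nonparasitic versus anadromous and parasitic — of a single panmictic species
rather than two lineages. Their larvae are morphologically identical, and
even metamorphosed fish are hard to separate without training. Genome-wide
they are nearly undifferentiated; what separates them is a handful of narrow
chromosomal regions ("genomic islands of divergence") where allele
frequencies differ strongly. `lampid` implements the full chain of methods
such a situation calls for:

1. a pooled low-coverage sequencing F~ST~ scan to find the islands,
2. selection of candidate assay SNPs and a small diagnostic panel,
3. a two-marker genus classifier (*Entosphenus* vs. *Lampetra*) and a
   multi-locus percent-WRL ecotype classifier with explicit missing-data
   rules,
4. concordance audits of genetic against morphological identifications, and
5. collection-level composition estimates with bootstrap confidence
   intervals, overlapping-CI stability tests, and a Mantel test of spatial
   structure in panel-allele frequencies.

A seeded synthetic-data generator reproduces the statistical structure these
methods assume, so the whole pipeline is exercised without sequencing data.

## The F~ST~ scan

For one bi-allelic SNP with allele frequencies $p_1, p_2$ in the two ecotype
pools, the package uses the Nei-style fixation index with equal group
weights,

$$H_S = \tfrac{1}{2}\left(2p_1q_1 + 2p_2q_2\right),\qquad
  \bar p = \tfrac{p_1 + p_2}{2},\qquad
  F_{ST} = \frac{H_T - H_S}{H_T},\quad H_T = 2\bar p \bar q ,$$

undefined when $H_T = 0$ and clamped below at zero. The upstream pooled
pipeline this emulates does not publish its exact estimator; the Nei form is
the simplest one consistent with reporting on a 0–1 scale. A Hudson-form
estimator (`snp_fst_hudson()`) ships alongside for cross-checks, and the test
suite verifies the default against an independently coded oracle to 1e-12.

Scan parameters (`scan_config()`), with defaults and reasoning:

* **window = 10 kb, step = 5 kb** — windows are anchored at position 1 per
  chromosome, half-open `[start, start + W)`; each interior SNP belongs to
  exactly `ceiling(W/s) = 2` windows. Window means smooth per-SNP noise at
  low depth.
* **min_ind_per_group = 4** — "minimum coverage of four individuals per
  site" is read symmetrically: a SNP is kept only when *each* ecotype pool
  has at least four individuals with one or more reads. This is the
  conservative reading of an ambiguous rule; an asymmetric or total-count
  reading would retain more noisy loci.
* **high_fst_abs = 0.5** — the operative definition of a "high-F~ST~" SNP is
  the absolute threshold; the empirical quantile of that threshold in the
  realized F~ST~ distribution is reported alongside (in the motivating study
  it sat at the 99.7th percentile) rather than used as a second filter.
* **enrichment_share = 0.01** — a chromosome is enriched when it carries
  strictly more than 1% of all high-F~ST~ SNPs; candidates are drawn from
  enriched chromosomes.
* **n_candidates = 47, panel_size = 5** — assay-budget defaults.

Candidate allocation across enriched chromosomes is proportional to their
high-F~ST~ SNP counts with a floor of two assays per included chromosome
(when the budget allows) and largest-remainder rounding; within a chromosome
the highest-F~ST~ SNPs win, ties going to the smaller position. The
published allocation ("43 assays on eight chromosomes plus two each on two
more") was set by hand, not by a stated algorithm, so any proportional rule
is a design choice; ours is deterministic and reproducible.

Because consecutive windows overlap by half a window, the k highest-mean
windows usually stack on the single strongest island.
`top_divergence_windows()` therefore reads the track the way one reads a
Manhattan plot: greedy descent by mean F~ST~ with a minimum same-chromosome
separation (default one window width) between accepted peaks. The
planted-island recovery test operates on those peaks.

## Panel fitting and classification

`ecotype_panel()` is the package's model-fitting verb. Amplicon genotypes of
the candidates on the voucher specimens are refit to F~ST~ (allele
frequencies from called genotypes, two copies per typed individual), the top
`panel_size` SNPs are kept, and each allele is designated WRL or WBL by
which ecotype shows the higher voucher frequency; an exact frequency tie
flags the locus non-diagnostic and drops it. The chromosome of the
top-ranked SNP becomes the *required chromosome* — in the motivating study,
chromosome 2 carried the two strongest SNPs.

`predict()` on the fit computes, per individual,

$$\%\mathrm{WRL} \;=\; \frac{\text{WRL-designated allele copies across typed
panel SNPs}}{2 \times \text{typed panel SNPs}},$$

defined only when at least three panel SNPs typed *and* at least one typed
SNP lies on the required chromosome. The call is WRL above 50%, WBL below,
`Intermediate` at exactly 50%, `Unknown` when undefined. Percentages are
reported at one decimal with half-away-from-zero rounding (`percent()`).

The genus rule is deliberately conditional: a heterozygote at either of the
two redundant markers (LampSD_478 G/A, LampSD_700 G/T) calls `Hybrid`
before anything else, because the heterozygote rule is stated
unconditionally in the assay's definition; single-marker calls are made when
one marker drops out; homozygous disagreement is a distinct `Conflict`
category excluded from every downstream denominator (it has never been
observed in practice). An edge the assay definition leaves open — exactly
one marker typed and heterozygous — is called `Hybrid` here; users screening
degraded samples should be aware of it.

## Concordance bookkeeping

Two denominator conventions coexist and both are first-class:

* **Voucher convention** (`voucher_concordance()`): specimens grouped by
  morphological class, genetic unknowns excluded, intermediates kept in the
  denominator: matches / (matches + mismatches + intermediates).
* **Survey convention** (`ecotype_concordance()`): the headline rate drops
  everything non-definitive on either side; a secondary rate keeps
  definitive morphological IDs in the denominator so intermediates count
  against the method; per-class rates divide matches by matches plus every
  definitive mismatch touching the class.

The *resolution* statistic sizes the non-definitive pool additively —
morph-unknowns plus genetic non-definitives, with a doubly non-definitive
specimen contributing to both counts — matching how survey totals are
reported in the field; the union reading would give a slightly smaller pool.
Genus concordance reports per-class rates on both the genetic-row and the
morphological-column basis, since published tables mix the two.

## Composition, bootstrap and spatial structure

Genus composition is estimated over all definitive genus calls (ecotype
unknowns stay inside *Lampetra*); ecotype composition is estimated over
ecotype-classified *Lampetra* only, with `Intermediate` as its own category.
Ecotype-unknown individuals are excluded *before* resampling because they
never enter the point estimate; whether to resample before exclusion is not
specified by the field convention, and this choice keeps the bootstrap
distribution centred on the reported proportion.

`bootstrap_ci()` resamples the n individuals of a collection with
replacement — implemented as multinomial draws of the category counts, which
is the same distribution — and takes percentile intervals with
linear-interpolation quantiles. Two collections are "unstable" for a
category when their intervals fail to overlap strictly; touching intervals
count as stable.

A known limitation worth stating precisely: percentile intervals undercover
near a boundary. At n = 50 and a true proportion of 0.9, the exact coverage
of the nominal 99% interval is 0.9652, because a sample of 49/50 yields the
interval [0.92, 1.00], which cannot contain 0.9. This is a property of the
percentile method itself, not of the implementation; the test suite checks
the Monte-Carlo coverage against this exactly enumerated value.

`mantel_test()` correlates the off-diagonal entries of two distance
matrices (typically |rkm~i~ − rkm~j~| against |f~i~ − f~j~| for
per-collection WRL-allele frequencies) and permutes the rows and columns of
one matrix jointly, with the standard upper-tail add-one p-value
$p = (1 + \#\{r^* \ge r\})/(1 + n_{perm})$, 9999 permutations by default.
At n = 4 the test suite checks the p-value against exhaustive enumeration of
all 24 permutations.

## The synthetic generator

`sim_config()` fixes the study conditions the generator emulates:

* **Voucher sizes 24 WBL + 15 WRL, mean depth 3** — the pooled-sequencing
  design the scan is meant to work at.
* **Background F~ST~ 0.01** — near-zero genome-wide differentiation.
  Background loci draw an ancestral frequency from Uniform(0.05, 0.95) and
  per-ecotype frequencies from a Balding–Nichols beta. The beta divergence
  parameter is set to twice the target because the two-group Nei estimator
  applied to two independent draws averages about half the single-group
  divergence parameter; the calibration is verified by a Monte-Carlo test
  (mean per-locus estimate within 0.005 of the 0.01 target over 10,000
  loci).
* **Islands** — each island assigns all its loci one frequency pair at
  distance δ centred on 0.5, with the high ecotype chosen at random per
  island. Centring makes per-locus F~ST~ monotone in δ (tested over a δ
  grid). Within-island loci share the pair but are sampled independently;
  real islands have linkage disequilibrium, so synthetic islands are
  *easier* to average over than real ones — passing recovery tests bounds
  the method's behaviour under the stated frequency architecture, not under
  real LD, reference bias or mapping artefacts.
* **Genus markers** are simulated as fixed differences between genera, the
  pattern the assay exploits (no hybrid has been observed at these loci).
* **Missingness and label noise** — amplicon dropout 3% per call; a 45%
  larval fraction whose morphological ecotype is always unknown; a 2%
  morphological misidentification rate for definitive labels. The larval
  fraction mirrors the roughly 45% of surveyed *Lampetra* that were
  morphologically unresolvable; the error rate is of the order implied by
  observed 1–4% discordance.

Every generator function takes an explicit seed, restores the caller's RNG
state, and is byte-reproducible; ground-truth labels are emitted next to
every table and consumed only by tests.

## Problem sizes and end-to-end run

`run_pipeline()` wires the stages together on synthetic data. Its default
problem size — 8 chromosomes × 500 loci, four survey collections of
100–150 fish — is chosen so a full discovery-to-composition run completes
in under a second while still producing a multi-chromosome island
architecture, a five-SNP panel, and non-trivial concordance and composition
sections. The test suite's heavier properties use 20 replicate scans of
5 × 1000 loci (island recovery) and 1000 replicate bootstrap datasets
(coverage); these sizes give Monte-Carlo noise comfortably below the
asserted tolerances.

```{r pipeline, eval = FALSE}
res <- run_pipeline(list(seed = 3, scan = list(n_candidates = 7)))
print(res)
```

## Known limitations

* The scan estimator weights the two pools equally regardless of pool size
  or depth; depth-weighted estimators would differ at very low coverage.
* Windows are anchored at position 1, so window coordinates are
  convention-dependent near chromosome starts.
* The classifier is a counting rule, not a likelihood model; it makes no
  admixture estimate beyond the raw percent-WRL value.
* Percentile bootstrap intervals undercover near proportion boundaries (see
  above); collections that are nearly pure should be compared with that in
  mind.
* The generator does not model read errors, mapping bias, or LD beyond
  island blocks; conclusions about real sequencing data require the real
  pipeline upstream.
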