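---
title: "Recombination landscapes and hotspot detection from RIL genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recombination landscapes and hotspot detection from RIL genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rilrec)
```

## The problem

Meiotic crossovers are not spread evenly along plant chromosomes. In
soybean, recombination concentrates in the gene-rich distal euchromatin
(about 1 cM per 197 kb) and is strongly suppressed in the repeat-rich
pericentromeric heterochromatin (about 1 cM per 3.5 Mb), and even within
euchromatin it clusters into narrow *recombination hotspots*. Breeders care
because hotspot positions determine which linkage blocks can be broken.

`rilrec` turns biparental recombinant-inbred-line (RIL) SNP genotypes into
a local recombination-rate landscape and a set of hotspot and coldspot
calls, and tests those calls for association with genomic features
(transposable-element classes, gene regions) and short sequence motifs.
Because real populations come with no ground truth, the package also ships
a forward simulator of F~k~-derived RIL populations whose true landscape is
known exactly; every analysis stage is validated against it.

## The model, stage by stage

### Marker QC

Markers are filtered in the order the field uses: remove markers with
**strictly more than 10%** missing calls; remove markers whose homozygous
A:B counts reject a 1:1 Mendelian ratio in a 1-df chi-square test at
P < 0.01 (heterozygous and missing calls are excluded — the F5 residual
heterozygote frequency of 6.25% is a nuisance parameter, not evidence of
distortion); collapse markers with byte-identical call patterns, keeping
the physically first. A 2-df variant testing AA:H:BB against
0.46875 : 0.0625 : 0.46875 is available behind the `df2` flag; the 1-df
form is the default because the heterozygote class is tiny and its
expectation depends on the exact generation. Missing calls are treated as
part of the duplicate pattern, which is conservative: two markers that
differ only in a missing call carry different information and are not
merged.

### Two-point mapping and the finite-generation correction

Marker order is fixed to physical (reference) order — the analysis needs a
Marey map on the reference axis and soybean structural variation is low —
so mapping reduces to adjacent-marker recombinant fractions. For each
adjacent pair, R = discordant homozygote pairs / double-homozygote pairs.

In a selfed RIL, crossovers accumulate over generations ("map expansion"),
so R overestimates the meiotic fraction r. At fixation the
Haldane–Waddington relation R = 2r/(1+2r) applies, inverted by
`correct_ril()`. A point this package makes explicit: **for F5 lines the
fixation formula is badly biased once you condition on double
homozygosity**. Propagating the exact two-locus diplotype distribution
through four rounds of selfing (`ril_expected_R()`) shows that, among
double-homozygous F5 lines, E[R] ≈ 0.733 × 2r for small r — conditioning
selects lines that fixed early and therefore accumulated fewer
crossovers. Using the fixation inverse on F5 data under-recovers map length
by about 27%, which forward simulation confirms. `correct_ril(R,
generation = 5)` therefore inverts the exact finite-generation relation
numerically; the fixation form remains the default for backward
comparability, and the simulation-validated pipeline passes
`generation = 5`.

Distances come from the Kosambi function by default (the convention of the
mapping software this replaces) or Haldane behind a flag. The simulator
draws crossovers without interference, so Haldane is exact there and
Kosambi about 5% short at r ≈ 0.05; on dense marker panels (r < 0.01) the
difference is negligible.

### Marey maps and rate profiles

The Marey map plots cumulative genetic position (cM) against physical
position (bp); its slope, rescaled to cM/Mbp, is the local recombination
rate. Two-point noise can make the raw map locally non-monotone, so
`isotonize()` applies isotonic regression first. `fit_spline()` fits a
cubic spline, in one of three modes:

* `"interpolating"` — a natural cubic spline through every point, matching
  the behaviour of the interpolating Marey-map spline this emulates;
* `"gcv"` (package default) — a smoothing spline with generalized
  cross-validation;
* an explicit smoothing level (`spar`, or `list(df = n)`).

`rate_profile()` evaluates the derivative on a uniform 10-kb grid (below
typical euchromatic marker spacing, above the spline's wiggle scale),
clamps negative slopes to zero and records the clamped fraction as a fit
diagnostic. `window_rate()` provides the model-free "frequency metric",
ΔcM/ΔMbp per fixed physical window, which conserves map length exactly by
telescoping; the spline profile conserves it within 1% on the package's
test battery.

**Why the validated pipeline does not use GCV for peak calling.** The
two-point Marey noise is heteroskedastic (binomial counting noise whose
variance tracks the local rate) and GCV reliably undersmooths it,
producing repeated twice-background excursions under a hotspot-free null
at the benchmark scale. A fixed `spar = 0.65` — chosen in a single
six-setting design sweep (spar 0.65/0.70/0.75, df 60/100/140) and not
revisited afterwards — suppresses those excursions while preserving
planted-hotspot recovery; the acceptance tests quantify both properties
(recovery ≥ 90%, spurious calls < 0.5 per null chromosome). GCV remains
the package default for rate estimation; peak calling in the validated
configuration passes the explicit smoothing level.

### Hotspot and coldspot calling

`call_hotspots()` scans the rate grid: a point is a peak if it strictly
exceeds every rate within ±`window` grid points (default 5) **and** is at
least `min_fold` (default 2) times the background, defined as the
per-chromosome median rate of its chromatin class — euchromatin and
heterochromatin are analyzed independently because their rates differ
several-fold. Boundaries extend from the peak until the rate drops below
max(background, `boundary_frac` × peak). Because the upstream peak caller
this emulates is unpublished, all three knobs are exposed and recorded in
the output rather than hard-coded.

Uneven marker spacing skews called sizes to the right, so
`tukey_filter()` removes, within each chromatin class, records larger than
Q3 + 1.5·IQR (type-7 linear-interpolation quantiles, recorded in the
output; classes with fewer than 4 records are left alone).
`call_coldspots()` reports maximal runs below `max_frac` (default 0.2) of
the class background, of at least `min_len_bp`; since
`min_fold` × background > `max_frac` × background, hotspots and coldspots
can never overlap. All coordinates are 0-based half-open (BED), including
the rule that a peak at an interval's start belongs to that interval.
`compare_hotspots()` declares two intervals shared when they overlap by at
least 1 bp on the same chromosome.

### Feature association and motifs

`make_feature_table()` tiles the genome into 100-kb windows (near the
euchromatic median hotspot size; configurable), labels each window
hotspot / coldspot / background (hotspot precedence) and computes, per
feature class, the fraction of the window covered (presence coding is
available). `logistic_assoc()` fits logit P(status = target) = β₀ + β₁x by
binomial GLM — which *is* iteratively reweighted least squares — and
reports the Wald statistic β₁/SE with a normal reference, labelled
`wald_t`: with hundreds of windows z and t are indistinguishable, and for
a binary covariate the fitted slope equals the 2×2 log odds ratio exactly.
No multiple-testing correction is applied by default, matching the raw
P-value thresholds the analysis this reproduces reports.

The motif module is a *scan-based surrogate* for de novo discovery: it
scans the 200 bp upstream flank plus hotspot body (both flanks optional)
for two fixed motifs — a poly-A run (≥8 by default; both-strand scanning
makes it a poly-A/T motif) and the degenerate CCN-like consensus
`CNCCNCCACAACCAANNCANNA` with ≤4 mismatches at non-N positions (pattern N
matches anything, sequence N matches nothing). Enrichment is assessed
against chromatin- and length-matched background windows by label
permutation with the add-one estimator P = (1 + #{perm ≥ obs})/(1 + n~perm~),
which is valid by construction and can never return 0.

## The simulator: what it emulates and what it does not

`simulate_ril_population()` advances each line from a single F1 by
single-seed descent: per generation, two gametes are drawn from the same
individual, each with a Poisson crossover count (mean = map length in
Morgans) and crossover positions placed by inverse-transform sampling on
the exact cumulative map of a piecewise-constant landscape
(`make_landscape()`: chromatin-class backgrounds plus rectangular hotspot
plateaus — rectangles keep the cumulative map exactly invertible; a
triangular bump would be the obvious alternative). Genotypes are read off
at marker positions with residual heterozygotes retained (DNA comes from
single F5 plants), missingness injected i.i.d., and segregation distortion
modelled as a gamete-level viability weight at named loci — the mechanism
the QC chi-square filter is meant to catch. A single seed drives every
draw and is recorded in the truth object; identical seeds reproduce the
genotype matrix byte-for-byte.

Deliberately not modelled: crossover interference (downstream methods are
interference-agnostic and the emulated study gives no interference data),
genotyping error beyond missingness, and selection other than
locus-specific distortion. A green simulation test therefore establishes
that the pipeline recovers landscapes *of this idealized form*; it cannot
certify behaviour under interference, clustered genotyping error, or
assay-specific artefacts.

Default simulation conditions mirror the emulated study where stated
(F5 by SSD, ~1,000 lines, SNP-array-like biallelic calls, euchromatic
1 cM/197 kb vs pericentromeric 1 cM/3.5 Mb). Where it is silent, values
were fixed once at field-realistic levels: 200-kb hotspots at 10× the
euchromatic background (near the reported euchromatic mean hotspot size),
25-kb marker spacing (the reported euchromatic median spacing range), and
a central pericentromeric block spanning 40% of each chromosome.

## The simulation benchmark

The validation gate (in `tests/testthat/test-acceptance.R`) simulates a
2 × 20 Mbp genome with four planted 200-kb, 10× hotspots, 1,000 F5 RILs
and 25-kb markers, 20 seeds, and requires ≥90% of planted hotspots
recovered with peak error within one half-width, plus fewer than 0.5
called hotspots per chromosome across 20 matched hotspot-free null seeds.
Companion gates check the closed-form oracles (Haldane–Waddington
inversion to 1e-12, mapping-function formulas, F5 heterozygosity 6.25%,
chi-square vs exact-binomial decisions, type-7 Tukey fences, GLM slope =
log odds ratio), map-length conservation of both rate estimators on 100
random landscapes, and 3–7% empirical size at nominal 5% for both the
logistic Wald test and the permutation enrichment test under their nulls.

## Numerical choices and degenerate inputs

* Observed R is capped at 0.4999 before correction so distances stay
  finite; adjacent markers on a dense panel are far from the cap.
* `correct_ril`'s finite-generation inverse is solved by `uniroot` to
  1e-10 on unique R values (two-point fractions repeat heavily).
* Chi-square distortion tests with fewer than 2 informative calls remove
  the marker as "uninformative" rather than emitting NaN.
* Duplicate marker physical positions are rejected at construction;
  duplicate Marey x-values are collapsed before spline fitting.
* Perfect separation in the GLM is flagged (`separation`) and the P-value
  withheld instead of reporting a meaningless Wald statistic.
* Flat rate profiles yield empty hotspot sets, not errors; single-marker
  chromosomes yield a 0-cM point map with a warning.

## Known limitations

* The finite-generation correction assumes the stated generation is exact
  and every line descends by strict SSD; mixtures of generations bias r
  accordingly.
* Physical marker order is trusted; a misassembled reference would smear
  true hotspots rather than relocate them.
* Hotspot "size" is the called interval at the grid resolution, not the
  distance between flanking markers; in sparse heterochromatin the
  interval can substantially exceed the underlying feature.
* The motif scanner tests two fixed motifs; it cannot discover new ones,
  and mismatch budgets trade sensitivity against specificity in a way the
  enrichment P-value inherits.
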