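---
title: "Inferring tumour clonality from Confetti lineage tracing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring tumour clonality from Confetti lineage tracing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyclone)
```

## The scientific problem

In mouse intestine carrying a multicolour Cre reporter (Confetti), a small
fraction of crypts is stochastically and permanently labelled with one of
several fluorophores. A tumour founded by a single labelled crypt lineage is
*homotypic* (one colour); a tumour showing two or more colours, or one colour
together with unlabelled glands, is *heterotypic* — microscopy's proxy for a
polyclonal origin. Three quantitative questions follow, and this package
implements the machinery for all of them:

1. **Labelling statistics.** At the observed per-colour frequencies, how are
   coloured crypts distributed into contiguous same-colour patches, and what
   fraction of crypts is labelled at all?
2. **Collision nulls.** Could heterotypic tumours simply be independent
   tumours that collided? This needs an analytic expectation, spatial-density
   diagnostics, and a growth-aware Monte-Carlo simulation.
3. **Clonal composition from sequencing.** Given amplicon variant calls, how
   many independent inactivating *Apc* mutations does a tumour carry, which
   clone is major and which minor, what is the tumour purity, and do major
   and minor clones differ in where along the APC protein they truncate?

A synthetic cohort generator with recorded ground truth backs every stage, so
the full pipeline is testable without any external data.

## Confetti labelling and patch statistics

`simulate_labelling(rows, cols, freqs, seed)` draws i.i.d. per-crypt labels on
a rectangular field (the reference field is 10 × 100 crypts) with per-colour
probabilities `confetti_freqs()` = CFP 2.7%, YFP 4.1%, RFP 3.8% (GFP kept in
the alphabet at frequency 0, since nuclear GFP is rarely scored); the
remainder is unlabelled. The expected labelled fraction is the sum,
10.6%.

`find_patches()` partitions labelled cells into maximal connected same-colour
components via a union–find scan. Two deliberate choices:

* **Connectivity 4 by default.** "Contiguous" is ambiguous; von Neumann
  adjacency is the conservative reading. 8-connectivity is available by flag.
* **Hard edges.** The field is a flat sheet of crypts, not a torus; no
  wrap-around.

`patch_size_summary()` tabulates, per fluorophore, the number of patches of
each size and the fraction of coloured crypts residing in patches of that
size (fractions sum to 1 per colour). For a 1 × N field with colour
probability p the expected number of patches has the closed form
`N·p − (N−1)·p²`, which the tests use as an oracle.

`score_confetti_status()` encodes the microscopy rule: heterotypic if at
least two colours, or one colour in the presence of unlabelled glands;
colours represented by a single intermixed gland are disregarded first (they
most probably are entrapped normal crypts). `heterotypic_fraction()` uses
coloured tumours only as its denominator, matching how the homotypic/
heterotypic split is quantified.

## Collision null models

### The analytic approximation and its domain of validity

For `n` adenomas of width `x` crypts in a one-dimensional arrangement of `y`
crypts, the number of inter-adenoma spacings shorter than `x` is treated as
binomial with per-spacing probability

> P = 1 − exp(−n·x/y),

giving expectation `n·P` and variance `n·P·(1 − P)`
(`collision_probability()`, `expected_collisions()`).

For *finite* n the exact law of one spacing of n uniform points on a circle
is `1 − (1 − x/y)^(n−1)` (`exact_spacing_probability()`). The exponential
form is its large-n limit: the absolute error of `n·P` is ≈ ρ·e^(−ρ) with
ρ = n·x/y, *independent of n*, while the Monte-Carlo standard error of a
placement simulation scales as √(nρ)/√reps. The approximation is therefore
validated where it is meant to apply — segments of ~3·10⁵ crypts carrying
thousands of adenomas (ρ between 0.02 and 0.2) — and the simulator itself is
unit-tested against the exact closed form at small n, where the two formulas
visibly differ.

`brute_force_collisions()` offers two distributionally identical samplers:
direct uniform placement with sorting, and the Dirichlet representation of
circular spacings (`gaps`, the default) which draws the spacing vector as
`y·E_i/ΣE` with `E_i` i.i.d. exponential — O(n) per replicate, making 10⁵
replicates at n = 24,000 affordable. A test cross-checks the two samplers.

### Growth-based simulation

`simulate_growth_collisions()` emulates tumour growth from initiation:
founder points are placed uniformly in a segment rectangle, each with a
Confetti label drawn at the observed frequencies and a per-day exponential
growth rate sampled with replacement from an observed-rate vector; discs of
radius `r₀·exp(rate·t)` grow until the humane-endpoint day; transitively
overlapping discs merge into clusters (connected components of the overlap
graph, hence order-independent); each cluster is scored by the same
microscopy rule applied to its founder labels. Uncoloured–uncoloured
collisions form clusters but are never scored heterotypic — they are
invisible to the microscope, exactly as in the experimental readout.
Defaults: 10,000 seeds per segment; founders either a fixed count or a
Poisson draw (both initialisation conventions are plausible readings, so it
is a config switch). Exponential growth is applied over the whole simulated
interval; late-phase plateaus are deliberately not modelled in the null — a
documented limitation that makes the null generous to collisions (larger
discs, more overlap).

`compare_observed_expected()` is the paired two-tailed t-test of per-segment
observed versus expected heterotypic counts, with the zero-variance
degenerate case (t = 0, p = 1 when means agree) handled explicitly.

### Spatial density diagnostics

`local_density_field()` evaluates a Gaussian kernel density of the tumour
point pattern at each tumour location (leave-self-in; bandwidth defaults to
the mean of the per-axis Silverman rules). `heterotypia_density_test()`
compares densities at heterotypic versus other tumours by a two-sample
Kolmogorov–Smirnov test plus matched Q–Q quantiles;
`density_fraction_regression()` regresses per-segment heterotypic fraction
on mean density and reports the adjusted R², the statistic whose
near-zero/negative value argues against a density-driven origin of
heterotypia.

## Variant filtering and clonality calling

`filter_params()` carries the amplicon filter: minimum VAF 0.01, at least 5
mutant reads, calls in at least 2 amplicons, indels removed (ENU causes
almost exclusively single-nucleotide variants). *Apc* codons 73–84 and
122–139 are covered by a single amplicon, so calls there can never satisfy
the two-amplicon rule; `filter_amplicon_variants()` routes them to a
`review_flagged` table when they have ≥ 5 mutant reads and VAF strictly
above 0.01 — the automated form of the manual-inspection rule —
and `accept_flagged = TRUE` folds them into the retained set. The package
default is `FALSE` (surface them for review), but full-protocol analyses,
including the package's own ground-truth recovery checks, run with the flag
on; otherwise a genuine major clone falling inside a window is silently
lost. `filter_longread_variants()` implements the separate long-read
thresholds (nonsense-only, VAF ≥ 0.02, depth ≥ 100).

`classify_clonality()` counts inactivating (nonsense-only) *Apc* mutations:
one → monoclonal, two or more → polyclonal, none → no driver. Clones are
ranked by descending VAF with codon as the deterministic tie-break; all
clones within `tie_delta` (default 0.02, configurable) of the maximum are
co-major and flag the call — at typical depths the binomial noise of a VAF
is ~0.015, so closer ranks are not honestly resolvable. Purity is
`min(1, 2·ΣVAF)`: each founder mutation is heterozygous in its clone and
clone fractions sum to one, so the summed VAF estimates half the tumour-cell
fraction. `purity_from_vafs()` also offers the `2 × mean VAF` convention
used for whole-genome cellularity.

## Domain bins and the stratified bootstrap

`apc_domain_bins()` provides half-open codon bins over the 2,842-aa mouse
APC protein: Pre-Armadillo [1,453), Armadillo [453,767), inter-domain
[767,1020), 15-aa repeats [1020,1170), the 20-aa repeats containing the
mutation cluster region [1170,1530), and the C-terminus including the
EB1-binding region [1530,2843). The source figures do not print their bin
boundaries, so these follow the standard APC domain literature and are fully
overridable (`domain_bins()`); the recombination-event anchor at codon 580
falls in Armadillo, as expected. A sample mutated in several bins
contributes an indicator to each such bin — probabilities are per-sample
indicator means (`bin_probabilities()`), not a multinomial over mutations;
the per-mutation alternative can be built from the clone table directly.

`bootstrap_diff_ci()` computes percentile confidence intervals for per-bin
probability differences via a stratified non-parametric bootstrap:
independent mode resamples each group within its own stratum (monoclonal
versus major, monoclonal versus minor); paired mode resamples whole
major–minor tumour pairs, preserving their dependence. Defaults B = 10,000
and level 0.95 (the source states the level only); the calibration tests use
B = 2,000 for runtime. `group_samples()` wires clonality calls into these
group indicator tables: each polyclonal tumour contributes its top-VAF clone
as major and its second-ranked clone as minor under a shared `pair_id`.

## Growth dynamics and pseudo-bulk mixtures

`fit_exponential_growth()` models log size inside the exponential window
(days 40–63 post-ENU by default) as a group main effect plus per-group slope
with a zero-mean random intercept per mouse, fitted by REML (`nlme::lme`).
Only a random intercept is used — mouse identity is the only named random
term — and on degenerate inputs (zero residual variance) the fit falls back
to a fixed-effects regression with mouse indicators, which recovers slopes
exactly in the noise-free case. The reported contrast is the
heterotypic/homotypic slope ratio; size may be area or diameter, since units
only shift the intercept on the log scale.

`mix_pseudobulk()` rebuilds a polyclonal tumour's expression profile from
its dissected clones: `⌈2D/3⌉` reads drawn multinomially from the major
clone's gene proportions and `⌊D/3⌋` from the minor clone's (2:1 by
default), summed per gene, so the pseudo-sample has exactly depth `D` and
expected proportions `(2/3)·p_major + (1/3)·p_minor`. Sampling gene-count
columns is distributionally equivalent to sampling raw reads for counting
purposes.

## The synthetic cohort generator

`cohort_config()` fixes the study conditions; `gen_tumour_field()`,
`gen_variant_table()`, `gen_growth_series()`, `gen_domain_mutation_cohort()`
and `gen_count_matrix()` generate every downstream input with recorded
ground truth. What it emulates, and the choices behind the defaults:

* **Tumour field**: homogeneous spatial Poisson process per segment
  (intensity 0.03/mm² over 60 × 10 mm segments, 7 segments × 5 mice — a
  high-multiplicity mutagenised cohort); founder labels drawn independently
  at the Confetti frequencies; Confetti status derived from founder labels
  by the same scoring rule used for real tumours.
* **Founders per polyclonal tumour**: truncated geometric (p = 0.5) on 2–9.
  Only the observed 2–9 range is documented; a geometric start reflects that
  two-founder tumours dominate.
* **Clone fractions**: symmetric Dirichlet with concentration 5 — clones of
  broadly comparable size, matching the fact that minor clones are large
  enough to micro-dissect and to show measurable, divergent VAFs. Heavier
  tails (concentration ≤ 1) would instead posit many sub-detection clones,
  which the amplicon data do not show.
* **Reads**: for a clone of fraction f in a tumour of purity ρ, the true VAF
  of its heterozygous mutation is f·ρ/2 (so summed VAF = ρ/2, reconciling
  the summed-VAF statistic with the 2 × VAF cellularity convention);
  observed alt reads are Binomial(depth, f·ρ/2) at depth 500; purities are
  uniform on [0.4, 0.9] (bulk-dissected material carries stroma).
  Background error calls arise at 10⁻³ per panel codon with few supporting
  reads, and are almost entirely removed by the filters.
* **Growth series**: log-linear growth with per-mouse Normal random
  intercepts and Normal measurement noise; both groups share the expected
  size at the first window day.
* **Seeding**: one cohort seed expands into fixed per-stage substreams, so
  stages are individually reproducible.

What it deliberately does **not** emulate: spatial correlation of crypt
labels (patch-forming drift in real epithelium), copy-number events (the
ENU model is copy-number sparse), caller-specific artefact spectra beyond a
flat error rate, amplicon dropout, plateauing late growth, and any
transcriptional structure beyond Dirichlet-multinomial counts. Passing
recovery tests on this cohort therefore demonstrates the statistical
machinery under the stated read-sampling model, not robustness to every
real-data pathology.

## Numerical choices and degenerate inputs

* Codons are 1-based inclusive throughout; bins are half-open `[start, end)`.
* VAF thresholds compare inclusively (`vaf ≥ min_vaf`) except the
  single-amplicon review rule, which requires strictly "more than 0.01".
* Near-equal VAFs (|Δ| < 0.02) give co-major ties, deterministically ordered
  by codon; the threshold is configurable.
* Zero-variance paired t-tests return t = 0, p = 1 (equal means) rather than
  erroring; empty denominators (no coloured tumours, empty VAF sets, empty
  groups) are signalled, not silently zero.
* All simulation functions accept explicit seeds and restore the caller's
  RNG state; identical config + seed reproduces outputs bit-for-bit.
* Problem sizes in the package's own checks: 1,000 grids of 10 × 100 crypts
  for labelling statistics; 10⁵ placement replicates per collision geometry
  (n up to 24,000 at ρ ≤ 0.2); ~200 tumours at depth 500 for clonality
  recovery; 500 replicate cohorts at n = 94/group with B = 2,000 for
  bootstrap calibration; 500 replicates of 30 tumours/group × 4 timepoints
  for growth-ratio recovery; 1,000 replicates (50 vs 150 samples) for the
  KS size check — sizes chosen so each Monte-Carlo check has standard error
  well below its tolerance.

## Worked example

```{r example, eval = FALSE}
library(polyclone)

cfg <- cohort_config(n_mice = 3, rng_seed = 42)
field <- gen_tumour_field(cfg)
calls <- gen_variant_table(field$truth, cfg)

retained <- filter_amplicon_variants(calls, accept_flagged = TRUE)$retained
cohort <- classify_cohort(retained)
table(cohort$samples$class)

samples <- group_samples(cohort)
bootstrap_diff_ci(samples[samples$group == "monoclonal", ],
                  samples[samples$group == "minor", ],
                  B = 2000, seed = 1)

fit_exponential_growth(gen_growth_series(seed = 7))
```

## Known limitations

* The analytic collision formula is used exactly as stated (exponent n, not
  n − 1); at small adenoma counts it overestimates collision probabilities,
  which is why the package also ships the exact finite-n form.
* Purity estimation ignores copy number; in copy-number unstable genomes the
  2 × VAF conventions are biased.
* The growth null assumes isotropic disc growth in 2-D; real tumours deform
  around each other.
* Bootstrap intervals are percentile intervals; no BCa correction is
  applied, consistent with the stated method.
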