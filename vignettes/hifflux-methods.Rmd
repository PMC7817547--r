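---
title: "Methods: HIF fine-mapping interval algebra and 15N flux bookkeeping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HIF fine-mapping interval algebra and 15N flux bookkeeping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hifflux)
```

# Scope

`hifflux` implements the computational machinery of a classical
quantitative-genetics workflow in *Arabidopsis thaliana*: fine mapping a
leaf-senescence QTL with a heterogeneous inbred family (HIF), and the
isotope bookkeeping of ¹⁵N pulse-labeling experiments used to quantify
nitrogen remobilization and uptake in the same material. Everything is
testable without external data because the package ships forward simulators
of both experimental designs with known ground truth.

# Fine-mapping model

## Genetic material

A HIF descends from a recombinant inbred line that is still heterozygous
over one residual genomic region; sibling plants fixed for the two parental
alleles are near-isogenic everywhere else, so a phenotypic difference
between them localizes the QTL to the residual region. Selfing the
heterozygous plant and genotyping the progeny over the region yields
recombinant lines (rHIFs) whose crossovers dissect the region.

## Breakpoints are intervals, not points

Genotyping resolves marker *states*, so a crossover is only known to lie
between the two nearest informative markers whose states differ.
`infer_breakpoints()` therefore reports each breakpoint as an uncertainty
interval; missing (`U`) calls widen it to the flanking informative markers.
A recombinant (`detect_recombinants()`) is a line with at least one state
transition inside the region — a line uniformly heterozygous across the
region carries no transition and is not a recombinant.

## Segregation testing

Each recombinant is scored by fixed-progeny testing: progeny fixed for the
two parental alleles at the line's residual heterozygous interval are
phenotyped and compared. `progeny_test()` uses a Welch two-sample t test.
The experimental literature this emulates names two-sample t tests but no
significance level, so `alpha = 0.05` is the package default and is
exposed everywhere. Groups with fewer than two values give an
`inconclusive` verdict; zero-variance degenerate groups are decided on
their means.

## Interval refinement

`refine_candidate_interval()` performs the interval algebra of the
campaign. Coordinates are 1-based bp; intervals are closed on marker
positions; width is `end − start`, which reproduces published interval
widths computed from printed marker bounds exactly (e.g.
8,298,328 − 8,290,453 = 7,875 bp). The candidate region is

> prior ∩ (⋂ het intervals of segregating lines) ∖ (⋃ open interiors of
> het intervals of non-segregating lines)

with bounds snapped outward to marker positions. Two deliberate choices:

* **Open-interior subtraction.** A non-segregating line excludes the causal
  locus from the *interior* of its het interval, but the QTL can sit at a
  bound marker shared with a segregating line, so bound markers survive
  subtraction (possibly as width-0 degenerate candidates).
* **Conflicts are reported, never dropped.** A segregating line disjoint
  from the surviving region is listed in `conflicts`; if nothing survives,
  a classed inconsistency error names the lines. Real campaigns contain
  phenotyping errors and the algebra must not hide them.

The brute-force oracle used in the test suite enumerates every atomic cell
of the marker grid (marker points and open inter-marker gaps) and keeps the
cells consistent with every call; the algebra agrees with this scan on
1,000 random instances per test run.

## Het-interval conventions in the campaign driver

`run_finemap_campaign()` assembles per-line het intervals from genotypes:

* **Segregating lines** contribute their *wide* span — from the informative
  homozygous marker flanking the first `H` call to the one flanking the
  last. The causal locus is somewhere in the true het region, which
  genotyping bounds only at the flanking homozygous markers, so the wide
  span is a sound superset.
* **Non-segregating lines** contribute each maximal `H` block separately
  (`het_blocks()`), and only the open interior of each block is subtracted.
  A double recombinant carries two het blocks; the homozygous gap between
  them is *not* evidence against the causal position, so subtracting the
  span across blocks would be wrong (and empirically empties the region).

## Verdicts in a multi-line campaign

A campaign tests tens of truly non-segregating lines. With a plain
`p < alpha` rule at `alpha = 0.05`, about one line in twenty would be
falsely declared segregating, and each false positive excises the causal
position from the candidate region — the campaign-level recovery rate
would collapse. The driver therefore also requires the progeny-class
difference to reach `min_effect` (default half the allelic effect), the
natural analogue of requiring a difference commensurate with the known
parental HIF contrast before accepting a line as segregating. With the
default power settings (class difference 0.2, noise sd 0.05, 12 plants per
class — three fixed plants per allele with four replicates each), both the
false-positive and miss rates of the guarded verdict are below 1e-5 per
line, and 200 simulated campaigns recover the causal position in ≥ 99% of
runs.

## Known limitation: invisible het segments

At genotyping resolution, a het segment produced by a double crossover
within one inter-marker interval is invisible (both flanking markers
homozygous). The driver models fixed-progeny selection at the *markers*,
so such segments keep segregating inside both fixed classes and produce a
non-segregating verdict — correct behavior, but the mirror case (a line
homozygous at the causal position yet heterozygous at both flanking
markers) remains undetectable and can, rarely (~0.2% of campaigns at the
default 25-marker grid), exclude the true position. Real campaigns resolve
this by adding markers; the simulation reports it as an uncovered campaign.

## Crossover model

Gametes are simulated under the Haldane map function,
`r = (1 − exp(−2d))/2` with `d` in Morgans, independently across intervals
(no interference) — the simplest defensible meiosis model. The default
3 cM/Mb is of the order implied by the published screen (77 recombinants
among 276 selfed progeny over 5.9 Mb); at that rate the simulator detects
≈ 82 recombinant progeny per screen because marker-level transitions also
reveal double crossovers that leave the region's endpoints intact. The
realized rate differs substantially between the two published screens, so
the rate stays a free parameter rather than a fitted constant.

# ¹⁵N flux bookkeeping

## Formulas

All mass units are mg internally; enrichment and allocations are
dimensionless fractions; percents appear only at the I/O boundary (this
avoids the ×100 ambiguity in formulas written as `DW × N%`):

* atom percent `A% = 100 · ¹⁵N/(¹⁵N + ¹⁴N)`;
* enrichment `E = (A%_sample − A%_control)/100`;
* `QtyN = DW · N%/100`, `Qty¹⁵N = QtyN · E`;
* `HI = DW_seeds / (DW_rosette + DW_stem + DW_seeds)`;
* N and ¹⁵N allocation per organ = organ share of the summed quantities;
  `NHI` and `¹⁵NHI` are the seed shares;
* `NRE = ¹⁵NHI / HI` (may exceed 1: tracer routed to seeds more
  efficiently than biomass);
* `NUpE = (Σ Qty¹⁵N / E_solution) / Σ DW`, in mg N g⁻¹ DW per 24-h pulse.

## Parameter choices

* `a_control = 0.3660` atom percent (the natural-abundance control of the
  emulated instrument setup); measured control samples in the input table
  override the constant.
* `E_solution` defaults to `(10 − 0.3660)/100 = 0.09634`: the labeling
  solution is 10 atom percent, and the enrichment in the NUpE denominator
  is taken as a *fraction* above natural background. The source formula
  writes "/E%" without fixing units; a percent instead of a fraction
  rescales NUpE 100-fold, so the choice is explicit and configurable.
* Negative enrichment within `tol = 1e-4` atom percent of the control is
  clipped to 0 (instrument noise at natural abundance); larger deficits
  are kept and flagged, never silently clipped.
* NUpE follows the shoot-based printed formula (rosette + stem +
  seeds/silique); roots are excluded by default even when harvested, with
  `include_root` available.
* In post-flowering uptake experiments the silique plays the seed role and
  is reported under the `seeds` columns.
* Undefined ratios (zero total tracer or N) are returned as `NA` with a
  flag string — NaN never propagates.

## Labeling simulator

`simulate_labeling_dataset()` draws organ dry weights lognormally around
genotype means (mean-preserving parameterization), splits a fixed tracer
mass across organs by Dirichlet shares around the true shares, and
back-computes each organ's atom percent so the analysis formulas invert the
generator exactly at zero noise. Measurement noise is multiplicative
lognormal on dry weight and N percent and additive Gaussian on atom
percent, qualitatively matching elemental-analyzer behavior; no error
model is published for the emulated data. Remobilization defaults (organ
means 60/15/25 mg, seed tracer share 0.5) give truth `HI = 0.25` and
`NRE = 2.0`; at 10% CVs the mean analyzed NRE over 500 plants is within
2% of truth (ratio statistics carry an O(CV²) bias that stays inside that
band).

## Genotype contrasts

`genotype_contrast()` wraps the conventional analysis stack: a
fixed-effects `aov(value ~ experiment + genotype)`, Tukey HSD on the
genotype term, least-square means via **emmeans** (adjusting genotype
means for experiment batch), and unpooled pairwise Welch t tests. The
compact letter display uses the insert-and-absorb algorithm ordered so the
highest adjusted mean gets letter `a`; it is implemented in the package
because no letter-display helper is among the package's dependencies.

# Senescence kinetics

`senescent_leaf_fraction()` scores whole leaves as yellow or not against
the leaf count at bolting. `assign_leaf_group()` applies the fixed pooling
windows OL 1–10, ML 11–20, YL 21–30, NL ≥ 31. `detect_senescence_onset()`
declares onset at the first observation after the series maximum that has
dropped by at least `drop_threshold` of the maximum for `k_consecutive`
successive observations; onset before flower-bud emergence is sequential
senescence, at or after it monocarpic. The emulated study never
quantifies "start of decrease", so the defaults `drop_threshold = 0.05`
and `k_consecutive = 2` were chosen for robustness to single-measurement
noise and are configurable. Onset is invariant under uniform rescaling of
the chlorophyll index because the threshold is relative to the observed
maximum.

The chlorophyll simulator rises logistically to a rank-dependent plateau
and declines linearly from a programmed day; the reported truth onset is
the first sampled day of decline (the estimand of the detector). At 2%
noise the detector recovers the programmed onset within one sampling
interval in well over 95% of series; at zero noise recovery is exact.

# Problem sizes and numerical choices

The test suite and the acceptance script run, by choice, at the scale of
the emulated study: screens of 276 progeny on a 25-marker grid,
200-campaign recovery experiments, 1,000-instance oracle comparisons,
500-plant labeling cohorts, and 250 noisy chlorophyll series. Allocation
identities are asserted to 1e-9; exact interval arithmetic is asserted
exactly. All simulators take explicit seeds and restore the caller's RNG
state; identical configurations produce byte-identical tables.

# What the simulations do and do not show

The generators emulate the *designs* (selfing meiosis over one region,
additive biallelic QTL with Gaussian noise, organ-level tracer
partitioning, piecewise chlorophyll kinetics). They do not model epistasis,
genotyping error, segregation distortion, interference, instrument drift,
or biological correlations between organ sizes and tracer shares. Passing
recovery tests therefore demonstrates the correctness and calibration of
the *analysis machinery* under the stated designs, not the biological
conclusions of any particular experiment; the published genotype-contrast
patterns themselves are not reproducible at desk scale because the
underlying raw data are not deposited.
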