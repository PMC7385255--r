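---
title: "Methods: seasonal structure of size-fractionated bacterial communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seasonal structure of size-fractionated bacterial communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sizeseason)
```

## The problem

Sequential filtration of seawater through a ladder of pore sizes (0.2–0.8,
0.8–3.0, 3.0–5.0, 5.0–10, 10–20 and 20–200 μm) partitions the bacterial
community along the particulate-matter continuum, from free-living cells
in the smallest fraction to communities attached to large particles in the
biggest. When such a six-fraction scheme is sampled monthly over two
years, several questions become quantitative: how does diversity partition
within and among fractions over the year, how strongly does each
fraction's community turn over seasonally, which taxa keep their
size-fraction preference and which shift it, and which environmental
variables track the community's annual cycle. This package implements
that analysis chain end to end, together with a seeded generator of
synthetic surveys so every stage can be validated without sequence data.

## Preprocessing

The input is an integer OTU × sample count table with per-sample date and
size-fraction metadata and per-OTU ranked taxonomy. The standard chain is

1. `filter_taxa()` — remove OTUs whose lineage contains chloroplast,
   mitochondria or eukaryota (case-insensitive substring on any rank);
2. `filter_min_total()` — remove OTUs with fewer than 5 reads summed over
   *all* samples (strict less-than: a total of 4 goes, 5 stays);
3. `rarefy_counts()` — exact without-replacement subsampling of every
   sample to a common depth, by default the global minimum (1,000 reads in
   the original survey design). A seed is mandatory; the subsampling is
   delegated to `vegan::rrarefy()`;
4. `aggregate_taxonomy()` — sum counts per taxon at a chosen rank
   (empty entries become "Unclassified"), then convert to percent. A
   `mixed_rules` list supports dominance tables whose groups span ranks
   from phylum to genus;
5. `select_abundant()` — keep groups exceeding 1 % (strict) in at least
   one sample of any fraction; pool the rest as "Other bacteria". The
   threshold is applied per sample, before any averaging: that is the most
   literal reading of "at least once, in at least one size-fraction", and
   it is the order we document because the alternative (after
   year-averaging) is not stated anywhere;
6. `month_average_cube()` — average percent compositions over years into
   x(g, f, m), group × fraction × calendar month. Averaging happens on
   proportions, not counts, because the published per-month profiles are
   explicit two-year averages of relative abundances; June contributes
   three observations in a 25-month June-to-June design.

Dates are folded onto a fixed 365-day calendar (29 February → ordinal 59)
so that all years share the harmonic model's period.

## True alpha, beta and gamma diversity

For each sampled month the six fractions form a community set.
`partition_month()` computes the multiplicative partition at diversity
order 0 (richness): alpha is the mean per-fraction OTU richness, gamma the
richness of the pooled counts, and beta = gamma/alpha, ranging from 1
(identical fractions) to the number of fractions (fully disjoint). We use
richness, not a general Hill number, because the quantities of interest
are defined as "average richness" and "total richness"; an
abundance-weighted generalization would be a straightforward extension
point but is deliberately out of scope. Partitions are computed on the
rarefied table so richness is depth-comparable. The identity
beta × alpha = gamma holds to machine precision in every output row and is
asserted by the tests.

## Bray–Curtis structure

`bray_curtis()` is Σ|a−b| / Σ(a+b); `bc_distance_matrix()` computes all
pairwise distances (via `vegan::vegdist`, cross-checked in the tests
against the scalar formula). Two summaries target specific scientific
displays:

- `reference_trajectory()` — for each fraction, the distance between the
  reference month's sample and the same fraction at every other date. The
  reference defaults to the maximum-gamma month, the "most diverse
  sample" criterion; in the original survey that was January of the
  second winter. Larger fractions are expected to show larger
  trajectories when seasonal turnover grows with particle size.
- `period_composition()` — mean percent composition per group and
  fraction in the warm (May–October) and cold (November–April) periods,
  the two regimes of the temperate annual cycle.

Community-level distances are computed on the rarefied OTU table, not the
group table; group tables serve only for composition summaries. That
split mirrors standard practice: ordination-level analyses use the finest
units, compositional bar summaries use the dominance groups.

## The Heterogeneous Distribution Index

For each group g the annual-mean profile A(g, f) is the mean over the 12
calendar months of x(g, f, m). The monthly HDI is the L1 deviation from
that profile,

HDI(g, m) = Σ_f |x(g, f, m) − A(g, f)| ,

in percentage points. Row means give each group's annual HDI, column
means over groups the monthly community HDI, and the mean of the row
means the grand average — the layout of the published dominance table,
reproduced by `write_hdi_tables()`.

Two documented subtleties:

- The index is 0, not 1, when all monthly distributions equal the annual
  profile. A published verbal gloss describes identical distributions as
  yielding 1, but that is inconsistent with the stated construction and
  with the table's own observed minimum (0.7); we implement the
  procedural definition. Consequently HDI is positively homogeneous
  (scaling a group's abundances by c scales its HDI by c), which the
  property tests assert.
- Months with unobserved (fraction, month) cells contribute only observed
  fractions, and `n_obs` is reported so users can filter sparse cells.

The implementation is vectorized; an independent brute-force loop over
the definition is kept in the test suite and the two must agree to 1e-12
on randomized cubes. The published 17-group monthly table ships as a
plain-text reference fixture (`hdi_reference_table()`); our aggregation
reproduces its printed row averages after one-decimal rounding for 16 of
17 groups and both printed grand-average paths (3.9). The single
exception (Deferribacteres, recomputed 5.2 vs printed 5.3) is a
printed-precision artifact of the source table, whose averages were
evidently computed on unrounded values.

## Harmonic regression

Seasonal series are fitted to Y = b1 + b2·cos(2πt/365 + b3) with t the
ordinal date: b1 is the annual mean, b2 the amplitude and b3 the phase in
radians. The phase is glossed in the source literature as "the ordinal
date of the annual maximum"; since the equation uses it inside a cosine,
we fit b3 in radians and report the derived peak ordinal
((−b3)·365/2π mod 365) separately, exposing both representations.

`fit_harmonic()` uses `minpack.lm::nls.lm` (Levenberg–Marquardt) from 12
equally spaced phase starts with b1 = mean(y) and b2 = half the data
range, keeping the best converged start (tolerances 1e-10, max 500
iterations per start) — the cosine's likelihood has period-2π local
optima, and a single start is not reliable on short noisy series.
Standard errors come from the Gauss–Newton Hessian JᵀJ at the optimum
scaled by RSS/(n−3); the 95 % band is a delta-method band with a
t-quantile on n−3 degrees of freedom (the uncertainty method behind the
original figures is unstated; this is the standard nonlinear-regression
choice). Fits are canonicalized to b2 ≥ 0, b3 ∈ (−π, π]; a fitted
amplitude below numerical noise is flagged non-identifiable rather than
given a meaningless peak date. A 25-point noiseless series is recovered
to better than 1e-6 in all three parameters, and at noise of 10 % of the
amplitude the ±2·se intervals cover the truth in ≥ 90 % of seeded
replicates — both asserted in the tests. `fit_all()` fits several series
and sorts them by peak date (stable, name-ordered ties), reproducing the
seasonal-succession ordering: day length (June) → SST (August) → beta →
gamma → alpha.

## PERMANOVA and bioenv

`permanova()` is a from-scratch single-factor implementation:
SS_total = Σ_{i<j} d²_ij / n, SS_within analogously within levels,
pseudo-F = (SS_between/(k−1))/(SS_within/(n−k)), and
p = (1 + #{F* ≥ F})/(1 + n_perm) under seeded label permutations — the
observed statistic is a member of its own reference set, so p is never 0
and never below 1/(n_perm+1). The tests check the sums of squares against
a brute-force double loop, the R² and F against `vegan::adonis2`, the
null rejection rate at α = 0.05 against its exact binomial interval over
500 simulations, and the complete-separation case (identical samples
within groups) for R² = 1 at the permutation floor. Only single-factor
tests are provided: the survey's three questions (size-fraction, month,
warm/cold cluster) are three separate one-factor tests, and sequential
multi-factor partitioning would add complexity without addressing them.

`bioenv_search()` standardizes each environmental variable (z-score; so
the search is invariant to affine rescaling), excludes constants, and
exhaustively scores every variable subset up to `max_subset` by the
Spearman (optionally Kendall) correlation between community distances and
Euclidean distances on the subset, reporting the best subset per size and
overall. It is cross-checked against `vegan::bioenv`.

The published survey statistics (PERMANOVA R² = 0.279/0.275/0.095 at
n = 120; directional correlations r = −0.92 and −0.82) require the
deposited sequence dataset (NCBI PRJNA345534) and are therefore not
recomputed here; `study_reproduction_notes()` documents the exact calls
for users holding that data. The directional r values additionally come
from a constrained-ordination axis, which is outside this package's
scope.

## The synthetic generator

`simulation_design()` fixes the study conditions: 25 mid-month samplings
(June 2011 – June 2013), the six canonical fractions, 17 named dominant
groups plus a rare pool, read depths uniform in [1,000, 20,000] (the
survey's rarefaction floor as the lower bound), latitude 41.67°N, and a
Dirichlet-multinomial count model. Choices the source material does not
quantify were fixed once on field-realism grounds and not revisited:

- **Noise model.** Counts are Dirichlet-multinomial with a single scalar
  concentration (default 200): amplicon data are overdispersed relative
  to multinomial sampling, and one concentration parameter is the
  simplest standard way to express that.
- **Group structure.** Preference classes mirror the observed dominance
  table's composition (2 small-fraction specialists, 1 small-but-not-
  smallest, 3 indifferent, 11 large-fraction specialists); group masses
  decay geometrically so a few groups dominate, as in real communities;
  per-group OTU weights are geometric within groups.
- **Seasonality.** Each group modulates its baseline multiplicatively by
  one annual cosine, (1 + a·cos(2π(t − peak)/365)) — the same harmonic
  framework used in the analysis, not a spline. With
  `amplitude_grows_with_size = TRUE` the per-fraction amplitude
  multipliers (0.15, 0.30, 0.45, 0.60, 0.80, 0.80) are non-decreasing in
  fraction rank, planting the "larger fractions vary more" signal; the
  plateau at the top reflects that the largest fraction showed no further
  increase in the original survey.
- **Environment.** Day length is deterministic (sunrise equation with
  −0.833° refraction horizon: maximum 15.2 h, minimum 9.15 h at
  41.67°N); SST is the annual cosine with mean 18.3 °C and amplitude
  5.8 °C (extremes 24.1/12.5 °C, peak mid-August); nutrients and
  chlorophyll peak in winter, secchi depth and organic carbon in summer,
  each with Gaussian noise.
- **Diversity series.** The count generator controls *composition*; it
  cannot place the harmonic phase of richness-derived series with
  day-level precision. The design therefore carries explicit harmonic
  truth for the alpha, beta and gamma series
  (`generate_diversity_series()`: cosine plus Gaussian noise at 10 % of
  amplitude, truth peaks at ordinals 310, 250 and 280, staggered after
  the SST peak), so peak-date recovery is testable against known truth.
  Peak-ordering recovery checks use those series; the count-based
  pipeline still produces its own observed diversity series, whose
  phases are emergent rather than planted.

What the generator does *not* emulate — and therefore what passing tests
do not demonstrate about real data — includes taxon-specific
overdispersion, allochthonous particle inputs, OTU-clustering and
chimera artifacts, autocorrelated environmental noise, and any coupling
of community composition to the environmental series beyond shared
seasonal phase.

## Numerical choices and problem sizes

Rarefaction and permutation tests take mandatory seeds; generators save
and restore the global RNG state so they never disturb a caller's
stream. Percent compositions are held to column sums of 100 within 1e-9;
HDI equality with its oracle is asserted at 1e-12. The test suite runs
the full synthetic design (150 samples, ~220 OTUs), 200-replicate
coverage simulations for the harmonic standard errors, 500 null
simulations at 199 permutations for the PERMANOVA type-I check, and
8-replicate trajectory-monotonicity checks — sizes chosen so the whole
suite completes in well under a minute while keeping every stochastic
assertion's sampling error far below its tolerance.

## Known limitations

- Diversity is richness-based; no Hill-number or phylogenetic
  generalization.
- PERMANOVA is single-factor with unrestricted permutations; no strata,
  no dispersion test (PERMDISP), no multi-factor partitioning.
- bioenv's exhaustive search is exponential in the number of variables;
  with the 13-variable dictionary, cap `max_subset` (the pipeline default
  is 3).
- Ordination displays (nMDS, dbRDA) are standard visualizations of the
  distance matrices this package emits and are left to `vegan`.
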