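---
title: "Quantifying carbon and nitrogen transfer from cyanobacteria to fungal parasites"
author: "parasip authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying carbon and nitrogen transfer from cyanobacteria to fungal parasites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parasip)
```

## The scientific problem

Filamentous, N~2~-fixing cyanobacteria such as *Dolichospermum* dominate
summer blooms in brackish and fresh waters and inject large amounts of new
nitrogen into the ecosystem. Chytrid fungi parasitize these filaments:
zoospores encyst on a host cell, rhizoids penetrate it, and an external
sporangium matures while draining the host's carbon and nitrogen. Because
infections concentrate on the storage cells (akinetes) and the N~2~-fixing
cells (heterocytes), parasitism can redirect a substantial share of newly
fixed carbon and nitrogen away from the cyanobacterial population and into
the microbial food web.

`parasip` implements the quantitative chain needed to measure this at the
single-cell level with stable-isotope probing (^13^C-bicarbonate +
^15^N-N~2~ dual labeling read out by SIMS ion imaging), and to extrapolate
single-cell rates to population-level fixation losses and a nitrogen-fate
budget. Every stage is also covered by a synthetic-data generator so the
full pipeline can be exercised and validated without instrument data.

## The measurement model

### From ion counts to isotope ratios

A SIMS acquisition yields, for each recorded ion species, a stack of count
images over many planes. For a region of interest (ROI) drawn on the
image, the isotope ratio is computed from the **cumulative** counts over
all planes:

* large-geometry instrument: $R_{13C} = \frac{{}^{13}C^{14}N}{{}^{12}C^{14}N}$,
  $R_{15N} = \frac{{}^{15}N^{12}C}{{}^{14}N^{12}C}$ (the CN^-^ secondary
  ions);
* nano-scale instrument: $R_{13C} = \frac{{}^{12}C^{13}C}{{}^{12}C_2} \times 0.5$
  (the factor 0.5 accounts for the two carbon positions of the C~2~^-^
  ion), $R_{15N}$ as above.

The counting-statistics (Poisson) error of a ratio is
$\sigma_R = R\sqrt{1/N_{num} + 1/N_{den}}$; when the numerator is zero a
one-count floor keeps the error finite. Ratios with a zero cumulative
denominator are rejected outright.

### Quality control

Two plane-level criteria are evaluated per ratio: the standard error of
the per-plane ratio series may not exceed twice the Poisson error, and the
relative standard deviation (RSD) across planes may not exceed 25%. Both
flags are always recorded (`qcEvaluate()`); how they combine is a
configuration choice with a real consequence. The per-plane RSD of a
minor-isotope ratio is bounded below by counting statistics at roughly
$\sqrt{n_{planes}/N_{num}}$: with 50 planes and a few hundred cumulative
^15^N^12^C counts the RSD cannot fall below ~30--40% no matter how stable
the measurement is. A disjunctive rule (reject if either criterion fails)
would therefore discard essentially every natural-abundance ^15^N ratio,
controls included. The package default is the conjunctive reading —
rejected only when *both* criteria fail — with `combine = "either"`
available for the conservative interpretation; the disjunctive rule is
what the QC property tests exercise, since for it the rejection boundary
is exactly the pair of stated thresholds.

### Calibration and atom percent excess

Instrument mass fractionation is corrected with one multiplicative factor
per isotope, $\alpha = R_{reference}/\bar R_{controls}$, estimated from
QC-passing non-enriched control ROIs against the bulk (EA-IRMS) reference;
applied multiplicatively it maps the mean control ratio exactly onto the
reference. Ratios convert to atom percent as $at\% = 100R/(1+R)$ and to
atom percent excess (APE) by subtracting the mean atom percent of the
control ROIs. APE values may be slightly negative by noise and are
retained unclipped. Isotope dilution by sample preparation (about 10% for
paraformaldehyde fixation) is deliberately not corrected by default — the
dilution factor is uncertain, so reported enrichments are conservative —
but an optional multiplicative correction can be applied by scaling APE
values.

Natural-abundance baselines default to ^13^C/^12^C = 0.0112372 and
^15^N/^14^N = 0.0036765 (`naturalRatios()`), the standard reference
values.

### From APE to rates

Specific assimilation rates use the linear tracer model
$k = APE_{cell}/(APE_{source}\,\Delta t)$ (d^-1^), the standard
short-incubation approximation; an exponential form
$k = \ln(1 + APE_{cell}/(APE_{source}-APE_{cell}))/\Delta t$ is available
for incubations where cell enrichment approaches the source. Per-cell net
incorporation rates multiply $k$ by cell-type carbon/nitrogen contents
(pmol cell^-1^). Bulk fixation rates follow the tracer mass balance
$rate = \frac{A_{PN}-A_{PN_0}}{A_N-A_{PN_0}}\cdot\frac{[PN]}{\Delta t}$.

The default cell contents (`cellTypeParams()`) set the vegetative carbon
content to 4.0 pmol C so that the observed mean vegetative carbon rate of
0.39 pmol C cell^-1^ d^-1^ arises at the default mean vegetative
enrichment; akinetes carry 10x the vegetative contents (they are storage
cells of about tenfold biomass) and heterocytes default to vegetative-like
contents. All three are configuration entries because direct per-cell
measurements are rarely available.

## The synthetic population

`simulatePopulation()` emulates the bloom snapshot the analysis assumes:

* **Composition** 91 / 7 / 2% vegetative cells / heterocytes / akinetes
  (marginal fractions; exactly recovered in expectation).
* **Filaments** are cell chains of at least four cells (shorter chains do
  not count as filaments). Lengths are lognormal, re-parameterized to
  272 ± 206 µm for infected-class and 99 ± 70 µm for non-infected
  filaments — lengths are positive and right-skewed. 57% of filaments are
  infected-class.
* **Akinete placement.** Akinetes are concentrated in infected-class
  filaments (relative abundance ratio 4.2, matching the observed 2.1% vs
  0.5%) and relocate next to heterocytes with probability 0.85, which
  makes akinete–heterocyte junctions the dominant arrangement and lets the
  per-type prevalences (5 / 44 / 82% for vegetative cells / heterocytes /
  akinetes) exceed the filament-level prevalence. Per-cell infection
  probabilities are scaled internally so the *marginal* per-type
  prevalences equal the configuration exactly.
* **Sporangia.** Each infected cell carries a sporangium; when both
  members of an akinete–heterocyte junction are infected they share a
  single junction sporangium linked to both hosts. Stages
  (encysted/mature/collapsed) are multinomial with configurable
  proportions (no observed stage frequencies exist; the default
  0.2/0.5/0.3 favors mature sporangia, the stage used in enrichment
  contrasts).
* **True enrichments** per ROI group are drawn from lognormal
  distributions matched to the observed group means and SDs (mature
  junction sporangia 1.42/0.25 APE ^13^C/^15^N, vegetative-host sporangia
  0.32/0.02, associated bacteria 0.59/0.08, and so on); host-cell groups
  derive from the incorporation-rate table through the linear tracer
  model, which keeps the simulated population internally consistent from
  enrichment to rate. Lognormals rather than zero-truncated Gaussians keep
  the group means unbiased.
* **Bacterial colonization** counts per host cell are zero-inflated
  negative binomial: ZINB(π = 0.6, µ = 0.5, k = 1.0) for non-infected and
  ZINB(π = 0.6, µ = 4.25, k = 1.31) for infected cells, chosen to
  reproduce the observed 0.2 ± 0.6 and 1.7 ± 3.4 bacteria cell^-1^ and a
  count-component rate ratio of 0.118. Bacteria at least 10 µm from the
  nearest host cell are classified free-living (inclusive boundary).
* **Determinism.** Each simulation entity (population, stack, bacteria,
  bulk) draws from its own sub-seed derived from the master seed, so
  sub-simulations are independently reproducible.

Ion-count stacks (`simulateIonStack()`) draw per-pixel, per-plane Poisson
counts whose rates encode each ROI's true ratio (times the simulated
fractionation factor, default 0.96) at a configurable cumulative
denominator depth (default 10^5^ counts per ROI). ROI geometry on the
raster is cosmetic ellipse rendering; quantification uses mask membership
only.

### What the generator does not emulate

No temporal epidemic dynamics (the incubation is a single snapshot), no
zoospore swimming or sporangium maturation kinetics, no detector dead-time
or charging artifacts, no spatial intra-ROI heterogeneity, and no
correlated measurement drift beyond what the QC tests inject explicitly.
Passing tests therefore validate the estimators under Poisson counting
statistics and the stated population structure, not instrument-specific
artifacts. Two consequences worth knowing: observed filament-level
prevalence runs a few points below the infected-class fraction (short
infected-class filaments can escape infection), and the mean length of
observably infected filaments is slightly above the infected-class target
because longer filaments are more likely to carry at least one sporangium.

## Host–parasite transfer and colonization statistics

Sporangia are paired with their linked host cells (junction sporangia
yield one pair per adjacent host). Two distinct "fold" conventions are
exposed on purpose, because they answer different questions and differ
numerically: per-pair APE ratios (and their group means, which also give
the origin-constrained trend-line slopes, y = mean ratio × host APE) and
ratios of group-mean APEs (behind "x-fold greater" statements). Pairs
whose host APE is not positive are excluded from ratio means but retained
in APE-level comparisons, with the exclusion counted.

Colonization counts are fit by maximum likelihood as zero-inflated Poisson
and zero-inflated negative binomial models with an optional two-level
group on the count component (log link) and intercept-only zero inflation;
the lower-AIC model is selected. The fit is authored in the package
(direct optimization of the frequency-table likelihood) with the
count-component rate ratio reported alongside a profile-likelihood
confidence interval (Wald fallback); an independent mixed-model
implementation and a dense grid search of the likelihood serve as
cross-checks in the test suite. The degenerate all-zero input returns the
boundary fit (π → 1) with a finite log-likelihood.

## The population budget

`weightedPrevalence()` gives the cell-level prevalence
$P = 100\sum_t f_t p_t$; the observed composition and prevalences give 9%,
and the epidemic anchor (infections in 100% of akinetes, 54% of
heterocytes, 6% of vegetative cells) gives 11%. Prevalence scenarios scale
the anchor *linearly* per cell type — the minimal assumption, replaceable
via configuration, since only the endpoint is constrained.

Population fixation at prevalence P mixes infected and non-infected
per-cell rates by composition; retention is expressed relative to the
zero-prevalence population. With the observed rate table (e.g. akinete
nitrogen incorporation 0.71 → 0.31 pmol N cell^-1^ d^-1^ under infection),
retention at the 11% anchor computes to 94.0% for carbon and 84.2% for
nitrogen, and the retained C:N ratio rises from 8.71 to 9.72. Values
computed from unrounded per-group data rather than the printed group means
land at 95%/87% and 8.4 → 9.2; the differences (about 1–3 percentage
points, and about 0.3–0.5 on the C:N ratio) are entirely attributable to
using the printed, rounded rate table as input.

The nitrogen fate splits the total newly fixed nitrogen inventory (a bulk
measurement, default 230 pmol N mL^-1^ d^-1^) among host retention, fungal
sporangia, host-associated and free-living bacteria, and a residual
"Others" pool (non-negative enforced). The sporangium nitrogen uptake
defaults to content × APE-based specific uptake (0.56 pmol N ×
0.25/(0.67 × 0.875) ≈ 0.24 pmol N sporangium^-1^ d^-1^) and the bacterial
nitrogen quota to 6.1 × 10^-4^ pmol N cell^-1^; both were calibrated once
against the observed abundances (2298 host cells mL^-1^, 1.13 × 10^6^
free-living bacteria mL^-1^) and enrichments so that fungi and bacteria
each receive about 22% of new nitrogen at 9% prevalence, and both are
plain configuration entries. With these defaults the fungal share rises to
about 27% at the 11% anchor, the associated:free split within the
bacterial pool is far below 1%:99%, and fate fractions sum to 100%
(checked to ±0.01) at every scanned prevalence.

## Numerical choices and degenerate inputs

* Cumulative-count ratios are exact integer sums; equivalence with a
  brute-force per-pixel, per-plane oracle is asserted in the tests.
* Planes with zero denominator counts are dropped from the per-plane
  series and counted; fewer than two usable planes leaves the plane-level
  statistics undefined (QC then fails the Poisson criterion).
* Zero numerator: ratio 0 with the one-count error floor. Zero
  denominator: rejected. Negative ratios and atom percents are input
  errors.
* `cnRatio()` flags non-positive nitrogen rates as undefined rather than
  returning infinities; `summarizeGroups()` omits (with a warning)
  categories lacking one of the infection groups.
* Percent changes are reported rounded to the nearest integer percent,
  alongside full-precision absolute differences.
* The ZI fits optimize on the unconstrained scale (logit π, log µ,
  log k); standard errors come from the numerically inverted Hessian.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen as
the smallest sizes at which the statistical assertions are
well-conditioned: recovery experiments use about 1,000 ROIs at 10^5^
cumulative denominator counts and 50 planes on 128 px rasters; population
metrics use 10,000–22,000 cells; the colonization fit uses 2,000–4,000
counts; interval-coverage checks use 200 replicate fits at the observed
group size of 100 cells per group.

## Known limitations

* At 10^5^ denominator counts the ^15^N counting floor (σ~APE~ ≈ 0.02)
  is of the same order as host-cell ^15^N enrichments (0.02–0.07 APE), so
  *individual-cell* nitrogen rates carry 30–50% relative error at this
  depth; group means remain unbiased and well-resolved. Carbon rates reach
  better than 10% median relative error. Deeper acquisitions shrink both.
* The budget treats the total newly fixed nitrogen inventory as constant
  across the prevalence scan; it is a measured bulk input, not a modeled
  quantity, and gross fixation is not modeled separately from retention.
* The single-cell uptake model is the linear short-incubation
  approximation; the exponential alternative is exposed but not the
  default.
* Junction sporangia are paired with both adjacent hosts; analyses that
  pair per host type only can subset the pair table.
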