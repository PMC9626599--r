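---
title: "Methods: segregation and fine-particulate metal exposure disparities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segregation and fine-particulate metal exposure disparities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segmetals)
```

# The analysis in one paragraph

`segmetals` estimates how exposure to trace metals measured within PM₂.₅
varies with racial residential segregation across US counties. Daily
speciated monitor records are quality-controlled and averaged into annual
county concentrations and PM₂.₅ mass proportions; segregation is
summarized per county by the dissimilarity index (DI) over census tracts;
counties are grouped into segregation categories; and disparity is
quantified two ways — a coefficient-of-variation statistic over
population-weighted category means, and a log-log regression whose slope
is the elasticity of concentration with respect to DI. Spatial structure
of the monitor values is described by global and local Moran's I. Because
the real inputs require bulk downloads, the package ships a first-class
synthetic-data generator that plants a known DI–concentration model, so
every stage is testable against ground truth.

# The models and their assumptions

## Dissimilarity index

For a county with tracts $i$, minority populations $x_i$ (total $X$) and
reference populations $y_i$ (total $Y$):

$$D = \tfrac{1}{2}\sum_i \left|\frac{x_i}{X} - \frac{y_i}{Y}\right| \in [0,1].$$

$D$ is an *evenness* index: it ignores where tracts sit inside the county
(a documented limitation of the index itself), and it needs at least two
tracts and positive totals for both groups. Counties violating these
preconditions are not silently scored 0 — a single-tract county raises an
*excluded-county* condition and a zero group total an *undefined-index*
condition, and `di_all_pairs()` tabulates both with reasons. Categories
use fixed thresholds with left-closed intervals $[0, 0.3)$, $[0.3, 0.6)$,
$[0.6, 1]$; the boundary convention is ours (the conventional band labels
overlap at their endpoints), chosen so each DI maps to exactly one
category. An empirical-tertile scheme is available for sensitivity
analyses.

## Monitor QC

Only valid samples with non-missing concentrations are used. A
monitor-component-year is retained iff it reports **strictly more** than
50% of the expected samples; the every-third-day schedule makes the
expectation ≈121, and the threshold is deliberately strict ("greater
than"), so 61 of 121 passes and 60 fails. Values below the minimum
detectable limit are kept as reported by default — truncating them would
bias annual means upward — with the standard MDL/√2 substitution as a
switch for sensitivity runs. County values are unweighted means across
retained monitors (no sample-count weighting: within-county monitor
counts are tiny and a weighting rule would be invented, not derived).
Mass proportions divide annual county means, metal over PM₂.₅, after a
single ×10³ unit harmonization from µg to ng; they are ratios of annual
quantities, not means of daily ratios, since only annual quantities are
defined after QC.

## Population-weighted disparity

Per category $i$, $Y_i = \sum_j P_j x_j / \sum_j P_j$ with $P_j$ the
*total* county population (not the group-specific one — the weighting
expresses how many people live under that exposure, not which group).
The relative disparity is the coefficient of variation
$RD = \sqrt{\mathrm{Var}(Y)}/\mu(Y)$; being scale-free it compares
components and years directly. **Variance convention:** with only $K = 3$
categories the population variance (÷K) and sample variance (÷(K−1))
differ by a factor $\sqrt{3/2} \approx 1.22$, and the defining literature
does not specify one. We default to the population variance and surface
the convention in every output row (`var_type`), with the sample variance
one switch away.

Confidence intervals are percentile bootstrap (2.5/97.5), resampling
**counties** with replacement independently within each category at its
observed size. The county is the resampling unit because it is the unit
of analysis; stratification preserves the category sizes that drive the
CV's sampling variability. We use the plain percentile interval rather
than BCa: the estimand is a smooth functional, the per-category sizes in
realistic runs are moderate, and the simpler interval is fully
reproducible from a single seed without jackknife machinery.

## Association model

OLS of $\log(\text{concentration})$ on $\log(DI)$. The slope $\beta$ is
an elasticity, hence base-invariant, and is reported as the percent
change per 10% **multiplicative** DI increase, $(1.1^\beta - 1)\times
100$; the multiplicative reading is forced by the log-log form (an
additive +0.1 in DI has no constant percent interpretation under this
model). CI endpoints on the percent scale are the monotone transform of
the slope CI. Counties with DI = 0 or concentration 0 are excluded with
a logged count; logs are undefined there and imputing an epsilon would
manufacture leverage. Region enters as one-hot fixed effects
(alphabetically first region as baseline); percent-NHB/NHW covariates
enter log-transformed by default so their coefficients convert with the
same per-10% map (a raw-percent switch exists because either reading of
"per 10% increase in NHB population" is defensible). Classical OLS
standard errors are the default; HC1 robust errors are a switch, not the
default, since the reference analysis gives no indication of robust
inference.

## Spatial autocorrelation

Global Moran's I with mean-centered values and row-standardized
k-nearest-neighbour weights (k = 8, great-circle distance; KNN avoids
islands under irregular monitor spacing, and no weight specification is
inherited from the reference analysis — this is our choice). Inference is
by random permutation of values across sites, one-sided
(greater-or-equal) with the $(r+1)/(n_{perm}+1)$ estimator, 999
permutations by default. Local Moran's I uses
$I_i = z_i \sum_j w_{ij} z_j / m_2$ with $m_2 = \sum z^2/n$, so
$\sum_i I_i = S_0 \cdot I$ (verified numerically in the tests);
site-level significance is by conditional permutation (own value held
fixed, neighbours drawn from the rest), one-sided in the direction of the
observed statistic, and HH/LL/HL/LH labels follow the sign pattern of
$(z_i, \text{lag}_i)$ at p < 0.05 raw — descriptive use, no multiplicity
correction by default, FDR by switch. Ties in neighbour distances are
broken by site order, making weights deterministic.

# The synthetic-data generator

The generator emulates the two input shapes (tract demographic tables and
daily monitor records) with a planted truth object for testing recovery.

**Tract mosaics.** Each county's minority populations are allocated by a
two-block construction: a fraction $\theta$ (`mixing_theta`) of each
minority group is packed into a dedicated first tract and the remainder
spread evenly; the NHW reference avoids the packed tract by the same
fraction. In the continuum this yields $DI = \theta$ exactly, so the knob
spans the whole index range with $DI(0) = 0$, $DI(1) = 1$, monotone in
between. Counts are integers via largest-remainder rounding, and county
group totals are made divisible by the tract count so $\theta = 0$
produces exactly even tracts.

**Monitor records.** For county $j$, component $m$:
$\log \mu_{jm} = \alpha_m + \beta_m \log DI_j + \gamma_{region(j)} +
\varepsilon_j$, $\varepsilon_j \sim N(0, \sigma_{annual}^2)$; daily
values are lognormal about $\mu_{jm}$ with log-scale SD $\sigma_{daily}$.
The within-year distribution is not dictated by any reference — lognormal
is our choice, with the mean-preserving parameterisation
$\text{meanlog} = \log\mu - \sigma_{daily}^2/2$ so daily expectations
equal the planted annual mean and the below-MDL fraction has the closed
form $\Phi\big((\log MDL - \text{meanlog})/\sigma_{daily}\big)$ used by
the tests. The calendar is day-of-year 1, 4, 7, … (122 scheduled days;
the completeness denominator stays at the conventional 121 and is
overridable); each scheduled sample is dropped independently with
probability `missing_rate`. Below-MDL values are **never truncated** —
censoring is downstream's decision.

**Default study conditions.** 100 counties × 20 tracts, θ spread evenly
over [0.05, 0.95] (keeping DI > 0 so logs are defined), county population
100,000, national-scale group shares (60% NHW, 13% NHB, 18% Hispanic, 6%
Asian, 3% Native American), elasticities ~0.9–1.6 for
anthropogenic-source metals (Cu, Zn, Ni, Cr, Pb, V: 9–16% per 10% DI),
~0.4–0.7 for crustal metals (Fe, Mn, Ti), 0.512 for PM₂.₅ (5%),
σ_annual = 0.3, σ_daily = 0.5, 10% missingness, half the counties urban.
Intercepts put annual means at realistic magnitudes (a few ng/m³ for most
metals, tens for Fe, ~10 µg/m³ for PM₂.₅).

**What the generator does not emulate** — and therefore what passing
tests do not establish about real data: real station placement and its
rural/low-DI under-representation, chemical covariance between metals
(each component draws independent noise), seasonality, true censoring
mechanisms, within-county monitor heterogeneity beyond independent noise,
and any spatial autocorrelation beyond what region offsets induce.
Recovery results certify the estimators, not the epidemiology.

**Seeding.** One master seed feeds hierarchical streams keyed by
(purpose, county, monitor, component), so regeneration is byte-identical
and adding a component or county never perturbs the other draws.

# Numerical choices and degenerate inputs

* DI for small integer counties is checked against an exact
  integer-arithmetic oracle ($\sum|x_i Y - y_i X| / 2XY$) to 10⁻¹².
* Completeness is a strict inequality; exactly 50% is rejected.
* Quantiles for bootstrap CIs and tertiles use R's default type-7
  definition.
* Degenerate inputs raise typed conditions rather than NA contagion:
  constant values for Moran's I, empty strata for ratios and CIs, µ(Y) ≤
  0 for RD, fewer counties than parameters for the regression.
* Singleton bootstrap strata legitimately produce degenerate CIs equal to
  the point estimate.
* The bootstrap of RD is vectorised (index matrices per category), making
  10,000 replicates cheap; replicates are returned for inspection.

# Problem sizes used in the shipped checks

The test-suite simulations are sized to certify behaviour while staying
quick to run: elasticity recovery uses 500 replicates of 200 counties
(planted β = ln 1.09/ln 1.1 ≈ 0.904, σ = 0.3); RD interval coverage uses
500 replications of a three-category study (47/165/16 counties, planted
category means 9/5/2 with log-scale SD 0.2, 2,000 bootstrap replicates
each) — the lognormal mean factor is common across categories and cancels
in the CV, so the true RD is known in closed form; Moran null uniformity
uses 500 independent null datasets at n = 25 with 999 permutations; the
DI oracle sweep uses 1,000 random counties of ≤5 tracts and populations
≤20. The end-to-end demo runs 100 counties with 2,000 bootstrap and 499
permutation replicates.

# Known limitations

* The DI is aspatial and scale-dependent (tract/county choices matter);
  no spatially aware segregation indices are provided.
* The multi-group ("integrated") dissimilarity index is not implemented:
  no formula is available to us, and guessing one would be worse than
  omitting it.
* No within-county exposure interpolation: a county's exposure is its
  monitor average, and most counties have a single monitor.
* The bootstrap treats counties as exchangeable within category; spatial
  dependence between nearby counties is not propagated into the CIs.
* Mass proportions require a retained PM₂.₅ value in the same
  county-year; otherwise they are NA, never imputed.
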