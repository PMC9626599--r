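# segmetals

Tools for quantifying how exposure to toxic trace metals in fine
particulate matter (PM₂.₅) varies with racial residential segregation
across US counties — and a synthetic-data generator with planted truth so
the entire analysis is testable without downloading monitoring or census
data.

## Who this is for

Environmental-health and exposure-disparity researchers working with
speciated PM₂.₅ monitoring records (CSN/IMPROVE-style daily measurements
of Cu, Zn, Ni, Cr, Pb, V, Fe, Mn, Ti and total PM₂.₅) and ACS-style census
tract demographic tables. The package turns those two inputs into
county-level disparity and association estimates with reproducible,
seed-controlled uncertainty.

## What it computes

**Segregation.** The dissimilarity index of a county, for a minority group
*x* and reference group *y* over census tracts *i*:

    D = 0.5 × Σᵢ | xᵢ/X − yᵢ/Y |,   D ∈ [0, 1]

with categories *well integrated* (D < 0.3), *moderately segregated*
(0.3 ≤ D < 0.6) and *highly segregated* (D ≥ 0.6), or empirical tertiles.

**Monitor QC.** Valid-sample filtering, a strict > 50%-of-expected
completeness rule (≈121 expected samples/year on an every-third-day
schedule), below-detection-limit values retained by default (MDL/√2
substitution available as a sensitivity switch), and unweighted averaging
of monitors within a county. Mass proportions are ratios of annual county
means (metal ng/m³ over PM₂.₅ µg/m³, unit-harmonized).

**Disparity.** Population-weighted mean exposure per segregation category,

    Yᵢ = Σⱼ Pⱼ xⱼ / Σⱼ Pⱼ,

and the relative disparity RD = √Var(Y) / µ(Y) (coefficient of variation
across category means), with percentile confidence intervals from a
bootstrap that resamples counties with replacement independently within
each category.

**Association.** OLS of log concentration on log DI; the slope β is
reported as the percent change per 10% DI increase, (1.1^β − 1)·100, with
urban/rural stratification, region fixed effects and racial-composition
covariates.

**Spatial structure.** Global and local Moran's I on k-nearest-neighbour
(great-circle) weights with permutation inference and HH/LL/HL/LH cluster
labels.

## Worked example

```r
library(segmetals)

# a 100-county synthetic study with a planted DI-concentration gradient
sc  <- synthetic_scenario(seed = 1)          # Pb elasticity 0.904 planted
cfg <- pipeline_config(scenario = sc, n_boot = 2000, n_perm = 499, seed = 1)
run_pipeline(cfg, "demo_out")

assoc <- read.csv("demo_out/association.csv")
subset(assoc, component == "Pb",
       select = c(beta, pct_per_10pct_di, ci_low, ci_high, p_value))
#>      beta pct_per_10pct_di   ci_low  ci_high      p_value
#>  0.920863         9.173439 8.095052 10.26259 5.299645e-32

disp <- read.csv("demo_out/disparity.csv")
subset(disp, component == "Pb" & mode == "concentration",
       select = c(rd, ci_low, ci_high))
#>         rd    ci_low   ci_high
#>  0.5291183 0.4633877 0.5996429
```

The fitted Pb slope (β = 0.92, +9.2% per 10% DI increase, CI 8.1–10.3%)
recovers the planted elasticity of 0.904 (+9%), and the relative disparity
of Pb concentrations across segregation categories (0.53) exceeds that of
total PM₂.₅ (0.31 in the same run), the qualitative signature the pipeline
is designed to measure. Every file in `demo_out/` (tables, exclusion log,
manifest with MD5 hashes) is bitwise reproducible from the config and
seed.

A thin command-line wrapper is installed at
`inst/scripts/run_pipeline.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/run_pipeline.R", package = "segmetals"))')" \
  --config config.yaml --out outdir --seed 1
```

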