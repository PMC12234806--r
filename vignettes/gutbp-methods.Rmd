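---
title: "Methods: gut microbiome and 24-hour blood pressure associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gut microbiome and 24-hour blood pressure associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutbp)
```

# Scope and model

`gutbp` implements a population-scale association analysis between gut
metagenomic species composition and blood pressure measured by 24-hour
ambulatory monitoring (ABPM), structured as a pipeline of independently
testable stages:

1. **Cohort assembly** — ABPM reading series are reduced to four outcomes per
   participant (24-h mean and within-person SD of systolic and diastolic
   pressure); exclusion rules are applied in a fixed order with per-rule
   accounting; diet, sodium and drug covariates are derived.
2. **Compositional preprocessing** — species prevalence filtering, a
   pseudo-count centred log-ratio (CLR) transform with a per-species
   zero-replacement policy, rarefaction of marker-gene counts, alpha
   diversity, and Bray–Curtis dissimilarities.
3. **Distance-based MANOVA** — how much compositional variance blood pressure
   explains beyond a covariate baseline, via trace pseudo-R² and a
   permutation pseudo-F test.
4. **Association screen** — ordinary least squares of each BP outcome on each
   species' CLR abundance (and on Shannon diversity), under Model 1 (with
   BMI) and Model 2 (without BMI), with Benjamini–Hochberg FDR per outcome
   and replication against office BP in the non-ABPM subsample.
5. **Set enrichment** — preranked running-sum enrichment of genus and gut
   metabolic module (GMM) carrier sets over the species results.
6. **Metabolite profiling** — partial Spearman correlations between
   BP-signature species and plasma metabolites.
7. **Sensitivity analysis** — dfbeta influence diagnostics plus exclusion and
   adjustment reruns.

A seeded synthetic-cohort generator reproduces the statistical structure each
stage assumes, so the whole pipeline is exercised end-to-end without access
to restricted cohort data.

# Per-stage models and conventions

## ABPM outcomes

The 24-h mean and SD are computed over all readings of a series, unweighted.
The measurement scheme this emulates samples every 30 minutes during the day
and every 90 minutes at night at one centre, so day readings dominate the
plain mean; because no day/night weighting convention is given for the
24-h mean, the unweighted mean is the default and a trapezoidal time-weighted
mean is available (`summarize_abpm(weighted = TRUE)`). Variability is the
sample SD (n−1). Series with fewer than two readings are an error, not an NA.

## Species filter and CLR policy

Species are retained when their relative abundance exceeds `min_abund`
(default 1e-4, i.e. 0.01%) in strictly more than `min_prev` (default 30%) of
samples. Retained columns are *not* re-closed: downstream log-ratio
quantities refer to the original composition.

The CLR uses a universal pseudo-value δ equal to the smallest non-zero entry
of the filtered matrix (computing δ after filtering is a deliberate choice —
the filter defines the analysis matrix, and a pre-filter δ would be dictated
by species that never enter any model). Each sample is transformed as
`log(x + δ)` minus its mean over included species; afterwards every cell that
was originally zero is replaced by the *minimum CLR value of that species
among samples where it was non-zero*, so all original zeros of a species
share one equally-low value. The replacement deliberately breaks the
row-sum-zero identity; the identity is asserted (to 1e-8) on the
pre-replacement matrix, which is kept in the `clr_table` object.

## Rarefaction and diversity

Marker-gene counts are subsampled without replacement to a fixed depth
(default 190,977 counts per sample) through `vegan::rrarefy` under a local
seed; samples below depth are an explicit error listing offenders. Shannon
diversity uses the natural logarithm (the convention of the ecology packages
this builds on); richness and inverse Simpson are provided as companion
metrics, but only Shannon feeds the association screen.

## Distance-based MANOVA

With `D` the Bray–Curtis matrix, `G = −½ C (D∘D) C` is the Gower-centred
inner-product matrix and `pseudoR²(X) = tr(H_X G H_X)/tr(G)` for the hat
matrix `H_X` of a design. The incremental pseudo-F for adding columns `Z` to
a reduced design `X₀` uses the rank gain `q` and full rank `p`:

```
F = [ (tr(Hf G Hf) − tr(H0 G H0)) / q ] / [ tr((I−Hf) G (I−Hf)) / (n − p) ]
```

P-values come from a Freedman–Lane permutation scheme: `G` is residualised on
the reduced model, rows and columns are permuted jointly, and F recomputed;
the observed statistic is evaluated on the same residualised matrix so the
identity permutation belongs to the null ensemble, and
`p = (1 + #{F_perm ≥ F_obs})/(n_perm + 1)`. Permutation was chosen over an
asymptotic moment-matching approximation because an exact small-sample oracle
(exhaustive enumeration) exists to validate it; an asymptotic mode is a
documented extension point. Numerical details: ranks come from pivoted QR at
tolerance `1e-8 ×` the leading diagonal; a saturated increment (zero residual
trace) reports `F = Inf`; the exceedance comparison uses a relative epsilon
of 1e-8 so permutations exactly tied with the observed statistic (for
example, group relabelings) are counted as exceedances despite floating-point
noise. Categorical covariates are expanded to treatment coding with the first
level as reference.

## Association screen

Each fit is ordinary least squares of one outcome on one exposure plus the
model covariates; the exposure coefficient is reported in mmHg per CLR unit
(CLR values are used unstandardised, matching the per-CLR-unit reporting
convention), with a two-sided t-test and a 95% CI from t quantiles at the
residual degrees of freedom. Rank-deficient designs are an error naming the
collinear columns; covariate columns that are constant in a subsample (e.g. a
medication nobody in the subsample uses) are dropped with a message before
fitting. BH adjustment is applied per outcome across the species exposures;
the Shannon exposure forms its own small BH family across outcomes, so a
handful of diversity tests neither dilutes nor inflates the species FDR.
Both families are computed, since the grouping is a genuine judgment call;
the per-phenotype species family is the primary one.

## Enrichment

The ranking metric is `sign(β)·(−log10 p)` — the standard signed metric that
realises "p-values stratified by effect direction" — with ties broken by
`|β|` then species id so the order is fully deterministic, and `p = 0`
capped at the smallest positive double. The enrichment score is the signed
extremum of the weighted running sum (weight exponent 1): members add
`|score|/Σ_set|score|`, non-members subtract `1/(N−|set|)`. A single signed
ranking is used rather than two one-sided runs; the null is random
membership of size-matched sets (`p = (1 + #{|ES_perm| ≥ |ES_obs|})/(n_perm+1)`),
with BH across all tested sets. Sets smaller than `min_set_size` (default 5,
for stability of the running-sum extremum) are pruned. Normalised enrichment
scores and multilevel split p-refinement are out of scope.

## GMM carriage

A module is a set of alternative paths, each an ordered list of steps, each
step a set of alternative KEGG Orthology identifiers. A step is covered when
any alternative KO is present; a path qualifies when the covered-step
*fraction* is ≥ 2/3 (so 4 of 6 passes), tightened to *all* steps for paths of
three or fewer steps (so 2 of 3 fails); a species carries the module when any
path qualifies. The two-thirds criterion is applied to covered steps rather
than raw KO counts — the step/path structure is what the rule's short-path
and alternative-path clauses refer to — and this reading is flagged in the
documentation because counting KOs is a defensible alternative.

## Metabolite profiling

"Partial Spearman" is implemented as rank residualisation: mid-ranks of both
variables are residualised on the covariate design by least squares and the
residuals correlated, with `df = n − 2 − k`. With no covariates this is
exactly plain Spearman. A probability-scale estimator is a known alternative;
rank residualisation was chosen for its transparency and its exact reduction
property. BH is applied within species across metabolites ("adjusted
p-values" per species), and the top-k (default 10) annotated associations
per species are selected by q.

## Influence rule and sensitivity scenarios

The most influential observation for an association is the one with the
largest *absolute* unscaled dfbeta on the exposure coefficient (ties broken
by lowest index); dfbeta is the closed-form leave-one-out change
`β_full − β_without_i`, property-tested against explicit refits. An
association is `reliable` iff, after dropping that observation, p < 0.05 and
the coefficient keeps its sign. The four scenario reruns (antibiotics
exclusion, IBD exclusion, PPI adjustment, 10 genetic PCs) rerun the complete
screen — not only the flagged species — so FDR families stay comparable, and
both raw p and re-applied FDR are emitted because the comparison convention
is not fixed; the side-by-side table is restricted to main-run discoveries.

## Derived covariates

Diet data are treated as missing for women reporting < 500 or > 5000
kcal/day and men < 550 or > 6000 (likely misreporting); fiber is expressed
per 1000 kcal. The 24-h urinary sodium excretion is estimated from spot
urine by the sex-specific Kawasaki equations (predicted 24-h creatinine in
mg/day: male `−12.63·age + 15.12·weight + 7.39·height − 79.9`, female
`−4.72·age + 8.58·weight + 5.09·height − 74.5`; estimate in mEq/day =
`16.3·√(spotNa/(spotCr[mg/dL]·10) · PRCr)`), converted to mg/day and entered
into models as its natural logarithm because the estimate is right-skewed.
Unit conversions (creatinine mmol/L → mg/dL via ×11.312, sodium mEq → mg via
×22.99) live in one constants block. PPI use is flagged when omeprazole
and/or pantoprazole is measurable in plasma.

# The synthetic cohort generator

`synth_config()` defaults encode the cohort structure the analysis assumes:
6465 participants with about 57% in the ABPM subsample, 268 analysis-scale
species, a 32-reading day grid and 6-reading night grid with a −10 mmHg night
level shift, participant-level outcome noise of 8 mmHg, overall zero fraction
0.5, and a 1302-column metabolite panel. Species abundances follow a
logistic-normal composition whose location decreases along the species index
(prevalent head, rare tail); zeros arise by thresholding small proportions at
the sparsity quantile and re-closing. BMI feeds both a random subset of
species and the outcomes, so BMI-adjusted and unadjusted models differ
qualitatively, as they should. Planted species effects are expressed in mmHg
per CLR unit *on the CLR matrix the default analysis settings produce*, so
the downstream screen targets the planted coefficients exactly; a planted
species that would not pass the default abundance filter is a configuration
error rather than a silently attenuated effect.

What the generator does **not** emulate: phylogenetic correlation structure,
realistic metabolite chemistry, measurement-device artefacts, informative
missingness, or day-to-day microbiome variability. Passing tests therefore
demonstrate correctness of the statistical machinery under the stated
generative assumptions — not that real-data effect sizes or discovery counts
would be reproduced.

GMM definitions are generated with 1–3 paths of 2–8 steps and KO identifiers
unique to each step, so the carriage truth table is exact by construction:
carriers receive precisely enough covered steps to qualify and non-carriers
one step fewer than required.

# Problem sizes and test design

The test and acceptance workloads use sizes chosen to make the Monte-Carlo
assertions sharp while keeping the suite quick to run: coverage of a planted
β = −1.5 is assessed over 100 replicate cohorts of n = 2000 (95% CI coverage
must land in [93%, 97%]); the D-MANOVA increment test is calibrated over
2000 null simulations at n = 50 with 199 permutations (type-I at α = 0.05
within [0.035, 0.065]) and validated exactly against exhaustive enumeration
of two-group labelings at n = 6; null FDR behaviour uses cohorts of n = 300
with 200 species. The end-to-end determinism check runs the full pipeline
twice at n ≈ 200 and compares output checksums. Under the global null the
probability that a BH screen at 5% FDR yields zero discoveries is itself
about 95%, so the null-FDR summary hovers at that boundary by construction.

# Known limitations

* The D-MANOVA p-value is permutation-based; results carry their `n_perm`
  and seed, and small p-values are bounded below by `1/(n_perm+1)`.
* The zero-replacement CLR is a policy, not an imputation model; estimates
  for very sparse species lean on the shared replacement value.
* ABPM quality control is study-specific and therefore a pluggable predicate
  (`run_config(abpm_qc = ...)`), with no default criteria.
* Alpha-diversity companions (richness, inverse Simpson) are stand-ins for
  unnamed secondary metrics; only Shannon enters the models.
* Formal mediation through BMI is out of scope; Model 1 vs Model 2
  comparison tables are descriptive.
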