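# gutbp

Association analysis between the gut metagenome and 24-hour ambulatory blood
pressure (ABPM), packaged as a tested, reusable R pipeline. It is aimed at
microbiome epidemiologists who have a species-level relative-abundance table,
a covariate/phenotype table, and repeated blood-pressure readings per
participant, and who want the full analysis chain — compositional
preprocessing, variance partitioning, per-species models with FDR control,
set enrichment, metabolite profiling, and influence-based sensitivity
analysis — with every stage independently testable on synthetic data.

## What it computes

* **Outcomes.** Per participant, the 24-h mean and within-person variability
  (sample SD) of systolic and diastolic pressure from an ABPM reading
  series, plus office BP for the replication subsample.
* **Compositional preprocessing.** Species kept at relative abundance
  > 0.01% in more than 30% of samples; centred log-ratio transform
  `clr(x)_j = log(x_j + δ) − mean_j log(x_j + δ)` with a universal
  pseudo-value δ (smallest non-zero abundance) and per-species replacement
  of original zeros by the species' minimal non-zero CLR value; rarefaction
  of marker-gene counts to a fixed depth; Shannon diversity
  `H = −Σ p log p`.
* **Distance-based MANOVA.** On the Gower-centred Bray–Curtis matrix
  `G = −½ C (D∘D) C`, the share of compositional variance a design explains,
  `pseudo-R²(X) = tr(H_X G H_X)/tr(G)`, and an incremental pseudo-F
  `F = [(tr(Hf G Hf) − tr(H0 G H0))/q] / [tr((I−Hf) G (I−Hf))/(n−p)]`
  with a Freedman–Lane permutation p-value, over the nested sequence
  baseline → + office BP → + 24-h BP.
* **Association screen.** OLS of each outcome on each species' CLR abundance
  (β in mmHg per CLR unit) and on Shannon diversity, under Model 1 (covariates
  including BMI) and Model 2 (without BMI), Benjamini–Hochberg FDR per
  outcome, and office-BP replication in the non-ABPM subsample.
* **Enrichment.** Preranked running-sum enrichment (signed
  `sign(β)·(−log10 p)` ranking, weight exponent 1) of genus sets and gut
  metabolic module (GMM) carrier sets, where a species carries a module if
  any path has ≥ 2/3 of steps covered (all steps for paths of ≤ 3 steps).
* **Metabolites.** Partial Spearman correlations (covariate-residualised
  ranks) between BP-signature species and plasma metabolites, top-k annotated
  hits per species.
* **Sensitivity.** Unscaled dfbeta influence rule (association "reliable" iff
  p < 0.05 and sign unchanged after dropping the most influential
  observation) and four scenario reruns: antibiotics exclusion, IBD
  exclusion, PPI adjustment, genetic-PC adjustment.

A seeded generator (`synth_config()` / `generate_cohort()`) produces
cohorts with the structure the analysis assumes — sparse logistic-normal
compositions, BMI confounding of both species and BP, planted species→BP
effects in mmHg per CLR unit, within-person ABPM reading noise, and KO
profiles with known GMM carriage — so everything is testable without
restricted cohort data.

## Worked example

```r
library(gutbp)

cfg <- synth_config(n_participants = 400, n_species = 60, n_metabolites = 30,
                    planted_effects = list(list(species = 2,
                                                outcome = "sbp_24h_mean",
                                                beta = -5)),
                    med_rate = list(antihypertensive = 0.05), seed = 42)
bp_simulate(cfg, "demo_in", n_modules = 8)
run <- bp_run(run_config("demo_in", "demo_out", n_perm = 199,
                         min_set_size = 4, seed = 1))
print(run$dmanova$sbp)
print(run$screen_model1)
```

```
D-MANOVA nested model sequence (199 permutations per increment)
    model pseudo_r2 f_increment p_increment
 baseline    0.1101          NA          NA
   office    0.1348    5.621742       0.005
   abpm24    0.1447    2.270098       0.010
Association screen: 152 fits (38 exposures x 4 outcomes), model 1
Discoveries at q < 0.05: 3
 exposure      outcome  beta ci_low ci_high        p        q
   sp0002 sbp_24h_mean -4.62 -5.332   -3.91 7.91e-28 2.93e-26
  shannon sbp_24h_mean  4.28  1.235    7.32 6.10e-03 1.22e-02
  shannon dbp_24h_mean  2.44  0.729    4.15 5.40e-03 1.22e-02
```

Reading this: the covariate baseline explains 11.0% of Bray–Curtis variance
in this small synthetic ABPM subsample (n = 218); adding office then 24-h
systolic BP raises pseudo-R² to 13.5% and 14.5%, each increment significant
by the permutation pseudo-F test. The species screen recovers the planted
effect on species 2 (true β = −5, estimated −4.62 mmHg per CLR unit,
q ≈ 3e-26); the Shannon associations form their own small FDR family. On a
small demo cohort the diversity estimates also pick up correlation with the
strongly planted species — an expected feature of compositional data, and one
reason the sensitivity stage reruns every screen. `bp_report("demo_out")`
renders the participant flow, diversity table, discovery list, enrichment
summary and sensitivity comparison as text; all stage outputs are TSV/JSON
files in `demo_out/`, including a `manifest.json` that makes reruns
byte-identical for the same configuration and seed.

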