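# Shared fixtures: the Model-1 covariate list and the covariate derivations
# (fiber density, estimated log sodium) applied to a generated cohort.

model1_covariates <- c("age", "sex", "country_of_birth", "smoker",
                       "fiber_density", "energy_kcal", "log_sodium",
                       "antidiabetic_med", "antihyperlipidemic_med",
                       "plate", "bmi")

derive_covariates <- function(cov) {
  cov$fiber_density <- fiber_per_1000kcal(cov$fiber_g, cov$energy_kcal)
  cov$log_sodium <- kawasaki_sodium(cov$sex, cov$age, cov$weight, cov$height,
                                    cov$spot_na, cov$spot_cr)$log_sodium
  cov
}

# Small cohort with one planted SBP effect, used by several suites.
small_planted_cohort <- function(seed = 1, n = 400, beta = -1.5,
                                 species = 3L, outcome = "sbp_24h_mean") {
  cfg <- synth_config(n_participants = n, n_species = 40, n_metabolites = 4,
                      planted_effects = list(list(species = species,
                                                  outcome = outcome,
                                                  beta = beta)),
                      seed = seed)
  generate_cohort(cfg)
}

# Model-1 design for all participants of a generated cohort.
cohort_design <- function(cohort) {
  suppressMessages(
    covariate_design(derive_covariates(cohort$covariates), model1_covariates))
}
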