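# Cohort assembly: ABPM summarisation, exclusion flow, derived covariates
# (energy plausibility, fiber density, estimated 24-h urinary sodium, PPI
# flag), complete-case selection.

#' Summarise an ambulatory blood-pressure reading series
#'
#' Computes the 24-h mean and the within-person variability (sample SD,
#' `n - 1` denominator) of systolic and diastolic pressure over all readings,
#' unweighted by time of day. A time-weighted mean (trapezoidal over the
#' reading timestamps) is available behind `weighted = TRUE` for schemes with
#' unequal day/night sampling.
#'
#' @param readings Data frame with columns `sbp` and `dbp` (mmHg) and, when
#'   `weighted = TRUE`, `timestamp_minutes`.
#' @param weighted Use a time-weighted mean instead of the plain mean.
#' @return Named numeric vector: `sbp_24h_mean`, `dbp_24h_mean`, `sbp_24h_sd`,
#'   `dbp_24h_sd`.
#' @export
summarize_abpm <- function(readings, weighted = FALSE) {
  if (!all(c("sbp", "dbp") %in% names(readings))) {
    stop_input("readings need 'sbp' and 'dbp' columns")
  }
  n <- nrow(readings)
  if (is.null(n) || n < 2L) {
    stop("insufficient-data error: at least 2 ABPM readings required", call. = FALSE)
  }
  mean_fun <- function(v) {
    if (!weighted) return(mean(v))
    t <- readings$timestamp_minutes
    o <- order(t)
    t <- t[o]; v <- v[o]
    w <- diff(t)
    sum(w * (v[-1] + v[-length(v)]) / 2) / sum(w)
  }
  c(sbp_24h_mean = mean_fun(readings$sbp),
    dbp_24h_mean = mean_fun(readings$dbp),
    sbp_24h_sd   = stats::sd(readings$sbp),
    dbp_24h_sd   = stats::sd(readings$dbp))
}

#' Apply exclusion rules in order, with a flow ledger
#'
#' Each rule is a named predicate returning `TRUE` for participants to remove.
#' Rules are applied in the given order and each participant is counted once,
#' at the first rule that removes them, reproducing participant-flow style
#' accounting.
#'
#' @param participants Data frame of participants.
#' @param rules Named list of functions, each taking the data frame and
#'   returning a logical removal vector.
#' @return List with `eligible` (surviving data frame), `ledger` (named
#'   integer removal counts per rule), `n_input`, `n_eligible`.
#' @export
apply_exclusions <- function(participants, rules) {
  if (length(rules) && (is.null(names(rules)) || any(names(rules) == ""))) {
    stop_config("every exclusion rule must be named")
  }
  if (!all(vapply(rules, is.function, logical(1)))) {
    stop_config("unknown rule: rules must be predicate functions")
  }
  removed <- rep(FALSE, nrow(participants))
  ledger <- stats::setNames(integer(length(rules)), names(rules))
  for (r in seq_along(rules)) {
    hit <- rules[[r]](participants)
    if (!is.logical(hit) || length(hit) != nrow(participants)) {
      stop_config("rule '%s' must return one logical per participant", names(rules)[r])
    }
    hit <- hit & !removed
    hit[is.na(hit)] <- FALSE
    ledger[r] <- sum(hit)
    removed <- removed | hit
  }
  list(eligible = participants[!removed, , drop = FALSE],
       ledger = ledger,
       n_input = nrow(participants),
       n_eligible = sum(!removed))
}

#' Flag implausible self-reported energy intake
#'
#' Diet fields are treated as missing for women reporting < 500 or > 5000
#' kcal/day and men reporting < 550 or > 6000 kcal/day (likely misreporting).
#'
#' @param sex Character/factor vector with levels `"female"`/`"male"`.
#' @param energy_kcal Reported daily energy intake (kcal/day).
#' @return Logical vector: `TRUE` where diet data should be flagged missing.
#' @export
energy_plausibility_filter <- function(sex, energy_kcal) {
  female <- as.character(sex) == "female"
  ifelse(female,
         energy_kcal < 500 | energy_kcal > 5000,
         energy_kcal < 550 | energy_kcal > 6000)
}

#' Energy-adjusted fiber intake
#'
#' Fiber density in grams per 1000 kcal of reported energy.
#'
#' @param fiber_g Fiber intake, g/day.
#' @param energy_kcal Energy intake, kcal/day; must be positive.
#' @return `fiber_g / (energy_kcal / 1000)`.
#' @export
fiber_per_1000kcal <- function(fiber_g, energy_kcal) {
  if (any(energy_kcal <= 0)) stop_domain("energy_kcal must be positive")
  fiber_g / (energy_kcal / 1000)
}

# Kawasaki spot-urine estimate of 24-h sodium excretion.
# Predicted 24-h creatinine excretion (mg/day), sex-specific:
#   male:   -12.63*age + 15.12*weight + 7.39*height - 79.90
#   female:  -4.72*age +  8.58*weight + 5.09*height - 74.50
# Estimated 24-h Na (mEq/day) = 16.3 * sqrt( spotNa / (spotCr_mg_dl * 10) * PRCr )
# Unit conversions: creatinine mmol/L -> mg/dL via * 11.312 (MW 113.12 g/mol,
# /10 for per-dL); sodium mmol/L == mEq/L; Na mEq -> mg via * 22.99.
.kawasaki_const <- list(
  male   = c(age = -12.63, weight = 15.12, height = 7.39, intercept = -79.90),
  female = c(age = -4.72,  weight = 8.58,  height = 5.09, intercept = -74.50),
  cr_mmol_to_mg_dl = 11.312,
  na_meq_to_mg = 22.99,
  scale = 16.3
)

#' Estimate 24-h urinary sodium excretion from a spot urine sample
#'
#' Sex-specific spot-urine estimator: the spot sodium-to-creatinine ratio is
#' scaled by a predicted 24-h creatinine excretion and the square root of the
#' product is mapped to an estimated 24-h sodium excretion. Returned in mg/day
#' together with its natural logarithm (the regression covariate, since the
#' estimate is right-skewed).
#'
#' @param sex `"male"`/`"female"` vector.
#' @param age Years.
#' @param weight kg.
#' @param height cm.
#' @param spot_na Spot urinary sodium, mmol/L.
#' @param spot_cr Spot urinary creatinine, mmol/L; must be positive.
#' @return Data frame with columns `sodium_mg_day` and `log_sodium`.
#' @export
kawasaki_sodium <- function(sex, age, weight, height, spot_na, spot_cr) {
  if (any(spot_cr <= 0)) stop_domain("spot creatinine must be positive")
  if (any(spot_na < 0)) stop_domain("spot sodium must be non-negative")
  if (any(age <= 0) || any(weight <= 0) || any(height <= 0)) {
    stop_domain("age, weight and height must be positive")
  }
  k <- .kawasaki_const
  male <- as.character(sex) == "male"
  co <- ifelse(male, 1, 0)
  prcr <- ifelse(male,
                 k$male["age"] * age + k$male["weight"] * weight +
                   k$male["height"] * height + k$male["intercept"],
                 k$female["age"] * age + k$female["weight"] * weight +
                   k$female["height"] * height + k$female["intercept"])
  if (any(prcr <= 0)) stop_domain("predicted 24-h creatinine non-positive; check anthropometrics")
  cr_mg_dl <- spot_cr * k$cr_mmol_to_mg_dl
  na_meq <- k$scale * sqrt(spot_na / (cr_mg_dl * 10) * prcr)
  data.frame(sodium_mg_day = na_meq * k$na_meq_to_mg,
             log_sodium = log(na_meq * k$na_meq_to_mg))
}

#' Proton-pump-inhibitor flag from plasma drug metabolites
#'
#' A participant is flagged as a PPI user when any named drug metabolite
#' (omeprazole and/or pantoprazole) is measurable, i.e. above the missing/zero
#' code.
#'
#' @param metabolite_table Samples x metabolites numeric matrix or data frame;
#'   `NA` or 0 encodes not measurable.
#' @param drug_metabolite_names Column names to test.
#' @return Logical vector per participant.
#' @export
ppi_flag <- function(metabolite_table, drug_metabolite_names = c("omeprazole", "pantoprazole")) {
  metabolite_table <- as.data.frame(metabolite_table)
  missing_cols <- setdiff(drug_metabolite_names, names(metabolite_table))
  if (length(missing_cols)) {
    stop_input("drug metabolite column(s) absent: %s", paste(missing_cols, collapse = ", "))
  }
  detected <- vapply(drug_metabolite_names, function(cn) {
    v <- metabolite_table[[cn]]
    !is.na(v) & v > 0
  }, logical(nrow(metabolite_table)))
  if (is.null(dim(detected))) detected <- matrix(detected, nrow = 1L)
  rowSums(detected) > 0
}

#' Complete-case selection over required analysis columns
#'
#' @param data Data frame.
#' @param required Character vector of columns that must be non-missing.
#' @return Logical vector: `TRUE` for complete cases.
#' @export
complete_cases_for <- function(data, required) {
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop_input("required column(s) absent: %s", paste(missing_cols, collapse = ", "))
  }
  stats::complete.cases(data[, required, drop = FALSE])
}
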