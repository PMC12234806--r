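# Seeded synthetic cohort generator. Emulates the statistical structure the
# downstream analysis assumes: sparse logistic-normal species compositions
# with a BMI path, covariate-confounded BP outcomes with planted species
# effects in mmHg per CLR unit, within-person ABPM reading noise, species-
# correlated metabolites, and KO profiles with known module-carriage truth.

#' Synthetic cohort configuration
#'
#' Builds and validates the configuration for [generate_cohort]. Defaults
#' mirror the structure of a two-centre middle-aged screening cohort: 6465
#' participants (about 57% in the ABPM subsample), 268 analysis-scale species,
#' a 30-min day / 90-min night ambulatory sampling scheme, and a plasma
#' metabolite panel of 1302 compounds.
#'
#' @param n_participants Number of participants (>= 10).
#' @param n_species Number of species.
#' @param n_metabolites Number of metabolites (besides the two drug-metabolite
#'   columns used for the PPI flag).
#' @param planted_effects List of `list(species = <index>, outcome = <name>,
#'   beta = <mmHg per CLR unit>)`; outcome one of `sbp_24h_mean`,
#'   `dbp_24h_mean`, `sbp_24h_sd`, `dbp_24h_sd`.
#' @param bmi_confounding Strength multiplier of the BMI paths to both species
#'   abundances and BP (1 = on, 0 = off).
#' @param sparsity Target fraction of zero cells in the species table, in
#'   `[0, 1)`.
#' @param abpm_day_readings,abpm_night_readings Reading counts per participant
#'   (30-min day grid, 90-min night grid).
#' @param night_shift Night-time level shift of SBP readings, mmHg.
#' @param noise_sd Participant-level residual SD of 24-h mean SBP, mmHg.
#' @param abpm_fraction Fraction of participants assigned to the ABPM
#'   subsample.
#' @param genus_size Species per genus in the synthetic taxonomy.
#' @param med_rate Named rates: `antihypertensive`, `antidiabetic`,
#'   `antihyperlipidemic`, `antibiotics`, `ibd`, `ppi`.
#' @param seed Integer seed; all randomness flows from it.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_participants = 6465L, n_species = 268L,
                         n_metabolites = 1302L, planted_effects = list(),
                         bmi_confounding = 1, sparsity = 0.5,
                         abpm_day_readings = 32L, abpm_night_readings = 6L,
                         night_shift = -10, noise_sd = 8,
                         abpm_fraction = 3695 / 6465, genus_size = 6L,
                         med_rate = list(), seed = 1L) {
  if (!is.numeric(n_participants) || n_participants < 10) {
    stop_config("n_participants must be at least 10")
  }
  if (n_species < 2) stop_config("n_species must be at least 2")
  if (sparsity < 0 || sparsity >= 1) stop_config("sparsity must lie in [0, 1)")
  if (abpm_day_readings < 1 || abpm_night_readings < 1) {
    stop_config("abpm_day_readings and abpm_night_readings must be positive")
  }
  valid_outcomes <- c("sbp_24h_mean", "dbp_24h_mean", "sbp_24h_sd", "dbp_24h_sd")
  for (pe in planted_effects) {
    if (!all(c("species", "outcome", "beta") %in% names(pe))) {
      stop_config("planted_effects entries need fields species, outcome, beta")
    }
    if (pe$species < 1 || pe$species > n_species) {
      stop_config("planted species index %d outside 1..%d", pe$species, n_species)
    }
    if (!pe$outcome %in% valid_outcomes) {
      stop_config("planted outcome '%s' not one of: %s", pe$outcome,
                  paste(valid_outcomes, collapse = ", "))
    }
  }
  rates <- utils::modifyList(
    list(antihypertensive = 0, antidiabetic = 0.016, antihyperlipidemic = 0.03,
         antibiotics = 0.10, ibd = 0.013, ppi = 0.025),
    med_rate)
  structure(list(n_participants = as.integer(n_participants),
                 n_species = as.integer(n_species),
                 n_metabolites = as.integer(n_metabolites),
                 planted_effects = planted_effects,
                 bmi_confounding = bmi_confounding, sparsity = sparsity,
                 abpm_day_readings = as.integer(abpm_day_readings),
                 abpm_night_readings = as.integer(abpm_night_readings),
                 night_shift = night_shift, noise_sd = noise_sd,
                 abpm_fraction = abpm_fraction,
                 genus_size = as.integer(genus_size),
                 med_rate = rates, seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic cohort
#'
#' Deterministic given the configuration seed. Species abundances follow a
#' logistic-normal composition whose per-species location decreases along the
#' species index (so low indices are prevalent and the rare tail supplies the
#' zeros introduced by thresholding small proportions); BMI feeds both a
#' subset of species abundances and the BP outcomes, so BMI-adjusted and
#' -unadjusted models differ qualitatively. Planted species effects are
#' expressed in mmHg per CLR unit, on the CLR matrix the default analysis
#' settings would produce, so the downstream association stage targets the
#' planted coefficients exactly.
#'
#' @param config A [synth_config].
#' @return Object of class `synth_cohort`: list with `abundance`
#'   ([abundance_table]), `gene_counts`, `covariates` (data frame),
#'   `abpm_series` (long data frame: `participant_id`, `timestamp_minutes`,
#'   `sbp`, `dbp`), `bp_outcomes` (per-participant 24-h summaries and office
#'   BP), `metabolites` (matrix + `annotated` attribute), `truth` (planted
#'   effect echo and true participant-level means).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_local_seed(config$seed, .generate_cohort_impl(config))
}

.generate_cohort_impl <- function(cfg) {
  n <- cfg$n_participants
  S <- cfg$n_species
  ids <- sprintf("P%05d", seq_len(n))
  species_ids <- sprintf("sp%04d", seq_len(S))
  genus_of <- stats::setNames(
    sprintf("g%03d", ceiling(seq_len(S) / cfg$genus_size)), species_ids)

  ## --- covariates -----------------------------------------------------
  sex <- factor(ifelse(stats::runif(n) < 0.53, "female", "male"),
                levels = c("female", "male"))
  age <- stats::runif(n, 50, 64)
  height <- ifelse(sex == "male", stats::rnorm(n, 178, 7), stats::rnorm(n, 165, 6.5))
  bmi <- pmax(16, stats::rnorm(n, 26.6, 4.2))
  weight <- bmi * (height / 100)^2
  smoker <- stats::runif(n) < 0.10
  country <- factor(sample(c("Scandinavia", "Europe", "Asia", "Other"), n,
                           replace = TRUE, prob = c(0.85, 0.07, 0.05, 0.03)),
                    levels = c("Scandinavia", "Europe", "Asia", "Other"))
  energy <- exp(stats::rnorm(n, log(1650), 0.28))
  fiber_g <- pmax(2, stats::rnorm(n, 18.5, 6) * energy / 1000)
  spot_na <- exp(stats::rnorm(n, log(55), 0.5))
  spot_cr <- exp(stats::rnorm(n, log(11), 0.45))
  plate <- factor(sprintf("plate%02d", sample.int(8, n, replace = TRUE)))
  r <- cfg$med_rate
  covariates <- data.frame(
    id = ids, age = age, sex = sex, country_of_birth = country,
    smoker = smoker, bmi = bmi, energy_kcal = energy, fiber_g = fiber_g,
    antidiabetic_med = stats::runif(n) < r$antidiabetic,
    antihyperlipidemic_med = stats::runif(n) < r$antihyperlipidemic,
    antihypertensive_med = stats::runif(n) < r$antihypertensive,
    antibiotics_6mo = stats::runif(n) < r$antibiotics,
    ibd = stats::runif(n) < r$ibd,
    ppi = stats::runif(n) < r$ppi,
    spot_na = spot_na, spot_cr = spot_cr, weight = weight, height = height,
    plate = plate, stringsAsFactors = FALSE)
  pcs <- matrix(stats::rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("pc", 1:10)))
  covariates <- cbind(covariates, pcs)

  ## --- species composition (logistic-normal, sparsified) --------------
  zbmi <- (bmi - 26.6) / 4.2
  mu <- seq(-2, -11, length.out = S)
  bmi_path <- stats::rnorm(S, 0, 0.25) * cfg$bmi_confounding
  logit <- matrix(mu, n, S, byrow = TRUE) +
    outer(zbmi, bmi_path) +
    matrix(stats::rnorm(n * S, 0, 2), n, S)
  props <- exp(logit - apply(logit, 1L, max))
  props <- props / rowSums(props)
  if (cfg$sparsity > 0) {
    thr <- stats::quantile(props, cfg$sparsity)
    props[props < thr] <- 0
    props <- props / rowSums(props)
  }
  dimnames(props) <- list(ids, species_ids)
  abundance <- abundance_table(props, genus_of)

  ## --- planted exposures: CLR under the default analysis policy -------
  clr_vals <- clr_transform(filter_species(abundance))$values
  effect_on <- function(outcome) {
    eff <- numeric(n)
    for (pe in cfg$planted_effects) {
      if (pe$outcome != outcome) next
      sp <- species_ids[pe$species]
      if (!sp %in% colnames(clr_vals)) {
        stop_config("planted species %s does not pass the default abundance filter", sp)
      }
      eff <- eff + pe$beta * clr_vals[, sp]
    }
    eff
  }

  ## --- blood-pressure outcome model -----------------------------------
  sodium <- kawasaki_sodium(as.character(sex), age, weight, height, spot_na, spot_cr)
  fiber_density <- fiber_per_1000kcal(fiber_g, energy)
  lin_pred <- 0.30 * (age - 57) - 3.0 * (sex == "female") + 2.0 * smoker +
    cfg$bmi_confounding * 0.9 * (bmi - 26.6) - 0.10 * (fiber_density - 18.5) +
    1.5 * (sodium$log_sodium - log(3100)) + 1.0 * covariates$antidiabetic_med
  mu_sbp <- 122 + lin_pred + effect_on("sbp_24h_mean") + stats::rnorm(n, 0, cfg$noise_sd)
  mu_dbp <- 75 + 0.55 * lin_pred + effect_on("dbp_24h_mean") +
    stats::rnorm(n, 0, 0.75 * cfg$noise_sd)
  sigma_sbp <- pmax(4, 15 + cfg$bmi_confounding * 0.3 * zbmi +
                      effect_on("sbp_24h_sd") + stats::rnorm(n, 0, 2))
  sigma_dbp <- pmax(3, 11.5 + cfg$bmi_confounding * 0.25 * zbmi +
                      effect_on("dbp_24h_sd") + stats::rnorm(n, 0, 1.6))

  ## --- ABPM reading series --------------------------------------------
  m_day <- cfg$abpm_day_readings
  m_night <- cfg$abpm_night_readings
  m <- m_day + m_night
  t_day <- seq(0, by = 30, length.out = m_day)
  t_night <- seq(max(t_day) + 60, by = 90, length.out = m_night)
  is_night <- c(rep(FALSE, m_day), rep(TRUE, m_night))
  abpm_idx <- sort(sample.int(n, round(cfg$abpm_fraction * n)))
  in_abpm <- seq_len(n) %in% abpm_idx
  n_abpm <- length(abpm_idx)
  sbp_read <- matrix(mu_sbp[abpm_idx], n_abpm, m) +
    matrix(cfg$night_shift * is_night, n_abpm, m, byrow = TRUE) +
    matrix(stats::rnorm(n_abpm * m, 0, sigma_sbp[abpm_idx]), n_abpm, m)
  dbp_read <- matrix(mu_dbp[abpm_idx], n_abpm, m) +
    matrix(0.6 * cfg$night_shift * is_night, n_abpm, m, byrow = TRUE) +
    matrix(stats::rnorm(n_abpm * m, 0, sigma_dbp[abpm_idx]), n_abpm, m)
  abpm_series <- data.frame(
    participant_id = rep(ids[abpm_idx], each = m),
    timestamp_minutes = rep(c(t_day, t_night), times = n_abpm),
    sbp = as.vector(t(sbp_read)), dbp = as.vector(t(dbp_read)))

  row_sd <- function(M) sqrt(rowSums((M - rowMeans(M))^2) / (ncol(M) - 1L))
  bp_outcomes <- data.frame(
    id = ids,
    subsample = ifelse(in_abpm, "ABPM", "non-ABPM"),
    sbp_24h_mean = NA_real_, dbp_24h_mean = NA_real_,
    sbp_24h_sd = NA_real_, dbp_24h_sd = NA_real_,
    office_sbp = mu_sbp + 2 + stats::rnorm(n, 0, 6),
    office_dbp = mu_dbp + 1.5 + stats::rnorm(n, 0, 5))
  bp_outcomes$sbp_24h_mean[abpm_idx] <- rowMeans(sbp_read)
  bp_outcomes$dbp_24h_mean[abpm_idx] <- rowMeans(dbp_read)
  bp_outcomes$sbp_24h_sd[abpm_idx] <- row_sd(sbp_read)
  bp_outcomes$dbp_24h_sd[abpm_idx] <- row_sd(dbp_read)

  ## --- marker gene counts (for rarefaction) ---------------------------
  totals <- round(stats::runif(n, 1.05, 1.6) * 190977)
  gene_counts <- t(vapply(seq_len(n), function(i) {
    pr <- props[i, ]
    as.integer(stats::rmultinom(1L, totals[i], pr))
  }, integer(S)))
  dimnames(gene_counts) <- list(ids, species_ids)

  ## --- metabolites -----------------------------------------------------
  M <- cfg$n_metabolites
  planted_species <- unique(vapply(cfg$planted_effects, function(pe) pe$species, 0))
  linked_species <- species_ids[unique(c(planted_species, seq_len(min(5L, S))))]
  linked_species <- intersect(linked_species, colnames(clr_vals))
  n_linked <- min(length(linked_species) * 2L, M)
  metab <- matrix(stats::rnorm(n * M), n, M,
                  dimnames = list(ids, sprintf("met_%04d", seq_len(M))))
  link_map <- character(0)
  if (n_linked > 0) {
    for (j in seq_len(n_linked)) {
      sp <- linked_species[(j - 1L) %% length(linked_species) + 1L]
      sgn <- if (j > length(linked_species)) -1 else 1
      metab[, j] <- sgn * 1.5 * scale(clr_vals[, sp])[, 1L] + stats::rnorm(n, 0, 0.5)
      link_map[colnames(metab)[j]] <- sp
    }
  }
  annotated <- stats::runif(M) < 0.7
  if (n_linked > 0) annotated[seq_len(n_linked)] <- TRUE
  drug <- matrix(NA_real_, n, 2, dimnames = list(ids, c("omeprazole", "pantoprazole")))
  ppi_users <- which(covariates$ppi)
  if (length(ppi_users)) {
    drug[ppi_users, "omeprazole"] <-
      ifelse(stats::runif(length(ppi_users)) < 0.8,
             exp(stats::rnorm(length(ppi_users))), NA_real_)
    need_panto <- ppi_users[is.na(drug[ppi_users, "omeprazole"])]
    drug[need_panto, "pantoprazole"] <- exp(stats::rnorm(length(need_panto)))
  }
  metabolites <- cbind(metab, drug)
  attr(metabolites, "annotated") <- c(annotated, FALSE, FALSE)

  structure(list(abundance = abundance, gene_counts = gene_counts,
                 covariates = covariates, abpm_series = abpm_series,
                 bp_outcomes = bp_outcomes, metabolites = metabolites,
                 truth = list(planted_effects = cfg$planted_effects,
                              bmi_path = stats::setNames(bmi_path, species_ids),
                              mu_sbp = mu_sbp, mu_dbp = mu_dbp,
                              sigma_sbp = sigma_sbp, sigma_dbp = sigma_dbp,
                              metabolite_links = link_map),
                 config = cfg),
            class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("synth_cohort: %d participants (%d ABPM), %d species, %d metabolites, seed %d\n",
              nrow(x$covariates), sum(x$bp_outcomes$subsample == "ABPM"),
              ncol(x$abundance), ncol(x$metabolites) - 2L, x$config$seed))
  if (length(x$truth$planted_effects)) {
    cat(sprintf("planted effects: %s\n",
                paste(vapply(x$truth$planted_effects, function(pe) {
                  sprintf("sp%04d->%s (%.2f)", pe$species, pe$outcome, pe$beta)
                }, ""), collapse = ", ")))
  }
  invisible(x)
}

#' Generate synthetic GMM definitions with known carriage truth
#'
#' Each module has 1-3 alternative paths of 2-8 steps, each step 1-3
#' alternative KO identifiers; KO identifiers are unique to their
#' module/path/step so carriage is fully controlled. Each species is then
#' assigned, per module, either a carrying KO repertoire (every step of one
#' path when the path has three or fewer steps, otherwise just enough steps to
#' reach the two-thirds fraction) or a deliberately deficient one, giving a
#' known ground-truth carriage table.
#'
#' @param n_modules Number of modules (>= 1).
#' @param species_ids Character vector of species.
#' @param carrier_prob Probability that a given species carries a given
#'   module.
#' @param seed Integer seed.
#' @return List: `gmms` (list of [gmm_definition]), `ko_profiles` (named list
#'   species -> KO vector), `truth` (species x module logical matrix).
#' @export
generate_gmm_definitions <- function(n_modules, species_ids, carrier_prob = 0.3,
                                     seed = 1L) {
  if (n_modules < 1) stop_config("n_modules must be at least 1")
  with_local_seed(seed, {
    ko_counter <- 0L
    new_kos <- function(k) {
      ko_counter <<- ko_counter + k
      sprintf("K%05d", seq(ko_counter - k + 1L, ko_counter))
    }
    gmms <- lapply(seq_len(n_modules), function(mi) {
      n_paths <- sample(1:3, 1L)
      paths <- lapply(seq_len(n_paths), function(pi) {
        n_steps <- sample(2:8, 1L)
        lapply(seq_len(n_steps), function(si) new_kos(sample(1:3, 1L)))
      })
      gmm_definition(sprintf("MF%04d", mi), paths)
    })
    truth <- matrix(FALSE, length(species_ids), n_modules,
                    dimnames = list(species_ids, vapply(gmms, `[[`, "", "module_id")))
    ko_profiles <- stats::setNames(vector("list", length(species_ids)), species_ids)
    for (s in seq_along(species_ids)) {
      kos <- character(0)
      for (mi in seq_len(n_modules)) {
        paths <- gmms[[mi]]$paths
        carrier <- stats::runif(1) < carrier_prob
        truth[s, mi] <- carrier
        path <- paths[[sample.int(length(paths), 1L)]]
        L <- length(path)
        need <- if (L <= 3L) L else ceiling(2 * L / 3)
        n_steps <- if (carrier) need else max(0L, min(need - 1L, L - 1L))
        if (n_steps > 0L) {
          chosen <- sample.int(L, n_steps)
          kos <- c(kos, vapply(path[chosen], function(st) st[sample.int(length(st), 1L)], ""))
        }
      }
      ko_profiles[[s]] <- kos
    }
    list(gmms = gmms, ko_profiles = ko_profiles, truth = truth)
  })
}
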