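# Orchestration: run configuration, file IO for the standard pipeline inputs,
# and the three entry points bp_simulate(), bp_run(), bp_report().

#' Build a run configuration
#'
#' @param input_dir Directory holding the pipeline input files (as written by
#'   [bp_simulate]).
#' @param output_dir Directory for result tables and the run manifest.
#' @param model1 Character vector of Model-1 covariates (includes `bmi`).
#' @param model2 Model-2 covariates (Model 1 without `bmi`).
#' @param min_abund,min_prev Species filter thresholds.
#' @param rarefaction_depth Counts per sample for rarefaction.
#' @param fdr Discovery threshold.
#' @param n_perm Permutations for D-MANOVA and enrichment.
#' @param min_set_size Minimum enrichment set size.
#' @param top_k Top annotated metabolite associations per species.
#' @param scenarios Sensitivity scenarios to run (subset of
#'   `c("antibiotics", "ibd", "ppi", "pcs")`).
#' @param abpm_qc Optional predicate: data frame of per-participant reading
#'   counts -> logical removal vector (ABPM quality control is study-specific
#'   and therefore pluggable).
#' @param seed Integer seed (mandatory).
#' @return Object of class `run_config`.
#' @export
run_config <- function(input_dir, output_dir,
                       model1 = c("age", "sex", "country_of_birth", "smoker",
                                  "fiber_density", "energy_kcal", "log_sodium",
                                  "antidiabetic_med", "antihyperlipidemic_med",
                                  "plate", "bmi"),
                       model2 = setdiff(model1, "bmi"),
                       min_abund = 1e-4, min_prev = 0.30,
                       rarefaction_depth = 190977L, fdr = 0.05,
                       n_perm = 999L, min_set_size = 5L, top_k = 10L,
                       scenarios = c("antibiotics", "ibd", "ppi", "pcs"),
                       abpm_qc = NULL, seed) {
  if (missing(seed)) stop_config("seed is mandatory")
  if (fdr <= 0 || fdr >= 1) stop_config("fdr must lie in (0, 1)")
  if (!dir.exists(input_dir)) stop_config("input_dir does not exist: %s", input_dir)
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 model1 = model1, model2 = model2,
                 min_abund = min_abund, min_prev = min_prev,
                 rarefaction_depth = as.integer(rarefaction_depth), fdr = fdr,
                 n_perm = as.integer(n_perm),
                 min_set_size = as.integer(min_set_size),
                 top_k = as.integer(top_k), scenarios = scenarios,
                 abpm_qc = abpm_qc, seed = as.integer(seed)),
            class = "run_config")
}

.write_tsv <- function(df, path, rownames_as = NULL) {
  if (!is.null(rownames_as)) {
    df <- cbind(stats::setNames(data.frame(rownames(df)), rownames_as),
                as.data.frame(df))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_matrix_tsv <- function(path, id_col) {
  tab <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(tab[, setdiff(names(tab), id_col), drop = FALSE])
  rownames(m) <- tab[[id_col]]
  m
}

#' Write a synthetic cohort to the standard pipeline input files
#'
#' Generates a cohort from `config` and writes `abundance.tsv`,
#' `species_genus.tsv`, `gene_counts.tsv`, `covariates.tsv`, `abpm.tsv`
#' (long format), `office_bp.tsv`, `metabolites.tsv`,
#' `metabolite_annotation.tsv`, `ko_profiles.tsv`, `gmm_definitions.tsv` and a
#' `truth.json` manifest into `dir`.
#'
#' @param config A [synth_config].
#' @param dir Output directory (created if needed).
#' @param n_modules Number of synthetic GMM definitions.
#' @return Invisibly, the generated `synth_cohort` (with `gmm` attached).
#' @export
bp_simulate <- function(config, dir, n_modules = 20L) {
  suppressWarnings(dir.create(dir, showWarnings = FALSE, recursive = TRUE))
  if (!dir.exists(dir)) stop_input("cannot create directory %s", dir)
  cohort <- generate_cohort(config)
  gmm <- generate_gmm_definitions(n_modules, colnames(cohort$abundance),
                                  seed = child_seed(config$seed, 99L))
  .write_tsv(unclass(cohort$abundance), file.path(dir, "abundance.tsv"), "sample_id")
  .write_tsv(data.frame(species = colnames(cohort$abundance),
                        genus = attr(cohort$abundance, "genus")),
             file.path(dir, "species_genus.tsv"))
  .write_tsv(cohort$gene_counts, file.path(dir, "gene_counts.tsv"), "sample_id")
  .write_tsv(cohort$covariates, file.path(dir, "covariates.tsv"))
  .write_tsv(cohort$abpm_series, file.path(dir, "abpm.tsv"))
  .write_tsv(cohort$bp_outcomes[, c("id", "subsample", "office_sbp", "office_dbp")],
             file.path(dir, "office_bp.tsv"))
  .write_tsv(cohort$metabolites, file.path(dir, "metabolites.tsv"), "sample_id")
  .write_tsv(data.frame(metabolite = colnames(cohort$metabolites),
                        annotated = attr(cohort$metabolites, "annotated")),
             file.path(dir, "metabolite_annotation.tsv"))
  .write_tsv(data.frame(species = names(gmm$ko_profiles),
                        kos = vapply(gmm$ko_profiles, paste, "", collapse = ",")),
             file.path(dir, "ko_profiles.tsv"))
  write_gmm_definitions(gmm$gmms, file.path(dir, "gmm_definitions.tsv"))
  truth <- list(planted_effects = config$planted_effects, seed = config$seed,
                gmm_truth = apply(gmm$truth, 1L, function(r) names(which(r)),
                                  simplify = FALSE))
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE)
  cohort$gmm <- gmm
  invisible(cohort)
}

# Read the standard input file set written by bp_simulate().
.read_inputs <- function(input_dir) {
  need <- function(f) {
    p <- file.path(input_dir, f)
    if (!file.exists(p)) stop_input("missing input file: %s", p)
    p
  }
  genus_tab <- utils::read.delim(need("species_genus.tsv"))
  ab <- .read_matrix_tsv(need("abundance.tsv"), "sample_id")
  ann <- utils::read.delim(need("metabolite_annotation.tsv"))
  ko_tab <- utils::read.delim(need("ko_profiles.tsv"))
  list(abundance = abundance_table(ab, stats::setNames(genus_tab$genus, genus_tab$species)),
       gene_counts = .read_matrix_tsv(need("gene_counts.tsv"), "sample_id"),
       covariates = utils::read.delim(need("covariates.tsv"), stringsAsFactors = FALSE),
       abpm = utils::read.delim(need("abpm.tsv")),
       office = utils::read.delim(need("office_bp.tsv")),
       metabolites = .read_matrix_tsv(need("metabolites.tsv"), "sample_id"),
       annotated = stats::setNames(ann$annotated, ann$metabolite),
       ko_profiles = stats::setNames(strsplit(ko_tab$kos, ","), ko_tab$species),
       gmms = read_gmm_definitions(need("gmm_definitions.tsv")))
}

# Stage 1: cohort assembly. Returns the analysis data frame (one row per
# eligible participant) plus the exclusion flow ledger.
.stage_cohort <- function(inp, cfg) {
  cov <- inp$covariates
  cov$country_of_birth <- factor(cov$country_of_birth,
                                 levels = c("Scandinavia", "Europe", "Asia", "Other"))
  cov$sex <- factor(cov$sex, levels = c("female", "male"))
  cov$plate <- factor(cov$plate)
  implausible <- energy_plausibility_filter(cov$sex, cov$energy_kcal)
  cov$energy_kcal[implausible] <- NA
  cov$fiber_g[implausible] <- NA
  cov$fiber_density <- ifelse(is.na(cov$energy_kcal), NA,
                              fiber_per_1000kcal(ifelse(is.na(cov$fiber_g), 0, cov$fiber_g),
                                                 ifelse(is.na(cov$energy_kcal), 1, cov$energy_kcal)))
  sodium <- kawasaki_sodium(cov$sex, cov$age, cov$weight, cov$height,
                            cov$spot_na, cov$spot_cr)
  cov$sodium_mg_day <- sodium$sodium_mg_day
  cov$log_sodium <- sodium$log_sodium
  cov$ppi <- ppi_flag(inp$metabolites[match(cov$id, rownames(inp$metabolites)), ,
                                      drop = FALSE])

  ## 24-h summaries from the reading series
  series <- split(inp$abpm, inp$abpm$participant_id)
  summaries <- do.call(rbind, lapply(series, function(s) {
    as.data.frame(as.list(summarize_abpm(s)))
  }))
  summaries$id <- names(series)
  n_readings <- vapply(series, nrow, 0L)
  dat <- merge(cov, inp$office, by = "id", all.x = TRUE)
  dat <- merge(dat, summaries, by = "id", all.x = TRUE)
  dat$n_readings <- n_readings[match(dat$id, names(n_readings))]
  dat <- dat[order(dat$id), , drop = FALSE]

  model1_cols <- c("age", "sex", "country_of_birth", "smoker", "fiber_density",
                   "energy_kcal", "log_sodium", "antidiabetic_med",
                   "antihyperlipidemic_med", "plate", "bmi")
  bp_cols <- c("office_sbp", "office_dbp")
  rules <- list(
    antihypertensive_med = function(d) as.logical(d$antihypertensive_med),
    missing_covariate_or_bp = function(d) !complete_cases_for(d, c(model1_cols, bp_cols)),
    abpm_qc_fail = function(d) {
      fail <- rep(FALSE, nrow(d))
      if (!is.null(cfg$abpm_qc)) {
        fail <- cfg$abpm_qc(d) & d$subsample == "ABPM"
      }
      fail
    })
  flow <- apply_exclusions(dat, rules)
  eligible <- flow$eligible
  eligible$subsample[is.na(eligible$sbp_24h_mean) & eligible$subsample == "ABPM"] <- "non-ABPM"
  list(data = eligible, ledger = flow$ledger, n_input = flow$n_input,
       n_eligible = flow$n_eligible)
}

#' Run the full analysis pipeline
#'
#' Executes cohort assembly, compositional preprocessing, the D-MANOVA model
#' sequence, the Model-1/Model-2 association screens with office-BP
#' replication, genus/GMM enrichment, the metabolite screen for BP-signature
#' species, and the sensitivity suite; writes every result table as TSV plus
#' a JSON run manifest into `config$output_dir`.
#'
#' @param config A [run_config].
#' @return Object of class `bp_run`: list of all stage results plus the
#'   manifest.
#' @export
bp_run <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(stage, fmt, ...) {
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  inp <- .read_inputs(config$input_dir)
  log_msg("input", "%d samples x %d species; %d metabolites",
          nrow(inp$abundance), ncol(inp$abundance), ncol(inp$metabolites))

  ## ---- cohort ---------------------------------------------------------
  coh <- .stage_cohort(inp, config)
  dat <- coh$data
  log_msg("cohort", "%d -> %d eligible (%s); ABPM %d, non-ABPM %d",
          coh$n_input, coh$n_eligible,
          paste(names(coh$ledger), coh$ledger, sep = "=", collapse = ", "),
          sum(dat$subsample == "ABPM"), sum(dat$subsample == "non-ABPM"))

  ## ---- compositional --------------------------------------------------
  ab_eligible <- structure(
    unclass(inp$abundance)[match(dat$id, rownames(inp$abundance)), , drop = FALSE],
    genus = attr(inp$abundance, "genus"),
    class = class(inp$abundance))
  filtered <- filter_species(ab_eligible, config$min_abund, config$min_prev)
  clr <- clr_transform(filtered)
  counts <- inp$gene_counts[match(dat$id, rownames(inp$gene_counts)), , drop = FALSE]
  rare <- rarefy_counts(counts, config$rarefaction_depth,
                        seed = child_seed(config$seed, 1L))
  dat$shannon <- alpha_diversity(rare, "shannon")
  log_msg("compositional", "%d/%d species retained; pseudo-value %.3g",
          ncol(filtered), ncol(inp$abundance), clr$pseudo_value)

  is_abpm <- dat$subsample == "ABPM"
  abpm <- dat[is_abpm, , drop = FALSE]
  nonabpm <- dat[!is_abpm, , drop = FALSE]
  clr_abpm <- clr$values[is_abpm, , drop = FALSE]
  clr_non <- clr$values[!is_abpm, , drop = FALSE]

  ## ---- D-MANOVA -------------------------------------------------------
  D <- bray_curtis(filtered[is_abpm, , drop = FALSE])
  G <- gower_center(D)
  baseline <- config$model1
  dmanova <- list(
    sbp = run_dmanova_sequence(
      G, list(baseline = baseline,
              office = c(baseline, "office_sbp"),
              abpm24 = c(baseline, "office_sbp", "sbp_24h_mean")),
      data = abpm, n_perm = config$n_perm, seed = child_seed(config$seed, 2L)),
    dbp = run_dmanova_sequence(
      G, list(baseline = baseline,
              office = c(baseline, "office_dbp"),
              abpm24 = c(baseline, "office_dbp", "dbp_24h_mean")),
      data = abpm, n_perm = config$n_perm, seed = child_seed(config$seed, 3L)))
  log_msg("dmanova", "baseline pseudo-R2 %.4f", dmanova$sbp$pseudo_r2[1L])

  ## ---- association screens -------------------------------------------
  outcomes24 <- abpm[, c("sbp_24h_mean", "dbp_24h_mean", "sbp_24h_sd", "dbp_24h_sd")]
  screen1 <- run_screen(clr_abpm, abpm$shannon, outcomes24, abpm,
                        config$model1, model = 1, fdr = config$fdr)
  screen2 <- run_screen(clr_abpm, abpm$shannon, outcomes24, abpm,
                        config$model2, model = 2, fdr = config$fdr)
  office_repl <- run_screen(clr_non, nonabpm$shannon,
                            nonabpm[, c("office_sbp", "office_dbp")],
                            nonabpm, config$model1, model = 1, fdr = config$fdr)
  model_comparison <- compare_models(screen1, screen2)
  log_msg("assoc", "model 1: %d discoveries; model 2: %d; office replication: %d",
          sum(screen1$discovery), sum(screen2$discovery), sum(office_repl$discovery))

  ## ---- enrichment -----------------------------------------------------
  catalog <- build_species_sets(filtered, inp$gmms, inp$ko_profiles,
                                config$min_set_size)
  s1 <- as.data.frame(screen1)
  enrich <- lapply(stats::setNames(nm = names(outcomes24)), function(oc) {
    block <- s1[s1$outcome == oc & s1$exposure_type == "species", ]
    enrichment_test(make_ranking(block), catalog, n_perm = config$n_perm,
                    seed = child_seed(config$seed, 4L),
                    min_set_size = config$min_set_size, fdr = config$fdr)
  })
  log_msg("enrich", "%d sets tested per outcome; flagged: %s",
          nrow(enrich[[1L]]),
          paste(vapply(enrich, function(e) sum(e$flagged), 0L), collapse = "/"))

  ## ---- metabolite profiling ------------------------------------------
  signature <- unique(s1$exposure[s1$discovery & s1$exposure_type == "species"])
  if (!length(signature)) {
    sp_rows <- s1[s1$exposure_type == "species", ]
    signature <- unique(sp_rows$exposure[order(sp_rows$p)])[seq_len(min(4L, ncol(clr_abpm)))]
    log_msg("metab", "no discoveries; profiling the %d smallest-p species instead",
            length(signature))
  }
  metab_cov <- covariate_design(dat, c("age", "sex", "country_of_birth", "plate", "bmi"))
  metab <- metabolite_screen(clr$values[, signature, drop = FALSE],
                             inp$metabolites[match(dat$id, rownames(inp$metabolites)),
                                             colnames(inp$metabolites) != "omeprazole" &
                                               colnames(inp$metabolites) != "pantoprazole",
                                             drop = FALSE],
                             annotated = inp$annotated[!names(inp$annotated) %in%
                                                         c("omeprazole", "pantoprazole")],
                             covariates = metab_cov, top_k = config$top_k)
  log_msg("metab", "%d signature species x %d metabolites",
          length(signature), length(unique(metab$results$metabolite)))

  ## ---- sensitivity ----------------------------------------------------
  influence <- NULL
  disc <- s1[s1$discovery & s1$exposure_type == "species", ]
  if (nrow(disc)) {
    X1 <- covariate_design(abpm, config$model1)
    influence <- do.call(rbind, lapply(seq_len(nrow(disc)), function(i) {
      rep_i <- influence_verdict(outcomes24[[disc$outcome[i]]],
                                 clr_abpm[, disc$exposure[i]], X1)
      data.frame(exposure = disc$exposure[i], outcome = disc$outcome[i],
                 beta_full = rep_i$beta_full, beta_dropped = rep_i$beta_dropped,
                 p_dropped = rep_i$p_dropped, verdict = rep_i$verdict)
    }))
  }
  sens <- sensitivity_suite(clr_abpm, abpm$shannon, outcomes24, abpm,
                            config$model1, main = screen1,
                            scenarios = config$scenarios, fdr = config$fdr)
  log_msg("robust", "%d influence verdicts; %d scenarios",
          if (is.null(influence)) 0L else nrow(influence), length(sens$screens))

  ## ---- outputs + manifest ---------------------------------------------
  .write_tsv(as.data.frame(screen1), file.path(out, "assoc_model1.tsv"))
  .write_tsv(as.data.frame(screen2), file.path(out, "assoc_model2.tsv"))
  .write_tsv(as.data.frame(office_repl), file.path(out, "assoc_office_replication.tsv"))
  .write_tsv(model_comparison, file.path(out, "model_comparison.tsv"))
  for (oc in names(enrich)) {
    .write_tsv(as.data.frame(enrich[[oc]]), file.path(out, sprintf("enrichment_%s.tsv", oc)))
  }
  .write_tsv(metab$results, file.path(out, "metabolite_correlations.tsv"))
  .write_tsv(metab$top, file.path(out, "metabolite_top.tsv"))
  if (!is.null(influence)) .write_tsv(influence, file.path(out, "influence_reports.tsv"))
  if (!is.null(sens$comparison)) .write_tsv(sens$comparison, file.path(out, "sensitivity_comparison.tsv"))
  for (scen in names(sens$screens)) {
    .write_tsv(as.data.frame(sens$screens[[scen]]),
               file.path(out, sprintf("sensitivity_%s.tsv", scen)))
  }
  dmj <- lapply(dmanova, function(d) as.data.frame(d))
  jsonlite::write_json(dmj, file.path(out, "dmanova.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(list(n_input = coh$n_input, exclusions = as.list(coh$ledger),
                            n_eligible = coh$n_eligible,
                            n_abpm = nrow(abpm), n_non_abpm = nrow(nonabpm)),
                       file.path(out, "flow_report.json"), auto_unbox = TRUE)

  cfg_manifest <- config[setdiff(names(config), "abpm_qc")]
  outputs <- sort(setdiff(list.files(out), "manifest.json"))
  manifest <- list(config = cfg_manifest, seed = config$seed,
                   n_species_retained = ncol(filtered),
                   pseudo_value = clr$pseudo_value,
                   flow = list(n_input = coh$n_input, n_eligible = coh$n_eligible,
                               n_abpm = nrow(abpm), n_non_abpm = nrow(nonabpm)),
                   output_md5 = as.list(stats::setNames(
                     unname(tools::md5sum(file.path(out, outputs))), outputs)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(list(cohort = coh, data = dat, clr = clr, dmanova = dmanova,
                 screen_model1 = screen1, screen_model2 = screen2,
                 office_replication = office_repl,
                 model_comparison = model_comparison, enrichment = enrich,
                 metabolites = metab, influence = influence, sensitivity = sens,
                 manifest = manifest),
            class = "bp_run")
}

#' @export
print.bp_run <- function(x, ...) {
  f <- x$manifest$flow
  cat(sprintf("bp_run: %d eligible (ABPM %d / non-ABPM %d); %d species retained\n",
              f$n_eligible, f$n_abpm, f$n_non_abpm, x$manifest$n_species_retained))
  cat(sprintf("Model 1 discoveries: %d; Model 2: %d\n",
              sum(x$screen_model1$discovery), sum(x$screen_model2$discovery)))
  invisible(x)
}

#' Human-readable summary of a pipeline output directory
#'
#' Renders the participant flow, the diversity association table, the species
#' discovery list, the enrichment summary and the sensitivity comparison from
#' the TSV/JSON files written by [bp_run].
#'
#' @param output_dir Directory written by [bp_run].
#' @return Invisibly, the character vector of report lines (also printed).
#' @export
bp_report <- function(output_dir) {
  need <- function(f) {
    p <- file.path(output_dir, f)
    if (!file.exists(p)) stop_input("missing pipeline output: %s (run bp_run first)", f)
    p
  }
  flow <- jsonlite::read_json(need("flow_report.json"))
  s1 <- utils::read.delim(need("assoc_model1.tsv"))
  lines <- c(
    "=== Gut microbiome / 24-h BP analysis report ===",
    sprintf("Participants: %d input, %d eligible (ABPM %d, non-ABPM %d)",
            flow$n_input, flow$n_eligible, flow$n_abpm, flow$n_non_abpm),
    sprintf("Exclusions: %s",
            paste(names(flow$exclusions), unlist(flow$exclusions),
                  sep = "=", collapse = ", ")),
    "", "Diversity associations (Model 1):")
  div <- s1[s1$exposure_type == "diversity", ]
  lines <- c(lines, sprintf("  %-14s beta %7.3f (%7.3f, %7.3f)  p %.3g  q %.3g",
                            div$outcome, div$beta, div$ci_low, div$ci_high,
                            div$p, div$q))
  disc <- s1[s1$exposure_type == "species" & s1$discovery, ]
  lines <- c(lines, "", sprintf("Species discoveries at 5%% FDR (Model 1): %d", nrow(disc)))
  if (nrow(disc)) {
    lines <- c(lines, sprintf("  %s ~ %s: beta %.3f (%.3f, %.3f), q %.3g",
                              disc$exposure, disc$outcome, disc$beta,
                              disc$ci_low, disc$ci_high, disc$q))
  } else {
    lines <- c(lines, "  none")
  }
  enr_files <- list.files(output_dir, pattern = "^enrichment_.*\\.tsv$")
  if (length(enr_files)) {
    lines <- c(lines, "", "Enrichment (flagged sets per outcome):")
    for (f in enr_files) {
      e <- utils::read.delim(file.path(output_dir, f))
      lines <- c(lines, sprintf("  %s: %d/%d flagged",
                                sub("^enrichment_(.*)\\.tsv$", "\\1", f),
                                sum(e$flagged), nrow(e)))
    }
  }
  sc <- file.path(output_dir, "sensitivity_comparison.tsv")
  if (file.exists(sc)) {
    comp <- utils::read.delim(sc)
    lines <- c(lines, "", "Sensitivity comparison (main vs scenario betas):",
               sprintf("  [%s] %s ~ %s: %.3f -> %.3f", comp$scenario,
                       comp$exposure, comp$outcome, comp$beta_main,
                       comp$beta_scenario))
  } else {
    lines <- c(lines, "", "Sensitivity comparison: no discoveries to compare")
  }
  missing_stage <- setdiff(c("assoc_model2.tsv", "metabolite_correlations.tsv"),
                           list.files(output_dir))
  if (length(missing_stage)) {
    lines <- c(lines, "", sprintf("Missing stage outputs: %s",
                                  paste(missing_stage, collapse = ", ")))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
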