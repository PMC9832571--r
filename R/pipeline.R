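#' Run the full mismatch-demography pipeline
#'
#' Orchestrates the stages end to end: simulate (or ingest) the three
#' tables, estimate phenologies and mismatches, score diet
#' generalization, impute brood cells where only cavity length was
#' recorded, fit the mismatch-recruitment models, and compute per-species
#' demography. Stage outputs are written as CSV under `out_dir` together
#' with a JSON run manifest recording the configuration digest, seed,
#' excluded taxon-seasons, imputation counts and warnings.
#'
#' @param config a `bee_scenario`, a path to a scenario YAML, or `NULL`
#'   when all three `inputs` paths are given.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for simulation and bootstraps.
#' @param inputs optional named list of CSV paths (`flowers`, `nests`,
#'   `pollen`) to ingest instead of simulating.
#' @param n_boot bootstrap resamples for demography and the cross-species
#'   mean.
#' @param threshold main-resource threshold.
#' @param stratify_sites keep sites separate in the flower pooling.
#' @return the run manifest (list), invisibly. Manifest fields:
#'   `package_version`, `config_digest`, `seed`, `stages` (named output
#'   paths), `excluded_years`, `n_imputed`, `cross_species`, `warnings`.
#' @export
run_pipeline <- function(config = default_scenario(), out_dir,
                         seed = 1L, inputs = NULL, n_boot = 1000,
                         threshold = 0.85, stratify_sites = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    message("[matchdem] ", msg)
    invisible(msg)
  }
  collect_warning <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  if (is.character(config)) config <- read_scenario(config)

  stages <- list()
  if (!is.null(inputs)) {
    if (!all(c("flowers", "nests", "pollen") %in% names(inputs)))
      md_config_error(
        "inputs must name flowers, nests and pollen CSV paths (or simulate)")
    note("ingesting field tables")
    flowers <- read_floral_surveys(inputs$flowers)
    nests <- read_nest_records(inputs$nests)
    pollen <- read_pollen_samples(inputs$pollen)
  } else {
    if (!inherits(config, "bee_scenario"))
      md_config_error("config must be a bee_scenario (or provide inputs)")
    note("simulating scenario (seed %d)", seed)
    sim <- simulate_scenario(config, seed = seed)
    flowers <- sim$flowers; nests <- sim$nests; pollen <- sim$pollen
  }
  stages$tables <- file.path(out_dir,
                             c("flowers.csv", "nests.csv", "pollen.csv"))
  write_canonical_csv(flowers, stages$tables[1])
  write_canonical_csv(nests[, .nest_cols], stages$tables[2])
  write_canonical_csv(pollen, stages$tables[3])

  note("phenology and mismatch")
  phen <- analyze_phenology(flowers, nests, pollen, threshold = threshold,
                            stratify_sites = stratify_sites)
  stages$phenology <- file.path(out_dir, "phenology_population.csv")
  write_canonical_csv(phen$per_population, stages$phenology)
  per_nest_path <- file.path(out_dir, "phenology_nests.csv")
  write_canonical_csv(phen$per_nest, per_nest_path)
  stages$phenology_nests <- per_nest_path
  for (i in seq_len(nrow(phen$excluded)))
    warnings_log <- c(warnings_log, sprintf(
      "excluded %s season %d: %s", phen$excluded$bee_taxon[i],
      phen$excluded$season_year[i], phen$excluded$reason[i]))

  note("diet generalization")
  gen <- generalization_scores(pollen, nests)
  stages$generalization <- file.path(out_dir, "generalization.csv")
  write_canonical_csv(gen, stages$generalization)

  note("brood-cell imputation")
  need_imp <- sort(unique(nests$bee_taxon[is.na(nests$brood_cells)]))
  if (length(need_imp) > 0) {
    models_cl <- collect_warning(fit_imputation_models(nests, need_imp))
    nests_full <- collect_warning(impute_brood_cells(nests, models_cl))
  } else {
    nests_full <- nests
    nests_full$estimated <- FALSE
  }
  n_imputed <- sum(nests_full$estimated)
  stages$imputation <- file.path(out_dir, "nests_imputed.csv")
  write_canonical_csv(nests_full, stages$imputation)

  note("mismatch-recruitment models")
  per_nest_full <- merge(phen$per_nest[, c("nest_id", "bee_taxon",
                                           "season_year", "end_day",
                                           "flowering_wmd",
                                           "mismatch_days")],
                         nests_full[, c("nest_id", "brood_cells",
                                        "estimated")],
                         by = "nest_id")
  fits <- collect_warning(fit_species_models(per_nest_full))
  xs <- cross_species_mean(setNames(fits$std_slope, fits$bee_taxon),
                           n_boot = n_boot, seed = seed)
  pop_tab <- population_table(phen$per_population, nests_full)
  rho <- do.call(rbind, lapply(split(pop_tab, pop_tab$bee_taxon),
                               function(d) {
    r <- tryCatch(collect_warning(population_spearman(d)),
                  matchdem_error = function(e) NULL)
    if (is.null(r)) return(NULL)
    data.frame(bee_taxon = d$bee_taxon[1], rho = r$rho, rho_se = r$rho_se,
               n_years = r$n_years)
  }))
  fits_out <- if (!is.null(rho)) merge(fits, rho, by = "bee_taxon",
                                       all.x = TRUE) else fits
  stages$models <- file.path(out_dir, "models.csv")
  write_canonical_csv(fits_out, stages$models)

  note("demography")
  demo <- do.call(rbind, lapply(split(nests_full, nests_full$bee_taxon),
                                function(d) {
    res <- tryCatch(collect_warning(
      species_demography(d, n_boot = n_boot, seed = seed)),
      matchdem_error = function(e) {
        warnings_log <<- c(warnings_log, sprintf(
          "demography undefined for %s: %s", d$bee_taxon[1],
          conditionMessage(e)))
        NULL
      })
    if (is.null(res)) return(NULL)
    data.frame(bee_taxon = res$bee_taxon, lambda_bar = res$lambda_bar,
               ci_low = res$ci_low, ci_high = res$ci_high,
               n_transitions = res$n_transitions, n_boot = res$n_boot)
  }))
  stages$demography <- file.path(out_dir, "demography.csv")
  write_canonical_csv(demo, stages$demography)

  manifest <- list(
    package_version = as.character(packageVersion("matchdem")),
    config_digest = config_digest(config),
    seed = seed,
    stages = lapply(stages, identity),
    excluded_years = phen$excluded,
    n_imputed = n_imputed,
    cross_species = list(mean = xs$mean_coefficient, ci_low = xs$ci_low,
                         ci_high = xs$ci_high),
    warnings = warnings_log)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  note("done: %d imputed nests, %d excluded taxon-seasons", n_imputed,
       nrow(phen$excluded))
  invisible(manifest)
}

# Stable digest of a scenario: md5 of its canonical YAML serialization.
config_digest <- function(config) {
  if (is.null(config)) return(NA_character_)
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  write_scenario(config, tf)
  unname(tools::md5sum(tf))
}
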