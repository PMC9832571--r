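#' Build a simulation scenario
#'
#' A scenario describes a multi-season trap-nest study: the seasons and
#' sites surveyed, the flowering plant community (Gaussian seasonal
#' abundance curves whose peaks shift from year to year), and the bee
#' species (diet composition over the plants, nesting-date distribution
#' around the flowering of their main resources, and the strength with
#' which per-nest brood production declines with nesting-flowering
#' mismatch on the log scale).
#'
#' @param plants data.frame with columns `taxon`, `peak_day` (day of
#'   season), `peak_sd` (days, width of the seasonal curve),
#'   `peak_abundance` (expected flowers per plot at the peak),
#'   `year_shift_sd` (sd in days of the year-specific peak shift).
#' @param bees data.frame with columns `taxon`, `mismatch_effect` (<= 0,
#'   change in log brood cells per day of mismatch), `mean_cells` (> 1,
#'   expected cells at zero mismatch), `nests_per_year` (Poisson mean),
#'   `nesting_spread` (sd in days of nest end dates around the yearly
#'   centre), `year_shift_sd` (sd in days of the bee-specific yearly
#'   nesting offset), `cells_resid_sd` and `year_effect_sd` (log-scale
#'   noise sds), `diet_concentration` (Dirichlet concentration of per-nest
#'   diets), `pollen_nests` (nests sampled for pollen), `length_measured`
#'   (logical: brood cells inferred from cavity length).
#' @param diet matrix (`nrow(bees)` x `nrow(plants)`) of mean diet
#'   proportions; rows sum to 1.
#' @param n_years,first_season,n_sites,plots_per_site,survey_interval
#'   study layout; surveys run every `survey_interval` days over
#'   `survey_days`.
#' @param survey_days integer vector of day-of-season survey dates.
#' @param pollen_seasons number of initial seasons in which pollen is
#'   collected.
#' @param mask_fraction fraction of a length-measured species' nests whose
#'   direct count is masked (to be imputed from cavity length).
#' @param length_intercept,length_slope,length_sd cavity-length model:
#'   `length = intercept + slope * cells + N(0, sd)` mm.
#' @param resource_threshold cumulative diet share defining each bee's
#'   true main-resource set.
#' @param pollen_grains expected grains counted per sampled nest.
#' @param seed default seed used by [simulate_scenario()].
#' @return object of class `bee_scenario` (a validated list).
#' @export
scenario_config <- function(plants, bees, diet,
                            n_years = 9, first_season = 2006, n_sites = 2,
                            plots_per_site = 3, survey_interval = 7,
                            survey_days = seq(28, 140, by = survey_interval),
                            pollen_seasons = 3, mask_fraction = 0.7,
                            length_intercept = 10, length_slope = 14,
                            length_sd = 5, resource_threshold = 0.85,
                            pollen_grains = 600, seed = 1L) {
  cfg <- structure(list(plants = plants, bees = bees, diet = as.matrix(diet),
                        n_years = n_years, first_season = first_season,
                        n_sites = n_sites, plots_per_site = plots_per_site,
                        survey_interval = survey_interval,
                        survey_days = survey_days,
                        pollen_seasons = pollen_seasons,
                        mask_fraction = mask_fraction,
                        length_intercept = length_intercept,
                        length_slope = length_slope, length_sd = length_sd,
                        resource_threshold = resource_threshold,
                        pollen_grains = pollen_grains, seed = seed),
                   class = "bee_scenario")
  validate_scenario(cfg)
}

#' @rdname scenario_config
#' @param x object to validate.
#' @export
validate_scenario <- function(x) {
  req_p <- c("taxon", "peak_day", "peak_sd", "peak_abundance", "year_shift_sd")
  req_b <- c("taxon", "mismatch_effect", "mean_cells", "nests_per_year",
             "nesting_spread", "year_shift_sd", "cells_resid_sd",
             "year_effect_sd", "diet_concentration", "pollen_nests",
             "length_measured")
  if (!all(req_p %in% names(x$plants)))
    md_config_error("plants table is missing required columns")
  if (!all(req_b %in% names(x$bees)))
    md_config_error("bees table is missing required columns")
  if (!identical(dim(x$diet), c(nrow(x$bees), nrow(x$plants))))
    md_config_error("diet matrix must be n_bees x n_plants")
  if (any(abs(rowSums(x$diet) - 1) > 1e-6))
    md_config_error("diet rows must sum to 1")
  if (any(x$plants$peak_sd <= 0) || any(x$plants$peak_abundance <= 0))
    md_config_error("plant spreads and abundances must be positive")
  if (any(x$bees$mismatch_effect > 0))
    md_config_error("mismatch_effect must be <= 0")
  if (any(x$bees$mean_cells <= 1))
    md_config_error("mean_cells must exceed 1")
  if (x$survey_interval < 1) md_config_error("survey_interval must be >= 1")
  if (x$n_years < 1 || x$n_sites < 1) md_config_error("invalid study layout")
  rownames(x$diet) <- x$bees$taxon
  colnames(x$diet) <- x$plants$taxon
  x
}

#' The default study scenario
#'
#' Emulates the scale of a nine-season, two-site trap-nest study of five
#' cavity-nesting bee species spanning a specialization gradient over an
#' eight-species flowering community. Species 1 is the strict specialist
#' (one cactus-like resource, strongest mismatch effect, cells inferred
#' from cavity length), species 5 the broad generalist (near-uniform diet,
#' no mismatch effect, also length-measured); expected nest totals across
#' the nine seasons are roughly 70/430/150/45/60 and pollen is examined
#' in the first three seasons only.
#'
#' @param seed stored default seed.
#' @return a `bee_scenario`.
#' @export
default_scenario <- function(seed = 1L) {
  plants <- data.frame(
    taxon = c("cactus_a", "shrub_a", "tree_a", "herb_a", "herb_b",
              "shrub_b", "herb_c", "herb_d"),
    peak_day = c(62, 78, 90, 52, 70, 84, 98, 108),
    peak_sd = c(10, 14, 12, 9, 11, 13, 10, 12),
    peak_abundance = c(180, 420, 260, 90, 120, 150, 80, 60),
    year_shift_sd = 6)
  bees <- data.frame(
    taxon = paste0("bee_sp", 1:5),
    mismatch_effect = c(-0.08, -0.05, -0.03, -0.013, 0),
    mean_cells = c(12, 8, 6, 5, 6),
    nests_per_year = c(8, 48, 17, 5, 7),
    nesting_spread = 14,
    year_shift_sd = 5,
    cells_resid_sd = 0.3,
    year_effect_sd = 0.12,
    diet_concentration = 30,
    pollen_nests = c(32, 51, 18, 8, 14),
    length_measured = c(TRUE, FALSE, FALSE, FALSE, TRUE))
  diet <- rbind(
    c(0.93, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01),
    c(0.02, 0.86, 0.04, 0.01, 0.02, 0.02, 0.02, 0.01),
    c(0.03, 0.12, 0.70, 0.02, 0.06, 0.03, 0.02, 0.02),
    c(0.10, 0.22, 0.16, 0.04, 0.38, 0.02, 0.06, 0.02),
    c(0.18, 0.16, 0.15, 0.13, 0.12, 0.10, 0.09, 0.07))
  scenario_config(plants, bees, diet, seed = seed)
}

#' Read / write a scenario as YAML
#'
#' @param path YAML file path.
#' @return `read_scenario()`: a validated `bee_scenario`;
#'   `write_scenario()`: `path`, invisibly.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) md_config_error(sprintf("file not found: %s", path))
  raw <- yaml::read_yaml(path)
  plants <- do.call(rbind.data.frame, lapply(raw$plants, as.data.frame))
  bees <- do.call(rbind.data.frame, lapply(raw$bees, as.data.frame))
  diet <- do.call(rbind, lapply(raw$diet, unlist))
  args <- raw[setdiff(names(raw), c("plants", "bees", "diet"))]
  do.call(scenario_config, c(list(plants = plants, bees = bees, diet = diet),
                             args))
}

#' @rdname read_scenario
#' @param config a `bee_scenario`.
#' @export
write_scenario <- function(config, path) {
  out <- list(
    plants = lapply(seq_len(nrow(config$plants)),
                    function(i) as.list(config$plants[i, ])),
    bees = lapply(seq_len(nrow(config$bees)),
                  function(i) as.list(config$bees[i, ])),
    diet = lapply(seq_len(nrow(config$diet)),
                  function(i) as.numeric(config$diet[i, ])))
  scalars <- setdiff(names(unclass(config)), c("plants", "bees", "diet"))
  out <- c(out, unclass(config)[scalars])
  yaml::write_yaml(out, path)
  invisible(path)
}

# Each bee's "true" main-resource set: greedy cumulative cut of its mean
# diet at the scenario's resource threshold (mirrors the 85% pollen rule).
scenario_resource_sets <- function(config) {
  sets <- lapply(seq_len(nrow(config$bees)), function(i)
    identify_main_resources(config$diet[i, ],
                            threshold = config$resource_threshold,
                            bee_taxon = config$bees$taxon[i])$plant_taxa)
  setNames(sets, config$bees$taxon)
}

#' Generate weekly floral surveys
#'
#' Each plant's expected abundance follows a Gaussian seasonal curve whose
#' peak day is displaced each year by a normal deviate (`year_shift_sd`).
#' Surveys visit every plot on the scenario's survey days; observed counts
#' are Poisson draws around the plot-level expectation.
#'
#' @param config a `bee_scenario`.
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return validated floral-survey table, with an attribute `peak_shifts`
#'   (matrix plant x year of the drawn peak displacements).
#' @export
generate_flowering <- function(config, seed = NULL) {
  config <- validate_scenario(config)
  with_seed(seed, {
    seasons <- config$first_season + seq_len(config$n_years) - 1L
    shifts <- matrix(rnorm(nrow(config$plants) * config$n_years, 0,
                           config$plants$year_shift_sd),
                     nrow = nrow(config$plants),
                     dimnames = list(config$plants$taxon, seasons))
    rows <- vector("list", 0)
    for (p in seq_len(nrow(config$plants))) {
      pl <- config$plants[p, ]
      for (yi in seq_along(seasons)) {
        mu_curve <- pl$peak_abundance *
          exp(-((config$survey_days - pl$peak_day - shifts[p, yi])^2) /
                (2 * pl$peak_sd^2))
        for (s in seq_len(config$n_sites)) {
          for (u in seq_len(config$plots_per_site)) {
            counts <- rpois(length(config$survey_days), mu_curve)
            rows[[length(rows) + 1]] <- data.frame(
              season_year = seasons[yi], day = config$survey_days,
              site = paste0("site", s), unit = paste0("plot", u),
              plant_taxon = pl$taxon, flower_count = counts)
          }
        }
      }
    }
    out <- do.call(rbind, rows)
    out <- validate_floral_surveys(out)
    attr(out, "peak_shifts") <- shifts
    out
  })
}

#' Generate nest records conditional on a flowering table
#'
#' For each bee species and season, the yearly nesting centre is the
#' pooled flowering WMD of the species' main-resource plants (computed
#' from the generated surveys) plus a species-by-year normal offset. Nest
#' end days are normal around that centre; brood cells follow
#' `max(1, round(exp(log(mean_cells) + mismatch_effect * |end - WMD| +
#' year_effect + noise)))`, so recruitment declines exponentially with
#' mismatch at the configured strength. Length-measured species carry an
#' occupied cavity length linear in the true cell count, with the direct
#' count masked in a configurable fraction of records.
#'
#' @param config a `bee_scenario`.
#' @param flowering floral-survey table from [generate_flowering()].
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return validated nest-record table with attribute `truth`: list with
#'   `flowering_wmd` (data.frame bee_taxon x season_year -> wmd),
#'   `resource_sets`, and `true_cells` (unmasked counts).
#' @export
generate_nests <- function(config, flowering, seed = NULL) {
  config <- validate_scenario(config)
  with_seed(seed, {
    seasons <- config$first_season + seq_len(config$n_years) - 1L
    pooled <- pool_floral_surveys(flowering)
    sets <- scenario_resource_sets(config)
    wmd_truth <- NULL
    rows <- vector("list", 0)
    for (b in seq_len(nrow(config$bees))) {
      bee <- config$bees[b, ]
      for (sy in seasons) {
        wmd <- tryCatch(
          pooled_flowering_wmd(pooled, sets[[bee$taxon]], sy)$wmd,
          matchdem_undefined_phenology = function(e) NA_real_)
        wmd_truth <- rbind(wmd_truth, data.frame(
          bee_taxon = bee$taxon, season_year = sy, wmd = wmd))
        if (is.na(wmd)) next
        n <- rpois(1, bee$nests_per_year)
        if (n == 0) next
        centre <- wmd + rnorm(1, 0, bee$year_shift_sd)
        year_eff <- rnorm(1, 0, bee$year_effect_sd)
        end_day <- pmax(0, round(rnorm(n, centre, bee$nesting_spread)))
        mism <- abs(end_day - wmd)
        log_mu <- log(bee$mean_cells) + bee$mismatch_effect * mism +
          year_eff + rnorm(n, 0, bee$cells_resid_sd)
        cells <- pmax(1, round(exp(log_mu)))
        rows[[length(rows) + 1]] <- data.frame(
          nest_id = sprintf("%s_%d_%03d", bee$taxon, sy, seq_len(n)),
          bee_taxon = bee$taxon, site = paste0("site",
            sample.int(config$n_sites, n, replace = TRUE)),
          season_year = sy, end_day = end_day, brood_cells = cells,
          cavity_length = NA_real_, true_cells = cells)
      }
    }
    nests <- do.call(rbind, rows)
    if (is.null(nests))
      md_config_error("scenario produced no nests")
    for (b in which(config$bees$length_measured)) {
      bt <- config$bees$taxon[b]
      sel <- which(nests$bee_taxon == bt)
      len <- config$length_intercept +
        config$length_slope * nests$brood_cells[sel] +
        rnorm(length(sel), 0, config$length_sd)
      nests$cavity_length[sel] <- round(pmax(len, 1), 1)
      mask <- sel[runif(length(sel)) < config$mask_fraction]
      nests$brood_cells[mask] <- NA_integer_
    }
    true_cells <- nests$true_cells
    nests$true_cells <- NULL
    nests <- validate_nest_records(nests)
    attr(nests, "truth") <- list(flowering_wmd = wmd_truth,
                                 resource_sets = sets,
                                 true_cells = true_cells)
    nests
  })
}

#' Generate pollen samples for a subset of nests
#'
#' Pollen is examined in the first `pollen_seasons` seasons. For each
#' sampled nest, the diet composition is a Dirichlet draw around the
#' species' mean diet (`diet_concentration` controls nest-to-nest
#' variability; a concentration loaded on a single plant yields a strict
#' specialist and a flat one a generalist), and grain counts are a
#' multinomial draw of about `pollen_grains` grains from that composition.
#'
#' @param config a `bee_scenario`.
#' @param nests nest-record table from [generate_nests()].
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return validated pollen-sample table (rows with zero grains dropped).
#' @export
generate_pollen <- function(config, nests, seed = NULL) {
  config <- validate_scenario(config)
  with_seed(seed, {
    pollen_cut <- config$first_season + config$pollen_seasons - 1L
    rows <- vector("list", 0)
    for (b in seq_len(nrow(config$bees))) {
      bee <- config$bees[b, ]
      ids <- nests$nest_id[nests$bee_taxon == bee$taxon &
                             nests$season_year <= pollen_cut]
      if (length(ids) == 0) next
      k <- min(bee$pollen_nests, length(ids))
      take <- if (k == length(ids)) ids else sample(ids, k)
      alpha <- config$diet[b, ] * bee$diet_concentration
      for (id in take) {
        g <- rgamma(length(alpha), shape = alpha)
        if (sum(g) <= 0) g[which.max(alpha)] <- 1
        comp <- g / sum(g)
        total <- rpois(1, config$pollen_grains)
        counts <- as.integer(rmultinom(1, max(total, 1), comp))
        keep <- counts > 0
        rows[[length(rows) + 1]] <- data.frame(
          nest_id = id, plant_taxon = config$plants$taxon[keep],
          grain_count = counts[keep])
      }
    }
    out <- do.call(rbind, rows)
    if (is.null(out)) md_config_error("no nests eligible for pollen sampling")
    validate_pollen_samples(out)
  })
}

#' Simulate a full study
#'
#' Runs the three generators under one seed: flowering first, then nests
#' conditional on flowering, then pollen conditional on nests. All output
#' is bit-reproducible given (`config`, `seed`).
#'
#' @param config a `bee_scenario`.
#' @param seed integer; defaults to the scenario's stored seed.
#' @return list with `flowers`, `nests` (carrying the `truth` attribute),
#'   and `pollen`.
#' @export
simulate_scenario <- function(config, seed = config$seed) {
  with_seed(seed, {
    flowers <- generate_flowering(config)
    nests <- generate_nests(config, flowers)
    pollen <- generate_pollen(config, nests)
    list(flowers = flowers, nests = nests, pollen = pollen)
  })
}
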