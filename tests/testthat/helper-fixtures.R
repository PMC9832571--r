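# In-code fixtures shared across test files.

make_nests <- function(bee_taxon = "bee_x", season_year, end_day,
                       brood_cells = NULL, cavity_length = NA_real_,
                       site = "site1") {
  n <- max(length(end_day), length(season_year),
           if (is.null(brood_cells)) 0L else length(brood_cells),
           length(cavity_length))
  data.frame(nest_id = paste0(bee_taxon, "_", seq_len(n)),
             bee_taxon = bee_taxon, site = site,
             season_year = rep_len(season_year, n),
             end_day = rep_len(end_day, n),
             brood_cells = if (is.null(brood_cells)) NA_integer_
                           else rep_len(brood_cells, n),
             cavity_length = rep_len(cavity_length, n))
}

make_surveys <- function(season_year, day, plant_taxon, flower_count,
                         site = "site1", unit = "plot1") {
  data.frame(season_year = season_year, day = day, site = site, unit = unit,
             plant_taxon = plant_taxon, flower_count = flower_count)
}

# Tiny two-plant, one-bee scenario for fast end-to-end tests.
tiny_scenario <- function(mismatch_effect = -0.03, nests_per_year = 150,
                          n_years = 9, mean_cells = 6, seed = 1L,
                          length_measured = FALSE, nesting_spread = 14) {
  plants <- data.frame(
    taxon = c("plant_a", "plant_b"),
    peak_day = c(70, 95), peak_sd = c(12, 12),
    peak_abundance = c(300, 150), year_shift_sd = 6)
  bees <- data.frame(
    taxon = "bee_x", mismatch_effect = mismatch_effect,
    mean_cells = mean_cells, nests_per_year = nests_per_year,
    nesting_spread = nesting_spread, year_shift_sd = 5,
    cells_resid_sd = 0.3, year_effect_sd = 0.12, diet_concentration = 30,
    pollen_nests = 30, length_measured = length_measured)
  diet <- matrix(c(0.93, 0.07), nrow = 1)
  scenario_config(plants, bees, diet, n_years = n_years, seed = seed)
}

# Nest table with cells drawn 1 + Poisson(mean_t - 1) so that the expected
# seasonal total grows by exactly exp(log_growth) per season.
growth_nests <- function(n_years = 9, nests_per_year = 60, log_growth = 0.2,
                         base_cells = 3, first_season = 2006) {
  rows <- lapply(seq_len(n_years), function(t) {
    m <- base_cells * exp(log_growth * (t - 1))
    make_nests(season_year = first_season + t - 1,
               end_day = rep(70, nests_per_year),
               brood_cells = 1 + rpois(nests_per_year, m - 1))
  })
  out <- do.call(rbind, rows)
  out$nest_id <- paste0("n", seq_len(nrow(out)))
  out
}
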