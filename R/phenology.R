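#' Abundance-weighted mean date (WMD)
#'
#' The phenological centre of a nesting or flowering distribution: each
#' observed day is weighted by the relative abundance recorded on it,
#' `sum(d_i * a_i / sum(a))`. For example, abundances 10, 60 and 30 on
#' days 60, 67 and 74 give `0.1*60 + 0.6*67 + 0.3*74 = 68.4`.
#'
#' @param day numeric vector of day-of-season values.
#' @param abundance non-negative numeric vector, same length as `day`.
#' @return the weighted mean day (numeric scalar), always within
#'   `[min(day), max(day)]`.
#' @examples
#' weighted_mean_date(c(60, 67, 74), c(10, 60, 30))
#' @export
weighted_mean_date <- function(day, abundance) {
  if (length(day) != length(abundance))
    md_contract_error("day and abundance must have equal length")
  if (length(day) == 0)
    md_undefined_phenology("no observations: phenology undefined")
  if (anyNA(day) || anyNA(abundance) || any(abundance < 0))
    md_validation_error("abundances must be non-negative and non-missing")
  total <- sum(abundance)
  if (total <= 0)
    md_undefined_phenology("all abundances zero: phenology undefined")
  sum(day * (abundance / total))
}

#' Identify a bee species' main floral resources
#'
#' Plant taxa are ranked by total (standardized) pollen abundance across
#' all examined nests of the species and taken greedily, in descending
#' order, until they jointly account for at least `threshold` (default
#' 85%) of the pollen. Equal abundances are broken lexicographically by
#' taxon name so the set is deterministic.
#'
#' @param pollen_totals named non-negative numeric vector: plant taxon ->
#'   summed standardized abundance (see
#'   [species_abundance_across_nests()]).
#' @param threshold cumulative proportion at which to stop; in (0, 1].
#' @param bee_taxon optional label stored in the result.
#' @return object of class `main_resources`: list with `bee_taxon`,
#'   `plant_taxa` (ordered), `shares`, `cumulative_share`, `threshold`.
#' @export
identify_main_resources <- function(pollen_totals, threshold = 0.85,
                                    bee_taxon = NA_character_) {
  if (length(pollen_totals) == 0 || is.null(names(pollen_totals)))
    md_contract_error("pollen_totals must be a named numeric vector")
  if (threshold <= 0 || threshold > 1)
    md_config_error("threshold must be in (0, 1]")
  total <- sum(pollen_totals)
  if (!is.finite(total) || total <= 0 || any(pollen_totals < 0))
    md_validation_error("pollen totals must be non-negative with positive sum")
  ord <- order(-pollen_totals, names(pollen_totals))
  shares <- pollen_totals[ord] / total
  cum <- cumsum(shares)
  k <- which(cum >= threshold - 1e-12)[1]
  structure(list(bee_taxon = bee_taxon,
                 plant_taxa = names(shares)[seq_len(k)],
                 shares = shares[seq_len(k)],
                 cumulative_share = unname(cum[k]),
                 threshold = threshold),
            class = "main_resources")
}

#' @export
print.main_resources <- function(x, ...) {
  cat(sprintf("Main floral resources%s (>= %.0f%% of pollen):\n",
              if (is.na(x$bee_taxon)) "" else paste0(" of ", x$bee_taxon),
              100 * x$threshold))
  print(round(x$shares, 3))
  cat(sprintf("cumulative share: %.3f\n", x$cumulative_share))
  invisible(x)
}

#' Flowering WMD of a main-resource set in one season
#'
#' Day-wise flower counts of all main-resource taxa are pooled into one
#' composite seasonal curve, which is then summarized by its weighted mean
#' date. Pooling (rather than averaging per-taxon WMDs) weights each taxon
#' by its floral abundance.
#'
#' @param surveys pooled floral surveys (see [pool_floral_surveys()]).
#' @param resources a `main_resources` object or character vector of plant
#'   taxa.
#' @param season_year season to evaluate.
#' @return object of class `phenology_estimate`: list with `taxon`
#'   (collapsed resource label), `season_year`, `wmd`, `total_abundance`.
#' @export
pooled_flowering_wmd <- function(surveys, resources, season_year) {
  taxa <- if (inherits(resources, "main_resources")) resources$plant_taxa
          else as.character(resources)
  sel <- surveys$season_year == season_year & surveys$plant_taxon %in% taxa
  sub <- surveys[sel, , drop = FALSE]
  if (nrow(sub) == 0 || sum(sub$flower_count) <= 0)
    md_undefined_phenology(sprintf(
      "no flowers of resource taxa [%s] recorded in season %d",
      paste(taxa, collapse = ", "), season_year))
  by_day <- tapply(sub$flower_count, sub$day, sum)
  days <- as.numeric(names(by_day))
  structure(list(taxon = paste(taxa, collapse = "+"),
                 season_year = as.integer(season_year),
                 wmd = weighted_mean_date(days, as.numeric(by_day)),
                 total_abundance = sum(sub$flower_count)),
            class = "phenology_estimate")
}

#' Nesting WMD of one bee population in one season
#'
#' Each completed nest contributes abundance 1 on its end-of-construction
#' day, so the nesting WMD is the mean end day weighted by the relative
#' abundance of nests per date.
#'
#' @param nests nest records of one bee taxon in one season.
#' @return `phenology_estimate` for nesting.
#' @export
nesting_wmd <- function(nests) {
  if (nrow(nests) == 0)
    md_season_excluded("no nests recorded: season excluded")
  by_day <- tapply(rep(1, nrow(nests)), nests$end_day, sum)
  structure(list(taxon = nests$bee_taxon[1],
                 season_year = as.integer(nests$season_year[1]),
                 wmd = weighted_mean_date(as.numeric(names(by_day)),
                                          as.numeric(by_day)),
                 total_abundance = nrow(nests)),
            class = "phenology_estimate")
}

#' Nest-level phenological mismatch
#'
#' Absolute difference, in days, between a nest's end-of-construction day
#' and the flowering WMD of the bee's main floral resources in the same
#' season.
#'
#' @param nest a single nest record (one-row data.frame or list with
#'   `end_day` and `season_year`).
#' @param flowering a `phenology_estimate` for the same season.
#' @return list of class `mismatch_record` with `scope = "nest"`.
#' @export
nest_mismatch <- function(nest, flowering) {
  if (!identical(as.integer(nest$season_year),
                 as.integer(flowering$season_year)))
    md_contract_error("nest and flowering estimate are from different seasons")
  structure(list(scope = "nest", id = nest$nest_id,
                 season_year = as.integer(nest$season_year),
                 mismatch_days = abs(nest$end_day - flowering$wmd)),
            class = "mismatch_record")
}

#' Population-level phenological mismatch
#'
#' Days between the nesting WMD (each nest weighted equally) and the
#' flowering WMD of the main resources, as an absolute value. Seasons with
#' zero nests raise a season-excluded condition rather than a crash, so
#' callers can drop them with a log entry.
#'
#' @param nests nest records of one bee taxon in one season.
#' @param flowering `phenology_estimate` for the same taxon's resources and
#'   season.
#' @return list of class `mismatch_record` with `scope = "population"` and
#'   additional fields `nesting_wmd`, `flowering_wmd`, `n_nests`.
#' @export
population_mismatch <- function(nests, flowering) {
  if (nrow(nests) == 0)
    md_season_excluded("no nests recorded: season excluded")
  if (!all(as.integer(nests$season_year) ==
           as.integer(flowering$season_year)))
    md_contract_error("nests and flowering estimate are from different seasons")
  nw <- nesting_wmd(nests)
  structure(list(scope = "population", id = nests$bee_taxon[1],
                 season_year = as.integer(flowering$season_year),
                 nesting_wmd = nw$wmd, flowering_wmd = flowering$wmd,
                 n_nests = nrow(nests),
                 mismatch_days = abs(nw$wmd - flowering$wmd)),
            class = "mismatch_record")
}

#' Full phenology and mismatch analysis
#'
#' Orchestrates the phenology stage: pools plot-level flower counts,
#' identifies each bee species' main floral resources from the pollen
#' table (pooled across the pollen-study seasons), computes per-season
#' flowering and nesting WMDs, and derives nest-level and
#' population-level mismatch tables. Bee-species seasons with no nests, or
#' with no recorded flowers of the main resources, are excluded and
#' reported in `excluded`.
#'
#' @param surveys validated floral-survey table.
#' @param nests validated nest-record table.
#' @param pollen validated pollen-sample table (used to identify main
#'   resources; nests absent from `nests` are ignored).
#' @param threshold main-resource cumulative share threshold.
#' @param stratify_sites passed to [pool_floral_surveys()].
#' @return list with `per_nest` (nest rows plus `mismatch_days` and
#'   `flowering_wmd`), `per_population` (one row per bee taxon x season),
#'   `resources` (named list of `main_resources`), and `excluded`
#'   (data.frame of excluded taxon-seasons with reasons).
#' @export
analyze_phenology <- function(surveys, nests, pollen, threshold = 0.85,
                              stratify_sites = FALSE) {
  pooled <- pool_floral_surveys(surveys, stratify_sites = FALSE)
  seasons <- sort(unique(nests$season_year))
  taxa <- sort(unique(nests$bee_taxon))

  resources <- lapply(taxa, function(bt) {
    totals <- species_pollen_totals(pollen, nests, bt)
    identify_main_resources(totals, threshold = threshold, bee_taxon = bt)
  })
  names(resources) <- taxa

  excluded <- data.frame(bee_taxon = character(), season_year = integer(),
                         reason = character())
  per_nest <- NULL
  per_pop <- NULL
  for (bt in taxa) {
    for (sy in seasons) {
      nb <- nests[nests$bee_taxon == bt & nests$season_year == sy, ,
                  drop = FALSE]
      if (nrow(nb) == 0) {
        excluded <- rbind(excluded, data.frame(
          bee_taxon = bt, season_year = sy, reason = "no nests"))
        next
      }
      fl <- tryCatch(pooled_flowering_wmd(pooled, resources[[bt]], sy),
                     matchdem_undefined_phenology = function(e) NULL)
      if (is.null(fl)) {
        excluded <- rbind(excluded, data.frame(
          bee_taxon = bt, season_year = sy,
          reason = "no resource flowers recorded"))
        next
      }
      pm <- population_mismatch(nb, fl)
      per_pop <- rbind(per_pop, data.frame(
        bee_taxon = bt, season_year = sy, nesting_wmd = pm$nesting_wmd,
        flowering_wmd = pm$flowering_wmd, mismatch_days = pm$mismatch_days,
        n_nests = pm$n_nests))
      nb$flowering_wmd <- fl$wmd
      nb$mismatch_days <- abs(nb$end_day - fl$wmd)
      per_nest <- rbind(per_nest, nb)
    }
  }
  list(per_nest = per_nest, per_population = per_pop,
       resources = resources, excluded = excluded)
}

# Summed standardized pollen abundance per plant taxon for one bee species:
# each nest's grain counts are normalized to proportions, then summed over
# the species' examined nests.
species_pollen_totals <- function(pollen, nests, bee_taxon) {
  ids <- nests$nest_id[nests$bee_taxon == bee_taxon]
  sub <- pollen[pollen$nest_id %in% ids, , drop = FALSE]
  if (nrow(sub) == 0)
    md_undefined_phenology(sprintf("no pollen samples for %s", bee_taxon))
  per_nest <- lapply(split(sub, sub$nest_id), function(s)
    nest_pollen_proportions(setNames(s$grain_count, s$plant_taxon)))
  species_abundance_across_nests(per_nest)
}
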