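#' Total brood cells produced per season
#'
#' `N_t` is the summed brood-cell count over all of a bee taxon's nests in
#' season `t`; it is the population-level production on which growth rates
#' are defined. Seasons inside the covered range with no nests yield
#' `N = 0`.
#'
#' @param nests nest records of one bee taxon with `brood_cells` present
#'   (imputed where necessary).
#' @param seasons integer vector of seasons to report; defaults to the
#'   full consecutive range spanned by the records.
#' @return named numeric vector: season_year -> total brood cells. Empty
#'   input gives an empty vector.
#' @export
yearly_brood_totals <- function(nests, seasons = NULL) {
  if (nrow(nests) == 0) return(setNames(numeric(0), character(0)))
  if (anyNA(nests$brood_cells))
    md_contract_error("brood_cells missing; impute before computing totals")
  if (is.null(seasons))
    seasons <- seq(min(nests$season_year), max(nests$season_year))
  sums <- tapply(nests$brood_cells, nests$season_year, sum)
  out <- setNames(rep(0, length(seasons)), seasons)
  out[names(sums)] <- as.numeric(sums)
  out
}

#' Mean log population growth rate
#'
#' Per-year growth is `lambda_t = N_{t+1} / N_t` over consecutive seasons;
#' the summary statistic is the arithmetic mean of `log(lambda_t)` (the
#' log of the geometric-mean growth rate), so `lambda_bar > 0` indicates
#' expected growth and `lambda_bar < 0` expected decline. Transitions in
#' which either season's total is zero, or whose seasons are not
#' consecutive, are skipped and reported in `skipped`.
#'
#' @param yearly_totals named numeric vector from [yearly_brood_totals()].
#' @return list with `lambda_series` (named `"t->t+1"`), `lambda_bar`,
#'   `n_transitions`, `skipped` (character vector of skipped transitions).
#' @export
mean_log_growth <- function(yearly_totals) {
  if (length(yearly_totals) < 2)
    md_error("need at least two seasons for growth rates",
             "matchdem_undefined_demography")
  yrs <- suppressWarnings(as.integer(names(yearly_totals)))
  if (anyNA(yrs)) yrs <- seq_along(yearly_totals)  # labels: assume given order
  ord <- order(yrs)
  yrs <- yrs[ord]; n <- as.numeric(yearly_totals[ord])
  lab0 <- names(yearly_totals)[ord]
  lab <- paste0(lab0[-length(lab0)], "->", lab0[-1])
  consecutive <- diff(yrs) == 1
  usable <- consecutive & n[-length(n)] > 0 & n[-1] > 0
  if (!any(usable))
    md_error("no usable season transition: demography undefined",
             "matchdem_undefined_demography")
  lambda <- n[-1][usable] / n[-length(n)][usable]
  list(lambda_series = setNames(lambda, lab[usable]),
       lambda_bar = mean(log(lambda)),
       n_transitions = sum(usable),
       skipped = lab[!usable])
}

#' Bootstrap confidence interval for the mean log growth rate
#'
#' Nests are resampled with replacement and `lambda_bar` recomputed per
#' replicate; the 95% interval is the 2.5% and 97.5% empirical quantiles
#' over replicates for which `lambda_bar` is defined (percentile
#' bootstrap). By default resampling is stratified by season, preserving
#' each season's nest count and hence the year structure `lambda_bar`
#' depends on; `stratify = FALSE` pools all nests instead, for
#' sensitivity. Replicate `r` draws from a deterministic stream derived
#' from (`seed`, taxon, `r`), so results are reproducible and independent
#' of execution order.
#'
#' @param nests nest records of one bee taxon with `brood_cells` complete.
#' @param n_boot number of bootstrap resamples (1000 by default).
#' @param seed integer seed governing all replicate streams.
#' @param stratify resample within seasons (default) or pooled.
#' @param seasons season range passed to [yearly_brood_totals()].
#' @return list with `ci_low`, `ci_high`, `n_boot`, `n_defined`,
#'   `replicates` (numeric vector, `NA` where undefined), and `degenerate`
#'   flag set when fewer than half the replicates are defined (also
#'   warned).
#' @export
bootstrap_lambda_ci <- function(nests, n_boot = 1000, seed = 1,
                                stratify = TRUE, seasons = NULL) {
  if (nrow(nests) == 0) md_contract_error("no nests to resample")
  if (anyNA(nests$brood_cells))
    md_contract_error("brood_cells missing; impute before bootstrapping")
  taxon <- nests$bee_taxon[1]
  if (is.null(seasons))
    seasons <- seq(min(nests$season_year), max(nests$season_year))
  cells_by_season <- split(nests$brood_cells, nests$season_year)
  all_cells <- nests$brood_cells
  all_seasons <- nests$season_year
  n_total <- length(all_cells)

  lam_of_totals <- function(totals) {
    tryCatch(mean_log_growth(totals)$lambda_bar,
             matchdem_undefined_demography = function(e) NA_real_,
             matchdem_undefined_phenology = function(e) NA_real_)
  }

  reps <- vapply(seq_len(n_boot), function(r) {
    with_seed(derive_seed(seed, taxon, r), {
      if (stratify) {
        totals <- vapply(cells_by_season, function(v)
          sum(v[sample.int(length(v), length(v), replace = TRUE)]),
          numeric(1))
        full <- setNames(rep(0, length(seasons)), seasons)
        full[names(totals)] <- totals
      } else {
        idx <- sample.int(n_total, n_total, replace = TRUE)
        sums <- tapply(all_cells[idx], all_seasons[idx], sum)
        full <- setNames(rep(0, length(seasons)), seasons)
        full[names(sums)] <- as.numeric(sums)
      }
      lam_of_totals(full)
    })
  }, numeric(1))

  n_defined <- sum(!is.na(reps))
  degenerate <- n_defined < n_boot / 2
  if (degenerate)
    warning(sprintf(
      "lambda_bar defined in only %d of %d bootstrap replicates",
      n_defined, n_boot), call. = FALSE)
  if (n_defined == 0)
    md_error("lambda_bar undefined in every bootstrap replicate",
             "matchdem_undefined_demography")
  ci <- unname(quantile(reps, c(0.025, 0.975), na.rm = TRUE))
  list(ci_low = ci[1], ci_high = ci[2], n_boot = n_boot,
       n_defined = n_defined, replicates = reps, degenerate = degenerate)
}

#' Per-species demography summary
#'
#' Computes yearly brood-cell totals, the per-transition growth rates, the
#' mean log growth rate and its bootstrap confidence interval for one bee
#' taxon.
#'
#' @inheritParams bootstrap_lambda_ci
#' @return object of class `demography_result`: list with `bee_taxon`,
#'   `yearly_totals`, `lambda_series`, `lambda_bar`, `ci_low`, `ci_high`,
#'   `n_boot`, `n_transitions`, `skipped`.
#' @export
species_demography <- function(nests, n_boot = 1000, seed = 1,
                               stratify = TRUE, seasons = NULL) {
  totals <- yearly_brood_totals(nests, seasons = seasons)
  growth <- mean_log_growth(totals)
  ci <- bootstrap_lambda_ci(nests, n_boot = n_boot, seed = seed,
                            stratify = stratify, seasons = seasons)
  structure(c(list(bee_taxon = nests$bee_taxon[1], yearly_totals = totals),
              growth[c("lambda_series", "lambda_bar", "n_transitions",
                       "skipped")],
              ci[c("ci_low", "ci_high", "n_boot", "n_defined",
                   "degenerate")]),
            class = "demography_result")
}

#' @export
print.demography_result <- function(x, ...) {
  cat(sprintf(
    "%s: lambda_bar = %.4f [%.4f, %.4f] (95%% percentile bootstrap, %d resamples, %d transitions)\n",
    x$bee_taxon, x$lambda_bar, x$ci_low, x$ci_high, x$n_boot,
    x$n_transitions))
  invisible(x)
}
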