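#' Fit a mismatch-recruitment mixed model for one bee species
#'
#' Linear mixed model relating per-nest recruitment to nesting-flowering
#' mismatch, with a random intercept per season year (years differ in
#' overall conditions; nests within a year share them). Two mean
#' structures are supported: `"linear"` uses the brood-cell count as the
#' response, `"exponential"` its natural logarithm (so the fitted mean
#' declines exponentially with mismatch on the original scale). Models are
#' estimated by maximum likelihood so AIC values are comparable across
#' mean structures. With `standardized = TRUE` both the predictor and the
#' response are z-scored (mean subtracted, divided by the standard
#' deviation) before fitting, yielding standardized coefficients
#' comparable across species.
#'
#' @param data data.frame with columns `mismatch_days`, `brood_cells`,
#'   `season_year` for one bee taxon.
#' @param form `"linear"` or `"exponential"`.
#' @param standardized z-score predictor and response before fitting.
#' @param min_nests below this many nests the fit proceeds with a warning
#'   (default 10); fewer than 3 nests is an error.
#' @return object of class `mismatch_fit`: list with `bee_taxon` (if a
#'   `bee_taxon` column is present), `form`, `slope`, `slope_se`,
#'   `intercept`, `aic`, `n_obs`, `n_years`, `standardized`, `degenerate`,
#'   the underlying `nlme::lme` fit (`NULL` when degenerate), and a data
#'   `fingerprint` used to guard model comparisons.
#' @export
fit_mismatch_model <- function(data, form = c("exponential", "linear"),
                               standardized = FALSE, min_nests = 10) {
  form <- match.arg(form)
  need <- c("mismatch_days", "brood_cells", "season_year")
  if (!all(need %in% names(data)))
    md_contract_error(paste("data must have columns",
                            paste(need, collapse = ", ")))
  data <- data[complete.cases(data[, need]), , drop = FALSE]
  n <- nrow(data)
  n_years <- length(unique(data$season_year))
  if (n < 3) md_contract_error("fewer than 3 nests: cannot fit")
  if (n < min_nests)
    warning(sprintf("only %d nests; estimates will be unstable", n),
            call. = FALSE)
  if (n_years < 2)
    md_contract_error("a single season: year random effect undefined")
  if (var(data$mismatch_days) == 0)
    md_contract_error("mismatch has zero variance: slope unidentifiable")
  if (form == "exponential" && any(data$brood_cells < 1))
    md_validation_error("exponential form requires brood_cells >= 1")

  y <- if (form == "exponential") log(data$brood_cells) else data$brood_cells
  x <- data$mismatch_days
  fingerprint <- c(n = n, sx = sum(x), sy2 = sum(data$brood_cells),
                   ny = n_years)

  if (standardized) {
    x <- (x - mean(x)) / sd(x)
    if (sd(y) > 0) y <- (y - mean(y)) / sd(y)
  }

  if (sd(y) == 0) {
    warning("response is constant: degenerate fit with zero slope",
            call. = FALSE)
    return(structure(list(bee_taxon = data$bee_taxon[1], form = form,
                          slope = 0, slope_se = NA_real_,
                          intercept = y[1], aic = NA_real_, n_obs = n,
                          n_years = n_years, standardized = standardized,
                          degenerate = TRUE, fit = NULL,
                          fingerprint = fingerprint),
                     class = "mismatch_fit"))
  }

  df <- data.frame(y = y, x = x, year = factor(data$season_year))
  fit <- nlme::lme(y ~ x, random = ~ 1 | year, data = df, method = "ML")
  tt <- summary(fit)$tTable
  structure(list(bee_taxon = data$bee_taxon[1], form = form,
                 slope = unname(tt["x", "Value"]),
                 slope_se = unname(tt["x", "Std.Error"]),
                 intercept = unname(tt["(Intercept)", "Value"]),
                 aic = AIC(fit), n_obs = n, n_years = n_years,
                 standardized = standardized, degenerate = FALSE,
                 fit = fit, fingerprint = fingerprint),
            class = "mismatch_fit")
}

#' @export
print.mismatch_fit <- function(x, ...) {
  cat(sprintf(
    "%s mixed model%s: slope %.4f (se %.4f), AIC %.2f, n = %d nests / %d years\n",
    x$form, if (x$standardized) " (standardized)" else "", x$slope,
    x$slope_se, x$aic, x$n_obs, x$n_years))
  invisible(x)
}

#' Select between the linear and exponential mean structures by AIC
#'
#' Both fits must come from the same data with the same standardization.
#' The lower-AIC fit is returned; numerically tied AICs favour the
#' exponential form.
#'
#' @param linear,exponential `mismatch_fit` objects of the respective
#'   forms.
#' @return the selected `mismatch_fit`.
#' @export
select_model <- function(linear, exponential) {
  if (!inherits(linear, "mismatch_fit") ||
      !inherits(exponential, "mismatch_fit") ||
      linear$form != "linear" || exponential$form != "exponential")
    md_contract_error("arguments must be linear and exponential mismatch_fits")
  if (!isTRUE(all.equal(linear$fingerprint, exponential$fingerprint)) ||
      linear$standardized != exponential$standardized)
    md_contract_error("fits were made on different data or standardization")
  if (is.na(linear$aic) || is.na(exponential$aic))
    md_contract_error("degenerate fit has no AIC; cannot select")
  if (exponential$aic <= linear$aic + 1e-6) exponential else linear
}

#' Population-level Spearman correlation
#'
#' Rank correlation, across years, between a species' population mismatch
#' and its mean brood cells per nest. The standard error uses the analytic
#' approximation `sqrt((1 - rho^2) / (n - 2))`; a bootstrap over years is
#' available as an alternative.
#'
#' @param data data.frame with one row per year: `mismatch_days` and
#'   `mean_cells`.
#' @param se_method `"analytic"` (default) or `"bootstrap"` (resampling
#'   years).
#' @param n_boot,seed bootstrap controls when `se_method = "bootstrap"`.
#' @return list of class `population_correlation`: `bee_taxon` (if
#'   present), `rho`, `rho_se`, `n_years`, `degenerate` (TRUE when either
#'   variable has tied ranks throughout, in which case `rho` is reported
#'   as 0 with a warning).
#' @export
population_spearman <- function(data, se_method = c("analytic", "bootstrap"),
                                n_boot = 1000, seed = 1) {
  se_method <- match.arg(se_method)
  if (!all(c("mismatch_days", "mean_cells") %in% names(data)))
    md_contract_error("data must have mismatch_days and mean_cells")
  data <- data[complete.cases(data[, c("mismatch_days", "mean_cells")]), ,
               drop = FALSE]
  n <- nrow(data)
  if (n < 4) md_contract_error("need at least 4 years for a rank correlation")
  degenerate <- sd(data$mismatch_days) == 0 || sd(data$mean_cells) == 0
  if (degenerate) {
    warning("zero-variance ranks: correlation undefined, reported as 0",
            call. = FALSE)
    rho <- 0
  } else {
    rho <- cor(data$mismatch_days, data$mean_cells, method = "spearman")
  }
  rho_se <- if (se_method == "analytic") {
    sqrt((1 - rho^2) / (n - 2))
  } else {
    reps <- vapply(seq_len(n_boot), function(r) {
      with_seed(derive_seed(seed, "spearman", r), {
        idx <- sample.int(n, n, replace = TRUE)
        suppressWarnings(cor(data$mismatch_days[idx], data$mean_cells[idx],
                             method = "spearman"))
      })
    }, numeric(1))
    sd(reps, na.rm = TRUE)
  }
  structure(list(bee_taxon = data$bee_taxon[1], rho = rho, rho_se = rho_se,
                 n_years = n, degenerate = degenerate),
            class = "population_correlation")
}

#' Cross-species mean coefficient with bootstrap confidence limits
#'
#' Unweighted mean of per-species (standardized) coefficients, with a 95%
#' percentile bootstrap interval obtained by resampling species with
#' replacement. With only a handful of species the interval is
#' necessarily wide.
#'
#' @param coefficients named numeric vector: bee taxon -> coefficient.
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed.
#' @return list of class `cross_species_summary`: `mean_coefficient`,
#'   `ci_low`, `ci_high`, `n_species`, `n_boot`, `per_species`.
#' @export
cross_species_mean <- function(coefficients, n_boot = 1000, seed = 1) {
  if (length(coefficients) < 3)
    md_contract_error("need at least 3 species for a cross-species mean")
  if (anyNA(coefficients))
    md_validation_error("coefficients must be non-missing")
  k <- length(coefficients)
  reps <- vapply(seq_len(n_boot), function(r) {
    with_seed(derive_seed(seed, "xspecies", r),
              mean(coefficients[sample.int(k, k, replace = TRUE)]))
  }, numeric(1))
  ci <- unname(quantile(reps, c(0.025, 0.975)))
  structure(list(mean_coefficient = mean(coefficients),
                 ci_low = ci[1], ci_high = ci[2], n_species = k,
                 n_boot = n_boot, per_species = coefficients),
            class = "cross_species_summary")
}

#' Fit and select mismatch-recruitment models for every bee species
#'
#' For each species with at least `min_nests` nests spread over two or
#' more seasons: fits the linear and exponential mixed models, selects by
#' AIC, and refits the selected form with standardized variables for
#' cross-species comparison. Species failing the preconditions are skipped
#' with a warning.
#'
#' @param per_nest per-nest mismatch table from [analyze_phenology()]
#'   with `brood_cells` complete.
#' @param min_nests minimum nests per species (default 10).
#' @return data.frame with one row per fitted species: `bee_taxon`,
#'   `form`, `slope`, `slope_se`, `intercept`, `aic_linear`,
#'   `aic_exponential`, `std_slope`, `std_slope_se`, `n_obs`, `n_years`.
#' @export
fit_species_models <- function(per_nest, min_nests = 10) {
  rows <- lapply(sort(unique(per_nest$bee_taxon)), function(bt) {
    d <- per_nest[per_nest$bee_taxon == bt, , drop = FALSE]
    res <- tryCatch({
      lin <- fit_mismatch_model(d, "linear", min_nests = min_nests)
      ex  <- fit_mismatch_model(d, "exponential", min_nests = min_nests)
      sel <- select_model(lin, ex)
      std <- fit_mismatch_model(d, sel$form, standardized = TRUE,
                                min_nests = min_nests)
      data.frame(bee_taxon = bt, form = sel$form, slope = sel$slope,
                 slope_se = sel$slope_se, intercept = sel$intercept,
                 aic_linear = lin$aic, aic_exponential = ex$aic,
                 std_slope = std$slope, std_slope_se = std$slope_se,
                 n_obs = sel$n_obs, n_years = sel$n_years)
    }, matchdem_error = function(e) {
      warning(sprintf("skipping %s: %s", bt, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    res
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    md_contract_error("no species could be fitted")
  out
}

#' Per-year population table for the Spearman analysis
#'
#' Joins the population mismatch series with the yearly mean brood cells
#' per nest.
#'
#' @param per_population population table from [analyze_phenology()].
#' @param nests nest records with `brood_cells` complete.
#' @return data.frame with `bee_taxon`, `season_year`, `mismatch_days`,
#'   `mean_cells`.
#' @export
population_table <- function(per_population, nests) {
  mc <- stats::aggregate(nests["brood_cells"],
                         by = nests[c("bee_taxon", "season_year")],
                         FUN = mean)
  names(mc)[names(mc) == "brood_cells"] <- "mean_cells"
  merge(per_population, mc, by = c("bee_taxon", "season_year"))
}
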