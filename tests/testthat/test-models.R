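# Simulate per-nest data with a known log-linear mismatch effect and a
# year random intercept.
sim_model_data <- function(n_per_year = 25, n_years = 8, b = -0.03,
                           mean_cells = 6, year_sd = 0.12, resid_sd = 0.3,
                           round_cells = TRUE) {
  rows <- lapply(seq_len(n_years), function(t) {
    mism <- abs(rnorm(n_per_year, 0, 10))
    mu <- log(mean_cells) + b * mism + rnorm(1, 0, year_sd)
    cells <- exp(mu + rnorm(n_per_year, 0, resid_sd))
    if (round_cells) cells <- pmax(1, round(cells))
    data.frame(mismatch_days = mism, brood_cells = cells,
               season_year = 2005 + t)
  })
  do.call(rbind, rows)
}

test_that("mixed-model fit preconditions and degenerate responses", {
  d <- sim_model_data(n_per_year = 15, n_years = 3)
  one_year <- d[d$season_year == 2006, ]
  expect_error(fit_mismatch_model(one_year), class = "matchdem_contract_error")
  flat_x <- d; flat_x$mismatch_days <- 4
  expect_error(fit_mismatch_model(flat_x), class = "matchdem_contract_error")
  flat_y <- d; flat_y$brood_cells <- 5
  expect_warning(f0 <- fit_mismatch_model(flat_y), "constant")
  expect_equal(f0$slope, 0)
  expect_true(f0$degenerate)
})

test_that("standardized single-cluster slope equals the Pearson correlation", {
  set.seed(110)
  x <- runif(40, 0, 20)
  y <- pmax(exp(1.6 - 0.04 * x + rnorm(40, 0, 0.2)), 1.01)
  # two identical pseudo-years so the year effect carries no information
  d <- data.frame(mismatch_days = rep(x, 2), brood_cells = rep(y, 2),
                  season_year = rep(c(2006, 2007), each = 40))
  f <- fit_mismatch_model(d, "exponential", standardized = TRUE)
  expect_equal(f$slope, cor(x, log(y)), tolerance = 1e-6)
  # perfect correlation gives slope 1
  d2 <- data.frame(mismatch_days = rep(x, 2), brood_cells = rep(exp(x), 2),
                   season_year = rep(c(2006, 2007), each = 40))
  f2 <- fit_mismatch_model(d2, "exponential", standardized = TRUE)
  expect_equal(f2$slope, 1, tolerance = 1e-6)
})

test_that("ML mixed model agrees with an independent lme4 fit", {
  skip_if_not_installed("lme4")
  set.seed(120)
  d <- sim_model_data()
  f <- fit_mismatch_model(d, "exponential")
  d$year <- factor(d$season_year)
  ref <- lme4::lmer(log(brood_cells) ~ mismatch_days + (1 | year),
                    data = d, REML = FALSE)
  expect_equal(f$slope, unname(lme4::fixef(ref)["mismatch_days"]),
               tolerance = 1e-4)
  expect_equal(f$aic, AIC(ref), tolerance = 1e-3)
})

test_that("AIC selection picks the lower AIC and prefers exponential on ties", {
  set.seed(130)
  d <- sim_model_data()
  lin <- fit_mismatch_model(d, "linear")
  ex <- fit_mismatch_model(d, "exponential")
  sel <- select_model(lin, ex)
  expect_identical(sel$form,
                   if (ex$aic <= lin$aic) "exponential" else "linear")
  # forced tie favours the exponential form
  lin2 <- lin; lin2$aic <- ex$aic
  expect_identical(select_model(lin2, ex)$form, "exponential")
  # fits on different data are rejected
  d2 <- sim_model_data()
  expect_error(select_model(fit_mismatch_model(d2, "linear"), ex),
               class = "matchdem_contract_error")
})

test_that("slope recovery: sign and CI behaviour under the generating model", {
  set.seed(140)
  sign_hits <- 0; ci_hits <- 0; n_rep <- 60
  for (r in 1:n_rep) {
    d <- sim_model_data(n_per_year = 25, n_years = 8, b = -0.03)
    f <- fit_mismatch_model(d, "exponential")
    if (f$slope < 0) sign_hits <- sign_hits + 1
    ci <- f$slope + c(-1, 1) * 1.96 * f$slope_se
    if (ci[1] <= -0.03 && -0.03 <= ci[2]) ci_hits <- ci_hits + 1
  }
  expect_gte(sign_hits, ceiling(0.95 * n_rep))
  expect_gte(ci_hits, ceiling(0.85 * n_rep))
})

test_that("population Spearman matches the hand-ranked example", {
  d <- data.frame(mismatch_days = 1:5, mean_cells = c(10, 8, 9, 5, 4))
  r <- population_spearman(d)
  expect_equal(r$rho, -0.9)
  expect_equal(r$rho_se, sqrt((1 - 0.81) / 3))
  dec <- data.frame(mismatch_days = 1:5, mean_cells = 5:1)
  expect_equal(population_spearman(dec)$rho, -1)
  flat <- data.frame(mismatch_days = 1:5, mean_cells = 2)
  expect_warning(rf <- population_spearman(flat), "zero-variance")
  expect_equal(rf$rho, 0)
  expect_true(rf$degenerate)
  expect_error(population_spearman(d[1:3, ]),
               class = "matchdem_contract_error")
})

test_that("cross-species mean and bootstrap CI behave at the edges", {
  same <- c(a = -0.2, b = -0.2, c = -0.2)
  cs <- cross_species_mean(same, n_boot = 100, seed = 1)
  expect_equal(cs$mean_coefficient, -0.2)
  expect_equal(c(cs$ci_low, cs$ci_high), c(-0.2, -0.2))
  sym <- cross_species_mean(c(a = -1, b = 0, c = 1), n_boot = 200, seed = 1)
  expect_equal(sym$mean_coefficient, 0)
  again <- cross_species_mean(c(a = -1, b = 0, c = 1), n_boot = 200, seed = 1)
  expect_identical(c(sym$ci_low, sym$ci_high), c(again$ci_low, again$ci_high))
  expect_error(cross_species_mean(c(a = 1, b = 2)),
               class = "matchdem_contract_error")
})
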