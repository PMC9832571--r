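test_that("scenario validation catches malformed configurations", {
  sc <- default_scenario()
  expect_s3_class(sc, "bee_scenario")
  bad <- sc; bad$diet <- bad$diet[, -1]
  expect_error(validate_scenario(bad), class = "matchdem_config_error")
  bad2 <- sc; bad2$bees$mismatch_effect[1] <- 0.1
  expect_error(validate_scenario(bad2), class = "matchdem_config_error")
  bad3 <- sc; bad3$diet[1, ] <- bad3$diet[1, ] * 2
  expect_error(validate_scenario(bad3), class = "matchdem_config_error")
})

test_that("scenarios round-trip through YAML", {
  sc <- default_scenario()
  f <- tempfile(fileext = ".yaml")
  write_scenario(sc, f)
  back <- read_scenario(f)
  expect_equal(back$bees$mismatch_effect, sc$bees$mismatch_effect)
  expect_equal(unname(back$diet), unname(sc$diet), tolerance = 1e-12)
  expect_equal(back$survey_days, sc$survey_days)
  # identical configs digest identically; different ones do not
  sim_a <- simulate_scenario(sc, seed = 5)
  sim_b <- simulate_scenario(back, seed = 5)
  expect_equal(sim_a$nests$end_day, sim_b$nests$end_day)
})

test_that("flowering curves are reproducible, unimodal and centred near the peak", {
  sc <- tiny_scenario()
  a <- generate_flowering(sc, seed = 11)
  b <- generate_flowering(sc, seed = 11)
  expect_identical(a$flower_count, b$flower_count)  # bit-reproducible
  # no interannual variation when the shift sd is zero (expected curves equal)
  sc0 <- tiny_scenario()
  sc0$plants$year_shift_sd <- 0
  f0 <- generate_flowering(sc0, seed = 12)
  shifts <- attr(f0, "peak_shifts")
  expect_true(all(shifts == 0))
  # WMD of the pooled generated curve sits near the configured peak
  pooled <- pool_floral_surveys(f0)
  wmds <- vapply(unique(pooled$season_year), function(sy)
    pooled_flowering_wmd(pooled, "plant_a", sy)$wmd, numeric(1))
  expect_true(all(abs(wmds - 70) < sc0$survey_interval / 2 + 1))
  # doubling abundance leaves the WMD essentially unchanged (scale inv.)
  sc2 <- tiny_scenario()
  sc2$plants$peak_abundance <- sc2$plants$peak_abundance * 2
  sc2$plants$year_shift_sd <- 0
  f2 <- generate_flowering(sc2, seed = 12)
  p2 <- pool_floral_surveys(f2)
  wmds2 <- vapply(unique(p2$season_year), function(sy)
    pooled_flowering_wmd(p2, "plant_a", sy)$wmd, numeric(1))
  expect_true(all(abs(wmds2 - wmds) < 1))
})

test_that("nests concentrate at the flowering WMD when spreads vanish", {
  sc <- tiny_scenario(nesting_spread = 1e-6)
  sc$bees$year_shift_sd <- 0
  fl <- generate_flowering(sc, seed = 21)
  ns <- generate_nests(sc, fl, seed = 22)
  truth <- attr(ns, "truth")$flowering_wmd
  merged <- merge(ns, truth, by = c("bee_taxon", "season_year"))
  # end days equal the rounded WMD, so mismatch is at most rounding error
  expect_true(all(abs(merged$end_day - merged$wmd) <= 0.5 + 1e-9))
})

test_that("a null mismatch effect yields a near-zero recovered slope", {
  set.seed(31)
  hits <- 0
  for (r in 1:20) {
    sc <- tiny_scenario(mismatch_effect = 0, nests_per_year = 60,
                        mean_cells = 6)
    sim <- simulate_scenario(sc, seed = 3100 + r)
    phen <- analyze_phenology(sim$flowers, sim$nests, sim$pollen)
    f <- fit_mismatch_model(phen$per_nest, "exponential")
    if (abs(f$slope) < 2 * f$slope_se) hits <- hits + 1
  }
  expect_gte(hits, 18)  # |slope| < 2 SE in >= 90% of replicates
})

test_that("pollen compositions encode the specialization gradient", {
  sc <- default_scenario()
  sim <- simulate_scenario(sc, seed = 41)
  g <- generalization_scores(sim$pollen, sim$nests)
  g <- g[match(sc$bees$taxon, g$bee_taxon), ]
  expect_true(all(diff(g$shannon_h) > 0))  # programmed gradient recovered

  # point-mass composition -> every nest single-taxon, H = 0
  sc1 <- tiny_scenario()
  sc1$diet <- matrix(c(1, 0), nrow = 1)
  sc1$bees$diet_concentration <- 1e6
  sim1 <- simulate_scenario(sc1, seed = 42)
  expect_true(all(sim1$pollen$plant_taxon == "plant_a"))
  expect_equal(generalization_scores(sim1$pollen, sim1$nests)$shannon_h, 0)

  # symmetric concentration over k plants, large totals -> H near log k
  sck <- tiny_scenario()
  sck$diet <- matrix(c(0.5, 0.5), nrow = 1)
  sck$bees$diet_concentration <- 1e5
  sck$pollen_grains <- 20000
  simk <- simulate_scenario(sck, seed = 43)
  hk <- generalization_scores(simk$pollen, simk$nests)$shannon_h
  expect_lt(abs(hk - log(2)) / log(2), 0.05)

  # determinism of the full simulated triple
  s1 <- simulate_scenario(sc, seed = 44)
  s2 <- simulate_scenario(sc, seed = 44)
  expect_identical(s1$pollen, s2$pollen)
  expect_identical(s1$nests$brood_cells, s2$nests$brood_cells)
})

test_that("H rank order matches the programmed gradient in most replicates", {
  sc <- default_scenario()
  ok <- 0
  for (r in 1:20) {
    sim <- simulate_scenario(sc, seed = 500 + r)
    g <- generalization_scores(sim$pollen, sim$nests)
    g <- g[match(sc$bees$taxon, g$bee_taxon), ]
    if (!is.unsorted(g$shannon_h, strictly = TRUE)) ok <- ok + 1
  }
  expect_gte(ok, 19)  # >= 95%
})
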