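# Brute-force oracle: explicit normalize-then-sum loop.
wmd_oracle <- function(day, abundance) {
  w <- abundance / sum(abundance)
  total <- 0
  for (i in seq_along(day)) total <- total + day[i] * w[i]
  total
}

test_that("weighted mean date reproduces the worked example and edge cases", {
  expect_equal(weighted_mean_date(c(60, 67, 74), c(10, 60, 30)), 68.4,
               tolerance = 1e-12)
  expect_equal(weighted_mean_date(100, 5), 100)
  expect_equal(weighted_mean_date(c(10, 20), c(3, 3)), 15)
  expect_error(weighted_mean_date(c(1, 2), c(0, 0)),
               class = "matchdem_undefined_phenology")
  expect_error(weighted_mean_date(numeric(0), numeric(0)),
               class = "matchdem_undefined_phenology")
})

test_that("weighted mean date matches the brute-force oracle and is scale invariant", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(1:12, 1)
    d <- sort(sample(0:200, n))
    a <- runif(n, 0, 50)
    a[sample(n, sample(0:(n - 1), 1))] <- 0
    if (sum(a) == 0) a[1] <- 1
    got <- weighted_mean_date(d, a)
    expect_equal(got, wmd_oracle(d, a), tolerance = 1e-9)
    expect_equal(got, weighted_mean_date(d, a * 7.3), tolerance = 1e-9)
    expect_gte(got, min(d)); expect_lte(got, max(d))
  }
})

test_that("main resources are taken greedily to the threshold with deterministic ties", {
  r <- identify_main_resources(c(A = 0.50, B = 0.30, C = 0.15, D = 0.05))
  expect_equal(r$plant_taxa, c("A", "B", "C"))
  expect_equal(r$cumulative_share, 0.95)

  expect_equal(identify_main_resources(c(A = 1.0))$plant_taxa, "A")

  tie <- identify_main_resources(c(B = 0.5, A = 0.5))
  expect_equal(tie$plant_taxa, c("A", "B"))  # lexicographic tie-break
  expect_equal(tie$cumulative_share, 1.0)

  # scale invariance and minimality
  r2 <- identify_main_resources(c(A = 50, B = 30, C = 15, D = 5))
  expect_equal(r2$plant_taxa, r$plant_taxa)
  expect_lt(r2$cumulative_share - r2$shares[length(r2$shares)], 0.85)
  expect_error(identify_main_resources(c(A = 0, B = 0)),
               class = "matchdem_validation_error")
})

test_that("pooled flowering WMD pools day-wise counts across resource taxa", {
  s <- rbind(make_surveys(2008, c(60, 80), "A", c(100, 0)),
             make_surveys(2008, c(60, 80), "B", c(0, 100)))
  pooled <- pool_floral_surveys(s)
  expect_equal(pooled_flowering_wmd(pooled, c("A", "B"), 2008)$wmd, 70)
  # single taxon: equals its own WMD; identical phenologies: unchanged
  expect_equal(pooled_flowering_wmd(pooled, "A", 2008)$wmd, 60)
  s2 <- rbind(make_surveys(2008, c(60, 74), "A", c(10, 30)),
              make_surveys(2008, c(60, 74), "B", c(20, 60)))
  p2 <- pool_floral_surveys(s2)
  expect_equal(pooled_flowering_wmd(p2, c("A", "B"), 2008)$wmd,
               pooled_flowering_wmd(p2, "A", 2008)$wmd)
  expect_error(pooled_flowering_wmd(pooled, "A", 2009),
               class = "matchdem_undefined_phenology")
})

test_that("nest and population mismatches are absolute and season-checked", {
  fl <- structure(list(taxon = "A", season_year = 2008L, wmd = 68.4,
                       total_abundance = 100), class = "phenology_estimate")
  nest <- make_nests(season_year = 2008, end_day = 70, brood_cells = 4)
  expect_equal(nest_mismatch(nest[1, ], fl)$mismatch_days, 1.6)
  fl74 <- within(unclass(fl), wmd <- 74)
  expect_equal(nest_mismatch(within(nest[1, ], end_day <- 60),
                             fl74)$mismatch_days, 14)
  expect_equal(nest_mismatch(within(nest[1, ], end_day <- 88),
                             fl74)$mismatch_days, 14)  # symmetric
  nest09 <- within(nest[1, ], season_year <- 2009L)
  expect_error(nest_mismatch(nest09, fl), class = "matchdem_contract_error")

  two <- make_nests(season_year = 2008, end_day = c(66, 70), brood_cells = 3)
  pm <- population_mismatch(two, fl)
  expect_equal(pm$nesting_wmd, 68)
  expect_equal(pm$mismatch_days, 0.4, tolerance = 1e-12)
  # single nest reduces to nest mismatch; symmetric nests give zero
  one <- population_mismatch(two[1, ], fl)
  expect_equal(one$mismatch_days, nest_mismatch(two[1, ], fl)$mismatch_days)
  sym <- make_nests(season_year = 2008,
                    end_day = c(68.4 - 5, 68.4 + 5), brood_cells = 3)
  expect_equal(population_mismatch(sym, fl)$mismatch_days, 0)
  expect_error(population_mismatch(two[0, ], fl),
               class = "matchdem_season_excluded")
})

test_that("analyze_phenology excludes zero-nest and zero-flower seasons with a log", {
  surveys <- rbind(make_surveys(2008, c(60, 67, 74), "A", c(10, 60, 30)),
                   make_surveys(2009, c(60, 67, 74), "B", c(5, 5, 5)))
  nests <- rbind(make_nests("bee1", 2008, c(66, 70), brood_cells = 4),
                 make_nests("bee1", 2009, 80, brood_cells = 2))
  nests$nest_id <- paste0("n", 1:3)
  pollen <- data.frame(nest_id = "n1", plant_taxon = "A", grain_count = 90)
  res <- analyze_phenology(surveys, nests, pollen)
  # bee1 feeds on A only; 2009 has no A flowers -> excluded
  expect_equal(res$excluded$season_year, 2009)
  expect_equal(res$excluded$reason, "no resource flowers recorded")
  expect_equal(res$per_population$season_year, 2008)
  expect_equal(res$per_population$flowering_wmd, 68.4)
  expect_equal(res$per_nest$mismatch_days, abs(c(66, 70) - 68.4))
})
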