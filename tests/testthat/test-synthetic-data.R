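# Synthetic-study generator: population, trials, environment layers.

test_that("tester usage per year follows the configuration", {
  pop <- generatePopulation(tinyConfig())
  ped <- pop$pedigree
  tester_of <- setNames(ped$Tester, ped$Hybrid)
  y <- names(pop$hybrids_by_year)
  expect_setequal(unique(tester_of[pop$hybrids_by_year[[y[1]]]]),
                  c("T1", "T2"))
  expect_setequal(setdiff(unique(tester_of[pop$hybrids_by_year[[y[2]]]]),
                          c("M1", "M2")),
                  c("T1", "T3", "T4", "T5"))
  ## later-year cohorts share the carried-over tester but not T2
  expect_false("T2" %in% tester_of[pop$hybrids_by_year[[y[3]]]])
})

test_that("one parent crossed to one tester gives exactly one hybrid", {
  cfg <- simConfig(n_parents = 1,
                   testers_by_year = list(`2020` = "T1"), years = 2020,
                   n_markers = 10, n_environments_per_year = 1,
                   n_other_testers = 0, seed = 1)
  pop <- generatePopulation(cfg)
  expect_equal(nrow(pop$pedigree), 1L)
  expect_equal(nrow(dosage(pop$geno)), 1L)
})

test_that("empirical MAF honours the configured range (with sampling slack)", {
  pop <- generatePopulation(simConfig(n_parents = 120, n_markers = 10000,
                                      maf_range = c(0.3, 0.5), seed = 3))
  p <- colMeans(dosage(pop$geno)) / 2
  maf <- pmin(p, 1 - p)
  expect_true(all(maf >= 0.25))
  expect_true(all(maf <= 0.5))
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(n_parents = 0), "n_parents")
  expect_error(simConfig(years = c(2020, 2020, 2021)), "strictly increasing")
  expect_error(simConfig(reps = 0), "reps")
  expect_error(simConfig(var_components = list(v_env = -1)), ">= 0")
  expect_error(simConfig(maf_range = c(0, 0.5)), "maf_range")
  expect_error(simConfig(testers_by_year =
                           list(`2019` = character(), `2020` = "T1",
                                `2021` = "T1")),
               "empty tester list")
})

test_that("degenerate variances give a flat field at the intercept", {
  cfg <- simConfig(n_parents = 5, n_markers = 20,
                   n_environments_per_year = 1, years = 2020,
                   var_components = list(v_g_add = 0, v_g_dom = 0,
                                         v_env = 0, v_gxe = 0, v_block = 0,
                                         v_row = 0, v_col = 0, v_resid = 0),
                   intercept = 10, seed = 2)
  st <- simulateStudy(cfg)
  expect_true(all(plotTable(st)$Yield_Mg_ha == 10))
})

test_that("phenotype decomposition is exact and variances are recoverable", {
  st <- tinyStudy()
  pt <- plotTable(st)
  tr <- truth(st)
  rec <- tr$intercept + tr$additive[pt$Hybrid] + tr$dominance[pt$Hybrid] +
    tr$env[pt$Env] + tr$gxe[cbind(pt$Hybrid, pt$Env)] +
    tr$block[paste(pt$Env, pt$Replicate, pt$Block, sep = ":")] +
    tr$row[paste(pt$Env, pt$Row, sep = ":")] +
    tr$col[paste(pt$Env, pt$Col, sep = ":")] + tr$residual
  expect_equal(unname(rec), pt$Yield_Mg_ha, tolerance = 0)

  ## method-of-moments recovery of v_env and v_resid over many
  ## environments with the other components switched off
  cfg <- simConfig(n_parents = 110,
                   testers_by_year = list(`2020` = c("T1", "T2")),
                   years = 2020, n_environments_per_year = 60,
                   n_markers = 100, coverage = 0.5,
                   var_components = list(v_g_add = 0, v_g_dom = 0,
                                         v_env = 1.5, v_gxe = 0,
                                         v_block = 0, v_row = 0,
                                         v_col = 0, v_resid = 0.8),
                   seed = 9)
  tr2 <- generateTrials(cfg, generatePopulation(cfg))
  ptv <- tr2$plot_table
  within_var <- tapply(ptv$Yield_Mg_ha, ptv$Env, stats::var)
  env_means <- tapply(ptv$Yield_Mg_ha, ptv$Env, mean)
  v_resid_hat <- mean(within_var)
  v_env_hat <- stats::var(env_means) - v_resid_hat / mean(table(ptv$Env))
  expect_lt(abs(v_resid_hat - 0.8) / 0.8, 0.15)
  expect_lt(abs(v_env_hat - 1.5) / 1.5, 0.15)
})

test_that("an identical configuration reproduces the study exactly", {
  cfg <- simConfig(n_parents = 4, n_markers = 50,
                   n_environments_per_year = 1, seed = 5)
  s1 <- simulateStudy(cfg)
  s2 <- simulateStudy(cfg)
  expect_identical(dosage(s1@geno), dosage(s2@geno))
  expect_identical(plotTable(s1), plotTable(s2))
  expect_identical(s1@weather, s2@weather)
  expect_identical(s1@ecs, s2@ecs)
  expect_identical(truth(s1), truth(s2))
})

test_that("study layers cover every environment and hybrid", {
  st <- tinyStudy()
  expect_true(validObject(st))
  envs <- unique(plotTable(st)$Env)
  expect_setequal(unique(st@weather$Env), envs)
  expect_setequal(st@soil$Env, envs)
  expect_setequal(rownames(st@ecs), envs)
  ## incomplete overlap: not every hybrid in every environment
  combos <- unique(plotTable(st)[, c("Env", "Hybrid")])
  expect_lt(nrow(combos),
            length(envs) * length(unique(plotTable(st)$Hybrid)))
})

test_that("a one-day season window yields 48 half-hour weather records", {
  cfg <- simConfig(n_parents = 2, n_markers = 10,
                   n_environments_per_year = 1, years = 2020,
                   season = c("06-01", "06-01"), seed = 1)
  lay <- generateEnvironmentLayers(cfg)
  expect_equal(nrow(lay$weather), 48L)
  expect_false(is.unsorted(lay$weather$Timestamp, strictly = TRUE))
})

test_that("EC layer is low-rank: top components capture ~all variance", {
  cfg <- simConfig(n_parents = 2, n_markers = 10,
                   n_environments_per_year = c(6, 7, 7), seed = 4)
  lay <- generateEnvironmentLayers(cfg, ec_rank = 5, ec_noise_sd = 0)
  d <- svd(lay$ecs)$d
  ## rank <= signal rank + 1 (the mean structure)
  expect_lte(sum(d > 1e-8 * d[1]), 6L)
  red <- reduceECs(lay$ecs, k = min(15, nrow(lay$ecs)))
  expect_gte(sum(red$explained), 0.999)
})

test_that("missing-data injection is off by default and on via config", {
  st <- tinyStudy()
  expect_false(anyNA(plotTable(st)$Yield_Mg_ha))
  cfg <- tinyConfig(seed = 8, missing_plot_frac = 0.1)
  tr <- generateTrials(cfg, generatePopulation(cfg))
  expect_equal(sum(is.na(tr$plot_table$Yield_Mg_ha)),
               round(0.1 * nrow(tr$plot_table)))
})

test_that("writeStudy emits the contract column names", {
  st <- tinyStudy()
  dir <- file.path(tempdir(), "study-io")
  files <- writeStudy(st, dir)
  pt <- utils::read.csv(files[["plot_table"]])
  expect_named(pt, c("Env", "Hybrid", "Replicate", "Block", "Row", "Col",
                     "Yield_Mg_ha"))
  expect_named(utils::read.csv(files[["soil"]]),
               c("Env", "Nitrate_ppm", "Nitrogen_lb_ac", "Calcium_pct"))
  expect_named(utils::read.csv(files[["coords"]]),
               c("Env", "Location", "Latitude", "Longitude"))
  ## genotypes round-trip through the VCF
  m2 <- markerMatrixFromVCF(files[["genotypes"]])
  expect_equal(dim(dosage(m2)), dim(dosage(st@geno)))
  expect_setequal(hybrids(m2), hybrids(st))
})
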