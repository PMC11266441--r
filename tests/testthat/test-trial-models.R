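# Single-trial mixed models: BLUEs, variance components, CV%, Cullis H2.

balancedToy <- function(seed = 1, n_h = 8, reps = 2, sd = 0.5) {
  set.seed(seed)
  hyb <- sprintf("H%02d", seq_len(n_h))
  g <- stats::setNames(stats::rnorm(n_h, 10, 1), hyb)
  out <- expand.grid(Hybrid = hyb, Replicate = c("Rep1", "Rep2")[seq_len(reps)],
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$Env <- "L01_2020"
  out$Block <- "B1"
  out$Row <- sprintf("R%02d", (seq_len(nrow(out)) - 1L) %% 4 + 1L)
  out$Col <- sprintf("C%02d", (seq_len(nrow(out)) - 1L) %/% 4 + 1L)
  rep_eff <- c(Rep1 = 0, Rep2 = 0.7)[out$Replicate]
  out$Yield_Mg_ha <- g[out$Hybrid] + rep_eff + stats::rnorm(nrow(out), 0, sd)
  out
}

test_that("the zero-variance limit reproduces two-way OLS estimates", {
  toy <- balancedToy()
  fit <- fitSingleTrial(toy, force_zero_variance = TRUE)
  ols <- stats::lm(Yield_Mg_ha ~ Hybrid + Replicate, data = toy)
  grid <- expand.grid(Hybrid = sort(unique(toy$Hybrid)),
                      Replicate = sort(unique(toy$Replicate)),
                      KEEP.OUT.ATTRS = FALSE)
  pred <- stats::predict(ols, newdata = grid)
  expected <- tapply(pred, grid$Hybrid, mean)
  expect_equal(blues(fit)[names(expected)], c(expected),
               tolerance = 1e-8)
  expect_equal(unname(varComponents(fit)[c("block", "row", "col")]),
               c(0, 0, 0))
})

test_that("a saturated single-plot design returns the observations as BLUEs", {
  df <- data.frame(Env = "E_2020", Hybrid = c("H1", "H2", "H3"),
                   Replicate = "Rep1", Block = "B1",
                   Row = c("R01", "R02", "R03"),
                   Col = c("C01", "C01", "C01"),
                   Yield_Mg_ha = c(9.1, 10.2, 11.3))
  fit <- suppressWarnings(fitSingleTrial(df))
  expect_equal(unname(blues(fit)[c("H1", "H2", "H3")]),
               c(9.1, 10.2, 11.3), tolerance = 1e-10)
})

test_that("REML estimates are invariant to plot order", {
  st <- tinyStudy()
  pt <- plotTable(st)
  one <- pt[pt$Env == pt$Env[1], ]
  f1 <- fitSingleTrial(one)
  set.seed(3)
  f2 <- fitSingleTrial(one[sample.int(nrow(one)), ])
  expect_equal(blues(f1), blues(f2)[names(blues(f1))], tolerance = 1e-10)
  expect_equal(varComponents(f1), varComponents(f2), tolerance = 1e-10)
  expect_equal(f1@sigmaG, f2@sigmaG, tolerance = 1e-10)
})

test_that("hybrids aliased with replicates raise an estimability error", {
  df <- data.frame(Env = "E_2020",
                   Hybrid = rep(c("H1", "H2"), each = 2),
                   Replicate = rep(c("Rep1", "Rep2"), each = 2),
                   Block = "B1", Row = c("R01", "R02", "R01", "R02"),
                   Col = c("C01", "C01", "C02", "C02"),
                   Yield_Mg_ha = c(10, 10.5, 11, 11.2))
  expect_error(fitSingleTrial(df), "estimability")
})

test_that("hybrids with only missing plots are dropped with a warning", {
  toy <- balancedToy()
  toy$Yield_Mg_ha[toy$Hybrid == "H01"] <- NA
  expect_warning(fit <- fitSingleTrial(toy, force_zero_variance = TRUE),
                 "H01")
  expect_false("H01" %in% names(blues(fit)))
  expect_true("H01" %in% fit@dropped)
})

test_that("CV% is 100 sqrt(var_resid) / mean prediction", {
  mk <- function(vr, mu) methods::new("SingleTrialFit",
    env = "E", blues = c(H1 = 1, H2 = 2), mu = mu,
    varComponents = c(block = 0, row = 0, col = 0, resid = vr),
    sigmaG = 1, pev = 0.5, meanFitted = mu, converged = TRUE,
    nIter = 1L, dropped = character())
  expect_equal(unname(coefficientOfVariation(mk(1, 10))), 10.0)
  expect_equal(unname(coefficientOfVariation(mk(4, 8))), 25.0)
  expect_error(coefficientOfVariation(mk(1, 0)), "undefined CV")
})

test_that("CV% matches the plug-in value on a simulated trial", {
  cfg <- simConfig(n_parents = 60,
                   testers_by_year = list(`2020` = c("T1", "T2")),
                   years = 2020, n_environments_per_year = 1,
                   n_markers = 50, coverage = 1,
                   var_components = list(v_g_add = 0.3, v_g_dom = 0,
                                         v_env = 0, v_gxe = 0,
                                         v_block = 0.02, v_row = 0,
                                         v_col = 0, v_resid = 1.0),
                   intercept = 10, seed = 21)
  tr <- generateTrials(cfg, generatePopulation(cfg))
  fit <- fitSingleTrial(tr$plot_table)
  expect_lt(abs(coefficientOfVariation(fit) - 100 * sqrt(1.0) / 10), 2)
})

test_that("Cullis H2 limits and clamping behave", {
  mk <- function(sg, pev) methods::new("SingleTrialFit",
    env = "E", blues = c(H1 = 1, H2 = 2), mu = 10,
    varComponents = c(block = 0, row = 0, col = 0, resid = 1),
    sigmaG = sg, pev = pev, meanFitted = 10, converged = TRUE,
    nIter = 1L, dropped = character())
  expect_equal(cullisHeritability(mk(1, 2)), 0)      # no information
  expect_equal(cullisHeritability(mk(1, 0)), 1)      # perfect information
  deg <- cullisHeritability(mk(0, 0))
  expect_equal(as.numeric(deg), 0)
  expect_true(attr(deg, "degenerate"))
  expect_warning(h <- cullisHeritability(mk(1, 2.5)), "clamped")
  expect_equal(h, 0)
})

test_that("H2 stays in [0, 1] across trials and tracks the signal ratio", {
  highH2 <- simConfig(n_parents = 40,
                      testers_by_year = list(`2020` = c("T1", "T2")),
                      years = 2020, n_environments_per_year = 2,
                      n_markers = 100, coverage = 1,
                      var_components = list(v_g_add = 1.2, v_g_dom = 0,
                                            v_env = 0, v_gxe = 0,
                                            v_block = 0.05, v_row = 0.02,
                                            v_col = 0.02, v_resid = 0.3),
                      seed = 31)
  lowH2 <- simConfig(n_parents = 40,
                     testers_by_year = list(`2020` = c("T1", "T2")),
                     years = 2020, n_environments_per_year = 2,
                     n_markers = 100, coverage = 1,
                     var_components = list(v_g_add = 0.3, v_g_dom = 0,
                                           v_env = 0, v_gxe = 0,
                                           v_block = 0.05, v_row = 0.02,
                                           v_col = 0.02, v_resid = 1.2),
                     seed = 31)
  h2s <- function(cfg) {
    tr <- generateTrials(cfg, generatePopulation(cfg))
    d <- fitTrials(tr$plot_table)$diagnostics
    d$H2_Cullis
  }
  h_hi <- h2s(highH2)
  h_lo <- h2s(lowH2)
  expect_true(all(c(h_hi, h_lo) >= 0 & c(h_hi, h_lo) <= 1))
  expect_gt(mean(h_hi), mean(h_lo))
})

test_that("fitTrials assembles the phenotypic matrix across environments", {
  st <- tinyStudy()
  tm <- fitTrials(plotTable(st))
  expect_named(tm$blues, c("Env", "Hybrid", "y"))
  expect_setequal(unique(tm$blues$Env), unique(plotTable(st)$Env))
  expect_equal(nrow(tm$blues),
               nrow(unique(plotTable(st)[, c("Env", "Hybrid")])))
  expect_true(all(tm$diagnostics$var_resid >= 0))
})
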