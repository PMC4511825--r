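test_that("generation is deterministic and stream-stable across patches", {
  cfg <- fray_jorge_config(n_trees = 3, seed = 42)
  expect_equal(generate_trait_data(cfg), generate_trait_data(cfg))

  # adding a patch must not perturb the draws of existing patches
  small <- one_zone_config(n_trees = 4, seed = 11)
  extra <- small
  extra$patches <- c(extra$patches, list(list(
    patch_id = "P9", size_class = "small",
    zones = list(zone_config("core", 4,
                             trait_means = c(LMA = 100),
                             trait_cvs = c(LMA = 0.2)))
  )))
  extra <- simulation_config(extra$patches, seed = 11)
  a <- generate_trait_data(small)
  b <- generate_trait_data(extra)
  expect_equal(a, b[b$patch_id == "P3", ], ignore_attr = TRUE)
})

test_that("degenerate configurations behave as documented", {
  expect_error(zone_config("core", 0, c(LMA = 100), c(LMA = 0.1)),
               regexp = "n_trees")
  expect_error(zone_config("core", 5, c(LMA = 100), c(LMA = 2.5)),
               regexp = "\\[0, 2\\)")

  # CV = 0 collapses the marginal to the exact mean
  cfg <- one_zone_config(n_trees = 20, seed = 3,
                         cvs = c(SD = 0, TD = 0.29, LMA = 0.27,
                                 VD = 0.12, VDi = 0.07))
  tm <- tree_level_means(generate_trait_data(cfg))
  expect_equal(tm$SD, rep(170.5, 20))
})

test_that("non-positive-definite correlations error unless repair is opted in", {
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- 0.9
  r[1, 3] <- r[3, 1] <- 0.9
  r[2, 3] <- r[3, 2] <- -0.9
  cm <- trait_cormat(r, c("SD", "TD", "LMA"))
  means <- c(SD = 100, TD = 10, LMA = 150)
  cvs <- c(SD = 0.1, TD = 0.1, LMA = 0.1)
  bad <- simulation_config(list(list(
    patch_id = "P1", size_class = "small",
    zones = list(zone_config("core", 10, means, cvs, correlation = cm))
  )), seed = 1)
  expect_error(generate_trait_data(bad), regexp = "repair_pd",
               class = "traitgrad_pd_error")

  repaired <- simulation_config(list(list(
    patch_id = "P1", size_class = "small",
    zones = list(zone_config("core", 10, means, cvs, correlation = cm,
                             repair_pd = TRUE))
  )), seed = 1)
  expect_message(generate_trait_data(repaired), regexp = "Repaired")
})

test_that("marginals are calibrated: means within 2%, CVs within 10% at n >= 1000", {
  cfg <- one_zone_config(n_trees = 1500, seed = 5,
                         correlation = fray_jorge_correlations("leeward"))
  tm <- tree_level_means(generate_trait_data(cfg))
  targets_mean <- c(SD = 170.5, TD = 10.7, LMA = 273, VD = 309.5, VDi = 16.9)
  targets_cv <- c(SD = 0.21, TD = 0.29, LMA = 0.27, VD = 0.12, VDi = 0.07)
  for (tr in morph_traits) {
    v <- tm[[tr]]
    expect_lt(abs(mean(v) / targets_mean[[tr]] - 1), 0.02)
    expect_lt(abs(sd(v) / mean(v) / targets_cv[[tr]] - 1), 0.10)
  }
})

test_that("the copula reproduces the target log-scale correlations within 0.05", {
  target <- fray_jorge_correlations("leeward")
  cfg <- one_zone_config(n_trees = 2000, seed = 8, correlation = target)
  tm <- tree_level_means(generate_trait_data(cfg))
  realized <- cor(log(as.matrix(tm[morph_traits])))
  expect_lt(max(abs(realized - target$r)), 0.05)
  # the spec'd spot check: r(SD, TD) targeted at 0.74
  expect_lt(abs(realized["SD", "TD"] - 0.74), 0.05)
})

test_that("integration index of the sample correlation recovers the generator's", {
  target <- fray_jorge_correlations("leeward")
  tm <- leeward_tree_matrix(n_trees = 1000, seed = 13)
  R_hat <- correlation_matrix(tm, morph_traits, log_transform = TRUE)
  expect_lt(abs(integration_index(R_hat) - integration_index(target)), 0.15)
})

test_that("flow logs behave as documented", {
  # zero flow, no noise: constant mass
  fl0 <- generate_flow_log(0, 300, noise_sd = 0)
  expect_true(all(fl0$mass_kg == 0))
  expect_true(all(diff(fl0$time_s) == 15))

  # noiseless line has exactly the configured slope
  fl <- generate_flow_log(1.333e-7, 600)
  slope <- coef(lm(mass_kg ~ time_s, fl))[["time_s"]]
  expect_equal(slope, 1.333e-7, tolerance = 1e-12)

  # noisy log: estimate_flow recovers the slope within 3 standard errors
  fln <- generate_flow_log(1.333e-7, 900, noise_sd = 2e-6, seed = 4)
  est <- estimate_flow(fln, window_s = 600)
  fit <- lm(mass_kg ~ time_s, fln)
  se <- summary(fit)$coefficients["time_s", "Std. Error"]
  expect_lt(abs(est$flow_kg_s - 1.333e-7), 3 * se)

  expect_error(generate_flow_log(1e-7, 300, noise_sd = -1), regexp = "noise_sd")
  expect_error(generate_flow_log(1e-7, 5), regexp = "duration")
})

test_that("null CV groups share the population CV and are reproducible", {
  g1 <- generate_null_cv_groups(2, 10, 0.2, mean = 5, seed = 99)
  g2 <- generate_null_cv_groups(2, 10, 0.2, mean = 5, seed = 99)
  expect_identical(g1, g2)
  expect_equal(unique(g1$group), c("g1", "g2"))

  big <- generate_null_cv_groups(1, 20000, 0.2, mean = 5, seed = 1)
  expect_lt(abs(coefficient_of_variation(big$value) - 0.2), 0.01)
  expect_lt(abs(mean(big$value) - 5), 0.05)

  expect_error(generate_null_cv_groups(2, 2, 0.2, 5), regexp = "n_per_group")
})

test_that("simulation configs round-trip through JSON and YAML", {
  cfg <- fray_jorge_config(n_trees = 2, seed = 17)
  for (ext in c(".json", ".yaml")) {
    path <- withr::local_tempfile(fileext = ext)
    write_simulation_config(cfg, path)
    back <- read_simulation_config(path)
    expect_equal(generate_trait_data(back), generate_trait_data(cfg))
  }
})
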