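test_that("trait_cormat enforces its invariants", {
  r <- diag(3)
  r[1, 2] <- 0.5  # asymmetric
  expect_error(trait_cormat(r), regexp = "symmetric")
  r[2, 1] <- 0.5
  diag(r) <- c(1, 1, 2)
  expect_error(trait_cormat(r), regexp = "diagonal")
  diag(r) <- 1
  r[1, 3] <- r[3, 1] <- 1.2
  expect_error(trait_cormat(r), regexp = "\\[-1, 1\\]")
})

test_that("integration_index matches analytic cases and the closed form", {
  expect_equal(integration_index(diag(5)), 0)

  ones <- matrix(1, 5, 5)
  expect_equal(integration_index(ones), 5)  # eigenvalues {5, 0, 0, 0, 0}

  # rank-one +/-1 matrix attains the upper bound k
  s <- c(1, -1, 1, 1, -1)
  expect_equal(integration_index(outer(s, s)), 5)

  # eigenvalue route and closed form agree to 1e-10 on random valid matrices
  withr::with_seed(10, {
    for (i in 1:30) {
      R <- random_cormat(sample(3:8, 1))
      k <- length(R$traits)
      closed <- 2 * sum(R$r[upper.tri(R$r)]^2) / (k - 1)
      expect_equal(integration_index(R), closed, tolerance = 1e-10)
      expect_lte(integration_index(R), k)
    }
  })

  # invariant under simultaneous row/column permutation
  R <- fray_jorge_correlations("leeward")
  p <- c(3, 1, 5, 2, 4)
  Rp <- trait_cormat(R$r[p, p], R$traits[p])
  expect_equal(integration_index(Rp), integration_index(R))
})

test_that("mean_r_squared relates to INT by the exact algebraic identity", {
  withr::with_seed(11, {
    for (i in 1:20) {
      R <- random_cormat(sample(3:7, 1))
      k <- length(R$traits)
      n_pairs <- k * (k - 1) / 2
      expect_equal(mean_r_squared(R),
                   integration_index(R) * (k - 1) / (2 * n_pairs))
    }
  })
  expect_equal(mean_r_squared(diag(4)), 0)
  r2 <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(mean_r_squared(r2), 0.25)
})

test_that("correlation_matrix builds valid matrices from tree means", {
  tm <- leeward_tree_matrix(n_trees = 30, seed = 21)
  R <- correlation_matrix(tm, morph_traits)
  expect_s3_class(R, "trait_cormat")
  expect_equal(R$r, t(R$r))
  expect_equal(unname(diag(R$r)), rep(1, 5))

  # perfectly proportional traits give r = 1 on the log scale
  tm2 <- tm
  tm2$TD <- 3.1 * tm2$SD
  R2 <- correlation_matrix(tm2, c("SD", "TD"))
  expect_equal(R2$r["SD", "TD"], 1)

  # independent traits at n = 2000 have |r| < 0.05
  big <- tree_level_means(generate_trait_data(one_zone_config(
    n_trees = 2000, seed = 22
  )))
  Rb <- correlation_matrix(big, morph_traits)
  expect_lt(max(abs(Rb$r[upper.tri(Rb$r)])), 0.05)

  # constant trait errors by name; too few rows error
  tm3 <- tm
  tm3$LMA <- 100
  expect_error(correlation_matrix(tm3, morph_traits), regexp = "LMA",
               class = "traitgrad_degenerate_error")
  expect_error(correlation_matrix(tm[1:2, ], morph_traits),
               class = "traitgrad_degenerate_error")
})

test_that("integration_ci is reproducible and handles degenerate resamples", {
  tm <- leeward_tree_matrix(n_trees = 40, seed = 23)
  a <- integration_ci(tm, morph_traits, B = 300, seed = 9)
  b <- integration_ci(tm, morph_traits, B = 300, seed = 9)
  expect_equal(tidy(a), tidy(b))
  expect_lte(a$ci_low, a$ci_high)
  expect_equal(a$n_individuals, 40)

  expect_warning(integration_ci(tm, morph_traits, B = 50, seed = 1),
                 regexp = "coarse")

  # a nearly-always-tied trait degenerates in > 10% of resamples
  tm_deg <- tibble::tibble(SD = c(1, rep(2, 9)),
                           TD = withr::with_seed(4, exp(rnorm(10))))
  expect_error(
    integration_ci(tm_deg, c("SD", "TD"), B = 400, seed = 2),
    class = "traitgrad_degenerate_error"
  )
})

test_that("matrix_similarity reproduces the printed zone comparisons", {
  w <- fray_jorge_correlations("windward")
  co <- fray_jorge_correlations("core")
  l <- fray_jorge_correlations("leeward")

  self <- matrix_similarity(w, w)
  expect_equal(self$index, 1)

  wc <- matrix_similarity(w, co, labels = c("windward", "core"))
  expect_equal(round(wc$index, 2), 0.11)
  expect_true(wc$exact)
  expect_equal(wc$n_permutations, 120)
  # exact p with k = 5 is a multiple of 1/120
  expect_equal(wc$p_value * 120, round(wc$p_value * 120))

  lc <- matrix_similarity(l, co)
  expect_equal(round(lc$index, 2), 0.72)
  expect_equal(lc$p_value * 120, round(lc$p_value * 120))

  # trait lists must match; featureless matrices are rejected
  sub <- trait_cormat(w$r[1:4, 1:4], w$traits[1:4])
  expect_error(matrix_similarity(w, sub), class = "traitgrad_validation_error")
  expect_error(matrix_similarity(trait_cormat(diag(5)), trait_cormat(diag(5))),
               class = "traitgrad_degenerate_error")

  # Monte Carlo mode approximates the exact p-value
  mc <- matrix_similarity(l, co, exhaustive = FALSE, n_permutations = 2000,
                          seed = 3)
  expect_lt(abs(mc$p_value - lc$p_value), 0.03)
})

test_that("the similarity index agrees with an independent Mantel statistic", {
  skip_if_not_installed("vegan")
  withr::with_seed(31, {
    R1 <- random_cormat(5)
    R2 <- random_cormat(5)
  })
  ours <- matrix_similarity(R1, R2)
  mantel <- vegan::mantel(stats::as.dist(R1$r), stats::as.dist(R2$r),
                          permutations = 99)
  expect_equal(ours$index, unname(mantel$statistic), tolerance = 1e-12)
})

test_that("correlation matrices round-trip through the upper-triangle CSV", {
  R <- fray_jorge_correlations("core")
  path <- withr::local_tempfile(fileext = ".csv")
  write_correlation_csv(R, path)
  back <- read_correlation_csv(path)
  expect_equal(back, R)

  # incomplete pair list is rejected
  df <- tidy(R)[1:7, ]
  readr::write_csv(df, path)
  expect_error(read_correlation_csv(path), class = "traitgrad_validation_error")
})
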