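test_that("coefficient_of_variation matches its definition", {
  expect_equal(coefficient_of_variation(c(5, 5, 5)), 0)
  expect_equal(coefficient_of_variation(c(2, 4, 6)), 0.5)
  x <- withr::with_seed(1, rlnorm_cv(30, 0.3, mean = 10))
  expect_equal(coefficient_of_variation(3.7 * x), coefficient_of_variation(x))
  expect_error(coefficient_of_variation(c(1)), regexp = "at least 2")
  expect_error(coefficient_of_variation(c(-3, 1)), regexp = "non-positive")
})

test_that("bootstrap_cv_test is deterministic, symmetric and sane under H0 identity", {
  x <- withr::with_seed(2, rlnorm_cv(10, 0.2, mean = 5))
  y <- withr::with_seed(3, rlnorm_cv(10, 0.35, mean = 8))

  a <- bootstrap_cv_test(x, y, B = 500, seed = 7)
  b <- bootstrap_cv_test(x, y, B = 500, seed = 7)
  expect_equal(tidy(a), tidy(b))

  # swapping the samples leaves the statistic and p-value unchanged
  swapped <- bootstrap_cv_test(y, x, B = 500, seed = 7)
  expect_equal(swapped$t_d, a$t_d)
  expect_equal(swapped$z_d, a$z_d)
  expect_equal(swapped$p_value, a$p_value)

  # identical samples: T_D = 0, Z_D = 0, p = 1
  same <- bootstrap_cv_test(x, x, B = 500, seed = 1)
  expect_equal(same$t_d, 0)
  expect_equal(same$z_d, 0)
  expect_equal(same$p_value, 1)

  expect_warning(bootstrap_cv_test(x, y, B = 50, seed = 1), regexp = "B < 100")
  expect_error(
    suppressWarnings(bootstrap_cv_test(c(5, 5, 5), c(3, 3, 3), B = 200)),
    class = "traitgrad_degenerate_error"
  )
})

test_that("pairwise tests apply the Bonferroni threshold and assign letters", {
  dat <- generate_null_cv_groups(3, 10, 0.25, mean = 10, seed = 5)
  dat$group <- rep(c("windward", "core", "leeward"), each = 10)
  res <- pairwise_cv_tests(dat, value, group, trait = "SD", B = 300, seed = 2)
  expect_equal(nrow(res$comparisons), 3)
  expect_equal(res$alpha_adjusted, 0.05 / 3)
  expect_equal(res$alpha_adjusted * 3, 0.05)
  expect_equal(round(res$alpha_adjusted, 3), 0.017)
  expect_setequal(res$letters$group, c("windward", "core", "leeward"))
  expect_equal(tidy(res), res$comparisons)
})

test_that("letters encode the significance graph exactly", {
  cmp <- function(p_ab, p_ac, p_bc) {
    tibble::tibble(
      group_a = c("A", "A", "B"), group_b = c("B", "C", "C"),
      p_value = c(p_ab, p_ac, p_bc)
    )
  }
  # A differs from both B and C; B and C indistinguishable
  l <- significance_letters(cmp(0.001, 0.001, 0.8), c("A", "B", "C"), 0.017)
  expect_equal(l$letters[l$group == "A"], "a")
  expect_equal(l$letters[l$group == "B"], "b")
  expect_equal(l$letters[l$group == "C"], "b")

  # nothing significant: everyone shares one letter
  l2 <- significance_letters(cmp(0.5, 0.9, 0.3), c("A", "B", "C"), 0.017)
  expect_equal(unique(l2$letters), "a")

  # everything significant: three distinct letters
  l3 <- significance_letters(cmp(0.001, 0.001, 0.001), c("A", "B", "C"), 0.017)
  expect_equal(sort(l3$letters), c("a", "b", "c"))

  # chain A~B, B~C but A!=C gives B both letters
  l4 <- significance_letters(cmp(0.5, 0.001, 0.5), c("A", "B", "C"), 0.017)
  expect_equal(l4$letters[l4$group == "B"], "ab")
})

test_that("rejection rate grows with the CV ratio (monotone power)", {
  n_rep <- 200
  rates <- withr::with_seed(12, {
    vapply(c(0.2, 0.4, 0.8), function(cv2) {
      rej <- 0
      for (i in seq_len(n_rep)) {
        x <- rlnorm_cv(10, 0.2, mean = 10)
        y <- rlnorm_cv(10, cv2, mean = 10)
        fit <- bootstrap_cv_test(x, y, B = 300)
        if (fit$p_value <= 0.05) rej <- rej + 1
      }
      rej / n_rep
    }, numeric(1))
  })
  se <- sqrt(0.5 * 0.5 / n_rep)
  expect_true(rates[2] >= rates[1] - se)
  expect_true(rates[3] >= rates[2] - se)
  expect_gt(rates[3], 0.5)  # ratio 4 at n = 10 is easy to detect
})

test_that("zone_cv_summary reproduces generator CVs and honours pooling", {
  # CV 0 passes through exactly
  cfg0 <- one_zone_config(n_trees = 10, seed = 1,
                          cvs = c(SD = 0, TD = 0.2, LMA = 0.2,
                                  VD = 0.2, VDi = 0.2))
  sm0 <- zone_cv_summary(tree_level_means(generate_trait_data(cfg0)))
  expect_equal(sm0$cv[sm0$trait == "SD"], 0)

  # large-n CV lands within 10% of the target
  tm <- leeward_tree_matrix(n_trees = 2000, seed = 6)
  sm <- zone_cv_summary(tm)
  expect_lt(abs(sm$cv[sm$trait == "SD"] / 0.21 - 1), 0.10)

  # pooling excludes the other size class
  cfg <- fray_jorge_config(n_trees = 2, seed = 3)
  tm_all <- tree_level_means(generate_trait_data(cfg))
  large <- zone_cv_summary(tm_all, traits = "LMA", pooling = "large")
  all_p <- zone_cv_summary(tm_all, traits = "LMA", pooling = "all")
  expect_true(all(large$n == 4))   # 2 trees x 2 large patches
  expect_true(all(all_p$n == 8))

  # a 1-tree cell yields NA with a warning
  one_tree <- tm_all[tm_all$tree_id == "t01" & tm_all$patch_id == "P3", ]
  expect_warning(sm1 <- zone_cv_summary(one_tree, traits = "LMA"),
                 regexp = "< 2 trees")
  expect_true(all(is.na(sm1$cv)))
})
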