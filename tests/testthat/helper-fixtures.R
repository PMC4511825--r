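# Fixtures are built in code; nothing is read from disk except the
# package's own bundled reference tables.

tiny_trait_table <- function() {
  tibble::tibble(
    patch_id = "P1",
    patch_size_class = "small",
    zone = rep(c("windward", "core", "leeward"), each = 2),
    tree_id = rep(c("t1", "t2"), 3),
    trait_name = "LMA",
    replicate_id = "r1",
    value = c(100, 120, 90, 95, 200, 260)
  )
}

# Single-zone generator config over the five morphological traits.
one_zone_config <- function(zone = "leeward", n_trees = 50, seed = 1,
                            within_tree_cv = 0, correlation = NULL,
                            cvs = NULL) {
  means <- c(SD = 170.5, TD = 10.7, LMA = 273, VD = 309.5, VDi = 16.9)
  if (is.null(cvs)) {
    cvs <- c(SD = 0.21, TD = 0.29, LMA = 0.27, VD = 0.12, VDi = 0.07)
  }
  zc <- zone_config(
    zone = zone, n_trees = n_trees, trait_means = means, trait_cvs = cvs,
    correlation = correlation, n_replicates = 1L,
    within_tree_cv = within_tree_cv
  )
  simulation_config(
    list(list(patch_id = "P3", size_class = "large", zones = list(zc))),
    seed = seed
  )
}

leeward_tree_matrix <- function(n_trees, seed) {
  cfg <- one_zone_config(
    n_trees = n_trees, seed = seed,
    correlation = fray_jorge_correlations("leeward")
  )
  tree_level_means(generate_trait_data(cfg))
}

morph_traits <- c("SD", "TD", "LMA", "VD", "VDi")

# Random valid correlation matrix from the Gram matrix of random data.
random_cormat <- function(k, n = k + 5) {
  trait_cormat(stats::cor(matrix(stats::rnorm(n * k), n, k)),
               paste0("T", seq_len(k)))
}

rlnorm_cv <- function(n, cv, mean = 1) {
  sl <- sqrt(log(1 + cv^2))
  mean * exp(stats::rnorm(n, -sl^2 / 2, sl))
}
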