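#' Zone configuration for the synthetic trait generator
#'
#' Describes one moisture zone of one patch: how many trees, the target
#' marginal mean and coefficient of variation of each trait, an optional
#' between-trait correlation structure (applied on the log scale, i.e. a
#' Gaussian copula with lognormal marginals), and the replicate design.
#'
#' @param zone Zone label (`windward`, `core` or `leeward`).
#' @param n_trees Number of trees to simulate in the zone.
#' @param trait_means Named numeric vector of positive target marginal means.
#' @param trait_cvs Named numeric vector of target coefficients of
#'   variation, one per trait in `trait_means`.  Must be `< 2` so the
#'   lognormal log-scale parameterisation stays numerically sane.
#' @param correlation Optional [trait_cormat()] over a subset of the traits
#'   in `trait_means`; enforced between the tree-level latent values on the
#'   log scale.
#' @param n_replicates Named integer vector (or single integer, recycled)
#'   of replicate measurements per tree per trait.
#' @param within_tree_cv CV of the multiplicative lognormal replicate noise
#'   around each tree value (0 makes replicates exact copies).
#' @param repair_pd If `TRUE`, a non-positive-definite `correlation` is
#'   repaired to the nearest correlation matrix (logged with a message)
#'   instead of raising an error.
#' @return A `zone_config` object.
#' @export
zone_config <- function(zone, n_trees, trait_means, trait_cvs,
                        correlation = NULL, n_replicates = 1L,
                        within_tree_cv = 0.1, repair_pd = FALSE) {
  if (!zone %in% ZONES) {
    abort(sprintf("`zone` must be one of %s.", paste(ZONES, collapse = ", ")))
  }
  if (!is.numeric(n_trees) || length(n_trees) != 1 || n_trees < 1) {
    abort("`n_trees` must be a positive integer.")
  }
  if (is.null(names(trait_means)) || is.null(names(trait_cvs))) {
    abort("`trait_means` and `trait_cvs` must be named vectors.")
  }
  if (!setequal(names(trait_means), names(trait_cvs))) {
    abort("`trait_means` and `trait_cvs` must name the same traits.")
  }
  if (any(trait_means <= 0)) abort("All `trait_means` must be positive.")
  if (any(trait_cvs < 0) || any(trait_cvs >= 2)) {
    abort("All `trait_cvs` must lie in [0, 2).")
  }
  if (!is.null(correlation)) {
    stopifnot(inherits(correlation, "trait_cormat"))
    extra <- setdiff(correlation$traits, names(trait_means))
    if (length(extra) > 0) {
      abort(sprintf(
        "Correlated trait(s) not in `trait_means`: %s.",
        paste(extra, collapse = ", ")
      ))
    }
  }
  if (is.null(names(n_replicates))) {
    n_replicates <- setNames(
      rep(as.integer(n_replicates), length(trait_means)), names(trait_means)
    )
  }
  if (any(n_replicates < 1)) abort("`n_replicates` must be >= 1.")
  check_scalar_number(within_tree_cv, "within_tree_cv", min = 0)
  structure(
    list(
      zone = zone, n_trees = as.integer(n_trees),
      trait_means = trait_means, trait_cvs = trait_cvs[names(trait_means)],
      correlation = correlation,
      n_replicates = n_replicates[names(trait_means)],
      within_tree_cv = within_tree_cv, repair_pd = repair_pd
    ),
    class = "zone_config"
  )
}

#' Simulation configuration
#'
#' Bundles patches (each a patch id, size class and per-zone
#' [zone_config()]s) with a master seed.  Per patch-and-zone random streams
#' are derived deterministically from the master seed and the patch/zone
#' labels, so adding a patch never perturbs the draws of another.
#'
#' @param patches A list of `list(patch_id =, size_class =, zones = list of
#'   zone_config)` entries.
#' @param seed Master integer seed, recorded in all outputs.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(patches, seed) {
  check_scalar_number(seed, "seed")
  ids <- vapply(patches, function(p) p$patch_id, character(1))
  if (anyDuplicated(ids)) abort("`patch_id`s must be unique.")
  for (p in patches) {
    if (!p$size_class %in% SIZE_CLASSES) {
      abort("Each patch `size_class` must be small or large.")
    }
    for (z in p$zones) stopifnot(inherits(z, "zone_config"))
  }
  structure(list(patches = patches, seed = as.integer(seed)),
            class = "simulation_config")
}

# Tree-level latent draws for one zone: multivariate normal on the log
# scale with sigma_log = sqrt(log(1 + CV^2)) and the configured correlation,
# exponentiated; mu_log = log(mean) - sigma^2/2 makes the marginal mean
# equal the target exactly.
draw_zone_trees <- function(zc) {
  traits <- names(zc$trait_means)
  n <- zc$n_trees
  sig <- sqrt(log(1 + zc$trait_cvs^2))
  mu <- log(zc$trait_means) - sig^2 / 2
  out <- matrix(NA_real_, n, length(traits), dimnames = list(NULL, traits))
  corr_traits <- if (is.null(zc$correlation)) character(0) else zc$correlation$traits
  if (length(corr_traits) > 0) {
    R <- zc$correlation$r
    ch <- tryCatch(chol(R), error = function(e) NULL)
    if (is.null(ch)) {
      if (!zc$repair_pd) {
        abort(paste(
          "Correlation matrix is not positive definite.",
          "Pass `repair_pd = TRUE` to zone_config() to repair it to the",
          "nearest correlation matrix (the repair is logged)."
        ), class = "traitgrad_pd_error")
      }
      R <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
      inform(sprintf(
        "Repaired non-positive-definite correlation matrix for zone %s.",
        zc$zone
      ))
      ch <- chol(R)
    }
    z <- matrix(rnorm(n * length(corr_traits)), n) %*% ch
    for (j in seq_along(corr_traits)) {
      tr <- corr_traits[j]
      out[, tr] <- exp(mu[tr] + sig[tr] * z[, j])
    }
  }
  for (tr in setdiff(traits, corr_traits)) {
    out[, tr] <- exp(mu[tr] + sig[tr] * rnorm(n))
  }
  out
}

#' Generate a synthetic trait table
#'
#' Draws tree-level trait values per zone from a Gaussian copula with
#' lognormal marginals (correlation enforced on the log scale), then draws
#' replicate-level values around each tree value with multiplicative
#' mean-one lognormal noise of the configured within-tree CV.  A fixed seed
#' gives bit-identical output.
#'
#' @param cfg A [simulation_config()].
#' @return A validated long-format trait table, with the master seed stored
#'   in attribute `"seed"`.
#' @export
generate_trait_data <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  rows <- list()
  for (p in cfg$patches) {
    for (zc in p$zones) {
      stream <- derive_seed(cfg$seed, p$patch_id, zc$zone)
      block <- withr::with_seed(stream, {
        trees <- draw_zone_trees(zc)
        traits <- colnames(trees)
        tree_ids <- sprintf("t%02d", seq_len(zc$n_trees))
        s_rep <- sqrt(log(1 + zc$within_tree_cv^2))
        sub <- list()
        for (tr in traits) {
          m <- zc$n_replicates[[tr]]
          noise <- if (s_rep == 0) {
            matrix(1, zc$n_trees, m)
          } else {
            matrix(exp(rnorm(zc$n_trees * m, -s_rep^2 / 2, s_rep)),
                   zc$n_trees, m)
          }
          vals <- trees[, tr] * noise
          sub[[tr]] <- tibble(
            patch_id = p$patch_id,
            patch_size_class = p$size_class,
            zone = zc$zone,
            tree_id = rep(tree_ids, times = m),
            trait_name = tr,
            replicate_id = rep(sprintf("r%02d", seq_len(m)), each = zc$n_trees),
            value = as.vector(vals)
          )
        }
        dplyr::bind_rows(sub)
      })
      rows[[paste(p$patch_id, zc$zone)]] <- block
    }
  }
  out <- dplyr::bind_rows(rows)
  validate_trait_table(out)
  attr(out, "seed") <- cfg$seed
  out
}

#' Generate a synthetic balance flow log
#'
#' Emulates the lab balance that records cumulative solution mass at a
#' fixed interval (15 s by default) while a stem segment conducts under a
#' constant pressure head.
#'
#' @param true_flow True steady flow rate (kg/s), `>= 0`.
#' @param duration_s Total log duration (s), at least one interval.
#' @param interval_s Sampling interval (s).
#' @param noise_sd Standard deviation of additive Gaussian mass noise (kg).
#' @param seed Optional seed for reproducible noise.
#' @param start_mass_kg Balance tare mass at time zero (kg).
#' @return A tibble with columns `time_s` (strictly increasing) and
#'   `mass_kg`.
#' @export
generate_flow_log <- function(true_flow, duration_s, interval_s = 15,
                              noise_sd = 0, seed = NULL, start_mass_kg = 0) {
  check_scalar_number(true_flow, "true_flow", min = 0)
  check_scalar_number(noise_sd, "noise_sd", min = 0)
  check_scalar_number(interval_s, "interval_s", min = 0, strict = TRUE)
  if (duration_s < interval_s) abort("`duration_s` must be >= `interval_s`.")
  time_s <- seq(0, duration_s, by = interval_s)
  mass <- start_mass_kg + true_flow * time_s
  if (noise_sd > 0) {
    mass <- mass + with_seed_if(seed, rnorm(length(time_s), 0, noise_sd))
  }
  tibble(time_s = time_s, mass_kg = mass)
}

#' Generate groups sharing a common population CV
#'
#' Simulation harness for studying the operating characteristics (type-I
#' error, power) of the bootstrap CV-equality test: each group is lognormal
#' with identical population coefficient of variation.
#'
#' @param n_groups Number of groups.
#' @param n_per_group Sample size per group (`>= 3`).
#' @param common_cv Shared population CV (positive, `< 2`).
#' @param mean Shared population mean (positive).
#' @param seed Optional seed.
#' @return A tibble with columns `group` (`g1`, `g2`, ...) and `value`.
#' @export
generate_null_cv_groups <- function(n_groups, n_per_group, common_cv, mean,
                                    seed = NULL) {
  if (n_per_group < 3) abort("`n_per_group` must be >= 3.")
  check_scalar_number(common_cv, "common_cv", min = 0, strict = TRUE)
  if (common_cv >= 2) abort("`common_cv` must be < 2.")
  check_scalar_number(mean, "mean", min = 0, strict = TRUE)
  sl <- sqrt(log(1 + common_cv^2))
  with_seed_if(seed, {
    tibble(
      group = rep(sprintf("g%d", seq_len(n_groups)), each = n_per_group),
      value = mean * exp(rnorm(n_groups * n_per_group, -sl^2 / 2, sl))
    )
  })
}

#' Read or write a simulation configuration
#'
#' Configurations serialise to JSON or YAML (chosen by file extension).
#'
#' @param cfg A [simulation_config()].
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return `read_simulation_config()` returns a [simulation_config()];
#'   `write_simulation_config()` returns `cfg` invisibly.
#' @export
write_simulation_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "simulation_config"))
  ser <- list(
    seed = cfg$seed,
    patches = lapply(cfg$patches, function(p) {
      list(
        patch_id = p$patch_id, size_class = p$size_class,
        zones = lapply(p$zones, function(z) {
          out <- list(
            zone = z$zone, n_trees = z$n_trees,
            trait_means = as.list(z$trait_means),
            trait_cvs = as.list(z$trait_cvs),
            n_replicates = as.list(z$n_replicates),
            within_tree_cv = z$within_tree_cv,
            repair_pd = z$repair_pd
          )
          if (!is.null(z$correlation)) {
            out$correlation <- list(
              traits = z$correlation$traits,
              r = lapply(seq_len(nrow(z$correlation$r)),
                         function(i) unname(z$correlation$r[i, ]))
            )
          }
          out
        })
      )
    })
  )
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(ser, path)
  } else {
    jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(cfg)
}

#' @rdname write_simulation_config
#' @export
read_simulation_config <- function(path) {
  ser <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  patches <- lapply(ser$patches, function(p) {
    list(
      patch_id = p$patch_id, size_class = p$size_class,
      zones = lapply(p$zones, function(z) {
        corr <- NULL
        if (!is.null(z$correlation)) {
          traits <- unlist(z$correlation$traits)
          r <- do.call(rbind, lapply(z$correlation$r, unlist))
          dimnames(r) <- list(traits, traits)
          corr <- trait_cormat(r)
        }
        zone_config(
          zone = z$zone, n_trees = z$n_trees,
          trait_means = unlist(z$trait_means),
          trait_cvs = unlist(z$trait_cvs),
          correlation = corr,
          n_replicates = unlist(z$n_replicates),
          within_tree_cv = z$within_tree_cv,
          repair_pd = isTRUE(z$repair_pd)
        )
      })
    )
  })
  simulation_config(patches, seed = ser$seed)
}
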