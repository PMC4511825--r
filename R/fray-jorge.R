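# Bundled defaults on the scale of published zone-level summaries for
# Aextoxicon punctatum in the Fray Jorge fog-forest patch mosaic.  They are
# realistic fixture values for the synthetic generator, not field data.

fj_extdata <- function(file) {
  system.file("extdata", file, package = "traitgrad", mustWork = TRUE)
}

#' Bundled fog-forest zone trait correlation matrices
#'
#' Returns the 5x5 Pearson correlation matrix of the morphological traits
#' (SD, TD, LMA, VD, VDi) for one moisture zone, as bundled with the
#' package.  These matrices are the canonical direct input to
#' [integration_index()], [mean_r_squared()] and [matrix_similarity()].
#'
#' @param zone `"windward"`, `"core"` or `"leeward"`.
#' @return A [trait_cormat()].
#' @export
fray_jorge_correlations <- function(zone = ZONES) {
  zone <- match.arg(zone)
  read_correlation_csv(fj_extdata(sprintf("fray_jorge_cor_%s.csv", zone)))
}

#' Bundled fog-forest zone trait means and CVs
#'
#' Zone-level trait means (per patch size class) and coefficients of
#' variation used as defaults by [fray_jorge_config()].  Means and CVs for
#' the six morphological/hydraulic traits follow published zone summaries;
#' soil moisture and water-potential CVs are fixture choices documented in
#' the methods vignette.
#'
#' @return A tibble.
#' @export
fray_jorge_trait_means <- function() {
  readr::read_csv(fj_extdata("fray_jorge_zone_means.csv"),
                  col_types = "cccd", progress = FALSE)
}

#' @rdname fray_jorge_trait_means
#' @export
fray_jorge_trait_cvs <- function() {
  readr::read_csv(fj_extdata("fray_jorge_zone_cvs.csv"),
                  col_types = "ccd", progress = FALSE)
}

#' Default fog-forest simulation configuration
#'
#' Builds a [simulation_config()] mirroring the field design: 5 trees per
#' zone in each of 4 patches (2 small, 2 large), 3 moisture zones, with
#' zone-specific trait means, CVs and between-trait correlations from the
#' bundled reference tables.  Correlations are applied to the five
#' morphological traits on the log scale.
#'
#' @param n_trees Trees per zone per patch.
#' @param seed Master seed.
#' @param within_tree_cv Within-tree replicate CV.
#' @param patches Optional patch skeleton: a data frame with columns
#'   `patch_id` and `size_class`; defaults to P1/P2 small + P3/P4 large.
#' @return A [simulation_config()].
#' @export
fray_jorge_config <- function(n_trees = 5, seed = 1, within_tree_cv = 0.1,
                              patches = NULL) {
  if (is.null(patches)) {
    patches <- tibble(
      patch_id = c("P1", "P2", "P3", "P4"),
      size_class = c("small", "small", "large", "large")
    )
  }
  means <- fray_jorge_trait_means()
  cvs <- fray_jorge_trait_cvs()
  cors <- lapply(setNames(ZONES, ZONES), fray_jorge_correlations)
  # Replicate design: ten leaves per tree for LMA, five TDR / pressure
  # chamber readings for moisture and water potentials, single
  # measurements otherwise.
  reps <- c(SM = 5L, psi_PD = 5L, psi_MD = 5L, SD = 1L, TD = 1L,
            LMA = 10L, VD = 1L, VDi = 1L, Ks = 1L)
  patch_list <- purrr::pmap(patches, function(patch_id, size_class) {
    zones <- lapply(ZONES, function(z) {
      mz <- means[means$size_class == size_class & means$zone == z, ]
      cz <- cvs[cvs$zone == z, ]
      mu <- setNames(mz$mean, mz$trait)
      cv <- setNames(cz$cv, cz$trait)[names(mu)]
      zone_config(
        zone = z, n_trees = n_trees, trait_means = mu, trait_cvs = cv,
        correlation = cors[[z]], n_replicates = reps[names(mu)],
        within_tree_cv = within_tree_cv
      )
    })
    list(patch_id = patch_id, size_class = size_class, zones = zones)
  })
  simulation_config(patch_list, seed = seed)
}
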