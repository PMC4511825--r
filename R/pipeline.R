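#' Run the full trait-gradient analysis pipeline
#'
#' Orchestrates an end-to-end run: obtain a trait table (from a
#' [simulation_config()], a CSV path, or an in-memory data frame), collapse
#' replicates to tree-level means, summarise zone means and CVs, run
#' Bonferroni-corrected pairwise bootstrap CV tests per trait, build
#' per-zone correlation matrices with integration indices (bootstrap CIs)
#' and between-zone similarity tests, and optionally process balance flow
#' logs into conductivity records.  All outputs are written as CSVs plus a
#' machine-readable JSON manifest; a rerun with the same inputs and seed is
#' byte-identical.
#'
#' @param input A [simulation_config()], a trait-table CSV path, or a
#'   trait-table data frame.
#' @param out_dir Output directory (created if needed).
#' @param traits Traits used for the CV and integration stages.
#' @param B Bootstrap replications for the CV tests and integration CIs.
#' @param alpha Familywise significance level for the pairwise CV tests.
#' @param seed Master seed for all stochastic stages (mandatory).
#' @param pooling Patch pooling passed to [zone_cv_summary()] and applied
#'   to the integration stage.
#' @param flow_logs,segments Optional hydraulics inputs for
#'   [conductivity_records()].
#' @param log_transform Correlate log-transformed tree means.
#' @return A `trait_pipeline` list with every stage's results and the
#'   manifest, invisibly.
#' @export
run_pipeline <- function(input, out_dir, traits = MORPH_TRAITS, B = 10000,
                         alpha = 0.05, seed = 1,
                         pooling = c("large", "all", "small"),
                         flow_logs = NULL, segments = NULL,
                         log_transform = TRUE) {
  pooling <- match.arg(pooling)
  check_scalar_number(seed, "seed")
  if (xor(is.null(flow_logs), is.null(segments))) {
    abort("Provide both `flow_logs` and `segments`, or neither.")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  trait_table <- if (inherits(input, "simulation_config")) {
    generate_trait_data(input)
  } else if (is.character(input)) {
    read_trait_table(input)
  } else {
    validate_trait_table(input)
  }

  tree_matrix <- tree_level_means(trait_table)
  pooled <- if (pooling == "all") {
    tree_matrix
  } else {
    tree_matrix[tree_matrix$patch_size_class == pooling, ]
  }
  zone_summary <- zone_cv_summary(tree_matrix, traits = NULL,
                                  pooling = pooling)

  multi_zone <- length(unique(pooled$zone)) >= 2
  if (multi_zone) {
    cv_results <- purrr::map(
      setNames(traits, traits),
      function(tr) {
        dat <- pooled[!is.na(pooled[[tr]]), c("zone", tr)]
        names(dat)[2] <- "value"
        pairwise_cv_tests(dat, value, zone, trait = tr, B = B, alpha = alpha,
                          seed = derive_seed(seed, "cv", tr))
      }
    )
    cv_comparisons <- purrr::map_dfr(cv_results, "comparisons")
    cv_letters <- purrr::map_dfr(cv_results, function(x) x$letters,
                                 .id = "trait")
  } else {
    cv_results <- list()
    cv_comparisons <- tibble(
      trait = character(), group_a = character(), group_b = character(),
      cv_a = double(), cv_b = double(), t_d = double(), v_d = double(),
      z_d = double(), p_value = double(), B = integer(),
      alpha_adjusted = double(), significant = logical()
    )
    cv_letters <- tibble(trait = character(), group = character(),
                         letters = character())
  }

  zones_present <- intersect(ZONES, unique(pooled$zone))
  cormats <- purrr::map(
    setNames(zones_present, zones_present),
    function(z) correlation_matrix(pooled, traits, zone = z,
                                   log_transform = log_transform)
  )
  integration <- purrr::map(
    setNames(zones_present, zones_present),
    function(z) integration_ci(pooled, traits, zone = z, B = B,
                               seed = derive_seed(seed, "int", z),
                               log_transform = log_transform)
  )
  integration_tbl <- purrr::map_dfr(integration, tidy)
  sim_pairs <- if (length(zones_present) >= 2) combn(zones_present, 2) else NULL
  similarity <- if (is.null(sim_pairs)) list() else purrr::map(
    seq_len(ncol(sim_pairs)),
    function(i) {
      a <- sim_pairs[1, i]
      b <- sim_pairs[2, i]
      matrix_similarity(cormats[[a]], cormats[[b]], labels = c(a, b))
    }
  )
  similarity_tbl <- if (length(similarity) == 0) {
    tibble(zone_a = character(), zone_b = character(), index = double(),
           p_value = double(), n_permutations = integer(), exact = logical())
  } else {
    purrr::map_dfr(similarity, tidy)
  }

  conductivity <- NULL
  if (!is.null(flow_logs)) {
    conductivity <- conductivity_records(flow_logs, segments)
  }

  files <- list(
    trait_table = "trait_table.csv",
    tree_matrix = "tree_matrix.csv",
    zone_summary = "zone_summary.csv",
    cv_comparisons = "cv_comparisons.csv",
    cv_letters = "cv_letters.csv",
    integration = "integration.csv",
    similarity = "similarity.csv"
  )
  readr::write_csv(trait_table, file.path(out_dir, files$trait_table),
                   progress = FALSE)
  readr::write_csv(tree_matrix, file.path(out_dir, files$tree_matrix),
                   progress = FALSE)
  readr::write_csv(zone_summary, file.path(out_dir, files$zone_summary),
                   progress = FALSE)
  readr::write_csv(cv_comparisons, file.path(out_dir, files$cv_comparisons),
                   progress = FALSE)
  readr::write_csv(cv_letters, file.path(out_dir, files$cv_letters),
                   progress = FALSE)
  readr::write_csv(integration_tbl, file.path(out_dir, files$integration),
                   progress = FALSE)
  readr::write_csv(similarity_tbl, file.path(out_dir, files$similarity),
                   progress = FALSE)
  for (z in zones_present) {
    f <- sprintf("correlation_%s.csv", z)
    write_correlation_csv(cormats[[z]], file.path(out_dir, f))
    files[[paste0("correlation_", z)]] <- f
  }
  if (!is.null(conductivity)) {
    files$conductivity <- "conductivity.csv"
    readr::write_csv(conductivity, file.path(out_dir, files$conductivity),
                     progress = FALSE)
  }

  paths <- file.path(out_dir, unlist(files))
  manifest <- list(
    package = "traitgrad",
    package_version = as.character(utils::packageVersion("traitgrad")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = as.integer(seed), B = as.integer(B), alpha = alpha,
    pooling = pooling, traits = traits,
    stages = list(
      trait_table_rows = nrow(trait_table),
      tree_matrix_rows = nrow(tree_matrix),
      cv_comparisons = nrow(cv_comparisons),
      integration_zones = length(integration),
      similarity_pairs = length(similarity),
      conductivity_segments = if (is.null(conductivity)) 0L else nrow(conductivity)
    ),
    files = purrr::imap(files, function(f, nm) {
      list(file = f, md5 = unname(tools::md5sum(file.path(out_dir, f))))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(
    list(
      trait_table = trait_table, tree_matrix = tree_matrix,
      zone_summary = zone_summary, cv_results = cv_results,
      cv_comparisons = cv_comparisons, cv_letters = cv_letters,
      correlations = cormats, integration = integration,
      integration_table = integration_tbl, similarity = similarity,
      similarity_table = similarity_tbl, conductivity = conductivity,
      manifest = manifest, out_dir = out_dir
    ),
    class = "trait_pipeline"
  )
}

#' @export
print.trait_pipeline <- function(x, ...) {
  cat(sprintf(
    "<trait_pipeline> %d trees, %d CV comparisons, %d zones integrated -> %s\n",
    nrow(x$tree_matrix), nrow(x$cv_comparisons), length(x$integration),
    x$out_dir
  ))
  invisible(x)
}

#' Render report tables from pipeline results
#'
#' Produces compact display tables: a zone-by-trait CV table with the
#' compact-letter columns kept separate from the numbers, the integration
#' table, and the similarity table.
#'
#' @param results A `trait_pipeline` object.
#' @return A named list of tibbles (`cv_table`, `integration`,
#'   `similarity`).
#' @export
render_tables <- function(results) {
  stopifnot(inherits(results, "trait_pipeline"))
  cvs <- results$zone_summary |>
    dplyr::filter(.data$trait %in% unique(results$cv_letters$trait)) |>
    dplyr::select("zone", "trait", "cv") |>
    tidyr::pivot_wider(names_from = "zone", values_from = "cv")
  if (nrow(results$cv_letters) > 0) {
    letters_wide <- results$cv_letters |>
      tidyr::pivot_wider(names_from = "group", values_from = "letters",
                         names_glue = "{group}_letters")
    cvs <- dplyr::left_join(cvs, letters_wide, by = "trait")
  }
  list(
    cv_table = cvs,
    integration = results$integration_table,
    similarity = results$similarity_table
  )
}
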