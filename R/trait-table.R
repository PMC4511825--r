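#' Validate a long-format trait table
#'
#' A trait table holds replicate-level measurements in long format, one row
#' per `(patch_id, zone, tree_id, trait_name, replicate_id)`.  Zones are the
#' closed set windward/core/leeward; patch size classes are small/large.
#' Water potentials are stored as positive magnitudes of \eqn{-\psi} (MPa),
#' so all values of the standard traits (SM, psi_PD, psi_MD, SD, TD, LMA,
#' VD, VDi, Ks) must be strictly positive.
#'
#' @param data A data frame with columns `patch_id`, `patch_size_class`,
#'   `zone`, `tree_id`, `trait_name`, `replicate_id`, `value`.
#' @return The validated table as a tibble (invisibly unchanged), so the
#'   function can sit in a pipe.
#' @export
validate_trait_table <- function(data) {
  required <- c(
    "patch_id", "patch_size_class", "zone", "tree_id",
    "trait_name", "replicate_id", "value"
  )
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    abort(
      sprintf("Missing required column(s): %s.", paste(missing, collapse = ", ")),
      class = "traitgrad_schema_error"
    )
  }
  data <- as_tibble(data)
  if (!is.numeric(data$value)) {
    abort("`value` must be numeric.", class = "traitgrad_parse_error")
  }
  bad_zone <- setdiff(unique(data$zone), ZONES)
  if (length(bad_zone) > 0) {
    abort(
      sprintf(
        "Unknown zone label(s): %s. Zones must be one of %s.",
        paste(bad_zone, collapse = ", "), paste(ZONES, collapse = ", ")
      ),
      class = "traitgrad_validation_error"
    )
  }
  bad_size <- setdiff(unique(data$patch_size_class), SIZE_CLASSES)
  if (length(bad_size) > 0) {
    abort(
      sprintf(
        "Unknown patch_size_class label(s): %s (must be small or large).",
        paste(bad_size, collapse = ", ")
      ),
      class = "traitgrad_validation_error"
    )
  }
  key <- paste(data$patch_id, data$zone, data$tree_id, data$trait_name,
               data$replicate_id, sep = "\r")
  if (anyDuplicated(key)) {
    abort(
      "Duplicate (patch_id, zone, tree_id, trait_name, replicate_id) keys.",
      class = "traitgrad_validation_error"
    )
  }
  if (any(!is.finite(data$value))) {
    abort("`value` contains non-finite entries.", class = "traitgrad_validation_error")
  }
  pos <- data$trait_name %in% POSITIVE_TRAITS
  if (any(data$value[pos] <= 0)) {
    offending <- unique(data$trait_name[pos & data$value <= 0])
    abort(
      sprintf(
        "Non-positive values for strictly positive trait(s): %s.",
        paste(offending, collapse = ", ")
      ),
      class = "traitgrad_validation_error"
    )
  }
  invisible(data)
}

#' Read a trait table from CSV
#'
#' Reads the long-format trait CSV dialect (UTF-8, comma-separated, header
#' row, decimal point) and validates it.  Non-numeric values are reported
#' with their data row numbers; a missing column or an unknown zone label is
#' a validation error.
#'
#' @param path Path to a CSV file with columns `patch_id`,
#'   `patch_size_class`, `zone`, `tree_id`, `trait_name`, `replicate_id`,
#'   `value`.
#' @return A validated trait-table tibble.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "traitgrad_io_error")
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  required <- c(
    "patch_id", "patch_size_class", "zone", "tree_id",
    "trait_name", "replicate_id", "value"
  )
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(
      sprintf("Missing required column(s): %s.", paste(missing, collapse = ", ")),
      class = "traitgrad_schema_error"
    )
  }
  value <- suppressWarnings(as.numeric(raw$value))
  bad <- which(is.na(value) & !is.na(raw$value))
  if (length(bad) > 0) {
    abort(
      sprintf(
        "Non-numeric `value` at data row(s): %s.",
        paste(utils::head(bad, 5), collapse = ", ")
      ),
      class = "traitgrad_parse_error"
    )
  }
  raw$value <- value
  validate_trait_table(raw)
  as_tibble(raw)
}

#' Write a trait table to CSV
#'
#' @param data A trait table (validated before writing).
#' @param path Output CSV path.
#' @return `data`, invisibly.
#' @export
write_trait_table <- function(data, path) {
  validate_trait_table(data)
  readr::write_csv(data, path, progress = FALSE)
  invisible(data)
}

#' Collapse replicates to tree-level means
#'
#' The sampling unit for all downstream statistics is the tree: replicate
#' leaves or readings are averaged first.  Returns a wide tibble with one
#' row per `(patch_id, zone, tree_id)` and one column per trait.  A trait a
#' tree was never measured for yields an absent (`NA`) cell, never a zero.
#'
#' @param data A long-format trait table.
#' @return A tibble with columns `patch_id`, `patch_size_class`, `zone`,
#'   `tree_id`, then one numeric column per trait.
#' @export
tree_level_means <- function(data) {
  validate_trait_table(data)
  if (nrow(data) == 0) {
    abort("Trait table is empty.", class = "traitgrad_validation_error")
  }
  data |>
    dplyr::group_by(
      .data$patch_id, .data$patch_size_class, .data$zone,
      .data$tree_id, .data$trait_name
    ) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "trait_name", values_from = "value") |>
    dplyr::arrange(.data$patch_id, .data$zone, .data$tree_id)
}

#' Write a tree-by-trait matrix to CSV
#'
#' @param tree_matrix Output of [tree_level_means()].
#' @param path Output CSV path.
#' @return `tree_matrix`, invisibly.
#' @export
write_tree_matrix <- function(tree_matrix, path) {
  readr::write_csv(tree_matrix, path, progress = FALSE)
  invisible(tree_matrix)
}
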