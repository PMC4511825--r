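# broom-style tidiers for the package's result objects.

#' Tidy a bootstrap CV test
#'
#' @param x A `cv_test` object.
#' @param ... Unused.
#' @return A one-row tibble with the CVs, T_D, V_D, Z_D and p-value.
#' @method tidy cv_test
#' @export
tidy.cv_test <- function(x, ...) {
  tibble(
    group_a = x$group_a, group_b = x$group_b,
    cv_a = x$cv_a, cv_b = x$cv_b,
    t_d = x$t_d, v_d = x$v_d, z_d = x$z_d, p_value = x$p_value
  )
}

#' @rdname tidy.cv_test
#' @method glance cv_test
#' @export
glance.cv_test <- function(x, ...) {
  tibble(
    B = x$B, null = x$null, n_a = x$n_a, n_b = x$n_b,
    seed = x$seed %||% NA_integer_
  )
}

#' Tidy pairwise CV comparisons
#'
#' @param x A `cv_pairwise` object.
#' @param ... Unused.
#' @return The comparisons tibble (one row per pair).
#' @method tidy cv_pairwise
#' @export
tidy.cv_pairwise <- function(x, ...) {
  x$comparisons
}

#' @rdname tidy.cv_pairwise
#' @method glance cv_pairwise
#' @export
glance.cv_pairwise <- function(x, ...) {
  tibble(
    n_comparisons = nrow(x$comparisons), alpha = x$alpha,
    alpha_adjusted = x$alpha_adjusted, B = x$B,
    seed = x$seed %||% NA_integer_
  )
}

#' Tidy an integration result
#'
#' @param x An `integration_result` object.
#' @param ... Unused.
#' @return A one-row tibble with INT and its CI.
#' @method tidy integration_result
#' @export
tidy.integration_result <- function(x, ...) {
  tibble(
    zone = x$zone, int = x$int, ci_low = x$ci_low, ci_high = x$ci_high,
    n_individuals = x$n_individuals, B = x$B
  )
}

#' @rdname tidy.integration_result
#' @method glance integration_result
#' @export
glance.integration_result <- function(x, ...) {
  tibble(
    conf = x$conf, n_skipped = x$n_skipped,
    ci_contains_point = x$ci_contains_point,
    seed = x$seed %||% NA_integer_
  )
}

#' Tidy a matrix-similarity result
#'
#' @param x A `matrix_similarity` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method tidy matrix_similarity
#' @export
tidy.matrix_similarity <- function(x, ...) {
  tibble(
    zone_a = x$pair[1], zone_b = x$pair[2], index = x$index,
    p_value = x$p_value, n_permutations = x$n_permutations, exact = x$exact
  )
}

#' Tidy a trait correlation matrix
#'
#' @param x A `trait_cormat` object.
#' @param ... Unused.
#' @return A long tibble with one row per unordered trait pair.
#' @method tidy trait_cormat
#' @export
tidy.trait_cormat <- function(x, ...) {
  idx <- upper_pairs(length(x$traits))
  tibble(
    trait_a = x$traits[idx[, 1]],
    trait_b = x$traits[idx[, 2]],
    r = x$r[idx]
  )
}

#' Tidy a flow estimate
#'
#' @param x A `flow_estimate` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method tidy flow_estimate
#' @export
tidy.flow_estimate <- function(x, ...) {
  tibble(
    flow_kg_s = x$flow_kg_s, window_start_s = x$window_start_s,
    window_end_s = x$window_end_s, r_squared = x$r_squared,
    diff_cv = x$diff_cv, n_points = x$n_points, r2_ok = x$r2_ok,
    negative_flow = x$negative_flow
  )
}
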