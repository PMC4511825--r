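# ggplot2 helpers for the package's result objects.

#' Heat map of a trait correlation matrix
#'
#' @param object A [trait_cormat()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trait_cormat
#' @export
autoplot.trait_cormat <- function(object, ...) {
  df <- expand.grid(
    trait_a = factor(object$traits, levels = object$traits),
    trait_b = factor(object$traits, levels = rev(object$traits))
  )
  df$r <- as.vector(object$r[cbind(as.integer(df$trait_a),
                                   match(df$trait_b, object$traits))])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trait_a, y = .data$trait_b,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166ac",
                                  mid = "white", high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal()
}

#' Bar chart of group CVs with significance letters
#'
#' @param object A `cv_pairwise` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cv_pairwise
#' @export
autoplot.cv_pairwise <- function(object, ...) {
  cvs <- dplyr::bind_rows(
    dplyr::select(object$comparisons, group = "group_a", cv = "cv_a"),
    dplyr::select(object$comparisons, group = "group_b", cv = "cv_b")
  ) |>
    dplyr::distinct() |>
    dplyr::left_join(object$letters, by = "group")
  ggplot2::ggplot(cvs, ggplot2::aes(x = .data$group, y = .data$cv)) +
    ggplot2::geom_col(fill = "grey65") +
    ggplot2::geom_text(ggplot2::aes(label = .data$letters),
                       vjust = -0.4, size = 4) +
    ggplot2::labs(x = NULL, y = "Coefficient of variation") +
    ggplot2::theme_minimal()
}

#' Integration indices with bootstrap confidence intervals
#'
#' @param integration_table A tibble as returned by
#'   `tidy.integration_result()` rows bound together (e.g. the pipeline's
#'   `integration_table`).
#' @return A ggplot object.
#' @export
plot_integration <- function(integration_table) {
  ggplot2::ggplot(integration_table,
                  ggplot2::aes(x = .data$zone, y = .data$int)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::labs(x = NULL, y = "Integration index (INT)") +
    ggplot2::theme_minimal()
}
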