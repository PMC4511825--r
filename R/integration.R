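#' Trait correlation matrix object
#'
#' A symmetric, unit-diagonal Pearson correlation matrix over an ordered
#' trait list; the input and output currency of the phenotypic-integration
#' stage.
#'
#' @param r A k x k numeric matrix (k >= 2), symmetric with unit diagonal
#'   and entries in `[-1, 1]`.
#' @param traits Ordered trait names; defaults to `colnames(r)`.
#' @return A `trait_cormat` object (list with `traits` and `r`).
#' @export
trait_cormat <- function(r, traits = colnames(r)) {
  r <- as.matrix(r)
  k <- nrow(r)
  if (k < 2 || ncol(r) != k) abort("`r` must be a square matrix with k >= 2.")
  if (is.null(traits)) traits <- paste0("T", seq_len(k))
  if (length(traits) != k) abort("`traits` length must match dim(r).")
  if (any(!is.finite(r))) abort("`r` contains non-finite entries.")
  if (max(abs(r - t(r))) > 1e-8) abort("`r` must be symmetric.")
  if (max(abs(diag(r) - 1)) > 1e-8) abort("`r` must have a unit diagonal.")
  if (max(abs(r)) > 1 + 1e-8) abort("Correlations must lie in [-1, 1].")
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r[r > 1] <- 1
  r[r < -1] <- -1
  dimnames(r) <- list(traits, traits)
  structure(list(traits = traits, r = r), class = "trait_cormat")
}

#' @export
print.trait_cormat <- function(x, digits = 2, ...) {
  cat(sprintf("<trait_cormat> %d traits: %s\n",
              length(x$traits), paste(x$traits, collapse = ", ")))
  print(round(x$r, digits))
  invisible(x)
}

upper_pairs <- function(k) {
  idx <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]  # row-wise pair order
}

offdiag_vector <- function(R) {
  idx <- upper_pairs(length(R$traits))
  R$r[idx]
}

#' Pearson correlation matrix of tree-level trait values
#'
#' Computes pairwise Pearson correlations between traits across trees,
#' on log-transformed tree means by default (matching the scale on which
#' both the synthetic generator and the bootstrap CI operate).  Missing
#' cells are handled pairwise-complete with a minimum number of complete
#' pairs.
#'
#' @param tree_matrix Output of [tree_level_means()] (or any tibble with
#'   the trait columns).
#' @param traits Ordered character vector of trait columns (k >= 2).
#' @param zone Optional zone filter.
#' @param log_transform Correlate log-transformed values (default `TRUE`).
#' @param min_complete Minimum complete observations per trait pair.
#' @return A [trait_cormat()].
#' @export
correlation_matrix <- function(tree_matrix, traits, zone = NULL,
                               log_transform = TRUE, min_complete = 3) {
  if (!is.null(zone)) {
    tree_matrix <- tree_matrix[tree_matrix$zone == zone, ]
  }
  missing <- setdiff(traits, names(tree_matrix))
  if (length(missing) > 0) {
    abort(sprintf("Trait column(s) not found: %s.",
                  paste(missing, collapse = ", ")),
          class = "traitgrad_schema_error")
  }
  X <- as.matrix(tree_matrix[traits])
  if (log_transform) {
    if (any(X <= 0, na.rm = TRUE)) {
      abort("log_transform = TRUE requires strictly positive trait values.")
    }
    X <- log(X)
  }
  sds <- apply(X, 2, sd, na.rm = TRUE)
  if (any(is.na(sds) | sds == 0)) {
    abort(sprintf("Constant or empty trait(s): %s.",
                  paste(traits[is.na(sds) | sds == 0], collapse = ", ")),
          class = "traitgrad_degenerate_error")
  }
  complete <- crossprod(!is.na(X))
  if (any(complete[upper.tri(complete)] < min_complete)) {
    abort(sprintf("Fewer than %d complete pairs for some trait pair.",
                  min_complete),
          class = "traitgrad_degenerate_error")
  }
  r <- cor(X, use = "pairwise.complete.obs")
  trait_cormat(r, traits)
}

#' Phenotypic integration index
#'
#' INT is the variance of the eigenvalues of a trait correlation matrix,
#' with the sample (k-1) divisor.  Because the eigenvalues of a correlation
#' matrix average exactly 1, INT equals the closed form
#' \eqn{2 \sum_{i<j} r_{ij}^2 / (k-1)}; both routes are computed and must
#' agree to numerical precision.  INT is 0 for independent traits and k for
#' perfectly coupled ones.
#'
#' @param R A [trait_cormat()] (or a plain symmetric unit-diagonal matrix).
#' @return The integration index, a dimensionless value in `[0, k]`.
#' @export
integration_index <- function(R) {
  if (!inherits(R, "trait_cormat")) R <- trait_cormat(R)
  k <- length(R$traits)
  lambda <- eigen(R$r, symmetric = TRUE, only.values = TRUE)$values
  int_eig <- var(lambda)
  int_closed <- 2 * sum(R$r[upper.tri(R$r)]^2) / (k - 1)
  if (abs(int_eig - int_closed) > 1e-10) {
    abort("Eigenvalue-variance and closed-form INT disagree beyond tolerance.")
  }
  int_eig
}

#' Mean squared pairwise correlation
#'
#' The mean of the squared off-diagonal Pearson coefficients, each
#' unordered pair counted once — a simple overall coupling summary related
#' to INT by `mean_r_squared = INT * (k-1) / (2 * n_pairs)`.
#'
#' @inheritParams integration_index
#' @return A value in `[0, 1]`.
#' @export
mean_r_squared <- function(R) {
  if (!inherits(R, "trait_cormat")) R <- trait_cormat(R)
  mean(R$r[upper.tri(R$r)]^2)
}

#' Bootstrap confidence interval for the integration index
#'
#' Resamples individuals (rows) with replacement `B` times, recomputes the
#' correlation matrix of the log-transformed values and its INT on each
#' replicate, and reports percentile bounds.  Replicates in which a trait
#' becomes constant are skipped and counted; more than 10% skipped is an
#' error.
#'
#' @inheritParams correlation_matrix
#' @param B Bootstrap replications (default 10,000).
#' @param seed Optional seed, stored in the result.
#' @param conf Confidence level (default 0.95).
#' @return An `integration_result` with `int`, `ci_low`, `ci_high`, `B`,
#'   `seed`, `n_individuals`, `n_skipped` and a flag
#'   `ci_contains_point`.
#' @export
integration_ci <- function(tree_matrix, traits, zone = NULL, B = 10000,
                           seed = NULL, log_transform = TRUE, conf = 0.95) {
  if (B < 100) warn("B < 100 gives very coarse percentile bounds.")
  if (!is.null(zone)) {
    tree_matrix <- tree_matrix[tree_matrix$zone == zone, ]
  }
  point_R <- correlation_matrix(tree_matrix, traits, zone = NULL,
                                log_transform = log_transform)
  point <- integration_index(point_R)
  X <- as.matrix(tree_matrix[traits])
  if (log_transform) X <- log(X)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  n <- nrow(X)
  k <- length(traits)
  ints <- with_seed_if(seed, {
    out <- numeric(B)
    skip <- 0L
    for (b in seq_len(B)) {
      Xb <- X[sample.int(n, n, replace = TRUE), , drop = FALSE]
      s2 <- colSums(Xb^2) - n * colMeans(Xb)^2
      if (any(s2 <= 0)) {
        out[b] <- NA_real_
        skip <- skip + 1L
        next
      }
      rb <- cor(Xb)
      out[b] <- 2 * sum(rb[upper.tri(rb)]^2) / (k - 1)
    }
    attr(out, "skip") <- skip
    out
  })
  n_skipped <- attr(ints, "skip")
  if (n_skipped > 0.1 * B) {
    abort(sprintf("%d of %d bootstrap replicates degenerate (> 10%%).",
                  n_skipped, B),
          class = "traitgrad_degenerate_error")
  }
  qs <- quantile(ints, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE,
                 names = FALSE)
  contains <- qs[1] <= point && point <= qs[2]
  if (!contains) {
    warn("Percentile CI does not contain the point estimate (flagged).")
  }
  structure(
    list(
      zone = zone %||% NA_character_, traits = traits, int = point,
      ci_low = qs[1], ci_high = qs[2], conf = conf, B = as.integer(B),
      seed = seed, n_individuals = n, n_skipped = n_skipped,
      ci_contains_point = contains
    ),
    class = "integration_result"
  )
}

#' @export
print.integration_result <- function(x, ...) {
  cat(sprintf(
    "<integration_result>%s INT = %.3f, %d%% CI [%.3f, %.3f] (n = %d, B = %d)\n",
    if (is.na(x$zone)) "" else paste0(" ", x$zone, ":"),
    x$int, round(100 * x$conf), x$ci_low, x$ci_high, x$n_individuals, x$B
  ))
  invisible(x)
}

#' Similarity of two trait correlation matrices
#'
#' The similarity index is the Pearson correlation between the two
#' matrices' vectors of k(k-1)/2 off-diagonal elements.  Its permutation
#' p-value relabels the traits of the second matrix: all k! relabelings are
#' enumerated when k <= 7 (so with k = 5 the p-value is a multiple of
#' 1/120), otherwise Monte Carlo sampling is used.  The test is two-sided
#' (`|index_perm| >= |index_obs|`) and the identity permutation is included
#' in both numerator and denominator.
#'
#' @param R1,R2 [trait_cormat()] objects over the same ordered trait list.
#' @param exhaustive Force (`TRUE`) or forbid (`FALSE`) exhaustive
#'   enumeration; default enumerates when k <= 7.
#' @param n_permutations Monte Carlo permutation count when not exhaustive.
#' @param seed Optional seed for Monte Carlo sampling.
#' @param labels Optional length-2 labels for the pair (e.g. zones).
#' @return A `matrix_similarity` object with `index`, `p_value`,
#'   `n_permutations` and `exact`.
#' @export
matrix_similarity <- function(R1, R2, exhaustive = NULL,
                              n_permutations = 999, seed = NULL,
                              labels = c("A", "B")) {
  if (!inherits(R1, "trait_cormat")) R1 <- trait_cormat(R1)
  if (!inherits(R2, "trait_cormat")) R2 <- trait_cormat(R2)
  if (!identical(R1$traits, R2$traits)) {
    abort("Trait lists (and their order) must match.",
          class = "traitgrad_validation_error")
  }
  k <- length(R1$traits)
  v1 <- offdiag_vector(R1)
  v2 <- offdiag_vector(R2)
  if (sd(v1) == 0 || sd(v2) == 0) {
    abort("Off-diagonal elements have zero variance; similarity undefined.",
          class = "traitgrad_degenerate_error")
  }
  index <- cor(v1, v2)
  exhaustive <- exhaustive %||% (k <= 7)
  idx <- upper_pairs(k)
  perm_stat <- function(p) {
    Rp <- R2$r[p, p]
    cor(v1, Rp[idx])
  }
  if (exhaustive) {
    perms <- all_permutations(k)
    stats <- apply(perms, 1, perm_stat)
    p_value <- mean(abs(stats) >= abs(index) - 1e-12)
    n_perm <- nrow(perms)
  } else {
    stats <- with_seed_if(seed, {
      vapply(seq_len(n_permutations),
             function(i) perm_stat(sample.int(k)), numeric(1))
    })
    p_value <- (1 + sum(abs(stats) >= abs(index) - 1e-12)) /
      (n_permutations + 1)
    n_perm <- n_permutations
  }
  structure(
    list(
      pair = labels, index = index, p_value = p_value,
      n_permutations = n_perm, exact = exhaustive, k = k, seed = seed
    ),
    class = "matrix_similarity"
  )
}

#' @export
print.matrix_similarity <- function(x, ...) {
  cat(sprintf(
    "<matrix_similarity> %s vs %s: index = %.3f, p = %.4f (%s, %d permutations)\n",
    x$pair[1], x$pair[2], x$index, x$p_value,
    if (x$exact) "exact" else "Monte Carlo", x$n_permutations
  ))
  invisible(x)
}

#' Read or write a correlation matrix as an upper-triangle CSV
#'
#' The CSV has columns `trait_a`, `trait_b`, `r`: one row per unordered
#' trait pair in row-wise upper-triangle order, so a published correlation
#' table can be typed in verbatim and fed directly to
#' [integration_index()], [mean_r_squared()] or [matrix_similarity()].
#'
#' @param path CSV path.
#' @param R A [trait_cormat()] (for writing).
#' @return `read_correlation_csv()` returns a [trait_cormat()];
#'   `write_correlation_csv()` returns `R` invisibly.
#' @export
read_correlation_csv <- function(path) {
  df <- readr::read_csv(path, col_types = "ccd", progress = FALSE)
  need <- c("trait_a", "trait_b", "r")
  if (!all(need %in% names(df))) {
    abort("Correlation CSV needs columns trait_a, trait_b, r.",
          class = "traitgrad_schema_error")
  }
  traits <- unique(c(df$trait_a, df$trait_b))
  k <- length(traits)
  if (nrow(df) != k * (k - 1) / 2) {
    abort(sprintf("Expected %d pairs for %d traits, got %d.",
                  k * (k - 1) / 2, k, nrow(df)),
          class = "traitgrad_validation_error")
  }
  r <- diag(k)
  dimnames(r) <- list(traits, traits)
  for (row in seq_len(nrow(df))) {
    i <- match(df$trait_a[row], traits)
    j <- match(df$trait_b[row], traits)
    r[i, j] <- r[j, i] <- df$r[row]
  }
  trait_cormat(r, traits)
}

#' @rdname read_correlation_csv
#' @export
write_correlation_csv <- function(R, path) {
  stopifnot(inherits(R, "trait_cormat"))
  idx <- upper_pairs(length(R$traits))
  readr::write_csv(
    tibble(
      trait_a = R$traits[idx[, 1]],
      trait_b = R$traits[idx[, 2]],
      r = R$r[idx]
    ),
    path, progress = FALSE
  )
  invisible(R)
}
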