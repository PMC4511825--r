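# Internal helpers shared across modules.

# Zones form a closed set: fog enters at the windward edge, the core is
# buffered, the leeward edge is the dry extreme.
ZONES <- c("windward", "core", "leeward")
SIZE_CLASSES <- c("small", "large")

# Traits whose values must be strictly positive.  Water potentials are
# stored as positive magnitudes of -psi (MPa), so they belong here too.
POSITIVE_TRAITS <- c(
  "SM", "psi_PD", "psi_MD", "SD", "TD", "LMA", "VD", "VDi", "Ks"
)

MORPH_TRAITS <- c("SD", "TD", "LMA", "VD", "VDi")

hash_string <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  h
}

# Deterministic sub-stream seed from a master seed and a sequence of labels.
# Doubles are exact below 2^53, so the modular arithmetic never loses bits,
# and the result always fits in a 32-bit integer.
derive_seed <- function(seed, ...) {
  h <- as.double(seed) %% 2147483647
  for (label in c(...)) {
    h <- (h * 69069 + hash_string(as.character(label))) %% 2147483647
  }
  as.integer(h)
}

# All n! permutations of 1:n as rows; guarded to the exhaustive-test regime.
all_permutations <- function(n) {
  stopifnot(n >= 1, n <= 7)
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  row <- 1L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (j in seq_len(nrow(sub))) {
      out[row, ] <- c(i, rest[sub[j, ]])
      row <- row + 1L
    }
  }
  out
}

# Column-wise sample CVs of a matrix (n-1 divisor), used in the vectorised
# bootstrap inner loop where calling sd() per column would dominate runtime.
col_cvs <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  s2 <- (colSums(m^2) - n * mu^2) / (n - 1)
  sqrt(pmax(s2, 0)) / mu
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

check_scalar_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict && x <= min) {
    abort(sprintf("`%s` must be > %s.", name, format(min)))
  }
  if (!strict && x < min) {
    abort(sprintf("`%s` must be >= %s.", name, format(min)))
  }
  invisible(x)
}
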