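# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base `round()` rounds half to even; contribution-rate tables use the
#' conventional half-up rule, so 44.445 prints as 44.45 (on the magnitude).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Deterministic substream seed from a base seed plus stream identifiers.
# Always in [0, 2^31 - 2] so it is a valid set.seed() argument.
mix_seed <- function(seed, ...) {
  ids <- c(seed, ...)
  h <- 0
  for (k in ids) {
    h <- (h * 48271 + (k %% 2147483647) + 1) %% 2147483647
  }
  as.integer(h)
}

# All permutations of 1..n, one per row. Only for tiny n (exhaustive nulls).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, factorial(n), n)
  row <- 0L
  for (k in seq_len(n)) {
    rest_vals <- setdiff(seq_len(n), k)
    for (r in seq_len(nrow(sub))) {
      row <- row + 1L
      out[row, ] <- c(k, rest_vals[sub[r, ]])
    }
  }
  out
}

# Lower-triangle vector of a square matrix / dist, in stats::dist order.
lower_tri <- function(m) {
  if (inherits(m, "dist")) return(as.vector(m))
  as.vector(stats::as.dist(m))
}

# Unordered sample pairs as a 2-column integer index matrix.
pair_index <- function(n) {
  if (n < 2) return(matrix(integer(0), 0, 2))
  idx <- utils::combn(n, 2)
  cbind(idx[1, ], idx[2, ])
}
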