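# Internal helpers shared across modules.

#' Draw from a Dirichlet distribution
#'
#' One row per draw, built from independent gamma variates.
#'
#' @param n number of draws.
#' @param alpha concentration vector (all > 0).
#' @return an `n x length(alpha)` matrix whose rows sum to 1.
#' @keywords internal
#' @noRd
rdirichlet <- function(n, alpha) {
  stopifnot(all(alpha > 0))
  x <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  x / rowSums(x)
}

# Empirical quantile, inverse-CDF (type 1), used for all percentile bounds.
q_type1 <- function(x, probs) {
  quantile(x, probs = probs, type = 1, names = FALSE)
}

# Row-wise type-1 quantiles of a matrix; returns length(probs) x nrow(m).
row_quantiles <- function(m, probs) {
  apply(m, 1L, q_type1, probs = probs)
}

# Derive a stream of per-stage seeds from one global seed. Stage k gets
# seed (seed + k * 10007) mod 2^31-1, keeping everything in integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + as.numeric(k) * 10007) %% 2147483647)
}

# Upper-triangle (i < j) index pairs of an n x n matrix, column-major order.
upper_pairs <- function(n) {
  i <- sequence(seq_len(n - 1L))
  j <- rep(2:n, 1:(n - 1L))
  list(i = i, j = j)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
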