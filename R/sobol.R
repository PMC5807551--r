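# Sobol low-discrepancy sequence (Gray-code construction) for the first six
# dimensions, using the standard Joe & Kuo primitive polynomials and initial
# direction numbers. Six dimensions suffice for the five measured variables;
# the generator is deterministic given (n, dim, skip).

# Per dimension d >= 2: s = polynomial degree, a = encoded coefficients,
# m = initial direction integers. Dimension 1 is the van der Corput base-2
# radical inverse (all m = 1).
.sobol_dirs <- list(
  list(s = 1L, a = 0L, m = c(1L)),
  list(s = 2L, a = 1L, m = c(1L, 3L)),
  list(s = 3L, a = 1L, m = c(1L, 3L, 1L)),
  list(s = 3L, a = 2L, m = c(1L, 1L, 1L)),
  list(s = 4L, a = 1L, m = c(1L, 1L, 3L, 3L))
)

#' Sobol low-discrepancy point set on the unit hypercube
#'
#' Generates the first `n` points (after an optional `skip`) of a Sobol
#' sequence in up to 6 dimensions. The construction is the usual Gray-code
#' one; the sequence starts at the origin when `skip = 0`, matching common
#' quasi-Monte-Carlo implementations. Deterministic: the same `(n, dim,
#' skip)` always yields the same matrix.
#'
#' @param n number of points (>= 1).
#' @param dim dimension (1 to 6).
#' @param skip number of initial points to drop (default 0).
#' @return `n` x `dim` matrix with entries in `[0, 1)`.
#' @examples
#' head(sobol_points(8, 2))
#' @export
sobol_points <- function(n, dim, skip = 0L) {
  stopifnot(n >= 1, dim >= 1, dim <= length(.sobol_dirs) + 1L, skip >= 0)
  total <- n + skip
  L <- max(1L, ceiling(log2(total + 1)))
  # direction numbers V[dim, L] as integers scaled by 2^L
  V <- matrix(0L, nrow = dim, ncol = L)
  V[1, ] <- bitwShiftL(1L, L - seq_len(L))
  if (dim > 1) {
    for (j in 2:dim) {
      dd <- .sobol_dirs[[j - 1L]]
      s <- dd$s
      m <- dd$m
      a <- dd$a
      if (L <= s) {
        V[j, ] <- bitwShiftL(m[seq_len(L)], L - seq_len(L))
      } else {
        V[j, seq_len(s)] <- bitwShiftL(m, L - seq_len(s))
        for (i in (s + 1L):L) {
          v <- bitwXor(V[j, i - s], bitwShiftR(V[j, i - s], s))
          if (s > 1) {
            for (kk in 1:(s - 1L)) {
              if (bitwAnd(bitwShiftR(a, s - 1L - kk), 1L) == 1L) {
                v <- bitwXor(v, V[j, i - kk])
              }
            }
          }
          V[j, i] <- v
        }
      }
    }
  }
  X <- integer(dim)
  out <- matrix(0, nrow = n, ncol = dim)
  if (skip == 0) out[1, ] <- 0
  for (i in seq_len(total - 1L)) {
    cbit <- 1L
    val <- i - 1L
    while (bitwAnd(val, 1L) == 1L) {
      val <- bitwShiftR(val, 1L)
      cbit <- cbit + 1L
    }
    X <- bitwXor(X, V[, cbit])
    idx <- i + 1L - skip
    if (idx >= 1L && idx <= n) out[idx, ] <- X / 2^L
  }
  out
}
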