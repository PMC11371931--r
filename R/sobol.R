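# Sobol low-discrepancy sequence (Gray-code construction, Joe-Kuo direction
# numbers for up to 6 dimensions) used to seed the multistart global stage.

.sobol_dirs <- list(
  list(s = 1, a = 0, m = c(1)),          # dimension 2
  list(s = 2, a = 1, m = c(1, 3)),       # dimension 3
  list(s = 3, a = 1, m = c(1, 3, 1)),    # dimension 4
  list(s = 3, a = 2, m = c(1, 1, 1)),    # dimension 5
  list(s = 4, a = 1, m = c(1, 1, 3, 3))  # dimension 6
)

#' Sobol quasi-random points in the unit hypercube
#'
#' Deterministic low-discrepancy sequence (the origin is skipped).
#'
#' @param n Number of points.
#' @param d Dimension (1 to 6).
#' @return An `n` x `d` matrix in `[0, 1)`.
#' @export
sobol_sequence <- function(n, d) {
  stopifnot(n >= 1, d >= 1, d <= 6)
  nbits <- max(ceiling(log2(n + 1)), 1) + 1
  # direction numbers V[k, j] for bit k, dimension j (as integers scaled 2^nbits)
  V <- matrix(0, nrow = nbits, ncol = d)
  V[, 1] <- bitwShiftL(1L, nbits - seq_len(nbits))  # first dim: van der Corput
  if (d > 1) {
    for (j in 2:d) {
      dd <- .sobol_dirs[[j - 1]]
      s <- dd$s; a <- dd$a; m <- dd$m
      v <- integer(nbits)
      for (k in seq_len(min(s, nbits)))
        v[k] <- bitwShiftL(m[k], nbits - k)
      if (nbits > s) {
        for (k in (s + 1):nbits) {
          val <- bitwXor(v[k - s], bitwShiftR(v[k - s], s))
          for (q in seq_len(s - 1)) {
            if (bitwAnd(bitwShiftR(a, s - 1 - q), 1L) == 1L)
              val <- bitwXor(val, v[k - q])
          }
          v[k] <- val
        }
      }
      V[, j] <- v
    }
  }
  X <- matrix(0, nrow = n, ncol = d)
  x <- integer(d)
  for (i in seq_len(n)) {
    # Gray-code: flip direction of lowest zero bit of (i - 1)
    c_bit <- 1L
    ii <- i - 1L
    while (bitwAnd(ii, 1L) == 1L) {
      ii <- bitwShiftR(ii, 1L)
      c_bit <- c_bit + 1L
    }
    x <- bitwXor(x, V[c_bit, ])
    X[i, ] <- x / 2^nbits
  }
  X
}
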