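# Exact enumeration oracle for the one-tailed Fisher test.
#
# Enumerates EVERY table compatible with the fixed margins of
# (a, b; c, d), computes each table's hypergeometric probability with
# exact integer binomials, and sums the tail with first cell >= a.
# For total N <= 40, choose() values (<= C(40,20) ~ 1.4e11), their
# pairwise products and their sums stay below 2^53, so double-precision
# integer arithmetic here is exact.
fet_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- r1 + r2
  a_min <- max(0L, c1 - r2)
  a_max <- min(r1, c1)
  avals <- a_min:a_max
  num <- choose(r1, avals) * choose(r2, c1 - avals)
  den <- choose(N, c1)
  stopifnot(abs(sum(num) - den) < 1e-6 * den)  # Vandermonde sanity check
  sum(num[avals >= a]) / den
}

# all (a, b, c, d) tables with a given total
tables_with_total <- function(N) {
  out <- list()
  for (a in 0:N) for (b in 0:(N - a)) for (c in 0:(N - a - b)) {
    out[[length(out) + 1L]] <- c(a, b, c, N - a - b - c)
  }
  do.call(rbind, out)
}
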