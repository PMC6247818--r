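#' One-tailed Fisher exact test on a 2x2 contingency table
#'
#' The statistical core of the caller. Given the table
#'
#' \preformatted{            col 1   col 2
#'   row 1       a       b
#'   row 2       c       d }
#'
#' with all margins held fixed, the one-tailed p-value is the sum of the
#' hypergeometric probabilities of the observed table and of every table
#' obtained by moving mass from the off-diagonal into the diagonal:
#' decrementing `b` and `c` while incrementing `a` and `d`, until either
#' `b` or `c` reaches zero. This is the tail in the direction of
#' enrichment of cell `a`, and equals the classic one-sided Fisher exact
#' tail for the fixed margins.
#'
#' Each term is the central hypergeometric probability
#' \deqn{P(a) = \frac{\binom{a+b}{a}\binom{c+d}{c}}{\binom{N}{a+c}}}
#' evaluated in log space (`lchoose`) and combined with a log-sum-exp, so
#' deep tails underflow gracefully rather than truncating to zero.
#'
#' @param a,b,c,d Non-negative integer cells of the 2x2 table.
#' @param log.p Return the natural-log p-value instead of the p-value.
#' @return The one-tailed p-value in `(0, 1]` (or its natural log).
#' @examples
#' one_tailed_fet(4, 0, 16, 20)   # ~ 0.053
#' one_tailed_fet(0, 0, 20, 20)   # degenerate row: exactly 1
#' @seealso [variant_pvalue()], [somatic_pvalue()]
#' @export
one_tailed_fet <- function(a, b, c, d, log.p = FALSE) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop("all contingency-table cells must be non-negative")
  if (any(cells != round(cells))) stop("contingency-table cells must be integers")
  k <- 0:min(b, c)
  # log hypergeometric probability of each tail table (a+k, b-k, c-k, d+k)
  lp <- lchoose(a + b, a + k) + lchoose(c + d, c - k) -
    lchoose(a + b + c + d, a + c)
  m <- max(lp)
  lse <- m + log(sum(exp(lp - m)))
  lse <- min(lse, 0)  # guard against rounding above log(1)
  if (log.p) lse else exp(lse)
}

#' Variant p-value against the sequencing-error null
#'
#' Tests whether the variant-supporting reads at a site exceed what
#' sequencing error alone would produce. The null expects
#' `floor(N * err_rate)` variant reads among the `N = n_obs_ref +
#' n_obs_var` reads; the observed and expected read splits form a 2x2
#' table whose one-tailed Fisher exact tail (toward more observed variant
#' reads) is returned.
#'
#' @param n_obs_ref,n_obs_var Observed high-quality reads supporting the
#'   reference and the variant allele.
#' @param cfg A [caller_config()]; only `err_rate` is used.
#' @param log.p Return the natural-log p-value.
#' @return p-value in `(0, 1]`.
#' @examples
#' variant_pvalue(16, 4)    # ~ 0.053
#' variant_pvalue(10, 10)   # ~ 2.2e-4
#' @export
variant_pvalue <- function(n_obs_ref, n_obs_var, cfg = caller_config(),
                           log.p = FALSE) {
  n_obs <- n_obs_ref + n_obs_var
  if (n_obs < 1) stop("variant_pvalue requires at least one observed read")
  exp_var <- floor(n_obs * cfg$err_rate)
  exp_ref <- n_obs - exp_var
  # Table 3 layout: rows variant/reference, columns observed/expected
  one_tailed_fet(n_obs_var, exp_var, n_obs_ref, exp_ref, log.p = log.p)
}

#' Somatic p-value for a tumor-normal allele-count contrast
#'
#' One-tailed Fisher exact test on the table
#'
#' \preformatted{           reference  variant
#'   tumor     tum_ref    tum_var
#'   normal    nor_ref    nor_var }
#'
#' in the direction of variant-allele enrichment in the tumor (tumor
#' reference count at or below the observed value). A small p-value means
#' the tumor carries significantly more variant reads than the matched
#' normal, the signature of a somatic event or loss of heterozygosity.
#'
#' @param tum_ref,tum_var,nor_ref,nor_var Non-negative read counts.
#' @param log.p Return the natural-log p-value.
#' @return p-value in `(0, 1]`.
#' @examples
#' somatic_pvalue(10, 10, 20, 0)   # tumor-only het variant: ~ 2.2e-4
#' somatic_pvalue(10, 10, 10, 10)  # identical samples: > 0.5
#' @export
somatic_pvalue <- function(tum_ref, tum_var, nor_ref, nor_var,
                           log.p = FALSE) {
  if (tum_ref + tum_var < 1 || nor_ref + nor_var < 1)
    stop("both samples must have at least one read")
  # Swap the columns so that the shared tail routine, which decrements its
  # b/c cells, reduces the tumor-reference cell toward zero.
  one_tailed_fet(tum_var, tum_ref, nor_var, nor_ref, log.p = log.p)
}

#' Genotype quality from a p-value
#'
#' `GQ = -10 * log10(p)`, capped at `cfg$gq_cap`. Accepts the p-value on
#' the natural-log scale (`log.p = TRUE`) so that deeply significant calls
#' whose p-value underflows a double still map to the cap rather than
#' `Inf`.
#'
#' @param p p-value in `(0, 1]`, or its natural log when `log.p = TRUE`.
#' @param cfg A [caller_config()]; only `gq_cap` is used.
#' @param log.p Interpret `p` as a natural-log p-value.
#' @return Genotype quality in `[0, gq_cap]`.
#' @examples
#' genotype_quality(0.01)  # 20
#' genotype_quality(1e-6)  # 60
#' @export
genotype_quality <- function(p, cfg = caller_config(), log.p = FALSE) {
  if (log.p) {
    if (p > 0) stop("log p-value must be <= 0")
    gq <- -10 * p / log(10)
  } else {
    if (p <= 0 || p > 1) stop("p must lie in (0, 1]")
    gq <- -10 * log10(p)
  }
  min(gq, cfg$gq_cap)
}
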