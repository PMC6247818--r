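#' Tally high-quality alleles at a site
#'
#' Drops observations below the base-quality cutoff entirely, then counts
#' the survivors per allele with a strand split and mean base quality.
#' Deleted-base placeholders and reference skips count toward the
#' high-quality depth but are excluded from the allele table.
#'
#' @param obs A data frame of read observations (see [decode_bases()]).
#' @param cfg A [caller_config()].
#' @return A list with `hq_depth` and `alleles`, a data frame with columns
#'   `allele`, `count`, `fwd`, `rev`, `mean_phred` (REF included).
#' @export
tally_alleles <- function(obs, cfg = caller_config()) {
  keep <- obs[obs$phred >= cfg$qbase, , drop = FALSE]
  hq_depth <- nrow(keep)
  keep <- keep[!(keep$allele %in% NON_ALLELE_OBS), , drop = FALSE]
  if (nrow(keep) == 0L) {
    alleles <- data.frame(allele = character(), count = integer(),
                          fwd = integer(), rev = integer(),
                          mean_phred = numeric(), stringsAsFactors = FALSE)
  } else {
    sp <- split(keep, keep$allele)
    alleles <- do.call(rbind, lapply(names(sp), function(a) {
      g <- sp[[a]]
      data.frame(allele = a, count = nrow(g),
                 fwd = sum(g$strand == "fwd"),
                 rev = sum(g$strand == "rev"),
                 mean_phred = mean(g$phred), stringsAsFactors = FALSE)
    }))
    rownames(alleles) <- NULL
  }
  list(hq_depth = hq_depth, alleles = alleles)
}

#' Does a site have enough high-quality coverage to call?
#' @param tally Output of [tally_alleles()].
#' @param cfg A [caller_config()].
#' @return `TRUE` iff `hq_depth >= rd_th`.
#' @export
passes_coverage <- function(tally, cfg = caller_config()) {
  tally$hq_depth >= cfg$rd_th
}

#' Candidate variant alleles at a site
#'
#' Non-reference alleles with at least `var_th` supporting reads and a
#' variant allele frequency (count over high-quality depth) of at least
#' `vaf_th`, ordered by count descending, then mean base quality
#' descending, then allele string (a final deterministic tie-break).
#' "N" observations are never candidates.
#'
#' @inheritParams passes_coverage
#' @return A data frame of candidate rows from the tally, best first.
#' @export
candidate_alleles <- function(tally, cfg = caller_config()) {
  al <- tally$alleles
  al <- al[!(al$allele %in% c("REF", "N")), , drop = FALSE]
  if (nrow(al) > 0L && tally$hq_depth > 0L) {
    al <- al[al$count >= cfg$var_th &
               al$count / tally$hq_depth >= cfg$vaf_th, , drop = FALSE]
  } else {
    al <- al[0, , drop = FALSE]
  }
  al <- al[order(-al$count, -al$mean_phred, al$allele), , drop = FALSE]
  rownames(al) <- NULL
  al
}

#' Strand-bias filter
#'
#' A variant whose support is concentrated on one strand is treated as a
#' PCR/sequencing artifact and discarded: discard iff the forward fraction
#' is at or beyond `strand_frac` (default 0.90) on either side.
#'
#' @param fwd,rev Supporting read counts per strand (must sum to >= 1).
#' @param cfg A [caller_config()].
#' @return `TRUE` to discard the allele. Always `FALSE` when the filter is
#'   switched off.
#' @export
strand_bias_discard <- function(fwd, rev, cfg = caller_config()) {
  if (!cfg$strand_bias_on) return(FALSE)
  if (fwd + rev == 0L) stop("strand bias is undefined with no supporting reads")
  fwd / (fwd + rev) >= cfg$strand_frac ||
    rev / (fwd + rev) >= cfg$strand_frac
}

#' Zygosity from variant allele frequency
#' @param vaf Variant allele frequency in `[0, 1]`.
#' @param cfg A [caller_config()].
#' @return `"HOM"` iff `vaf > vaf_homo` (strictly), else `"HET"`.
#' @export
zygosity <- function(vaf, cfg = caller_config()) {
  stopifnot(vaf >= 0, vaf <= 1)
  if (vaf > cfg$vaf_homo) "HOM" else "HET"
}
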