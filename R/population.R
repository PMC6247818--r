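#' @title Population (multi-sample) genotyping
#' @description Runs the germline filter chain per sample, reports up to
#'   two alternate alleles per site ranked by total supporting reads, and
#'   assigns VCF-style genotype codes (0/0, 0/1, 1/1, 0/2, 2/2) plus a
#'   cohort minor allele frequency.
#' @name population
NULL

#' Genotype one multi-sample pileup site
#'
#' @param site A `pileup_site` with `N >= 1` samples.
#' @param cfg A [caller_config()].
#' @return `NULL` when no sample carries a variant; else a list with
#'   `chrom`, `pos`, `ref`, `alt` (VCF alleles, length 1 or 2),
#'   `alleles` (pileup notation), `codes` (per-sample genotype strings),
#'   `gq`, `depth` and `maf` (percentage or `NA`).
#' @export
call_population_site <- function(site, cfg = caller_config()) {
  gts <- lapply(site$samples, function(obs)
    genotype_sample(tally_alleles(obs, cfg), cfg))
  carriers <- !vapply(gts, function(g) g$genotype == "HOMREF", TRUE)
  if (!any(carriers)) return(NULL)

  support <- tapply(
    vapply(gts[carriers], `[[`, 0L, "alt_count"),
    vapply(gts[carriers], `[[`, "", "allele"), sum)
  alleles <- names(support)[order(-support, names(support))]
  alleles <- alleles[seq_len(min(2L, length(alleles)))]

  codes <- vapply(gts, function(g) {
    if (g$genotype == "HOMREF") return("0/0")
    k <- match(g$allele, alleles)
    if (is.na(k)) return("0/0")  # carries only a dropped third allele
    if (g$genotype == "HOM") paste0(k, "/", k) else paste0("0/", k)
  }, "")

  rep <- vcf_repr(site$ref, alleles)
  best_lp <- min(vapply(gts[carriers], `[[`, 0, "log_p"))
  out <- list(chrom = site$chrom, pos = site$pos, ref = rep$ref,
              alt = rep$alt, alleles = alleles, codes = codes,
              gq = genotype_quality(best_lp, cfg, log.p = TRUE),
              depth = sum(vapply(site$samples, function(obs)
                sum(obs$phred >= cfg$qbase), 0L)))
  out$maf <- compute_maf(out)
  out
}

#' Cohort minor allele frequency from genotype codes
#'
#' Each sample contributes two allele copies (`0/0` two reference, `0/k`
#' one reference and one alt-k, `k/k` two alt-k). The MAF is 100 times
#' the frequency of the second most common allele; when the cohort is
#' monomorphic there is no minor allele and `NA` is returned. An exact
#' 50/50 tie between reference and an alternate is resolved by reporting
#' the alternate as the minor allele.
#'
#' @param pop_call Output of [call_population_site()] (or any list with a
#'   `codes` character vector).
#' @return MAF as a percentage in `[0, 50]`, or `NA`.
#' @export
compute_maf <- function(pop_call) {
  codes <- unlist(strsplit(pop_call$codes, "/", fixed = TRUE))
  counts <- table(codes)
  if (length(counts) < 2L) return(NA_real_)
  # order by count descending; on ties the reference ("0") ranks first,
  # so a tied alternate is the reported minor allele
  o <- order(-counts, names(counts) != "0")
  100 * as.numeric(counts[o[2]]) / sum(counts)
}

#' Rare/common classification of a minor allele frequency
#'
#' @param maf MAF as a fraction in `[0, 0.5]`, or `NA`.
#' @return `"rare"` (maf < 0.01), `"common"` (maf >= 0.01), or `NA`.
#' @export
classify_maf <- function(maf) {
  if (is.na(maf)) return(NA_character_)
  if (maf < 0.01) "rare" else "common"
}

#' Genotype a cohort over a multi-sample mpileup stream
#'
#' @param x Path to an N-sample mpileup file, or a list of `pileup_site`
#'   objects.
#' @param n_samples Number of samples per line (required with a path).
#' @param cfg A [caller_config()].
#' @return A data frame (class `fetvar_popcalls`): one row per variant
#'   site, with `alt` comma-joined, per-sample genotype columns
#'   `gt_1..gt_N`, and `maf` as a percentage.
#' @export
call_population <- function(x, n_samples = NULL, cfg = caller_config()) {
  sites <- if (is.character(x)) {
    stopifnot(!is.null(n_samples))
    read_mpileup(x, n_samples)
  } else x
  rows <- lapply(sites, call_population_site, cfg = cfg)
  rows <- rows[!vapply(rows, is.null, TRUE)]
  n <- if (length(rows)) length(rows[[1]]$codes) else (n_samples %||% 0L)
  gt_cols <- stats::setNames(
    lapply(seq_len(n), function(i) vapply(rows, function(r) r$codes[i], "")),
    paste0("gt_", seq_len(n)))
  df <- data.frame(
    chrom = vapply(rows, `[[`, "", "chrom"),
    pos = vapply(rows, `[[`, 0L, "pos"),
    ref = vapply(rows, `[[`, "", "ref"),
    alt = vapply(rows, function(r) paste(r$alt, collapse = ","), ""),
    gq = vapply(rows, `[[`, 0, "gq"),
    depth = vapply(rows, `[[`, 0L, "depth"),
    maf = vapply(rows, `[[`, 0, "maf"),
    stringsAsFactors = FALSE)
  for (nm in names(gt_cols)) df[[nm]] <- gt_cols[[nm]]
  class(df) <- c("fetvar_popcalls", "data.frame")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
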