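#' @title Paired tumor-normal (somatic) calling
#' @description Each sample is genotyped independently with the germline
#'   filter chain. Matching variant genotypes are pooled and reported as
#'   Germline; diverging genotypes are contrasted with the one-tailed
#'   Fisher exact test ([somatic_pvalue()]) and classified as Somatic,
#'   LOH, Unknown or Germline, with a High/Low confidence grade.
#' @name somatic
NULL

# read counts for one specific allele within a tally (0 when absent);
# ref count is everything else among the high-quality depth
allele_counts <- function(tally, allele) {
  i <- match(allele, tally$alleles$allele)
  v <- if (is.na(i)) 0L else tally$alleles$count[i]
  list(var = v, ref = tally$hq_depth - v)
}

#' Classify one paired tumor-normal site
#'
#' Decision rules, applied after genotyping tumor and normal
#' independently (`HOMREF` when any filter fails):
#' * both `HOMREF`: no call.
#' * genotypes (and allele) match: pooled variant p-value, status
#'   `Germline`.
#' * normal homozygous-variant while tumor is `HOMREF` or `HET`:
#'   `Unknown`.
#' * otherwise the somatic p-value decides: if `<= p_somatic` the status
#'   is `Somatic` (normal `HOMREF`), `LOH` (normal `HET`) or `Unknown`;
#'   if above the cutoff, the site is a pooled-count `Germline`.
#'
#' @param tumor_site,normal_site `pileup_site` objects at the same
#'   coordinate (single-sample each).
#' @param cfg A [caller_config()].
#' @return A one-row calls data frame with tumor/normal per-sample fields,
#'   or `NULL`.
#' @export
classify_paired_site <- function(tumor_site, normal_site,
                                 cfg = caller_config()) {
  if (!identical(tumor_site$chrom, normal_site$chrom) ||
      tumor_site$pos != normal_site$pos)
    stop("tumor and normal sites are not paired: coordinates differ")
  tt <- tally_alleles(tumor_site$samples[[1]], cfg)
  nt <- tally_alleles(normal_site$samples[[1]], cfg)
  gt <- genotype_sample(tt, cfg)
  gn <- genotype_sample(nt, cfg)
  if (gt$genotype == "HOMREF" && gn$genotype == "HOMREF") return(NULL)

  allele <- if (gt$genotype != "HOMREF") gt$allele else gn$allele
  tc <- allele_counts(tt, allele)
  nc <- allele_counts(nt, allele)
  tumor_vaf <- if (tt$hq_depth > 0) tc$var / tt$hq_depth else 0
  normal_vaf <- if (nt$hq_depth > 0) nc$var / nt$hq_depth else 0

  genotypes_match <- gt$genotype == gn$genotype &&
    identical(gt$allele, gn$allele)

  status <- NULL
  somatic_lp <- NA_real_
  if (!genotypes_match) {
    somatic_lp <- somatic_pvalue(tc$ref, tc$var, nc$ref, nc$var, log.p = TRUE)
    if (gn$genotype == "HOM" && gt$genotype %in% c("HOMREF", "HET")) {
      status <- "Unknown"
    } else if (exp(somatic_lp) <= cfg$p_somatic) {
      status <- switch(gn$genotype, HOMREF = "Somatic", HET = "LOH",
                       "Unknown")
    } else {
      status <- "Germline"
    }
  } else {
    status <- "Germline"
  }

  pooled_lp <- variant_pvalue(tc$ref + nc$ref, tc$var + nc$var, cfg,
                              log.p = TRUE)
  lp <- if (status == "Germline") pooled_lp else somatic_lp
  genotype <- gt$genotype
  rep <- vcf_repr(tumor_site$ref, allele)
  df <- data.frame(chrom = tumor_site$chrom, pos = tumor_site$pos,
                   ref = rep$ref, alt = rep$alt, genotype = genotype,
                   vaf = tumor_vaf, depth = tt$hq_depth + nt$hq_depth,
                   alt_count = tc$var + nc$var,
                   variant_p = exp(pooled_lp),
                   somatic_p = if (is.na(somatic_lp)) NA_real_
                               else exp(somatic_lp),
                   gq = genotype_quality(lp, cfg, log.p = TRUE),
                   status = status, confidence = NA_character_,
                   tumor_gt = gt$genotype, normal_gt = gn$genotype,
                   tumor_depth = tt$hq_depth, normal_depth = nt$hq_depth,
                   tumor_alt = tc$var, normal_alt = nc$var,
                   tumor_vaf = tumor_vaf, normal_vaf = normal_vaf,
                   stringsAsFactors = FALSE)
  df$confidence <- assign_confidence(df$status, tumor_vaf, normal_vaf,
                                     df$somatic_p, cfg)
  class(df) <- c("fetvar_calls", "data.frame")
  df
}

#' High/Low confidence grade for a paired-mode call
#'
#' @param status Call status ("Somatic", "LOH", "Germline", "Unknown").
#' @param tumor_vaf,normal_vaf Variant allele frequencies per sample.
#' @param somatic_p Somatic p-value (may be `NA` for pooled Germline).
#' @param cfg A [caller_config()]; uses `conf_vaf_tumor` (0.10),
#'   `conf_vaf_normal` (0.05) and `conf_p` (0.07).
#' @return `"High"` or `"Low"`.
#' @export
assign_confidence <- function(status, tumor_vaf, normal_vaf, somatic_p,
                              cfg = caller_config()) {
  high <- switch(status,
    Somatic = tumor_vaf >= cfg$conf_vaf_tumor &&
      normal_vaf < cfg$conf_vaf_normal &&
      !is.na(somatic_p) && somatic_p < cfg$conf_p,
    LOH = normal_vaf >= cfg$conf_vaf_tumor &&
      !is.na(somatic_p) && somatic_p < cfg$conf_p,
    Germline = tumor_vaf >= cfg$conf_vaf_tumor &&
      normal_vaf >= cfg$conf_vaf_tumor,
    FALSE)
  if (isTRUE(high)) "High" else "Low"
}

# split a two-sample site into two single-sample sites
split_paired <- function(site) {
  if (length(site$samples) != 2L)
    stop("somatic mode needs exactly two samples per site (tumor, normal)")
  t <- site; t$samples <- site$samples[1]
  n <- site; n$samples <- site$samples[2]
  list(tumor = t, normal = n)
}

#' Call somatic/LOH/germline variants from paired tumor-normal pileups
#'
#' @param x Path to a two-sample mpileup file (tumor first, normal
#'   second), or a list of two-sample `pileup_site` objects.
#' @param cfg A [caller_config()].
#' @return A calls data frame with per-sample tumor/normal columns.
#' @export
call_somatic <- function(x, cfg = caller_config()) {
  sites <- if (is.character(x)) read_mpileup(x, 2L) else x
  rows <- lapply(sites, function(s) {
    p <- split_paired(s)
    classify_paired_site(p$tumor, p$normal, cfg)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    df <- empty_calls()
    for (col in c("tumor_gt", "normal_gt")) df[[col]] <- character()
    for (col in c("tumor_depth", "normal_depth", "tumor_alt", "normal_alt"))
      df[[col]] <- integer()
    for (col in c("tumor_vaf", "normal_vaf")) df[[col]] <- numeric()
    class(df) <- c("fetvar_calls", "data.frame")
    return(df)
  }
  df <- do.call(rbind, rows)
  class(df) <- c("fetvar_calls", "data.frame")
  df
}
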