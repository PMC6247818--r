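#' Caller configuration
#'
#' Bundles every tunable threshold of the variant-calling pipeline. The
#' defaults are the tool's standard operating point for Illumina-style
#' short-read data: reads below `qbase` are invisible to all statistics,
#' a site needs `rd_th` high-quality reads to be considered, and a
#' candidate allele needs both `var_th` supporting reads and a variant
#' allele frequency (VAF) of at least `vaf_th`. Significance is assessed
#' by a one-tailed Fisher exact test against a sequencing-error-only null
#' (`err_rate`), at cutoff `p_germline` for single-sample calls and
#' `p_somatic` for the tumor-normal contrast.
#'
#' @param qbase Minimum Phred base quality for a read to count (default 15).
#' @param rd_th Minimum high-quality depth at a site (default 10).
#' @param var_th Minimum reads supporting a variant allele (default 2).
#' @param vaf_th Minimum variant allele frequency (default 0.20).
#' @param vaf_homo VAF above which (strictly) a genotype is homozygous
#'   (default 0.75).
#' @param p_germline p-value cutoff for calling a variant against the
#'   sequencing-error null (default 0.01).
#' @param p_somatic p-value cutoff for the tumor-vs-normal test (default 0.05).
#' @param strand_bias_on Apply the strand-bias filter? (default `TRUE`).
#' @param strand_frac Strand fraction at or beyond which support is
#'   considered biased (default 0.90; the complementary bound 1 - 0.90
#'   applies on the other strand).
#' @param err_rate Assumed per-base sequencing error rate used to build the
#'   null contingency table (default 0.001).
#' @param conf_vaf_tumor Tumor VAF bound for High-confidence somatic calls
#'   (default 0.10).
#' @param conf_vaf_normal Normal VAF bound for High-confidence somatic calls
#'   (default 0.05; the normal must be strictly below it).
#' @param conf_p Somatic p-value bound for High confidence (default 0.07).
#' @param gq_cap Maximum reported genotype quality (default 255).
#'
#' @return An object of class `caller_config` (a named list).
#' @examples
#' cfg <- caller_config()
#' cfg$qbase
#' caller_config(rd_th = 5)$rd_th
#' @export
caller_config <- function(qbase = 15, rd_th = 10, var_th = 2, vaf_th = 0.20,
                          vaf_homo = 0.75, p_germline = 0.01, p_somatic = 0.05,
                          strand_bias_on = TRUE, strand_frac = 0.90,
                          err_rate = 0.001, conf_vaf_tumor = 0.10,
                          conf_vaf_normal = 0.05, conf_p = 0.07,
                          gq_cap = 255) {
  cfg <- list(qbase = qbase, rd_th = rd_th, var_th = var_th, vaf_th = vaf_th,
              vaf_homo = vaf_homo, p_germline = p_germline,
              p_somatic = p_somatic, strand_bias_on = isTRUE(strand_bias_on),
              strand_frac = strand_frac, err_rate = err_rate,
              conf_vaf_tumor = conf_vaf_tumor,
              conf_vaf_normal = conf_vaf_normal, conf_p = conf_p,
              gq_cap = gq_cap)
  stopifnot(cfg$vaf_th > 0, cfg$vaf_th <= cfg$vaf_homo, cfg$vaf_homo <= 1,
            cfg$err_rate > 0, cfg$err_rate < 1,
            cfg$p_germline > 0, cfg$p_germline <= 1,
            cfg$p_somatic > 0, cfg$p_somatic <= 1,
            cfg$qbase >= 0, cfg$rd_th >= 0, cfg$var_th >= 0,
            cfg$strand_frac > 0.5, cfg$strand_frac <= 1, cfg$gq_cap > 0)
  class(cfg) <- "caller_config"
  cfg
}

#' @export
print.caller_config <- function(x, ...) {
  cat("Variant caller configuration\n")
  for (nm in names(x)) cat(sprintf("  %-16s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
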