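#' @title Germline (single-sample) variant calling
#' @description Per-site pipeline: quality tally, coverage gate, candidate
#'   allele selection, strand-bias filter, Fisher-exact significance against
#'   the sequencing-error null, then zygosity by variant allele frequency.
#' @name germline
NULL

# VCF left-anchored representation of one or more alleles at a site.
# Returns list(ref =, alt = character vector) with the anchor base shared.
vcf_repr <- function(ref_base, alleles) {
  del <- alleles[startsWith(alleles, "-")]
  dseq <- if (length(del)) substring(del[which.max(nchar(del))], 2) else ""
  ref <- paste0(ref_base, dseq)
  alt <- vapply(alleles, function(a) {
    if (startsWith(a, "+")) {
      paste0(ref_base, substring(a, 2), dseq)
    } else if (startsWith(a, "-")) {
      s <- substring(a, 2)
      if (substr(dseq, 1, nchar(s)) != s)
        stop("deletion alleles at one site must be nested for a shared REF")
      paste0(ref_base, substring(dseq, nchar(s) + 1))
    } else {
      paste0(a, dseq)
    }
  }, "", USE.NAMES = FALSE)
  list(ref = ref, alt = alt)
}

empty_calls <- function() {
  df <- data.frame(chrom = character(), pos = integer(), ref = character(),
                   alt = character(), genotype = character(), vaf = numeric(),
                   depth = integer(), alt_count = integer(),
                   variant_p = numeric(), somatic_p = numeric(),
                   gq = numeric(), status = character(),
                   confidence = character(), stringsAsFactors = FALSE)
  class(df) <- c("fetvar_calls", "data.frame")
  df
}

#' Call a variant at one single-sample pileup site
#'
#' @param site A `pileup_site` with one sample.
#' @param cfg A [caller_config()].
#' @return A one-row calls data frame, or `NULL` when no allele survives
#'   the filters or reaches significance.
#' @export
call_germline_site <- function(site, cfg = caller_config()) {
  tally <- tally_alleles(site$samples[[1]], cfg)
  g <- genotype_sample(tally, cfg)
  if (g$genotype == "HOMREF") return(NULL)
  rep <- vcf_repr(site$ref, g$allele)
  df <- data.frame(chrom = site$chrom, pos = site$pos, ref = rep$ref,
                   alt = rep$alt, genotype = g$genotype, vaf = g$vaf,
                   depth = tally$hq_depth, alt_count = g$alt_count,
                   variant_p = exp(g$log_p), somatic_p = NA_real_,
                   gq = genotype_quality(g$log_p, cfg, log.p = TRUE),
                   status = "Germline", confidence = NA_character_,
                   stringsAsFactors = FALSE)
  class(df) <- c("fetvar_calls", "data.frame")
  df
}

#' Genotype one sample's tally
#'
#' Shared by the somatic and population modes: applies the full germline
#' filter chain and returns `HOMREF` whenever any stage fails, otherwise
#' `HET`/`HOM` for the top-ranked surviving allele.
#'
#' @param tally Output of [tally_alleles()].
#' @param cfg A [caller_config()].
#' @return A list: `genotype` ("HOMREF"/"HET"/"HOM"), and for variant
#'   genotypes `allele` (pileup notation), `alt_count`, `ref_count`,
#'   `vaf`, `log_p`.
#' @export
genotype_sample <- function(tally, cfg = caller_config()) {
  homref <- list(genotype = "HOMREF", allele = NA_character_,
                 alt_count = 0L, ref_count = tally$hq_depth,
                 vaf = 0, log_p = 0)
  if (!passes_coverage(tally, cfg)) return(homref)
  cand <- candidate_alleles(tally, cfg)
  if (nrow(cand) > 0L && cfg$strand_bias_on) {
    biased <- mapply(strand_bias_discard, cand$fwd, cand$rev,
                     MoreArgs = list(cfg = cfg))
    cand <- cand[!biased, , drop = FALSE]
  }
  if (nrow(cand) == 0L) return(homref)
  top <- cand[1, ]
  ref_count <- tally$hq_depth - top$count
  log_p <- variant_pvalue(ref_count, top$count, cfg, log.p = TRUE)
  if (exp(log_p) > cfg$p_germline) return(homref)
  vaf <- top$count / tally$hq_depth
  list(genotype = zygosity(vaf, cfg), allele = top$allele,
       alt_count = top$count, ref_count = ref_count, vaf = vaf,
       log_p = log_p)
}

#' Call germline variants over an mpileup stream
#'
#' @param x Path to a single-sample mpileup file, or a list of
#'   `pileup_site` objects.
#' @param cfg A [caller_config()].
#' @return A calls data frame (class `fetvar_calls`), possibly empty.
#' @examples
#' line <- paste("chr1", 100, "A", 20,
#'               paste(rep(c(".", "T", ",", "t"), 5), collapse = ""),
#'               strrep("I", 20), sep = "\t")
#' call_germline(list(parse_mpileup_line(line)))
#' @export
call_germline <- function(x, cfg = caller_config()) {
  if (is.character(x)) {
    lines <- if (length(x) == 1L && file.exists(x))
      readLines(if (grepl("\\.gz$", x)) gzfile(x) else x)
    else x
    return(germline_from_lines(lines[nzchar(lines)], cfg))
  }
  rows <- lapply(x, call_germline_site, cfg = cfg)
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) return(empty_calls())
  df <- do.call(rbind, rows)
  class(df) <- c("fetvar_calls", "data.frame")
  df
}

# Bulk single-sample engine. A cheap vectorized screen finds the sites that
# could possibly yield a candidate allele (any candidate needs var_th
# non-reference high-quality reads making up vaf_th of the high-quality
# depth, so sites whose *total* non-reference support falls short can never
# call); only those, plus lines using the richer pileup grammar, go through
# the full per-site pipeline. Results are identical to calling
# call_germline_site on every site.
germline_from_lines <- function(lines, cfg) {
  if (length(lines) == 0L) return(empty_calls())
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 6L)
  if (length(bad))
    stop(sprintf("mpileup format error at line %d: expected 6 fields for 1 sample(s), found %d",
                 bad[1], lengths(f)[bad[1]]))
  bases <- vapply(f, `[[`, "", 5L)
  depth <- as.integer(vapply(f, `[[`, "", 4L))
  complex <- grepl("[+^$*><N-]", bases) | grepl("n", bases, fixed = TRUE)
  full <- which(complex & depth > 0L)

  simple <- which(!complex & depth > 0L)
  if (length(simple)) {
    bb <- strsplit(bases[simple], "", fixed = TRUE)
    if (any(lengths(bb) != depth[simple])) {
      i <- simple[which(lengths(bb) != depth[simple])[1]]
      stop(sprintf("mpileup consistency error at line %d: depth %d but %d decoded observations (sample 1)",
                   i, depth[i], lengths(bb)[[which(simple == i)]]))
    }
    flat_b <- unlist(bb, use.names = FALSE)
    flat_q <- unlist(lapply(vapply(f[simple], `[[`, "", 6L), utf8ToInt),
                     use.names = FALSE) - 33L
    if (length(flat_q) != length(flat_b))
      stop("base/quality length mismatch in pileup sample")
    site_id <- rep.int(seq_along(simple), lengths(bb))
    hq <- flat_q >= cfg$qbase
    nonref <- !(flat_b %in% c(".", ","))
    ns <- length(simple)
    hq_depth <- tabulate(site_id[hq], nbins = ns)
    nonref_hq <- tabulate(site_id[hq & nonref], nbins = ns)
    pass <- hq_depth >= cfg$rd_th & nonref_hq >= cfg$var_th &
      nonref_hq >= cfg$vaf_th * hq_depth
    full <- sort(c(full, simple[pass]))
  }
  rows <- lapply(full, function(i) {
    call_germline_site(parse_mpileup_line(lines[i], 1L, i), cfg)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) return(empty_calls())
  df <- do.call(rbind, rows)
  class(df) <- c("fetvar_calls", "data.frame")
  df
}

#' @export
print.fetvar_calls <- function(x, ...) {
  cat(sprintf("%d variant call(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 20))
  if (nrow(x) > 20) cat(sprintf("... and %d more\n", nrow(x) - 20))
  invisible(x)
}
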