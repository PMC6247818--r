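#' @title VCF v4.1 output
#' @name vcf_out
NULL

fmt_num <- function(x, digits = 4) {
  ifelse(is.na(x), ".",
         trimws(formatC(x, format = "g", digits = digits)))
}

gt_code <- function(genotype) {
  switch(genotype, HOM = "1/1", HET = "0/1", HOMREF = "0/0", "./.")
}

vcf_header <- function(sample_names, cfg = caller_config(),
                       info_keys = c("VPV", "SPV", "STATUS", "CONF", "MAF")) {
  info_defs <- c(
    VPV = '##INFO=<ID=VPV,Number=1,Type=Float,Description="Variant p-value vs sequencing-error null (one-tailed Fisher exact test)">',
    SPV = '##INFO=<ID=SPV,Number=1,Type=Float,Description="Somatic p-value, tumor vs normal allele counts (one-tailed Fisher exact test)">',
    STATUS = '##INFO=<ID=STATUS,Number=1,Type=String,Description="Call status: Germline, Somatic, LOH or Unknown">',
    CONF = '##INFO=<ID=CONF,Number=1,Type=String,Description="Confidence grade: High or Low">',
    MAF = '##INFO=<ID=MAF,Number=1,Type=String,Description="Cohort minor allele frequency, percent (NA if monomorphic)">')
  params <- paste(sprintf("%s=%s", names(unclass(cfg)),
                          vapply(unclass(cfg), format, "")), collapse = ",")
  c("##fileformat=VCFv4.1",
    sprintf("##source=fetvar %s",
            as.character(utils::packageVersion("fetvar"))),
    sprintf("##fetvarParams=<%s>", params),
    unname(info_defs[info_keys]),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=GQ,Number=1,Type=Float,Description="Genotype quality, -10*log10(p)">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="High-quality read depth">',
    '##FORMAT=<ID=AD,Number=1,Type=Integer,Description="Reads supporting the alternate allele">',
    '##FORMAT=<ID=FREQ,Number=1,Type=String,Description="Variant allele frequency, percent">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t"))
}

pct <- function(vaf) {
  paste0(trimws(formatC(100 * vaf, format = "g", digits = 4)), "%")
}

#' Write variant calls as VCF v4.1
#'
#' The QUAL column carries the genotype quality; per-call statistics go to
#' INFO (`VPV`, and for paired mode `SPV`, `STATUS`, `CONF`; for
#' population mode `MAF` as a percentage); per-sample fields use
#' `GT:GQ:DP:AD:FREQ` with VarScan-style percentage frequencies. All
#' emitted records are `FILTER=PASS`: filters discard sites before
#' emission rather than flagging them. Indels are left-anchored (the REF
#' and ALT alleles share the anchor base).
#'
#' @param calls A `fetvar_calls` or `fetvar_popcalls` data frame, sorted
#'   by `(chrom, pos)`.
#' @param path Output path.
#' @param sample_names Sample column names; defaults to `"SAMPLE"`,
#'   `c("TUMOR", "NORMAL")`, or `S1..SN` by mode.
#' @param mode One of "germline", "somatic", "population"; inferred from
#'   the calls class/columns when missing.
#' @param cfg The [caller_config()] recorded in the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, sample_names = NULL, mode = NULL,
                      cfg = caller_config()) {
  if (is.null(mode)) {
    mode <- if (inherits(calls, "fetvar_popcalls")) "population"
            else if ("tumor_gt" %in% names(calls)) "somatic" else "germline"
  }
  if (nrow(calls) > 1L &&
      !identical(order(calls$chrom, calls$pos), seq_len(nrow(calls))))
    stop("calls must be sorted by (chrom, pos)")

  if (mode == "population") {
    gt_cols <- grep("^gt_", names(calls), value = TRUE)
    if (is.null(sample_names)) sample_names <- paste0("S", seq_along(gt_cols))
    header <- vcf_header(sample_names, cfg)
    recs <- vapply(seq_len(nrow(calls)), function(i) {
      r <- calls[i, ]
      info <- sprintf("MAF=%s",
                      if (is.na(r$maf)) "NA"
                      else trimws(formatC(r$maf, format = "g", digits = 4)))
      paste(c(r$chrom, r$pos, ".", r$ref, r$alt, fmt_num(r$gq), "PASS",
              info, "GT", unlist(r[gt_cols])), collapse = "\t")
    }, "")
  } else if (mode == "somatic") {
    if (is.null(sample_names)) sample_names <- c("TUMOR", "NORMAL")
    header <- vcf_header(sample_names, cfg)
    recs <- vapply(seq_len(nrow(calls)), function(i) {
      r <- calls[i, ]
      info <- sprintf("VPV=%s;STATUS=%s;CONF=%s",
                      fmt_num(r$variant_p), r$status, r$confidence)
      if (!is.na(r$somatic_p))
        info <- sub("STATUS", sprintf("SPV=%s;STATUS", fmt_num(r$somatic_p)),
                    info, fixed = TRUE)
      tum <- paste(gt_code(r$tumor_gt), fmt_num(r$gq), r$tumor_depth,
                   r$tumor_alt, pct(r$tumor_vaf), sep = ":")
      nor <- paste(gt_code(r$normal_gt), ".", r$normal_depth,
                   r$normal_alt, pct(r$normal_vaf), sep = ":")
      paste(c(r$chrom, r$pos, ".", r$ref, r$alt, fmt_num(r$gq), "PASS",
              info, "GT:GQ:DP:AD:FREQ", tum, nor), collapse = "\t")
    }, "")
  } else {
    if (is.null(sample_names)) sample_names <- "SAMPLE"
    header <- vcf_header(sample_names, cfg)
    recs <- vapply(seq_len(nrow(calls)), function(i) {
      r <- calls[i, ]
      smp <- paste(gt_code(r$genotype), fmt_num(r$gq), r$depth, r$alt_count,
                   pct(r$vaf), sep = ":")
      paste(c(r$chrom, r$pos, ".", r$ref, r$alt, fmt_num(r$gq), "PASS",
              sprintf("VPV=%s", fmt_num(r$variant_p)), "GT:GQ:DP:AD:FREQ",
              smp), collapse = "\t")
    }, "")
  }
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Read a VCF file into header and record table
#'
#' A minimal reader for the files this package writes (and any VCF with
#' the eight fixed columns); used by [split_vcf()], [evaluate_calls()]
#' and the annotation module.
#'
#' @param path VCF path (optionally gzipped).
#' @return A list with `header` (character) and `records` (data frame
#'   with CHROM, POS, ID, REF, ALT, QUAL, FILTER, INFO, and any FORMAT /
#'   sample columns as raw strings).
#' @export
read_vcf <- function(path) {
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  cols <- strsplit(sub("^#", "", hdr[length(hdr)]), "\t", fixed = TRUE)[[1]]
  if (length(body) == 0L) {
    rec <- as.data.frame(stats::setNames(
      replicate(length(cols), character(0), simplify = FALSE), cols),
      check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    m <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
    rec <- as.data.frame(m, stringsAsFactors = FALSE)
    names(rec) <- cols[seq_len(ncol(rec))]
  }
  rec$POS <- as.integer(rec$POS)
  list(header = hdr, records = rec)
}

info_field <- function(info, key) {
  out <- rep(NA_character_, length(info))
  hit <- vapply(regmatches(info, regexpr(sprintf("(^|;)%s=[^;]*", key), info)),
                length, 0L) == 1L
  val <- sub(sprintf("^;?%s=", key), "",
             unlist(regmatches(info, regexpr(sprintf("(^|;)%s=[^;]*", key),
                                             info))))
  out[hit] <- val
  out
}

#' Split a paired-mode VCF by call status
#'
#' Writes four VCF files (`<prefix>.Somatic.vcf`, `.Germline.vcf`,
#' `.LOH.vcf`, `.Unknown.vcf`); every input record lands in exactly one
#' of them according to its `STATUS` INFO key, and the input header is
#' preserved in each.
#'
#' @param vcf_path Input VCF with a STATUS INFO key on every record.
#' @param out_prefix Output path prefix.
#' @return Named character vector of the four paths, invisibly.
#' @export
split_vcf <- function(vcf_path, out_prefix) {
  v <- read_vcf(vcf_path)
  statuses <- c("Somatic", "Germline", "LOH", "Unknown")
  st <- info_field(v$records$INFO, "STATUS")
  if (nrow(v$records) > 0L && anyNA(st))
    stop("split_vcf: records without a STATUS INFO key")
  body <- readLines(vcf_path)
  body <- body[!startsWith(body, "#") & nzchar(body)]
  paths <- stats::setNames(sprintf("%s.%s.vcf", out_prefix, statuses),
                           statuses)
  for (s in statuses) writeLines(c(v$header, body[which(st == s)]), paths[s])
  invisible(paths)
}
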