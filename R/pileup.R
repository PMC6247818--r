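#' @title Pileup input/output
#' @description Parsing and writing of the samtools mpileup text dialect.
#'   A parsed site is a `pileup_site`: a list with `chrom`, `pos` (1-based),
#'   `ref` (reference base) and `samples`, an ordered list holding one
#'   data frame of decoded read observations per sample. Each observation
#'   has an `allele` ("REF", an SNV base, "+SEQ" / "-SEQ" for an indel
#'   attached to the preceding read base, "*" for a deleted-base
#'   placeholder, ">"/"<" for reference skips), a `strand` ("fwd"/"rev")
#'   and a `phred` base quality (ASCII - 33).
#' @name pileup_io
NULL

# Observation alleles that occupy depth but can never be variant candidates.
NON_ALLELE_OBS <- c("*", ">", "<")

obs_frame <- function(allele = character(), strand = character(),
                      phred = integer()) {
  data.frame(allele = allele, strand = strand, phred = phred,
             stringsAsFactors = FALSE)
}

#' Decode one sample's pileup base/quality strings
#'
#' Implements the mpileup base-column grammar: "." / "," are
#' reference-matching bases on the forward / reverse strand; upper / lower
#' case ACGTN are substitutions (case encodes strand); `+n<seq>` /
#' `-n<seq>` attach an insertion / deletion to the preceding read
#' observation; `^X` marks a read start and consumes the mapping-quality
#' character `X`; `$` marks a read end; `*` is a placeholder within a
#' deletion; `>` and `<` are reference skips. Every emitted observation
#' consumes one character of `qual_string` (Phred+33).
#'
#' @param base_string The mpileup base column for one sample.
#' @param qual_string The matching base-quality column.
#' @param ref_base The reference base at the site (unused in decoding but
#'   kept for interface symmetry and validation hooks).
#' @return A data frame with columns `allele`, `strand`, `phred`, one row
#'   per read observation (equal to the depth column).
#' @examples
#' decode_bases("..", "II")
#' decode_bases(".+2AT.", "II")
#' @export
decode_bases <- function(base_string, qual_string, ref_base = "N") {
  quals <- utf8ToInt(qual_string) - 33L
  if (grepl("^[.,ACGTNacgtn*><]*$", base_string)) {
    # fast path: no read-start/end markers, no indels
    ch <- strsplit(base_string, "", fixed = TRUE)[[1]]
    if (length(ch) != length(quals))
      stop("base/quality length mismatch in pileup sample")
    allele <- ch
    allele[ch == "."] <- "REF"
    allele[ch == ","] <- "REF"
    low <- ch %in% c("a", "c", "g", "t", "n")
    allele[low] <- toupper(ch[low])
    strand <- ifelse(ch %in% c(",", "a", "c", "g", "t", "n", "<"),
                     "rev", "fwd")
    return(obs_frame(allele, strand, quals))
  }

  ch <- strsplit(base_string, "", fixed = TRUE)[[1]]
  n <- length(ch)
  allele <- character(0); strand <- character(0)
  i <- 1L
  while (i <= n) {
    x <- ch[i]
    if (x == "^") {
      if (i + 1L > n) stop("dangling '^' at end of pileup base string")
      i <- i + 2L  # consume the mapping-quality character
    } else if (x == "$") {
      i <- i + 1L
    } else if (x == "+" || x == "-") {
      # indel attached to the preceding observation
      j <- i + 1L
      while (j <= n && grepl("[0-9]", ch[j])) j <- j + 1L
      if (j == i + 1L) stop("indel marker not followed by a length")
      len <- as.integer(paste(ch[(i + 1L):(j - 1L)], collapse = ""))
      if (j + len - 1L > n) stop("indel sequence shorter than declared length")
      seq <- toupper(paste(ch[j:(j + len - 1L)], collapse = ""))
      if (length(allele) == 0L)
        stop("indel marker with no preceding read observation")
      allele[length(allele)] <- paste0(x, seq)
      i <- j + len
    } else {
      if (x %in% c(".", ",")) {
        allele <- c(allele, "REF")
        strand <- c(strand, if (x == ".") "fwd" else "rev")
      } else if (x %in% c("A", "C", "G", "T", "N")) {
        allele <- c(allele, x); strand <- c(strand, "fwd")
      } else if (x %in% c("a", "c", "g", "t", "n")) {
        allele <- c(allele, toupper(x)); strand <- c(strand, "rev")
      } else if (x == "*") {
        allele <- c(allele, "*"); strand <- c(strand, "fwd")
      } else if (x == ">") {
        allele <- c(allele, ">"); strand <- c(strand, "fwd")
      } else if (x == "<") {
        allele <- c(allele, "<"); strand <- c(strand, "rev")
      } else {
        stop(sprintf("unrecognized pileup character '%s'", x))
      }
      i <- i + 1L
    }
  }
  if (length(allele) != length(quals))
    stop("base/quality length mismatch in pileup sample")
  obs_frame(allele, strand, quals)
}

#' Parse one mpileup line into a pileup site
#'
#' For `n_samples` samples the line has `3 + 3 * n_samples` tab-separated
#' fields; sample `m`'s depth, bases and qualities occupy columns
#' `4 + 3(m-1)`, `5 + 3(m-1)` and `6 + 3(m-1)` (1-based).
#'
#' @param line One mpileup text line.
#' @param n_samples Declared number of samples on the line.
#' @param line_number Used in error messages.
#' @return A `pileup_site` list.
#' @export
parse_mpileup_line <- function(line, n_samples = 1L, line_number = NA) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) != 3L + 3L * n_samples)
    stop(sprintf(
      "mpileup format error at line %s: expected %d fields for %d sample(s), found %d",
      format(line_number), 3L + 3L * n_samples, n_samples, length(f)))
  pos <- as.integer(f[2])
  if (is.na(pos) || pos < 1) stop("mpileup position must be a positive integer")
  samples <- vector("list", n_samples)
  for (m in seq_len(n_samples)) {
    depth <- as.integer(f[4L + 3L * (m - 1L)])
    if (depth == 0L) {
      samples[[m]] <- obs_frame()
      next
    }
    obs <- decode_bases(f[5L + 3L * (m - 1L)], f[6L + 3L * (m - 1L)],
                        ref_base = f[3])
    if (nrow(obs) != depth)
      stop(sprintf(
        "mpileup consistency error at line %s: depth %d but %d decoded observations (sample %d)",
        format(line_number), depth, nrow(obs), m))
    samples[[m]] <- obs
  }
  structure(list(chrom = f[1], pos = pos, ref = toupper(f[3]),
                 samples = samples),
            class = "pileup_site")
}

#' Read an mpileup file (gzip-transparent)
#'
#' @param path Path to an mpileup text file (optionally gzipped).
#' @param n_samples Number of samples per line.
#' @return A list of `pileup_site` objects, in file order.
#' @export
read_mpileup <- function(path, n_samples = 1L) {
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(i)
    parse_mpileup_line(lines[i], n_samples, line_number = i))
}

encode_sample <- function(obs) {
  if (nrow(obs) == 0L) return(c("0", "*", "*"))
  fwd <- obs$strand == "fwd"
  base <- character(nrow(obs))
  indel <- grepl("^[+-]", obs$allele)
  base[obs$allele == "REF"] <- ifelse(fwd[obs$allele == "REF"], ".", ",")
  snv <- obs$allele %in% c("A", "C", "G", "T", "N")
  base[snv] <- ifelse(fwd[snv], obs$allele[snv], tolower(obs$allele[snv]))
  base[obs$allele == "*"] <- "*"
  base[obs$allele == ">"] <- ">"
  base[obs$allele == "<"] <- "<"
  if (any(indel)) {
    op <- substr(obs$allele[indel], 1, 1)
    seq <- substring(obs$allele[indel], 2)
    anchor <- ifelse(fwd[indel], ".", ",")
    seq_cased <- ifelse(fwd[indel], seq, tolower(seq))
    base[indel] <- paste0(anchor, op, nchar(seq), seq_cased)
  }
  c(as.character(nrow(obs)), paste(base, collapse = ""),
    intToUtf8(obs$phred + 33L))
}

#' Write pileup sites in the mpileup dialect
#'
#' Inverse of [parse_mpileup_line()] for marker-free sites: indel-bearing
#' observations are written as a reference-matching anchor base followed by
#' the `+n`/`-n` event, with case encoding strand. Sites must be sorted by
#' `(chrom, pos)`.
#'
#' @param sites A list of `pileup_site` objects.
#' @param path Output path, or `NULL` to return the lines.
#' @return The lines, invisibly when written to `path`.
#' @export
write_mpileup <- function(sites, path = NULL) {
  if (length(sites) > 1L) {
    chrom <- vapply(sites, `[[`, "", "chrom")
    pos <- vapply(sites, `[[`, 0L, "pos")
    o <- order(chrom, pos)
    if (!identical(o, seq_along(sites)))
      stop("sites must be sorted by (chrom, pos)")
  }
  lines <- vapply(sites, function(s) {
    paste(c(s$chrom, s$pos, s$ref,
            unlist(lapply(s$samples, encode_sample))), collapse = "\t")
  }, "")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
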