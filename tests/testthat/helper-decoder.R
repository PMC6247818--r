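# Independent mpileup base-string decoder, written against the format
# grammar with regex tokenization (distinct from the package's
# character-walk implementation). Returns the same allele/strand/phred
# frame for cross-checking.
oracle_decode <- function(base_string, qual_string) {
  quals <- utf8ToInt(qual_string) - 33L
  s <- base_string
  allele <- character(0); strand <- character(0)
  while (nchar(s) > 0L) {
    if (grepl("^\\^", s)) {
      s <- substring(s, 3)
    } else if (grepl("^\\$", s)) {
      s <- substring(s, 2)
    } else if (grepl("^[+-][0-9]+", s)) {
      m <- regmatches(s, regexpr("^[+-][0-9]+", s))
      len <- as.integer(substring(m, 2))
      seq <- substring(s, nchar(m) + 1L, nchar(m) + len)
      allele[length(allele)] <- paste0(substring(m, 1, 1), toupper(seq))
      s <- substring(s, nchar(m) + len + 1L)
    } else {
      ch <- substring(s, 1, 1)
      al <- switch(ch, "." = "REF", "," = "REF", "*" = "*",
                   ">" = ">", "<" = "<", toupper(ch))
      st <- if (ch %in% c(",", "a", "c", "g", "t", "n", "<")) "rev" else "fwd"
      allele <- c(allele, al); strand <- c(strand, st)
      s <- substring(s, 2)
    }
  }
  data.frame(allele = allele, strand = strand, phred = quals,
             stringsAsFactors = FALSE)
}

# random marker-free pileup site generator for round-trip properties
random_site <- function(chrom = "chr1", pos = 1L, n_samples = 1L,
                        max_depth = 12L) {
  ref <- sample(c("A", "C", "G", "T"), 1)
  samples <- lapply(seq_len(n_samples), function(i) {
    n <- sample(0:max_depth, 1)
    if (n == 0L) {
      return(data.frame(allele = character(), strand = character(),
                        phred = integer(), stringsAsFactors = FALSE))
    }
    pool <- c("REF", "REF", "REF", setdiff(c("A", "C", "G", "T"), ref),
              "*", paste0("+", paste(sample(c("A", "C", "G", "T"), 2,
                                            replace = TRUE), collapse = "")),
              "-AC")
    d <- data.frame(allele = sample(pool, n, replace = TRUE),
                    strand = sample(c("fwd", "rev"), n, replace = TRUE),
                    phred = sample(0:60, n, replace = TRUE),
                    stringsAsFactors = FALSE)
    # '*' carries no case, so the text format cannot encode its strand
    d$strand[d$allele == "*"] <- "fwd"
    d
  })
  structure(list(chrom = chrom, pos = as.integer(pos), ref = ref,
                 samples = samples), class = "pileup_site")
}
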