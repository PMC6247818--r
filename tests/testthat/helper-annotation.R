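# Fixture: one contig, a + strand two-exon coding gene GP and a - strand
# single-exon coding gene GM, with hand-placed codons so every coding
# effect is known by construction.
make_fixture_reference <- function() {
  s <- rep("A", 6000)
  s[3051:3053] <- c("A", "T", "G")  # GP codon 1: M
  s[3054:3056] <- c("A", "A", "A")  # GP codon 2: K
  s[3057:3059] <- c("T", "A", "C")  # GP codon 3: Y
  s[5148:5150] <- c("C", "A", "T")  # GM codon 1 (revcomp ATG): M
  s[5145:5147] <- c("T", "T", "T")  # GM codon 2 (revcomp AAA): K
  paste(s, collapse = "")
}

write_fixture_model <- function() {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    paste(GENE_MODEL_COLS, collapse = "\t"),
    paste("GP", "chrT", "+", 3001, 3300, "3001-3100,3151-3300", 3051, 3259,
          sep = "\t"),
    paste("GM", "chrT", "-", 5001, 5200, "5001-5200", 5051, 5150,
          sep = "\t")), path)
  path
}

fixture_model <- function() read_gene_model(write_fixture_model())
fixture_ref <- function() c(chrT = make_fixture_reference())

write_fixture_tables <- function() {
  dir <- tempfile(); dir.create(dir)
  w <- function(name, header, rows) {
    writeLines(c(paste(header, collapse = "\t"), rows),
               file.path(dir, paste0(name, ".tsv")))
  }
  w("impact", TABLE_SCHEMAS$impact, c(
    paste("chrT", 3056, "A", "G", 0.9, 0.1, 0.1, 0.2, 0.1, sep = "\t"),
    paste("chrT", 3055, "A", "G", 0.7, 0.2, 0.1, 0.1, 0.1, sep = "\t")))
  w("known_variants", TABLE_SCHEMAS$known_variants,
    paste("chrT", 3056, "A", "G", "rs100", sep = "\t"))
  w("clinical", TABLE_SCHEMAS$clinical,
    paste("chrT", 3056, "A", "G", "Pathogenic", "TestPhenotype",
          "COSM1", "100100", sep = "\t"))
  w("decipher", TABLE_SCHEMAS$decipher,
    c(paste("GP", 0.9, 7, sep = "\t"), paste("GM", 0.4, 25, sep = "\t")))
  w("drugs_variant", TABLE_SCHEMAS$drugs_variant,
    paste("rs100", "drugX", "resistance", "high", sep = "\t"))
  w("drugs_gene", TABLE_SCHEMAS$drugs_gene,
    paste("GP", "drugY", "sensitivity", "low", sep = "\t"))
  dir
}
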