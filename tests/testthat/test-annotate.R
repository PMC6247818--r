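test_that("gene model TSVs are read and validated", {
  model <- fixture_model()
  expect_s3_class(model, "gene_model")
  expect_length(model, 2L)
  expect_equal(model[[1]]$name, "GP")
  expect_equal(model[[1]]$exon_starts, c(3001L, 3151L))
  expect_equal(model[[1]]$exon_ends, c(3100L, 3300L))
  expect_equal(model[[2]]$strand, "-")

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("name\tchrom", "G\tchr1"), bad)
  expect_error(read_gene_model(bad), "columns")

  overlap <- tempfile(fileext = ".tsv")
  writeLines(c(paste(GENE_MODEL_COLS, collapse = "\t"),
               paste("G", "chr1", "+", 1, 100, "1-50,40-100", NA, NA,
                     sep = "\t")), overlap)
  expect_error(read_gene_model(overlap), "overlap")

  badcds <- tempfile(fileext = ".tsv")
  writeLines(c(paste(GENE_MODEL_COLS, collapse = "\t"),
               paste("G", "chr1", "+", 1, 100, "1-40,60-100", 45, 80,
                     sep = "\t")), badcds)
  expect_error(read_gene_model(badcds), "CDS")
})

test_that("coding SNVs translate to synonymous / missense / nonsense", {
  model <- fixture_model()
  ref <- fixture_ref()
  cl <- function(pos, r, a)
    classify_locus("chrT", pos, r, a, model, ref)

  syn <- cl(3056, "A", "G")          # AAA -> AAG, both K
  expect_equal(syn$category, "synonymous")
  expect_equal(syn$gene, "GP")
  expect_equal(syn$aa_change, "K2K")

  mis <- cl(3055, "A", "G")          # AAA -> AGA, K -> R
  expect_equal(mis$category, "missense")
  expect_equal(mis$aa_change, "K2R")

  non <- cl(3059, "C", "A")          # TAC -> TAA, Y -> stop
  expect_equal(non$category, "nonsense")
  expect_equal(non$aa_change, "Y3*")

  # minus strand: genomic T>C at 5147 is coding A>G, K -> E
  mm <- cl(5147, "T", "C")
  expect_equal(mm$category, "missense")
  expect_equal(mm$gene, "GM")
  expect_equal(mm$aa_change, "K2E")

  expect_error(cl(3056, "C", "G"), "reference mismatch")
})

test_that("coding indels are frameshift unless a multiple of three", {
  model <- fixture_model()
  ref <- fixture_ref()
  fs <- classify_locus("chrT", 3060, "A", "AG", model, ref)
  expect_equal(fs$category, "frameshift")
  inf <- classify_locus("chrT", 3060, "A", "AGGG", model, ref)
  expect_equal(inf$category, "inframe_indel")
  # 2 bp deletion inside the CDS
  del <- classify_locus("chrT", 3060, "AAA", "A", model, ref)
  expect_equal(del$category, "frameshift")
})

test_that("non-coding categories follow the gene geometry", {
  model <- fixture_model()
  ref <- fixture_ref()
  cat_at <- function(pos)
    classify_locus("chrT", pos, "A", "G", model, ref)$category

  # GP intron is 3101-3150; first/last two intronic bases are splice sites
  expect_equal(cat_at(3101), "splice_site")
  expect_equal(cat_at(3102), "splice_site")
  expect_equal(cat_at(3103), "intron")
  expect_equal(cat_at(3125), "intron")
  expect_equal(cat_at(3148), "intron")
  expect_equal(cat_at(3149), "splice_site")
  expect_equal(cat_at(3150), "splice_site")

  # exonic flanks of the CDS, strand-aware
  expect_equal(cat_at(3010), "utr5")
  expect_equal(cat_at(3280), "utr3")
  expect_equal(cat_at(5180), "utr5")   # minus strand: high side is 5'
  expect_equal(cat_at(5010), "utr3")

  # promoter: 2 kb upstream of the TSS, strand-aware
  expect_equal(cat_at(3000), "promoter")
  expect_equal(cat_at(1001), "promoter")
  expect_equal(classify_locus("chrT", 3000, "A", "G", model, ref)$gene, "GP")
  expect_equal(cat_at(5250), "promoter")  # GM promoter lies above tx_end
  expect_equal(cat_at(1000), "intergenic")

  ig <- classify_locus("chrT", 4000, "A", "G", model, ref)
  expect_equal(ig$category, "intergenic")
  expect_equal(ig$preceding, "GP")
  expect_equal(ig$following, "GM")
  ig2 <- classify_locus("chrT", 100, "A", "G", model, ref)
  expect_true(is.na(ig2$preceding))
  expect_equal(ig2$following, "GP")
})

test_that("classification agrees with a brute-force interval oracle", {
  model <- fixture_model()
  ref <- fixture_ref()
  # independent oracle for the + strand gene, coding effects collapsed
  oracle <- function(pos) {
    if (pos >= 3001 && pos <= 3300) {
      exonic <- (pos >= 3001 && pos <= 3100) || (pos >= 3151 && pos <= 3300)
      if (!exonic) {
        if (pos %in% c(3101, 3102, 3149, 3150)) return("splice_site")
        return("intron")
      }
      if (pos >= 3051 && pos <= 3259 &&
          !(pos >= 3101 && pos <= 3150)) return("coding")
      if (pos < 3051) return("utr5")
      return("utr3")
    }
    if (pos >= 1001 && pos <= 3000) return("promoter")
    "intergenic"
  }
  for (pos in 2995:3310) {
    base <- substring(ref[["chrT"]], pos, pos)
    got <- classify_locus("chrT", pos, base,
                          setdiff(c("A", "C", "G", "T"), base)[1],
                          model, ref)$category
    if (got %in% c("synonymous", "missense", "nonsense")) got <- "coding"
    expect_equal(got, oracle(pos), label = sprintf("pos %d", pos))
  }
})


test_that("annotation tables load with schema and range validation", {
  dir <- write_fixture_tables()
  tabs <- load_annotation_tables(dir)
  expect_s3_class(tabs, "annotation_tables")
  expect_equal(tabs$known_variants$rsid, "rs100")

  file.remove(file.path(dir, "clinical.tsv"))
  expect_error(load_annotation_tables(dir), "missing annotation table")

  dir2 <- write_fixture_tables()
  writeLines(c(paste(TABLE_SCHEMAS$impact, collapse = "\t"),
               paste("chrT", 1, "A", "G", 1.5, 0, 0, 0, 0, sep = "\t")),
             file.path(dir2, "impact.tsv"))
  expect_error(load_annotation_tables(dir2), "\\[0, 1\\]")

  dir3 <- write_fixture_tables()
  writeLines("a\tb", file.path(dir3, "decipher.tsv"))
  expect_error(load_annotation_tables(dir3), "expected columns")
})

test_that("annotate_variants is a pure join with the documented priority rule", {
  model <- fixture_model()
  ref <- fixture_ref()
  tabs <- load_annotation_tables(write_fixture_tables())
  calls <- data.frame(chrom = "chrT", pos = c(3056L, 3055L, 3125L, 5147L),
                      ref = c("A", "A", "A", "T"),
                      alt = c("G", "G", "G", "C"),
                      stringsAsFactors = FALSE)
  ann <- annotate_variants(calls, model, tabs, ref)
  expect_s3_class(ann, "fetvar_annotated")
  expect_equal(ann$locus_category,
               c("synonymous", "missense", "intron", "missense"))

  # full three-category variant: impact 0.9 + clinical + drug -> High
  expect_equal(ann$max_impact[1], 0.9)
  expect_equal(ann$rsid[1], "rs100")
  expect_equal(ann$clin_sign[1], "Pathogenic")
  expect_match(ann$drugs[1], "drugX")
  expect_equal(ann$priority[1], "High")

  # impact only (0.7 > 0.65) -> Medium; nothing at all -> Low
  expect_equal(ann$priority[2], "Medium")
  expect_equal(ann$priority[3], "Low")

  # haploinsufficiency: DECIPHER percentage 7 in [0,10] TRUE; 25 FALSE
  expect_equal(ann$haploinsufficient, c(TRUE, TRUE, TRUE, FALSE))

  # flexible drug mode joins by gene, promoting the drug category
  flex <- annotate_variants(calls, model, tabs, ref, drug_mode = "flexible")
  expect_match(flex$drugs[2], "drugY")
  expect_match(flex$drugs[3], "drugY")
  expect_true(is.na(flex$drugs[4]))  # GM has no gene-level drug

  # determinism: identical inputs give identical outputs
  expect_identical(ann, annotate_variants(calls, model, tabs, ref))
})

test_that("prioritize is strict at 0.65 and monotone in its categories", {
  expect_equal(prioritize(0.651, TRUE, TRUE), "High")
  expect_equal(prioritize(0.65, TRUE, TRUE), "Medium")  # strictly above
  expect_equal(prioritize(NA, FALSE, FALSE), "Low")
  expect_equal(prioritize(NA, TRUE, FALSE), "Medium")
  expect_equal(prioritize(NA, FALSE, TRUE), "Medium")
  expect_equal(prioritize(0.9, FALSE, FALSE), "Medium")

  rank <- c(Low = 1, Medium = 2, High = 3)
  for (s in c(NA, 0.2, 0.9)) for (cl in c(FALSE, TRUE))
    for (dr in c(FALSE, TRUE)) {
      base <- rank[prioritize(s, cl, dr)]
      expect_gte(rank[prioritize(0.9, cl, dr)], base)
      expect_gte(rank[prioritize(s, TRUE, dr)], base)
      expect_gte(rank[prioritize(s, cl, TRUE)], base)
    }
})

test_that("find_recurrent_genes counts sample incidence, not variant counts", {
  sets <- lapply(1:24, function(i) {
    genes <- character(0)
    if (i <= 13) genes <- c(genes, "GP", "GP")  # two variants, one gene
    if (i <= 6) genes <- c(genes, "GM")
    if (length(genes) == 0) genes <- NA_character_
    data.frame(gene = genes, stringsAsFactors = FALSE)
  })
  rec <- find_recurrent_genes(sets, min_fraction = 0.15)
  expect_equal(rec$gene, c("GP", "GM"))
  expect_equal(rec$n_samples, c(13, 6))
  expect_equal(rec$fraction, c(13 / 24, 6 / 24))
  expect_true(rec$sample1[1])
  expect_false(rec$sample14[1])

  # fraction threshold drops genes below it
  rec2 <- find_recurrent_genes(sets, min_fraction = 0.5)
  expect_equal(rec2$gene, "GP")
  expect_equal(nrow(find_recurrent_genes(sets, min_fraction = 1.0)), 0L)
})
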