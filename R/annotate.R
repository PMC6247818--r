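#' @title Variant annotation and prioritization
#' @description Gene-locus classification against a local gene model,
#'   joining of local annotation tables (functional-impact scores,
#'   known-variant IDs, clinical records, haploinsufficiency, drug
#'   associations), and the three-category High/Medium/Low priority rule.
#' @name annotate
NULL

in_iv <- function(pos, starts, ends) any(starts <= pos & ends >= pos)

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Classify the gene-locus category of a variant
#'
#' SNVs inside a coding sequence are translated (strand-aware, standard
#' genetic code): synonymous, missense or nonsense (stop-gain). Coding
#' indels are frameshift when their length is not a multiple of three,
#' else inframe_indel. Intronic positions within `splice_width` bases of
#' an exon-intron junction are splice_site. Exonic non-coding positions
#' are utr5/utr3 by their side of the CDS; positions within
#' `promoter_width` bases upstream of the transcription start site
#' (strand-aware) are promoter; everything else is intron or intergenic
#' (with the nearest preceding/following genes reported).
#'
#' @param chrom,pos,ref,alt Variant in VCF left-anchored convention.
#' @param model A `gene_model`.
#' @param reference Named character vector (or single string) of contig
#'   sequences; required for coding classification.
#' @param promoter_width Promoter window upstream of the TSS (default
#'   2000 bp).
#' @param splice_width Intronic bases flagged as splice site at each
#'   junction (default 2).
#' @return A list: `category`, `gene` (or `NA`), `aa_change` (or `NA`),
#'   and for intergenic variants `preceding`/`following` gene names.
#' @export
classify_locus <- function(chrom, pos, ref, alt, model, reference = NULL,
                           promoter_width = 2000, splice_width = 2) {
  chrom_seq <- if (is.null(reference)) NULL
               else if (is.null(names(reference))) reference[[1]]
               else reference[[chrom]]
  if (!is.null(chrom_seq) && nchar(ref) >= 1) {
    have <- substring(chrom_seq, pos, pos + nchar(ref) - 1L)
    if (have != ref)
      stop(sprintf("reference mismatch at %s:%d: model has %s, variant ref %s",
                   chrom, pos, have, ref))
  }
  is_snv <- nchar(ref) == 1L && nchar(alt) == 1L
  # genomic footprint used for containment tests
  foot <- if (nchar(ref) > 1L) c(pos + 1L, pos + nchar(ref) - 1L)
          else c(pos, pos)

  genes <- Filter(function(g) g$chrom == chrom, model)
  host <- Filter(function(g) g$tx_start <= foot[1] && g$tx_end >= foot[2],
                 genes)
  if (length(host) > 0L) {
    g <- host[[1]]
    res <- classify_in_gene(g, pos, ref, alt, is_snv, foot, chrom_seq,
                            splice_width)
    return(c(res, list(preceding = NA_character_,
                       following = NA_character_)))
  }
  for (g in genes) {
    prom <- if (g$strand == "+")
      c(g$tx_start - promoter_width, g$tx_start - 1L)
    else c(g$tx_end + 1L, g$tx_end + promoter_width)
    if (prom[1] <= foot[1] && prom[2] >= foot[2])
      return(list(category = "promoter", gene = g$name,
                  aa_change = NA_character_, preceding = NA_character_,
                  following = NA_character_))
  }
  prev <- Filter(function(g) g$tx_end < pos, genes)
  nxt <- Filter(function(g) g$tx_start > pos, genes)
  list(category = "intergenic", gene = NA_character_,
       aa_change = NA_character_,
       preceding = if (length(prev))
         prev[[which.max(vapply(prev, `[[`, 0L, "tx_end"))]]$name
       else NA_character_,
       following = if (length(nxt))
         nxt[[which.min(vapply(nxt, `[[`, 0L, "tx_start"))]]$name
       else NA_character_)
}

classify_in_gene <- function(g, pos, ref, alt, is_snv, foot, chrom_seq,
                             splice_width) {
  seg <- cds_segments(g)
  in_cds <- !is.null(seg) &&
    any(seg$start <= foot[1] & seg$end >= foot[2])
  if (in_cds) {
    if (is_snv) {
      return(list(category = NA, gene = g$name,
                  aa_change = NA_character_) |>
               snv_coding_effect(g, pos, alt, chrom_seq))
    }
    len <- abs(nchar(alt) - nchar(ref))
    cat <- if (len %% 3L != 0L) "frameshift" else "inframe_indel"
    return(list(category = cat, gene = g$name, aa_change = NA_character_))
  }
  in_exon <- in_iv(foot[1], g$exon_starts, g$exon_ends) &&
    in_iv(foot[2], g$exon_starts, g$exon_ends)
  if (!in_exon) {
    # intron side: splice window = first/last splice_width intronic bases
    n_ex <- length(g$exon_starts)
    if (n_ex > 1L) {
      int_start <- g$exon_ends[-n_ex] + 1L
      int_end <- g$exon_starts[-1L] - 1L
      near <- any((foot[1] >= int_start & foot[1] <= int_start + splice_width - 1L) |
                  (foot[1] >= int_end - splice_width + 1L & foot[1] <= int_end) |
                  (foot[2] >= int_start & foot[2] <= int_start + splice_width - 1L) |
                  (foot[2] >= int_end - splice_width + 1L & foot[2] <= int_end))
      if (near)
        return(list(category = "splice_site", gene = g$name,
                    aa_change = NA_character_))
    }
    return(list(category = "intron", gene = g$name,
                aa_change = NA_character_))
  }
  if (is.na(g$cds_start))
    return(list(category = if (g$strand == "+") "utr5" else "utr3",
                gene = g$name, aa_change = NA_character_))
  upstream <- foot[2] < g$cds_start
  cat <- if ((upstream && g$strand == "+") || (!upstream && g$strand == "-"))
    "utr5" else "utr3"
  list(category = cat, gene = g$name, aa_change = NA_character_)
}

snv_coding_effect <- function(res, g, pos, alt, chrom_seq) {
  if (is.null(chrom_seq))
    stop("coding classification requires the contig sequence")
  cs <- coding_sequence(g, chrom_seq)
  ci <- match(pos, cs$gpos)  # coding position, 1-based
  codon_i <- (ci - 1L) %/% 3L
  frame <- (ci - 1L) %% 3L
  codon <- cs$seq[(codon_i * 3L + 1L):(codon_i * 3L + 3L)]
  alt_cs <- if (g$strand == "+") alt else chartr("ACGT", "TGCA", alt)
  new_codon <- codon; new_codon[frame + 1L] <- alt_cs
  aa_ref <- translate_codon(paste(codon, collapse = ""))
  aa_alt <- translate_codon(paste(new_codon, collapse = ""))
  res$category <- if (aa_ref == aa_alt) "synonymous"
                  else if (aa_alt == "*") "nonsense" else "missense"
  res$aa_change <- paste0(aa_ref, codon_i + 1L, aa_alt)
  res
}

TABLE_SCHEMAS <- list(
  impact = c("chrom", "pos", "ref", "alt", "sift", "polyphen2",
             "mutation_taster", "phylop", "lrt"),
  known_variants = c("chrom", "pos", "ref", "alt", "rsid"),
  clinical = c("chrom", "pos", "ref", "alt", "clin_sign", "phenotype",
               "cosmic_id", "omim_id"),
  decipher = c("gene", "probability", "percentage"),
  drugs_variant = c("rsid", "drug", "association_type", "confidence_level"),
  drugs_gene = c("gene", "drug", "association_type", "confidence_level"))

#' Load the local annotation tables
#'
#' Reads the six documented TSVs from a directory: `impact.tsv`
#' (per-variant SIFT / Polyphen2 / MutationTaster / PhyloP / LRT scores
#' in \[0,1\]), `known_variants.tsv` (rsIDs), `clinical.tsv` (clinical
#' significance, phenotype, COSMIC and OMIM IDs), `decipher.tsv`
#' (per-gene haploinsufficiency probability and percentage),
#' `drugs_variant.tsv` and `drugs_gene.tsv` (drug associations keyed by
#' rsID and by gene). Headers are validated against the schemas; scores
#' outside \[0,1\] are a load-time error.
#'
#' @param dir Directory containing the TSVs.
#' @return An `annotation_tables` list of data frames.
#' @export
load_annotation_tables <- function(dir) {
  tabs <- lapply(names(TABLE_SCHEMAS), function(nm) {
    path <- file.path(dir, paste0(nm, ".tsv"))
    if (!file.exists(path)) stop(sprintf("missing annotation table: %s", path))
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!identical(names(df), TABLE_SCHEMAS[[nm]]))
      stop(sprintf("%s: expected columns %s", path,
                   paste(TABLE_SCHEMAS[[nm]], collapse = ", ")))
    df
  })
  names(tabs) <- names(TABLE_SCHEMAS)
  sc <- tabs$impact[, c("sift", "polyphen2", "mutation_taster", "phylop",
                        "lrt")]
  if (nrow(sc) && any(sc < 0 | sc > 1, na.rm = TRUE))
    stop("impact.tsv: scores must lie in [0, 1]")
  structure(tabs, class = "annotation_tables")
}

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' High/Medium/Low priority from the three annotation categories
#'
#' High requires all three categories: a functional-impact score strictly
#' above 0.65 from any of the five resources, at least one clinical
#' association, and at least one drug association. Medium requires at
#' least one of the three; anything else is Low.
#'
#' @param max_score Maximum of the five impact scores (`NA` when none).
#' @param has_clinical Any clinical association present?
#' @param has_drug Any drug association present?
#' @return `"High"`, `"Medium"` or `"Low"`.
#' @export
prioritize <- function(max_score, has_clinical, has_drug) {
  score_cat <- !is.na(max_score) && max_score > 0.65
  if (score_cat && has_clinical && has_drug) return("High")
  if (score_cat || has_clinical || has_drug) return("Medium")
  "Low"
}

#' Attach annotations and a priority to called variants
#'
#' Pure join: each call is keyed by `(chrom, pos, ref, alt)` against the
#' impact, known-variant and clinical tables; the haploinsufficiency flag
#' is set when the gene's DECIPHER percentage lies in \[0, 10\]; drug
#' records join by rsID in `"stringent"` mode or by gene in `"flexible"`
#' mode. Absent keys yield empty annotation, never errors.
#'
#' @param calls A calls data frame (`chrom`, `pos`, `ref`, `alt`), e.g.
#'   from [call_germline()] or [read_vcf()].
#' @param model A `gene_model` (or `NULL` to skip locus classification).
#' @param tables An `annotation_tables` list.
#' @param reference Contig sequences for coding classification.
#' @param drug_mode `"stringent"` (rsID join) or `"flexible"` (gene join).
#' @param promoter_width,splice_width Passed to [classify_locus()].
#' @return The calls with annotation columns and `priority` appended.
#' @export
annotate_variants <- function(calls, model = NULL, tables,
                              reference = NULL,
                              drug_mode = c("stringent", "flexible"),
                              promoter_width = 2000, splice_width = 2) {
  drug_mode <- match.arg(drug_mode)
  out <- as.data.frame(calls, stringsAsFactors = FALSE)
  n <- nrow(out)
  key <- variant_key(out$chrom, out$pos, out$ref, out$alt)

  if (!is.null(model)) {
    loc <- lapply(seq_len(n), function(i)
      classify_locus(out$chrom[i], out$pos[i], out$ref[i], out$alt[i],
                     model, reference, promoter_width, splice_width))
    out$locus_category <- vapply(loc, `[[`, "", "category")
    out$gene <- vapply(loc, function(l) as.character(l$gene), "")
    out$aa_change <- vapply(loc, function(l) as.character(l$aa_change), "")
  } else {
    out$locus_category <- NA_character_
    out$gene <- NA_character_
    out$aa_change <- NA_character_
  }

  imp <- tables$impact
  m <- match(key, variant_key(imp$chrom, imp$pos, imp$ref, imp$alt))
  for (col in c("sift", "polyphen2", "mutation_taster", "phylop", "lrt"))
    out[[col]] <- imp[[col]][m]
  out$max_impact <- suppressWarnings(apply(
    out[, c("sift", "polyphen2", "mutation_taster", "phylop", "lrt"),
        drop = FALSE],
    1, function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)))

  kv <- tables$known_variants
  out$rsid <- kv$rsid[match(key, variant_key(kv$chrom, kv$pos, kv$ref,
                                             kv$alt))]
  cl <- tables$clinical
  mcl <- match(key, variant_key(cl$chrom, cl$pos, cl$ref, cl$alt))
  for (col in c("clin_sign", "phenotype", "cosmic_id", "omim_id"))
    out[[col]] <- cl[[col]][mcl]

  dec <- tables$decipher
  pctg <- dec$percentage[match(out$gene, dec$gene)]
  out$haploinsufficient <- !is.na(pctg) & pctg >= 0 & pctg <= 10

  drug_tab <- if (drug_mode == "stringent") tables$drugs_variant
              else tables$drugs_gene
  drug_key <- if (drug_mode == "stringent") out$rsid else out$gene
  out$drugs <- vapply(drug_key, function(k) {
    if (is.na(k)) return(NA_character_)
    hits <- drug_tab[drug_tab[[1]] == k, , drop = FALSE]
    if (nrow(hits) == 0L) return(NA_character_)
    paste(sprintf("%s(%s,%s)", hits$drug, hits$association_type,
                  hits$confidence_level), collapse = ";")
  }, "", USE.NAMES = FALSE)

  has_clin <- !is.na(out$clin_sign) | !is.na(out$cosmic_id) |
    !is.na(out$omim_id)
  out$priority <- vapply(seq_len(n), function(i)
    prioritize(out$max_impact[i], has_clin[i], !is.na(out$drugs[i])), "")
  class(out) <- c("fetvar_annotated", "data.frame")
  out
}

#' Genes recurrently mutated across samples
#'
#' Tabulates, per gene, which samples carry at least one variant in it
#' (the variants need not be identical across samples) and keeps genes
#' mutated in at least `min_fraction` of the samples.
#'
#' @param annotated_sets Named list of annotated call data frames (one
#'   per sample; need `gene` columns).
#' @param min_fraction Minimum fraction of samples carrying the gene.
#' @return Data frame `gene`, `n_samples`, `fraction`, plus one logical
#'   column per sample; sorted by recurrence descending then gene name.
#' @export
find_recurrent_genes <- function(annotated_sets, min_fraction = 0) {
  stopifnot(length(annotated_sets) >= 1L)
  if (is.null(names(annotated_sets)))
    names(annotated_sets) <- paste0("sample", seq_along(annotated_sets))
  per_sample <- lapply(annotated_sets, function(d)
    unique(stats::na.omit(d$gene)))
  genes <- sort(unique(unlist(per_sample)))
  inc <- vapply(per_sample, function(gs) genes %in% gs,
                logical(length(genes)))
  inc <- matrix(inc, nrow = length(genes),
                dimnames = list(genes, names(annotated_sets)))
  n_samples <- rowSums(inc)
  frac <- n_samples / length(annotated_sets)
  keep <- frac >= min_fraction
  out <- data.frame(gene = genes[keep], n_samples = n_samples[keep],
                    fraction = frac[keep], stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(inc[keep, , drop = FALSE]))
  out <- out[order(-out$fraction, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
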