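#' Generate synthetic annotation tables for a set of variants
#'
#' Writes the six documented TSV tables filled with seeded synthetic
#' records: a configurable fraction of the supplied variants receive
#' impact scores, rsIDs, clinical records and drug associations, and
#' each supplied gene gets a DECIPHER-style haploinsufficiency row.
#' These tables stand in for locally exported database snapshots; the
#' schemas (not the values) are the contract.
#'
#' @param variants Data frame with `chrom`, `pos`, `ref`, `alt` (and
#'   optionally `gene`).
#' @param genes Character vector of gene names for the per-gene tables.
#' @param dir Output directory (created if needed).
#' @param seed RNG seed.
#' @param p_impact,p_known,p_clinical,p_drug Fractions of variants given
#'   each annotation type.
#' @return `dir`, invisibly; side effect: the six TSVs are written.
#' @export
simulate_annotation_tables <- function(variants, genes, dir,
                                       seed = 1, p_impact = 0.6,
                                       p_known = 0.5, p_clinical = 0.3,
                                       p_drug = 0.3) {
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(variants)
  pick <- function(p) if (n) which(stats::runif(n) < p) else integer(0)

  i <- pick(p_impact)
  impact <- cbind(variants[i, c("chrom", "pos", "ref", "alt"), drop = FALSE],
                  sift = round(stats::runif(length(i)), 3),
                  polyphen2 = round(stats::runif(length(i)), 3),
                  mutation_taster = round(stats::runif(length(i)), 3),
                  phylop = round(stats::runif(length(i)), 3),
                  lrt = round(stats::runif(length(i)), 3))

  k <- pick(p_known)
  known <- cbind(variants[k, c("chrom", "pos", "ref", "alt"), drop = FALSE],
                 rsid = sprintf("rs%07d", sample.int(9999999, length(k))))

  cl <- pick(p_clinical)
  clinical <- cbind(variants[cl, c("chrom", "pos", "ref", "alt"),
                             drop = FALSE],
                    clin_sign = sample(c("Pathogenic", "Benign", "VUS"),
                                       length(cl), replace = TRUE),
                    phenotype = sample(paste0("phenotype", 1:5), length(cl),
                                       replace = TRUE),
                    cosmic_id = ifelse(stats::runif(length(cl)) < 0.5,
                                       sprintf("COSM%06d",
                                               sample.int(999999, length(cl))),
                                       NA),
                    omim_id = ifelse(stats::runif(length(cl)) < 0.5,
                                     sprintf("%06d",
                                             sample.int(999999, length(cl))),
                                     NA))

  decipher <- data.frame(gene = genes,
                         probability = round(stats::runif(length(genes)), 3),
                         percentage = round(stats::runif(length(genes),
                                                         0, 100), 1))

  rs <- known$rsid
  dv <- data.frame(rsid = sample(rs, size = round(length(rs) * p_drug)),
                   stringsAsFactors = FALSE)
  dv$drug <- sample(paste0("drug", 1:9), nrow(dv), replace = TRUE)
  dv$association_type <- sample(c("efficacy", "toxicity", "dosage"),
                                nrow(dv), replace = TRUE)
  dv$confidence_level <- sample(c("1A", "1B", "2A", "2B", "3"), nrow(dv),
                                replace = TRUE)

  dg <- data.frame(gene = sample(genes,
                                 size = max(0L, round(length(genes) * p_drug))),
                   stringsAsFactors = FALSE)
  dg$drug <- sample(paste0("drug", 1:9), nrow(dg), replace = TRUE)
  dg$association_type <- sample(c("efficacy", "toxicity", "dosage"),
                                nrow(dg), replace = TRUE)
  dg$confidence_level <- sample(c("1A", "1B", "2A", "2B", "3"), nrow(dg),
                                replace = TRUE)

  tabs <- list(impact = impact, known_variants = known, clinical = clinical,
               decipher = decipher, drugs_variant = dv, drugs_gene = dg)
  for (nm in names(tabs))
    utils::write.table(tabs[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
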