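#' @title Gene models
#' @description A gene model is a list of gene records (`name`, `chrom`,
#'   `strand`, `tx_start`, `tx_end`, `exon_starts`, `exon_ends`,
#'   `cds_start`, `cds_end`; all coordinates 1-based inclusive), read
#'   either from an 8-column TSV or from GFF3. Non-coding genes use
#'   `NA` CDS bounds.
#' @name genemodel
NULL

GENE_MODEL_COLS <- c("name", "chrom", "strand", "tx_start", "tx_end",
                     "exons", "cds_start", "cds_end")

validate_gene <- function(g) {
  stopifnot(g$strand %in% c("+", "-"),
            g$tx_start >= 1, g$tx_end >= g$tx_start,
            length(g$exon_starts) == length(g$exon_ends),
            all(g$exon_starts <= g$exon_ends))
  o <- order(g$exon_starts)
  g$exon_starts <- g$exon_starts[o]; g$exon_ends <- g$exon_ends[o]
  if (length(g$exon_starts) > 1L &&
      any(g$exon_starts[-1L] <= g$exon_ends[-length(g$exon_ends)]))
    stop(sprintf("gene %s: exons overlap", g$name))
  if (!is.na(g$cds_start)) {
    in_exon <- any(g$exon_starts <= g$cds_start & g$exon_ends >= g$cds_start) &&
      any(g$exon_starts <= g$cds_end & g$exon_ends >= g$cds_end)
    if (!in_exon) stop(sprintf("gene %s: CDS bounds outside exons", g$name))
  }
  g
}

#' Read a gene model from the documented 8-column TSV
#'
#' Columns (tab-separated, with header): `name`, `chrom`, `strand` (+/-),
#' `tx_start`, `tx_end`, `exons` (comma-separated `start-end` pairs),
#' `cds_start`, `cds_end` (`NA` for non-coding genes).
#'
#' @param path TSV path.
#' @return A `gene_model`: list of validated gene records.
#' @export
read_gene_model <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!identical(names(df), GENE_MODEL_COLS))
    stop(sprintf("gene model TSV must have columns: %s",
                 paste(GENE_MODEL_COLS, collapse = ", ")))
  genes <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    ex <- strsplit(strsplit(r$exons, ",", fixed = TRUE)[[1]], "-",
                   fixed = TRUE)
    validate_gene(list(
      name = r$name, chrom = r$chrom, strand = r$strand,
      tx_start = as.integer(r$tx_start), tx_end = as.integer(r$tx_end),
      exon_starts = vapply(ex, function(p) as.integer(p[1]), 0L),
      exon_ends = vapply(ex, function(p) as.integer(p[2]), 0L),
      cds_start = suppressWarnings(as.integer(r$cds_start)),
      cds_end = suppressWarnings(as.integer(r$cds_end))))
  })
  structure(genes, class = "gene_model")
}

#' Read a gene model from GFF3
#'
#' Expects `gene`, `exon` and `CDS` features whose `Parent`/`ID`
#' attributes link exons and CDS to their gene. Requires the rtracklayer
#' package.
#'
#' @param path GFF3 path.
#' @return A `gene_model`.
#' @export
read_gene_model_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GFF3 gene models requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gff3")
  md <- as.data.frame(gr)
  gene_rows <- md[md$type == "gene", , drop = FALSE]
  genes <- lapply(seq_len(nrow(gene_rows)), function(i) {
    g <- gene_rows[i, ]
    id <- g$ID
    kids <- md[!is.na(md$Parent) & vapply(md$Parent, function(p)
      id %in% unlist(p), TRUE), , drop = FALSE]
    ex <- kids[kids$type == "exon", , drop = FALSE]
    cds <- kids[kids$type == "CDS", , drop = FALSE]
    if (nrow(ex) == 0L) ex <- g
    validate_gene(list(
      name = if (!is.null(g$Name) && !is.na(g$Name)) g$Name else id,
      chrom = as.character(g$seqnames), strand = as.character(g$strand),
      tx_start = g$start, tx_end = g$end,
      exon_starts = ex$start, exon_ends = ex$end,
      cds_start = if (nrow(cds)) min(cds$start) else NA_integer_,
      cds_end = if (nrow(cds)) max(cds$end) else NA_integer_))
  })
  structure(genes, class = "gene_model")
}

# exonic [start,end] intervals clipped to the CDS bounds
cds_segments <- function(g) {
  if (is.na(g$cds_start)) return(NULL)
  s <- pmax(g$exon_starts, g$cds_start)
  e <- pmin(g$exon_ends, g$cds_end)
  keep <- s <= e
  list(start = s[keep], end = e[keep])
}

# coding sequence of a gene (5'->3') and the mapping from genomic
# position to coding position
coding_sequence <- function(g, chrom_seq) {
  seg <- cds_segments(g)
  if (is.null(seg)) return(NULL)
  gpos <- unlist(mapply(seq, seg$start, seg$end, SIMPLIFY = FALSE))
  bases <- substring(chrom_seq, gpos, gpos)
  if (g$strand == "-") {
    gpos <- rev(gpos)
    bases <- chartr("ACGT", "TGCA", rev(bases))
  }
  list(seq = bases, gpos = gpos)
}
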