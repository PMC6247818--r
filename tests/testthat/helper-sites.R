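# Build observation frames and pileup sites in code for the mode tests.
make_obs <- function(...) {
  # make_obs(REF = c(fwd, rev), T = c(fwd, rev), phred = 40)
  args <- list(...)
  phred <- args$phred %||% 40L
  args$phred <- NULL
  rows <- lapply(names(args), function(al) {
    counts <- args[[al]]
    if (length(counts) == 1L) counts <- c(counts, 0L)
    data.frame(allele = rep(al, sum(counts)),
               strand = rep(c("fwd", "rev"), counts),
               phred = phred, stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(data.frame(allele = character(), strand = character(),
                      phred = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

make_site <- function(chrom = "chr1", pos = 100L, ref = "A", ...) {
  structure(list(chrom = chrom, pos = as.integer(pos), ref = ref,
                 samples = unname(list(...))), class = "pileup_site")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# balanced-strand observation set: n_ref REF + n_var reads of `allele`
balanced_sample <- function(n_ref, n_var, allele = "T", phred = 40L) {
  args <- list(REF = c(ceiling(n_ref / 2), floor(n_ref / 2)))
  if (n_var > 0)
    args[[allele]] <- c(ceiling(n_var / 2), floor(n_var / 2))
  args$phred <- phred
  do.call(make_obs, args)
}
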