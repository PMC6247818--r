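#' @title Simulation benchmark
#' @description Plants SNVs and small indels into a reference sequence,
#'   builds a diploid genome by concatenation (mutated+mutated for
#'   homozygous events, mutated+reference for heterozygous ones),
#'   simulates uniformly placed substitution-error reads, converts them
#'   to mpileup text using their true placement (no aligner), and scores
#'   calls against the planted truth by sensitivity, precision and
#'   F-score.
#' @name simbench
NULL

#' Random reference sequence
#' @param length Sequence length in bp (default 16569).
#' @param seed RNG seed.
#' @return A single character string of uniform A/C/G/T.
#' @export
random_reference <- function(length = 16569, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

#' Plan non-overlapping variants to plant
#'
#' Positions are drawn uniformly with a minimum spacing of `spacing`
#' bases (at least a read length) between events and away from the
#' sequence ends, so that no read overlaps two events.
#'
#' @param reference Reference sequence (character string).
#' @param n_snv Number of SNVs.
#' @param indel_sizes Integer sizes; each size yields one insertion and
#'   one deletion (`NULL` for none).
#' @param zygosity "HOM" or "HET", recycled over events.
#' @param spacing Minimum distance between events (default 150).
#' @param seed RNG seed (optional; inherit the caller's RNG state when NULL).
#' @return A data frame: `pos` (anchor, 1-based), `type`
#'   (SNV/INS/DEL), `seq` (alt base, inserted, or deleted sequence),
#'   `zygosity`. Deletions remove `pos+1 .. pos+nchar(seq)`; insertions
#'   insert after `pos`.
#' @export
plan_variants <- function(reference, n_snv = 12, indel_sizes = NULL,
                          zygosity = "HOM", spacing = 150, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- nchar(reference)
  types <- c(rep("SNV", n_snv),
             rep(c("INS", "DEL"), each = length(indel_sizes)))
  sizes <- c(rep(1L, n_snv), indel_sizes, indel_sizes)
  n <- length(types)
  if (n == 0L) {
    return(data.frame(pos = integer(), type = character(),
                      seq = character(), zygosity = character(),
                      stringsAsFactors = FALSE))
  }
  lo <- spacing; hi <- L - spacing
  repeat {
    pos <- sort(sample(lo:hi, n))
    if (n == 1L || min(diff(pos)) >= spacing) break
  }
  ord <- sample(n)  # decouple event type from genomic order
  types <- types[ord]; sizes <- sizes[ord]
  zyg <- rep_len(zygosity, n)
  ref_chars <- strsplit(reference, "", fixed = TRUE)[[1]]
  seq <- character(n)
  for (i in seq_len(n)) {
    if (types[i] == "SNV") {
      seq[i] <- sample(setdiff(c("A", "C", "G", "T"), ref_chars[pos[i]]), 1)
    } else if (types[i] == "INS") {
      seq[i] <- paste(sample(c("A", "C", "G", "T"), sizes[i], replace = TRUE),
                      collapse = "")
    } else {
      seq[i] <- substr(reference, pos[i] + 1L, pos[i] + sizes[i])
    }
  }
  data.frame(pos = pos, type = types, seq = seq, zygosity = zyg,
             stringsAsFactors = FALSE)
}

# apply events to the reference; returns list(seq = character string,
# map = integer vector, hap position -> reference position, NA for
# inserted bases)
mutate_sequence <- function(reference, events) {
  chars <- strsplit(reference, "", fixed = TRUE)[[1]]
  map <- seq_along(chars)
  if (nrow(events)) {
    events <- events[order(events$pos), , drop = FALSE]
    out_chars <- list(); out_map <- list()
    cur <- 1L
    for (i in seq_len(nrow(events))) {
      e <- events[i, ]
      if (e$type == "SNV") {
        idx <- cur:e$pos
        seg <- chars[idx]; seg[length(seg)] <- e$seq
        out_chars[[length(out_chars) + 1L]] <- seg
        out_map[[length(out_map) + 1L]] <- idx
        cur <- e$pos + 1L
      } else if (e$type == "INS") {
        idx <- cur:e$pos
        out_chars[[length(out_chars) + 1L]] <-
          c(chars[idx], strsplit(e$seq, "", fixed = TRUE)[[1]])
        out_map[[length(out_map) + 1L]] <-
          c(idx, rep(NA_integer_, nchar(e$seq)))
        cur <- e$pos + 1L
      } else {
        idx <- cur:e$pos
        out_chars[[length(out_chars) + 1L]] <- chars[idx]
        out_map[[length(out_map) + 1L]] <- idx
        cur <- e$pos + nchar(e$seq) + 1L
      }
    }
    if (cur <= length(chars)) {
      out_chars[[length(out_chars) + 1L]] <- chars[cur:length(chars)]
      out_map[[length(out_map) + 1L]] <- cur:length(chars)
    }
    chars <- unlist(out_chars); map <- unlist(out_map)
  }
  list(seq = paste(chars, collapse = ""), map = map)
}

#' Build a diploid genome from a variant plan
#'
#' Haplotype 1 carries every planted event; haplotype 2 carries only the
#' homozygous ones. With an all-homozygous plan this is the
#' mutated-reference concatenated to itself; with an all-heterozygous
#' plan it is the mutated reference alongside the unmodified reference.
#'
#' @param reference Reference sequence (character string).
#' @param plan Output of [plan_variants()].
#' @return List with `hap1`, `hap2` (sequences), `map1`, `map2`
#'   (haplotype-to-reference coordinate maps) and `ref_len`.
#' @export
build_diploid <- function(reference, plan) {
  if (nrow(plan) > 1L) {
    s <- plan[order(plan$pos), , drop = FALSE]
    extent <- ifelse(s$type == "DEL", nchar(s$seq) + 1L, 1L)
    if (any(s$pos[-1L] <= s$pos[-nrow(s)] + extent[-nrow(s)]))
      stop("planted events overlap")
  }
  h1 <- mutate_sequence(reference, plan)
  hom <- plan[plan$zygosity == "HOM", , drop = FALSE]
  h2 <- mutate_sequence(reference, hom)
  list(hap1 = h1$seq, hap2 = h2$seq, map1 = h1$map, map2 = h2$map,
       ref_len = nchar(reference))
}

#' Planted truth in VCF coordinates
#' @param plan Output of [plan_variants()].
#' @param reference The reference sequence.
#' @param chrom Contig name for the truth records.
#' @return Data frame `chrom`, `pos`, `ref`, `alt`, `zygosity`
#'   (left-anchored like the caller's output).
#' @export
truth_vcf <- function(plan, reference, chrom = "ref") {
  if (nrow(plan) == 0L)
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      zygosity = character(), stringsAsFactors = FALSE))
  anchor <- substring(reference, plan$pos, plan$pos)
  ref <- ifelse(plan$type == "DEL", paste0(anchor, plan$seq),
                ifelse(plan$type == "SNV", anchor, anchor))
  alt <- ifelse(plan$type == "SNV", plan$seq,
                ifelse(plan$type == "INS", paste0(anchor, plan$seq), anchor))
  data.frame(chrom = chrom, pos = plan$pos, ref = ref, alt = alt,
             zygosity = plan$zygosity, stringsAsFactors = FALSE)
}

#' Simulate uniformly placed substitution-error reads from a diploid
#'
#' Reads are drawn uniformly from both haplotypes to the target mean
#' depth, with per-base substitution errors at `err_rate` (uniform over
#' the three alternatives) and no indel errors. Base qualities default to
#' a constant Phred 35; a mixture can be requested through `qual_levels`
#' / `qual_probs`.
#'
#' @param diploid Output of [build_diploid()].
#' @param coverage Target mean depth over the diploid (e.g. 60).
#' @param read_len Read length in bp.
#' @param err_rate Per-base substitution error probability.
#' @param seed RNG seed (optional).
#' @param qual_levels,qual_probs Phred level(s) and sampling weights for
#'   simulated base qualities.
#' @return List with `reads` (data frame `hap`, `start`, `strand`),
#'   `seq` (read sequences after errors), and the simulation parameters.
#' @export
simulate_reads <- function(diploid, coverage, read_len, err_rate = 0.001,
                           seed = NULL, qual_levels = 35, qual_probs = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(coverage > 0, read_len < nchar(diploid$hap1))
  n <- round(coverage * diploid$ref_len / read_len)
  hap <- sample(2L, n, replace = TRUE)
  lens <- c(nchar(diploid$hap1), nchar(diploid$hap2))
  start <- 1L + floor(stats::runif(n) * (lens[hap] - read_len + 1L))
  strand <- sample(c("fwd", "rev"), n, replace = TRUE)
  seqs <- ifelse(hap == 1L,
                 substring(diploid$hap1, start, start + read_len - 1L),
                 substring(diploid$hap2, start, start + read_len - 1L))
  n_err <- stats::rbinom(1L, n * read_len, err_rate)
  if (n_err > 0L) {
    flat <- sample.int(n * read_len, n_err)
    rid <- (flat - 1L) %/% read_len + 1L
    off <- (flat - 1L) %% read_len + 1L
    for (k in seq_len(n_err)) {
      old <- substr(seqs[rid[k]], off[k], off[k])
      substr(seqs[rid[k]], off[k], off[k]) <-
        sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    }
  }
  list(reads = data.frame(hap = hap, start = start, strand = strand,
                          stringsAsFactors = FALSE),
       seq = seqs, read_len = read_len, err_rate = err_rate,
       qual_levels = qual_levels, qual_probs = qual_probs)
}

#' Convert truth-placed reads to mpileup text
#'
#' Each read base is stacked at its true reference coordinate via the
#' haplotype coordinate map: planted SNVs and sequencing errors appear as
#' substituted bases, insertions as `+n<seq>` attached to the anchor
#' observation of reads that span the whole inserted segment, and
#' deletions as `-n<seq>` at the anchor plus `*` placeholders at the
#' deleted positions, with case encoding strand throughout. Zero-depth
#' positions are omitted (as samtools does).
#'
#' @param sim Output of [simulate_reads()].
#' @param diploid The [build_diploid()] object the reads came from.
#' @param reference The reference sequence.
#' @param plan The variant plan (needed to place indel markers).
#' @param chrom Contig name.
#' @return Character vector of mpileup lines.
#' @export
reads_to_mpileup <- function(sim, diploid, reference, plan = NULL,
                             chrom = "ref") {
  rl <- sim$read_len
  n <- nrow(sim$reads)
  ref_chars <- strsplit(reference, "", fixed = TRUE)[[1]]

  read_id <- rep.int(seq_len(n), rep.int(rl, n))
  happos <- rep.int(sim$reads$start, rep.int(rl, n)) +
    rep.int(0:(rl - 1L), n)
  hapv <- sim$reads$hap[read_id]
  refpos <- integer(length(happos))
  i1 <- hapv == 1L
  refpos[i1] <- diploid$map1[happos[i1]]
  refpos[!i1] <- diploid$map2[happos[!i1]]
  ch <- unlist(strsplit(sim$seq, "", fixed = TRUE), use.names = FALSE)
  strand_f <- sim$reads$strand[read_id] == "fwd"

  # indel markers (few events; per-event vectorized over reads)
  marker <- character(length(happos))  # appended after the base character
  star_pos <- integer(0); star_fwd <- logical(0)
  if (!is.null(plan) && nrow(plan)) {
    ends <- sim$reads$start + rl - 1L
    for (i in which(plan$type != "SNV")) {
      e <- plan[i, ]
      carriers <- if (e$zygosity == "HOM") c(1L, 2L) else 1L
      for (h in carriers) {
        map <- if (h == 1L) diploid$map1 else diploid$map2
        h_anchor <- match(e$pos, map)
        if (e$type == "INS") {
          span <- sim$reads$hap == h & sim$reads$start <= h_anchor &
            ends >= h_anchor + nchar(e$seq)
          idx <- which(hapv == h & happos == h_anchor & span[read_id])
          seqc <- ifelse(strand_f[idx], e$seq, tolower(e$seq))
          marker[idx] <- paste0("+", nchar(e$seq), seqc)
        } else {
          span <- sim$reads$hap == h & sim$reads$start <= h_anchor &
            ends > h_anchor
          idx <- which(hapv == h & happos == h_anchor & span[read_id])
          seqc <- ifelse(strand_f[idx], e$seq, tolower(e$seq))
          marker[idx] <- paste0("-", nchar(e$seq), seqc)
          # '*' placeholders at deleted reference positions
          dpos <- e$pos + seq_len(nchar(e$seq))
          w <- which(span)
          if (length(w)) {
            reach <- map[pmin(ends[w], length(map))]
            for (d in dpos) {
              cov <- w[reach >= d]
              star_pos <- c(star_pos, rep.int(d, length(cov)))
              star_fwd <- c(star_fwd, sim$reads$strand[cov] == "fwd")
            }
          }
        }
      }
    }
  }

  keep <- !is.na(refpos)
  refpos <- refpos[keep]; ch <- ch[keep]; fwd <- strand_f[keep]
  marker <- marker[keep]

  is_ref <- ch == ref_chars[refpos]
  enc <- character(length(ch))
  enc[is_ref & fwd] <- "."
  enc[is_ref & !fwd] <- ","
  enc[!is_ref & fwd] <- ch[!is_ref & fwd]
  enc[!is_ref & !fwd] <- tolower(ch[!is_ref & !fwd])
  enc <- paste0(enc, marker)

  if (length(star_pos)) {
    refpos <- c(refpos, star_pos)
    enc <- c(enc, rep.int("*", length(star_pos)))
    fwd <- c(fwd, star_fwd)
  }

  nq <- length(enc)
  q <- if (length(sim$qual_levels) == 1L) rep.int(sim$qual_levels, nq)
       else sample(sim$qual_levels, nq, replace = TRUE, prob = sim$qual_probs)
  qc <- strsplit(intToUtf8(q + 33L), "", fixed = TRUE)[[1]]

  o <- order(refpos)
  f <- factor(refpos[o], levels = sort(unique(refpos)))
  base_str <- vapply(split(enc[o], f), paste, "", collapse = "")
  qual_str <- vapply(split(qc[o], f), paste, "", collapse = "")
  depth <- tabulate(f)
  pos <- as.integer(levels(f))
  paste(chrom, pos, ref_chars[pos], depth, base_str, qual_str, sep = "\t")
}

#' Score calls against planted truth
#'
#' A call is a true positive when `(chrom, pos, ref, alt)` matches a
#' truth record exactly (both sides are left-anchored). Sensitivity =
#' TP/(TP+FN), precision = TP/(TP+FP) (0 when undefined), F-score is
#' their harmonic mean (0 when TP = 0). Zygosity concordance over the
#' true positives is reported separately.
#'
#' @param truth Truth data frame ([truth_vcf()]) or a VCF path.
#' @param calls A calls data frame or a VCF path.
#' @return A `fetvar_metrics` list: `tp`, `fp`, `fn`, `sensitivity`,
#'   `precision`, `f_score`, `zygosity_concordance`.
#' @export
evaluate_calls <- function(truth, calls) {
  if (is.character(truth)) {
    v <- read_vcf(truth)$records
    truth <- data.frame(chrom = v$CHROM, pos = v$POS, ref = v$REF,
                        alt = v$ALT, zygosity = NA_character_,
                        stringsAsFactors = FALSE)
  }
  if (is.character(calls)) {
    v <- read_vcf(calls)$records
    calls <- data.frame(chrom = v$CHROM, pos = v$POS, ref = v$REF,
                        alt = v$ALT, genotype = NA_character_,
                        stringsAsFactors = FALSE)
  }
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  tk <- key(truth); ck <- key(calls)
  tp <- sum(tk %in% ck)
  fp <- sum(!(ck %in% tk))
  fn <- sum(!(tk %in% ck))
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f <- if (tp == 0) 0 else 2 * sens * prec / (sens + prec)
  zc <- NA_real_
  if (tp > 0 && "zygosity" %in% names(truth) && "genotype" %in% names(calls) &&
      !all(is.na(truth$zygosity))) {
    m <- match(tk, ck)
    hit <- !is.na(m)
    zc <- mean(truth$zygosity[hit] == calls$genotype[m[hit]])
  }
  structure(list(tp = tp, fp = fp, fn = fn, sensitivity = sens,
                 precision = prec, f_score = f,
                 zygosity_concordance = zc),
            class = "fetvar_metrics")
}

#' @export
print.fetvar_metrics <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d\n", x$tp, x$fp, x$fn))
  cat(sprintf("sensitivity %.4f  precision %.4f  F-score %.4f\n",
              x$sensitivity, x$precision, x$f_score))
  if (!is.na(x$zygosity_concordance))
    cat(sprintf("zygosity concordance %.4f\n", x$zygosity_concordance))
  invisible(x)
}

#' Run one seeded simulation replicate end to end
#'
#' Plants variants, builds the diploid, simulates reads, synthesizes the
#' mpileup, runs germline calling and scores against the truth.
#'
#' @param reference Reference sequence.
#' @param seed Replicate seed (drives plan, reads and errors).
#' @param n_snv,indel_sizes,zygosity Plan parameters ([plan_variants()]).
#' @param coverage,read_len,err_rate Read simulation parameters.
#' @param cfg A [caller_config()].
#' @param qual_levels,qual_probs Base-quality model.
#' @param spacing Minimum event spacing (default `3 * read_len`).
#' @return The [evaluate_calls()] metrics, with the calls and truth
#'   attached as attributes.
#' @export
run_sim_replicate <- function(reference, seed, n_snv = 12,
                              indel_sizes = NULL, zygosity = "HOM",
                              coverage = 60, read_len = 100,
                              err_rate = 0.001, cfg = caller_config(),
                              qual_levels = 35, qual_probs = NULL,
                              spacing = NULL) {
  set.seed(seed)
  spacing <- spacing %||% (3L * read_len)
  plan <- plan_variants(reference, n_snv = n_snv,
                        indel_sizes = indel_sizes, zygosity = zygosity,
                        spacing = spacing)
  dip <- build_diploid(reference, plan)
  sim <- simulate_reads(dip, coverage, read_len, err_rate,
                        qual_levels = qual_levels, qual_probs = qual_probs)
  lines <- reads_to_mpileup(sim, dip, reference, plan)
  calls <- call_germline(lines, cfg)
  truth <- truth_vcf(plan, reference)
  m <- evaluate_calls(truth, calls)
  attr(m, "calls") <- calls
  attr(m, "truth") <- truth
  m
}

#' Average metrics over seeded replicates
#'
#' @inheritParams run_sim_replicate
#' @param n_replicates Number of replicates.
#' @param base_seed Seed for replicate `i` is `base_seed + i`.
#' @param ... Passed to [run_sim_replicate()].
#' @return A data frame of per-replicate metrics with mean columns
#'   available via `colMeans`.
#' @export
run_benchmark <- function(reference, n_replicates = 20, base_seed = 0, ...) {
  rows <- lapply(seq_len(n_replicates), function(i) {
    m <- run_sim_replicate(reference, seed = base_seed + i, ...)
    data.frame(replicate = i, tp = m$tp, fp = m$fp, fn = m$fn,
               sensitivity = m$sensitivity, precision = m$precision,
               f_score = m$f_score)
  })
  do.call(rbind, rows)
}
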