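test_that("diploid construction places events on the right haplotypes", {
  ref <- random_reference(4000, seed = 3)
  empty <- plan_variants(ref, n_snv = 0)
  dip0 <- build_diploid(ref, empty)
  expect_equal(dip0$hap1, ref)
  expect_equal(dip0$hap2, ref)
  expect_equal(dip0$map1, seq_len(4000))

  plan <- plan_variants(ref, n_snv = 12, zygosity = "HOM", spacing = 150,
                        seed = 9)
  expect_equal(nrow(plan), 12L)
  expect_true(all(diff(sort(plan$pos)) >= 150))
  dip <- build_diploid(ref, plan)
  expect_equal(dip$hap1, dip$hap2)  # all-HOM: both haplotypes mutated
  diffs <- which(strsplit(dip$hap1, "")[[1]] != strsplit(ref, "")[[1]])
  expect_equal(diffs, sort(plan$pos))

  # HET 5 bp deletion: hap1 shorter by 5, hap2 untouched
  del_plan <- data.frame(pos = 1000L, type = "DEL",
                         seq = substr(ref, 1001, 1005), zygosity = "HET",
                         stringsAsFactors = FALSE)
  dipd <- build_diploid(ref, del_plan)
  expect_equal(nchar(dipd$hap1), 4000L - 5L)
  expect_equal(dipd$hap2, ref)
  expect_equal(dipd$map1[1000:1001], c(1000L, 1006L))

  # insertions add unmapped bases
  ins_plan <- data.frame(pos = 1000L, type = "INS", seq = "GG",
                         zygosity = "HOM", stringsAsFactors = FALSE)
  dipi <- build_diploid(ref, ins_plan)
  expect_equal(nchar(dipi$hap1), 4002L)
  expect_true(all(is.na(dipi$map1[1001:1002])))

  overlap <- data.frame(pos = c(100L, 100L), type = "SNV", seq = "A",
                        zygosity = "HOM", stringsAsFactors = FALSE)
  expect_error(build_diploid(ref, overlap), "overlap")
})

test_that("truth records are VCF left-anchored", {
  ref <- paste(rep("ACGT", 100), collapse = "")
  plan <- data.frame(pos = c(10L, 50L, 90L), type = c("SNV", "INS", "DEL"),
                     seq = c("A", "TT", substr(ref, 51, 52)),
                     zygosity = "HOM", stringsAsFactors = FALSE)
  plan$seq[3] <- substr(ref, 91, 92)
  tv <- truth_vcf(plan, ref)
  expect_equal(tv$ref[1], substr(ref, 10, 10))
  expect_equal(tv$alt[1], "A")
  expect_equal(tv$ref[2], substr(ref, 50, 50))
  expect_equal(tv$alt[2], paste0(substr(ref, 50, 50), "TT"))
  expect_equal(tv$ref[3], substr(ref, 90, 92))
  expect_equal(tv$alt[3], substr(ref, 90, 90))
})

test_that("read simulation hits the target depth and error model", {
  ref <- random_reference(5000, seed = 4)
  dip <- build_diploid(ref, plan_variants(ref, n_snv = 0))
  sim <- simulate_reads(dip, coverage = 30, read_len = 100, err_rate = 0,
                        seed = 5)
  expect_equal(length(sim$seq), round(30 * 5000 / 100))
  expect_true(all(nchar(sim$seq) == 100))
  # err = 0: every read is an exact substring of its haplotype
  for (i in sample(length(sim$seq), 25)) {
    hapseq <- if (sim$reads$hap[i] == 1) dip$hap1 else dip$hap2
    expect_equal(sim$seq[i],
                 substring(hapseq, sim$reads$start[i],
                           sim$reads$start[i] + 99L))
  }

  # same seed, same reads; different seed differs
  sim2 <- simulate_reads(dip, coverage = 30, read_len = 100, err_rate = 0,
                         seed = 5)
  expect_identical(sim, sim2)
  sim3 <- simulate_reads(dip, coverage = 30, read_len = 100, err_rate = 0,
                         seed = 6)
  expect_false(identical(sim$reads$start, sim3$reads$start))

  # with errors, the number of mismatching bases is plausible for the rate
  simE <- simulate_reads(dip, coverage = 30, read_len = 100,
                         err_rate = 0.01, seed = 7)
  n_mismatch <- sum(vapply(seq_along(simE$seq), function(i) {
    hapseq <- if (simE$reads$hap[i] == 1) dip$hap1 else dip$hap2
    true <- substring(hapseq, simE$reads$start[i], simE$reads$start[i] + 99L)
    sum(strsplit(simE$seq[i], "")[[1]] != strsplit(true, "")[[1]])
  }, 0L))
  expect_gt(n_mismatch, 0.005 * 30 * 5000)
  expect_lt(n_mismatch, 0.02 * 30 * 5000)
})

test_that("truth-placed mpileup synthesis encodes variants correctly", {
  ref <- paste(rep("A", 200), collapse = "")
  dip <- build_diploid(ref, plan_variants(ref, n_snv = 0))
  # one forward read of length 5 at position 11
  sim <- list(reads = data.frame(hap = 1L, start = 11L, strand = "fwd",
                                 stringsAsFactors = FALSE),
              seq = "AATAA", read_len = 5L, err_rate = 0,
              qual_levels = 35, qual_probs = NULL)
  lines <- reads_to_mpileup(sim, dip, ref)
  expect_length(lines, 5L)
  f <- do.call(rbind, strsplit(lines, "\t"))
  expect_equal(as.integer(f[, 2]), 11:15)
  expect_equal(f[, 5], c(".", ".", "T", ".", "."))
  expect_equal(f[, 6], rep(intToUtf8(35 + 33), 5))

  # hand-checked HOM deletion: "-2<seq>" at the anchor, "*" at deleted sites
  del_plan <- data.frame(pos = 100L, type = "DEL", seq = substr(ref, 101, 102),
                         zygosity = "HOM", stringsAsFactors = FALSE)
  dipd <- build_diploid(ref, del_plan)
  simd <- simulate_reads(dipd, coverage = 40, read_len = 30, err_rate = 0,
                         seed = 11)
  linesd <- reads_to_mpileup(simd, dipd, ref, del_plan)
  fd <- do.call(rbind, strsplit(linesd, "\t"))
  anchor <- fd[fd[, 2] == "100", ]
  expect_match(anchor[5], "-2(AA|aa)")
  for (p in c("101", "102")) {
    row <- fd[fd[, 2] == p, ]
    expect_true(grepl("*", row[5], fixed = TRUE))
    expect_false(grepl("[.,]", row[5]))  # no read carries these bases
  }
  # the parser accepts every synthesized line, and calling recovers the event
  sites <- lapply(seq_along(linesd), function(i)
    parse_mpileup_line(linesd[i], 1L, i))
  calls <- call_germline(linesd)
  expect_equal(evaluate_calls(truth_vcf(del_plan, ref), calls)$f_score, 1)

  # depth tracks coverage
  expect_equal(mean(as.integer(fd[, 4])), 40, tolerance = 0.15)
})

test_that("metric arithmetic matches the closed forms", {
  t12 <- data.frame(chrom = "ref", pos = 1:12, ref = "A", alt = "T",
                    zygosity = "HOM", stringsAsFactors = FALSE)
  perfect <- t12; perfect$genotype <- "HOM"
  m <- evaluate_calls(t12, perfect)
  expect_equal(c(m$tp, m$fp, m$fn), c(12L, 0L, 0L))
  expect_equal(c(m$sensitivity, m$precision, m$f_score), c(1, 1, 1))
  expect_equal(m$zygosity_concordance, 1)

  # TP 9, FP 1, FN 3
  calls <- t12[1:9, ]
  calls$genotype <- c(rep("HOM", 8), "HET")
  calls <- rbind(calls, data.frame(chrom = "ref", pos = 99L, ref = "A",
                                   alt = "G", zygosity = NA,
                                   genotype = "HET"))
  m2 <- evaluate_calls(t12, calls)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(9L, 1L, 3L))
  expect_equal(m2$sensitivity, 9 / 12)
  expect_equal(m2$precision, 9 / 10)
  expect_equal(m2$f_score, 2 * (9 / 12) * (9 / 10) / (9 / 12 + 9 / 10))
  expect_equal(m2$zygosity_concordance, 8 / 9)

  empty <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      genotype = character(), stringsAsFactors = FALSE)
  m3 <- evaluate_calls(t12, empty)
  expect_equal(c(m3$sensitivity, m3$precision, m3$f_score), c(0, 0, 0))
})

test_that("a full replicate is seed-deterministic and scores its own truth", {
  ref <- random_reference(6000, seed = 2)
  m1 <- run_sim_replicate(ref, seed = 41, coverage = 40, read_len = 80)
  m2 <- run_sim_replicate(ref, seed = 41, coverage = 40, read_len = 80)
  expect_identical(m1, m2)
  expect_equal(m1$tp + m1$fn, 12L)  # the 12 planted SNVs partition

  bench <- run_benchmark(ref, n_replicates = 2, base_seed = 40,
                         coverage = 40, read_len = 80)
  expect_equal(nrow(bench), 2L)
  expect_equal(bench$sensitivity[2], m1$sensitivity)
})
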