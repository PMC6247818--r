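germline_calls <- function() {
  sites <- list(
    make_site(pos = 100L, ref = "A", samples = balanced_sample(10, 10)),
    make_site(pos = 200L, ref = "G",
              samples = rbind(make_obs(REF = c(2, 2)),
                              make_obs(`+AT` = c(6, 6)))))
  call_germline(sites)
}

test_that("germline VCF records carry GT/GQ/DP/AD/FREQ and VPV", {
  calls <- germline_calls()
  path <- tempfile(fileext = ".vcf")
  write_vcf(calls, path)
  v <- read_vcf(path)

  expect_equal(v$header[1], "##fileformat=VCFv4.1")
  expect_true(any(grepl("^##fetvarParams=<", v$header)))
  expect_equal(nrow(v$records), 2L)
  expect_equal(v$records$FILTER, c("PASS", "PASS"))
  expect_equal(v$records$POS, c(100L, 200L))

  r1 <- v$records[1, ]
  expect_equal(r1$REF, "A")
  expect_equal(r1$ALT, "T")
  expect_equal(r1$FORMAT, "GT:GQ:DP:AD:FREQ")
  f <- strsplit(r1$SAMPLE, ":", fixed = TRUE)[[1]]
  expect_equal(f[1], "0/1")
  expect_equal(as.numeric(f[2]), calls$gq[1], tolerance = 1e-3)
  expect_equal(f[3], "20")
  expect_equal(f[4], "10")
  expect_equal(f[5], "50%")
  expect_equal(as.numeric(sub("VPV=", "", r1$INFO)), calls$variant_p[1],
               tolerance = 1e-3)
  # QUAL mirrors the genotype quality
  expect_equal(as.numeric(r1$QUAL), calls$gq[1], tolerance = 1e-3)

  # indel record stays left-anchored
  r2 <- v$records[2, ]
  expect_equal(r2$REF, "G")
  expect_equal(r2$ALT, "GAT")
})

test_that("an empty call set writes a header-only VCF and unsorted calls error", {
  calls <- call_germline(list())
  path <- tempfile(fileext = ".vcf")
  write_vcf(calls, path)
  v <- read_vcf(path)
  expect_equal(nrow(v$records), 0L)
  expect_true(all(startsWith(readLines(path), "#")))

  bad <- germline_calls()
  bad <- bad[2:1, ]
  expect_error(write_vcf(bad, tempfile()), "sorted")
})

test_that("vcfR parses the files this package writes", {
  skip_if_not_installed("vcfR")
  calls <- germline_calls()
  path <- tempfile(fileext = ".vcf")
  write_vcf(calls, path)
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  expect_equal(nrow(v@fix), 2L)
  expect_equal(unname(v@fix[, "ALT"]), c("T", "GAT"))
  expect_equal(colnames(v@gt), c("FORMAT", "SAMPLE"))
})

test_that("split_vcf partitions records by STATUS, preserving headers", {
  pairs <- list(
    list(balanced_sample(10, 10), balanced_sample(20, 0)),   # Somatic
    list(balanced_sample(1, 19), balanced_sample(10, 10)),   # LOH
    list(balanced_sample(10, 10), balanced_sample(10, 10)),  # Germline
    list(balanced_sample(20, 0), balanced_sample(1, 19)))    # Unknown
  calls <- do.call(rbind, lapply(seq_along(pairs), function(i) {
    classify_paired_site(make_site(pos = i * 10L, samples = pairs[[i]][[1]]),
                         make_site(pos = i * 10L, samples = pairs[[i]][[2]]))
  }))
  class(calls) <- c("fetvar_calls", "data.frame")
  path <- tempfile(fileext = ".vcf")
  write_vcf(calls, path, mode = "somatic")

  prefix <- tempfile()
  paths <- split_vcf(path, prefix)
  expect_equal(names(paths), c("Somatic", "Germline", "LOH", "Unknown"))
  parts <- lapply(paths, read_vcf)
  # conservation: every record lands in exactly one file
  expect_equal(sum(vapply(parts, function(p) nrow(p$records), 0L)), 4L)
  for (s in names(paths)) {
    p <- parts[[s]]
    expect_equal(nrow(p$records), 1L)
    expect_equal(info_field(p$records$INFO, "STATUS"), s)
    expect_equal(p$header, read_vcf(path)$header)
  }

  # all records of one status: other files are header-only
  germ <- calls[calls$status == "Germline", , drop = FALSE]
  class(germ) <- c("fetvar_calls", "data.frame")
  gpath <- tempfile(fileext = ".vcf")
  write_vcf(germ, gpath, mode = "somatic")
  gpaths <- split_vcf(gpath, tempfile())
  expect_equal(nrow(read_vcf(gpaths[["Germline"]])$records), 1L)
  expect_equal(nrow(read_vcf(gpaths[["Somatic"]])$records), 0L)

  # records lacking STATUS are an error
  nostat <- germline_calls()
  npath <- tempfile(fileext = ".vcf")
  write_vcf(nostat, npath)
  expect_error(split_vcf(npath, tempfile()), "STATUS")
})

test_that("population VCF emits per-sample codes and the MAF INFO key", {
  sites <- list(make_site(pos = 50L, ref = "A",
                          samples = balanced_sample(10, 10)))
  sites[[1]]$samples <- list(balanced_sample(10, 10), balanced_sample(20, 0),
                             balanced_sample(1, 19))
  calls <- call_population(sites, n_samples = 3)
  path <- tempfile(fileext = ".vcf")
  write_vcf(calls, path)
  v <- read_vcf(path)
  r <- v$records[1, ]
  expect_equal(unlist(r[c("S1", "S2", "S3")], use.names = FALSE),
               c("0/1", "0/0", "1/1"))
  expect_equal(info_field(r$INFO, "MAF"), "50")  # 3 alt copies of 6
})
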