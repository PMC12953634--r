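# Readers and writers: round-trip identity, strict validation, and the
# female/XX chromosome convention.

test_that("VCF writer and reader round-trip the variant table", {
  vt <- toy_variant_table()
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(vt, path)
  back <- read_vcf(path)
  expect_equal(back$sites, vt$sites)
  expect_equal(back$ad_ref, vt$ad_ref)
  expect_equal(back$ad_alt, vt$ad_alt)
  expect_equal(back$dp, vt$dp)
  expect_equal(back$samples, vt$samples)
})

test_that("VCF reader maps AD/DP fields and rejects dialect violations", {
  path <- withr::local_tempfile(fileext = ".vcf")
  head_lines <- c("##fileformat=VCFv4.2",
                  '##FORMAT=<ID=GT,Number=1,Type=String,Description="G">',
                  '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="A">',
                  '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="D">',
                  "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1")
  writeLines(c(head_lines, "1\t10\t.\tA\tT\t.\tPASS\t.\tGT:AD:DP\t0/1:5,3:8"),
             path)
  vt <- read_vcf(path)
  expect_equal(as.integer(vt$ad_ref[1, 1]), 5L)
  expect_equal(as.integer(vt$ad_alt[1, 1]), 3L)
  expect_equal(as.integer(vt$dp[1, 1]), 8L)
  # multi-allelic record rejected, naming the site
  writeLines(c(head_lines, "1\t10\t.\tA\tT,G\t.\tPASS\t.\tGT:AD:DP\t0/1:5,3,2:10"),
             path)
  expect_error(read_vcf(path), "multi-allelic.*1:10")
  # missing DP in FORMAT rejected
  writeLines(c(head_lines, "1\t10\t.\tA\tT\t.\tPASS\t.\tGT:AD\t0/1:5,3"),
             path)
  expect_error(read_vcf(path), "AD and DP")
})

test_that("Y-chromosome records are dropped on read (female/XX convention)", {
  sites <- data.frame(chrom = c("1", "Y"), pos = c(5, 9),
                      ref = c("A", "C"), alt = c("G", "T"),
                      stringsAsFactors = FALSE)
  vt <- variant_table(sites, cbind(S = c(4L, 4L)), cbind(S = c(4L, 4L)),
                      cbind(S = c(8L, 8L)), "S")
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(vt, path)
  expect_equal(read_vcf(path)$sites$chrom, "1")
  w <- data.frame(chrom = c("1", "chrY"), start = c(0, 0), end = c(100, 100),
                  count = c(5, 5))
  wpath <- withr::local_tempfile(fileext = ".tsv")
  write_window_counts(w, wpath)
  expect_equal(read_window_counts(wpath)$chrom, "1")
})

test_that("window-count TSVs round-trip and invalid schemas are rejected", {
  w <- data.frame(chrom = "1", start = c(0, 50000), end = c(50000, 100000),
                  count = c(120, 130), gc = c(0.41, 0.45))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_window_counts(w, path)
  back <- read_window_counts(path)
  expect_equal(back$count, w$count)
  expect_equal(back$end - back$start, c(50000, 50000))
  # overlapping windows named by line
  bad <- w; bad$start[2] <- 25000
  write_window_counts(bad, path)
  expect_error(read_window_counts(path), "overlapping.*lines 2 and 3")
  # negative counts rejected
  bad <- w; bad$count[1] <- -1
  write_window_counts(bad, path)
  expect_error(read_window_counts(path), "negative count")
})

test_that("matrix reader/writer round-trip and reject non-numeric cells", {
  m <- matrix(rnorm(6), 2, dimnames = list(c("f1", "f2"), c("s1", "s2", "s3")))
  path <- withr::local_tempfile(fileext = ".csv")
  write_matrix(m, path)
  expect_equal(read_matrix(path), m, tolerance = 1e-12)
  writeLines(c("feature,s1,s2", "f1,1.0,oops"), path)
  expect_error(read_matrix(path), "non-numeric cell.*s2")
})

test_that("config loading validates keys and propagates overrides", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("window_size_bp: 10000", "seed: 42"), path)
  cfg <- load_config(path)
  expect_equal(cfg$window_size_bp, 10000)
  expect_equal(cfg$seed, 42)
  expect_equal(cfg$mean_depth, default_pipeline_config()$mean_depth)
  writeLines("not_a_real_key: 1", path)
  expect_error(load_config(path), "unknown config key")
})

test_that("variant tables enforce depth invariants and merge by outer join", {
  sites <- data.frame(chrom = "1", pos = 1, ref = "A", alt = "T")
  expect_error(variant_table(sites, cbind(S = 5L), cbind(S = 5L),
                             cbind(S = 8L), "S"), "exceed dp")
  a <- variant_table(sites, cbind(P = 10L), cbind(P = 2L), cbind(P = 12L), "P")
  sites2 <- data.frame(chrom = "1", pos = 9, ref = "C", alt = "G")
  b <- variant_table(sites2, cbind(R = 7L), cbind(R = 3L), cbind(R = 10L), "R")
  m <- merge_variant_tables(list(a, b))
  expect_equal(n_sites(m), 2L)
  expect_equal(as.vector(m$dp[, "R"]), c(0L, 10L))  # absent site: zero reads
})
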