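# Copy-number profiling: ratio normalisation, GC correction, segmentation
# and state calling.

test_that("count-to-ratio applies the median-normalisation formula", {
  w <- data.frame(chrom = "1", start = (0:4) * 5e4, end = (1:5) * 5e4,
                  count = c(50, 100, 100, 100, 200))
  expect_equal(count_to_ratio(w, 4L)$ratio, c(2, 4, 4, 4, 8))
  w$count <- rep(100, 5)
  expect_equal(count_to_ratio(w, 2L)$ratio, rep(2, 5))
  w$count <- rep(0, 5)
  expect_error(count_to_ratio(w, 2L), "cannot normalise")
})

test_that("ratios are invariant to uniform count scaling and exclude X from the median", {
  w <- data.frame(chrom = rep(c("1", "X"), each = 50),
                  start = rep((0:49) * 5e4, 2), end = rep((1:50) * 5e4, 2),
                  count = c(rep(100, 50), rep(50, 50)))
  r1 <- count_to_ratio(w, 2L)
  w2 <- w; w2$count <- w$count * 7.3
  expect_equal(count_to_ratio(w2, 2L)$ratio, r1$ratio)
  # autosomal median is 100, so the X windows sit at ratio 1 (one copy)
  expect_equal(unique(r1$ratio[r1$chrom == "X"]), 1)
})

test_that("GC correction rescales by per-bin medians and undoes injected bias", {
  # two GC bins with medians 80 and 120 against a global median of 100
  w <- data.frame(chrom = "1", start = (0:99) * 5e4, end = (1:100) * 5e4,
                  count = rep(c(80, 120), each = 50),
                  gc = rep(c(0.35, 0.55), each = 50))
  corrected <- gc_correct(w, n_bins = 2L)
  expect_equal(unique(corrected$count[w$gc == 0.35]), 80 * 100 / 80)
  expect_equal(unique(corrected$count[w$gc == 0.55]), 120 * 100 / 120)
  # sparse bins are left unscaled
  w2 <- w; w2$gc[1] <- 0.95
  expect_equal(gc_correct(w2, n_bins = 10L)$count[1], w2$count[1])
  expect_error(gc_correct(w[, -5], 2L), "gc column")
  # end to end: injected GC slope, corrected ratios recover the ploidy
  cfg <- tiny_config(seed = 13L, length_bp = 5e7, n_snvs = 0L,
                     depth_dispersion = 0.01)
  sq <- sample_sequencing(simulate_parental(cfg), NULL, cfg, "S")
  biased <- apply_gc_bias(sq$windows, slope = 2)
  track <- count_to_ratio(gc_correct(biased), 2L)
  expect_equal(median(track$ratio), 2, tolerance = 0.02)
  expect_equal(mean(track$ratio), 2, tolerance = 0.02)
})

test_that("segmentation recovers breakpoints and leaves flat tracks whole", {
  mk_track <- function(ratio) {
    n <- length(ratio)
    w <- data.frame(chrom = "1", start = (0:(n - 1)) * 5e4, end = (1:n) * 5e4,
                    count = 100)
    t <- count_to_ratio(w, 2L)
    t$ratio <- ratio
    t
  }
  set.seed(41)
  flat <- mk_track(rnorm(300, 2, 0.1))
  expect_equal(nrow(segment_track(flat)), 1L)
  # 200 windows at 2 then 200 at 3: breakpoint within +/- 2 windows
  step <- mk_track(c(rnorm(200, 2, 0.1), rnorm(200, 3, 0.1)))
  segs <- segment_track(step)
  expect_equal(nrow(segs), 2L)
  expect_lte(abs(segs$end[1] / 5e4 - 200), 2)
  expect_equal(round(segs$mean_ratio), c(2, 3))
  # too short to split
  short <- mk_track(c(1, 1, 5, 5))
  expect_equal(nrow(segment_track(short, min_windows = 3L)), 1L)
  # determinism: identical input, identical breakpoints
  expect_identical(segment_track(step), segment_track(step))
})

test_that("state calling applies the margin rule around the ploidy", {
  segs <- data.frame(chrom = "1", start = 0, end = 1e6,
                     mean_ratio = c(3.0, 2.2, 1.2), n_windows = 20L)
  called <- call_states(segs, 2L, margin = 0.5)
  expect_equal(called$state, c("gain", "neutral", "loss"))
  expect_equal(called$estimated_cn, c(3L, 2L, 1L))
})

test_that("a WGD genome with one focal loss yields exactly one loss segment", {
  cfg <- tiny_config(seed = 17L, length_bp = 5e7, n_snvs = 0L)
  par <- simulate_parental(cfg)
  ev <- resistance_events(TRUE, data.frame(chrom = "1", start_bp = 2e7,
                                           end_bp = 3e7, delta_copies = -1L))
  res <- derive_resistant(par, ev, seed = 1L)
  sq <- sample_sequencing(res, NULL, cfg, "S")
  segs <- call_states(segment_track(count_to_ratio(sq$windows, 4L)), 4L)
  expect_equal(sum(segs$state == "loss"), 1L)
  expect_equal(sum(segs$state == "gain"), 0L)
  expect_equal(segs$estimated_cn[segs$state == "loss"], 3L)
})

test_that("gene-level copy number is the median ratio of overlapping fine windows", {
  w <- data.frame(chrom = "1", start = (0:99) * 5000, end = (1:100) * 5000,
                  count = 100)
  w$count[41:43] <- c(200, 200, 250)  # gene region amplified
  gene <- list(chrom = "1", start = 200000, end = 215000)
  track_ratio <- gene_copy_number(w, gene, 2L)
  expect_equal(track_ratio, median(c(4, 4, 5)))
  expect_error(gene_copy_number(w, list(chrom = "7", start = 0, end = 1e4), 2L),
               "no windows overlap")
})
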