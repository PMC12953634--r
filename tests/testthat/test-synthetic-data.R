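# Clone-genome and sequencing simulators: determinism, event algebra and
# the distributional contracts the downstream analyses rely on.

test_that("parental simulation honours the configuration and is deterministic", {
  cfg <- tiny_config(seed = 3L, n_snvs = 100L)
  g1 <- simulate_parental(cfg)
  g2 <- simulate_parental(cfg)
  expect_identical(g1, g2)
  expect_equal(nrow(g1$segments), 1L)
  expect_equal(g1$segments$total_copies, 2L)
  expect_equal(nrow(g1$snvs), 100L)
  expect_true(all(g1$snvs$total_copies == 2L))
  expect_true(all(g1$snvs$alt_copies %in% 1:2))
  expect_true(all(g1$snvs$pos >= 1 & g1$snvs$pos <= 1e7))
  # empty case
  g0 <- simulate_parental(tiny_config(n_snvs = 0L))
  expect_equal(nrow(g0$snvs), 0L)
  # invalid genomes rejected
  expect_error(sim_config(seed = 1, chromosomes = data.frame(
    name = character(), length_bp = numeric())), "at least one")
  expect_error(sim_config(seed = 1, chromosomes = data.frame(
    name = "1", length_bp = 0)), "positive")
})

test_that("whole-genome duplication doubles copies and preserves allele fractions", {
  par <- simulate_parental(tiny_config(seed = 5L, n_snvs = 200L))
  res <- derive_resistant(par, resistance_events(whole_genome_duplication = TRUE),
                          seed = 7L)
  expect_equal(res$segments$total_copies, 4L)
  expect_equal(res$snvs$alt_copies, par$snvs$alt_copies * 2L)
  expect_equal(res$snvs$total_copies, par$snvs$total_copies * 2L)
  expect_equal(res$snvs$alt_copies / res$snvs$total_copies,
               par$snvs$alt_copies / par$snvs$total_copies)
})

test_that("segmental events split segments and update covered SNVs", {
  # WGD then delta = -1 on half the chromosome: hand-traced copy numbers
  par <- simulate_parental(tiny_config(seed = 2L, n_snvs = 500L))
  ev <- resistance_events(
    whole_genome_duplication = TRUE,
    segmental_events = data.frame(chrom = "1", start_bp = 0, end_bp = 5e6,
                                  delta_copies = -1L))
  res <- derive_resistant(par, ev, seed = 1L)
  expect_equal(res$segments$start, c(0, 5e6))
  expect_equal(res$segments$total_copies, c(3L, 4L))
  in_ev <- res$snvs$pos <= 5e6
  expect_true(all(res$snvs$total_copies[in_ev] == 3L))
  expect_true(all(res$snvs$total_copies[!in_ev] == 4L))
  expect_true(all(res$snvs$alt_copies <= res$snvs$total_copies))
  # an event driving copies negative is rejected
  bad <- resistance_events(segmental_events = data.frame(
    chrom = "1", start_bp = 0, end_bp = 5e6, delta_copies = -3L))
  expect_error(derive_resistant(par, bad, seed = 1L), "negative copy number")
})

test_that("SNV fixation raises alt copies to the site total", {
  par <- simulate_parental(tiny_config(seed = 9L, n_snvs = 50L))
  par$snvs$alt_copies <- 1L  # make every SNV heterozygous, hence eligible
  res <- derive_resistant(par, resistance_events(snv_fixations = 50L), seed = 3L)
  expect_true(all(res$snvs$alt_copies == res$snvs$total_copies))
  # more fixations than eligible SNVs is rejected
  expect_error(derive_resistant(res, resistance_events(snv_fixations = 1L),
                                seed = 3L), "eligible")
})

test_that("sequencing observables match their sampling distributions", {
  # 10,000 sites at alt 1/4, depth 100: mean AF within 0.25 +/- 0.005,
  # mean DP near 200 (copy number 4 at base ploidy 2)
  cfg <- sim_config(seed = 21L,
                    chromosomes = data.frame(name = "1", length_bp = 5e7),
                    mean_depth = 100, depth_dispersion = 0.01,
                    n_somatic_snvs = 10000L, n_het_sites_per_chrom = 0L)
  par <- simulate_parental(cfg)
  res <- derive_resistant(par, resistance_events(whole_genome_duplication = TRUE),
                          seed = 1L)
  # force every SNV to one alt copy of four
  res$snvs$alt_copies <- 1L
  sq <- sample_sequencing(res, NULL, cfg, "S")
  af <- sq$variants$ad_alt[, 1] / sq$variants$dp[, 1]
  expect_equal(mean(af), 0.25, tolerance = 0.005 / 0.25)
  expect_equal(mean(sq$variants$dp[, 1]), 200, tolerance = 0.02)
  # windows in the duplicated genome double the baseline count
  expect_equal(mean(sq$windows$count),
               100 * 50000 / 150 * 2, tolerance = 0.02)
})

test_that("sequencing is deterministic given seed and sample name", {
  cfg <- tiny_config(seed = 4L, n_snvs = 50L, n_het = 100L)
  clone <- simulate_parental(cfg)
  panel <- simulate_panel_sites(cfg)
  s1 <- sample_sequencing(clone, panel, cfg, "A")
  s2 <- sample_sequencing(clone, panel, cfg, "A")
  s3 <- sample_sequencing(clone, panel, cfg, "B")
  expect_identical(s1$variants$ad_alt, s2$variants$ad_alt)
  expect_identical(s1$windows$count, s2$windows$count)
  expect_false(identical(s1$variants$ad_alt, s3$variants$ad_alt))
})

test_that("window counts scale linearly with local copy number", {
  cfg <- sim_config(seed = 31L,
                    chromosomes = data.frame(name = "1", length_bp = 5e7),
                    depth_dispersion = 0.01, n_somatic_snvs = 0L,
                    n_het_sites_per_chrom = 0L)
  par <- simulate_parental(cfg)
  ev <- resistance_events(whole_genome_duplication = TRUE,
                          segmental_events = data.frame(
                            chrom = "1", start_bp = 0, end_bp = 2.5e7,
                            delta_copies = 2L))  # copies 6 vs 4
  res <- derive_resistant(par, ev, seed = 1L)
  sq <- sample_sequencing(res, NULL, cfg, "S")
  cn <- ifelse(sq$windows$start < 2.5e7, 6, 4)
  slope <- coef(lm(sq$windows$count ~ cn))[["cn"]]
  baseline <- 60 * 50000 / 150 / 2
  expect_equal(slope, baseline, tolerance = 0.05)
})

test_that("phospho simulation places the promised number of true shifts", {
  sim <- simulate_phospho(1000, 6, 0.1, 3, seed = 8L)
  expect_equal(sum(sim$truth), 100L)
  expect_equal(dim(sim$matrix), c(1000L, 12L))
  null_sim <- simulate_phospho(200, 3, 0, 3, seed = 8L)
  expect_false(any(null_sim$truth))
  # a 3-SD shift at n = 6 per group is comfortably detectable on average
  tstats <- vapply(which(sim$truth), function(i)
    s0_t_statistic(sim$matrix[i, 1:6], sim$matrix[i, 7:12], s0 = 0), numeric(1))
  expect_gt(mean(abs(tstats)), 2)
  expect_error(simulate_phospho(10, 6, 1.2, 1, seed = 1), "frac_differential")
})

test_that("drug-screen simulation reproduces the dilution series and 4PL anchors", {
  expect_equal(dose_series(100, 5, 7),
               sort(c(100, 20, 4, 0.8, 0.16, 0.032, 0.0064)))
  # noise-free midpoint: POC = 50 exactly at the IC50
  expect_equal(fourpl_poc(1, ic50 = 1, hill = 1), 50)
  # steep curve with ic50 at the top dose: ~100 below it
  steep <- fourpl_poc(dose_series(100, 5, 7), ic50 = 100, hill = 20)
  expect_true(all(steep[1:6] > 99.9))
  scr <- simulate_drug_screen(c(L1 = 4), noise_cv = 0, seed = 2L)
  expect_equal(scr$L1$poc[scr$L1$doses_uM == 4, ], rep(50, 3))
  expect_error(dose_series(100, 1, 7), "dilution")
})

test_that("combination grids embed their monotherapies and requested synergy", {
  doses <- c(0, dose_series(2, 2, 6))
  cA <- list(ic50 = 2, hill = 1); cB <- list(ic50 = 4, hill = 1)
  g0 <- simulate_combination(cA, cB, doses, doses, synergy_delta = 0,
                             noise_cv = 0, seed = 1L)
  expect_equal(g0$poc[, 1], fourpl_poc(doses, 2, 1))
  expect_equal(g0$poc[1, ], fourpl_poc(doses, 4, 1))
  expect_equal(max(abs(bliss_excess(g0))), 0)
  g10 <- simulate_combination(cA, cB, doses, doses, synergy_delta = 10,
                              noise_cv = 0, seed = 1L)
  be <- bliss_excess(g10)
  expect_equal(unique(round(as.vector(be[-1, -1]), 10)), 10)
  expect_error(simulate_combination(cA, cB, doses[-1], doses, 0, 0, 1L),
               "zero dose")
})
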