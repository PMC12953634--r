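# Frequency-shift testing: Fisher exact, zero-read loss test, BH FDR and
# the gain/loss/fixation classification.

test_that("Fisher shift test matches enumeration and the reference implementation", {
  expect_equal(fisher_shift_test(c(10, 10), c(10, 10)), 1.0)
  expect_true(is.na(fisher_shift_test(c(0, 0), c(5, 5))))
  # hand-picked and random tables against an independent brute-force oracle
  # and against stats::fisher.test
  tables <- list(rbind(c(10, 10), c(20, 0)), rbind(c(1, 9), c(9, 1)),
                 rbind(c(0, 5), c(5, 0)), rbind(c(2, 2), c(2, 2)))
  set.seed(7)
  for (i in 1:200) tables[[length(tables) + 1L]] <-
    matrix(rpois(4, sample(3:20, 1)), 2)
  for (t in tables) {
    if (sum(t) == 0 || any(rowSums(t) == 0)) next
    p <- fisher_shift_test(t[1, ], t[2, ])
    expect_equal(p, fisher_oracle(t[1, ], t[2, ]), tolerance = 1e-12)
    if (all(colSums(t) > 0)) {
      expect_equal(p, stats::fisher.test(t)$p.value, tolerance = 1e-12)
    }
  }
})

test_that("loss test follows the zero-read binomial closed form and monotonicity", {
  expect_equal(loss_binomial_test(0.5, 1), 0.5)
  expect_equal(loss_binomial_test(0.5, 0), 1.0)
  expect_equal(loss_binomial_test(1 / 3, 30), (2 / 3)^30, tolerance = 1e-12)
  # monotone decreasing in depth and in expected frequency
  p_by_dp <- loss_binomial_test(0.3, 0:50)
  expect_true(all(diff(p_by_dp) < 0))
  p_by_af <- vapply(seq(0.05, 0.95, 0.05), loss_binomial_test,
                    numeric(1), dp_resistant = 20)
  expect_true(all(diff(p_by_af) < 0))
  expect_error(loss_binomial_test(0, 10), "expected_af")
})

test_that("BH adjustment follows the step-up rule, passes NAs, ignores order", {
  expect_equal(adjust_fdr(0.03), 0.03)
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  p <- c(0.001, NA, 0.04, 0.9, NA, 0.02)
  q <- adjust_fdr(p)
  expect_true(all(is.na(q[is.na(p)])))
  expect_equal(q[!is.na(p)], p.adjust(p[!is.na(p)], "BH"))
  # permutation invariance
  set.seed(11)
  p2 <- runif(50)
  perm <- sample(50)
  expect_equal(adjust_fdr(p2)[perm], adjust_fdr(p2[perm]))
  # q-values never fall below their p-values
  expect_true(all(adjust_fdr(p2) >= p2))
  expect_error(adjust_fdr(1.2), "0, 1")
})

test_that("classification traces gained, lost and fixed variants correctly", {
  sites <- data.frame(chrom = "1", pos = c(10, 20, 30, 40), ref = "A",
                      alt = "T", stringsAsFactors = FALSE)
  # pos 10: novel in R with a strong shift -> gained
  # pos 20: parental AF 0.5, zero alt reads at depth 40 in R -> lost
  # pos 30: parental AF 0.4, resistant AF 1.0 -> fixed
  # pos 40: identical depths -> stable
  p_tab <- variant_table(sites,
                         ad_ref = cbind(P = c(30L, 15L, 30L, 20L)),
                         ad_alt = cbind(P = c(0L, 15L, 20L, 20L)),
                         dp = cbind(P = c(30L, 30L, 50L, 40L)), "P")
  r_tab <- variant_table(sites,
                         ad_ref = cbind(R = c(15L, 40L, 0L, 20L)),
                         ad_alt = cbind(R = c(15L, 0L, 50L, 20L)),
                         dp = cbind(R = c(30L, 40L, 50L, 40L)), "R")
  cls <- classify_variants(p_tab, r_tab, c("P", "R"))
  expect_equal(cls$results$category, c("gained", "lost", "fixed", "stable"))
  expect_equal(cls$results$binom_loss_p[2], 0.5^40, tolerance = 1e-12)
  expect_equal(cls$summary$n_gain_loss, 2L)
  expect_true(cls$results$novel[1])
  expect_error(classify_variants(p_tab, r_tab, c("P", "nope")), "not found")
})

test_that("fixation fraction counts fixed among novel variants", {
  res <- data.frame(novel = c(rep(TRUE, 10), rep(FALSE, 5)),
                    category = c(rep("fixed", 4), rep("gained", 6),
                                 rep("stable", 5)))
  expect_equal(fixation_fraction(res), 0.4)
  res_none <- data.frame(novel = FALSE, category = "stable")
  expect_true(is.na(fixation_fraction(res_none)))
})

test_that("an end-to-end resistant clone recovers its engineered fixation fraction", {
  cfg <- tiny_config(seed = 55L, n_snvs = 0L)
  par <- simulate_parental(cfg)
  res <- derive_resistant(par, resistance_events(snv_gains = 100L,
                                                 snv_fixations = 20L),
                          seed = 3L)
  sp <- sample_sequencing(par, NULL, cfg, "P")
  sr <- sample_sequencing(res, NULL, cfg, "R")
  cls <- classify_variants(sp$variants, sr$variants, c("P", "R"))
  expect_equal(fixation_fraction(cls$results), 0.2, tolerance = 0.05 / 0.2)
})

test_that("parental-vs-parental resequencing stays at the nominal error rate", {
  # one clone sequenced twice: any q < 0.05 call is a false positive
  cfg <- tiny_config(seed = 91L, n_snvs = 2000L)
  clone <- simulate_parental(cfg)
  s1 <- sample_sequencing(clone, NULL, cfg, "draw1")
  s2 <- sample_sequencing(clone, NULL, cfg, "draw2")
  cls <- classify_variants(s1$variants, s2$variants, c("draw1", "draw2"))
  frac_sig <- mean(cls$results$q_fisher < 0.05, na.rm = TRUE)
  expect_lte(frac_sig, 0.05 + 3 * sqrt(0.05 * 0.95 / 2000))
})
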