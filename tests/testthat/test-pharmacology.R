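# Dose-response fitting, AUC hit calling and assay utilities.

test_that("POC normalisation is linear in the raw signal", {
  doses <- dose_series(100, 5, 4)
  curve <- normalize_poc(c(2, 2.4, 0), vehicle = c(1.9, 2.1),
                         doses_uM = doses[1:3])
  expect_equal(as.vector(curve$poc), c(100, 120, 0))
  expect_error(normalize_poc(c(2, 2.4, 0), c(0, 0), doses[1:3]),
               "vehicle mean")
})

test_that("4PL fitting recovers exact curves and flags flat ones", {
  doses <- dose_series()
  fit <- fit_4pl(dose_response_curve("L", "c", doses,
                                     fourpl_poc(doses, ic50 = 1, hill = 1)))
  expect_equal(fit$ic50_uM, 1, tolerance = 1e-6)
  expect_equal(fit$hill, 1, tolerance = 1e-6)
  expect_equal(fit$top, 100, tolerance = 1e-6)
  expect_equal(fit$bottom, 0, tolerance = 1e-4)
  flat <- fit_4pl(dose_response_curve("L", "c", doses, rep(100, 7)))
  expect_true(is.na(flat$ic50_uM) || flat$extrapolated)
  expect_equal(flat$auc, 100)
  expect_error(fit_4pl(dose_response_curve("L", "c", doses[1:3],
                                           rep(50, 3))), "4 distinct doses")
})

test_that("noisy 7-dose screens recover IC50 within ten percent in most seeds", {
  hits <- 0L
  for (s in 1:20) {
    scr <- simulate_drug_screen(c(L = 1), noise_cv = 0.05, seed = 3000 + s)
    fit <- fit_4pl(scr$L, fix_top = 100, fix_bottom = 0,
                   weighting = "relative")
    hits <- hits + (abs(fit$ic50_uM - 1) <= 0.1)
  }
  expect_gte(hits, 18L)
  # the constrained fit honours its constraints
  scr1 <- simulate_drug_screen(c(L = 1), noise_cv = 0.05, seed = 3001)
  cfit <- fit_4pl(scr1$L, fix_top = 100, fix_bottom = 0)
  expect_equal(cfit$top, 100)
  expect_equal(cfit$bottom, 0)
})

test_that("AUC is the span-normalised trapezoid with replicate-propagated SD", {
  doses <- dose_series(100, 10, 4)
  expect_equal(compute_auc(dose_response_curve("L", "c", doses,
                                               matrix(100, 4, 3)))[["auc"]], 100)
  expect_equal(compute_auc(dose_response_curve("L", "c", doses,
                                               matrix(0, 4, 2)))[["auc"]], 0)
  # POC linear in log10 dose from 100 down to 0: area is exactly 50
  lin <- 100 - 100 * (log10(doses) - log10(min(doses))) / 3
  expect_equal(compute_auc(dose_response_curve("L", "c", doses,
                                               lin))[["auc"]], 50)
  expect_error(compute_auc(dose_response_curve("L", "c", 1, matrix(50))),
               ">= 2 doses")
})

test_that("POC/AUC/IC50/hit decisions are invariant to uniform signal scaling", {
  doses <- dose_series(100, 5, 7)
  set.seed(19)
  raw <- fourpl_poc(doses, 2, 1.2) * 0.02 * (1 + rnorm(7, 0, 0.03))
  c1 <- normalize_poc(raw, vehicle = rep(0.02, 3), doses_uM = doses)
  c2 <- normalize_poc(raw * 37, vehicle = rep(0.02 * 37, 3), doses_uM = doses)
  expect_equal(c1$poc, c2$poc, tolerance = 1e-12)
  expect_equal(fit_4pl(c1)$ic50_uM, fit_4pl(c2)$ic50_uM, tolerance = 1e-9)
  expect_equal(compute_auc(c1), compute_auc(c2), tolerance = 1e-12)
})

test_that("hit calling reproduces the worked SD-inequality decisions", {
  # fib 400 +/- 20 vs line 300 +/- 30: 380 > 330 and diff 100 > 50 -> pass
  # fib 400 +/- 20 vs line 370 +/- 20: 380 < 390 -> fail
  tbl <- data.frame(cell_line = c("L1", "L2", "L3"),
                    auc = c(300, 370, 310), sd = c(30, 20, 10))
  hc <- call_hits(tbl, fib_auc = 400, fib_sd = 20)
  expect_equal(hc$lines$eq1_pass, c(TRUE, FALSE, TRUE))
  expect_equal(hc$lines$auc_diff_pass, c(TRUE, FALSE, TRUE))
  expect_equal(hc$n_lines_passing, 2L)
  expect_true(hc$hit)  # two of three lines pass
  # single-line screening mode
  hc1 <- call_hits(tbl[1, ], 400, 20, min_lines = 1L)
  expect_true(hc1$hit)
  expect_error(call_hits(data.frame(cell_line = "L", auc = 1, sd = NA_real_),
                         400, 20), "SD")
})

test_that("hit decisions survive a uniform AUC rescaling with matched threshold", {
  tbl <- data.frame(cell_line = c("a", "b"), auc = c(250, 340),
                    sd = c(15, 25))
  h1 <- call_hits(tbl, 400, 10, auc_diff_threshold = 50)
  tbl2 <- tbl; tbl2$auc <- tbl$auc * 2; tbl2$sd <- tbl$sd * 2
  h2 <- call_hits(tbl2, 800, 20, auc_diff_threshold = 100)
  expect_equal(h1$lines$line_pass, h2$lines$line_pass)
  expect_equal(h1$hit, h2$hit)
})

test_that("assay utilities follow their printed formulas", {
  expect_equal(tumour_volume(10, 5), 125)
  expect_equal(tumour_volume(2, 2), 4)
  expect_error(tumour_volume(2, 0), "positive")
  expect_warning(tumour_volume(2, 5), "swapped")
  expect_equal(ddcq_fold_change(20, 20, 20, 20), 1)
  expect_equal(ddcq_fold_change(19, 20, 20, 20), 2)  # ddCq = -1
  expect_equal(ddcq_fold_change(23.3219, 20, 20, 20), 0.1, tolerance = 1e-4)
  expect_error(ddcq_fold_change(NA, 1, 1, 1), "finite")
})
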