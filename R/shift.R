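# Parental-vs-resistant variant frequency-shift testing: Fisher exact test
# on allele depths, zero-read binomial loss test, BH FDR, and the
# gain/loss/changed/fixed classification with summary counts.

#' Two-sided Fisher exact test on a 2x2 allele-depth table
#'
#' Exact two-sided p-value for the table
#' rows = (parental, resistant), columns = (ref, alt), computed by
#' enumerating the hypergeometric distribution over the fixed margins and
#' summing the probabilities of all tables no more likely than the observed
#' one (with the customary 1 + 1e-7 relative tolerance on "no more likely").
#'
#' @param ad_parental integer vector c(ref, alt) of parental allele depths.
#' @param ad_resistant integer vector c(ref, alt) of resistant allele depths.
#' @return p-value in (0, 1]; NA for an all-zero or single-row/column table
#'   with no information (flagged degenerate).
#' @export
fisher_shift_test <- function(ad_parental, ad_resistant) {
  a <- ad_parental[1]; b <- ad_parental[2]
  cc <- ad_resistant[1]; d <- ad_resistant[2]
  check_that(all(c(a, b, cc, d) >= 0), "allele depths must be non-negative")
  row1 <- a + b; col1 <- a + cc; col2 <- b + d; N <- row1 + cc + d
  if (row1 == 0 || cc + d == 0 || col1 == 0 || col2 == 0) {
    # a zero margin: the table carries no association information
    if (N == 0) return(NA_real_)
    return(if (row1 == 0 || cc + d == 0) NA_real_ else 1)
  }
  support <- max(0, row1 - col2):min(row1, col1)
  dens <- stats::dhyper(support, col1, col2, row1)
  p_obs <- dens[match(a, support)]
  min(1, sum(dens[dens <= p_obs * (1 + 1e-7)]))
}

#' Zero-read binomial loss test
#'
#' Probability of observing zero alternate reads at depth `dp_resistant`
#' when the allele is truly present at `expected_af`:
#' p = (1 - expected_af)^dp. Applied to variants with no alternate reads in
#' the resistant sample; a small p is evidence of genuine allele loss.
#'
#' @param expected_af expected allele frequency in (0, 1] (the parental AF
#'   by default in the pipeline).
#' @param dp_resistant resistant-sample read depth (>= 0); depth 0 returns
#'   p = 1 (no evidence).
#' @return p-value.
#' @export
loss_binomial_test <- function(expected_af, dp_resistant) {
  check_that(all(expected_af > 0 & expected_af <= 1),
             "expected_af must lie in (0, 1]")
  check_that(all(dp_resistant >= 0 & dp_resistant == round(dp_resistant)),
             "dp_resistant must be a non-negative integer")
  # log-space; dp = 0 is the empty product (p = 1), even at af = 1
  ifelse(dp_resistant == 0, 1, exp(dp_resistant * log1p(-expected_af)))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted values with monotonicity enforcement. Missing p-values
#' are excluded from the ranking (they do not count toward the number of
#' tests) and returned as NA.
#'
#' @param pvals numeric p-values in [0, 1], NAs allowed.
#' @param method only "BH".
#' @return q-values, same length and order as the input.
#' @export
adjust_fdr <- function(pvals, method = "BH") {
  method <- match.arg(method)
  ok <- !is.na(pvals)
  check_that(all(pvals[ok] >= 0 & pvals[ok] <= 1),
             "p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(pvals))
  q[ok] <- stats::p.adjust(pvals[ok], method = "BH")
  q
}

#' Classify variant frequency shifts between parental and resistant samples
#'
#' Outer-joins the two tables on (chrom, pos, ref, alt) — a site absent from
#' one table contributes zero reads there — then per variant:
#' a two-sided [fisher_shift_test()] on the ref/alt depths, and for variants
#' with no alternate reads in the resistant sample but a positive parental
#' AF, a [loss_binomial_test()] at the parental AF. The two p-value families
#' are FDR-adjusted separately (they carry distinct significance thresholds).
#' Categories, in precedence order lost > fixed > gained > changed > stable:
#'
#' * lost — zero resistant alt reads with q_binom < alpha_binom;
#' * fixed — a novel variant (no parental alt reads) or a
#'   parental-intermediate variant (0 < parental AF < fixation_af) whose
#'   resistant AF >= fixation_af;
#' * gained — novel with q_fisher < alpha_fisher;
#' * changed — any other variant with q_fisher < alpha_fisher;
#' * stable — the remainder.
#'
#' @param parental,resistant single-sample [variant_table()]s, or one
#'   multi-sample table passed as both arguments.
#' @param sample_pair character vector c(parental_name, resistant_name).
#' @param alpha_fisher FDR threshold for the Fisher family (default 0.05).
#' @param alpha_binom FDR threshold for the loss family (default 0.1).
#' @param fixation_af AF threshold for fixation (default 0.95).
#' @return list with `results` (per-variant data.frame: key columns, AFs,
#'   p/q values, category) and `summary` (list of category totals,
#'   `fraction_fixed_of_novel`, thresholds).
#' @export
classify_variants <- function(parental, resistant, sample_pair,
                              alpha_fisher = 0.05, alpha_binom = 0.1,
                              fixation_af = 0.95) {
  check_that(length(sample_pair) == 2L,
             "sample_pair must name a parental and a resistant sample")
  merged <- if (identical(parental, resistant)) parental else
    merge_variant_tables(list(parental, resistant))
  check_that(all(sample_pair %in% merged$samples),
             "sample(s) %s not found",
             paste(setdiff(sample_pair, merged$samples), collapse = ", "))
  p_name <- sample_pair[1]; r_name <- sample_pair[2]
  p_ref <- merged$ad_ref[, p_name]; p_alt <- merged$ad_alt[, p_name]
  r_ref <- merged$ad_ref[, r_name]; r_alt <- merged$ad_alt[, r_name]
  dp_p <- merged$dp[, p_name]; dp_r <- merged$dp[, r_name]
  af_p <- ifelse(dp_p > 0, p_alt / dp_p, NA_real_)
  af_r <- ifelse(dp_r > 0, r_alt / dp_r, NA_real_)
  n <- length(p_ref)
  fisher_p <- vapply(seq_len(n), function(i)
    fisher_shift_test(c(p_ref[i], p_alt[i]), c(r_ref[i], r_alt[i])),
    numeric(1))
  loss_candidate <- !is.na(af_p) & af_p > 0 & r_alt == 0
  binom_p <- rep(NA_real_, n)
  binom_p[loss_candidate] <- loss_binomial_test(af_p[loss_candidate],
                                                dp_r[loss_candidate])
  q_fisher <- adjust_fdr(fisher_p)
  q_binom <- adjust_fdr(binom_p)
  novel <- p_alt == 0 & r_alt > 0
  sig_fisher <- !is.na(q_fisher) & q_fisher < alpha_fisher
  is_lost <- loss_candidate & !is.na(q_binom) & q_binom < alpha_binom
  is_fixed <- !is.na(af_r) & af_r >= fixation_af &
    (novel | (!is.na(af_p) & af_p > 0 & af_p < fixation_af))
  is_gained <- novel & sig_fisher
  category <- rep("stable", n)
  category[sig_fisher] <- "changed"
  category[is_gained] <- "gained"
  category[is_fixed] <- "fixed"
  category[is_lost] <- "lost"
  results <- data.frame(
    chrom = merged$sites$chrom, pos = merged$sites$pos,
    ref = merged$sites$ref, alt = merged$sites$alt,
    af_parental = af_p, af_resistant = af_r,
    fisher_p = fisher_p, q_fisher = q_fisher,
    binom_loss_p = binom_p, q_binom = q_binom,
    novel = novel, category = category, stringsAsFactors = FALSE
  )
  n_novel <- sum(novel)
  summary <- list(
    sample_pair = stats::setNames(sample_pair, c("parental", "resistant")),
    n_tested = n,
    totals = as.list(table(factor(category, levels = c(
      "gained", "lost", "changed", "fixed", "stable")))),
    n_gain_loss = sum(category %in% c("gained", "lost")),
    n_significant_change = sum(sig_fisher),
    fraction_fixed_of_novel = if (n_novel > 0)
      sum(category == "fixed" & novel) / n_novel else NA_real_,
    alpha_fisher = alpha_fisher, alpha_binom = alpha_binom,
    fixation_af = fixation_af,
    category_precedence = c("lost", "fixed", "gained", "changed", "stable")
  )
  list(results = results, summary = summary)
}

#' Fraction of novel variants that reached fixation
#'
#' Among variants absent from the parental sample but observed in the
#' resistant sample, the fraction classified as fixed.
#'
#' @param results per-variant data.frame from [classify_variants()].
#' @return The fraction, or NA (flagged missing) when no novel variants exist.
#' @export
fixation_fraction <- function(results) {
  check_that(is.data.frame(results) &&
               all(c("novel", "category") %in% names(results)),
             "results must come from classify_variants")
  check_that(nrow(results) > 0L, "results is empty")
  n_novel <- sum(results$novel)
  if (n_novel == 0L) return(NA_real_)
  sum(results$category == "fixed" & results$novel) / n_novel
}
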