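#' Simulate a phospho-intensity matrix
#'
#' Generates a features x samples matrix of log2 intensities for a two-group
#' design: every entry is standard-normal noise around a feature-specific
#' baseline, and a fixed fraction of features receives a mean shift of
#' `effect_size_sd_units` standard deviations in group B. Ground-truth
#' differential labels are returned alongside.
#'
#' @param n_features number of features (phospho-peptides).
#' @param n_per_group samples per group (>= 2).
#' @param frac_differential fraction of features with a true shift, in [0,1].
#' @param effect_size_sd_units size of the true shift, in within-group SD units.
#' @param seed integer seed.
#' @param baseline_mean,baseline_sd distribution of feature baselines
#'   (log2-intensity location); defaults emulate a typical DIA-MS dynamic range.
#' @return list with `matrix` (rownames F1.., colnames A1..,B1..), `groups`
#'   (factor of "A"/"B" per column) and `truth` (logical per feature).
#' @export
simulate_phospho <- function(n_features, n_per_group, frac_differential,
                             effect_size_sd_units, seed,
                             baseline_mean = 20, baseline_sd = 2) {
  check_that(is_count(n_features, 1L), "n_features must be a positive integer")
  check_that(is_count(n_per_group, 2L), "n_per_group must be >= 2")
  check_that(is_prob(frac_differential),
             "frac_differential must lie in [0, 1]")
  with_seed(derive_seed(seed, "phospho"), {
    n_diff <- round(n_features * frac_differential)
    truth <- c(rep(TRUE, n_diff), rep(FALSE, n_features - n_diff))
    base <- stats::rnorm(n_features, baseline_mean, baseline_sd)
    m <- matrix(stats::rnorm(n_features * 2 * n_per_group), n_features) + base
    shift_cols <- n_per_group + seq_len(n_per_group)
    m[truth, shift_cols] <- m[truth, shift_cols] + effect_size_sd_units
    rownames(m) <- sprintf("F%04d", seq_len(n_features))
    colnames(m) <- c(sprintf("A%d", seq_len(n_per_group)),
                     sprintf("B%d", seq_len(n_per_group)))
    groups <- factor(rep(c("A", "B"), each = n_per_group))
    list(matrix = m, groups = groups, truth = truth)
  })
}
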