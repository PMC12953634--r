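# Differential phospho-peptide statistics: row z-scoring, the s0-penalised
# two-sample t statistic, and permutation-based FDR thresholding.

#' Z-score matrix rows
#'
#' Per row, subtract the mean and divide by the sample SD over non-missing
#' entries. Rows with fewer than 2 non-missing values or zero SD are left
#' unscaled and flagged in the `flagged` attribute.
#'
#' @param m numeric matrix (features x samples), NAs allowed.
#' @return The z-scored matrix, with attribute `flagged` (logical per row).
#' @export
zscore_rows <- function(m) {
  check_that(is.matrix(m) && is.numeric(m), "m must be a numeric matrix")
  mu <- rowMeans(m, na.rm = TRUE)
  s <- apply(m, 1, stats::sd, na.rm = TRUE)
  n_ok <- rowSums(!is.na(m))
  flagged <- n_ok < 2L | is.na(s) | s == 0
  scale_rows <- !flagged
  out <- m
  out[scale_rows, ] <- (m[scale_rows, , drop = FALSE] - mu[scale_rows]) /
    s[scale_rows]
  attr(out, "flagged") <- flagged
  out
}

#' s0-penalised two-sample t statistic
#'
#' t_s0 = (mean_B - mean_A) / (se_pooled + s0), where se_pooled is the
#' classical pooled-variance standard error of the mean difference. The s0
#' constant damps features whose tiny variance would otherwise inflate the
#' statistic; with s0 = 0 this is exactly the Student t statistic.
#'
#' @param groupA,groupB numeric vectors (NAs dropped); >= 2 valid values each.
#' @param s0 non-negative fudge constant (the screen's convention is 0.1).
#' @return The statistic, or NA for a degenerate group.
#' @export
s0_t_statistic <- function(groupA, groupB, s0 = 0.1) {
  check_that(is.numeric(s0) && length(s0) == 1L && s0 >= 0,
             "s0 must be a single non-negative number")
  a <- groupA[!is.na(groupA)]; b <- groupB[!is.na(groupB)]
  if (length(a) < 2L || length(b) < 2L) return(NA_real_)
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  (mean(b) - mean(a)) / (se + s0)
}

# Vectorised t_s0 over matrix rows for one group labelling.
# grp_b: logical column selector for group B. Pairwise-complete within group.
s0_t_rows <- function(m, grp_b, s0) {
  a <- m[, !grp_b, drop = FALSE]; b <- m[, grp_b, drop = FALSE]
  na <- rowSums(!is.na(a)); nb <- rowSums(!is.na(b))
  ma <- rowMeans(a, na.rm = TRUE); mb <- rowMeans(b, na.rm = TRUE)
  va <- rowSums((a - ma)^2, na.rm = TRUE) / (na - 1)
  vb <- rowSums((b - mb)^2, na.rm = TRUE) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- (mb - ma) / (se + s0)
  t[na < 2L | nb < 2L] <- NA_real_
  t
}

# All (or a seeded sample of) distinct group-B column subsets of size nb.
permutation_subsets <- function(n, nb, n_permutations, seed) {
  total <- choose(n, nb)
  if (total <= max(n_permutations, 1e5)) {
    all_sub <- utils::combn(n, nb, simplify = FALSE)
    if (total <= n_permutations) return(all_sub)
    idx <- with_seed(derive_seed(seed, "perm_subsets"),
                     sample.int(length(all_sub), n_permutations))
    return(all_sub[idx])
  }
  with_seed(derive_seed(seed, "perm_subsets"), {
    seen <- new.env(hash = TRUE)
    out <- vector("list", n_permutations)
    got <- 0L
    while (got < n_permutations) {
      s <- sort(sample.int(n, nb))
      key <- paste(s, collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        got <- got + 1L
        out[[got]] <- s
      }
    }
    out
  })
}

#' Permutation-based FDR thresholding of s0 t statistics
#'
#' Computes the observed |t_s0| per feature, re-computes it under
#' group-label permutations (all distinct relabellings when few enough,
#' otherwise a seeded sample of `n_permutations`), and estimates, for each
#' candidate cutoff c, FDR(c) = mean permuted #\{|t*| >= c\} / observed
#' #\{|t| >= c\}, clipped to [0,1] and made monotone non-increasing in c.
#' The significance cutoff is the smallest observed |t| with
#' FDR(c) <= fdr_target; significant features are split by the sign of the
#' mean difference. Features with fewer than 2 valid values in either group
#' are excluded before permutation (keeping the permutation null
#' exchangeable) and tallied.
#'
#' @param m numeric matrix, features x samples.
#' @param groups two-level factor/character vector over columns; the second
#'   level is "group B" (differences are B minus A).
#' @param s0 fudge constant (default 0.1).
#' @param fdr_target target FDR (default 0.05).
#' @param n_permutations maximum permutations (default 250, minimum 25).
#' @param seed integer seed for permutation sampling.
#' @return An object of class `diff_result`: `features` data.frame
#'   (feature, mean_diff, t_s0, significant, side), plus cutoff, the FDR
#'   curve, counts per side and the run's parameters.
#' @export
permutation_fdr <- function(m, groups, s0 = 0.1, fdr_target = 0.05,
                            n_permutations = 250L, seed = 1L) {
  check_that(is.matrix(m), "m must be a matrix")
  groups <- factor(groups)
  check_that(nlevels(groups) == 2L && length(groups) == ncol(m),
             "groups must be a two-level labelling of the columns")
  nb_all <- table(groups)
  check_that(all(nb_all >= 2L), "both groups need >= 2 samples")
  check_that(ncol(m) >= 4L, "need >= 4 samples in total")
  check_that(is_count(n_permutations, 25L), "n_permutations must be >= 25")
  grp_b <- groups == levels(groups)[2]
  valid <- rowSums(!is.na(m[, !grp_b, drop = FALSE])) >= 2L &
    rowSums(!is.na(m[, grp_b, drop = FALSE])) >= 2L
  n_excluded <- sum(!valid)
  mm <- m[valid, , drop = FALSE]
  t_obs <- s0_t_rows(mm, grp_b, s0)
  mean_diff <- rowMeans(mm[, grp_b, drop = FALSE], na.rm = TRUE) -
    rowMeans(mm[, !grp_b, drop = FALSE], na.rm = TRUE)
  subsets <- permutation_subsets(ncol(mm), sum(grp_b), n_permutations, seed)
  abs_perm <- unlist(lapply(subsets, function(s) {
    gb <- seq_len(ncol(mm)) %in% s
    abs(s0_t_rows(mm, gb, s0))
  }))
  abs_perm <- sort(abs_perm[!is.na(abs_perm)])
  n_perm <- length(subsets)
  abs_obs <- abs(t_obs)
  cutoffs <- sort(unique(abs_obs))
  n_obs_ge <- length(abs_obs) -
    findInterval(cutoffs - 1e-12, sort(abs_obs))
  n_perm_ge <- (length(abs_perm) -
                  findInterval(cutoffs - 1e-12, abs_perm)) / n_perm
  fdr <- pmin(pmax(n_perm_ge / n_obs_ge, 0), 1)
  fdr <- cummin(fdr)  # enforce monotone non-increasing in the cutoff
  ok <- fdr <= fdr_target
  cutoff <- if (any(ok)) cutoffs[which(ok)[1]] else Inf
  significant <- abs_obs >= cutoff
  side <- ifelse(!significant, "none",
                 ifelse(mean_diff > 0, "up", "down"))
  features <- data.frame(
    feature = if (!is.null(rownames(mm))) rownames(mm) else
      as.character(seq_len(nrow(mm))),
    mean_diff = mean_diff, t_s0 = t_obs,
    significant = significant, side = side,
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(
    features = features, cutoff = cutoff,
    fdr_curve = data.frame(cutoff = cutoffs, fdr = fdr),
    s0 = s0, fdr_target = fdr_target, n_permutations = n_perm,
    seed = seed, n_excluded = n_excluded,
    n_up = sum(side == "up"), n_down = sum(side == "down")
  ), class = "diff_result")
}

#' @export
print.diff_result <- function(x, ...) {
  cat(sprintf(
    "diff_result: %d features, cutoff |t| >= %.3f at FDR <= %g (s0 = %g)\n",
    nrow(x$features), x$cutoff, x$fdr_target, x$s0))
  cat(sprintf("  significant: %d up, %d down (%d excluded pre-test)\n",
              x$n_up, x$n_down, x$n_excluded))
  invisible(x)
}

#' Per-side counts of significant features
#'
#' @param result a `diff_result` from [permutation_fdr()].
#' @return Named integer vector c(n_up =, n_down =).
#' @export
differential_counts <- function(result) {
  check_that(inherits(result, "diff_result"),
             "result must come from permutation_fdr")
  c(n_up = result$n_up, n_down = result$n_down)
}
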