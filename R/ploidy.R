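# Allele-frequency-spectrum ploidy inference: heterozygous-panel filtering,
# per-chromosome AF spectra, and a normal+uniform mixture with component
# means fixed at the k/m grid, selected across candidate ploidies by BIC.

#' Filter a panel to consistently heterozygous sites
#'
#' Keeps sites whose allele frequency lies in [af_low, af_high] in at least
#' `min_sample_frac` of the samples with positive depth at the site (the
#' boundary is inclusive on both the AF band and the sample fraction).
#'
#' @param panel a [variant_table()] with >= 1 sample.
#' @param af_low,af_high heterozygous AF band (defaults 0.25, 0.75).
#' @param min_sample_frac minimum fraction of covered samples inside the
#'   band (default 0.5).
#' @return Logical vector over `panel$sites` rows (TRUE = kept), with the
#'   filtered `variant_table` in attribute `table`.
#' @export
filter_het_panel <- function(panel, af_low = 0.25, af_high = 0.75,
                             min_sample_frac = 0.5) {
  check_that(inherits(panel, "variant_table"), "panel must be a variant_table")
  check_that(length(panel$samples) >= 1L && nrow(panel$sites) >= 1L,
             "panel is empty")
  check_that(af_low < af_high, "af_low must be below af_high")
  af <- panel$ad_alt / ifelse(panel$dp > 0, panel$dp, NA_real_)
  in_band <- !is.na(af) & af >= af_low & af <= af_high
  n_cov <- rowSums(panel$dp > 0)
  keep <- n_cov > 0 & rowSums(in_band) >= min_sample_frac * n_cov
  filtered <- variant_table(panel$sites[keep, , drop = FALSE],
                            panel$ad_ref[keep, , drop = FALSE],
                            panel$ad_alt[keep, , drop = FALSE],
                            panel$dp[keep, , drop = FALSE], panel$samples)
  structure(keep, table = filtered)
}

#' Per-chromosome allele-frequency spectra
#'
#' AF = ad_alt / dp per site for one sample. Sites with dp = 0 are dropped
#' (tallied per chromosome); AFs of exactly 0 or 1 are excluded from the
#' spectra — the mixture's interior peaks cannot host them — but remain in
#' the variant table for fixation analysis.
#'
#' @param table a [variant_table()].
#' @param sample sample name.
#' @return Named list per chromosome: `af` (values strictly inside (0,1)),
#'   `n_sites_used`, `n_zero_depth`, `n_boundary` (AF exactly 0 or 1).
#' @export
compute_af <- function(table, sample) {
  check_that(inherits(table, "variant_table"), "table must be a variant_table")
  check_that(sample %in% table$samples, "unknown sample '%s'", sample)
  dp <- table$dp[, sample]
  alt <- table$ad_alt[, sample]
  chrom <- table$sites$chrom
  out <- lapply(unique(chrom), function(ch) {
    i <- chrom == ch
    covered <- i & dp > 0
    af <- alt[covered] / dp[covered]
    interior <- af > 0 & af < 1
    list(af = af[interior],
         n_sites_used = sum(interior),
         n_zero_depth = sum(i & dp == 0),
         n_boundary = sum(!interior))
  })
  names(out) <- unique(chrom)
  out
}

#' Expected heterozygous AF peaks at a given ploidy
#'
#' For total copy number m, heterozygous allele fractions concentrate at
#' k/m for k = 1..m-1: 0.5 for diploid, 1/3 and 2/3 for triploid, and
#' 0.25, 0.5, 0.75 for tetraploid chromosomes.
#'
#' @param m candidate ploidy (integer >= 2).
#' @return Ascending vector of the m - 1 peak positions.
#' @export
expected_af_peaks <- function(m) {
  check_that(is_count(m, 2L), "ploidy m must be an integer >= 2")
  seq_len(m - 1) / m
}

# log density of a normal truncated to (0, 1)
log_dtruncnorm01 <- function(x, mean, sd) {
  z <- stats::pnorm(1, mean, sd) - stats::pnorm(0, mean, sd)
  stats::dnorm(x, mean, sd, log = TRUE) - log(z)
}

#' Fit a fixed-peak mixture to an AF spectrum
#'
#' Expectation-maximisation for a mixture of m - 1 normal components with
#' means fixed at k/m (truncated to (0,1) by renormalising the density), a
#' shared free standard deviation, free weights, plus one Uniform(0,1)
#' component absorbing background. The shared sigma is bounded above by
#' 0.15: heterozygous-peak widths are limited by binomial allele-sampling
#' noise at usable depths, and the bound keeps near-flat wide normals from
#' impersonating the uniform background. The sigma update maximises the
#' expected complete-data log-likelihood numerically (generalised EM), so
#' the log-likelihood is non-decreasing across iterations. BIC counts
#' m - 1 free weights plus sigma (the uniform weight is implied by
#' normalisation).
#'
#' @param af numeric vector of allele frequencies strictly inside (0,1)
#'   (e.g. one chromosome's spectrum from [compute_af()]), or one element of
#'   that list.
#' @param m candidate ploidy >= 2.
#' @param max_iter EM iteration cap (default 200).
#' @param tol absolute log-likelihood convergence tolerance (default 1e-6).
#' @return An object of class `ploidy_fit`: m, component_means,
#'   component_weights, sigma, uniform_weight, loglik, bic, n, n_iter,
#'   converged, loglik_trace.
#' @export
fit_af_mixture <- function(af, m, max_iter = 200L, tol = 1e-6) {
  if (is.list(af)) af <- af$af
  check_that(is.numeric(af) && all(af > 0 & af < 1),
             "af values must lie strictly inside (0, 1)")
  n <- length(af)
  check_that(n >= 50L,
             "need >= 50 AF values (have %d); consider pooling chromosomes", n)
  check_that(is_count(m, 2L), "ploidy m must be an integer >= 2")
  means <- expected_af_peaks(m)
  K <- length(means)
  w <- rep(0.9 / K, K)        # component weights
  w_u <- 0.1                  # uniform background weight
  sigma <- 0.05
  loglik_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # E-step: responsibilities (components + uniform, log-space)
    logd <- vapply(seq_len(K), function(k)
      log(w[k]) + log_dtruncnorm01(af, means[k], sigma), numeric(n))
    logd <- cbind(logd, log(w_u))  # uniform(0,1) has density 1
    mx <- apply(logd, 1, max)
    dens <- exp(logd - mx)
    rowsum_d <- rowSums(dens)
    ll <- sum(mx + log(rowsum_d))
    loglik_trace <- c(loglik_trace, ll)
    resp <- dens / rowsum_d
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
    # M-step: weights in closed form, sigma by 1-D maximisation of the
    # expected complete-data log-likelihood (cheap: depends on af only
    # through per-component responsibilities' sums)
    Nk <- colSums(resp)
    w <- pmax(Nk[seq_len(K)], 1e-12) / n
    w_u <- pmax(Nk[K + 1L], 1e-12) / n
    s <- sum(c(w, w_u)); w <- w / s; w_u <- w_u / s
    SSk <- vapply(seq_len(K), function(k)
      sum(resp[, k] * (af - means[k])^2), numeric(1))
    q_sigma <- function(sig) {
      sum(vapply(seq_len(K), function(k) {
        z <- stats::pnorm(1, means[k], sig) - stats::pnorm(0, means[k], sig)
        -Nk[k] * (log(sig) + log(z)) - SSk[k] / (2 * sig^2)
      }, numeric(1)))
    }
    sigma <- stats::optimize(q_sigma, c(1e-4, 0.15), maximum = TRUE)$maximum
  }
  p <- K + 1L  # free parameters: K weights + sigma
  structure(list(m = as.integer(m), component_means = means,
                 component_weights = w, sigma = sigma, uniform_weight = w_u,
                 loglik = ll, bic = -2 * ll + p * log(n), n = n,
                 n_iter = length(loglik_trace), converged = converged,
                 loglik_trace = loglik_trace),
            class = "ploidy_fit")
}

#' @export
print.ploidy_fit <- function(x, ...) {
  cat(sprintf(
    "ploidy_fit m=%d: sigma %.4f, uniform %.3f, loglik %.2f, BIC %.2f (n=%d)\n",
    x$m, x$sigma, x$uniform_weight, x$loglik, x$bic, x$n))
  invisible(x)
}

#' Classify per-chromosome ploidy from an AF spectrum
#'
#' For each chromosome of one sample: drop low-coverage sites (whose allele
#' fractions are too noisy to resolve adjacent k/m peaks), subsample up to
#' `n_subsample` AF values without replacement (seeded, reproducible), fit
#' the fixed-peak mixture for every candidate ploidy, and pick the best
#' model by BIC with a parsimony rule: the smallest candidate within
#' `bic_margin` of the minimum BIC wins, so extra peak components must earn
#' decisively better fit (the conventional "very strong evidence" threshold
#' of 10 BIC units) before a higher ploidy is called. Exact ties therefore
#' also resolve toward the smaller ploidy.
#'
#' @param table a [variant_table()].
#' @param sample sample name.
#' @param candidates candidate ploidies (default c(2, 3, 4)).
#' @param n_subsample per-chromosome AF subsample size (default 10000).
#' @param seed integer seed for the subsampling.
#' @param min_sites chromosomes with fewer interior AF values are skipped
#'   with an NA call (default 50, the mixture's minimum).
#' @param min_depth_frac sites below this fraction of the sample's median
#'   positive depth are excluded from spectra (default 0.5).
#' @param bic_margin BIC parsimony margin in favour of smaller ploidies
#'   (default 10).
#' @return An object of class `ploidy_call`: `calls` data.frame (chrom,
#'   best_m, delta_bic, n_sites) plus `bic` matrix (chrom x candidate) and
#'   the per-fit objects.
#' @export
select_ploidy <- function(table, sample, candidates = c(2L, 3L, 4L),
                          n_subsample = 10000L, seed = 1L, min_sites = 50L,
                          min_depth_frac = 0.5, bic_margin = 10) {
  check_that(length(candidates) >= 1L, "candidates must be nonempty")
  candidates <- sort(unique(as.integer(candidates)))
  check_that(sample %in% table$samples, "unknown sample '%s'", sample)
  dp <- table$dp[, sample]
  min_dp <- min_depth_frac * stats::median(dp[dp > 0])
  keep <- dp >= min_dp
  filtered <- variant_table(table$sites[keep, , drop = FALSE],
                            table$ad_ref[keep, , drop = FALSE],
                            table$ad_alt[keep, , drop = FALSE],
                            table$dp[keep, , drop = FALSE], table$samples)
  spectra <- compute_af(filtered, sample)
  chroms <- names(spectra)
  bic <- matrix(NA_real_, length(chroms), length(candidates),
                dimnames = list(chroms, paste0("m", candidates)))
  fits <- vector("list", length(chroms))
  names(fits) <- chroms
  calls <- data.frame(chrom = chroms, best_m = NA_integer_,
                      delta_bic = NA_real_, n_sites = NA_integer_,
                      stringsAsFactors = FALSE)
  for (ci in seq_along(chroms)) {
    af <- spectra[[ci]]$af
    if (length(af) > n_subsample) {
      af <- with_seed(derive_seed(seed, paste0("subsample:", chroms[ci])),
                      sample(af, n_subsample))
    }
    calls$n_sites[ci] <- length(af)
    if (length(af) < min_sites) next
    fit_list <- lapply(candidates, function(m) fit_af_mixture(af, m))
    names(fit_list) <- paste0("m", candidates)
    fits[[ci]] <- fit_list
    bic[ci, ] <- vapply(fit_list, `[[`, numeric(1), "bic")
    # smallest m within the parsimony margin of the minimum BIC
    best <- which(bic[ci, ] <= min(bic[ci, ]) + bic_margin)[1]
    calls$best_m[ci] <- candidates[best]
    if (length(candidates) > 1L) {
      calls$delta_bic[ci] <- sort(bic[ci, ] - min(bic[ci, ]))[2]
    }
  }
  structure(list(sample = sample, calls = calls, bic = bic, fits = fits,
                 candidates = candidates, n_subsample = n_subsample,
                 seed = seed),
            class = "ploidy_call")
}

#' @export
print.ploidy_call <- function(x, ...) {
  cat(sprintf("ploidy_call for sample %s:\n", x$sample))
  print(x$calls)
  invisible(x)
}
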