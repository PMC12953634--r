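#' Variant table
#'
#' The package's in-memory container for per-site, per-sample allele depths:
#' a site data.frame (chrom, pos, ref, alt; pos 1-based, sorted within
#' chromosome) plus integer matrices `ad_ref`, `ad_alt` and `dp` with one
#' column per sample.
#'
#' @param sites data.frame with columns chrom, pos, ref, alt.
#' @param ad_ref,ad_alt,dp integer matrices, rows = sites, cols = samples.
#' @param samples character vector of sample names (column order).
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(sites, ad_ref, ad_alt, dp, samples) {
  check_that(is.data.frame(sites) &&
               all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
             "sites needs columns chrom, pos, ref, alt")
  ad_ref <- as.matrix(ad_ref); ad_alt <- as.matrix(ad_alt); dp <- as.matrix(dp)
  n <- nrow(sites)
  check_that(nrow(ad_ref) == n && nrow(ad_alt) == n && nrow(dp) == n,
             "depth matrices must have one row per site")
  check_that(ncol(ad_ref) == length(samples) && ncol(dp) == length(samples),
             "depth matrices must have one column per sample")
  check_that(all(ad_ref >= 0) && all(ad_alt >= 0) && all(dp >= 0),
             "allele depths must be non-negative")
  check_that(all(ad_ref + ad_alt <= dp),
             "ad_ref + ad_alt must not exceed dp")
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, c("chrom", "pos", "ref", "alt"), drop = FALSE]
  rownames(sites) <- NULL
  colnames(ad_ref) <- colnames(ad_alt) <- colnames(dp) <- samples
  structure(list(sites = sites,
                 ad_ref = ad_ref[ord, , drop = FALSE],
                 ad_alt = ad_alt[ord, , drop = FALSE],
                 dp = dp[ord, , drop = FALSE],
                 samples = as.character(samples)),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d site(s) x %d sample(s) [%s]\n",
              nrow(x$sites), length(x$samples),
              paste(x$samples, collapse = ", ")))
  invisible(x)
}

#' Number of sites in a variant table
#' @param table a `variant_table`.
#' @return Integer site count.
#' @export
n_sites <- function(table) {
  check_that(inherits(table, "variant_table"), "table must be a variant_table")
  nrow(table$sites)
}

site_key <- function(sites) {
  paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = ":")
}

#' Merge variant tables over the union of their sites
#'
#' Outer join by (chrom, pos, ref, alt). Sites absent from a table get
#' ad_ref = ad_alt = dp = 0 for that table's samples (no reads observed).
#'
#' @param tables list of `variant_table` objects with disjoint sample names.
#' @return A single `variant_table` over the union of sites.
#' @export
merge_variant_tables <- function(tables) {
  check_that(length(tables) >= 1L, "need at least one table")
  for (t in tables) check_that(inherits(t, "variant_table"),
                               "all inputs must be variant_table objects")
  samples <- unlist(lapply(tables, `[[`, "samples"))
  check_that(!anyDuplicated(samples), "sample names must be distinct")
  all_sites <- unique(do.call(rbind, lapply(tables, `[[`, "sites")))
  all_sites <- all_sites[order(all_sites$chrom, all_sites$pos), , drop = FALSE]
  rownames(all_sites) <- NULL
  key <- site_key(all_sites)
  n <- nrow(all_sites)
  mk <- function() matrix(0L, n, length(samples), dimnames = list(NULL, samples))
  ad_ref <- mk(); ad_alt <- mk(); dp <- mk()
  for (t in tables) {
    idx <- match(site_key(t$sites), key)
    ad_ref[idx, t$samples] <- t$ad_ref
    ad_alt[idx, t$samples] <- t$ad_alt
    dp[idx, t$samples] <- t$dp
  }
  variant_table(all_sites, ad_ref, ad_alt, dp, samples)
}
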