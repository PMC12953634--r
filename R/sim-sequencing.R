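# Sequencing-level simulation: allele depths at SNV and panel sites, and
# windowed read counts proportional to local copy number.

# nominal read length used to convert per-site depth into window read counts
READ_LENGTH_BP <- 150

#' Simulate germline-like heterozygous panel sites
#'
#' Draws `n_het_sites_per_chrom` positions per chromosome, uniformly at
#' random. These emulate a fixed panel of sites heterozygous in (nearly) all
#' samples, the substrate for B-allele-frequency spectra; at sequencing time
#' each sample carries the alternate allele on k of its local m copies with k
#' uniform on 1..m-1, so expected allele fractions sit on the k/m grid.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns chrom, pos, ref, alt.
#' @export
simulate_panel_sites <- function(config) {
  check_that(inherits(config, "sim_config"), "config must be a sim_config")
  with_seed(derive_seed(config$seed, "panel_sites"), {
    per <- config$n_het_sites_per_chrom
    if (per == 0L) {
      return(data.frame(chrom = character(), pos = numeric(),
                        ref = character(), alt = character(),
                        stringsAsFactors = FALSE))
    }
    out <- lapply(seq_len(nrow(config$chromosomes)), function(i) {
      random_snv_positions(config$chromosomes[i, , drop = FALSE], per)
    })
    sites <- do.call(rbind, out)
    al <- random_alleles(nrow(sites))
    data.frame(chrom = sites$chrom, pos = sites$pos, ref = al$ref,
               alt = al$alt, stringsAsFactors = FALSE)
  })
}

#' Simulate sequencing of a clone
#'
#' Emulates the observable layer of whole-genome sequencing for one clone:
#'
#' * per site (panel sites plus the clone's somatic SNVs), total depth DP is
#'   negative-binomial with mean `mean_depth * total_copies / base_ploidy`
#'   and dispersion `depth_dispersion`; the alternate depth is binomial
#'   (beta-binomial when `af_overdispersion > 0`) with success probability
#'   `alt_copies / total_copies`;
#' * per `window_size_bp` window, a read count that is negative-binomial with
#'   mean proportional to the length-weighted mean copy number of the window.
#'
#' Panel sites receive a per-sample allele configuration k/m with k uniform
#' on 1..m-1 given the local total copy number m. Sites on zero-copy
#' regions get `ad_alt = 0` and are flagged in the `zero_copy_sites`
#' attribute. Output is deterministic given `config$seed` and `sample_name`.
#'
#' @param clone a `clone_genome`.
#' @param panel_sites data.frame (chrom, pos, ref, alt) from
#'   [simulate_panel_sites()], or NULL for none.
#' @param config a [sim_config()].
#' @param sample_name text label; part of the random stream's seed.
#' @return list with `variants` (a [variant_table()] with one sample) and
#'   `windows` (data.frame chrom, start, end, count, gc; 0-based half-open).
#' @export
sample_sequencing <- function(clone, panel_sites, config, sample_name) {
  check_that(inherits(clone, "clone_genome"), "clone must be a clone_genome")
  check_that(inherits(config, "sim_config"), "config must be a sim_config")
  check_that(is.character(sample_name) && length(sample_name) == 1L,
             "sample_name must be a single string")
  if (is.null(panel_sites)) {
    panel_sites <- data.frame(chrom = character(), pos = numeric(),
                              ref = character(), alt = character(),
                              stringsAsFactors = FALSE)
  }
  seed <- derive_seed(config$seed, paste0("sequencing:", sample_name))
  with_seed(seed, {
    # --- site table: panel sites then somatic SNVs -------------------------
    n_pan <- nrow(panel_sites)
    snvs <- clone$snvs
    sites <- rbind(
      panel_sites[, c("chrom", "pos", "ref", "alt")],
      snvs[, c("chrom", "pos", "ref", "alt")]
    )
    total <- integer(0)
    altc <- integer(0)
    if (nrow(sites)) {
      tc_pan <- if (n_pan) segment_copies_at(clone$segments, panel_sites$chrom,
                                             panel_sites$pos) else integer()
      k_pan <- ifelse(tc_pan >= 2L,
                      1L + floor(stats::runif(n_pan) * pmax(tc_pan - 1L, 1L)),
                      ifelse(tc_pan == 1L, 1L, 0L))
      total <- c(tc_pan, snvs$total_copies)
      altc <- c(as.integer(k_pan), snvs$alt_copies)
    }
    n <- nrow(sites)
    mu <- config$mean_depth * total / config$base_ploidy
    dp <- rnbinom_disp(n, mu, config$depth_dispersion)
    p_alt <- ifelse(total > 0L, altc / pmax(total, 1L), 0)
    ad_alt <- rbetabinom(n, dp, p_alt, config$af_overdispersion)
    ad_alt[total == 0L] <- 0L
    ad_ref <- dp - ad_alt
    vt <- variant_table(sites, ad_ref, ad_alt, dp, sample_name)
    ord <- order(sites$chrom, sites$pos)
    attr(vt, "zero_copy_sites") <- which((total == 0L)[ord])
    # --- windowed read counts ---------------------------------------------
    windows <- make_windows(clone$segments, config$window_size_bp)
    cn <- window_mean_copies(clone$segments, windows)
    base_mu <- config$mean_depth * (windows$end - windows$start) / READ_LENGTH_BP
    wmu <- base_mu * cn / config$base_ploidy
    windows$count <- rnbinom_disp(nrow(windows), wmu, config$depth_dispersion)
    windows$gc <- round(stats::runif(nrow(windows), 0.35, 0.55), 4)
    list(variants = vt, windows = windows)
  })
}

# Tile each chromosome with fixed-width windows (terminal window shorter).
make_windows <- function(segments, window_size_bp) {
  chrs <- unique(segments$chrom)
  out <- lapply(chrs, function(ch) {
    len <- max(segments$end[segments$chrom == ch])
    start <- seq(0, len - 1, by = window_size_bp)
    data.frame(chrom = ch, start = start,
               end = pmin(start + window_size_bp, len),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# Length-weighted mean total copy number of each window.
window_mean_copies <- function(segments, windows) {
  cn <- numeric(nrow(windows))
  for (ch in unique(windows$chrom)) {
    seg <- segments[segments$chrom == ch, , drop = FALSE]
    idx <- which(windows$chrom == ch)
    for (i in idx) {
      ov_start <- pmax(seg$start, windows$start[i])
      ov_end <- pmin(seg$end, windows$end[i])
      w <- pmax(ov_end - ov_start, 0)
      cn[i] <- sum(w * seg$total_copies) / (windows$end[i] - windows$start[i])
    }
  }
  cn
}

#' Inject a GC-content bias into window counts
#'
#' Multiplies each window's count by `1 + slope * (gc - mean(gc))`, the
#' canonical unimodal-free linear distortion used to exercise GC correction.
#'
#' @param windows window-count data.frame with a `gc` column.
#' @param slope strength of the linear GC effect.
#' @return The data.frame with distorted (real-valued) counts.
#' @export
apply_gc_bias <- function(windows, slope) {
  check_that("gc" %in% names(windows), "windows must carry a gc column")
  f <- 1 + slope * (windows$gc - mean(windows$gc))
  check_that(all(f > 0), "bias slope too strong: non-positive scale factor")
  windows$count <- windows$count * f
  windows
}
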