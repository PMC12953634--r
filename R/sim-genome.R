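#' Simulation configuration
#'
#' Bundles every knob of the synthetic tumour-clone generator: the genome
#' layout, the parental ploidy, sequencing depth and its overdispersion, and
#' the number of germline-like heterozygous panel sites and somatic SNVs.
#'
#' Defaults describe a clonal tumour sequenced at 60x with mild
#' negative-binomial overdispersion and 50 kbp read-count windows; 10,000
#' heterozygous panel sites per chromosome match the per-chromosome
#' subsampling depth used for allele-frequency-spectrum ploidy fits.
#'
#' @param seed integer; fully determines every downstream draw.
#' @param chromosomes data.frame with columns `name` and `length_bp`.
#' @param base_ploidy integer parental ploidy (default 2).
#' @param window_size_bp read-count window width in bp (default 50000).
#' @param mean_depth expected per-site read depth at `base_ploidy` copies.
#' @param depth_dispersion negative-binomial dispersion phi (Var = mu + phi mu^2).
#' @param af_overdispersion beta-binomial intraclass rho for allele depths;
#'   0 gives pure binomial sampling.
#' @param n_het_sites_per_chrom heterozygous panel sites per chromosome.
#' @param n_somatic_snvs somatic SNVs placed on the parental clone.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed,
                       chromosomes = data.frame(
                         name = c("1", "2"),
                         length_bp = c(2e7, 2e7),
                         stringsAsFactors = FALSE
                       ),
                       base_ploidy = 2L,
                       window_size_bp = 50000L,
                       mean_depth = 60,
                       depth_dispersion = 0.01,
                       af_overdispersion = 0,
                       n_het_sites_per_chrom = 10000L,
                       n_somatic_snvs = 2000L) {
  check_that(is_count(seed, 0L), "seed must be a non-negative integer")
  check_that(is.data.frame(chromosomes) &&
               all(c("name", "length_bp") %in% names(chromosomes)),
             "chromosomes must be a data.frame with columns name, length_bp")
  check_that(nrow(chromosomes) >= 1L, "at least one chromosome is required")
  check_that(all(chromosomes$length_bp > 0),
             "all chromosome lengths must be positive")
  check_that(is_count(base_ploidy, 1L), "base_ploidy must be a positive integer")
  check_that(is_count(window_size_bp, 1L), "window_size_bp must be positive")
  check_that(is.numeric(mean_depth) && mean_depth > 0, "mean_depth must be > 0")
  check_that(is.numeric(depth_dispersion) && depth_dispersion >= 0,
             "depth_dispersion must be >= 0")
  check_that(is.numeric(af_overdispersion) &&
               af_overdispersion >= 0 && af_overdispersion < 1,
             "af_overdispersion must lie in [0, 1)")
  check_that(is_count(n_het_sites_per_chrom, 0L),
             "n_het_sites_per_chrom must be a non-negative integer")
  check_that(is_count(n_somatic_snvs, 0L),
             "n_somatic_snvs must be a non-negative integer")
  structure(list(
    seed = as.integer(seed),
    chromosomes = data.frame(name = as.character(chromosomes$name),
                             length_bp = as.numeric(chromosomes$length_bp),
                             stringsAsFactors = FALSE),
    base_ploidy = as.integer(base_ploidy),
    window_size_bp = as.integer(window_size_bp),
    mean_depth = mean_depth,
    depth_dispersion = depth_dispersion,
    af_overdispersion = af_overdispersion,
    n_het_sites_per_chrom = as.integer(n_het_sites_per_chrom),
    n_somatic_snvs = as.integer(n_somatic_snvs)
  ), class = "sim_config")
}

#' Resistance event set
#'
#' Describes how a resistant derivative differs from its parental clone:
#' optional whole-genome duplication, segmental copy-number events, and counts
#' of gained, lost and fixated somatic SNVs.
#'
#' @param whole_genome_duplication logical; double every copy number first.
#' @param segmental_events data.frame with columns `chrom`, `start_bp`,
#'   `end_bp` (0-based half-open) and `delta_copies`; applied after WGD.
#' @param snv_gains number of novel SNVs acquired at one copy.
#' @param snv_losses number of existing SNVs dropped to zero copies.
#' @param snv_fixations number of SNVs raised to all copies at their site.
#' @return An object of class `resistance_events`.
#' @export
resistance_events <- function(whole_genome_duplication = FALSE,
                              segmental_events = NULL,
                              snv_gains = 0L,
                              snv_losses = 0L,
                              snv_fixations = 0L) {
  if (is.null(segmental_events)) {
    segmental_events <- data.frame(chrom = character(), start_bp = numeric(),
                                   end_bp = numeric(), delta_copies = integer(),
                                   stringsAsFactors = FALSE)
  }
  check_that(is.logical(whole_genome_duplication) &&
               length(whole_genome_duplication) == 1L,
             "whole_genome_duplication must be a single logical")
  check_that(all(c("chrom", "start_bp", "end_bp", "delta_copies") %in%
                   names(segmental_events)),
             "segmental_events needs columns chrom, start_bp, end_bp, delta_copies")
  check_that(all(segmental_events$end_bp > segmental_events$start_bp),
             "segmental events must have end_bp > start_bp")
  check_that(is_count(snv_gains, 0L) && is_count(snv_losses, 0L) &&
               is_count(snv_fixations, 0L),
             "SNV event counts must be non-negative integers")
  structure(list(
    whole_genome_duplication = whole_genome_duplication,
    segmental_events = segmental_events,
    snv_gains = as.integer(snv_gains),
    snv_losses = as.integer(snv_losses),
    snv_fixations = as.integer(snv_fixations)
  ), class = "resistance_events")
}

new_clone_genome <- function(segments, snvs) {
  structure(list(segments = segments, snvs = snvs), class = "clone_genome")
}

#' @export
print.clone_genome <- function(x, ...) {
  cat(sprintf("clone_genome: %d segment(s) on %d chromosome(s), %d SNV(s)\n",
              nrow(x$segments), length(unique(x$segments$chrom)),
              nrow(x$snvs)))
  invisible(x)
}

BASES <- c("A", "C", "G", "T")

random_snv_positions <- function(chromosomes, n, used = NULL) {
  # uniform over the concatenated genome, unique per chromosome
  probs <- chromosomes$length_bp / sum(chromosomes$length_bp)
  n_per <- as.vector(stats::rmultinom(1, n, probs))
  out <- vector("list", nrow(chromosomes))
  for (i in seq_len(nrow(chromosomes))) {
    if (n_per[i] == 0L) next
    avoid <- used$pos[used$chrom == chromosomes$name[i]]
    pos <- unique(ceiling(stats::runif(n_per[i] * 2L) * chromosomes$length_bp[i]))
    pos <- setdiff(pos, avoid)
    while (length(pos) < n_per[i]) {
      extra <- ceiling(stats::runif(n_per[i]) * chromosomes$length_bp[i])
      pos <- setdiff(unique(c(pos, extra)), avoid)
    }
    pos <- sort(pos[seq_len(n_per[i])])
    out[[i]] <- data.frame(chrom = chromosomes$name[i], pos = pos,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

random_alleles <- function(n) {
  ref <- BASES[sample.int(4L, n, replace = TRUE)]
  shift <- sample.int(3L, n, replace = TRUE)
  alt <- BASES[(match(ref, BASES) - 1L + shift) %% 4L + 1L]
  list(ref = ref, alt = alt)
}

#' Simulate a parental tumour clone
#'
#' Builds a clonal genome at the configured base ploidy: one copy-number
#' segment per chromosome and `n_somatic_snvs` somatic SNVs placed uniformly
#' at random, each carried on 1 to `base_ploidy` copies.
#'
#' @param config a [sim_config()].
#' @return A `clone_genome`: `$segments` (chrom, start, end, total_copies;
#'   0-based half-open) and `$snvs` (chrom, pos — 1-based, ref, alt,
#'   alt_copies, total_copies).
#' @export
simulate_parental <- function(config) {
  check_that(inherits(config, "sim_config"), "config must be a sim_config")
  chrs <- config$chromosomes
  segments <- data.frame(chrom = chrs$name, start = 0,
                         end = chrs$length_bp,
                         total_copies = config$base_ploidy,
                         stringsAsFactors = FALSE)
  snvs <- with_seed(derive_seed(config$seed, "parental_snvs"), {
    if (config$n_somatic_snvs == 0L) {
      data.frame(chrom = character(), pos = numeric(), ref = character(),
                 alt = character(), alt_copies = integer(),
                 total_copies = integer(), stringsAsFactors = FALSE)
    } else {
      sites <- random_snv_positions(chrs, config$n_somatic_snvs)
      al <- random_alleles(nrow(sites))
      data.frame(chrom = sites$chrom, pos = sites$pos,
                 ref = al$ref, alt = al$alt,
                 alt_copies = sample.int(config$base_ploidy, nrow(sites),
                                         replace = TRUE),
                 total_copies = config$base_ploidy,
                 stringsAsFactors = FALSE)
    }
  })
  new_clone_genome(segments, snvs)
}

# Split segment rows of one chromosome at the given breakpoints.
split_segments_at <- function(segments, chrom, breaks) {
  rows <- segments$chrom == chrom
  seg <- segments[rows, , drop = FALSE]
  breaks <- sort(unique(breaks))
  for (b in breaks) {
    hit <- which(seg$start < b & seg$end > b)
    if (length(hit) == 1L) {
      left <- seg[hit, , drop = FALSE]; right <- left
      left$end <- b; right$start <- b
      seg <- rbind(seg[seq_len(hit - 1L), , drop = FALSE], left, right,
                   seg[-seq_len(hit), , drop = FALSE])
    }
  }
  seg <- seg[order(seg$start), , drop = FALSE]
  out <- rbind(segments[!rows, , drop = FALSE], seg)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Derive a resistant clone from a parental clone
#'
#' Applies, in order: whole-genome duplication (doubling every segment's
#' total copies and every SNV's alt and total copies, which leaves expected
#' allele fractions unchanged), segmental copy-number events (segments are
#' split at event boundaries; under a loss the surviving copies carrying the
#' alternate allele are drawn hypergeometrically, under a gain duplicated
#' copies are drawn likewise), then SNV gains (novel sites at one copy),
#' losses (alt copies set to 0) and fixations (alt copies raised to the site
#' total). Losses and fixations pick disjoint random subsets of SNVs with
#' 0 < alt_copies < total_copies.
#'
#' @param parental a `clone_genome`.
#' @param events a [resistance_events()].
#' @param seed integer controlling every random choice in the derivation.
#' @return A `clone_genome` for the resistant derivative.
#' @export
derive_resistant <- function(parental, events, seed) {
  check_that(inherits(parental, "clone_genome"), "parental must be a clone_genome")
  check_that(inherits(events, "resistance_events"),
             "events must be a resistance_events")
  segments <- parental$segments
  snvs <- parental$snvs
  with_seed(derive_seed(seed, "derive_resistant"), {
    if (events$whole_genome_duplication) {
      segments$total_copies <- segments$total_copies * 2L
      snvs$alt_copies <- snvs$alt_copies * 2L
      snvs$total_copies <- snvs$total_copies * 2L
    }
    ev <- events$segmental_events
    for (i in seq_len(nrow(ev))) {
      segments <- split_segments_at(segments, ev$chrom[i],
                                    c(ev$start_bp[i], ev$end_bp[i]))
      hit <- segments$chrom == ev$chrom[i] &
        segments$start >= ev$start_bp[i] & segments$end <= ev$end_bp[i]
      new_cn <- segments$total_copies[hit] + ev$delta_copies[i]
      if (any(new_cn < 0)) {
        stop(sprintf("segmental event %d on chromosome %s would produce negative copy number",
                     i, ev$chrom[i]), call. = FALSE)
      }
      old_cn <- segments$total_copies[hit]
      segments$total_copies[hit] <- new_cn
      # re-draw allele configuration of covered SNVs
      in_ev <- snvs$chrom == ev$chrom[i] & snvs$pos > ev$start_bp[i] &
        snvs$pos <= ev$end_bp[i]
      if (any(in_ev)) {
        t_old <- snvs$total_copies[in_ev]
        a_old <- snvs$alt_copies[in_ev]
        t_new <- t_old + ev$delta_copies[i]
        if (ev$delta_copies[i] < 0) {
          # survivors drawn without replacement from the old copies
          a_new <- stats::rhyper(length(t_old), a_old, t_old - a_old, t_new)
        } else {
          # each event duplicates delta distinct existing copies
          dup <- stats::rhyper(length(t_old), a_old, t_old - a_old,
                               pmin(ev$delta_copies[i], t_old))
          a_new <- a_old + dup
        }
        snvs$alt_copies[in_ev] <- a_new
        snvs$total_copies[in_ev] <- t_new
      }
    }
    # novel SNV gains at one copy, before losses/fixations so those can
    # also strike newly gained variants
    if (events$snv_gains > 0L) {
      chrs <- data.frame(name = unique(segments$chrom),
                         length_bp = tapply(segments$end, segments$chrom, max)[
                           unique(segments$chrom)],
                         stringsAsFactors = FALSE)
      sites <- random_snv_positions(chrs, events$snv_gains, used = snvs)
      al <- random_alleles(nrow(sites))
      tc <- segment_copies_at(segments, sites$chrom, sites$pos)
      gained <- data.frame(chrom = sites$chrom, pos = sites$pos,
                           ref = al$ref, alt = al$alt,
                           alt_copies = ifelse(tc > 0L, 1L, 0L),
                           total_copies = tc, stringsAsFactors = FALSE)
      snvs <- rbind(snvs, gained)
    }
    # SNV losses then fixations on disjoint random subsets
    eligible <- which(snvs$alt_copies > 0L & snvs$alt_copies < snvs$total_copies)
    check_that(events$snv_losses + events$snv_fixations <= length(eligible),
               "snv_losses + snv_fixations (%d) exceed eligible SNVs (%d)",
               events$snv_losses + events$snv_fixations, length(eligible))
    picked <- if (length(eligible))
      sample(eligible, events$snv_losses + events$snv_fixations) else integer()
    lose <- utils::head(picked, events$snv_losses)
    fix <- utils::tail(picked, events$snv_fixations)
    snvs$alt_copies[lose] <- 0L
    snvs$alt_copies[fix] <- snvs$total_copies[fix]
    snvs <- snvs[order(snvs$chrom, snvs$pos), , drop = FALSE]
    rownames(snvs) <- NULL
    new_clone_genome(segments, snvs)
  })
}

# Total copy number of the segment covering each (chrom, pos) pair
# (pos is 1-based; segments are 0-based half-open).
segment_copies_at <- function(segments, chrom, pos) {
  out <- integer(length(chrom))
  for (ch in unique(chrom)) {
    seg <- segments[segments$chrom == ch, , drop = FALSE]
    idx <- which(chrom == ch)
    j <- findInterval(pos[idx] - 1, seg$start)
    bad <- j < 1L | pos[idx] > seg$end[pmax(j, 1L)]
    check_that(!any(bad), "position(s) outside segments on chromosome %s", ch)
    out[idx] <- seg$total_copies[j]
  }
  out
}
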