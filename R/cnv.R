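# Windowed copy-number profiling: median-normalised ratios, GC correction,
# recursive binary segmentation and gain/loss calling.

#' Window counts to copy-number ratios
#'
#' ratio_i = count_i / median(counts) * ploidy, where the genome-wide median
#' is taken over autosomal windows with non-zero counts (the female/XX
#' convention: Y windows are dropped at read time and X windows are excluded
#' from the median but still receive ratios).
#'
#' @param counts window-count data.frame (chrom, start, end, count[, gc]).
#' @param ploidy integer normalisation ploidy of the sample.
#' @return An object of class `cn_track`: the windows with a `ratio` column;
#'   attributes `ploidy` and `median_count`.
#' @export
count_to_ratio <- function(counts, ploidy) {
  check_that(is.data.frame(counts) &&
               all(c("chrom", "start", "end", "count") %in% names(counts)),
             "counts needs columns chrom, start, end, count")
  check_that(is_count(ploidy, 1L), "ploidy must be a positive integer")
  counts <- counts[!is_y_chrom(counts$chrom), , drop = FALSE]
  usable <- counts$count > 0 & !is_x_chrom(counts$chrom)
  check_that(any(usable),
             "no non-zero autosomal window counts: cannot normalise")
  med <- stats::median(counts$count[usable])
  counts$ratio <- counts$count / med * ploidy
  structure(counts, class = c("cn_track", "data.frame"),
            ploidy = as.integer(ploidy), median_count = med)
}

#' GC-content correction of window counts
#'
#' Windows are binned by GC fraction into `n_bins` bins of equal GC width
#' over the observed range; each bin's counts are rescaled by
#' (global median) / (bin median). Bins holding fewer than 20 windows are
#' left unscaled (too few observations to estimate a bias).
#'
#' @param counts window-count data.frame with a `gc` column.
#' @param n_bins number of equal-width GC bins (default 20).
#' @param min_bin_windows minimum windows per bin for rescaling (default 20).
#' @return The window-count data.frame with corrected (real-valued) counts.
#' @export
gc_correct <- function(counts, n_bins = 20L, min_bin_windows = 20L) {
  check_that("gc" %in% names(counts),
             "no gc column present: skip GC correction for this input")
  check_that(is_count(n_bins, 1L), "n_bins must be a positive integer")
  nz <- counts$count > 0
  rng <- range(counts$gc)
  if (diff(rng) == 0) return(counts)  # single GC value: nothing to correct
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- cut(counts$gc, breaks, include.lowest = TRUE, labels = FALSE)
  global_med <- stats::median(counts$count[nz])
  for (b in unique(bin)) {
    in_bin <- bin == b & nz
    if (sum(in_bin) < min_bin_windows) next
    bin_med <- stats::median(counts$count[in_bin])
    if (bin_med > 0) {
      counts$count[bin == b] <- counts$count[bin == b] * global_med / bin_med
    }
  }
  counts
}

# Best split of a numeric vector by two-sided mean-difference z-score.
# The noise scale is estimated from first differences (sd(diff)/sqrt(2)),
# which is insensitive to the level shifts being searched for.
best_split <- function(x, min_windows) {
  n <- length(x)
  if (n < 2L * min_windows) return(NULL)
  cs <- cumsum(x)
  i <- seq(min_windows, n - min_windows)
  mean_l <- cs[i] / i
  mean_r <- (cs[n] - cs[i]) / (n - i)
  s <- stats::sd(diff(x)) / sqrt(2)
  if (!is.finite(s) || s == 0) return(NULL)
  z <- abs(mean_l - mean_r) / (s * sqrt(1 / i + 1 / (n - i)))
  k <- which.max(z)
  list(at = i[k], z = z[k])
}

# Backfitting pass: re-locate each internal breakpoint by the max-|z|
# split within the union of its two flanking segments. Recursive splitting
# can misplace a boundary when a candidate segment still holds two
# change-points; refitting each boundary against its immediate neighbours
# removes that bias. Iterated to a fixed point (bounded).
refine_breakpoints <- function(x, segs, min_windows) {
  if (nrow(segs) < 2L) return(segs)
  for (pass in 1:5) {
    moved <- FALSE
    for (i in seq_len(nrow(segs) - 1L)) {
      lo <- segs$first[i]; hi <- segs$last[i + 1L]
      sp <- best_split(x[lo:hi], min_windows)
      if (is.null(sp)) next
      new_last <- lo + sp$at - 1L
      if (new_last != segs$last[i]) {
        segs$last[i] <- new_last
        segs$first[i + 1L] <- new_last + 1L
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  segs
}

segment_recurse <- function(x, offset, min_windows, z_threshold) {
  sp <- best_split(x, min_windows)
  if (is.null(sp) || sp$z <= z_threshold) {
    return(data.frame(first = offset + 1L, last = offset + length(x)))
  }
  rbind(
    segment_recurse(x[seq_len(sp$at)], offset, min_windows, z_threshold),
    segment_recurse(x[-seq_len(sp$at)], offset + sp$at, min_windows,
                    z_threshold)
  )
}

#' Segment a copy-number track
#'
#' Recursive binary segmentation per chromosome on the window ratios: each
#' candidate segment is split at the position maximising the two-sided
#' mean-difference z-score, provided the score exceeds `z_threshold` and
#' both sides keep at least `min_windows` windows. Deterministic and
#' seed-free. Each segment's `mean_ratio` is the median of its member
#' windows' ratios.
#'
#' @param track a `cn_track` from [count_to_ratio()].
#' @param min_windows minimum windows per segment (default 5).
#' @param z_threshold split acceptance threshold (default 6).
#' @return data.frame of segments: chrom, start, end, mean_ratio, n_windows.
#' @export
segment_track <- function(track, min_windows = 5L, z_threshold = 6) {
  check_that(inherits(track, "cn_track"), "track must come from count_to_ratio")
  check_that(is_count(min_windows, 1L), "min_windows must be >= 1")
  check_that(nrow(track) > 0L, "track is empty")
  out <- lapply(unique(track$chrom), function(ch) {
    w <- track[track$chrom == ch, , drop = FALSE]
    segs <- segment_recurse(w$ratio, 0L, min_windows, z_threshold)
    segs <- refine_breakpoints(w$ratio, segs, min_windows)
    data.frame(
      chrom = ch,
      start = w$start[segs$first],
      end = w$end[segs$last],
      mean_ratio = vapply(seq_len(nrow(segs)), function(i)
        stats::median(w$ratio[segs$first[i]:segs$last[i]]), numeric(1)),
      n_windows = segs$last - segs$first + 1L,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Call gain/loss states on segments
#'
#' state = "gain" when mean_ratio > ploidy + margin, "loss" when
#' mean_ratio < ploidy - margin, "neutral" otherwise; the integer copy
#' number estimate is round(mean_ratio), clipped at 0.
#'
#' @param segments data.frame from [segment_track()].
#' @param ploidy integer reference ploidy.
#' @param margin half-width of the neutral band in copies (default 0.5).
#' @return The segments with `state` and `estimated_cn` columns.
#' @export
call_states <- function(segments, ploidy, margin = 0.5) {
  check_that(is.data.frame(segments) && "mean_ratio" %in% names(segments),
             "segments must come from segment_track")
  check_that(is_count(ploidy, 1L), "ploidy must be a positive integer")
  segments$state <- ifelse(segments$mean_ratio > ploidy + margin, "gain",
                           ifelse(segments$mean_ratio < ploidy - margin,
                                  "loss", "neutral"))
  segments$estimated_cn <- pmax(0L, as.integer(round(segments$mean_ratio)))
  segments
}

#' Gene-level copy number from fine windows
#'
#' Median copy-number ratio of the fine (e.g. 5 kbp or 1 kbp) windows
#' overlapping a gene interval, after median normalisation at the given
#' ploidy.
#'
#' @param counts_fine fine-window count data.frame.
#' @param gene_interval list or vector-like with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param ploidy integer normalisation ploidy.
#' @return The gene's copy-number estimate (real).
#' @export
gene_copy_number <- function(counts_fine, gene_interval, ploidy) {
  track <- count_to_ratio(counts_fine, ploidy)
  hit <- track$chrom == gene_interval$chrom &
    track$start < gene_interval$end & track$end > gene_interval$start
  check_that(any(hit), "no windows overlap the interval %s:%s-%s",
             gene_interval$chrom, format(gene_interval$start),
             format(gene_interval$end))
  stats::median(track$ratio[hit])
}
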