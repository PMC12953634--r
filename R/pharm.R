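# Dose-response normalisation, 4PL/IC50 fitting, AUC screen hit calling,
# and small assay utilities.

#' Dose-response curve container
#'
#' @param cell_line,compound text labels.
#' @param doses_uM ascending positive dose vector.
#' @param poc matrix of percent-of-control viability, one row per dose and
#'   one column per replicate (a vector is treated as a single replicate).
#' @return An object of class `dose_response_curve`.
#' @export
dose_response_curve <- function(cell_line, compound, doses_uM, poc) {
  poc <- as.matrix(poc)
  check_that(all(doses_uM > 0), "doses must be strictly positive")
  check_that(!is.unsorted(doses_uM, strictly = TRUE),
             "doses must be strictly ascending")
  check_that(nrow(poc) == length(doses_uM),
             "poc needs one row per dose")
  check_that(all(is.finite(poc)), "POC values must be finite")
  structure(list(cell_line = cell_line, compound = compound,
                 doses_uM = as.numeric(doses_uM), poc = poc),
            class = "dose_response_curve")
}

#' @export
print.dose_response_curve <- function(x, ...) {
  cat(sprintf("dose_response_curve: %s / %s, %d doses x %d replicate(s)\n",
              x$cell_line, x$compound, length(x$doses_uM), ncol(x$poc)))
  invisible(x)
}

#' Normalise raw viability to percent of control
#'
#' POC = 100 * raw / mean(vehicle).
#'
#' @param raw replicate matrix (doses x replicates) of raw viability signal.
#' @param vehicle vector of vehicle-control (untreated) readings.
#' @param cell_line,compound labels for the resulting curve.
#' @param doses_uM the dose vector.
#' @return A [dose_response_curve()].
#' @export
normalize_poc <- function(raw, vehicle, doses_uM, cell_line = "line",
                          compound = "compound") {
  check_that(length(vehicle) >= 1L && mean(vehicle) > 0,
             "vehicle mean must be positive")
  dose_response_curve(cell_line, compound, doses_uM,
                      100 * as.matrix(raw) / mean(vehicle))
}

#' Fit a four-parameter logistic dose-response model
#'
#' Least-squares fit of POC(d) = bottom + (top - bottom) / (1 + (d/ic50)^hill)
#' over all replicate points, using multi-start optimisation (IC50 started at
#' every observed dose, Hill slope at +/-1 and +/-2) followed by a
#' Gauss-Newton polish. Fits with a negative Hill slope are renormalised to
#' hill > 0 by swapping the asymptotes. IC50s outside the tested dose range
#' are flagged as extrapolated; an effectively flat curve returns
#' `ic50 = NA`.
#'
#' For vehicle-normalised POC data the asymptotes may be constrained to
#' their construction values (`fix_top = 100`, `fix_bottom = 0`), the
#' normalised-response convention; and when the residual scatter is
#' proportional to the signal — the usual situation for plate-reader
#' viability — `weighting = "relative"` applies iteratively reweighted
#' least squares with weights 1/fitted^2, which substantially tightens IC50
#' estimates.
#'
#' @param curve a [dose_response_curve()] with >= 4 distinct doses.
#' @param fix_top,fix_bottom optional fixed asymptote values (NULL = free).
#' @param weighting "none" (ordinary least squares, default) or "relative"
#'   (weights 1/fitted^2, floored at one POC unit).
#' @return An object of class `fourpl_fit`: top, bottom, ic50_uM, hill, rss,
#'   auc (and auc_sd, from [compute_auc()]), converged, extrapolated.
#' @export
fit_4pl <- function(curve, fix_top = NULL, fix_bottom = NULL,
                    weighting = c("none", "relative")) {
  check_that(inherits(curve, "dose_response_curve"),
             "curve must be a dose_response_curve")
  weighting <- match.arg(weighting)
  doses <- curve$doses_uM
  check_that(length(unique(doses)) >= 4L, "need >= 4 distinct doses")
  d <- rep(doses, ncol(curve$poc))
  y <- as.vector(curve$poc)
  auc <- compute_auc(curve)
  free_top <- is.null(fix_top); free_bot <- is.null(fix_bottom)
  unpack <- function(par) {
    i <- 0L
    top <- if (free_top) par[i <- i + 1L] else fix_top
    bottom <- if (free_bot) par[i <- i + 1L] else fix_bottom
    c(top = top, bottom = bottom, l10ic = par[i + 1L], hill = par[i + 2L])
  }
  mu_of <- function(par) {
    p <- unpack(par)
    p[["bottom"]] + (p[["top"]] - p[["bottom"]]) /
      (1 + (d / 10^p[["l10ic"]])^p[["hill"]])
  }
  wts <- rep(1, length(y))
  obj <- function(par) sum(wts * (y - mu_of(par))^2)
  top0 <- max(rowMeans(curve$poc)); bot0 <- min(rowMeans(curve$poc))
  starts <- expand.grid(l10ic = log10(doses), hill = c(1, 2, -1, -2))
  run_starts <- function() {
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      p0 <- c(if (free_top) top0, if (free_bot) bot0,
              starts$l10ic[i], starts$hill[i])
      fit <- try(stats::optim(p0, obj, method = "BFGS",
                              control = list(maxit = 500, reltol = 1e-12)),
                 silent = TRUE)
      if (inherits(fit, "try-error")) next
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    best
  }
  best <- run_starts()
  check_that(!is.null(best), "4PL optimisation failed from every start")
  if (weighting == "relative") {
    for (iter in 1:4) {  # IRLS: weights from the current fitted curve
      wts <- 1 / pmax(abs(mu_of(best$par)), 1)^2
      ref <- try(stats::optim(best$par, obj, method = "BFGS",
                              control = list(maxit = 500, reltol = 1e-12)),
                 silent = TRUE)
      if (!inherits(ref, "try-error")) best <- ref
    }
  }
  converged <- TRUE
  if (free_top && free_bot && weighting == "none") {
    # Gauss-Newton polish for machine-precision convergence on clean data
    polished <- try(suppressWarnings(stats::nls(
      y ~ bottom + (top - bottom) / (1 + (d / 10^l10ic)^hill),
      start = list(top = best$par[1], bottom = best$par[2],
                   l10ic = best$par[3], hill = best$par[4]),
      control = stats::nls.control(maxiter = 200, warnOnly = TRUE,
                                   scaleOffset = 1, minFactor = 1e-12))),
      silent = TRUE)
    if (!inherits(polished, "try-error")) {
      if (sum(stats::resid(polished)^2) <= best$value) {
        best$par <- as.numeric(stats::coef(polished))
        best$value <- sum(stats::resid(polished)^2)
      }
      converged <- polished$convInfo$isConv ||
        best$value < 1e-6 * max(1, sum(y^2))
    }
  }
  p <- unpack(best$par)
  top <- p[["top"]]; bottom <- p[["bottom"]]
  ic50 <- 10^p[["l10ic"]]; hill <- p[["hill"]]
  if (hill < 0) { tmp <- top; top <- bottom; bottom <- tmp; hill <- -hill }
  flat <- abs(top - bottom) < 1e-6 * max(1, abs(top))
  extrapolated <- flat || ic50 < min(doses) || ic50 > max(doses)
  if (flat) ic50 <- NA_real_
  structure(list(top = top, bottom = bottom, ic50_uM = ic50, hill = hill,
                 rss = best$value, auc = auc[["auc"]], auc_sd = auc[["sd"]],
                 converged = converged, extrapolated = extrapolated,
                 weighting = weighting),
            class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf(
    "fourpl_fit: top %.2f bottom %.2f IC50 %s uM hill %.3f (AUC %.1f +/- %.2f)\n",
    x$top, x$bottom, ifelse(is.na(x$ic50_uM), "NA", format(x$ic50_uM, digits = 4)),
    x$hill, x$auc, x$auc_sd))
  invisible(x)
}

#' Area under the dose-response curve
#'
#' Trapezoid integral of mean POC over log10 dose, divided by the log10 dose
#' span, so a curve pinned at POC = c has AUC = c regardless of the dose
#' grid. The SD is the standard deviation of per-replicate AUCs.
#'
#' @param curve a [dose_response_curve()] with >= 2 doses.
#' @return Named vector c(auc =, sd =).
#' @export
compute_auc <- function(curve) {
  check_that(inherits(curve, "dose_response_curve"),
             "curve must be a dose_response_curve")
  ld <- log10(curve$doses_uM)
  check_that(length(ld) >= 2L, "need >= 2 doses for an AUC")
  span <- max(ld) - min(ld)
  trap <- function(yv) sum(diff(ld) * (utils::head(yv, -1) + utils::tail(yv, -1)) / 2) / span
  per_rep <- apply(curve$poc, 2, trap)
  c(auc = trap(rowMeans(curve$poc)),
    sd = if (length(per_rep) > 1L) stats::sd(per_rep) else 0)
}

#' Call screen hits from AUC summaries
#'
#' A cell line passes for a compound when both of the screen's rules hold
#' against the fibroblast reference:
#' `auc_fib - sd_fib > auc_line + sd_line` (the SD-separated inequality) and
#' `auc_fib - auc_line > auc_diff_threshold`. The compound is a hit for the
#' tumour when at least `min_lines` lines pass (`min_lines = 1` is allowed
#' for compounds screened in a single line).
#'
#' @param tumour_aucs data.frame with columns `cell_line`, `auc`, `sd`.
#' @param fib_auc,fib_sd fibroblast reference AUC and its SD.
#' @param auc_diff_threshold minimum fibroblast-minus-tumour AUC difference
#'   (default 50).
#' @param min_lines lines required to pass for a hit (default 2).
#' @return An object of class `hit_call`: per-line table with `eq1_pass`,
#'   `auc_diff_pass`, `line_pass`, plus `hit` and `n_lines_passing`.
#' @export
call_hits <- function(tumour_aucs, fib_auc, fib_sd,
                      auc_diff_threshold = 50, min_lines = 2L) {
  check_that(is.data.frame(tumour_aucs) &&
               all(c("cell_line", "auc", "sd") %in% names(tumour_aucs)),
             "tumour_aucs needs columns cell_line, auc, sd")
  check_that(is.numeric(fib_auc) && length(fib_auc) == 1L,
             "fibroblast reference AUC is required")
  check_that(is.numeric(fib_sd) && length(fib_sd) == 1L && !is.na(fib_sd),
             "fibroblast AUC SD is required")
  check_that(!any(is.na(tumour_aucs$sd)), "per-line AUC SDs are required")
  lines <- tumour_aucs
  lines$auc_fib <- fib_auc
  lines$sd_fib <- fib_sd
  lines$eq1_pass <- (fib_auc - fib_sd) > (lines$auc + lines$sd)
  lines$auc_diff_pass <- (fib_auc - lines$auc) > auc_diff_threshold
  lines$line_pass <- lines$eq1_pass & lines$auc_diff_pass
  n_pass <- sum(lines$line_pass)
  structure(list(lines = lines, n_lines_passing = n_pass,
                 hit = n_pass >= min_lines, min_lines = as.integer(min_lines),
                 auc_diff_threshold = auc_diff_threshold),
            class = "hit_call")
}

#' @export
print.hit_call <- function(x, ...) {
  cat(sprintf("hit_call: %d/%d line(s) passing (min %d) -> hit = %s\n",
              x$n_lines_passing, nrow(x$lines), x$min_lines, x$hit))
  invisible(x)
}

#' Xenograft tumour volume
#'
#' volume = length x width^2 / 2 (calliper convention, mm).
#'
#' @param length_mm,width_mm calliper measurements in mm; width should not
#'   exceed length (warned, not rejected).
#' @return Volume in mm^3.
#' @export
tumour_volume <- function(length_mm, width_mm) {
  check_that(all(length_mm > 0) && all(width_mm > 0),
             "length and width must be positive")
  if (any(width_mm > length_mm)) {
    warning("width exceeds length; measurements may be swapped")
  }
  length_mm * width_mm^2 / 2
}

#' Comparative-Cq fold change
#'
#' 2^-ddCq with ddCq = (Cq_target,treated - Cq_ref,treated) -
#' (Cq_target,control - Cq_ref,control).
#'
#' @param cq_target_treated,cq_ref_treated,cq_target_control,cq_ref_control
#'   quantification cycles of the target and reference gene in the treated
#'   and control conditions.
#' @return Relative fold change.
#' @export
ddcq_fold_change <- function(cq_target_treated, cq_ref_treated,
                             cq_target_control, cq_ref_control) {
  vals <- c(cq_target_treated, cq_ref_treated, cq_target_control,
            cq_ref_control)
  check_that(all(is.finite(vals)), "all Cq values must be finite")
  ddcq <- (cq_target_treated - cq_ref_treated) -
    (cq_target_control - cq_ref_control)
  2^(-ddcq)
}
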