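# Combination-synergy scoring: Bliss, Loewe and ZIP excess surfaces and the
# most-synergistic-area summary.

#' Combination dose grid
#'
#' @param doses_a,doses_b ascending dose vectors including 0 (the
#'   monotherapy margins).
#' @param poc matrix of POC viability, rows = doses of drug A, cols = doses
#'   of drug B; `poc[1, 1]` is the untreated well.
#' @return An object of class `combo_grid`.
#' @export
combo_grid <- function(doses_a, doses_b, poc) {
  poc <- as.matrix(poc)
  check_that(doses_a[1] == 0 && doses_b[1] == 0,
             "dose vectors must start at 0")
  check_that(!is.unsorted(doses_a, strictly = TRUE) &&
               !is.unsorted(doses_b, strictly = TRUE),
             "doses must be strictly ascending")
  check_that(nrow(poc) == length(doses_a) && ncol(poc) == length(doses_b),
             "poc must be length(doses_a) x length(doses_b)")
  structure(list(doses_a = as.numeric(doses_a), doses_b = as.numeric(doses_b),
                 poc = poc), class = "combo_grid")
}

#' @export
print.combo_grid <- function(x, ...) {
  cat(sprintf("combo_grid: %d x %d doses (A: 0..%g, B: 0..%g)\n",
              length(x$doses_a), length(x$doses_b),
              max(x$doses_a), max(x$doses_b)))
  invisible(x)
}

# Fractional inhibition surface of a grid: y = 1 - POC/100, clipped to [0,1].
grid_inhibition <- function(grid) {
  check_that(inherits(grid, "combo_grid"), "grid must be a combo_grid")
  pmin(pmax(1 - grid$poc / 100, 0), 1)
}

#' Bliss-independence excess surface
#'
#' Expected combined inhibition under independence is
#' yA + yB - yA*yB, computed from the observed monotherapy margins of the
#' grid; excess = (observed - expected) x 100 percentage points. Monotherapy
#' rows and columns are exactly zero by construction.
#'
#' @param grid a [combo_grid()].
#' @return Excess matrix in percentage points, same shape as `grid$poc`.
#' @export
bliss_excess <- function(grid) {
  y <- grid_inhibition(grid)
  yA <- y[, 1]
  yB <- y[1, ]
  expected <- outer(yA, yB, function(a, b) a + b - a * b)
  (y - expected) * 100
}

# Inverse 4PL dose on the inhibition scale. fit: fourpl_fit in POC units.
inv_dose_fourpl <- function(fit, y) {
  y_min <- 1 - fit$top / 100
  y_max <- 1 - fit$bottom / 100
  f <- (y - y_min) / (y_max - y)
  ifelse(f <= 0, 0, fit$ic50_uM * f^(1 / fit$hill))
}

fourpl_inhibition <- function(fit, dose) {
  1 - fourpl_poc(dose, fit$ic50_uM, fit$hill, fit$top, fit$bottom) / 100
}

#' Loewe-additivity excess surface
#'
#' The Loewe expected response y at dose pair (a, b) solves
#' a / D_A(y) + b / D_B(y) = 1, where D_X(y) is the inverse monotherapy 4PL
#' dose producing inhibition y. Solved by bisection over the achievable
#' inhibition range to a tolerance of 1e-6; dose pairs with no root inside
#' the range take the nearer boundary and are flagged in the
#' `boundary` attribute. Excess = (observed - expected) x 100.
#'
#' @param grid a [combo_grid()].
#' @param fitA,fitB monotherapy [fit_4pl()] fits for drugs A and B, with
#'   positive Hill slopes and finite IC50s.
#' @return Excess matrix in percentage points.
#' @export
loewe_excess <- function(grid, fitA, fitB) {
  y <- grid_inhibition(grid)
  for (f in list(fitA, fitB)) {
    check_that(inherits(f, "fourpl_fit"), "fits must be fourpl_fit objects")
    check_that(is.finite(f$ic50_uM) && f$hill > 0,
               "Loewe needs monotone fits with finite IC50")
  }
  lo <- max(1 - fitA$top / 100, 1 - fitB$top / 100) + 1e-9
  hi <- min(1 - fitA$bottom / 100, 1 - fitB$bottom / 100) - 1e-9
  g <- function(yy, a, b) a / inv_dose_fourpl(fitA, yy) +
    b / inv_dose_fourpl(fitB, yy) - 1
  expected <- matrix(NA_real_, nrow(y), ncol(y))
  boundary <- matrix(FALSE, nrow(y), ncol(y))
  for (i in seq_along(grid$doses_a)) {
    for (j in seq_along(grid$doses_b)) {
      a <- grid$doses_a[i]; b <- grid$doses_b[j]
      if (a == 0 && b == 0) { expected[i, j] <- 0; next }
      if (b == 0) { expected[i, j] <- fourpl_inhibition(fitA, a); next }
      if (a == 0) { expected[i, j] <- fourpl_inhibition(fitB, b); next }
      glo <- g(lo, a, b); ghi <- g(hi, a, b)
      if (glo <= 0) { expected[i, j] <- lo; boundary[i, j] <- TRUE; next }
      if (ghi >= 0) { expected[i, j] <- hi; boundary[i, j] <- TRUE; next }
      root <- stats::uniroot(g, c(lo, hi), a = a, b = b, tol = 1e-6)
      expected[i, j] <- root$root
    }
  }
  out <- (y - expected) * 100
  attr(out, "boundary") <- boundary
  out
}

# Two-parameter logistic (fixed baseline/top on the inhibition scale):
# y(d) = base + (1 - base) * (d/m)^lambda / (1 + (d/m)^lambda).
fit_conditional_logistic <- function(dose, y, base, start_m, start_lambda) {
  obj <- function(par) {
    m <- exp(par[1]); lam <- par[2]
    r <- (dose / m)^lam
    mu <- base + (1 - base) * r / (1 + r)
    sum((y - mu)^2)
  }
  fit <- try(stats::optim(c(log(start_m), start_lambda), obj,
                          method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-14)),
             silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  list(m = exp(fit$par[1]), lambda = fit$par[2], rss = fit$value,
       predict = function(d) {
         r <- (d / exp(fit$par[1]))^fit$par[2]
         base + (1 - base) * r / (1 + r)
       })
}

#' Zero-interaction-potency (ZIP) delta surface
#'
#' Following the ZIP construction: monotherapy margins are fitted with
#' two-parameter logistic curves on the inhibition scale (baseline 0, top 1);
#' for every positive dose of one drug, the responses along the other drug's
#' doses are re-fitted with the partner's fitted monotherapy inhibition as
#' the fixed lower asymptote. The delta at a dose pair is the mean of the two
#' conditional fitted responses minus the ZIP expectation
#' yA + yB - yA*yB from the marginal fits, in percentage points. Rows or
#' columns with fewer than 4 positive doses cannot be conditionally fitted
#' and yield NA cells (flagged via the `unfit` attribute).
#'
#' @param grid a [combo_grid()].
#' @return Delta matrix in percentage points (0 on monotherapy margins).
#' @export
zip_delta <- function(grid) {
  y <- grid_inhibition(grid)
  da <- grid$doses_a; db <- grid$doses_b
  pa <- which(da > 0); pb <- which(db > 0)
  check_that(length(pa) >= 4L && length(pb) >= 4L,
             "ZIP needs >= 4 positive doses of each drug")
  margA <- fit_conditional_logistic(da[pa], y[pa, 1], 0,
                                    stats::median(da[pa]), 1)
  margB <- fit_conditional_logistic(db[pb], y[1, pb], 0,
                                    stats::median(db[pb]), 1)
  check_that(!is.null(margA) && !is.null(margB),
             "monotherapy margins could not be fitted")
  yA_hat <- c(0, margA$predict(da[pa]))
  yB_hat <- c(0, margB$predict(db[pb]))
  expected <- outer(yA_hat, yB_hat, function(a, b) a + b - a * b)
  # conditional fits: along A for each positive dose of B, and vice versa
  condA <- matrix(NA_real_, nrow(y), ncol(y))  # fitted y from row-wise fits
  condB <- matrix(NA_real_, nrow(y), ncol(y))
  unfit <- matrix(FALSE, nrow(y), ncol(y))
  for (j in pb) {
    base <- margB$predict(db[j])
    f <- fit_conditional_logistic(da[pa], y[pa, j], base, margA$m, margA$lambda)
    if (is.null(f)) { unfit[pa, j] <- TRUE; next }
    condA[pa, j] <- f$predict(da[pa])
  }
  for (i in pa) {
    base <- margA$predict(da[i])
    f <- fit_conditional_logistic(db[pb], y[i, pb], base, margB$m, margB$lambda)
    if (is.null(f)) { unfit[i, pb] <- TRUE; next }
    condB[i, pb] <- f$predict(db[pb])
  }
  delta <- ((condA + condB) / 2 - expected) * 100
  delta[1, ] <- 0
  delta[, 1] <- 0
  attr(delta, "unfit") <- unfit
  delta
}

#' Most-synergistic-area score
#'
#' Maximum over all contiguous `window` x `window` submatrices of the
#' interior (strictly positive dose) cells of the mean excess. When the
#' interior is smaller than the requested window, the largest available
#' square is used and flagged in the `window_used` attribute.
#'
#' @param excess excess/delta matrix whose first row and column are the
#'   monotherapy margins (as returned by the surface functions).
#' @param window square window edge in cells (default 3).
#' @return The MSA score (percentage points), with attribute `window_used`.
#' @export
msa_score <- function(excess, window = 3L) {
  check_that(is.matrix(excess) && nrow(excess) >= 2L && ncol(excess) >= 2L,
             "excess must be a matrix with interior cells")
  interior <- excess[-1, -1, drop = FALSE]
  w <- min(window, nrow(interior), ncol(interior))
  best <- -Inf
  for (i in seq_len(nrow(interior) - w + 1L)) {
    for (j in seq_len(ncol(interior) - w + 1L)) {
      best <- max(best, mean(interior[i:(i + w - 1L), j:(j + w - 1L)],
                             na.rm = TRUE))
    }
  }
  structure(best, window_used = w)
}

#' Score a combination grid with all three synergy models
#'
#' Convenience wrapper computing Bliss, Loewe and ZIP excess surfaces and
#' their MSA scores for one grid. Loewe requires monotherapy 4PL fits, which
#' are derived from the grid margins.
#'
#' @param grid a [combo_grid()].
#' @param msa_window MSA window edge (default 3).
#' @param models character subset of c("bliss", "loewe", "zip").
#' @return List with per-model `surfaces` and `msa` scores.
#' @export
score_synergy <- function(grid, msa_window = 3L,
                          models = c("bliss", "loewe", "zip")) {
  models <- match.arg(models, c("bliss", "loewe", "zip"), several.ok = TRUE)
  surfaces <- list()
  if ("bliss" %in% models) surfaces$bliss <- bliss_excess(grid)
  if ("loewe" %in% models) {
    pa <- grid$doses_a > 0; pb <- grid$doses_b > 0
    curveA <- dose_response_curve("A", "A", grid$doses_a[pa],
                                  grid$poc[pa, 1, drop = FALSE])
    curveB <- dose_response_curve("B", "B", grid$doses_b[pb],
                                  t(grid$poc[1, pb, drop = FALSE]))
    surfaces$loewe <- loewe_excess(grid, fit_4pl(curveA), fit_4pl(curveB))
  }
  if ("zip" %in% models) surfaces$zip <- zip_delta(grid)
  msa <- lapply(surfaces, msa_score, window = msa_window)
  list(surfaces = surfaces, msa = lapply(msa, as.numeric),
       msa_window = msa_window)
}
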