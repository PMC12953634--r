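# Pharmacology-side simulators: 4PL monotherapy screens and combination
# dose grids with controllable synergy.

#' Four-parameter-logistic viability at given doses
#'
#' POC(d) = bottom + (top - bottom) / (1 + (d / ic50)^hill); hill > 0 gives a
#' decreasing viability curve. Dose 0 returns `top` exactly.
#'
#' @param dose dose vector (same units as ic50; conventionally uM).
#' @param ic50 half-maximal dose.
#' @param hill Hill slope.
#' @param top,bottom upper/lower POC asymptotes (defaults 100 and 0).
#' @return POC values.
#' @export
fourpl_poc <- function(dose, ic50, hill, top = 100, bottom = 0) {
  check_that(all(dose >= 0), "doses must be non-negative")
  check_that(ic50 > 0, "ic50 must be positive")
  out <- bottom + (top - bottom) / (1 + (dose / ic50)^hill)
  out[dose == 0] <- top
  out
}

#' Serial-dilution dose series
#'
#' Geometric series of `n_doses` doses descending from `top_dose_uM` by
#' `dilution_factor`, the screen's 1:5 series from 100 uM by default.
#'
#' @param top_dose_uM highest dose (default 100).
#' @param dilution_factor fold-dilution between consecutive doses (default 5).
#' @param n_doses number of doses (default 7).
#' @return Ascending dose vector.
#' @export
dose_series <- function(top_dose_uM = 100, dilution_factor = 5, n_doses = 7) {
  check_that(top_dose_uM > 0, "top dose must be positive")
  check_that(dilution_factor > 1, "dilution factor must exceed 1")
  check_that(is_count(n_doses, 2L), "need at least 2 doses")
  sort(top_dose_uM / dilution_factor^(seq_len(n_doses) - 1))
}

#' Simulate a monotherapy drug screen
#'
#' For each cell line, POC viability is generated from a 4PL curve
#' (top 100, bottom 0) at a serial-dilution dose series, with multiplicative
#' Gaussian noise of coefficient of variation `noise_cv` and 3 replicates
#' per dose.
#'
#' @param ic50s_by_line named numeric vector/list: true IC50 (uM) per cell line.
#' @param top_dose_uM,dilution_factor,n_doses dose series, see [dose_series()].
#' @param hill Hill slope shared by all lines.
#' @param noise_cv multiplicative noise CV (0 = noise-free).
#' @param seed integer seed.
#' @param n_replicates replicates per dose (default 3).
#' @return Named list of [dose_response_curve()] objects.
#' @export
simulate_drug_screen <- function(ic50s_by_line, top_dose_uM = 100,
                                 dilution_factor = 5, n_doses = 7,
                                 hill = 1, noise_cv = 0.05, seed = 1,
                                 n_replicates = 3) {
  ic50s <- unlist(ic50s_by_line)
  check_that(length(ic50s) >= 1L && all(ic50s > 0),
             "ic50s_by_line must be named positive values")
  check_that(!is.null(names(ic50s)) && all(nzchar(names(ic50s))),
             "every cell line needs a name")
  check_that(hill > 0, "hill must be positive")
  doses <- dose_series(top_dose_uM, dilution_factor, n_doses)
  out <- lapply(names(ic50s), function(line) {
    with_seed(derive_seed(seed, paste0("screen:", line)), {
      mu <- fourpl_poc(doses, ic50s[[line]], hill)
      poc <- matrix(rep(mu, n_replicates), ncol = n_replicates)
      if (noise_cv > 0) {
        poc <- poc * (1 + stats::rnorm(length(poc), 0, noise_cv))
      }
      dose_response_curve(line, "compound", doses, poc)
    })
  })
  names(out) <- names(ic50s)
  out
}

#' Simulate a combination dose grid
#'
#' Builds a (doses_A x doses_B) viability grid. Under `synergy_delta = 0` the
#' combined fractional inhibition follows Bliss independence of the two
#' monotherapy 4PL curves, y = yA + yB - yA*yB; `synergy_delta` adds that many
#' percentage points of extra inhibition at every strictly positive dose pair.
#' Multiplicative noise with CV `noise_cv` is applied to POC values.
#'
#' @param curveA,curveB lists with elements `ic50`, `hill` (and optionally
#'   `top`, `bottom` on the POC scale) for drugs A and B.
#' @param doses_A,doses_B dose vectors; must include 0 (monotherapy margins).
#' @param synergy_delta extra inhibition in percentage points (default 0).
#' @param noise_cv multiplicative noise CV (default 0).
#' @param seed integer seed.
#' @return A `combo_grid`: list with `doses_a`, `doses_b` and `poc` matrix
#'   (rows = doses of A ascending, cols = doses of B ascending).
#' @export
simulate_combination <- function(curveA, curveB, doses_A, doses_B,
                                 synergy_delta = 0, noise_cv = 0, seed = 1) {
  check_that(any(doses_A == 0) && any(doses_B == 0),
             "dose grids must include zero dose for each drug")
  doses_A <- sort(unique(doses_A)); doses_B <- sort(unique(doses_B))
  getp <- function(cv, nm, def) if (!is.null(cv[[nm]])) cv[[nm]] else def
  yA <- 1 - fourpl_poc(doses_A, curveA$ic50, curveA$hill,
                       getp(curveA, "top", 100), getp(curveA, "bottom", 0)) / 100
  yB <- 1 - fourpl_poc(doses_B, curveB$ic50, curveB$hill,
                       getp(curveB, "top", 100), getp(curveB, "bottom", 0)) / 100
  y <- outer(yA, yB, function(a, b) a + b - a * b)
  interior <- outer(doses_A > 0, doses_B > 0, `&`)
  y[interior] <- y[interior] + synergy_delta / 100
  y <- pmin(pmax(y, 0), 1)
  poc <- 100 * (1 - y)
  if (noise_cv > 0) {
    poc <- with_seed(derive_seed(seed, "combination"), {
      poc * (1 + stats::rnorm(length(poc), 0, noise_cv))
    })
  }
  combo_grid(doses_A, doses_B, poc)
}
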