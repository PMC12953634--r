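# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library calls never perturb user RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically mix a base seed with a text label (sample name, stage
# name, chromosome) into a new 31-bit seed. Plain multiplicative hash over
# the Mersenne prime 2^31 - 1; doubles stay exact (< 2^53) throughout.
derive_seed <- function(seed, label) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (v in utf8ToInt(as.character(label))) {
    h <- (h * 48271 + v) %% m
  }
  as.integer(h %% 2147483646L + 1)
}

# stopifnot() with a formatted message
check_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

is_prob <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1

# Negative binomial draw parameterised by mean and a dispersion phi such that
# Var = mu + phi * mu^2; phi = 0 degenerates to Poisson.
rnbinom_disp <- function(n, mu, dispersion) {
  mu <- rep_len(mu, n)
  out <- integer(n)
  pos <- mu > 0
  if (dispersion <= 0) {
    out[pos] <- stats::rpois(sum(pos), mu[pos])
  } else {
    out[pos] <- stats::rnbinom(sum(pos), size = 1 / dispersion, mu = mu[pos])
  }
  out
}

# Beta-binomial draw with mean prob p and intraclass correlation rho.
rbetabinom <- function(n, size, prob, rho) {
  size <- rep_len(size, n)
  prob <- rep_len(prob, n)
  if (rho <= 0) return(stats::rbinom(n, size, prob))
  nu <- (1 - rho) / rho                  # a + b
  a <- prob * nu
  b <- (1 - prob) * nu
  p <- stats::rbeta(n, pmax(a, 1e-12), pmax(b, 1e-12))
  stats::rbinom(n, size, p)
}

# Chromosomes treated as sex chromosomes for the female (XX) convention:
# Y dropped at read time, X excluded from autosomal medians.
is_y_chrom <- function(chrom) tolower(sub("^chr", "", chrom)) %in% c("y")
is_x_chrom <- function(chrom) tolower(sub("^chr", "", chrom)) %in% c("x")
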