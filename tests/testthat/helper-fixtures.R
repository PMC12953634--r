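# Shared fixtures, built in code at test time.

# one-chromosome configuration small enough for fast unit tests
tiny_config <- function(seed = 1L, length_bp = 1e7, n_snvs = 100L,
                        n_het = 0L, ...) {
  sim_config(seed = seed,
             chromosomes = data.frame(name = "1", length_bp = length_bp),
             n_somatic_snvs = n_snvs, n_het_sites_per_chrom = n_het, ...)
}

# hand-built two-sample variant table
toy_variant_table <- function() {
  sites <- data.frame(chrom = c("1", "1", "2"), pos = c(100, 200, 50),
                      ref = c("A", "C", "G"), alt = c("T", "G", "A"),
                      stringsAsFactors = FALSE)
  variant_table(sites,
                ad_ref = cbind(P = c(30L, 15L, 40L), R = c(15L, 40L, 0L)),
                ad_alt = cbind(P = c(0L, 15L, 10L), R = c(15L, 0L, 50L)),
                dp = cbind(P = c(30L, 30L, 50L), R = c(30L, 40L, 50L)),
                samples = c("P", "R"))
}

# simulated ploidy-study chromosome: returns a single-sample variant table
simulated_spectrum_table <- function(true_m, seed, n_sites = 10000L,
                                     depth = 60, dispersion = 0.2) {
  cfg <- sim_config(seed = 1L,
                    chromosomes = data.frame(name = "1", length_bp = 5e7),
                    base_ploidy = 2L, mean_depth = depth,
                    depth_dispersion = dispersion,
                    n_het_sites_per_chrom = n_sites, n_somatic_snvs = 0L)
  par <- simulate_parental(cfg)
  clone <- switch(as.character(true_m),
    "2" = par,
    "3" = derive_resistant(par, resistance_events(segmental_events =
            data.frame(chrom = "1", start_bp = 0, end_bp = 5e7,
                       delta_copies = 1L)), seed = 2L),
    "4" = derive_resistant(par, resistance_events(
            whole_genome_duplication = TRUE), seed = 2L))
  panel <- simulate_panel_sites(cfg)
  cfg_draw <- cfg
  cfg_draw$seed <- as.integer(seed)
  sample_sequencing(clone, panel, cfg_draw, paste0("S", seed))$variants
}

# independent two-sided Fisher oracle: brute-force hypergeometric
# enumeration from binomial coefficients (no dhyper)
fisher_oracle <- function(ad_p, ad_r) {
  a <- ad_p[1]; b <- ad_p[2]; cc <- ad_r[1]; d <- ad_r[2]
  N <- a + b + cc + d; r1 <- a + b; c1 <- a + cc
  support <- max(0, r1 - (N - c1)):min(r1, c1)
  logp <- lchoose(c1, support) + lchoose(N - c1, r1 - support) -
    lchoose(N, r1)
  probs <- exp(logp)
  p_obs <- probs[match(a, support)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}
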