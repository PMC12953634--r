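# End-to-end orchestration: simulate -> cnv / ploidy / shift / phospho /
# screen / synergy, each stage independently runnable, with a single JSON
# run manifest. One global seed fans out to per-stage seeds by label.

#' Default pipeline configuration
#'
#' The demo-scale study conditions: a two-chromosome diploid parental clone,
#' a resistant derivative with whole-genome duplication, one focal loss and
#' one focal gain plus gained/lost/fixated SNVs, sequenced at 60x; a
#' 6-vs-6 phospho matrix with 10% true shifts; a 7-dose 1:5 screen from
#' 100 uM over three tumour lines and a fibroblast reference; an 8x8
#' combination grid with 10 points of injected synergy.
#'
#' @return Named list of configuration values.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    stages = c("simulate", "cnv", "ploidy", "shift", "phospho", "screen",
               "synergy"),
    chromosome_length_bp = 2e7,
    n_chromosomes = 2L,
    base_ploidy = 2L,
    window_size_bp = 50000L,
    mean_depth = 60,
    depth_dispersion = 0.01,
    af_overdispersion = 0,
    n_het_sites_per_chrom = 5000L,
    n_somatic_snvs = 2000L,
    wgd = TRUE,
    focal_loss_frac = c(0.2, 0.5),     # on chromosome 1, fraction of length
    focal_gain_frac = c(0.5, 0.8),     # on chromosome 2
    snv_gains = 300L,
    snv_losses = 100L,
    snv_fixations = 60L,
    ploidy_candidates = c(2L, 3L, 4L),
    n_subsample = 10000L,
    alpha_fisher = 0.05,
    alpha_binom = 0.1,
    fixation_af = 0.95,
    min_windows = 5L,
    z_threshold = 6,
    gc_bins = 20L,
    phospho_features = 1000L,
    phospho_per_group = 6L,
    phospho_frac_diff = 0.1,
    phospho_effect_sd = 3,
    phospho_s0 = 0.1,
    phospho_fdr = 0.05,
    phospho_n_perm = 250L,
    screen_ic50s = list(DFT1_S1 = 0.05, DFT1_C5065 = 0.1, DFT2_SN = 0.2,
                        FIB = 50),
    screen_fibroblast = "FIB",
    screen_hill = 1,
    screen_noise_cv = 0.05,
    auc_diff_threshold = 50,
    min_lines = 2L,
    synergy_delta = 10,
    synergy_noise_cv = 0.02,
    msa_window = 3L
  )
}

validate_pipeline_config <- function(cfg) {
  check_that(is_count(cfg$seed, 0L), "config: seed must be an integer")
  known <- c("simulate", "cnv", "ploidy", "shift", "phospho", "screen",
             "synergy")
  bad <- setdiff(cfg$stages, known)
  check_that(length(bad) == 0L, "config: unknown stage(s): %s",
             paste(bad, collapse = ", "))
  check_that(cfg$n_chromosomes >= 1L, "config: need >= 1 chromosome")
  check_that(cfg$chromosome_length_bp > cfg$window_size_bp,
             "config: chromosomes must span multiple windows")
  check_that(is_prob(cfg$phospho_frac_diff),
             "config: phospho_frac_diff must lie in [0,1]")
  check_that(cfg$screen_fibroblast %in% names(cfg$screen_ic50s),
             "config: screen_fibroblast must appear in screen_ic50s")
  invisible(cfg)
}

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in dependency order against a simulated
#' ground-truth dataset, writing each stage's outputs (VCF, TSV, CSV, JSON)
#' under `outdir` and collecting headline results into a JSON run manifest.
#' Later stages consume earlier stages' files through the declared readers
#' only, so each stage can be re-run independently. Any stage failure aborts
#' with the stage named.
#'
#' @param config configuration list from [default_pipeline_config()] or
#'   [load_config()].
#' @param outdir output directory (created if absent).
#' @return The run manifest (also written to `outdir/manifest.json`),
#'   invisibly.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         outdir = tempfile("tkiresist_run_")) {
  validate_pipeline_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  if (any(c("cnv", "ploidy", "shift") %in% stages)) {
    stages <- union("simulate", stages)  # genomic stages need inputs
  }
  manifest <- list(tool = "tkiresist",
                   version = as.character(utils::packageVersion("tkiresist")),
                   seed = config$seed, outdir = outdir, stages = list())
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    res$seconds <- round(proc.time()[["elapsed"]] - t0, 2)
    manifest$stages[[name]] <<- res
  }
  paths <- list(
    parental_vcf = file.path(outdir, "parental.vcf"),
    resistant_vcf = file.path(outdir, "resistant.vcf"),
    parental_windows = file.path(outdir, "parental_windows.tsv"),
    resistant_windows = file.path(outdir, "resistant_windows.tsv"),
    phospho_matrix = file.path(outdir, "phospho_matrix.csv")
  )

  if ("simulate" %in% stages) run_stage("simulate", function() {
    cfg <- sim_config(
      seed = derive_seed(config$seed, "simulate"),
      chromosomes = data.frame(
        name = as.character(seq_len(config$n_chromosomes)),
        length_bp = config$chromosome_length_bp),
      base_ploidy = config$base_ploidy,
      window_size_bp = config$window_size_bp,
      mean_depth = config$mean_depth,
      depth_dispersion = config$depth_dispersion,
      af_overdispersion = config$af_overdispersion,
      n_het_sites_per_chrom = config$n_het_sites_per_chrom,
      n_somatic_snvs = config$n_somatic_snvs)
    parental <- simulate_parental(cfg)
    L <- config$chromosome_length_bp
    seg_events <- data.frame(
      chrom = c("1", as.character(min(2L, config$n_chromosomes))),
      start_bp = c(config$focal_loss_frac[1], config$focal_gain_frac[1]) * L,
      end_bp = c(config$focal_loss_frac[2], config$focal_gain_frac[2]) * L,
      delta_copies = c(-1L, 1L), stringsAsFactors = FALSE)
    events <- resistance_events(
      whole_genome_duplication = config$wgd,
      segmental_events = seg_events,
      snv_gains = config$snv_gains, snv_losses = config$snv_losses,
      snv_fixations = config$snv_fixations)
    resistant <- derive_resistant(parental, events,
                                  derive_seed(config$seed, "resistant"))
    panel <- simulate_panel_sites(cfg)
    seq_p <- sample_sequencing(parental, panel, cfg, "parental")
    seq_r <- sample_sequencing(resistant, panel, cfg, "resistant")
    write_vcf(seq_p$variants, paths$parental_vcf)
    write_vcf(seq_r$variants, paths$resistant_vcf)
    write_window_counts(seq_p$windows, paths$parental_windows)
    write_window_counts(seq_r$windows, paths$resistant_windows)
    truth <- list(resistant_segments = resistant$segments,
                  events = unclass(events))
    jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    list(params = cfg[c("seed", "base_ploidy", "window_size_bp",
                        "mean_depth", "depth_dispersion")],
         outputs = paths[1:4],
         n_snvs_parental = nrow(parental$snvs),
         n_snvs_resistant = nrow(resistant$snvs))
  })

  if ("cnv" %in% stages) run_stage("cnv", function() {
    resistant_ploidy <- if (config$wgd) 2L * config$base_ploidy else
      config$base_ploidy
    counts <- read_window_counts(paths$resistant_windows)
    counts <- gc_correct(counts, n_bins = config$gc_bins)
    track <- count_to_ratio(counts, resistant_ploidy)
    segs <- call_states(segment_track(track, config$min_windows,
                                      config$z_threshold),
                        resistant_ploidy)
    utils::write.table(
      segs[, c("chrom", "start", "end", "mean_ratio", "state")],
      file.path(outdir, "segments.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    list(params = list(ploidy = resistant_ploidy,
                       min_windows = config$min_windows,
                       z_threshold = config$z_threshold),
         outputs = list(segments = file.path(outdir, "segments.tsv")),
         n_segments = nrow(segs),
         states = as.list(table(segs$state)))
  })

  if ("ploidy" %in% stages) run_stage("ploidy", function() {
    vt <- read_vcf(paths$resistant_vcf)
    call <- select_ploidy(vt, "resistant",
                          candidates = config$ploidy_candidates,
                          n_subsample = config$n_subsample,
                          seed = derive_seed(config$seed, "ploidy"))
    jsonlite::write_json(
      list(calls = call$calls, bic = as.data.frame(call$bic)),
      file.path(outdir, "ploidy.json"), auto_unbox = TRUE, digits = NA)
    list(params = list(candidates = config$ploidy_candidates,
                       n_subsample = config$n_subsample),
         outputs = list(report = file.path(outdir, "ploidy.json")),
         best_m = stats::setNames(call$calls$best_m, call$calls$chrom))
  })

  if ("shift" %in% stages) run_stage("shift", function() {
    vt_p <- read_vcf(paths$parental_vcf)
    vt_r <- read_vcf(paths$resistant_vcf)
    cls <- classify_variants(vt_p, vt_r, c("parental", "resistant"),
                             alpha_fisher = config$alpha_fisher,
                             alpha_binom = config$alpha_binom,
                             fixation_af = config$fixation_af)
    utils::write.table(cls$results, file.path(outdir, "variant_shift.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(cls$summary, file.path(outdir, "shift_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    list(params = cls$summary[c("alpha_fisher", "alpha_binom", "fixation_af")],
         outputs = list(per_variant = file.path(outdir, "variant_shift.tsv"),
                        summary = file.path(outdir, "shift_summary.json")),
         totals = cls$summary$totals,
         fraction_fixed_of_novel = cls$summary$fraction_fixed_of_novel)
  })

  if ("phospho" %in% stages) run_stage("phospho", function() {
    sim <- simulate_phospho(config$phospho_features, config$phospho_per_group,
                            config$phospho_frac_diff, config$phospho_effect_sd,
                            seed = derive_seed(config$seed, "phospho"))
    write_matrix(sim$matrix, paths$phospho_matrix)
    m <- read_matrix(paths$phospho_matrix)
    res <- permutation_fdr(m, sim$groups, s0 = config$phospho_s0,
                           fdr_target = config$phospho_fdr,
                           n_permutations = config$phospho_n_perm,
                           seed = derive_seed(config$seed, "phospho_perm"))
    utils::write.table(res$features, file.path(outdir, "phospho_diff.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(params = list(s0 = config$phospho_s0, fdr = config$phospho_fdr,
                       n_permutations = res$n_permutations),
         outputs = list(matrix = paths$phospho_matrix,
                        per_feature = file.path(outdir, "phospho_diff.tsv")),
         counts = as.list(differential_counts(res)))
  })

  if ("screen" %in% stages) run_stage("screen", function() {
    curves <- simulate_drug_screen(config$screen_ic50s,
                                   hill = config$screen_hill,
                                   noise_cv = config$screen_noise_cv,
                                   seed = derive_seed(config$seed, "screen"))
    aucs <- lapply(curves, compute_auc)
    fib <- aucs[[config$screen_fibroblast]]
    tumour <- setdiff(names(curves), config$screen_fibroblast)
    tbl <- data.frame(cell_line = tumour,
                      auc = vapply(aucs[tumour], `[[`, numeric(1), "auc"),
                      sd = vapply(aucs[tumour], `[[`, numeric(1), "sd"),
                      stringsAsFactors = FALSE)
    hits <- call_hits(tbl, fib[["auc"]], fib[["sd"]],
                      auc_diff_threshold = config$auc_diff_threshold,
                      min_lines = config$min_lines)
    fits <- lapply(curves, fit_4pl, fix_top = 100, fix_bottom = 0,
                   weighting = "relative")
    report <- list(
      ic50_uM = lapply(fits, `[[`, "ic50_uM"),
      auc = lapply(aucs, function(x) x[["auc"]]),
      lines = hits$lines, hit = hits$hit,
      n_lines_passing = hits$n_lines_passing)
    jsonlite::write_json(report, file.path(outdir, "screen.json"),
                         auto_unbox = TRUE, digits = NA)
    list(params = list(auc_diff_threshold = config$auc_diff_threshold,
                       min_lines = config$min_lines),
         outputs = list(report = file.path(outdir, "screen.json")),
         hit = hits$hit, n_lines_passing = hits$n_lines_passing)
  })

  if ("synergy" %in% stages) run_stage("synergy", function() {
    doses <- c(0, dose_series(10, 2, 7))
    grid <- simulate_combination(list(ic50 = 0.5, hill = 1),
                                 list(ic50 = 1, hill = 1),
                                 doses, doses,
                                 synergy_delta = config$synergy_delta,
                                 noise_cv = config$synergy_noise_cv,
                                 seed = derive_seed(config$seed, "synergy"))
    sc <- score_synergy(grid, msa_window = config$msa_window)
    jsonlite::write_json(
      list(msa = sc$msa, msa_window = sc$msa_window,
           doses_a = grid$doses_a, doses_b = grid$doses_b),
      file.path(outdir, "synergy.json"), auto_unbox = TRUE, digits = NA)
    list(params = list(synergy_delta = config$synergy_delta,
                       msa_window = config$msa_window),
         outputs = list(report = file.path(outdir, "synergy.json")),
         msa = sc$msa)
  })

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
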