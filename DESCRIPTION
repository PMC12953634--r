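Package: tkiresist
Title: Clonal Genomics and Pharmacology of Kinase-Inhibitor Resistance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis chain for studying how tumour clones evolve resistance
    to tyrosine kinase inhibitors: windowed read-depth copy-number profiling
    with median normalisation, GC correction and recursive binary
    segmentation; per-chromosome ploidy inference from allele-frequency
    spectra via a fixed-peak normal+uniform mixture selected by BIC;
    parental-versus-resistant variant frequency-shift testing (Fisher exact
    and zero-read binomial loss tests with FDR control) and
    gain/loss/fixation classification; s0-penalised two-sample t statistics
    with permutation-based FDR for differential phospho-proteomics; and
    dose-response pharmacology (4PL/IC50 fitting, AUC screen hit calling,
    Bliss/Loewe/ZIP synergy surfaces with most-synergistic-area scores).
    Includes a synthetic-data generator with known ground truth for every
    input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
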