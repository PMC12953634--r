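---
title: "Methods: models, estimators and design choices in tkiresist"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in tkiresist}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tkiresist)
```

`tkiresist` implements the computational chain used to characterise how
clonally transmissible tumour cell lines evolve resistance to tyrosine
kinase inhibitors (TKIs): copy-number profiling from windowed read counts,
ploidy classification from allele-frequency (AF) spectra, statistical
testing of variant frequency shifts between parental and resistant lines,
SAM-style differential phospho-proteomics, and dose–response/synergy
pharmacology with an explicit screen hit rule. Every analysis module is
paired with a synthetic-data generator that produces its inputs with known
ground truth, so each estimator can be validated by recovery rather than by
fixture files.

This vignette explains the models, their assumptions, the tunable
parameters that matter, and the places where the design was genuinely open
and we had to choose.

## The synthetic tumour-clone generator

A `clone_genome` is a set of copy-number segments tiling each chromosome
plus a list of somatic SNVs, each carrying `alt_copies` of
`total_copies` at its site. `simulate_parental()` creates a clonal
population at the configured base ploidy (default 2) with SNVs placed
uniformly; `derive_resistant()` applies, in order, whole-genome duplication
(WGD; doubles every copy number, so expected allele fractions are
unchanged), segmental gains/losses (segments are split at event
boundaries; which allele copies are duplicated or lost is drawn
hypergeometrically), then SNV gains (novel, one copy), losses and
fixations on disjoint random subsets of heterozygous SNVs.

`sample_sequencing()` emulates the observable layer:

* per-site depth is negative-binomial with mean
  `mean_depth * total_copies / base_ploidy` and dispersion
  `depth_dispersion` (`Var = mu + phi mu^2`); real WGS depth is
  overdispersed relative to Poisson and the ploidy fit must tolerate it;
* alternate read counts are binomial in `alt_copies / total_copies`
  (beta-binomial with intraclass `af_overdispersion` when requested;
  default off so closed-form oracles stay exact);
* 50 kbp windows receive negative-binomial read counts proportional to the
  length-weighted mean copy number of the window;
* germline-like "panel" heterozygous sites (default 10,000 per chromosome,
  the spectra's canonical subsample size) are emitted per sample with
  `k` of the local `m` copies carrying the alternate allele, `k` uniform
  on `1..m-1`, which puts the expected AF of het sites on the `k/m` grid.

Defaults (`mean_depth = 60`, `depth_dispersion = 0.01` giving roughly 10%
window-count CV at 50 kbp, two 20 Mbp chromosomes) are what we consider a
realistic desk-scale rendering of a well-covered tumour genome. The
generator deliberately does **not** model read-level artefacts, mutational
signatures, sequencing error, or subclonal mixtures: every simulated
population is clonal. Consequently, passing recovery tests demonstrate
estimator correctness under clonal, moderately overdispersed data — they
do not certify behaviour under subclonality (for instance a pre-existing
tetraploid subpopulation, which this simulator cannot express) or
alignment artefacts.

## Copy-number profiling

The copy-number ratio of window *i* is
`count_i / median(counts) * ploidy`, with the median taken over non-zero
autosomal windows: median normalisation is robust to focal amplifications,
Y windows are dropped and X excluded from the median (all samples treated
as female/XX to avoid sex-chromosome artefacts), and `ploidy` is an input
so each sample is normalised at its own known/estimated ploidy. GC
correction rescales counts by the ratio of global to per-GC-bin medians
over bins of equal GC width (default 20 bins; bins with fewer than 20
windows are left untouched).

Segmentation is recursive binary segmentation: each candidate segment is
split at the position maximising the two-sided mean-difference z-score
when it exceeds `z_threshold` (default 6) with at least `min_windows`
(default 5) on both sides. Two numerical choices matter:

* the noise scale is estimated from first differences,
  `sd(diff(x)) / sqrt(2)`, which is insensitive to the very level shifts
  being searched for — using the raw segment SD inflates the denominator
  when an event is present and masks 20–30%-length focal events;
* after the recursive pass each internal breakpoint is re-located by the
  maximal-z split within the union of its two flanking segments
  (a bounded backfitting pass). Recursive splitting alone can misplace a
  boundary by several windows when a candidate segment still contains two
  change-points.

The procedure is deterministic and seed-free: identical input gives
identical breakpoints. Segment means are medians of member windows;
states are called by a half-copy margin around the reference ploidy
(default 0.5, the midpoint between adjacent integer states) and integer
copy number is the rounded median ratio. Gene-level estimates reuse the
same ratio machinery on fine (5 or 1 kbp) windows and report the median
over windows overlapping the gene.

## Ploidy from allele-frequency spectra

Heterozygous allele fractions on a chromosome with total copy number *m*
concentrate at `k/m`, `k = 1..m-1`: one peak at 0.5 for diploid, peaks at
0.33/0.66 for triploid, and 0.25/0.5/0.75 for tetraploid chromosomes.
`fit_af_mixture()` fits, by EM, a mixture of `m - 1` normal components
with **means fixed at k/m** (truncated to (0,1) by renormalising the
density), one shared free standard deviation, free weights, and one
Uniform(0,1) background component. Fixing the means turns the fit into
the hypothesis test we actually want — *which ploidy* — and avoids label
switching; a shared sigma keeps the m = 4 model identifiable at moderate
site counts.

Numerical choices:

* the sigma M-step maximises the expected complete-data log-likelihood
  numerically (a generalised EM), so the log-likelihood is non-decreasing
  across iterations — asserted in tests;
* sigma is bounded above at 0.15. Peak width is physically limited by
  binomial allele-sampling noise at usable depths (at depth 20 the sd of
  an AF at 0.5 is 0.11); without the bound a near-flat wide normal can
  impersonate the uniform background and the degenerate all-background
  case is not recovered;
* convergence is absolute log-likelihood change below `tol` (default
  1e-6) or `max_iter` (default 200). The all-uniform optimum is
  approached slowly, so degenerate-data checks use a larger budget.

`select_ploidy()` compares candidate ploidies (default 2, 3, 4) per
chromosome by BIC with `p = (m - 1) + 1` free parameters. Two
data-quality rules make the comparison robust under heavy depth
overdispersion:

* sites below half the sample's median positive depth are excluded from
  spectra. Low-coverage sites have AF noise comparable to the peak
  spacing; their heavy tails are exactly what the spurious side
  components of an over-complex model absorb;
* the smallest candidate within `bic_margin` (default 10, the
  conventional "very strong evidence" threshold) of the minimum BIC wins.
  Extra peak components must earn decisively better fit before a higher
  ploidy is called; exact ties therefore also resolve to the smaller
  ploidy.

AF values of exactly 0 or 1 are excluded from spectra (interior peaks
cannot host them) but are retained in the variant table, where the
fixation logic needs them. Fits are per sample and per chromosome;
subsampling to `n_subsample` (default 10,000) sites is seeded and
reproducible.

## Variant frequency shifts

For every variant shared (by outer join) between a parental and a
resistant sample, `classify_variants()` runs a two-sided Fisher exact test
on the 2×2 table of ref/alt read counts. The test is implemented as
explicit hypergeometric enumeration over the fixed margins, summing all
tables no more likely than the observed one (with the customary
`1 + 1e-7` relative tolerance); a test over all-zero or single-row tables
is flagged missing rather than forced. Two-sided was chosen because gains
and losses are both of interest; the upstream convention is not
documented anywhere we could follow.

Apparent losses — variants with parental AF > 0 but zero alternate reads
in the resistant sample — get a binomial zero-read test,
`p = (1 - f)^D` at resistant depth `D`, with `f` the parental point
estimate AF (a ploidy-expected `k/m` frequency would be a reasonable
alternative; the point estimate is the default because it needs no ploidy
call). The Fisher and binomial p-value families are Benjamini–Hochberg
adjusted **separately**, mirroring the two distinct significance
thresholds they carry downstream (0.05 and 0.1).

Categories are assigned with precedence
`lost > fixed > gained > changed > stable`:
lost (zero resistant alt reads, q_binom < 0.1), fixed (novel or
parental-intermediate variant reaching resistant AF ≥ 0.95 — the
threshold is configurable and recorded in the output), gained (novel with
q_fisher < 0.05), changed (any other q_fisher < 0.05). Placing `fixed`
above `gained` makes the fixation summary well-defined: the fraction of
novel variants that reached fixation would otherwise always be zero, as
every novel fixed variant would be labelled gained first. The precedence
order ships in the result metadata.

## Differential phospho-statistics

Log2 intensity matrices are compared between two groups with the
s0-penalised t statistic
`t_s0 = (mean_B - mean_A) / (se_pooled + s0)`; `s0` (default 0.1) damps
features whose tiny variance would otherwise dominate the top of the
list. The base statistic is the pooled-variance Student t (the upstream
software's convention is not printed; Welch is a documented alternative),
and with `s0 = 0` the statistic is exactly classical — asserted to 1e-12.

Significance is by permutation FDR: group labels are permuted over all
distinct relabellings when `choose(n, nB)` is small (at 3 vs 3 that is 20,
so the attainable FDR values are coarse — a design-inherited granularity,
not a bug), otherwise a seeded sample of `n_permutations` distinct
relabellings (default 250). For a cutoff `c`,
`FDR(c) = mean permuted #{|t*| >= c} / observed #{|t| >= c}`, clipped to
[0,1] and made monotone non-increasing in `c`; the significance cutoff is
the smallest observed |t| with FDR at or below the target. The permuted
statistic includes the same `s0`, no pi0 correction is applied
(conservative), and features with fewer than two valid values in either
group are excluded *before* permutation so the permutation null stays
exchangeable. Row z-scoring (sample-SD convention) is provided for
display-style normalisation; constant rows are flagged, not scaled.

## Pharmacology

Viability is normalised to percent-of-control, `100 * raw /
mean(vehicle)`. Dose–response curves are fitted with the four-parameter
logistic `POC(d) = bottom + (top - bottom) / (1 + (d/ic50)^hill)` by
multi-start least squares (IC50 started at every observed dose, Hill at
±1 and ±2) with a Gauss–Newton polish; negative-Hill solutions are
renormalised to `hill > 0` by swapping asymptotes, and IC50s outside the
tested range (or on flat curves) are flagged extrapolated. For
vehicle-normalised data the asymptotes can be constrained to their
construction values (`fix_top = 100`, `fix_bottom = 0`, the
normalised-response convention), and `weighting = "relative"` performs
iteratively reweighted least squares with weights `1/fitted^2` — the
maximum-likelihood choice when residual scatter is proportional to the
signal, as it is for plate-reader viability and for this package's own
generator. The recovery analyses in the test suite use that convention;
the defaults remain fully free and unweighted.

The screen summary is the span-normalised trapezoid AUC of mean POC over
log10 dose (a 0–100-scale quantity: a flat POC = c curve has AUC = c,
making the "AUC difference > 50" rule meaningful), with SD propagated
from per-replicate AUCs. A cell line passes for a compound when both
`auc_fib - sd_fib > auc_line + sd_line` and
`auc_fib - auc_line > 50`; a compound is a hit when at least two lines
pass (one suffices for compounds screened in a single line).

Synergy on combination grids is scored three ways and reported side by
side rather than adjudicated: Bliss excess
(`observed - (yA + yB - yA*yB)` on the fractional-inhibition scale, ×100),
Loewe excess (the expected response solves
`a/DA(y) + b/DB(y) = 1` by bisection to 1e-6 over the achievable
inhibition range, with out-of-range dose pairs taking the nearer boundary
and a flag), and ZIP delta (marginal two-parameter logistic fits on each
monotherapy margin, conditional re-fits along each row/column with the
partner's fitted effect as the fixed lower asymptote, delta = mean
conditional response minus the multiplicative expectation). The
most-synergistic-area score is the best mean over contiguous 3×3 windows
of strictly-positive-dose cells (window size is a parameter and is
recorded in the output; 3×3 is the common convention). By construction
Bliss and ZIP are exactly zero on monotherapy margins. Note that the
generator applies its synergy offset before clipping inhibition to [0,1]:
grids driven close to full kill saturate, so recovery experiments use
dose ranges whose expected combined inhibition stays below 1.

Small assay utilities follow their standard formulas: calliper tumour
volume `L × W² / 2` and comparative-Cq expression fold change
`2^-ΔΔCq`.

## Pipeline and reproducibility

`run_pipeline()` wires the stages (simulate → cnv / ploidy / shift /
phospho / screen / synergy) through their declared file formats only —
minimal VCF v4.2 (`GT:AD:DP`, biallelic, strictly validated), 0-based
half-open window TSVs, labelled CSV matrices — and writes a JSON manifest
holding every stage's parameters, seeds and headline outputs. One global
seed fans out to per-stage seeds through a label-keyed hash, so any stage
can be re-run in isolation bit-identically; all randomness in the package
flows through this mechanism and never perturbs the caller's RNG state.
A thin command-line wrapper (`inst/scripts/tkiresist.R`) exposes the
stages as subcommands.

Problem sizes used by the shipped validation suite: 10,000 het sites per
chromosome at depth 60 and dispersion 0.2 across 20 seeds per ploidy for
ploidy recovery; all 2×2 tables with total ≤ 60 for the Fisher oracle;
5,000 variants × 20 replicates and 1,000 features × 10 seeds for the null
calibrations; 1,000 windows with two 250-window focal events × 20 seeds
for segmentation recovery; 20 seeds for IC50 recovery. These are the
sizes we consider sufficient for stable recovery statistics at desk
scale.

## Known limitations

* Clonal populations only: no subclonal copy-number states, no mixture
  deconvolution, no contamination model.
* The ploidy mixture fixes component means at `k/m` and shares one sigma;
  chromosomes with genuinely fractional (subclonal) ploidy will be forced
  to the nearest integer model or absorbed by the uniform background.
* The Fisher/binomial shift tests treat read counts as independent draws;
  mapping artefacts and strand biases are out of scope.
* The permutation FDR at 3-vs-3 designs has coarse granularity (20
  distinct relabellings) and should be read accordingly.
* Loewe scoring requires monotone fitted monotherapies with finite IC50;
  compounds without measurable monotherapy response are only scoreable by
  Bliss/ZIP.
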