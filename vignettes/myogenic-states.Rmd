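---
title: "Myogenic cell-state analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Myogenic cell-state analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myostate)
library(dplyr)
```

## The problem

Alveolar rhabdomyosarcoma (aRMS) is a pediatric soft-tissue sarcoma driven
by the PAX3::FOXO1 fusion. Its tumour cells occupy a spectrum of aberrant
myogenic states — from muscle-stem-cell-like (MuSC-like) cells through
cycling and committed progenitors to post-mitotic, myosin-heavy-chain
(MyHC) positive differentiated cells. Three analytical layers recur in
studies of this biology, and this package implements them as a tested,
reusable pipeline:

1. **Single-cell RNA-seq preprocessing**: per-cell quality control,
   hashtag-oligo (HTO) demultiplexing, log-normalization, gene-module
   scoring, cell-cycle classification and marker derivation.
2. **High-content imaging screens**: gating cells into five myogenic
   states from myogenin / Ki-67 / MyHC immunofluorescence, per-well
   composition summaries, and drug scores that quantify composition
   shifts toward differentiation or dedifferentiation.
3. **Clinical association**: a signed-signature statistic on a patient
   cohort with live/dead vital status, tested by label-flip permutation.

Every layer is exercisable on synthetic data with planted ground truth,
so the whole pipeline is testable without access to any external dataset.

## Single-cell QC and demultiplexing

`qc_metrics()` computes, per cell, the number of detected genes, total
UMIs, and the percentage of UMIs on mitochondrial features (matched by a
caller-supplied id set or the `"MT-"` name prefix; mitochondrial gene
inventories differ across references, so the list is never hard-coded).
`filter_cells()` removes low-quality cells by three rules with **strict**
boundaries: fewer than 200 or more than 8,000 genes, fewer than 1,000 or
more than 50,000 UMIs, or more than 15% mitochondrial UMIs. A cell sitting
exactly on a boundary survives, because the removal conditions are strict
inequalities. All five thresholds are exposed in `qc_thresholds()`.

HTO demultiplexing uses the centered log-ratio (CLR) transform with
pseudocount 1 (`clr_normalize_hto()`) followed by argmax assignment
(`demux_hashtags()`). The CLR vector of every cell sums to zero, which is
asserted in the tests, and the assignment rule is the *maximal HTO
signal*. We deliberately implement the stated decision rule rather than a
mixture-model demultiplexer: the rule is the auditable contract, and an
optional `min_margin` guards against near-ties by labelling such cells
`AMBIGUOUS`. How ambiguous cells are handled downstream is left to the
caller — the package flags, it does not silently drop.

## Module scores, cycling labels, markers

`log_normalize()` maps counts to `log1p(10^4 * x / cell_total)`.
`module_score()` implements expression-bin-matched signature scoring: all
genes are ranked by mean expression and cut into 25 equal-occupancy bins;
each signature gene draws 100 control genes from its own bin (seeded;
without replacement when the bin suffices, with replacement otherwise);
the score is the per-cell mean of signature genes minus the mean of the
control draw. Matching controls on expression removes the depth/abundance
component, so a randomly drawn signature scores zero in expectation — a
property the acceptance tests verify to within ±0.05 at 1,000 cells.

`classify_cycling()` labels a cell `HIGH_CYCLING` when its S-phase *or*
G2-M module score is strictly positive, otherwise `LOW_CYCLING`. Scores
exactly at zero — a measure-zero event for continuous scores — fall to
`LOW_CYCLING`; the choice is arbitrary but deterministic and documented.
The S and G2-M gene lists ship as editable text files
(`default_cell_cycle_genes()`), not as hard-coded truth.

`find_markers()` derives over-expressed cluster markers: candidates must
be expressed in at least 5% of the cluster's cells and exceed a log
fold change (difference of mean log-normalized expression) of 0.25; the
threshold is a plain parameter on the log scale of the data. Candidates
are tested with a two-sample Wilcoxon rank-sum test and
Bonferroni-corrected by the number of tests actually performed, retaining
`p < 0.05`. The rank-sum test is the package default; a bimodal
likelihood-ratio test is a recognised alternative for this task but is
out of scope here. Pairwise mode — used for survival signatures — keeps a
gene only if it clears every threshold against *each* other cluster, and
reports the weakest fold change and largest p-value across comparisons.

## Imaging gates and drug scores

`estimate_background()` takes the unstained control well included on
every plate and sets, per marker, the background threshold at its 99th
percentile (the quantile is a parameter; 1.0 gives the unstained
maximum). Positivity is strict (`> threshold`), so boundary intensities
are negative, and raising a threshold can never increase a positive
count. Thresholds are per plate by default because each plate carries its
own unstained reference.

`gate_cells()` assigns exactly one of five states: MyHC+ cells are
`DIFFERENTIATED` regardless of the other channels; the rest resolve on
the (myogenin, Ki-67) 2x2: −/− quiescent MuSC-like, −/+ cycling
MuSC-like, +/+ cycling progenitors, +/− noncycling committed progenitors.
`compose_wells()` aggregates to per-well percentages that sum to 100
exactly, flagging wells under 20 nuclei as low-confidence.

The **differentiating score** of a condition is
`(%committed + %differentiated − %cycling progenitors)` minus the same
bracket for the untreated control; the **dedifferentiating score** is
`(%quiescent + %cycling MuSC-like)` minus control. Replicate wells are
averaged at the *composition* level before scoring, which keeps the
control-vs-itself identity exactly zero and the scores exactly
antisymmetric. Hit rules: a differentiating hit strictly increases
committed+differentiated and strictly decreases cycling progenitors; a
dedifferentiating hit raises the MuSC-like percentage at least 1.5-fold
(boundary included, "at least"). Hits are called at the 1 µM reference
dose by default. When the control MuSC fraction is zero the fold is +Inf
if the treated fraction is positive (a hit) and undefined (`NA`, not a
hit) when both vanish. `combined_differentiating_score()` averages a
compound's differentiating scores at 10 µM, 1 µM, 100 nM and 10 nM and
subtracts the backbone score (e.g. 50 nM trametinib alone).
`classify_responder()` separates responders from nonresponders at a
strict 10% differentiated-cell threshold.

The strict hit inequalities carry no noise allowance, so with finitely
many nuclei per well a null compound can cross them by counting noise
alone. `screen_score()` therefore exposes a `margin` (percent points,
default 0 to match the stated rule exactly). The relevant noise scale is
the treated-minus-control bracket difference: at 2,000 nuclei per well
each state percentage has a binomial standard error of about 1 point, so
the difference has about 1.5; and because the percentages of one well are
multinomially *anticorrelated* (correlation around −0.5 between
committed+differentiated and cycling progenitors), a chance upward
excursion of one bracket tends to come with a downward excursion of the
other, inflating the joint false-positive rate of the two-sided rule well
above the independent-normal estimate. Our synthetic-screen checks use
`margin = 5` — about 3.3 standard errors of the bracket difference —
which brings the expected number of false positives among ~90 null
compounds below 0.01 per screen while leaving the planted 30-40-point
effects untouched. On real screens with replicate wells the margin can
stay at 0.

## The signed-signature survival test

For a signature in which each gene carries a direction (+1 up, −1 down),
`signature_statistic()` computes per gene the mean log-expression
difference between deceased and living patients and averages it over the
signature with the direction as sign; down-regulated genes contribute
with minus signs. The statistic reduces to a difference of group means of
a per-patient signed score, which makes each permutation O(patients).

`permutation_test()` builds the null by randomly flipping the live/dead
labels (permuting the status vector, preserving group sizes) and applies
the add-one correction `p = (1 + #extreme)/(1 + B)`. The correction keeps
permutation p-values valid and strictly positive — the attainable floor
is `1/(B+1)`, matching how very strong associations are reported as
bounds (e.g. `p < 1e-6` at 10^7 replicates). The default is two-sided,
because signatures can be enriched in deceased (positive T) or in living
(negative T) patients; one-sided variants are flags. `B` defaults to
10^4, enough to resolve p-values to 10^-4 at desk scale; larger `B` is
linear in time.

## The synthetic-data generators

`sim_config()` fixes the study conditions; every generator is a pure
function of it (plus, for HTO, a truth map), and identical configurations
yield byte-identical output. Defaults:

* **Counts**: negative binomial with shared dispersion 0.5
  (`variance = mu + 0.5 mu^2`) and baseline mean 0.5 per gene — typical
  UMI-scale sparsity; 20 marker genes per state elevated 4-fold
  (`marker_log2fc = 2`), three states of 200 cells. The mitochondrial
  fraction is drawn uniformly from [0.01, 0.10] per cell and realised
  *exactly* by allocating that share of the cell's UMIs to ten `MT-*`
  genes, so QC filtering on mitochondrial percentage is exactly
  controllable.
* **HTO**: background mean 10, true hashtag mean `signal_to_noise x 10`,
  dispersion 0.1 — antibody-derived tag counts are far less overdispersed
  than RNA UMIs, and at signal-to-noise 20 this yields the clean
  assignments the demultiplexing contract expects, while signal-to-noise
  1 is information-free by construction.
* **Plate**: each marker intensity is two-component lognormal
  (`meanlog` 4.6 for background, +2.5 in the positive component, `sdlog`
  0.4). The 2.5 log-unit separation (~6 sd) represents a clean stain;
  shrinking `intensity_sep` makes gating arbitrarily hard, which is how
  the difficulty knob is meant to be used.
* **Cohort**: Gaussian log2 expression (mean 5, sd 1) for 30 live + 30
  dead patients; a planted signature shifts up-genes by `+effect_log2fc`
  and down-genes by `−effect_log2fc` in the deceased, so the signed
  statistic has expectation `effect_log2fc` exactly.

What the generators do *not* emulate: doublets, ambient RNA, batch
effects, segmentation errors, spatial plate effects, or censored survival
times. Passing tests therefore demonstrate correctness of the
computational contracts on data with the assumed statistical structure,
not robustness to every artefact of real experiments.

## Problem sizes and numerical choices

The shipped test suite runs the whole pipeline at desk scale: 50 QC
matrices of 1,000 cells, 500-cell demultiplexing runs, 50 seeded
module-scoring simulations, a 96-compound screen at 2,000 nuclei per
well, and 500 null cohorts at B = 2,000 permutations for calibration
(empirical type-I error at alpha = 0.05 must land in the 99% binomial
interval [0.027, 0.078], and the p-values must pass a Kolmogorov-Smirnov
uniformity check at alpha = 0.01). These sizes keep the full suite under
a minute per stage while leaving the planted effects many standard errors
clear of their tolerances.

Other deliberate numerical choices: CLR uses pseudocount 1; quantiles use
R's default type-7 definition; equal-occupancy expression bins are cut on
ranks with ties broken by first occurrence, making binning deterministic;
`demux_hashtags()` ties and sub-margin leads are `AMBIGUOUS` rather than
arbitrarily resolved; ranking of shared screen hits breaks score ties
lexicographically by compound id so output order is reproducible.

## A worked example

```{r example, eval = FALSE}
layout <- dplyr::bind_rows(
  tibble::tibble(plate = "P1", well = "A1", compound = "drugA", dose_um = 1,
                 n_cells = 2000L, unstained = FALSE,
                 p_quiescent_musc = 0.2, p_cycling_musc = 0.2,
                 p_cycling_progenitor = 0.3, p_committed = 0.2,
                 p_differentiated = 0.1),
  tibble::tibble(plate = "P1", well = "H12", compound = "UNSTAINED",
                 dose_um = 0, n_cells = 500L, unstained = TRUE,
                 p_quiescent_musc = 0, p_cycling_musc = 0,
                 p_cycling_progenitor = 0, p_committed = 0,
                 p_differentiated = 0)
)
cfg <- sim_config(seed = 204, plate_layout = layout)
sim <- simulate_plate(cfg)
bg <- estimate_background(dplyr::filter(sim$cells, well == "H12"))
sim$cells |>
  dplyr::filter(well != "H12") |>
  gate_cells(bg) |>
  compose_wells()
```

## Limitations

* The marker test is the rank-sum approximation with normal p-values;
  exact small-sample p-values and the bimodal likelihood-ratio test are
  not provided.
* The Bonferroni denominator is the number of tests actually computed in
  the call; a caller comparing across several independent runs must
  correct across runs themselves.
* `AMBIGUOUS` hashtag cells and doublets are flagged, never imputed.
* The survival module tests a fixed signed signature; it does not derive
  signatures from the cohort, fit Cox models, or handle censoring.
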