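---
title: "Mapping a symptom-based cortico-hippocampal network: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a symptom-based cortico-hippocampal network: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippnet)
```

## The scientific problem

Amnestic mild cognitive impairment (aMCI) is a memory-predominant prodromal
state between normal aging and dementia, and long-term delayed recall (the
fifth part of the Auditory Verbal Learning Test, AVLT 5) is its most
sensitive behavioural marker. A recurring idea in network neuroscience is
that symptoms live on circuits rather than in single regions: a
symptom-based network is the set of regions whose *connectivity* with a seed
structure carries the symptom. hippnet implements one concrete recipe for
mapping such a network around the hippocampus, jointly constrained by
structural and functional connectivity, and for analysing what that network
does.

The pipeline has five stages:

1. **Structural constraint.** Candidate cortical nodes must have a
   white-matter connection to the hippocampal seed. Per subject and seed, a
   probabilistic-tractography connectivity value map over target regions is
   thresholded at a fraction (default 0.15) of its own maximum; a region is
   *consensus-connected* when it is suprathreshold in at least half of the
   control-group subjects.
2. **Functional connectivity.** Pearson correlations of regional mean time
   series, standardized by Fisher's z transform, `z = atanh(r)`.
3. **Network identification.** Per hemisphere, a Gaussian-identity GLM
   `score ~ group * (z_1 + ... + z_k)` over the consensus candidates. A
   candidate joins the network when its connectivity term is significant at
   `alpha = 0.05`; the seed is always a member.
4. **Graph analysis.** The network's FC matrix is binarized across a
   sparsity grid (0.15 to 0.45, step 0.01) and eight global properties are
   computed at each sparsity; each metric curve is summarized by its area
   under the curve (AUC).
5. **Association statistics.** Two-group comparisons with Cohen's *d*,
   Bonferroni-corrected score correlations, per-property group-by-property
   GLMs, and moderated regression with bootstrap confidence intervals.

## Design choices where the design was genuinely open

Several details of this recipe are under-determined in common usage, so the
package fixes a default and exposes the alternative:

* **Threshold strictness.** The proportion-of-maximum rule uses an
  *inclusive* comparison (`value >= fraction * max`). This keeps the
  all-equal map non-degenerate and guarantees the maximal unit is always
  retained.
* **Consensus rule.** How per-subject thresholded maps combine into one
  connection table is rarely stated in applied work; hippnet treats the
  required subject fraction as an explicit parameter (`consensus`,
  default 0.5, computed over control subjects only, matching the practice
  of running tractography in the control group).
* **Selection statistic.** Group-specific connectivity effects can be read
  off a group-by-FC model in three ways: the reference-group simple slope
  (default, with controls as the reference, matching the convention of
  reporting control-group effects), the best slope in either group, or the
  interaction term. All three are implemented (`rule =` in
  `select_nodes()`); the rule applied is recorded in the output. No
  multiplicity correction is applied at the selection step — selection
  p-values are screening statistics, and this is recorded in the rule
  record; the downstream property and correlation analyses are
  Bonferroni-corrected.
* **GLM family.** The behavioural score is approximately continuous
  (AVLT 5 ranges 0–12), so the default family is Gaussian with identity
  link; the `family` argument accepts any `stats::family`.
* **Metric conventions.** Published definitions of the eight global
  properties vary. hippnet adopts the conventions common to graph-theoretic
  neuroimaging toolboxes: nodal clustering averaged with zeros for
  degree-< 2 nodes; characteristic path length over connected pairs only
  (disconnected pairs contribute zero efficiency, not infinite length);
  local efficiency as the global efficiency of each node's
  neighbour-induced subgraph (note that igraph's `local_efficiency()`
  routes paths through the full graph, which is a different quantity, so
  this metric is computed directly); hierarchy as the exponent `beta` in
  `C ~ k^-beta`, estimated by least squares on log-log scale over nodes
  with degree >= 2 and positive clustering; synchronization as the
  Laplacian eigenratio `lambda_2 / lambda_max` of the largest connected
  component; and small-world sigma against degree-preserving rewired nulls
  (100 by default, `10 * |E|` attempted swaps each). Metrics undefined on
  a given graph (e.g. assortativity of a regular graph) return an `NA`
  sentinel.
* **Binarization arithmetic.** The edge count at sparsity `s` is
  `round(s * n(n-1)/2)` with round-half-away-from-zero; ties in edge weight
  are broken deterministically (weight descending, then lexicographic node
  pair), so binarization is a pure function of the matrix.
* **AUC with gaps.** Trapezoidal integration on the actual grid spacing;
  intervals with an undefined endpoint are dropped and the covered fraction
  is recorded; a curve with more than half its points undefined gets an
  undefined AUC.
* **Moderation.** `moderation_analysis()` mean-centres the predictor and
  moderator before forming the product (the convention of the common
  moderation macros), uses case-resampling percentile bootstrap intervals
  (bias-corrected variants are deliberately not the default), and reports
  both the raw and the standardized interaction coefficient, since
  published moderation effects are sometimes printed on the standardized
  scale.
* **Group tests.** The pooled-variance t test is the default (matching
  classical cohort tables); Welch's test is behind the `welch` flag. The
  Cohen's *d* confidence interval uses the standard normal approximation
  with `SE = sqrt(1/n1 + 1/n2 + d^2/(2(n1+n2)))`.

## The synthetic cohort: what it emulates and what it does not

`generate_cohort()` draws a full multi-modal dataset with planted ground
truth, sized by default like a typical memory-clinic case-control cohort
(58 controls, 73 patients). Its model:

* **Time series** follow a one-factor-per-hemisphere Gaussian model: the
  hippocampal seed signal is the factor, and each ipsilateral cortical
  region loads on it with a subject-specific latent correlation drawn as
  `tanh` of a Gaussian on the Fisher-z scale (mean 0.3, SD 0.1). Only
  second-order statistics matter downstream, so no attempt is made to
  emulate autocorrelation, physiological noise, or head motion.
* **The behavioural score** is a linear function of the subject's *sample*
  Fisher-z connectivity for the planted seed–region pairs, with
  group-specific slopes, group intercepts (6.7 controls / 2.1 patients, on
  the AVLT 5 scale), covariate terms (age uniform on 55–80 years;
  an everyday-cognition score, Gaussian, shifted +4 in patients — both
  seeded by published cohort summaries), an optional moderation term
  `gamma * age_c * z_moderator`, and Gaussian noise. Using the sample
  rather than the latent connectivity makes stage outputs compose exactly:
  with `noise_sd = 0` and covariate slopes zero, the identification GLM
  recovers the planted slopes to machine precision, which is the package's
  strongest self-test.
* **Structural maps** draw white-matter-connected targets uniformly in
  [0.45, 1] and unconnected targets in [0.005, 0.06] times a subject-level
  scale, so the 15%-of-maximum threshold separates them with certainty:
  consensus recovery of the planted wiring is exact by construction. Real
  tractography maps have no such margin; the structural stage's tests
  therefore validate the *rule*, not tractography.
* **Default planted effects** echo the magnitudes of published
  hippocampus–cortex connectivity slopes on a delayed-recall scale (about
  3–7 score points per unit Fisher-z, present in the control group and
  absent in patients): five left-hemisphere pairs and two right-hemisphere
  pairs. These magnitudes are calibrated to published fitted coefficients,
  not ground truth about any real cohort.
* **Reproducibility.** One RNG substream per subject, split from the cohort
  seed by counter, so enlarging a cohort leaves earlier subjects bitwise
  unchanged.

Passing tests on this generator show that the pipeline's algebra and
selection logic are correct under a well-specified linear world. They do
not show robustness to preprocessing artefacts, autocorrelated BOLD noise,
non-linear FC–symptom coupling, or tractography false positives.

## Numerical and calibration notes

Problem sizes for the replication studies were chosen to keep the full
suite comfortably fast while leaving the Monte-Carlo error well inside each
tolerance band:

* Zero-noise slope recovery is checked to `1e-8` on a 60-subject cohort.
* Node-set recovery uses 200 replicate cohorts of 60 + 60 subjects with 200
  timepoints and strong left-lateralized effects (slopes 3.2 to 7.3, score
  noise SD 0.5, covariate slopes zero so the covariate-free selection model
  is correctly specified); recovery means the selected left set *equals*
  the planted set. Pilot power analysis puts per-node power near 1 and the
  exact-recovery rate near 0.95, dominated by the 5% per-candidate
  false-positive rate among unplanted consensus candidates.
* Type-I calibration pools the control-group slope p-values of eight null
  candidates over 100 null cohorts (800 tests, Monte-Carlo SE about 0.008
  for a 0.05 rate).
* Bootstrap coverage uses 500 replicates at n = 100 with 1000 resamples
  each; percentile intervals for a well-specified interaction sit near
  0.96 there.
* The KS uniformity check of the interaction p-value under equal planted
  slopes uses 150 small replicate cohorts.

Degenerate inputs are first-class: all-zero structural maps, zero-variance
series, perfectly correlated duplicate signals, rank-deficient designs,
constant properties, sparsities yielding zero edges, and graphs on which a
metric is undefined all raise typed errors or return documented sentinels
rather than propagating NaNs.

## Worked example

```{r example, eval = FALSE}
cfg <- simulation_config(n_hc = 30, n_amci = 30, n_timepoints = 200,
                         rng_seed = 7)
cohort <- generate_cohort(cfg)

wm <- consensus_nodes(
  dplyr::semi_join(cohort$structural,
                   dplyr::filter(cohort$subjects, group == "HC"),
                   by = "subject_id"))
fc <- build_fc_matrices(cohort)
nets <- identify_network(cohort$subjects, fc, wm)
nets$L$nodes

curves <- global_property_curves(fc, nodes = nets$L$nodes,
                                 n_null = 100, rng_seed = 7)
auc <- property_auc(curves)
autoplot(curves, groups = cohort$subjects[, c("subject_id", "group")])

property_interaction_glm(cohort$subjects, auc)
```

Or, end to end with every intermediate persisted and checksummed:

```{r runall, eval = FALSE}
manifest <- run_all(list(simulate = list(n_hc = 30, n_amci = 30),
                         n_null = 100, seed = 7),
                    out_dir = "run1")
```

## Known limitations

* The pipeline consumes *preprocessed* inputs: regional time series and
  tractography value maps. Eddy/motion correction, registration, nuisance
  regression, and streamline generation are upstream concerns.
* Only full Pearson correlation is implemented for FC (no partial
  correlation, no sliding-window variants).
* Graph analysis is restricted to the eight global properties of
  undirected, unweighted networks; no weighted metrics, nodal statistics,
  or community structure.
* Moderation is a single-moderator linear model; no mediation or SEM.
* Left/right networks are identified independently; inter-hemispheric
  connectivity never enters a model.
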