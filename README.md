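# hippnet

**Symptom-guided cortico-hippocampal network mapping from structural and
functional connectivity.**

hippnet is for researchers studying memory-related brain networks in
case-control cohorts (for example amnestic mild cognitive impairment, aMCI,
versus healthy controls). It implements a complete, testable pipeline for
mapping a *symptom-based* brain network: the set of cortical regions whose
connectivity with a hippocampal seed carries a behavioural symptom — here
long-term delayed recall (AVLT part 5) — with candidate nodes jointly
constrained by structural *and* functional connectivity.

## The method

For a two-group cohort with regional fMRI time series, per-seed
probabilistic-tractography connectivity value maps, and behavioural scores:

1. **Structural constraint.** Per subject and hippocampal seed, a target
   region survives when its connectivity value is at least a fraction
   (default 0.15) of the map's maximum; a region is consensus-connected
   when suprathreshold in at least half of the control subjects.
2. **Functional connectivity.** Fisher-z transformed Pearson correlations
   of the regional mean time series, *z* = atanh(*r*).
3. **Network identification.** Per hemisphere, a Gaussian GLM

   score ~ group + Σⱼ zⱼ + Σⱼ group × zⱼ

   over the consensus candidates *z*ⱼ (seed-to-region Fisher-z). A
   candidate joins the network when its group-specific simple slope
   (controls by default) has *p* < α = 0.05; the seed is always a member.
4. **Graph analysis.** The network's FC matrix is binarized over the
   sparsity grid 0.15–0.45 (step 0.01, 31 points) and eight global
   properties are computed at each point — assortativity, hierarchy
   (*C* ∝ *k*^−β), synchronization (Laplacian eigenratio λ₂/λ_max),
   small-world sigma (against degree-preserving rewired nulls), clustering
   coefficient Cp, characteristic path length Lp, global efficiency
   E_global, and local efficiency E_local — each summarized by its area
   under the curve (AUC) across the grid.
5. **Association statistics.** Two-group comparisons with Cohen's *d*
   (pooled SD), Bonferroni-corrected Pearson correlations, per-property
   group × property GLMs, and moderated regression (mean-centred
   *y* ~ *x* + *m* + *x·m*) with case-resampling percentile bootstrap
   confidence intervals.

A synthetic-cohort generator with planted ground truth
(`simulation_config()` / `generate_cohort()`) makes every stage testable
end-to-end without any imaging data: with zero score noise the pipeline
recovers planted effects to machine precision, and replication studies
measure node-recovery rates, type-I error, and bootstrap coverage.

## Worked example

```r
library(hippnet)

cfg <- simulation_config(n_hc = 60, n_amci = 60, n_timepoints = 200,
                         rng_seed = 7, noise_sd = 0.5,
                         covariate_spec = list(beta_age = 0, beta_ecog = 0))
cohort <- generate_cohort(cfg)

wm <- consensus_nodes(
  dplyr::semi_join(cohort$structural,
                   dplyr::filter(cohort$subjects, group == "HC"),
                   by = "subject_id"))
fc   <- build_fc_matrices(cohort)
nets <- identify_network(cohort$subjects, fc, wm)
nets$L
#> <hippnet_network> seed HIP.L: 6 node(s) [rule ref_slope, alpha 0.05]
#>    HIP.L, CTX.L.01, CTX.L.02, CTX.L.03, CTX.L.04, CTX.L.05
cohort$truth$true_nodes$L
#> [1] "CTX.L.01" "CTX.L.02" "CTX.L.03" "CTX.L.04" "CTX.L.05"
```

The identified left network contains the seed plus exactly the five
planted regions. Graph properties of that network over the sparsity grid
(a couple of minutes for 120 subjects with 100 sigma nulls per point):

```r
curves <- global_property_curves(fc, nodes = nets$L$nodes,
                                 n_null = 100, rng_seed = 7)
auc <- property_auc(curves)
dplyr::filter(auc, subject_id == "sub001")
#>   subject_id metric             auc coverage
#> 1 sub001     assortativity   -0.146    0.733
#> 2 sub001     cp               0.119    1
#> 3 sub001     eglobal          0.119    1
#> 4 sub001     elocal           0.122    1
#> 5 sub001     hierarchy        0.467    0.7
#> 6 sub001     lp               0.405    1
#> 7 sub001     sigma            0.280    0.933
#> 8 sub001     synchronization  0.117    1
```

`auc` is the trapezoidal area of each metric curve over sparsity 0.15–0.45;
`coverage` < 1 flags grid points where the metric was undefined on the
small binarized graph (an `NA` sentinel, excluded pairwise from the
integral). Effect sizes from group summary statistics:

```r
cohens_d(28.33, 1.43, 58, 26.70, 1.71, 73)   # e.g. an MMSE group contrast
#>       d conf_low conf_high
#> 1  1.02    0.657      1.39
```

`run_all()` chains all five stages from a single config (YAML/JSON file or
list), persists every intermediate as CSV/JSON, and returns a checksummed
manifest; re-running with the same config and seed reproduces identical
checksums.

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the model and its
assumptions, every convention choice (threshold strictness, consensus
rule, selection statistic, metric definitions, binarization arithmetic,
bootstrap flavour), what the synthetic cohort does and does not emulate,
and known limitations.
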