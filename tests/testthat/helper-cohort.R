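# Small cohort configurations used across tests.

tiny_config <- function(..., rng_seed = 11) {
  simulation_config(
    n_hc = 10, n_amci = 10, n_regions = 10, n_timepoints = 60,
    rng_seed = rng_seed, ...
  )
}

# Effects planted in the left hemisphere only, no covariate influence and no
# score noise: downstream model fits are exact linear algebra.
exact_config <- function(n_hc = 30, n_amci = 30, n_timepoints = 150,
                         rng_seed = 21, betas = c(3, -4)) {
  simulation_config(
    n_hc = n_hc, n_amci = n_amci, n_regions = 12, n_timepoints = n_timepoints,
    wm_connected_regions = list(L = c(2, 3, 4), R = c(8, 9)),
    fc_effect_map = tibble::tibble(
      seed = "L", region = c(2L, 3L),
      beta_hc = betas, beta_amci = c(betas[1] / 2, 0)
    ),
    noise_sd = 0,
    covariate_spec = list(beta_age = 0, beta_ecog = 0, gamma = 0),
    rng_seed = rng_seed
  )
}

hc_structural <- function(cohort) {
  ids <- cohort$subjects$subject_id[as.character(cohort$subjects$group) == "HC"]
  cohort$structural[cohort$structural$subject_id %in% ids, ]
}
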