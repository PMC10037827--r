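#' Configure a synthetic two-group cohort
#'
#' Builds a validated configuration for [generate_cohort()]. The simulated
#' design mirrors a case-control memory-clinic study: two groups (healthy
#' controls and amnestic MCI patients), regional resting-state time series
#' whose hippocampus-cortex functional connectivity carries group-dependent
#' linear effects on a delayed-recall score, per-seed structural connectivity
#' value maps with planted suprathreshold target regions, and covariates
#' (age, an everyday-cognition score) with an optional planted moderation
#' slope of the score-age relationship by a designated connectivity pair.
#'
#' Regions are indexed `1:n_regions`; the first half belong to the left
#' hemisphere, the second half to the right, and `seed_regions` names the two
#' hippocampal seeds (one per hemisphere). Subject time series follow a
#' one-factor-per-hemisphere Gaussian model: each cortical region loads on
#' its ipsilateral seed signal with a subject-specific latent correlation
#' (drawn as `tanh` of a Gaussian Fisher-z), so the pipeline's second-order
#' statistics are controlled directly. The behavioural score is a linear
#' function of the subject's *sample* Fisher-z connectivity (not the latent
#' value), so that with `noise_sd = 0` downstream model fits recover the
#' planted slopes exactly.
#'
#' @param n_hc,n_amci Group sizes. Defaults follow a typical published
#'   case-control cohort (58 controls, 73 patients).
#' @param n_regions Total number of regions (seeds + cortical targets),
#'   split evenly between hemispheres.
#' @param n_timepoints Length of each regional time series (>= 50).
#' @param seed_regions Integer vector of length 2: indices of the left and
#'   right hippocampal seed within `1:n_regions`.
#' @param wm_connected_regions Named list (`L`, `R`) of cortical region
#'   indices with a planted white-matter connection to the ipsilateral seed.
#' @param fc_effect_map Data frame with columns `seed` ("L"/"R"), `region`
#'   (index), `beta_hc`, `beta_amci`: slopes linking each pair's Fisher-z
#'   connectivity to the behavioural score, per group. Every region must be
#'   white-matter connected to its seed.
#' @param noise_sd Standard deviation of the Gaussian score noise.
#' @param intercept_hc,intercept_amci Group-specific score intercepts
#'   (delayed-recall scale, 0-12 in the emulated instrument).
#' @param covariate_spec List controlling covariates and moderation:
#'   `age_min`/`age_max` (uniform age range, years), `ecog_mean`/`ecog_sd`
#'   (daily-function score), `ecog_shift_amci` (additive patient-group
#'   shift), `beta_age`, `beta_ecog` (main-effect slopes on the centred
#'   covariates), `gamma` (moderation slope: change in the score-age slope
#'   per unit Fisher-z of the moderator pair), `moderator` (list with
#'   `seed`, `region`, or `NULL` for no moderation term).
#' @param latent_z_mean,latent_z_sd Mean and SD of the latent Fisher-z
#'   seed-cortex coupling from which subject loadings are drawn.
#' @param rng_seed Integer seed; the cohort is a deterministic function of
#'   the configuration including this seed.
#'
#' @return A `hippnet_sim_config` list.
#' @seealso [generate_cohort()]
#' @export
simulation_config <- function(n_hc = 58,
                              n_amci = 73,
                              n_regions = 18,
                              n_timepoints = 200,
                              seed_regions = c(1L, n_regions / 2 + 1L),
                              wm_connected_regions = NULL,
                              fc_effect_map = NULL,
                              noise_sd = 1.5,
                              intercept_hc = 6.7,
                              intercept_amci = 2.1,
                              covariate_spec = list(),
                              latent_z_mean = 0.3,
                              latent_z_sd = 0.1,
                              rng_seed = 1L) {
  for (nm in c("n_hc", "n_amci", "n_regions", "n_timepoints")) {
    if (!is_count(get(nm))) stop_config(sprintf("`%s` must be a positive integer", nm), nm)
  }
  if (n_regions < 6 || n_regions %% 2 != 0) {
    stop_config("`n_regions` must be an even count >= 6", "n_regions")
  }
  if (n_timepoints < 50) {
    stop_config("`n_timepoints` must be >= 50 so sample correlations are estimable",
                "n_timepoints")
  }
  half <- n_regions / 2
  seed_regions <- as.integer(seed_regions)
  if (length(seed_regions) != 2 ||
      !(seed_regions[1] %in% 1:half) ||
      !(seed_regions[2] %in% (half + 1):n_regions)) {
    stop_config("`seed_regions` must hold one left-hemisphere and one right-hemisphere index",
                "seed_regions")
  }

  if (is.null(wm_connected_regions)) {
    cortical_l <- setdiff(1:half, seed_regions[1])
    cortical_r <- setdiff((half + 1):n_regions, seed_regions[2])
    wm_connected_regions <- list(
      L = cortical_l[seq_len(min(5, length(cortical_l)))],
      R = cortical_r[seq_len(min(3, length(cortical_r)))]
    )
  }
  if (!is.list(wm_connected_regions) ||
      !all(c("L", "R") %in% names(wm_connected_regions))) {
    stop_config("`wm_connected_regions` must be a named list with elements L and R",
                "wm_connected_regions")
  }
  wm_connected_regions <- lapply(wm_connected_regions, as.integer)
  cortical <- list(L = setdiff(1:half, seed_regions[1]),
                   R = setdiff((half + 1):n_regions, seed_regions[2]))
  for (h in c("L", "R")) {
    if (length(wm_connected_regions[[h]]) < 1 ||
        !all(wm_connected_regions[[h]] %in% cortical[[h]])) {
      stop_config(sprintf(
        "`wm_connected_regions$%s` must name >= 1 ipsilateral cortical region", h),
        "wm_connected_regions")
    }
  }

  if (is.null(fc_effect_map)) {
    # Default planted effects echo the magnitude of published hippocampus-
    # cortex connectivity slopes on a delayed-recall scale: five left pairs
    # and two right pairs with control-group effects, absent in patients.
    betas <- c(3.2, 4.2, 3.8, -7.3, 5.3, 6.7, 4.4)
    pairs <- rbind(
      data.frame(seed = "L", region = wm_connected_regions$L[seq_len(min(5, length(wm_connected_regions$L)))]),
      data.frame(seed = "R", region = wm_connected_regions$R[seq_len(min(2, length(wm_connected_regions$R)))])
    )
    fc_effect_map <- tibble::tibble(
      seed = pairs$seed, region = as.integer(pairs$region),
      beta_hc = betas[seq_len(nrow(pairs))], beta_amci = 0
    )
  }
  fc_effect_map <- tibble::as_tibble(fc_effect_map)
  require_columns(fc_effect_map, c("seed", "region", "beta_hc", "beta_amci"),
                  "`fc_effect_map`")
  fc_effect_map$region <- as.integer(fc_effect_map$region)
  for (i in seq_len(nrow(fc_effect_map))) {
    s <- fc_effect_map$seed[i]
    if (!s %in% c("L", "R")) stop_config("`fc_effect_map$seed` must be 'L' or 'R'", "fc_effect_map")
    if (!fc_effect_map$region[i] %in% wm_connected_regions[[s]]) {
      stop_config(sprintf(
        "fc_effect_map region %d is not white-matter connected to seed %s",
        fc_effect_map$region[i], s), "fc_effect_map")
    }
  }

  cov_default <- list(
    age_min = 55, age_max = 80,
    ecog_mean = 17.4, ecog_sd = 5.5, ecog_shift_amci = 4,
    beta_age = -0.08, beta_ecog = -0.04,
    gamma = 0, moderator = NULL
  )
  unknown <- setdiff(names(covariate_spec), names(cov_default))
  if (length(unknown) > 0) {
    stop_config(paste0("unknown covariate_spec field(s): ",
                       paste(unknown, collapse = ", ")), "covariate_spec")
  }
  cov <- utils::modifyList(cov_default, covariate_spec)
  if (cov$age_min >= cov$age_max) stop_config("age_min must be < age_max", "covariate_spec")
  if (cov$ecog_sd < 0) stop_config("ecog_sd must be >= 0", "covariate_spec")
  if (!is.null(cov$moderator)) {
    ms <- cov$moderator$seed
    mr <- as.integer(cov$moderator$region)
    if (is.null(ms) || is.null(mr) || !ms %in% c("L", "R") || !mr %in% cortical[[ms]]) {
      stop_config("covariate_spec$moderator must give a valid seed ('L'/'R') and ipsilateral cortical region",
                  "covariate_spec")
    }
    cov$moderator <- list(seed = ms, region = mr)
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || noise_sd < 0) {
    stop_config("`noise_sd` must be a single value >= 0", "noise_sd")
  }
  if (!is_prob(latent_z_sd, open_left = FALSE) && latent_z_sd > 1) {
    stop_config("`latent_z_sd` must be small and nonnegative", "latent_z_sd")
  }
  if (!is_count(rng_seed %||% NA)) stop_config("`rng_seed` must be a positive integer", "rng_seed")

  structure(list(
    n_hc = as.integer(n_hc), n_amci = as.integer(n_amci),
    n_regions = as.integer(n_regions), n_timepoints = as.integer(n_timepoints),
    seed_regions = seed_regions,
    wm_connected_regions = wm_connected_regions,
    fc_effect_map = fc_effect_map,
    noise_sd = noise_sd,
    intercept_hc = intercept_hc, intercept_amci = intercept_amci,
    covariate_spec = cov,
    latent_z_mean = latent_z_mean, latent_z_sd = latent_z_sd,
    rng_seed = as.integer(rng_seed)
  ), class = "hippnet_sim_config")
}

#' Node catalog for a simulation configuration
#'
#' @param config A `hippnet_sim_config`.
#' @return Tibble with columns `region` (name), `index`, `hemisphere`,
#'   `role` ("seed" or "cortex").
#' @export
node_catalog <- function(config) {
  stopifnot(inherits(config, "hippnet_sim_config"))
  half <- config$n_regions / 2
  hemi <- rep(c("L", "R"), each = half)
  idx <- seq_len(config$n_regions)
  role <- ifelse(idx %in% config$seed_regions, "seed", "cortex")
  # stable names: HIP.<h> for seeds, CTX.<h>.<k> for cortical targets
  name <- character(config$n_regions)
  for (h in c("L", "R")) {
    ih <- which(hemi == h)
    ctx <- ih[role[ih] == "cortex"]
    name[ih[role[ih] == "seed"]] <- paste0("HIP.", h)
    name[ctx] <- sprintf("CTX.%s.%02d", h, seq_along(ctx))
  }
  tibble::tibble(region = name, index = idx, hemisphere = hemi, role = role)
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Draws a full multi-modal dataset from a [simulation_config()]: a subject
#' phenotype table, per-subject regional time series, per-seed structural
#' connectivity value maps, and the planted ground truth. The generator uses
#' one RNG substream per subject, derived from `rng_seed` by counter, so
#' enlarging the cohort leaves earlier subjects unchanged.
#'
#' Structural maps draw white-matter-connected regions uniformly in
#' \[0.45, 1\] and unconnected regions in \[0.005, 0.06\] (times a
#' subject-level scale), so a 15%-of-maximum threshold always separates them:
#' the planted margins respect the thresholding rule by construction.
#'
#' @param config A `hippnet_sim_config`.
#' @return A `hippnet_cohort` list with elements `subjects` (tibble:
#'   `subject_id`, `group`, `avlt5`, `age`, `ecog`), `timeseries` (named list
#'   of time-by-region matrices), `structural` (tibble: `subject_id`, `seed`,
#'   `region`, `value`), `nodes` (node catalog), `truth` (planted
#'   `true_nodes`, `true_betas`, `true_gamma`, per-subject latent loadings),
#'   and `config`.
#' @examples
#' cfg <- simulation_config(n_hc = 8, n_amci = 8, n_timepoints = 60, rng_seed = 7)
#' cohort <- generate_cohort(cfg)
#' cohort$subjects
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "hippnet_sim_config")) {
    stop_config("`config` must be built with simulation_config()", "config")
  }
  nodes <- node_catalog(config)
  n_total <- config$n_hc + config$n_amci
  cov <- config$covariate_spec
  half <- config$n_regions / 2
  hemi_of <- nodes$hemisphere
  seed_idx <- setNames(config$seed_regions, c("L", "R"))

  groups <- rep(c("HC", "aMCI"), times = c(config$n_hc, config$n_amci))
  ids <- sprintf("sub%03d", seq_len(n_total))

  # per-subject substreams split by counter from the cohort stream
  sub_seeds <- with_rng(config$rng_seed,
                        sample.int(.Machine$integer.max - 1L, n_total))

  age_mid <- (cov$age_min + cov$age_max) / 2
  betas <- config$fc_effect_map

  timeseries <- vector("list", n_total)
  names(timeseries) <- ids
  structural <- vector("list", n_total)
  loadings <- vector("list", n_total)
  subjects <- vector("list", n_total)

  for (i in seq_len(n_total)) {
    out <- with_rng(sub_seeds[i], {
      grp <- groups[i]
      # latent seed-cortex coupling per cortical region (Fisher-z scale)
      z_lat <- rnorm(config$n_regions, config$latent_z_mean, config$latent_z_sd)
      lambda <- tanh(z_lat)
      # one latent factor per hemisphere = the seed signal
      tpts <- config$n_timepoints
      fac <- list(L = rnorm(tpts), R = rnorm(tpts))
      ts <- matrix(NA_real_, tpts, config$n_regions,
                   dimnames = list(NULL, nodes$region))
      for (j in seq_len(config$n_regions)) {
        h <- hemi_of[j]
        if (j %in% seed_idx) {
          ts[, j] <- fac[[h]]
        } else {
          ts[, j] <- lambda[j] * fac[[h]] +
            sqrt(1 - lambda[j]^2) * rnorm(tpts)
        }
      }
      # sample Fisher-z for pairs entering the score
      z_of <- function(s, r) atanh(cor(ts[, seed_idx[[s]]], ts[, r]))
      age <- runif(1, cov$age_min, cov$age_max)
      ecog <- rnorm(1, cov$ecog_mean + if (grp == "aMCI") cov$ecog_shift_amci else 0,
                    cov$ecog_sd)
      score <- if (grp == "HC") config$intercept_hc else config$intercept_amci
      if (nrow(betas) > 0) {
        bcol <- if (grp == "HC") betas$beta_hc else betas$beta_amci
        for (k in seq_len(nrow(betas))) {
          score <- score + bcol[k] * z_of(betas$seed[k], betas$region[k])
        }
      }
      score <- score + cov$beta_age * (age - age_mid) +
        cov$beta_ecog * (ecog - cov$ecog_mean)
      if (!is.null(cov$moderator) && cov$gamma != 0) {
        score <- score + cov$gamma * (age - age_mid) *
          z_of(cov$moderator$seed, cov$moderator$region)
      }
      score <- score + if (config$noise_sd > 0) rnorm(1, 0, config$noise_sd) else 0

      # structural value maps: ipsilateral cortical targets per seed
      smap <- lapply(c("L", "R"), function(h) {
        ctx <- nodes$index[nodes$hemisphere == h & nodes$role == "cortex"]
        connected <- ctx %in% config$wm_connected_regions[[h]]
        scale <- runif(1, 500, 5000)
        val <- ifelse(connected,
                      runif(length(ctx), 0.45, 1),
                      runif(length(ctx), 0.005, 0.06)) * scale
        tibble::tibble(subject_id = ids[i], seed = paste0("HIP.", h),
                       region = nodes$region[match(ctx, nodes$index)],
                       value = val)
      })
      list(ts = ts, smap = dplyr::bind_rows(smap), lambda = lambda,
           row = tibble::tibble(subject_id = ids[i], group = grp,
                                avlt5 = score, age = age, ecog = ecog))
    })
    timeseries[[i]] <- out$ts
    structural[[i]] <- out$smap
    loadings[[i]] <- out$lambda
    subjects[[i]] <- out$row
  }

  subjects <- dplyr::bind_rows(subjects)
  subjects$group <- factor(subjects$group, levels = c("HC", "aMCI"))

  true_nodes <- lapply(c("L", "R"), function(h) {
    idx <- betas$region[betas$seed == h &
                          (betas$beta_hc != 0 | betas$beta_amci != 0)]
    nodes$region[match(sort(unique(idx)), nodes$index)]
  })
  names(true_nodes) <- c("L", "R")

  structure(list(
    subjects = subjects,
    timeseries = timeseries,
    structural = dplyr::bind_rows(structural),
    nodes = nodes,
    truth = list(true_nodes = true_nodes,
                 true_betas = betas,
                 true_gamma = cov$gamma,
                 latent_loadings = do.call(rbind, loadings)),
    config = config
  ), class = "hippnet_cohort")
}

#' @export
print.hippnet_cohort <- function(x, ...) {
  cat("<hippnet_cohort>\n")
  cat(sprintf("  subjects:   %d (%s)\n", nrow(x$subjects),
              paste(sprintf("%s n=%d", levels(x$subjects$group),
                            table(x$subjects$group)), collapse = ", ")))
  cat(sprintf("  regions:    %d (%d per hemisphere), %d timepoints\n",
              x$config$n_regions, x$config$n_regions / 2, x$config$n_timepoints))
  cat(sprintf("  planted nodes: L {%s}; R {%s}\n",
              paste(x$truth$true_nodes$L, collapse = ", "),
              paste(x$truth$true_nodes$R, collapse = ", ")))
  invisible(x)
}
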