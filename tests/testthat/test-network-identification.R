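test_that("zero-noise cohorts yield exact recovery of the planted slopes", {
  cfg <- exact_config()
  co <- generate_cohort(cfg)
  fc <- build_fc_matrices(co)
  cand <- co$nodes$region[cfg$wm_connected_regions$L]
  fit <- fit_symptom_glm(co$subjects, fc, "HIP.L", cand)
  tb <- cfg$fc_effect_map
  ss <- dplyr::filter(fit$simple_slopes, .data$term == "simple_slope")
  for (k in seq_len(nrow(tb))) {
    reg <- co$nodes$region[tb$region[k]]
    expect_equal(ss$estimate[ss$region == reg & ss$group == "HC"],
                 tb$beta_hc[k], tolerance = 1e-8)
    expect_equal(ss$estimate[ss$region == reg & ss$group == "aMCI"],
                 tb$beta_amci[k], tolerance = 1e-8)
  }
  # the unplanted candidate has an exactly-zero slope in both groups
  null_reg <- setdiff(cand, co$nodes$region[tb$region])
  expect_equal(ss$estimate[ss$region == null_reg], c(0, 0), tolerance = 1e-8)
})

test_that("single-predictor Wald test matches brute-force least squares", {
  co <- generate_cohort(tiny_config(noise_sd = 1))
  fc <- build_fc_matrices(co)
  target <- co$nodes$region[co$config$wm_connected_regions$L[1]]
  fit <- fit_symptom_glm(co$subjects, fc, "HIP.L", target)

  # hand-built design: intercept, group dummy, z, group x z
  z <- vapply(co$subjects$subject_id,
              function(id) fc[[id]]["HIP.L", target], numeric(1))
  g <- as.integer(co$subjects$group == "aMCI")
  X <- cbind(1, g, z, g * z)
  y <- co$subjects$avlt5
  bh <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% bh
  s2 <- sum(res^2) / (length(y) - ncol(X))
  Vh <- s2 * solve(t(X) %*% X)
  t_z <- bh[3] / sqrt(Vh[3, 3])
  p_z <- 2 * pt(-abs(t_z), length(y) - ncol(X))

  hc_row <- fit$simple_slopes[fit$simple_slopes$group == "HC" &
                                fit$simple_slopes$term == "simple_slope", ]
  expect_equal(hc_row$estimate, bh[3], tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(hc_row$p_value, p_z, tolerance = 1e-10, ignore_attr = TRUE)
  int_row <- fit$simple_slopes[fit$simple_slopes$term == "interaction", ]
  expect_equal(int_row$estimate, bh[4], tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("selection respects alpha monotonicity and the structural filter", {
  cfg <- exact_config(betas = c(6, -6))
  co <- generate_cohort(cfg)
  fc <- build_fc_matrices(co)
  wm <- consensus_nodes(hc_structural(co))
  cand <- wm$region[wm$seed == "HIP.L" & wm$consensus]
  fit <- fit_symptom_glm(co$subjects, fc, "HIP.L", cand)

  sel <- lapply(c(0.2, 0.05, 0.001, 0), function(a) {
    suppressWarnings(select_nodes(fit, wm, alpha = a)$nodes)
  })
  for (i in seq_len(length(sel) - 1)) {
    expect_true(all(sel[[i + 1]] %in% sel[[i]]))
  }
  expect_identical(sel[[4]], "HIP.L")  # alpha = 0 keeps only the seed

  # nodes failing the consensus filter can never be selected
  wm_none <- dplyr::mutate(wm, consensus = FALSE)
  expect_warning(select_nodes(fit, wm_none, alpha = 0.5),
                 class = "hippnet_warning_empty_network")
  empty <- suppressWarnings(select_nodes(fit, wm_none, alpha = 0.5))
  expect_identical(empty$nodes, "HIP.L")
})

test_that("relabelling the group flips interaction signs but not the selected set", {
  co <- generate_cohort(exact_config(betas = c(5, -5)))
  fc <- build_fc_matrices(co)
  cand <- co$nodes$region[co$config$wm_connected_regions$L]
  f_hc <- fit_symptom_glm(co$subjects, fc, "HIP.L", cand, ref_group = "HC")
  f_am <- fit_symptom_glm(co$subjects, fc, "HIP.L", cand, ref_group = "aMCI")
  i_hc <- f_hc$simple_slopes[f_hc$simple_slopes$term == "interaction", ]
  i_am <- f_am$simple_slopes[f_am$simple_slopes$term == "interaction", ]
  expect_equal(i_hc$estimate, -i_am$estimate[match(i_hc$region, i_am$region)],
               tolerance = 1e-8)
  s1 <- suppressWarnings(select_nodes(f_hc, alpha = 0.05, rule = "any_slope"))
  s2 <- suppressWarnings(select_nodes(f_am, alpha = 0.05, rule = "any_slope"))
  expect_setequal(s1$nodes, s2$nodes)
})

test_that("interaction p-values are uniform when both groups share the slope", {
  reps <- 150
  pvals <- vapply(seq_len(reps), function(r) {
    cfg <- simulation_config(
      n_hc = 15, n_amci = 15, n_regions = 6, n_timepoints = 60,
      wm_connected_regions = list(L = 2L, R = 5L),
      fc_effect_map = tibble::tibble(seed = "L", region = 2L,
                                     beta_hc = 2, beta_amci = 2),
      noise_sd = 1, rng_seed = 5000 + r)
    co <- generate_cohort(cfg)
    fc <- build_fc_matrices(co)
    fit <- fit_symptom_glm(co$subjects, fc, "HIP.L", "CTX.L.01")
    fit$simple_slopes$p_value[fit$simple_slopes$term == "interaction"]
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("degenerate designs and undersized samples raise typed errors", {
  # two candidates carrying identical signals alias each other
  set.seed(91)
  ts <- lapply(1:30, function(i) {
    hip <- rnorm(60)
    a <- 0.5 * hip + rnorm(60)
    cbind(HIP.L = hip, A = a, B = a)
  })
  names(ts) <- sprintf("s%02d", 1:30)
  subjects <- tibble::tibble(subject_id = names(ts),
                             group = rep(c("HC", "aMCI"), 15),
                             avlt5 = rnorm(30))
  fc_dup <- build_fc_matrices(ts, clip = TRUE)
  expect_error(
    fit_symptom_glm(subjects, fc_dup, "HIP.L", c("A", "B")),
    class = "hippnet_error_collinear")
  small <- generate_cohort(simulation_config(
    n_hc = 4, n_amci = 4, n_regions = 10, n_timepoints = 60, rng_seed = 2))
  fc_small <- build_fc_matrices(small)
  expect_error(
    fit_symptom_glm(small$subjects, fc_small, "HIP.L",
                    small$nodes$region[2:4]),
    class = "hippnet_error_samplesize")
})
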