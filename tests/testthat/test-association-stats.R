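test_that("cohens_d reproduces published worked examples from group summaries", {
  # mean (SD) per group for n = 58 controls vs n = 73 patients
  expect_equal(cohens_d(28.33, 1.43, 58, 26.70, 1.71, 73)$d, 1.024,
               tolerance = 0.005)
  expect_equal(cohens_d(82.62, 7.15, 58, 77.07, 7.09, 73)$d, 0.780,
               tolerance = 0.005)
  expect_equal(cohens_d(6.71, 1.88, 58, 2.07, 1.47, 73)$d, 2.790,
               tolerance = 0.005)
})

test_that("cohens_d is symmetric in the groups and zero for identical groups", {
  a <- cohens_d(10, 2, 30, 8, 3, 40)
  b <- cohens_d(8, 3, 40, 10, 2, 30)
  expect_equal(a$d, b$d)
  expect_equal(cohens_d(5, 1, 10, 5, 1, 10)$d, 0)
  expect_true(a$conf_low <= a$d && a$d <= a$conf_high)
  expect_error(cohens_d(5, 0, 10, 6, 0, 10), class = "hippnet_error_degenerate")
})

test_that("group_tests matches the hand pooled-SE t formula and handles categories", {
  set.seed(601)
  tab <- tibble::tibble(
    group = rep(c("HC", "aMCI"), c(20, 25)),
    score = c(rnorm(20, 5), rnorm(25, 4)),
    sex = sample(c("F", "M"), 45, replace = TRUE)
  )
  out <- group_tests(tab)
  row <- out[out$variable == "score", ]
  n1 <- 20; n2 <- 25
  x1 <- tab$score[tab$group == "HC"]; x2 <- tab$score[tab$group == "aMCI"]
  sp <- sqrt(((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2))
  t_hand <- (mean(x1) - mean(x2)) / (sp * sqrt(1 / n1 + 1 / n2))
  expect_equal(abs(row$statistic), abs(t_hand), tolerance = 1e-12)
  expect_equal(row$test, "t")
  expect_equal(out$test[out$variable == "sex"], "chisq")

  # equal groups: t = 0, p = 1
  eq <- tibble::tibble(group = rep(c("a", "b"), each = 4),
                       v = rep(c(1, 2, 3, 4), 2))
  r <- group_tests(eq)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$d, 0)

  # balanced 2x2 contingency: chi-square 0
  bal <- tibble::tibble(group = rep(c("a", "b"), each = 20),
                        f = rep(rep(c("x", "y"), each = 10), 2))
  rb <- group_tests(bal)
  expect_equal(rb$statistic, 0)

  expect_error(group_tests(tibble::tibble(group = "a", v = 1)),
               class = "hippnet_error_schema")
})

test_that("welch option changes the reference test but not the effect size", {
  set.seed(602)
  tab <- tibble::tibble(group = rep(c("a", "b"), c(15, 30)),
                        v = c(rnorm(15, 0, 1), rnorm(30, 1, 4)))
  pooled <- group_tests(tab)
  welch <- group_tests(tab, welch = TRUE)
  expect_false(isTRUE(all.equal(pooled$p_value, welch$p_value)))
  expect_equal(pooled$d, welch$d)
})

test_that("correlation matrix applies the Bonferroni family arithmetic", {
  set.seed(603)
  tab <- tibble::tibble(a = rnorm(40), b = rnorm(40), c = rnorm(40),
                        dup = NA_real_)
  tab$dup <- tab$a
  out <- correlation_matrix(tab, c("a", "b", "c", "dup"))
  expect_equal(out$r[out$var1 == "a" & out$var2 == "dup"], 1)
  expect_equal(attr(out, "family_size"), 6)
  expect_true(all(out$p_adj >= out$p_value - 1e-15))
  expect_true(all(out$p_adj <= 1))
  # declared family size scales raw p tenfold (capped at 1)
  out10 <- correlation_matrix(tab, c("a", "b"), family_size = 10)
  expect_equal(out10$p_adj, pmin(1, 10 * out10$p_value))
  # internal consistency with the FC correlation path
  expect_equal(out$r[out$var1 == "a" & out$var2 == "b"],
               pearson_fc(tab$a, tab$b), tolerance = 1e-12)
  # constant column yields the undefined sentinel
  cst <- correlation_matrix(tibble::tibble(a = rnorm(10), k = rep(1, 10)),
                            c("a", "k"))
  expect_true(is.na(cst$r))
})

test_that("property-interaction models find a planted group-specific slope", {
  set.seed(604)
  n <- 120
  subjects <- tibble::tibble(
    subject_id = sprintf("s%03d", 1:n),
    group = rep(c("HC", "aMCI"), each = n / 2)
  )
  auc <- dplyr::bind_rows(
    tibble::tibble(subject_id = subjects$subject_id, metric = "cp",
                   auc = rnorm(n, 0.3, 0.05)),
    tibble::tibble(subject_id = subjects$subject_id, metric = "lp",
                   auc = rnorm(n, 0.5, 0.05))
  )
  cp <- auc$auc[auc$metric == "cp"]
  subjects$avlt5 <- ifelse(subjects$group == "HC", 20 * cp, 0) + rnorm(n, 0, 0.5)
  out <- property_interaction_glm(subjects, auc, family_size = 2)
  cp_int <- out[out$metric == "cp" & out$term == "interaction", ]
  lp_int <- out[out$metric == "lp" & out$term == "interaction", ]
  expect_lt(cp_int$p_adj, 0.05)
  expect_gt(lp_int$p_value, 0.001)
  expect_equal(out$p_adj, pmin(1, 2 * out$p_value))

  flat <- dplyr::mutate(auc, auc = 1)
  expect_error(property_interaction_glm(subjects, flat),
               class = "hippnet_error_collinear")
})

test_that("moderation recovers exact and planted interactions", {
  # y an exact linear function of x alone: zero interaction, CI covers 0
  set.seed(605)
  d0 <- tibble::tibble(x = rnorm(50), m = rnorm(50))
  d0$y <- 2 * d0$x
  # the noiseless fit triggers base R's perfect-fit note; irrelevant here
  f0 <- suppressWarnings(
    moderation_analysis(d0, "y", "x", "m", n_boot = 1000, rng_seed = 1))
  expect_equal(f0$interaction$estimate, 0, tolerance = 1e-10)
  expect_lte(f0$interaction$conf_low, 0)
  expect_gte(f0$interaction$conf_high, 0)

  set.seed(606)
  d1 <- tibble::tibble(x = rnorm(200), m = rnorm(200))
  d1$y <- d1$x + 0.5 * d1$x * d1$m + rnorm(200, 0, 0.2)
  f1 <- moderation_analysis(d1, "y", "x", "m", n_boot = 2000, rng_seed = 2)
  expect_equal(f1$interaction$estimate, 0.5, tolerance = 0.05)
  expect_gt(f1$interaction$conf_low, 0)
  # simple slopes reconstruct from the coefficients
  b <- f1$coefficients$estimate
  expect_equal(f1$simple_slopes$slope[2], b[2], tolerance = 1e-12)
  expect_equal(f1$simple_slopes$slope[3] - f1$simple_slopes$slope[1],
               2 * b[4] * sd(d1$m), tolerance = 1e-10)
})

test_that("bootstrap intervals are bit-reproducible under a fixed seed", {
  set.seed(607)
  d <- tibble::tibble(x = rnorm(60), m = rnorm(60))
  d$y <- d$x + 0.3 * d$x * d$m + rnorm(60, 0, 0.5)
  f1 <- moderation_analysis(d, "y", "x", "m", n_boot = 1500, rng_seed = 99)
  f2 <- moderation_analysis(d, "y", "x", "m", n_boot = 1500, rng_seed = 99)
  expect_identical(f1$interaction$conf_low, f2$interaction$conf_low)
  expect_identical(f1$interaction$conf_high, f2$interaction$conf_high)
  f3 <- moderation_analysis(d, "y", "x", "m", n_boot = 1500, rng_seed = 100)
  expect_false(identical(f1$interaction$conf_low, f3$interaction$conf_low))
})

test_that("moderation rejects collinear and undersized inputs", {
  d <- tibble::tibble(x = rnorm(30))
  d$m <- d$x
  d$y <- rnorm(30)
  expect_error(moderation_analysis(d, "y", "x", "m", n_boot = 1000),
               class = "hippnet_error_collinear")
  d2 <- tibble::tibble(x = rnorm(10), m = rnorm(10), y = rnorm(10))
  expect_error(moderation_analysis(d2, "y", "x", "m", n_boot = 1000),
               class = "hippnet_error_schema")
  d3 <- tibble::tibble(x = rnorm(30), m = rnorm(30), y = rnorm(30))
  expect_error(moderation_analysis(d3, "y", "x", "m", n_boot = 500),
               class = "hippnet_error_range")
})

test_that("tidy and glance methods expose the fitted summaries", {
  set.seed(608)
  d <- tibble::tibble(x = rnorm(40), m = rnorm(40))
  d$y <- d$x + rnorm(40, 0, 0.5)
  f <- moderation_analysis(d, "y", "x", "m", n_boot = 1000, rng_seed = 3)
  td <- tidy(f)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 4)
  gl <- glance(f)
  expect_equal(gl$n, 40)
  expect_equal(gl$n_boot, 1000)
})
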