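#' Cohen's d from group summary statistics
#'
#' Pooled-SD standardized mean difference,
#' `d = |m1 - m2| / sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`,
#' reported as an absolute value, with a normal-approximation confidence
#' interval using `SE(d) = sqrt(1/n1 + 1/n2 + d^2 / (2 (n1 + n2)))`.
#'
#' @param mean1,sd1,n1 Summary statistics of the first group.
#' @param mean2,sd2,n2 Summary statistics of the second group.
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble with `d`, `conf_low`, `conf_high`.
#' @examples
#' cohens_d(28.33, 1.43, 58, 26.70, 1.71, 73)  # d ~ 1.024
#' @export
cohens_d <- function(mean1, sd1, n1, mean2, sd2, n2, conf_level = 0.95) {
  if (sd1 < 0 || sd2 < 0) stop_range("standard deviations must be >= 0")
  if (n1 < 2 || n2 < 2) stop_range("group sizes must be >= 2")
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  diff <- mean1 - mean2
  if (sp == 0) {
    if (diff != 0) abort("pooled SD is zero with unequal means: effect size infinite",
                         class = "hippnet_error_degenerate")
    return(tibble::tibble(d = 0, conf_low = 0, conf_high = 0))
  }
  d <- abs(diff) / sp
  se <- sqrt(1 / n1 + 1 / n2 + d^2 / (2 * (n1 + n2)))
  zc <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(d = d, conf_low = d - zc * se, conf_high = d + zc * se)
}

#' Two-group comparisons of cohort characteristics
#'
#' For each requested variable: continuous variables get a two-sample t test
#' (pooled-variance by default, Welch optionally) plus Cohen's d with CI;
#' categorical variables get a Pearson chi-square test on the contingency
#' table. P values are two-tailed.
#'
#' @param table Data frame with a two-level group column.
#' @param vars Character vector of variable names to compare (default: all
#'   columns except the group column and `subject_id`).
#' @param group_col Name of the group column.
#' @param welch Use Welch's unequal-variance t test instead of the pooled
#'   test.
#' @param correct Continuity correction for 2x2 chi-square tables.
#' @return Tibble with one row per variable: per-group summaries, `test`,
#'   `statistic`, `p_value`, `d`, `d_conf_low`, `d_conf_high` (d columns
#'   `NA` for categorical variables).
#' @export
group_tests <- function(table, vars = NULL, group_col = "group",
                        welch = FALSE, correct = FALSE) {
  table <- tibble::as_tibble(table)
  require_columns(table, group_col, "`table`")
  g <- factor(table[[group_col]])
  if (nlevels(g) != 2) stop_schema("group column must have exactly two levels")
  if (is.null(vars)) vars <- setdiff(names(table), c(group_col, "subject_id"))
  lev <- levels(g)

  purrr::map_dfr(vars, function(v) {
    x <- table[[v]]
    ok <- !is.na(x) & !is.na(g)
    xs <- x[ok]; gs <- g[ok]
    if (is.numeric(xs)) {
      m <- tapply(xs, gs, mean); s <- tapply(xs, gs, sd); n <- tapply(xs, gs, length)
      tt <- t.test(xs ~ gs, var.equal = !welch)
      dd <- cohens_d(m[[1]], s[[1]], n[[1]], m[[2]], s[[2]], n[[2]])
      tibble::tibble(
        variable = v, type = "continuous",
        group1 = lev[1], n1 = n[[1]], mean1 = m[[1]], sd1 = s[[1]],
        group2 = lev[2], n2 = n[[2]], mean2 = m[[2]], sd2 = s[[2]],
        test = if (welch) "welch_t" else "t",
        statistic = unname(tt$statistic), p_value = tt$p.value,
        d = dd$d, d_conf_low = dd$conf_low, d_conf_high = dd$conf_high
      )
    } else {
      tab <- table(factor(xs), gs)
      ct <- suppressWarnings(chisq.test(tab, correct = correct))
      tibble::tibble(
        variable = v, type = "categorical",
        group1 = lev[1], n1 = sum(tab[, 1]), mean1 = NA_real_, sd1 = NA_real_,
        group2 = lev[2], n2 = sum(tab[, 2]), mean2 = NA_real_, sd2 = NA_real_,
        test = "chisq",
        statistic = unname(ct$statistic), p_value = ct$p.value,
        d = NA_real_, d_conf_low = NA_real_, d_conf_high = NA_real_
      )
    }
  })
}

#' Pairwise score correlations with Bonferroni correction
#'
#' Pearson correlations between every pair of the requested score columns,
#' with Bonferroni-adjusted p values (`p_adj = min(1, m * p)` where `m` is
#' the number of tested pairs, or an explicitly declared family size).
#'
#' @param table Data frame of scores.
#' @param vars Score column names (>= 2).
#' @param family_size Bonferroni family size `m`; defaults to the number of
#'   tested pairs.
#' @return Tibble `var1`, `var2`, `n`, `r`, `p_value`, `p_adj` (`NA`
#'   sentinel rows for pairs involving a constant column).
#' @export
correlation_matrix <- function(table, vars, family_size = NULL) {
  table <- tibble::as_tibble(table)
  require_columns(table, vars, "`table`")
  if (length(vars) < 2) stop_schema("need >= 2 variables to correlate")
  pairs <- utils::combn(vars, 2)
  m <- family_size %||% ncol(pairs)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    v1 <- pairs[1, i]; v2 <- pairs[2, i]
    ok <- complete.cases(table[, c(v1, v2)])
    x <- table[[v1]][ok]; y <- table[[v2]][ok]
    if (length(x) < 3) stop_schema(sprintf("fewer than 3 complete rows for %s-%s", v1, v2))
    if (var(x) == 0 || var(y) == 0) {
      return(tibble::tibble(var1 = v1, var2 = v2, n = length(x),
                            r = NA_real_, p_value = NA_real_, p_adj = NA_real_))
    }
    ct <- cor.test(x, y, method = "pearson")
    tibble::tibble(var1 = v1, var2 = v2, n = length(x),
                   r = unname(ct$estimate), p_value = ct$p.value,
                   p_adj = min(1, m * ct$p.value))
  })
  attr(out, "family_size") <- m
  out
}

#' Group-by-property interaction models for the network's global metrics
#'
#' For each global property AUC, fits a separate Gaussian GLM
#' `score ~ group + property + group:property` and reports the group-specific
#' simple slopes and the interaction term, Bonferroni-corrected across the
#' family of tested properties (8 by default).
#'
#' @param subjects Data frame with `subject_id`, the group column and score.
#' @param auc Tibble from [property_auc()] (`subject_id`, `metric`, `auc`).
#' @param score,group_col,ref_group As in [fit_symptom_glm()].
#' @param family_size Bonferroni family size (default: number of properties
#'   tested).
#' @return Tibble with one row per property and term (`simple_slope` per
#'   group, `interaction`): `estimate`, `std_error`, `statistic`, `p_value`,
#'   `p_adj`.
#' @export
property_interaction_glm <- function(subjects, auc, score = "avlt5",
                                     group_col = "group", ref_group = "HC",
                                     family_size = NULL) {
  subjects <- tibble::as_tibble(subjects)
  require_columns(subjects, c("subject_id", group_col, score), "`subjects`")
  require_columns(auc, c("subject_id", "metric", "auc"), "`auc`")
  metrics <- unique(auc$metric)
  m <- family_size %||% length(metrics)
  lev <- unique(as.character(subjects[[group_col]]))
  if (length(lev) != 2 || !ref_group %in% lev) {
    stop_schema("group column must have two levels including `ref_group`")
  }
  other <- setdiff(lev, ref_group)

  purrr::map_dfr(metrics, function(met) {
    dat <- dplyr::inner_join(
      subjects[, c("subject_id", group_col, score)],
      auc[auc$metric == met, c("subject_id", "auc")],
      by = "subject_id"
    )
    dat <- dat[complete.cases(dat), ]
    if (nrow(dat) < 10) {
      warn(sprintf("property '%s' has %d complete cases; model skipped",
                   met, nrow(dat)),
           class = "hippnet_warning_insufficient_data")
      return(tibble::tibble())
    }
    if (var(dat$auc) == 0) {
      stop_collinear(sprintf("property '%s' is constant across subjects", met))
    }
    dat[[group_col]] <- factor(dat[[group_col]], levels = c(ref_group, other))
    fml <- stats::as.formula(paste0("`", score, "` ~ ", group_col, " * auc"))
    fit <- glm(fml, family = gaussian(), data = dat)
    if (anyNA(coef(fit))) stop_collinear(sprintf("aliased terms for property '%s'", met))
    b <- coef(fit); V <- vcov(fit); dfres <- df.residual(fit)
    intn <- paste0(group_col, other, ":auc")
    est <- c(b[["auc"]], b[["auc"]] + b[[intn]], b[[intn]])
    se <- c(sqrt(V["auc", "auc"]),
            sqrt(V["auc", "auc"] + V[intn, intn] + 2 * V["auc", intn]),
            sqrt(V[intn, intn]))
    tibble::tibble(
      metric = met,
      term = c("simple_slope", "simple_slope", "interaction"),
      group = c(ref_group, other, NA_character_),
      estimate = est, std_error = se,
      statistic = est / se,
      p_value = 2 * pt(-abs(est / se), dfres),
      p_adj = pmin(1, m * .data$p_value),
      n = nrow(dat)
    )
  })
}
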