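#' Fit the symptom-connectivity generalized linear model
#'
#' Models a behavioural score as a function of the ipsilateral
#' seed-to-cortex functional connectivities, group, and group-by-connectivity
#' interactions, in one model per hemisphere:
#' `score ~ group + z_1 + ... + z_k + group:z_1 + ... + group:z_k`
#' (Gaussian family, identity link by default). Per-group simple slopes for
#' each connectivity are derived from the coefficients: the reference group's
#' slope is the main-effect coefficient, the other group's slope adds the
#' interaction coefficient, with standard errors from the coefficient
#' covariance and Wald t tests on the residual degrees of freedom.
#'
#' @param subjects Data frame with `subject_id`, a two-level group column and
#'   the score column.
#' @param fc A `hippnet_fc_set` (per-subject Fisher-z matrices).
#' @param seed Seed region name for this hemisphere (e.g. `"HIP.L"`).
#' @param targets Candidate cortical region names (typically the
#'   consensus white-matter-connected set).
#' @param score Name of the score column (default `"avlt5"`).
#' @param group_col Name of the group column (default `"group"`).
#' @param ref_group Reference level of the group factor (default `"HC"`,
#'   so reported main-effect slopes are the control-group effects).
#' @param family A [stats::family] object; default Gaussian-identity.
#' @return A `hippnet_symptom_glm` with the underlying `glm` fit, a tidy
#'   coefficient table, and a `simple_slopes` tibble
#'   (`region`, `group`, `estimate`, `std_error`, `statistic`, `p_value`).
#' @export
fit_symptom_glm <- function(subjects, fc, seed, targets,
                            score = "avlt5", group_col = "group",
                            ref_group = "HC", family = gaussian()) {
  subjects <- tibble::as_tibble(subjects)
  require_columns(subjects, c("subject_id", group_col, score), "`subjects`")
  if (length(targets) < 1) stop_schema("`targets` must name >= 1 candidate region")
  grp <- subjects[[group_col]]
  lev <- unique(as.character(grp))
  if (length(lev) != 2) stop_schema("group column must have exactly two levels")
  if (!ref_group %in% lev) stop_schema("`ref_group` is not a level of the group column")
  other_group <- setdiff(lev, ref_group)

  y <- subjects[[score]]
  if (anyNA(y)) stop_schema("missing scores for included subjects")

  zt <- fc_pairs(fc, seed, targets) |>
    tidyr::pivot_wider(id_cols = "subject_id", names_from = "region",
                       values_from = "z") |>
    dplyr::mutate(dplyr::across(-"subject_id", as.numeric))
  dat <- dplyr::inner_join(subjects[, c("subject_id", group_col, score)], zt,
                           by = "subject_id")
  if (nrow(dat) < nrow(subjects)) {
    stop_schema("some subjects have no FC matrix")
  }
  n_terms <- 2 * length(targets) + 2
  if (nrow(dat) <= n_terms + 5) {
    abort(sprintf("insufficient sample size: n = %d for %d model terms",
                  nrow(dat), n_terms),
          class = "hippnet_error_samplesize")
  }
  dat[[group_col]] <- factor(dat[[group_col]], levels = c(ref_group, other_group))

  zcols <- targets
  safe <- paste0("z", seq_along(zcols))  # syntactic names for the formula
  names(dat)[match(zcols, names(dat))] <- safe
  fml <- stats::as.formula(paste0(
    "`", score, "` ~ ", group_col, " * (", paste(safe, collapse = " + "), ")"))
  fit <- glm(fml, family = family, data = dat)

  if (fit$rank < length(coef(fit)) || anyNA(coef(fit))) {
    aliased <- names(coef(fit))[is.na(coef(fit))]
    stop_collinear(paste0("rank-deficient design; aliased term(s): ",
                          paste(aliased, collapse = ", ")))
  }

  V <- vcov(fit)
  b <- coef(fit)
  dfres <- df.residual(fit)
  p_of <- function(est, se) 2 * pt(-abs(est / se), dfres)

  ss <- purrr::map_dfr(seq_along(zcols), function(k) {
    main <- safe[k]
    intn <- paste0(group_col, other_group, ":", safe[k])
    est_ref <- b[[main]]
    se_ref <- sqrt(V[main, main])
    est_oth <- b[[main]] + b[[intn]]
    se_oth <- sqrt(V[main, main] + V[intn, intn] + 2 * V[main, intn])
    tibble::tibble(
      region = rep(zcols[k], 3),
      term = c("simple_slope", "simple_slope", "interaction"),
      group = c(ref_group, other_group, NA_character_),
      estimate = c(est_ref, est_oth, b[[intn]]),
      std_error = c(se_ref, se_oth, sqrt(V[intn, intn]))
    )
  }) |>
    dplyr::mutate(statistic = .data$estimate / .data$std_error,
                  p_value = p_of(.data$estimate, .data$std_error))

  coefs <- tibble::tibble(
    term = names(b),
    estimate = unname(b),
    std_error = sqrt(diag(V)),
    statistic = unname(b) / sqrt(diag(V)),
    p_value = p_of(unname(b), sqrt(diag(V)))
  )
  # restore region names in term labels
  for (k in seq_along(zcols)) {
    coefs$term <- gsub(paste0("\\b", safe[k], "\\b"), zcols[k], coefs$term)
  }

  structure(list(
    model = fit,
    coefficients = coefs,
    simple_slopes = ss,
    seed = seed, targets = zcols, score = score,
    group_col = group_col, ref_group = ref_group, other_group = other_group,
    n = nrow(dat), df_residual = dfres
  ), class = "hippnet_symptom_glm")
}

#' @export
print.hippnet_symptom_glm <- function(x, ...) {
  cat(sprintf("<hippnet_symptom_glm> %s ~ %s * (%d FC terms), n = %d\n",
              x$score, x$group_col, length(x$targets), x$n))
  print(x$coefficients, n = Inf)
  invisible(x)
}

#' @rdname fit_symptom_glm
#' @param x A `hippnet_symptom_glm`.
#' @param ... Unused.
#' @method tidy hippnet_symptom_glm
#' @export
tidy.hippnet_symptom_glm <- function(x, ...) x$coefficients

#' @rdname fit_symptom_glm
#' @method glance hippnet_symptom_glm
#' @export
glance.hippnet_symptom_glm <- function(x, ...) {
  tibble::tibble(n = x$n, df_residual = x$df_residual,
                 deviance = x$model$deviance,
                 null_deviance = x$model$null.deviance,
                 aic = x$model$aic)
}

#' Select symptom-relevant network nodes
#'
#' Applies the node-selection rule to a fitted symptom GLM: a cortical
#' candidate joins the network when its connectivity term is significant at
#' `alpha` *and* the node is consensus white-matter connected. The seed is
#' always a member. Three rules are available: `"ref_slope"` tests the
#' reference (control) group's simple slope, `"any_slope"` tests both
#' groups' simple slopes, and `"interaction"` tests the group-by-FC
#' interaction coefficient. No multiplicity correction is applied at this
#' step; the rule applied is recorded in the output.
#'
#' @param fit A `hippnet_symptom_glm`.
#' @param wm A `hippnet_wm_table` from [consensus_nodes()] (or `NULL` to
#'   skip the structural filter, e.g. when `fit` was already restricted).
#' @param alpha Significance level in \[0, 1).
#' @param rule Selection rule (see above).
#' @return A `hippnet_network` with `seed`, `nodes` (seed + selected
#'   cortical nodes), `evidence` (per-candidate tibble), and the rule
#'   record. If no cortical node passes, a warning of class
#'   `hippnet_warning_empty_network` is issued and the network is the seed
#'   alone.
#' @export
select_nodes <- function(fit, wm = NULL, alpha = 0.05,
                         rule = c("ref_slope", "any_slope", "interaction")) {
  if (!inherits(fit, "hippnet_symptom_glm")) {
    stop_schema("`fit` must come from fit_symptom_glm()")
  }
  rule <- match.arg(rule)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha >= 1) {
    stop_range("`alpha` must lie in [0, 1)")
  }

  wm_ok <- fit$targets
  if (!is.null(wm)) {
    wmt <- tibble::as_tibble(wm)
    if ("seed" %in% names(wmt)) wmt <- wmt[wmt$seed == fit$seed, ]
    wm_ok <- intersect(fit$targets, wmt$region[wmt$consensus])
  }

  ss <- fit$simple_slopes
  p_by_region <- switch(rule,
    ref_slope = ss |>
      dplyr::filter(.data$term == "simple_slope", .data$group == fit$ref_group),
    any_slope = ss |>
      dplyr::filter(.data$term == "simple_slope") |>
      dplyr::group_by(.data$region) |>
      dplyr::slice_min(.data$p_value, n = 1, with_ties = FALSE) |>
      dplyr::ungroup(),
    interaction = ss |> dplyr::filter(.data$term == "interaction")
  )
  evidence <- p_by_region |>
    dplyr::transmute(.data$region, estimate = .data$estimate,
                     p_value = .data$p_value,
                     wm_connected = .data$region %in% wm_ok,
                     selected = .data$p_value < alpha & .data$region %in% wm_ok)

  selected <- evidence$region[evidence$selected]
  if (length(selected) == 0) {
    warn(sprintf("no cortical node selected for seed %s at alpha = %g; network is the seed alone",
                 fit$seed, alpha),
         class = "hippnet_warning_empty_network")
  }
  structure(list(
    seed = fit$seed,
    nodes = c(fit$seed, selected),
    evidence = evidence,
    rule = list(rule = rule, alpha = alpha, score = fit$score,
                ref_group = fit$ref_group, multiplicity = "none")
  ), class = "hippnet_network")
}

#' @export
print.hippnet_network <- function(x, ...) {
  cat(sprintf("<hippnet_network> seed %s: %d node(s) [rule %s, alpha %g]\n",
              x$seed, length(x$nodes), x$rule$rule, x$rule$alpha))
  cat("  ", paste(x$nodes, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname select_nodes
#' @param x A `hippnet_network`.
#' @param ... Unused.
#' @method tidy hippnet_network
#' @export
tidy.hippnet_network <- function(x, ...) x$evidence

#' Identify both hemisphere networks from a cohort
#'
#' Convenience wrapper running [fit_symptom_glm()] and [select_nodes()]
#' per hemisphere with candidates from the consensus white-matter table.
#'
#' @param subjects,fc As in [fit_symptom_glm()].
#' @param wm A `hippnet_wm_table` with a `seed` column.
#' @param score,group_col,ref_group,alpha,rule Passed through.
#' @return Named list (`L`, `R`) of `hippnet_network` objects, with the
#'   fitted models attached as attribute `"fits"`.
#' @export
identify_network <- function(subjects, fc, wm, score = "avlt5",
                             group_col = "group", ref_group = "HC",
                             alpha = 0.05, rule = "ref_slope") {
  wmt <- tibble::as_tibble(wm)
  require_columns(wmt, c("seed", "region", "consensus"), "`wm`")
  seeds <- unique(wmt$seed)
  fits <- list()
  nets <- lapply(seeds, function(sd) {
    cand <- wmt$region[wmt$seed == sd & wmt$consensus]
    if (length(cand) == 0) {
      warn(sprintf("no consensus WM-connected candidates for seed %s", sd),
           class = "hippnet_warning_empty_network")
      return(structure(list(seed = sd, nodes = sd,
                            evidence = tibble::tibble(),
                            rule = list(rule = rule, alpha = alpha)),
                       class = "hippnet_network"))
    }
    fit <- fit_symptom_glm(subjects, fc, sd, cand, score = score,
                           group_col = group_col, ref_group = ref_group)
    fits[[sd]] <<- fit
    select_nodes(fit, wmt, alpha = alpha, rule = rule)
  })
  names(nets) <- sub("^HIP\\.", "", seeds)
  attr(nets, "fits") <- fits
  nets
}
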