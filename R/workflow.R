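#' Validate a pipeline run configuration
#'
#' Accepts a YAML/JSON file path or a plain list, fills documented defaults
#' (structural threshold 0.15, consensus 0.5, selection alpha 0.05, sparsity
#' grid 0.15-0.45 step 0.01, 100 sigma nulls, 5000 bootstrap draws), range
#' checks every parameter, and reports *all* problems at once.
#'
#' Recognised keys: `inputs` (directory in the [write_cohort()] layout, or
#' absent when `simulate` is given), `simulate` (list of
#' [simulation_config()] arguments), `fraction`, `consensus`, `alpha`,
#' `rule`, `score`, `sparsity` (list `min`, `max`, `step`), `n_null`,
#' `n_boot`, `seed`, `moderator_x` (independent variable of the moderation
#' stage, default `"age"`).
#'
#' @param config File path or list.
#' @return A validated `hippnet_config` list with defaults filled.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop_config(paste0("config file not found: ", config))
    config <- if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  if (!is.list(config)) stop_config("`config` must be a list or a YAML/JSON file path")

  defaults <- list(
    inputs = NULL, simulate = NULL,
    fraction = 0.15, consensus = 0.5, alpha = 0.05, rule = "ref_slope",
    score = "avlt5",
    sparsity = list(min = 0.15, max = 0.45, step = 0.01),
    n_null = 100, n_boot = 5000, seed = 1L, moderator_x = "age"
  )
  problems <- character(0)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    problems <- c(problems, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, config[intersect(names(config), names(defaults))])

  if (is.null(cfg$inputs) && is.null(cfg$simulate)) {
    problems <- c(problems, "one of `inputs` or `simulate` is required")
  }
  if (!is.null(cfg$inputs) && !dir.exists(cfg$inputs)) {
    problems <- c(problems, paste0("`inputs`: directory does not exist: ", cfg$inputs))
  }
  for (k in c("fraction", "consensus", "alpha")) {
    if (!is_prob(cfg[[k]], open_left = (k != "alpha"))) {
      problems <- c(problems, sprintf("`%s` = %s is out of range (0, 1]", k,
                                      format(cfg[[k]])))
    }
  }
  if (!cfg$rule %in% c("ref_slope", "any_slope", "interaction")) {
    problems <- c(problems, "`rule` must be one of ref_slope, any_slope, interaction")
  }
  sp <- cfg$sparsity
  if (!is.list(sp) || !all(c("min", "max", "step") %in% names(sp)) ||
      !(is.numeric(sp$min) && is.numeric(sp$max) && is.numeric(sp$step)) ||
      !(sp$min > 0 && sp$max <= 1 && sp$min < sp$max && sp$step > 0)) {
    problems <- c(problems, "`sparsity` must give 0 < min < max <= 1 and step > 0")
  }
  if (!is_count(cfg$n_null) || cfg$n_null < 10) {
    problems <- c(problems, "`n_null` must be an integer >= 10")
  }
  if (!is_count(cfg$n_boot) || cfg$n_boot < 1000) {
    problems <- c(problems, "`n_boot` must be an integer >= 1000")
  }
  if (!is_count(cfg$seed)) problems <- c(problems, "`seed` must be a positive integer")
  if (length(problems) > 0) {
    stop_config(paste0("invalid configuration:\n- ",
                       paste(problems, collapse = "\n- ")))
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "hippnet_config")
}

stage_checksums_ <- function(paths) {
  paths <- paths[file.exists(paths)]
  tibble::tibble(file = basename(paths),
                 md5 = unname(tools::md5sum(paths)))
}

#' Run the full network-mapping pipeline
#'
#' Orchestrates the five analysis stages on real or simulated inputs:
#' structural constraint (consensus thresholding of tractography value maps,
#' control-group subjects only), functional connectivity (Fisher-z matrices),
#' network identification (group-by-FC GLMs per hemisphere), graph analysis
#' (eight global properties over the sparsity grid, AUC per metric, on the
#' identified left-hemisphere network), and association statistics (group
#' comparisons, property-by-group interaction models, and a moderation
#' analysis of the score-age relationship by each property AUC). Every
#' intermediate is persisted as CSV/JSON under `out_dir` and checksummed in
#' the returned manifest; deterministic stages reproduce identical checksums
#' on re-run with the same config.
#'
#' @param config A `hippnet_config` (or anything [validate_config()]
#'   accepts).
#' @param out_dir Output directory.
#' @return A `hippnet_manifest` tibble (stage, file, md5), with the stage
#'   results attached as attribute `"results"`.
#' @export
run_all <- function(config, out_dir) {
  cfg <- if (inherits(config, "hippnet_config")) config else validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  manifest <- list()
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            class = "hippnet_error_stage", parent = e)
    })
  }

  # inputs
  data <- stage("inputs", {
    if (!is.null(cfg$simulate)) {
      sim_args <- cfg$simulate
      if (is.null(sim_args$rng_seed)) sim_args$rng_seed <- cfg$seed
      cohort <- do.call(simulation_config, sim_args)
      cohort <- generate_cohort(cohort)
      write_cohort(cohort, file.path(out_dir, "inputs"))
      list(subjects = cohort$subjects, nodes = cohort$nodes,
           structural = cohort$structural, timeseries = cohort$timeseries,
           truth = cohort$truth)
    } else {
      read_cohort(cfg$inputs)
    }
  })
  results$inputs <- data

  # stage 1: structural constraint (control subjects only)
  wm <- stage("constrain", {
    hc_ids <- data$subjects$subject_id[as.character(data$subjects$group) == "HC"]
    maps <- data$structural[data$structural$subject_id %in% hc_ids, ]
    wm <- consensus_nodes(maps, fraction = cfg$fraction, consensus = cfg$consensus)
    readr::write_csv(wm, file.path(out_dir, "wm_connections.csv"))
    wm
  })
  results$wm <- wm
  manifest$constrain <- file.path(out_dir, "wm_connections.csv")

  # stage 2: functional connectivity
  fc <- stage("fc", {
    fc <- build_fc_matrices(data$timeseries, nodes = data$nodes$region)
    readr::write_csv(fc_long(fc), file.path(out_dir, "fc_long.csv"))
    fc
  })
  results$fc <- fc
  manifest$fc <- file.path(out_dir, "fc_long.csv")

  # stage 3: network identification
  nets <- stage("select-nodes", {
    nets <- identify_network(data$subjects, fc, wm, score = cfg$score,
                             alpha = cfg$alpha, rule = cfg$rule)
    ev <- purrr::map_dfr(nets, function(nw) {
      if (nrow(nw$evidence) == 0) return(tibble::tibble())
      dplyr::mutate(nw$evidence, seed = nw$seed, .before = 1)
    })
    readr::write_csv(ev, file.path(out_dir, "selection_evidence.csv"))
    jsonlite::write_json(
      lapply(nets, function(nw) list(seed = nw$seed, nodes = nw$nodes,
                                     rule = nw$rule)),
      file.path(out_dir, "network_definition.json"),
      auto_unbox = TRUE, pretty = TRUE)
    nets
  })
  results$networks <- nets
  manifest$select_nodes <- file.path(out_dir,
                                     c("selection_evidence.csv", "network_definition.json"))

  # stage 4: graph properties of the identified left network
  props <- stage("graph-metrics", {
    left_nodes <- nets$L$nodes
    if (length(left_nodes) < 4) {
      warn("left network has < 4 nodes; graph-property stage skipped",
           class = "hippnet_warning_small_network")
      NULL
    } else {
      grid <- sparsity_grid(cfg$sparsity$min, cfg$sparsity$max, cfg$sparsity$step)
      curves <- global_property_curves(fc, nodes = left_nodes, sparsities = grid,
                                       n_null = cfg$n_null, rng_seed = cfg$seed)
      auc <- property_auc(curves)
      readr::write_csv(curves, file.path(out_dir, "property_curves.csv"))
      readr::write_csv(auc, file.path(out_dir, "property_auc.csv"))
      list(curves = curves, auc = auc)
    }
  })
  results$properties <- props
  manifest$graph_metrics <- file.path(out_dir,
                                      c("property_curves.csv", "property_auc.csv"))

  # stage 5: association statistics
  stats_out <- stage("stats", {
    gt <- group_tests(data$subjects,
                      vars = intersect(c(cfg$score, "age", "ecog"),
                                       names(data$subjects)))
    readr::write_csv(gt, file.path(out_dir, "group_comparisons.csv"))
    out <- list(group = gt)
    if (!is.null(props)) {
      pig <- property_interaction_glm(data$subjects, props$auc,
                                      score = cfg$score)
      readr::write_csv(pig, file.path(out_dir, "property_interactions.csv"))
      mods <- purrr::map_dfr(unique(props$auc$metric), function(met) {
        wide <- dplyr::inner_join(
          data$subjects,
          dplyr::filter(props$auc, .data$metric == met)[, c("subject_id", "auc")],
          by = "subject_id")
        if (sum(complete.cases(wide[, c(cfg$score, cfg$moderator_x, "auc")])) < 20) {
          return(tibble::tibble())
        }
        fit <- moderation_analysis(wide, cfg$score, cfg$moderator_x, "auc",
                                   n_boot = cfg$n_boot, rng_seed = cfg$seed)
        tibble::tibble(moderator = met,
                       estimate = fit$interaction$estimate,
                       std_estimate = fit$interaction$std_estimate,
                       conf_low = fit$interaction$conf_low,
                       conf_high = fit$interaction$conf_high,
                       p_value = fit$coefficients$p_value[4])
      })
      readr::write_csv(mods, file.path(out_dir, "moderation.csv"))
      out$property_interactions <- pig
      out$moderation <- mods
    }
    out
  })
  results$stats <- stats_out
  manifest$stats <- file.path(out_dir,
                              intersect(c("group_comparisons.csv",
                                          "property_interactions.csv",
                                          "moderation.csv"),
                                        list.files(out_dir)))

  mf <- purrr::imap_dfr(manifest, function(paths, st) {
    dplyr::mutate(stage_checksums_(paths), stage = st, .before = 1)
  })
  mf <- dplyr::bind_rows(
    tibble::tibble(stage = "config", file = NA_character_,
                   md5 = digest_config_(cfg)),
    mf
  )
  jsonlite::write_json(mf, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  attr(mf, "results") <- results
  class(mf) <- c("hippnet_manifest", class(mf))
  mf
}

digest_config_ <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg)[order(names(unclass(cfg)))], tmp,
                       auto_unbox = TRUE, null = "null")
  unname(tools::md5sum(tmp))
}
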