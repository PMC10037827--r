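#' Threshold a structural connectivity value map
#'
#' Retains the target units of a per-subject, per-seed probabilistic
#' tractography value map whose connectivity value is at least
#' `fraction` times the map's maximum (the classic 15%-of-maximum rule).
#' The comparison is inclusive, so the unit attaining the maximum is always
#' retained and an all-equal map keeps every unit.
#'
#' @param map Data frame with one row per target unit; must contain a
#'   `value` column of nonnegative connectivity values, plus any identifier
#'   columns (e.g. `region`).
#' @param fraction Threshold as a proportion of the maximum value, in (0, 1].
#' @return The suprathreshold rows of `map` as a tibble, with an added
#'   `threshold` column (the absolute cutoff applied).
#' @examples
#' m <- tibble::tibble(region = c("a", "b", "c", "d"),
#'                     value = c(100, 20, 14, 0))
#' threshold_map(m, 0.15)  # keeps a and b
#' @export
threshold_map <- function(map, fraction = 0.15) {
  map <- tibble::as_tibble(map)
  require_columns(map, "value", "`map`")
  if (!is_prob(fraction)) stop_range("`fraction` must lie in (0, 1]")
  v <- map$value
  if (any(!is.finite(v)) || any(v < 0)) {
    stop_schema("`map$value` must be finite and nonnegative")
  }
  mx <- max(v)
  if (mx <= 0) {
    stop_degenerate("all connectivity values are zero: no connections resolvable")
  }
  cut <- fraction * mx
  out <- map[v >= cut, , drop = FALSE]
  out$threshold <- cut
  out
}

#' Reduce a voxel-level value map to region level
#'
#' Voxel-wise maps are summarised by counting suprathreshold voxels per
#' region (threshold applied at the whole-map level); a region is flagged
#' connected when it holds at least `min_voxels` suprathreshold voxels.
#'
#' @param map Data frame with columns `region`, `value` (one row per voxel).
#' @param fraction Proportion-of-maximum threshold, as in [threshold_map()].
#' @param min_voxels Minimum suprathreshold voxel count per region.
#' @return Tibble with `region`, `n_voxels`, `n_suprathreshold`, `connected`.
#' @export
reduce_voxel_map <- function(map, fraction = 0.15, min_voxels = 1) {
  map <- tibble::as_tibble(map)
  require_columns(map, c("region", "value"), "`map`")
  if (!is_count(min_voxels)) stop_range("`min_voxels` must be a positive integer")
  supra <- threshold_map(map, fraction)
  map |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(n_voxels = dplyr::n(), .groups = "drop") |>
    dplyr::left_join(
      supra |>
        dplyr::group_by(.data$region) |>
        dplyr::summarise(n_suprathreshold = dplyr::n(), .groups = "drop"),
      by = "region"
    ) |>
    dplyr::mutate(
      n_suprathreshold = dplyr::coalesce(.data$n_suprathreshold, 0L),
      connected = .data$n_suprathreshold >= min_voxels
    )
}

#' Consensus white-matter connection table across subjects
#'
#' Applies [threshold_map()] per subject and flags a target region as
#' consensus-connected to the seed when it is suprathreshold in at least a
#' `consensus` fraction of subjects. How per-subject thresholded maps are
#' combined into one connection table is exposed as this parameter rather
#' than fixed.
#'
#' @param maps Data frame of region-level maps stacked across subjects:
#'   columns `subject_id`, `region`, `value`, and optionally `seed` (the
#'   rule is applied within each seed).
#' @param fraction Per-subject proportion-of-maximum threshold.
#' @param consensus Required fraction of subjects, in (0, 1].
#' @return A `hippnet_wm_table` tibble: `seed` (if present), `region`,
#'   `n_subjects`, `n_suprathreshold`, `prop_suprathreshold`, `consensus`
#'   (logical), plus the `fraction` and `consensus_fraction` used.
#' @examples
#' cfg <- simulation_config(n_hc = 6, n_amci = 6, n_timepoints = 60, rng_seed = 3)
#' cohort <- generate_cohort(cfg)
#' consensus_nodes(cohort$structural)
#' @export
consensus_nodes <- function(maps, fraction = 0.15, consensus = 0.5) {
  maps <- tibble::as_tibble(maps)
  require_columns(maps, c("subject_id", "region", "value"), "`maps`")
  if (!is_prob(consensus)) stop_range("`consensus` must lie in (0, 1]")
  has_seed <- "seed" %in% names(maps)
  if (!has_seed) maps$seed <- "seed"

  out <- lapply(split(maps, maps$seed), function(ms) {
    subs <- split(ms, ms$subject_id)
    if (length(subs) < 2) {
      stop_schema("consensus requires maps from >= 2 subjects")
    }
    ref <- sort(unique(subs[[1]]$region))
    for (s in subs) {
      if (!identical(sort(unique(s$region)), ref) || nrow(s) != length(ref)) {
        stop_schema("all subjects must share one target region index per seed")
      }
    }
    flags <- vapply(subs, function(s) {
      keep <- threshold_map(s, fraction)$region
      ref %in% keep
    }, logical(length(ref)))
    n_sub <- length(subs)
    tibble::tibble(
      seed = ms$seed[1],
      region = ref,
      n_subjects = n_sub,
      n_suprathreshold = rowSums(flags),
      prop_suprathreshold = rowSums(flags) / n_sub,
      consensus = rowSums(flags) / n_sub >= consensus
    )
  })
  out <- dplyr::bind_rows(out)
  # present regions in catalog (input) order, not alphabetical
  ord <- match(out$region, unique(maps$region))
  out <- out[order(match(out$seed, unique(maps$seed)), ord), ]
  if (!has_seed) out$seed <- NULL
  out <- tibble::as_tibble(out)
  attr(out, "fraction") <- fraction
  attr(out, "consensus_fraction") <- consensus
  class(out) <- c("hippnet_wm_table", class(out))
  out
}
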