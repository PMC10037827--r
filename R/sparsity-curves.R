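#' The default sparsity grid
#'
#' The binarization grid used throughout: sparsity 0.15 to 0.45 in steps of
#' 0.01 (31 points).
#'
#' @param s_min,s_max,step Grid limits and increment.
#' @return Numeric vector of sparsity values.
#' @export
sparsity_grid <- function(s_min = 0.15, s_max = 0.45, step = 0.01) {
  if (!(s_min > 0 && s_max <= 1 && s_min < s_max && step > 0)) {
    stop_range("sparsity grid must satisfy 0 < s_min < s_max <= 1, step > 0")
  }
  seq(s_min, s_max, by = step)
}

metric_funs_ <- function(n_null, rng_seed) {
  list(
    assortativity = assortativity,
    hierarchy = hierarchy,
    synchronization = synchronization,
    sigma = function(g) small_world_sigma(g, n_null = n_null, rng_seed = rng_seed),
    cp = clustering_coefficient,
    lp = characteristic_path_length,
    eglobal = global_efficiency,
    elocal = local_efficiency
  )
}

#' Global property curves over the sparsity grid
#'
#' Binarizes each subject's functional connectivity matrix at every sparsity
#' in the grid and evaluates the eight global properties (assortativity,
#' hierarchy, synchronization, small-world sigma, Cp, Lp, Eglobal, Elocal).
#'
#' @param fc A `hippnet_fc_set`, or a single FC matrix.
#' @param nodes Optional character vector restricting the network to these
#'   regions (e.g. the identified network nodes).
#' @param sparsities Sparsity grid (default [sparsity_grid()]).
#' @param n_null Null-graph count for sigma.
#' @param rng_seed Seed for the sigma null ensemble; each
#'   (subject, sparsity) cell uses a distinct seed derived from it, so
#'   results are reproducible and independent of evaluation order.
#' @return A `hippnet_property_curves` tibble:
#'   `subject_id`, `sparsity`, `metric`, `value` (`NA` where undefined).
#' @export
global_property_curves <- function(fc, nodes = NULL,
                                   sparsities = sparsity_grid(),
                                   n_null = 100, rng_seed = NULL) {
  if (is.matrix(fc)) fc <- structure(list(subject = fc), class = "hippnet_fc_set")
  if (!is.list(fc)) stop_schema("`fc` must be an FC matrix set or a single matrix")
  metric_names <- names(metric_funs_(10, NULL))
  out <- purrr::imap_dfr(unclass(fc), function(m, id) {
    if (!is.null(nodes)) {
      absent <- setdiff(nodes, rownames(m))
      if (length(absent) > 0) {
        stop_schema(paste0("FC matrix missing node(s): ", paste(absent, collapse = ", ")))
      }
      m <- m[nodes, nodes, drop = FALSE]
    }
    purrr::map_dfr(seq_along(sparsities), function(si) {
      s <- sparsities[si]
      cell_seed <- if (is.null(rng_seed)) NULL else
        (rng_seed + 131L * si + 7919L * match(id, names(fc))) %% .Machine$integer.max
      g <- binarize_at_sparsity(m, s)
      funs <- metric_funs_(n_null, cell_seed)
      tibble::tibble(
        subject_id = id, sparsity = s, metric = metric_names,
        value = vapply(metric_names, function(nm) {
          v <- funs[[nm]](g)
          if (is.null(v) || !is.finite(v)) NA_real_ else v
        }, numeric(1))
      )
    })
  })
  class(out) <- c("hippnet_property_curves", class(out))
  out
}

#' Area under a metric curve over the sparsity grid
#'
#' Trapezoidal integration of a metric curve across the sparsity range.
#' Undefined points (`NA` sentinels) are excluded pairwise: only intervals
#' with both endpoints finite contribute. The fraction of the grid covered
#' is attached as attribute `"coverage"`. If more than half the points are
#' undefined the AUC itself is `NA`.
#'
#' @param values Metric values on the grid (may contain `NA`).
#' @param sparsities The grid (same length as `values`).
#' @return The AUC (scalar, possibly `NA`), with attribute `coverage`.
#' @examples
#' auc_over_sparsity(sparsity_grid(), sparsity_grid())  # integral of f(s)=s
#' @export
auc_over_sparsity <- function(values, sparsities = sparsity_grid()) {
  if (length(values) != length(sparsities)) {
    stop_schema("`values` and `sparsities` must have equal length")
  }
  if (is.unsorted(sparsities, strictly = TRUE)) {
    stop_schema("`sparsities` must be strictly increasing")
  }
  fin <- is.finite(values)
  if (mean(fin) < 0.5) {
    out <- NA_real_
    attr(out, "coverage") <- mean(fin)
    return(out)
  }
  n <- length(values)
  both <- fin[-n] & fin[-1]
  widths <- diff(sparsities)
  auc <- sum(((values[-n] + values[-1]) / 2 * widths)[both])
  attr(auc, "coverage") <- sum(widths[both]) / sum(widths)
  auc
}

#' Summarise property curves by their AUC scalars
#'
#' @param curves A `hippnet_property_curves` tibble from
#'   [global_property_curves()].
#' @return Tibble `subject_id`, `metric`, `auc`, `coverage`.
#' @export
property_auc <- function(curves) {
  require_columns(curves, c("subject_id", "sparsity", "metric", "value"),
                  "`curves`")
  curves |>
    dplyr::group_by(.data$subject_id, .data$metric) |>
    dplyr::arrange(.data$sparsity, .by_group = TRUE) |>
    dplyr::summarise(
      auc = {
        a <- auc_over_sparsity(.data$value, .data$sparsity)
        as.numeric(a)
      },
      coverage = attr(auc_over_sparsity(.data$value, .data$sparsity), "coverage"),
      .groups = "drop"
    )
}
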