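#' Pearson correlation between two regional time series
#'
#' @param x,y Numeric vectors of equal length (>= 3) with positive variance.
#' @return The Pearson correlation coefficient, in \[-1, 1\].
#' @export
pearson_fc <- function(x, y) {
  if (length(x) != length(y)) stop_schema("`x` and `y` must have equal length")
  if (length(x) < 3) stop_schema("series must have length >= 3")
  if (anyNA(x) || anyNA(y)) stop_schema("series must not contain missing values")
  if (var(x) == 0 || var(y) == 0) {
    stop_degenerate("zero-variance series: correlation undefined")
  }
  cor(x, y)
}

#' Fisher z-transform of a correlation coefficient
#'
#' Standardizes correlations via `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))`.
#'
#' @param r Correlation value(s) with `|r| < 1`.
#' @param clip If `TRUE`, values with `|r| >= 1` are clipped to
#'   `1 - 1e-7` in absolute value instead of erroring.
#' @return Fisher-z value(s).
#' @export
fisher_z <- function(r, clip = FALSE) {
  if (any(!is.finite(r))) stop_range("`r` must be finite")
  if (any(abs(r) >= 1)) {
    if (!clip) stop_range("|r| >= 1: Fisher z undefined (use clip = TRUE to truncate)")
    r <- pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)
  }
  atanh(r)
}

#' Inverse Fisher z-transform
#' @param z Fisher-z value(s).
#' @return Correlation value(s) in (-1, 1).
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Build per-subject Fisher-z functional connectivity matrices
#'
#' Computes the full node-by-node matrix of Fisher-z transformed Pearson
#' correlations of the regional mean time series, per subject. Diagonal
#' entries are stored as `NA` and excluded from all downstream statistics.
#'
#' @param timeseries Named list of time-by-region matrices (columns named by
#'   region), or a `hippnet_cohort`.
#' @param nodes Character vector of region names to include (default: all
#'   columns of the first subject).
#' @param clip Passed to [fisher_z()]; by default a pair with `|r| = 1`
#'   (e.g. duplicated region signals) raises a degenerate-input error.
#' @return A `hippnet_fc_set`: named list of symmetric Fisher-z matrices.
#' @examples
#' cohort <- generate_cohort(
#'   simulation_config(n_hc = 4, n_amci = 4, n_timepoints = 60, rng_seed = 2))
#' fc <- build_fc_matrices(cohort)
#' fc[[1]][1:4, 1:4]
#' @export
build_fc_matrices <- function(timeseries, nodes = NULL, clip = FALSE) {
  if (inherits(timeseries, "hippnet_cohort")) timeseries <- timeseries$timeseries
  if (!is.list(timeseries) || length(timeseries) == 0) {
    stop_schema("`timeseries` must be a non-empty list of time-by-region matrices")
  }
  if (is.null(nodes)) nodes <- colnames(timeseries[[1]])
  out <- lapply(timeseries, function(ts) {
    absent <- setdiff(nodes, colnames(ts))
    if (length(absent) > 0) {
      stop_schema(paste0("time series missing node(s): ",
                         paste(absent, collapse = ", ")))
    }
    m <- ts[, nodes, drop = FALSE]
    if (anyNA(m)) stop_schema("time series contain missing values")
    if (any(apply(m, 2, var) == 0)) {
      stop_degenerate("zero-variance regional series in time-series matrix")
    }
    r <- cor(m)
    off <- r[upper.tri(r)]
    if (!clip && any(abs(off) >= 1)) {
      stop_degenerate("off-diagonal |r| = 1 (duplicated regional signals?)")
    }
    z <- fisher_z(ifelse(abs(r) < 1, r, sign(r)), clip = TRUE)
    diag(z) <- NA_real_
    z
  })
  structure(out, class = "hippnet_fc_set")
}

#' Extract seed-to-target Fisher-z connectivity as a tidy table
#'
#' @param fc A `hippnet_fc_set` (or plain list of FC matrices).
#' @param seed Seed region name (e.g. `"HIP.L"`).
#' @param targets Character vector of target region names.
#' @return Tibble with columns `subject_id`, `seed`, `region`, `z`.
#' @export
fc_pairs <- function(fc, seed, targets) {
  if (!is.list(fc)) stop_schema("`fc` must be a list of FC matrices")
  purrr::imap_dfr(unclass(fc), function(m, id) {
    absent <- setdiff(c(seed, targets), rownames(m))
    if (length(absent) > 0) {
      stop_schema(paste0("FC matrix missing node(s): ", paste(absent, collapse = ", ")))
    }
    zvals <- unname(m[seed, targets])
    tibble::tibble(subject_id = id, seed = seed, region = targets, z = zvals)
  })
}

#' Long-format view of an FC matrix set
#'
#' @param fc A `hippnet_fc_set`.
#' @return Tibble with `subject_id`, `region_a`, `region_b` (upper triangle),
#'   and Fisher-z `z`.
#' @export
fc_long <- function(fc) {
  purrr::imap_dfr(unclass(fc), function(m, id) {
    ut <- which(upper.tri(m), arr.ind = TRUE)
    tibble::tibble(subject_id = id,
                   region_a = rownames(m)[ut[, 1]],
                   region_b = colnames(m)[ut[, 2]],
                   z = m[ut])
  })
}
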