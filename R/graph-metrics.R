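#' Binarize a connectivity matrix at a target sparsity
#'
#' Retains the `round(s * n * (n - 1) / 2)` largest off-diagonal weights
#' (round half away from zero) as the edges of an undirected, unweighted
#' graph. Ties are broken deterministically by weight (descending) then by
#' the lexicographic order of the node-index pair.
#'
#' @param fc Symmetric numeric matrix (diagonal ignored; `NA` diagonal
#'   allowed).
#' @param s Target sparsity (proportion of possible edges) in (0, 1].
#' @return A `hippnet_graph`: list with the `igraph` object, the binary
#'   `adjacency` matrix, `sparsity`, and `n_edges`.
#' @examples
#' cohort <- generate_cohort(
#'   simulation_config(n_hc = 4, n_amci = 4, n_timepoints = 60, rng_seed = 2))
#' fc <- build_fc_matrices(cohort)
#' g <- binarize_at_sparsity(fc[[1]], 0.2)
#' g$n_edges
#' @export
binarize_at_sparsity <- function(fc, s) {
  if (!is.matrix(fc) || nrow(fc) != ncol(fc)) stop_schema("`fc` must be a square matrix")
  n <- nrow(fc)
  if (n < 2) stop_schema("`fc` must have >= 2 nodes")
  offd <- fc; diag(offd) <- 0
  if (max(abs(offd - t(offd)), na.rm = TRUE) > 1e-8) {
    stop_schema("`fc` must be symmetric")
  }
  if (!is_prob(s)) stop_range("`s` (sparsity) must lie in (0, 1]")
  m_possible <- n * (n - 1) / 2
  k <- as.integer(round_half_up(s * m_possible))
  if (k < 1) stop_degenerate("requested sparsity yields zero edges")

  ut <- which(upper.tri(fc), arr.ind = TRUE)
  w <- fc[upper.tri(fc)]
  ord <- order(-w, ut[, 1], ut[, 2])
  keep <- ord[seq_len(k)]
  A <- matrix(0L, n, n, dimnames = dimnames(fc))
  A[ut[keep, , drop = FALSE]] <- 1L
  A <- A + t(A)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  structure(list(graph = g, adjacency = A, sparsity = s, n_edges = k),
            class = "hippnet_graph")
}

as_igraph_ <- function(g) {
  if (inherits(g, "hippnet_graph")) g$graph
  else if (igraph::is_igraph(g)) g
  else if (is.matrix(g)) igraph::graph_from_adjacency_matrix(
    (g != 0) * 1, mode = "undirected", diag = FALSE)
  else stop_schema("expected a hippnet_graph, igraph, or adjacency matrix")
}

#' Global graph properties of a binarized network
#'
#' Eight global metrics of an undirected, unweighted graph, under the
#' conventions spelled out below. Metrics undefined for a given graph
#' return `NA` (a sentinel excluded from area-under-curve summaries).
#'
#' * `clustering_coefficient()` (Cp): mean over nodes of
#'   triangles / (k(k-1)/2); nodes with degree < 2 contribute 0.
#' * `characteristic_path_length()` (Lp): mean shortest-path length over
#'   connected unordered node pairs.
#' * `global_efficiency()` (Eglobal): mean over pairs of 1/d(i,j), with
#'   1/Inf = 0 for disconnected pairs.
#' * `local_efficiency()` (Elocal): mean over nodes of the global
#'   efficiency of the subgraph induced by the node's neighbours
#'   (0 for degree < 2).
#' * `assortativity()`: Pearson correlation of endpoint degrees over all
#'   edges (both orientations); `NA` when endpoint degrees are constant.
#' * `hierarchy()`: exponent beta of C ~ k^(-beta), the negated slope of
#'   the least-squares regression of log nodal clustering on log degree
#'   over nodes with degree >= 2 and clustering > 0; `NA` with < 3
#'   eligible nodes or a degenerate regressor.
#' * `synchronization()`: eigenratio lambda_2 / lambda_max of the
#'   combinatorial Laplacian of the largest connected component; `NA` for
#'   components of < 3 nodes.
#' * `small_world_sigma()`: (Cp/Cp_rand) / (Lp/Lp_rand) against
#'   degree-preserving rewired null graphs.
#'
#' @param g A `hippnet_graph`, `igraph` object, or adjacency matrix.
#' @return A single numeric value (or `NA` sentinel).
#' @name graph-metrics
NULL

#' @rdname graph-metrics
#' @export
clustering_coefficient <- function(g) {
  g <- as_igraph_(g)
  if (igraph::vcount(g) < 2) stop_schema("graph needs >= 2 nodes")
  igraph::transitivity(g, type = "localaverage", isolates = "zero")
}

#' @rdname graph-metrics
#' @export
characteristic_path_length <- function(g) {
  g <- as_igraph_(g)
  if (igraph::vcount(g) < 2) stop_schema("graph needs >= 2 nodes")
  if (igraph::ecount(g) == 0) return(NA_real_)
  igraph::mean_distance(g, unconnected = TRUE)
}

#' @rdname graph-metrics
#' @export
global_efficiency <- function(g) {
  g <- as_igraph_(g)
  if (igraph::vcount(g) < 2) stop_schema("graph needs >= 2 nodes")
  igraph::global_efficiency(g)
}

#' @rdname graph-metrics
#' @export
local_efficiency <- function(g) {
  # neighbour-induced-subgraph convention; igraph's own local_efficiency()
  # routes paths through the full graph, which is a different quantity
  g <- as_igraph_(g)
  n <- igraph::vcount(g)
  if (n < 2) stop_schema("graph needs >= 2 nodes")
  vals <- vapply(seq_len(n), function(v) {
    nb <- as.integer(igraph::neighbors(g, v))
    if (length(nb) < 2) return(0)
    igraph::global_efficiency(igraph::induced_subgraph(g, nb))
  }, numeric(1))
  mean(vals)
}

#' @rdname graph-metrics
#' @export
assortativity <- function(g) {
  g <- as_igraph_(g)
  if (igraph::ecount(g) < 2) return(NA_real_)
  el <- igraph::as_edgelist(g, names = FALSE)
  k <- igraph::degree(g)
  d1 <- c(k[el[, 1]], k[el[, 2]])
  d2 <- c(k[el[, 2]], k[el[, 1]])
  if (var(d1) == 0 || var(d2) == 0) return(NA_real_)
  cor(d1, d2)
}

#' @rdname graph-metrics
#' @export
hierarchy <- function(g) {
  g <- as_igraph_(g)
  k <- igraph::degree(g)
  ci <- igraph::transitivity(g, type = "local", isolates = "zero")
  ci[is.na(ci)] <- 0
  eligible <- which(k >= 2 & ci > 0)
  if (length(eligible) < 3) return(NA_real_)
  lk <- log(k[eligible]); lc <- log(ci[eligible])
  if (var(lk) == 0) return(NA_real_)
  -unname(coef(lm(lc ~ lk))[2])
}

#' @rdname graph-metrics
#' @export
synchronization <- function(g) {
  g <- as_igraph_(g)
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  nc <- igraph::vcount(sub)
  if (nc < 3) return(NA_real_)
  L <- as.matrix(igraph::laplacian_matrix(sub))
  ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  lam_max <- ev[nc]
  if (lam_max <= 0) return(NA_real_)
  ev[2] / lam_max
}

#' @rdname graph-metrics
#' @param n_null Number of degree-preserving rewired null graphs.
#' @param rng_seed Integer seed making the null ensemble reproducible
#'   (`NULL` uses, and advances, the current RNG stream).
#' @export
small_world_sigma <- function(g, n_null = 100, rng_seed = NULL) {
  g <- as_igraph_(g)
  if (!is_count(n_null) || n_null < 10) stop_range("`n_null` must be >= 10")
  if (igraph::ecount(g) < 2) return(NA_real_)
  cp <- clustering_coefficient(g)
  lp <- characteristic_path_length(g)
  if (!is.finite(cp) || !is.finite(lp)) return(NA_real_)
  nulls <- with_rng(rng_seed, {
    lapply(seq_len(n_null), function(i) {
      igraph::rewire(g, igraph::keeping_degseq(niter = 10 * igraph::ecount(g)))
    })
  })
  cp_r <- mean(vapply(nulls, clustering_coefficient, numeric(1)))
  lp_r <- mean(vapply(nulls, characteristic_path_length, numeric(1)))
  if (!is.finite(cp_r) || cp_r <= 0 || !is.finite(lp_r) || lp_r <= 0) {
    return(NA_real_)
  }
  (cp / cp_r) / (lp / lp_r)
}
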