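# Brute-force reference implementations, independent of the package's code
# paths: plain-R loops over adjacency matrices (Floyd-Warshall distances,
# triangle enumeration, edge-list correlation, dense eigensolver on a
# hand-built Laplacian). Used to cross-check the graph metrics.

oracle_floyd_warshall <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

oracle_cp <- function(A) {
  n <- nrow(A)
  k <- rowSums(A)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    if (k[i] < 2) next
    nb <- which(A[i, ] > 0)
    tri <- sum(A[nb, nb]) / 2
    ci[i] <- tri / (k[i] * (k[i] - 1) / 2)
  }
  mean(ci)
}

oracle_lp <- function(A) {
  d <- oracle_floyd_warshall(A)[upper.tri(A)]
  mean(d[is.finite(d)])
}

oracle_eglobal <- function(A) {
  inv <- 1 / oracle_floyd_warshall(A)[upper.tri(A)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

oracle_elocal <- function(A) {
  n <- nrow(A)
  e <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) next
    e[i] <- oracle_eglobal(A[nb, nb, drop = FALSE])
  }
  mean(e)
}

oracle_assortativity <- function(A) {
  el <- which(A > 0 & upper.tri(A), arr.ind = TRUE)
  k <- rowSums(A)
  d1 <- c(k[el[, 1]], k[el[, 2]])
  d2 <- c(k[el[, 2]], k[el[, 1]])
  if (stats::var(d1) == 0) return(NA_real_)
  stats::cor(d1, d2)
}

oracle_hierarchy <- function(A) {
  n <- nrow(A)
  k <- rowSums(A)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    if (k[i] < 2) next
    nb <- which(A[i, ] > 0)
    ci[i] <- (sum(A[nb, nb]) / 2) / (k[i] * (k[i] - 1) / 2)
  }
  el <- which(k >= 2 & ci > 0)
  if (length(el) < 3) return(NA_real_)
  x <- log(k[el]); y <- log(ci[el])
  if (stats::var(x) == 0) return(NA_real_)
  # closed-form simple-regression slope
  -(sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2))
}

# largest connected component by breadth-first search, then the eigenratio
# of its combinatorial Laplacian
oracle_synchronization <- function(A) {
  n <- nrow(A)
  comp <- rep(0L, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(A[v, ] > 0 & comp == 0L)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  big <- which(comp == which.max(tabulate(comp)))
  if (length(big) < 3) return(NA_real_)
  B <- A[big, big, drop = FALSE]
  L <- diag(rowSums(B)) - B
  ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  ev[2] / ev[length(ev)]
}

oracle_auc <- function(v, s) {
  # plain trapezoid sum over intervals with both endpoints finite
  total <- 0
  for (i in seq_len(length(v) - 1)) {
    if (is.finite(v[i]) && is.finite(v[i + 1])) {
      total <- total + (v[i] + v[i + 1]) / 2 * (s[i + 1] - s[i])
    }
  }
  total
}

random_adjacency <- function(n, p) {
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  A + t(A)
}

random_weight_matrix <- function(n) {
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- stats::rnorm(n * (n - 1) / 2)
  W <- W + t(W)
  diag(W) <- NA_real_
  dimnames(W) <- list(paste0("r", seq_len(n)), paste0("r", seq_len(n)))
  W
}
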