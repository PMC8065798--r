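# Independent oracles used across the suite.  These deliberately take
# different computational routes from the package code they check.

# Correspondence decomposition via generic eigendecomposition of the
# standardized residual cross-products (no SVD call).
ca_eigen_oracle <- function(A, tol = 1e-12) {
  A <- as.matrix(A)
  N <- sum(A); P <- A / N
  r <- rowSums(P); cc <- colSums(P)
  S <- (P - outer(r, cc)) / outer(sqrt(r), sqrt(cc))
  ec <- eigen(crossprod(S), symmetric = TRUE)       # S'S = Q Lambda Q'
  lam <- pmax(ec$values, 0)
  keep <- which(lam > tol)
  lam <- lam[keep]
  Q <- ec$vectors[, keep, drop = FALSE]
  er <- eigen(tcrossprod(S), symmetric = TRUE)      # SS' = U Lambda U'
  U <- er$vectors[, keep, drop = FALSE]
  list(eigenvalues = lam,
       F = sweep(U, 2L, sqrt(lam), `*`) / sqrt(r),
       G = sweep(Q, 2L, sqrt(lam), `*`) / sqrt(cc))
}

# max over axes of the distance between coordinate columns, allowing an
# independent sign flip per axis
coord_diff_up_to_sign <- function(A, B) {
  stopifnot(ncol(A) == ncol(B))
  max(vapply(seq_len(ncol(A)), function(s) {
    min(max(abs(A[, s] - B[, s])), max(abs(A[, s] + B[, s])))
  }, 0))
}

# exhaustive k-means optimum: minimal mean Euclidean distance over every
# assignment of n points to k non-empty clusters (centroid centers)
exhaustive_kmeans_cost <- function(points, k) {
  n <- nrow(points)
  stopifnot(n <= 9, k <= 4)
  grid <- do.call(expand.grid, rep(list(seq_len(k)), n))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    asg <- as.integer(grid[g, ])
    if (length(unique(asg)) < k) next
    centers <- t(vapply(seq_len(k), function(cl)
      colMeans(points[asg == cl, , drop = FALSE]), numeric(ncol(points))))
    cost <- mean(sqrt(rowSums((points - centers[asg, , drop = FALSE])^2)))
    if (cost < best) best <- cost
  }
  best
}

# deterministic table with the exact printed level counts of the
# 1022-patient cohort (variables mutually unshuffled; marginals exact)
table1_exact_df <- function() {
  cts <- mcakm:::table1_counts()
  df <- as.data.frame(lapply(cts, function(ct)
    factor(rep(names(ct), ct), levels = names(ct))))
  rownames(df) <- sprintf("P%04d", seq_len(1022))
  df
}

# per-column chi-squared/N contributions of a nonnegative matrix
chi2_column_inertia <- function(A) {
  N <- sum(A); P <- A / N
  r <- rowSums(P); cc <- colSums(P)
  E <- outer(r, cc)
  colSums((P - E)^2 / E)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

random_categorical_table <- function(n, vars, max_levels = 3L, seed = 1L) {
  set.seed(seed)
  as.data.frame(lapply(seq_len(vars), function(v) {
    nl <- sample(2:max_levels, 1L)
    repeat {
      x <- sample(letters[seq_len(nl)], n, replace = TRUE)
      if (length(unique(x)) >= 2L) break
    }
    factor(x)
  }), col.names = paste0("V", seq_len(vars)))
}
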