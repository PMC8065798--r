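## K-means clustering of MCA coordinates with v-fold cross-validated
## cluster-count selection.
##
## The clustering cost of a solution is the mean Euclidean distance of
## points to their assigned cluster centers (optionally the mean squared
## distance).  The number of clusters is scanned over k_min..k_max; for
## each k the v-fold cross-validated cost is the mean, over folds, of the
## held-out points' cost against centers trained on the complement.  The
## scan stops at the first k whose cost differs from that at k+1 by less
## than a tolerance (the parsimony rule), or -- under the alternative
## rule -- at the smallest k whose per-fold costs do not differ
## significantly from those at k+1.

#' Clustering configuration
#'
#' @param k_min,k_max Range of cluster counts scanned (defaults 2 and 10).
#' @param v Number of cross-validation folds (default 5).
#' @param cost_tolerance Plateau threshold on successive cross-validated
#'   costs (default 0.01, in the units of the coordinates).
#' @param max_iter Maximum Lloyd iterations per run.
#' @param n_restarts Random restarts per k-means fit; the restart with
#'   the lowest within-cost wins.
#' @param seed Integer seed governing initial centers and fold shuffles.
#' @param selection_rule `"cost_plateau"` (default) or
#'   `"fold_significance"` (paired two-sided comparison of per-fold costs
#'   at alpha = 0.05).
#' @param metric `"distance"` (mean Euclidean distance, default) or
#'   `"squared"` (mean squared distance, the within-cluster
#'   sum-of-squares variant).
#' @return A `clustering_config` list.
#' @export
clustering_config <- function(k_min = 2L, k_max = 10L, v = 5L,
                              cost_tolerance = 0.01, max_iter = 100L,
                              n_restarts = 10L, seed = 1L,
                              selection_rule = c("cost_plateau",
                                                 "fold_significance"),
                              metric = c("distance", "squared")) {
  selection_rule <- match.arg(selection_rule)
  metric <- match.arg(metric)
  stopifnot(k_min >= 2L, k_min <= k_max, v >= 2L, cost_tolerance > 0,
            max_iter >= 1L, n_restarts >= 1L)
  structure(list(k_min = as.integer(k_min), k_max = as.integer(k_max),
                 v = as.integer(v), cost_tolerance = cost_tolerance,
                 max_iter = as.integer(max_iter),
                 n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed),
                 selection_rule = selection_rule, metric = metric),
            class = "clustering_config")
}

## n x k matrix of Euclidean distances from points to centers
dist_to_centers <- function(points, centers) {
  d2 <- outer(rowSums(points^2), rep(1, nrow(centers))) -
    2 * tcrossprod(points, centers) +
    outer(rep(1, nrow(points)), rowSums(centers^2))
  sqrt(pmax(d2, 0))
}

## nearest center per point; ties break to the lowest center index
nearest_center <- function(points, centers) {
  apply(dist_to_centers(points, centers), 1L, which.min)
}

cost_of <- function(points, centers, assign, metric) {
  d <- sqrt(pmax(rowSums((points - centers[assign, , drop = FALSE])^2), 0))
  if (metric == "squared") mean(d^2) else mean(d)
}

#' K-means with deterministic seeding and lowest-label tie-breaks
#'
#' Lloyd iteration from initial centers drawn uniformly among the
#' distinct points; assignments use Euclidean distance with ties broken
#' toward the lowest cluster index; an emptied cluster is repaired by
#' moving in the point currently farthest from its own center.  The best
#' of `n_restarts` runs (by within-cost) is returned.
#'
#' @param points Numeric matrix (rows = points, with rownames).
#' @param k Number of clusters, `1 <= k <=` number of distinct points.
#' @param config A [clustering_config()] (its `k_min` bound does not
#'   apply here; `k = 1` is allowed).
#' @param seed Seed for this fit; defaults to `config$seed`.
#' @return A `km_solution`: `k`, `centers`, `assignment` (named integer
#'   vector), `within_cost` in the configured metric, and `iter_costs`
#'   (mean squared distance objective per Lloyd iteration of the winning
#'   run -- the quantity the iteration monotonically decreases).
#' @export
km_cluster <- function(points, k, config = clustering_config(),
                       seed = config$seed) {
  points <- as.matrix(points)
  stopifnot(nrow(points) >= 1L, k >= 1L)
  uniq <- unique(points)
  if (k > nrow(uniq))
    stop(sprintf("k = %d exceeds the %d distinct points", k, nrow(uniq)),
         call. = FALSE)
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  best <- NULL
  for (rs in seq_len(config$n_restarts)) {
    centers <- uniq[sample.int(nrow(uniq), k), , drop = FALSE]
    assign_prev <- rep(0L, nrow(points))
    iter_costs <- numeric(0)
    for (it in seq_len(config$max_iter)) {
      asg <- nearest_center(points, centers)
      ## empty-cluster repair: donate the worst-fitting point
      for (cl in which(tabulate(asg, k) == 0L)) {
        resid <- rowSums((points - centers[asg, , drop = FALSE])^2)
        asg[which.max(resid)] <- cl
      }
      for (cl in seq_len(k))
        centers[cl, ] <- colMeans(points[asg == cl, , drop = FALSE])
      iter_costs <- c(iter_costs, cost_of(points, centers, asg, "squared"))
      if (identical(asg, assign_prev)) break
      assign_prev <- asg
    }
    wc <- cost_of(points, centers, asg, config$metric)
    if (is.null(best) || wc < best$within_cost) {
      rownames(centers) <- paste0("C", seq_len(k))
      best <- list(k = as.integer(k), centers = centers,
                   assignment = stats::setNames(asg, rownames(points)),
                   within_cost = wc, metric = config$metric,
                   iter_costs = iter_costs,
                   converged = it < config$max_iter)
    }
  }
  structure(best, class = "km_solution")
}

#' @export
print.km_solution <- function(x, ...) {
  cat(sprintf("k-means solution: k = %d, within-cost (%s) = %.6f\n",
              x$k, x$metric, x$within_cost))
  print(table(cluster = x$assignment))
  invisible(x)
}

#' Near-equal random folds
#' @param n Number of points.
#' @param v Number of folds.
#' @param seed Shuffle seed.
#' @return Integer vector of fold ids (1..v), sizes differing by at most 1.
#' @export
make_folds <- function(n, v, seed = 1L) {
  stopifnot(v >= 2L, v <= n)
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fold <- rep(seq_len(v), length.out = n)
  fold[sample.int(n)]
}

#' Cross-validated clustering cost at a given k
#'
#' For each fold, centers are trained on the complement and the cost is
#' the mean distance (in the configured metric) of the held-out points
#' to their nearest trained center; every point is held out exactly once.
#'
#' @param points Coordinate matrix.
#' @param k Number of clusters.
#' @param config A [clustering_config()].
#' @param folds Optional fold assignment from [make_folds()]; generated
#'   from `config$seed` if missing.
#' @return List `cv_cost` (mean of fold costs), `fold_costs`, `folds`.
#' @export
vfold_cost <- function(points, k, config = clustering_config(),
                       folds = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (config$v > n)
    stop(sprintf("v = %d exceeds the %d points", config$v, n), call. = FALSE)
  if (is.null(folds)) folds <- make_folds(n, config$v, config$seed)
  fold_costs <- numeric(config$v)
  for (i in seq_len(config$v)) {
    train <- points[folds != i, , drop = FALSE]
    if (nrow(unique(train)) < k)
      stop(sprintf(
        "training complement of fold %d has fewer than k = %d distinct points; use a smaller k or v",
        i, k), call. = FALSE)
    sol <- km_cluster(train, k, config, seed = config$seed + 131L * i + k)
    test <- points[folds == i, , drop = FALSE]
    dmin <- apply(dist_to_centers(test, sol$centers), 1L, min)
    fold_costs[i] <- if (config$metric == "squared") mean(dmin^2) else mean(dmin)
  }
  list(cv_cost = mean(fold_costs), fold_costs = fold_costs, folds = folds)
}

#' Select the number of clusters by cross-validated cost
#'
#' Scans `k = k_min..k_max` with one seeded fold shuffle reused across k.
#' Under `"cost_plateau"`, the scan returns the first k at which the
#' absolute change in cross-validated cost to k+1 falls below
#' `cost_tolerance` (stop dividing further); under
#' `"fold_significance"`, the smallest k whose per-fold costs do not
#' differ significantly from those at k+1 (paired two-sided t-test,
#' alpha = 0.05).  If no k satisfies the rule the global cost minimum is
#' returned with `flagged = TRUE`.
#'
#' @param points Coordinate matrix with rownames.
#' @param config A [clustering_config()].
#' @return A `k_selection`: `optimal_k`, `solutions` (full-data
#'   [km_cluster()] fit per k), `trace` (data frame of k, within-cost,
#'   cv-cost and the per-step decision), `fold_costs` (matrix v x
#'   number-of-k), `folds`, `flagged`.
#' @export
select_k <- function(points, config = clustering_config()) {
  points <- as.matrix(points)
  n <- nrow(points)
  k_max <- min(config$k_max, n - 1L)
  if (k_max < config$k_min)
    stop("too few points for the requested k range", call. = FALSE)
  ks <- config$k_min:k_max
  folds <- make_folds(n, config$v, config$seed)

  solutions <- vector("list", length(ks)); names(solutions) <- ks
  cv <- numeric(length(ks))
  fold_costs <- matrix(NA_real_, config$v, length(ks),
                       dimnames = list(NULL, ks))
  for (i in seq_along(ks)) {
    k <- ks[i]
    solutions[[i]] <- km_cluster(points, k, config,
                                 seed = config$seed + 977L * k)
    vc <- vfold_cost(points, k, config, folds = folds)
    cv[i] <- vc$cv_cost
    fold_costs[, i] <- vc$fold_costs
  }

  optimal_k <- NA_integer_; flagged <- FALSE
  decision <- rep("", length(ks))
  if (config$selection_rule == "cost_plateau") {
    for (i in seq_len(length(ks) - 1L)) {
      delta <- abs(cv[i + 1L] - cv[i])
      decision[i] <- sprintf("|D(k+1)-D(k)| = %.6f", delta)
      if (delta < config$cost_tolerance) { optimal_k <- ks[i]; break }
    }
  } else {
    for (i in seq_len(length(ks) - 1L)) {
      diffs <- fold_costs[, i] - fold_costs[, i + 1L]
      if (all(abs(diffs - mean(diffs)) < 1e-12)) {
        p <- if (all(abs(diffs) < 1e-12)) 1 else 0
      } else {
        p <- stats::t.test(fold_costs[, i], fold_costs[, i + 1L],
                           paired = TRUE)$p.value
      }
      decision[i] <- sprintf("paired p = %.4f", p)
      if (p >= 0.05) { optimal_k <- ks[i]; break }
    }
  }
  if (is.na(optimal_k)) {
    optimal_k <- ks[which.min(cv)]
    flagged <- TRUE
  }

  structure(list(optimal_k = optimal_k, solutions = solutions,
                 trace = data.frame(
                   k = ks,
                   within_cost = vapply(solutions, `[[`, 0, "within_cost"),
                   cv_cost = cv, decision = decision,
                   stringsAsFactors = FALSE),
                 fold_costs = fold_costs, folds = folds,
                 flagged = flagged, rule = config$selection_rule),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("Cluster-count selection (%s rule): optimal k = %d%s\n",
              x$rule, x$optimal_k,
              if (x$flagged) " (no stopping point in range; cost minimum)" else ""))
  print(x$trace[, c("k", "within_cost", "cv_cost")], row.names = FALSE)
  invisible(x)
}

#' Category-to-cluster classification table
#'
#' @param solution A [km_cluster()] fit of category coordinates.
#' @param labels Data frame with `variable` and `level` columns aligned
#'   with the clustered points (e.g. the `labels` of the fitted MCA).
#' @return Data frame `(variable, level, cluster)` with cluster labels
#'   renumbered 1..k by first appearance, sorted by cluster then label.
#' @export
classify_categories <- function(solution, labels) {
  stopifnot(inherits(solution, "km_solution"),
            nrow(labels) == length(solution$assignment),
            all(c("variable", "level") %in% names(labels)))
  asg <- unname(solution$assignment)
  first_seen <- unique(asg)
  renum <- match(asg, first_seen)
  out <- data.frame(variable = labels$variable, level = labels$level,
                    cluster = renum, stringsAsFactors = FALSE)
  out <- out[order(out$cluster, out$variable, out$level), ]
  rownames(out) <- NULL
  out
}

#' Export the cost-versus-k table as CSV
#' @param selection A [select_k()] result.
#' @param path Output path.
#' @export
write_cost_csv <- function(selection, path) {
  stopifnot(inherits(selection, "k_selection"))
  utils::write.csv(selection$trace[, c("k", "within_cost", "cv_cost")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Export a classification table as CSV
#' @param classification A [classify_categories()] table.
#' @param path Output path.
#' @export
write_classification_csv <- function(classification, path) {
  utils::write.csv(classification, path, row.names = FALSE)
  invisible(path)
}
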