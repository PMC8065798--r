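## Headline model fitter: MCA embedding + cross-validated k-means of the
## category points, the estimator around which the package is organised.

#' Fit the MCA--k-means risk-factor clustering model
#'
#' Embeds the category levels of a categorical patient table in
#' Euclidean space by multiple correspondence analysis, retains the
#' leading axes by cumulative inertia, and clusters the category
#' principal coordinates with k-means, choosing the number of clusters
#' by v-fold cross-validated clustering cost.  Designed for rare-outcome
#' settings where logistic regression degenerates: categories that
#' co-occur (e.g. a rare comorbidity and a rare psychiatric outcome)
#' land in the same cluster.
#'
#' @param data Data frame of factors (patients x categorical variables),
#'   no missing cells.  Outcome variables take part as active variables.
#' @param basis MCA basis, `"indicator"` (default) or `"burt"`.
#' @param dim_rule,dim_threshold Axis-retention rule passed to
#'   [select_dimensions()]; default: smallest dimension count reaching
#'   80% of total inertia.
#' @param cluster_input `"columns"` (default) clusters the category
#'   points G; `"rows"` clusters the patient points F.
#' @param k_min,k_max,v,cost_tolerance,selection_rule,metric,n_restarts,max_iter
#'   Clustering controls, see [clustering_config()].
#' @param seed Integer seed for all stochastic stages.
#' @param drop_constant If `TRUE`, variables with a single observed
#'   level are dropped with a warning instead of raising an error; a
#'   zero-variance category has no mass-centered representation, but a
#'   sampled cohort can legitimately miss the rarest level of a very
#'   rare comorbidity.
#' @return An object of class `mca_kmeans` with components `mca`,
#'   `profile`, `n_dims`, `selection` (the [select_k()] trace and
#'   per-k solutions), `k`, `classification` (the category-to-cluster
#'   table) and `config`.
#' @seealso [encode_indicator()], [fit_mca()], [select_k()],
#'   [classify_categories()]
#' @examples
#' cohort <- generate_cohort(table1_planted_spec(seed = 7))
#' fit <- mca_kmeans(cohort, seed = 7)
#' print(fit)
#' head(fitted(fit))
#' @export
mca_kmeans <- function(data, basis = c("indicator", "burt"),
                       dim_rule = c("cumulative_threshold", "all"),
                       dim_threshold = 0.80,
                       cluster_input = c("columns", "rows"),
                       k_min = 2L, k_max = 10L, v = 5L,
                       cost_tolerance = 0.01,
                       selection_rule = c("cost_plateau",
                                          "fold_significance"),
                       metric = c("distance", "squared"),
                       n_restarts = 10L, max_iter = 100L, seed = 1L,
                       drop_constant = FALSE) {
  basis <- match.arg(basis)
  dim_rule <- match.arg(dim_rule)
  cluster_input <- match.arg(cluster_input)
  selection_rule <- match.arg(selection_rule)
  metric <- match.arg(metric)

  if (drop_constant) {
    constant <- names(data)[vapply(data, function(x)
      length(unique(x[!is.na(x)])) < 2L, NA)]
    if (length(constant)) {
      warning("dropping single-level variable(s): ",
              paste(constant, collapse = ", "), call. = FALSE)
      data <- data[, setdiff(names(data), constant), drop = FALSE]
    }
  }
  X <- encode_indicator(data)
  model <- fit_mca(X, basis = basis)
  profile <- inertia_profile(model)
  n_dims <- select_dimensions(profile, rule = dim_rule,
                              threshold = dim_threshold)
  pts <- if (cluster_input == "columns") model$G else model$F
  pts <- pts[, seq_len(n_dims), drop = FALSE]

  config <- clustering_config(k_min = k_min,
                              k_max = min(k_max, nrow(pts) - 1L),
                              v = v, cost_tolerance = cost_tolerance,
                              max_iter = max_iter, n_restarts = n_restarts,
                              seed = seed, selection_rule = selection_rule,
                              metric = metric)
  selection <- select_k(pts, config)
  best <- selection$solutions[[as.character(selection$optimal_k)]]
  classification <- if (cluster_input == "columns")
    classify_categories(best, model$labels)
  else {
    asg <- unname(best$assignment)
    renum <- match(asg, unique(asg))
    data.frame(variable = rownames(pts), level = NA_character_,
               cluster = renum, stringsAsFactors = FALSE)
  }

  structure(list(mca = model, profile = profile, n_dims = n_dims,
                 cluster_input = cluster_input,
                 selection = selection, k = selection$optimal_k,
                 solution = best, classification = classification,
                 config = config, call = match.call()),
            class = "mca_kmeans")
}

#' @export
print.mca_kmeans <- function(x, ...) {
  cat("MCA-k-means risk-factor clustering\n")
  cat(sprintf("  %d category points embedded in %d dimension(s) (%s basis, %.1f%% of inertia)\n",
              nrow(x$mca$G), x$n_dims, x$mca$basis,
              100 * x$profile$per_dimension$cumulative[x$n_dims]))
  cat(sprintf("  optimal k = %d (%s rule, v = %d folds)%s\n",
              x$k, x$config$selection_rule, x$config$v,
              if (x$selection$flagged) " [no plateau in range; cost minimum]" else ""))
  invisible(x)
}

#' @export
summary.mca_kmeans <- function(object, ...) {
  print(object)
  cat("\nCross-validated clustering cost by k:\n")
  print(object$selection$trace[, c("k", "within_cost", "cv_cost")],
        row.names = FALSE)
  cat("\nFinal classification:\n")
  print(object$classification, row.names = FALSE)
  invisible(object$classification)
}

#' @export
fitted.mca_kmeans <- function(object, ...) object$classification

#' Plot cross-validated clustering cost against the number of clusters
#'
#' @param x A fitted [mca_kmeans()] object.
#' @param ... Further arguments passed to [graphics::plot.default()].
#' @export
plot.mca_kmeans <- function(x, ...) {
  tr <- x$selection$trace
  graphics::plot(tr$k, tr$cv_cost, type = "b", pch = 19,
                 xlab = "number of clusters k",
                 ylab = sprintf("cross-validated clustering cost (%s)",
                                x$config$metric), ...)
  graphics::points(tr$k, tr$within_cost, type = "b", lty = 2, pch = 1)
  graphics::abline(v = x$k, lty = 3)
  graphics::legend("topright", legend = c("cross-validated", "within-sample"),
                   lty = c(1, 2), pch = c(19, 1), bty = "n")
  invisible(x)
}
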