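## Multiple correspondence analysis.
##
## The raw patients x variables table is one-hot expanded into an
## indicator matrix X (both levels of binary variables are expanded, so
## every category level is a column point).  Analysis runs on either the
## indicator matrix or the Burt matrix B = X'X.  With P the probability
## matrix (the analysed matrix divided by its grand total), r and c its
## row and column margins, the SVD of the standardized residual matrix
##   S = Dr^{-1/2} (P - r c') Dc^{-1/2} = U Delta Q'
## yields principal coordinates F = Dr^{-1/2} U Delta (rows) and
## G = Dc^{-1/2} Q Delta (columns); eigenvalues are squared singular
## values and their sum is the total inertia (Pearson chi-squared / N).

#' One-hot encode a categorical table into an indicator matrix
#'
#' Every level of every variable becomes a 0/1 column labelled
#' `"Variable=Level"`; each row activates exactly one level per variable.
#'
#' @param raw Data frame of factors or character columns, no missing
#'   cells.
#' @return An `indicator_matrix`: list with `values` (I x J 0/1 matrix),
#'   `labels` (data frame `variable`, `level` per column), and
#'   `variable_index` (variable -> column span).
#' @export
encode_indicator <- function(raw) {
  stopifnot(is.data.frame(raw), nrow(raw) >= 1L, ncol(raw) >= 1L)
  if (anyNA(raw))
    stop("missing cells are not supported; resolve them before encoding",
         call. = FALSE)
  cols <- list(); labs_var <- character(0); labs_lev <- character(0)
  variable_index <- list()
  at <- 0L
  for (v in names(raw)) {
    x <- factor(raw[[v]])
    x <- droplevels(x)
    if (nlevels(x) < 2L)
      stop(sprintf("variable '%s' has a single observed level", v),
           call. = FALSE)
    for (lev in levels(x)) cols[[length(cols) + 1L]] <- as.integer(x == lev)
    variable_index[[v]] <- at + seq_len(nlevels(x))
    at <- at + nlevels(x)
    labs_var <- c(labs_var, rep(v, nlevels(x)))
    labs_lev <- c(labs_lev, levels(x))
  }
  values <- do.call(cbind, cols)
  colnames(values) <- paste0(labs_var, "=", labs_lev)
  rownames(values) <- rownames(raw)
  structure(list(values = values,
                 labels = data.frame(variable = labs_var, level = labs_lev,
                                     stringsAsFactors = FALSE),
                 variable_index = variable_index,
                 n_vars = ncol(raw)),
            class = "indicator_matrix")
}

#' @export
print.indicator_matrix <- function(x, ...) {
  cat(sprintf("Indicator matrix: %d rows x %d category columns (%d variables)\n",
              nrow(x$values), ncol(x$values), x$n_vars))
  invisible(x)
}

#' Burt matrix of an indicator matrix
#'
#' @param X An [encode_indicator()] result.
#' @return The symmetric J x J matrix `t(X) %*% X`: diagonal blocks are
#'   diagonal level-count matrices, off-diagonal blocks are pairwise
#'   two-way contingency tables.
#' @export
build_burt <- function(X) {
  stopifnot(inherits(X, "indicator_matrix"))
  crossprod(X$values)
}

#' Fit a multiple correspondence analysis
#'
#' @param X An [encode_indicator()] result.
#' @param basis `"indicator"` (default) analyses X itself; `"burt"`
#'   analyses the Burt matrix, whose eigenvalues are the squares of the
#'   indicator-basis eigenvalues.
#' @param tol Singular values at or below `tol` are treated as null
#'   dimensions and dropped from the coordinates.
#' @return An object of class `mca`: margins `r`, `c`, the retained
#'   `singular_values` and `eigenvalues`, principal coordinates `F`
#'   (rows) and `G` (columns, one row per category level), `labels`,
#'   `total_inertia` and the grand total `N`.  Each axis is oriented so
#'   that its largest-magnitude category coordinate is positive.
#' @export
fit_mca <- function(X, basis = c("indicator", "burt"), tol = 1e-12) {
  stopifnot(inherits(X, "indicator_matrix"))
  basis <- match.arg(basis)
  A <- if (basis == "indicator") X$values else build_burt(X)
  if (nrow(X$values) < 2L) stop("need at least 2 observations", call. = FALSE)
  dec <- ca_decompose(A, tol = tol)
  structure(c(list(basis = basis), dec,
              list(labels = X$labels, n_vars = X$n_vars)),
            class = "mca")
}

## Core correspondence decomposition of a nonnegative matrix A:
## P = A / sum(A), margins r and c, SVD of the standardized residuals
## Dr^{-1/2}(P - r c')Dc^{-1/2}, principal coordinates, total inertia.
ca_decompose <- function(A, tol = 1e-12) {
  A <- as.matrix(A)
  if (any(A < 0)) stop("negative entries", call. = FALSE)
  N <- sum(A)
  if (N <= 0) stop("empty matrix", call. = FALSE)
  P <- A / N
  r <- rowSums(P); cc <- colSums(P)
  if (any(r <= 0))
    stop("zero row mass at row(s): ",
         paste(utils::head(which(r <= 0)), collapse = ", "), call. = FALSE)
  if (any(cc <= 0)) {
    bad <- if (is.null(colnames(A))) which(cc <= 0) else colnames(A)[cc <= 0]
    stop("zero column mass at column(s): ",
         paste(utils::head(bad), collapse = ", "), call. = FALSE)
  }

  S <- (P - tcrossprod(r, cc)) / tcrossprod(sqrt(r), sqrt(cc))
  sv <- svd(S)
  keep <- which(sv$d > tol)
  d <- sv$d[keep]
  U <- sv$u[, keep, drop = FALSE]
  Q <- sv$v[, keep, drop = FALSE]

  Fmat <- sweep(U, 2L, d, `*`) / sqrt(r)
  Gmat <- sweep(Q, 2L, d, `*`) / sqrt(cc)
  ## orient each axis: largest |category coordinate| positive
  for (s in seq_along(d)) {
    j <- which.max(abs(Gmat[, s]))
    if (Gmat[j, s] < 0) {
      Gmat[, s] <- -Gmat[, s]; Fmat[, s] <- -Fmat[, s]
    }
  }
  if (length(d)) {
    dn <- paste0("Dim", seq_along(d))
    dimnames(Fmat) <- list(rownames(A), dn)
    dimnames(Gmat) <- list(colnames(A), dn)
  }

  list(N = N, r = r, c = cc,
       singular_values = d, eigenvalues = d^2,
       F = Fmat, G = Gmat, total_inertia = sum(sv$d^2))
}

#' @export
print.mca <- function(x, ...) {
  cat(sprintf("Multiple correspondence analysis (%s basis)\n", x$basis))
  cat(sprintf("  %d row points, %d category points, %d non-null dimensions\n",
              nrow(x$F), nrow(x$G), length(x$singular_values)))
  cat(sprintf("  total inertia %.6f\n", x$total_inertia))
  invisible(x)
}

#' @export
summary.mca <- function(object, ...) {
  prof <- inertia_profile(object)
  cat(sprintf("MCA (%s basis): total inertia %.6f over %d dimensions\n\n",
              object$basis, object$total_inertia,
              length(object$singular_values)))
  print(round(prof$per_dimension, 4))
  invisible(prof)
}

#' Inertia decomposition of a fitted MCA
#'
#' Eigenvalue, proportion of total inertia and cumulative proportion per
#' axis, plus mass-weighted per-point inertias over the retained axes
#' (`r_i * ||F_i||^2` for rows, `c_j * ||G_j||^2` for columns), so that
#' the column point inertias sum to the retained eigenvalues.
#'
#' @param model A fitted [fit_mca()] object.
#' @param subset_dims Number of leading axes to retain; `NULL` keeps all.
#' @return An `inertia_profile`: `per_dimension` data frame
#'   (`eigenvalue`, `proportion`, `cumulative`), `row_point_inertias`,
#'   `column_point_inertias`, `subset_dims`.
#' @export
inertia_profile <- function(model, subset_dims = NULL) {
  stopifnot(inherits(model, "mca"))
  nd <- length(model$singular_values)
  if (is.null(subset_dims)) subset_dims <- nd
  stopifnot(subset_dims >= 1L, subset_dims <= nd)
  ev <- model$eigenvalues
  prop <- ev / model$total_inertia
  keep <- seq_len(subset_dims)
  structure(list(
    per_dimension = data.frame(dim = seq_len(nd), eigenvalue = ev,
                               proportion = prop, cumulative = cumsum(prop)),
    row_point_inertias = model$r *
      rowSums(model$F[, keep, drop = FALSE]^2),
    column_point_inertias = model$c *
      rowSums(model$G[, keep, drop = FALSE]^2),
    subset_dims = subset_dims),
    class = "inertia_profile")
}

#' Choose how many MCA axes to retain
#'
#' @param profile An [inertia_profile()].
#' @param rule `"cumulative_threshold"` (default) returns the smallest
#'   dimension count whose cumulative proportion of inertia reaches
#'   `threshold`; `"all"` returns every non-null axis.
#' @param threshold Proportion in (0, 1]; default 0.80.
#' @return Integer dimension count.
#' @export
select_dimensions <- function(profile,
                              rule = c("cumulative_threshold", "all"),
                              threshold = 0.80) {
  stopifnot(inherits(profile, "inertia_profile"))
  rule <- match.arg(rule)
  nd <- nrow(profile$per_dimension)
  if (rule == "all") return(nd)
  stopifnot(threshold > 0, threshold <= 1)
  hit <- which(profile$per_dimension$cumulative >= threshold - 1e-12)
  if (!length(hit)) nd else min(hit)
}

#' Export a fitted MCA as JSON
#'
#' Serializes margins, eigenvalues and labelled coordinates.
#' @param model A fitted [fit_mca()] object.
#' @param path Output path.
#' @export
write_mca_json <- function(model, path) {
  stopifnot(inherits(model, "mca"))
  obj <- list(basis = model$basis, N = model$N,
              total_inertia = model$total_inertia,
              singular_values = model$singular_values,
              eigenvalues = model$eigenvalues,
              row_mass = model$r, column_mass = model$c,
              row_coordinates = as.data.frame(model$F),
              column_coordinates = cbind(model$labels,
                                         as.data.frame(model$G)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' Export labelled category coordinates as CSV
#' @param model A fitted [fit_mca()] object.
#' @param path Output path.
#' @export
write_coordinates_csv <- function(model, path) {
  stopifnot(inherits(model, "mca"))
  utils::write.csv(cbind(model$labels, as.data.frame(model$G)), path,
                   row.names = FALSE)
  invisible(path)
}
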