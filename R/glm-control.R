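## Logistic-regression comparison arm.
##
## With outcome prevalences of one-to-three percent and comorbidity
## prevalences of the same order, two-way tables against the outcome
## routinely contain zero cells, maximum-likelihood logistic coefficients
## drift toward +/- infinity (quasi-separation) and their standard errors
## explode.  This arm fits the conventional models anyway and flags the
## pathology explicitly rather than correcting it, since exhibiting the
## failure is the point of the comparison.

as_binary_outcome <- function(outcome) {
  if (is.factor(outcome)) outcome <- as.integer(outcome) - 1L
  if (is.logical(outcome)) outcome <- as.integer(outcome)
  if (!all(outcome %in% c(0L, 1L))) stop("outcome must be binary", call. = FALSE)
  if (length(unique(outcome)) < 2L)
    stop("outcome is constant; the model is undefined", call. = FALSE)
  as.integer(outcome)
}

#' Rao score test of a categorical covariate
#'
#' Tests the covariate's entry into an intercept-only logistic model.
#' With fitted null probability p0 (the outcome prevalence), the score is
#' `U = X'(y - p0)` over the J-1 non-reference dummy columns and the
#' statistic `U' V^{-1} U` is chi-squared with J-1 degrees of freedom,
#' where `V = p0 (1 - p0) (X'X - X'1 1'X / n)`.  For a binary covariate
#' this equals the Pearson chi-squared of the 2x2 table (no continuity
#' correction).
#'
#' @param outcome Binary vector or two-level factor (second level =
#'   event).
#' @param covariate Factor (or character) covariate; its first level is
#'   the reference.
#' @return An object of class `htest` with `statistic`, `parameter`
#'   (degrees of freedom) and `p.value`.
#' @export
score_test <- function(outcome, covariate) {
  y <- as_binary_outcome(outcome)
  x <- droplevels(factor(covariate))
  if (nlevels(x) < 2L) stop("covariate has a single level", call. = FALSE)
  if (length(y) != length(x)) stop("length mismatch", call. = FALSE)
  X <- stats::model.matrix(~x)[, -1L, drop = FALSE]
  n <- length(y); p0 <- mean(y)
  U <- crossprod(X, y - p0)
  cs <- colSums(X)
  V <- p0 * (1 - p0) * (crossprod(X) - tcrossprod(cs) / n)
  stat <- drop(crossprod(U, solve(V, U)))
  df <- ncol(X)
  structure(list(statistic = c("score" = stat),
                 parameter = c(df = df),
                 p.value = stats::pchisq(stat, df, lower.tail = FALSE),
                 method = "Rao score test (logistic, intercept-only null)",
                 data.name = deparse(substitute(covariate))),
            class = "htest")
}

#' Score-test screen of every covariate (per outcome)
#'
#' @param data Data frame of factors containing outcome and covariates.
#' @param outcome Name of the binary outcome column.
#' @param covariates Covariate column names; defaults to all other
#'   columns except `exclude`.
#' @param exclude Columns never used as covariates (e.g. the other
#'   outcome).
#' @return Data frame `(variable, score, df, p_value)`.
#' @export
score_screen <- function(data, outcome, covariates = NULL,
                         exclude = character(0)) {
  if (is.null(covariates))
    covariates <- setdiff(names(data), c(outcome, exclude))
  rows <- lapply(covariates, function(v) {
    ht <- score_test(data[[outcome]], data[[v]])
    data.frame(variable = v, score = unname(ht$statistic),
               df = unname(ht$parameter), p_value = ht$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Multiple logistic regression with separation diagnostics
#'
#' Maximum-likelihood fit (IRLS via [stats::glm()], capped at
#' `max_iter` iterations) of a binary outcome on categorical covariates,
#' without variable selection.  Coefficients are reported as-is; a
#' separation flag is raised per term whenever its standard error
#' exceeds 50 or its absolute coefficient exceeds 10, the signature of
#' quasi-separation under rare events.
#'
#' @param data Data frame of factors.
#' @param outcome Name of the binary outcome column (second factor level
#'   = event).
#' @param covariates Covariate column names; defaults to all other
#'   columns except `exclude`.
#' @param exclude Columns dropped from the default covariate list.
#' @param max_iter IRLS iteration cap (default 100).
#' @param epsilon Relative convergence tolerance on the deviance.
#' @param se_flag,beta_flag Thresholds for the separation flags.
#' @return A `glm_report`: `coefficients` data frame
#'   (`term, beta, se, odds_ratio, p_value, separation_flag`, covariate
#'   terms first, `Constant` last), `converged`, `outcome`, and the
#'   underlying `fit`.
#' @export
fit_logistic <- function(data, outcome, covariates = NULL,
                         exclude = character(0), max_iter = 100L,
                         epsilon = 1e-8, se_flag = 50, beta_flag = 10) {
  if (is.null(covariates))
    covariates <- setdiff(names(data), c(outcome, exclude))
  df <- data[, c(outcome, covariates), drop = FALSE]
  if (length(covariates)) {
    df[covariates] <- lapply(df[covariates], function(x) droplevels(factor(x)))
    single <- covariates[vapply(df[covariates], nlevels, 0L) < 2L]
    if (length(single))
      stop("constant covariate column(s): ", paste(single, collapse = ", "),
           call. = FALSE)
  }
  y <- as_binary_outcome(df[[outcome]])
  df[[outcome]] <- y

  rhs <- if (length(covariates))
    paste(sprintf("`%s`", covariates), collapse = " + ") else "1"
  form <- stats::as.formula(paste(outcome, "~", rhs))
  fit <- suppressWarnings(
    stats::glm(form, family = stats::binomial(), data = df,
               control = stats::glm.control(maxit = max_iter,
                                            epsilon = epsilon)))
  if (any(is.na(stats::coef(fit)))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; aliased terms: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  terms <- rownames(sm)
  ord <- c(setdiff(seq_along(terms), which(terms == "(Intercept)")),
           which(terms == "(Intercept)"))
  sm <- sm[ord, , drop = FALSE]
  terms <- rownames(sm)
  terms[terms == "(Intercept)"] <- "Constant"
  beta <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
  structure(list(
    coefficients = data.frame(
      term = terms, beta = unname(beta), se = unname(se),
      odds_ratio = unname(exp(beta)),
      p_value = unname(sm[, "Pr(>|z|)"]),
      separation_flag = unname(se > se_flag | abs(beta) > beta_flag),
      stringsAsFactors = FALSE),
    converged = fit$converged, outcome = outcome,
    covariates = covariates, fit = fit),
    class = "glm_report")
}

#' @export
print.glm_report <- function(x, digits = 3, ...) {
  cat(sprintf("Logistic regression report: outcome = %s%s\n", x$outcome,
              if (!x$converged) " (IRLS did not converge)" else ""))
  tab <- x$coefficients
  tab$beta <- signif(tab$beta, digits)
  tab$se <- signif(tab$se, digits)
  tab$odds_ratio <- signif(tab$odds_ratio, digits)
  tab$p_value <- signif(tab$p_value, digits)
  print(tab, row.names = FALSE)
  nflag <- sum(x$coefficients$separation_flag)
  if (nflag)
    cat(sprintf("%d term(s) flagged for quasi-separation (SE or |beta| beyond threshold)\n",
                nflag))
  invisible(x)
}

#' Rare-event pathology summary of a logistic report
#'
#' Lists the separation-flagged terms, finds the zero cells of each
#' covariate's two-way table against the outcome (the usual cause of the
#' divergence), and states a recommendation.  Purely descriptive.
#'
#' @param report A [fit_logistic()] result.
#' @return A `rare_event_diagnostics` list: `flagged_terms`,
#'   `zero_cells` (data frame `variable, level, outcome_class`),
#'   `recommendation`.
#' @export
rare_event_diagnostics <- function(report) {
  stopifnot(inherits(report, "glm_report"))
  flagged <- report$coefficients$term[report$coefficients$separation_flag]
  mf <- stats::model.frame(report$fit)
  y <- mf[[1L]]
  zero <- data.frame(variable = character(), level = character(),
                     outcome_class = character(), stringsAsFactors = FALSE)
  for (v in names(mf)[-1L]) {
    tab <- table(mf[[v]], y)
    idx <- which(tab == 0L, arr.ind = TRUE)
    if (nrow(idx))
      zero <- rbind(zero, data.frame(
        variable = v, level = rownames(tab)[idx[, 1L]],
        outcome_class = colnames(tab)[idx[, 2L]],
        stringsAsFactors = FALSE))
  }
  rec <- if (length(flagged) || nrow(zero))
    paste("Maximum-likelihood estimates are unreliable for the flagged",
          "terms (quasi-separation from zero outcome cells); consider a",
          "penalized fit or the clustering-based risk-factor analysis",
          "rather than interpreting these coefficients.")
  else
    "No separation flags; estimates are well conditioned."
  structure(list(outcome = report$outcome, flagged_terms = flagged,
                 zero_cells = zero, recommendation = rec),
            class = "rare_event_diagnostics")
}

#' @export
print.rare_event_diagnostics <- function(x, ...) {
  cat(sprintf("Rare-event diagnostics (outcome = %s)\n", x$outcome))
  if (length(x$flagged_terms))
    cat("  flagged terms:", paste(x$flagged_terms, collapse = ", "), "\n")
  if (nrow(x$zero_cells)) {
    cat(sprintf("  %d zero cell(s) in covariate-by-outcome tables:\n",
                nrow(x$zero_cells)))
    print(x$zero_cells, row.names = FALSE)
  }
  cat(" ", x$recommendation, "\n")
  invisible(x)
}

#' Export a logistic report as CSV
#' @param report A [fit_logistic()] result.
#' @param path Output path.
#' @export
write_glm_csv <- function(report, path) {
  stopifnot(inherits(report, "glm_report"))
  utils::write.csv(report$coefficients, path, row.names = FALSE)
  invisible(path)
}
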