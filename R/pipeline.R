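## End-to-end run orchestration: cohort input -> MCA -> cross-validated
## k-means -> control-arm reports, with a reproducible run manifest.

#' Assemble a run configuration
#'
#' @param input Path to a cohort CSV (header = variable names, cells =
#'   level labels), or `NULL` to generate a cohort from `preset`.
#' @param preset Generator preset used when `input` is `NULL`:
#'   `"table1"` or `"table1_planted"`.
#' @param n_patients Rows for a generated cohort.
#' @param exclude_variables Variables dropped before analysis.
#' @param outcomes Outcome columns for the control-arm reports; each is
#'   regressed on all remaining variables (the other outcome excluded).
#' @param basis,dim_rule,dim_threshold MCA options, see [mca_kmeans()].
#' @param k_min,k_max,v,cost_tolerance,selection_rule,metric Clustering
#'   options, see [clustering_config()].
#' @param out_dir Output directory for artifacts.
#' @param drop_constant Drop single-level variables with a warning
#'   rather than erroring (default `TRUE`; a sampled cohort can miss the
#'   rarest level of a very rare comorbidity).
#' @param seed Integer seed propagated to every stochastic stage.
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL, preset = "table1_planted",
                       n_patients = 1022L,
                       exclude_variables = character(0),
                       outcomes = c("Depression", "Anxiety"),
                       basis = "indicator",
                       dim_rule = "cumulative_threshold",
                       dim_threshold = 0.80,
                       k_min = 2L, k_max = 10L, v = 5L,
                       cost_tolerance = 0.01,
                       selection_rule = "cost_plateau",
                       metric = "distance",
                       out_dir = "mcakm-run", drop_constant = TRUE,
                       seed = 1L) {
  structure(list(input = input, preset = preset,
                 n_patients = as.integer(n_patients),
                 exclude_variables = exclude_variables,
                 outcomes = outcomes, basis = basis,
                 dim_rule = dim_rule, dim_threshold = dim_threshold,
                 k_min = as.integer(k_min), k_max = as.integer(k_max),
                 v = as.integer(v), cost_tolerance = cost_tolerance,
                 selection_rule = selection_rule, metric = metric,
                 out_dir = out_dir, drop_constant = isTRUE(drop_constant),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from YAML or JSON
#' @param path Configuration file; keys as in [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs",
           call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, cfg)
}

#' Run the full analysis pipeline
#'
#' Stages: load or generate the cohort; fit the MCA--k-means model; fit
#' the per-outcome score-test screens and multiple logistic regressions.
#' Artifacts written under `config$out_dir`: `mca_model.json`,
#' `cost_vs_k.csv`, `classification.csv`, `glm_<outcome>.csv` and
#' `score_<outcome>.csv` per outcome, and `manifest.json` (the full
#' configuration, seed and package version).  Re-running with the
#' configuration embedded in a manifest reproduces the artifacts.
#'
#' @param config A [run_config()], or a path accepted by
#'   [read_run_config()].
#' @return Invisibly, a list with the fitted `model`, `reports`,
#'   `screens`, and the `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  stage <- "setup"
  res <- tryCatch({
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

    stage <- "cohort"
    cohort <- if (!is.null(config$input)) read_cohort_csv(config$input)
    else {
      spec <- switch(config$preset,
                     table1 = table1_spec(config$n_patients,
                                          seed = config$seed),
                     table1_planted = table1_planted_spec(
                       config$n_patients, seed = config$seed),
                     stop(sprintf("unknown preset '%s'", config$preset),
                          call. = FALSE))
      generate_cohort(spec)
    }
    bad <- setdiff(c(config$exclude_variables, config$outcomes),
                   names(cohort))
    if (length(bad))
      stop("variables not in input header: ", paste(bad, collapse = ", "),
           call. = FALSE)
    cohort <- cohort[, setdiff(names(cohort), config$exclude_variables),
                     drop = FALSE]
    if (config$drop_constant) {
      constant <- names(cohort)[vapply(cohort, function(x)
        length(unique(x[!is.na(x)])) < 2L, NA)]
      constant <- setdiff(constant, config$outcomes)
      if (length(constant)) {
        warning("dropping single-level variable(s): ",
                paste(constant, collapse = ", "), call. = FALSE)
        cohort <- cohort[, setdiff(names(cohort), constant), drop = FALSE]
      }
    }
    rare <- names(cohort)[vapply(cohort, function(x) min(table(x)), 0) < 5]
    if (length(rare))
      warning("variable(s) with a level observed fewer than 5 times: ",
              paste(rare, collapse = ", "), call. = FALSE)

    stage <- "mca_kmeans"
    model <- mca_kmeans(cohort, basis = config$basis,
                        dim_rule = config$dim_rule,
                        dim_threshold = config$dim_threshold,
                        k_min = config$k_min, k_max = config$k_max,
                        v = config$v,
                        cost_tolerance = config$cost_tolerance,
                        selection_rule = config$selection_rule,
                        metric = config$metric, seed = config$seed,
                        drop_constant = config$drop_constant)
    write_mca_json(model$mca, file.path(config$out_dir, "mca_model.json"))
    write_cost_csv(model$selection,
                   file.path(config$out_dir, "cost_vs_k.csv"))
    write_classification_csv(model$classification,
                             file.path(config$out_dir, "classification.csv"))

    stage <- "control_glm"
    reports <- list(); screens <- list()
    for (oc in config$outcomes) {
      other <- setdiff(config$outcomes, oc)
      screens[[oc]] <- score_screen(cohort, oc, exclude = other)
      utils::write.csv(screens[[oc]],
                       file.path(config$out_dir,
                                 sprintf("score_%s.csv", tolower(oc))),
                       row.names = FALSE)
      reports[[oc]] <- fit_logistic(cohort, oc, exclude = other)
      write_glm_csv(reports[[oc]],
                    file.path(config$out_dir,
                              sprintf("glm_%s.csv", tolower(oc))))
    }

    stage <- "manifest"
    manifest <- list(
      package = "mcakm",
      version = as.character(utils::packageVersion("mcakm")),
      seed = config$seed,
      config = unclass(config),
      artifacts = c("mca_model.json", "cost_vs_k.csv",
                    "classification.csv",
                    sprintf("score_%s.csv", tolower(config$outcomes)),
                    sprintf("glm_%s.csv", tolower(config$outcomes))),
      optimal_k = model$k, n_dims = model$n_dims)
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    list(model = model, reports = reports, screens = screens,
         manifest = manifest)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}

#' Re-run a pipeline from a written manifest
#' @param manifest_path Path to a `manifest.json` written by
#'   [run_pipeline()].
#' @return See [run_pipeline()].
#' @export
rerun_manifest <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- man$config
  cfg$input <- if (is.null(cfg$input) || !length(cfg$input)) NULL
               else cfg$input
  run_pipeline(do.call(run_config, cfg))
}
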