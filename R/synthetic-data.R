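## Synthetic cohort and claims generation.
##
## The generator emulates a claims-derived cohort of young lung-cancer
## patients: a patients x categorical-variables table with specified
## marginal level frequencies, optionally carrying "planted blocks" --
## sets of category levels made to co-occur with tunable strength -- so
## that cluster-recovery behaviour can be evaluated against known truth.

#' Declare a categorical variable for a cohort specification
#'
#' @param name Variable name (column header in the generated table).
#' @param levels Character vector of level labels, in order; the first
#'   level is treated as the reference level downstream.
#' @param probs Marginal probabilities per level; must sum to 1.
#' @return A `cohort_variable` list.
#' @export
cohort_variable <- function(name, levels, probs) {
  stopifnot(is.character(name), length(name) == 1L, nchar(name) > 0L)
  if (length(levels) != length(probs) || length(levels) < 2L)
    stop("'levels' and 'probs' must have equal length >= 2", call. = FALSE)
  if (abs(sum(probs) - 1) > 1e-9)
    stop(sprintf("marginal probabilities of '%s' sum to %.12f, not 1",
                 name, sum(probs)), call. = FALSE)
  if (any(probs < 0)) stop("negative marginal probability", call. = FALSE)
  if (anyDuplicated(levels))
    stop(sprintf("duplicated level label in '%s'", name), call. = FALSE)
  structure(list(name = name, levels = as.character(levels),
                 probs = as.numeric(probs)),
            class = "cohort_variable")
}

#' Declare a planted association block
#'
#' A block names category levels (as `"Variable=Level"` strings) that are
#' made to co-occur.  Dependence is induced by a shared latent Bernoulli
#' per block: with probability `q * strength` (where `q` is the smallest
#' marginal probability among the members) a row is "activated" and every
#' member level is switched on; otherwise each member's variable is drawn
#' from a residual distribution chosen so that marginal level frequencies
#' are preserved exactly in expectation.  `strength = 0` gives mutual
#' independence; `strength = 1` with equal member marginals gives
#' deterministic co-occurrence.
#'
#' @param members Character vector of `"Variable=Level"` strings.
#' @param strength Association strength in `[0, 1]`.
#' @return A `planted_block` list.
#' @export
planted_block <- function(members, strength = 1) {
  stopifnot(is.character(members), length(members) >= 2L,
            is.numeric(strength), length(strength) == 1L,
            strength >= 0, strength <= 1)
  if (any(!grepl("=", members, fixed = TRUE)))
    stop("block members must be 'Variable=Level' strings", call. = FALSE)
  ## split on the first '=' only; level labels may themselves contain '='
  structure(list(variable = sub("=.*$", "", members),
                 level    = sub("^[^=]*=", "", members),
                 strength = strength),
            class = "planted_block")
}

#' Specify a synthetic categorical cohort
#'
#' @param n_patients Number of rows to generate.
#' @param variables List of [cohort_variable()] objects.
#' @param blocks List of [planted_block()] objects.
#' @param seed Integer seed stored with the specification (used by
#'   [generate_cohort()] unless overridden).
#' @return A validated `cohort_spec`.
#' @export
cohort_spec <- function(n_patients, variables, blocks = list(), seed = 1L) {
  stopifnot(is.numeric(n_patients), n_patients >= 1)
  n_patients <- as.integer(n_patients)
  if (!length(variables)) stop("at least one variable required", call. = FALSE)
  vnames <- vapply(variables, `[[`, "", "name")
  if (anyDuplicated(vnames)) stop("duplicated variable names", call. = FALSE)
  names(variables) <- vnames

  seen_in_block <- character(0)
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    lab <- paste(paste0(b$variable, "=", b$level), collapse = ", ")
    if (anyDuplicated(b$variable))
      stop(sprintf("infeasible block {%s}: two members share a variable", lab),
           call. = FALSE)
    for (j in seq_along(b$variable)) {
      v <- b$variable[j]
      if (!v %in% vnames)
        stop(sprintf("block {%s}: unknown variable '%s'", lab, v),
             call. = FALSE)
      if (!b$level[j] %in% variables[[v]]$levels)
        stop(sprintf("block {%s}: variable '%s' has no level '%s'",
                     lab, v, b$level[j]), call. = FALSE)
    }
    clash <- intersect(b$variable, seen_in_block)
    if (length(clash))
      stop(sprintf("infeasible block {%s}: variable '%s' already belongs to another block",
                   lab, clash[1L]), call. = FALSE)
    seen_in_block <- c(seen_in_block, b$variable)
  }
  structure(list(n_patients = n_patients, variables = variables,
                 blocks = blocks, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Cohort specification: %d patients, %d variables, %d planted block(s)\n",
              x$n_patients, length(x$variables), length(x$blocks)))
  invisible(x)
}

member_prob <- function(spec, variable, level) {
  v <- spec$variables[[variable]]
  v$probs[match(level, v$levels)]
}

#' Generate a synthetic categorical cohort
#'
#' Draws `n_patients` rows. Variables outside any block are sampled
#' independently from their marginals; block members follow the shared
#' latent Bernoulli mechanism of [planted_block()], which preserves all
#' marginal frequencies in expectation at every strength.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; defaults to the seed stored in `spec`.
#' @return A `data.frame` of factors (one column per variable) with the
#'   planted block activation indicators attached as attribute
#'   `"block_active"` (an n x n_blocks 0/1 matrix).
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  n <- spec$n_patients
  out <- vector("list", length(spec$variables))
  names(out) <- names(spec$variables)

  blocked_vars <- unlist(lapply(spec$blocks, `[[`, "variable"))
  block_active <- matrix(0L, n, length(spec$blocks))

  ## free variables: iid draws from marginals
  for (v in spec$variables) {
    if (v$name %in% blocked_vars) next
    out[[v$name]] <- factor(sample(v$levels, n, TRUE, prob = v$probs),
                            levels = v$levels)
  }

  ## block members: latent activation + marginal-preserving residual draw
  for (bi in seq_along(spec$blocks)) {
    b <- spec$blocks[[bi]]
    p_mem <- mapply(member_prob, b$variable, b$level,
                    MoreArgs = list(spec = spec))
    q <- min(p_mem)
    z <- stats::runif(n) < q                     # shared latent
    for (j in seq_along(b$variable)) {
      v <- spec$variables[[b$variable[j]]]
      forced <- z & (stats::runif(n) < b$strength)   # P(forced) = q * strength
      qs <- q * b$strength
      li <- match(b$level[j], v$levels)
      resid <- v$probs / (1 - qs)
      resid[li] <- (v$probs[li] - qs) / (1 - qs)
      if (resid[li] < -1e-12)
        stop(sprintf("infeasible block member %s=%s: marginal %.4f below activation rate %.4f",
                     b$variable[j], b$level[j], v$probs[li], qs), call. = FALSE)
      resid[li] <- max(resid[li], 0)
      draw <- sample(v$levels, n, TRUE, prob = resid)
      draw[forced] <- b$level[j]
      out[[v$name]] <- factor(draw, levels = v$levels)
    }
    block_active[, bi] <- as.integer(z)
  }

  df <- as.data.frame(out, stringsAsFactors = TRUE)
  rownames(df) <- sprintf("P%04d", seq_len(n))
  attr(df, "block_active") <- block_active
  df
}

## Level counts from Table-style marginal frequencies of the 1022-patient
## young lung cancer cohort (15 binary variables + 3-level CCI).
table1_counts <- function() {
  list(
    Sex            = c(Female = 502, Male = 520),
    Age            = c("20-29" = 154, "30-39" = 868),
    CCI            = c("0" = 870, "1" = 91, ">=2" = 61),
    DM             = c(No = 999,  Yes = 23),
    Hypertension   = c(No = 999,  Yes = 23),
    Asthma         = c(No = 1006, Yes = 16),
    LiverCirrhosis = c(No = 1013, Yes = 9),
    COPD           = c(No = 971,  Yes = 51),
    Autoimmune     = c(No = 1014, Yes = 8),
    Cerebral       = c(No = 1011, Yes = 11),
    HeartFailure   = c(No = 1020, Yes = 2),
    HBV            = c(No = 988,  Yes = 34),
    Renal          = c(No = 1016, Yes = 6),
    Osteoporosis   = c(No = 1006, Yes = 16),
    Depression     = c(No = 997,  Yes = 25),
    Anxiety        = c(No = 1007, Yes = 15)
  )
}

#' Cohort specification matching the published demographic table
#'
#' Sixteen categorical variables (sex, age band, 3-level Charlson
#' comorbidity index, and thirteen binary comorbidity/outcome flags) with
#' marginal probabilities equal to the printed counts of the n = 1022
#' young lung-cancer cohort.
#'
#' @param n_patients Rows to generate (default 1022, the study size).
#' @param blocks Optional planted blocks (see [planted_block()]).
#' @param seed Integer seed.
#' @return A [cohort_spec()].
#' @export
table1_spec <- function(n_patients = 1022L, blocks = list(), seed = 1L) {
  cts <- table1_counts()
  vars <- lapply(names(cts), function(nm) {
    cohort_variable(nm, names(cts[[nm]]), unname(cts[[nm]]) / 1022)
  })
  cohort_spec(n_patients, vars, blocks, seed)
}

#' Planted-block variant of the demographic-table cohort
#'
#' Plants three association blocks among category levels whose marginal
#' prevalence is at least 2%, emulating the qualitative finding that rare
#' comorbidities co-cluster with the rare psychiatric outcomes.  The
#' blocks are \{DM=Yes, Hypertension=Yes\}, \{COPD=Yes, HBV=Yes\} and
#' \{Depression=Yes, CCI=">=2"\}.
#'
#' @param n_patients Rows to generate.
#' @param strength Within-block association strength (default 0.95).
#' @param seed Integer seed.
#' @return A [cohort_spec()] carrying the three blocks.
#' @export
table1_planted_spec <- function(n_patients = 1022L, strength = 0.95,
                                seed = 1L) {
  table1_spec(n_patients,
              blocks = list(
                planted_block(c("DM=Yes", "Hypertension=Yes"), strength),
                planted_block(c("COPD=Yes", "HBV=Yes"), strength),
                planted_block(c("Depression=Yes", "CCI=>=2"), strength)),
              seed = seed)
}

#' Generate well-separated Gaussian point blobs
#'
#' Planted-cluster fixture for the k-means / cluster-count machinery:
#' `k` isotropic Gaussian blobs whose centres sit on a circle with
#' minimum pairwise separation `separation`.
#'
#' @param k Number of blobs.
#' @param n_per Points per blob.
#' @param sd Within-blob standard deviation per coordinate.
#' @param separation Minimum centre-to-centre distance.
#' @param seed Integer seed.
#' @return List with `points` (matrix, rownames are point ids) and
#'   `blob` (integer vector of true blob memberships).
#' @export
generate_blobs <- function(k, n_per = 30L, sd = 0.05, separation = 5,
                           seed = 1L) {
  stopifnot(k >= 1, n_per >= 1, sd > 0, separation > 0)
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  if (k == 1L) centers <- matrix(0, 1, 2)
  else {
    R <- separation / (2 * sin(pi / k))
    ang <- 2 * pi * (seq_len(k) - 1) / k
    centers <- cbind(R * cos(ang), R * sin(ang))
  }
  n <- k * n_per
  blob <- rep(seq_len(k), each = n_per)
  pts <- centers[blob, , drop = FALSE] +
    matrix(stats::rnorm(2 * n, sd = sd), n, 2)
  rownames(pts) <- sprintf("pt%03d", seq_len(n))
  list(points = pts, blob = blob)
}

## ---------------------------------------------------------------------
## Claims generation

new_claims <- function(patient_id = character(), visit_date = as.Date(character()),
                       icd9 = character(), setting = character()) {
  data.frame(patient_id = as.character(patient_id),
             visit_date = as.Date(visit_date),
             icd9 = as.character(icd9),
             setting = as.character(setting),
             stringsAsFactors = FALSE)
}

#' Available claims scenario presets
#' @return Character vector of preset names accepted by [generate_claims()].
#' @export
claims_presets <- function() {
  c("lung_cancer_followup", "toy_mixed", "baseline_exclusion", "empty")
}

#' Generate toy long-format claims records
#'
#' Builds small claims tables (patient id, visit date, ICD-9-CM code,
#' outpatient/inpatient setting) exercising the cohort-construction
#' rules: an index lung-cancer diagnosis inside the 2001--2007 study
#' window, baseline psychiatric exclusions inside calendar 2001, and the
#' repeated-diagnosis confirmation of the outcome conditions.  Patient
#' birthdates are attached as attribute `"birthdates"` (named `Date`
#' vector; see [claims_birthdates()]).
#'
#' Presets:
#' \describe{
#'   \item{lung_cancer_followup}{one index visit per patient; every 5th
#'     patient is a depression case (3 distinct-date post-index visits
#'     coded 311.0), every 7th an anxiety case (3 visits coded 300.00);
#'     some patients get only 2 depression-coded visits and stay
#'     non-cases.}
#'   \item{toy_mixed}{five hand-enumerable patients: two confirmed
#'     depression cases, one with only two confirmation visits, one with
#'     a baseline bipolar exclusion, one over-age.}
#'   \item{baseline_exclusion}{one patient with a 2001 bipolar visit
#'     (296.4) followed by a valid lung-cancer index visit.}
#'   \item{empty}{no records.}
#' }
#'
#' @param cohort_spec A [cohort_spec()]; its `n_patients` scales the
#'   `lung_cancer_followup` preset (other presets have fixed casts).
#' @param scenario Preset name, one of [claims_presets()].
#' @param seed Integer seed for date jitter.
#' @return Claims `data.frame` with columns
#'   `patient_id, visit_date, icd9, setting`.
#' @export
generate_claims <- function(cohort_spec, scenario = "lung_cancer_followup",
                            seed = cohort_spec$seed) {
  if (!scenario %in% claims_presets())
    stop(sprintf("unknown scenario '%s'; available: %s", scenario,
                 paste(claims_presets(), collapse = ", ")), call. = FALSE)
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  if (scenario == "empty") {
    cl <- new_claims()
    attr(cl, "birthdates") <- structure(as.Date(character()), names = character())
    return(cl)
  }

  if (scenario == "baseline_exclusion") {
    cl <- new_claims(
      patient_id = c("EX01", "EX01"),
      visit_date = as.Date(c("2001-06-15", "2003-03-10")),
      icd9 = c("296.4", "162.3"),
      setting = c("outpatient", "outpatient"))
    attr(cl, "birthdates") <- c(EX01 = as.Date("1975-01-01"))
    return(cl)
  }

  if (scenario == "toy_mixed") {
    rows <- list(
      ## A, B: index + 3 distinct-date depression confirmations
      new_claims(rep("A", 4), as.Date(c("2002-05-01", "2002-06-01",
                                        "2002-07-01", "2002-08-01")),
                 c("162.3", "300.4", "300.4", "311"), rep("outpatient", 4)),
      new_claims(rep("B", 4), as.Date(c("2003-01-10", "2003-02-10",
                                        "2003-03-10", "2003-04-10")),
                 c("162.9", "296.25", "296.30", "300.4"), rep("outpatient", 4)),
      ## C: only 2 confirmations -> not a case
      new_claims(rep("C", 3), as.Date(c("2004-02-01", "2004-03-01",
                                        "2004-04-01")),
                 c("162.2", "300.4", "300.4"), rep("outpatient", 3)),
      ## D: baseline bipolar in 2001 -> excluded
      new_claims(rep("D", 2), as.Date(c("2001-03-01", "2002-09-01")),
                 c("296.4", "162.5"), rep("outpatient", 2)),
      ## E: over-age at index -> excluded
      new_claims("E", as.Date("2002-06-01"), "162.8", "outpatient"))
    cl <- do.call(rbind, rows)
    attr(cl, "birthdates") <- c(
      A = as.Date("1972-01-01"), B = as.Date("1980-05-05"),
      C = as.Date("1978-11-30"), D = as.Date("1976-06-06"),
      E = as.Date("1955-02-02"))
    return(cl)
  }

  ## lung_cancer_followup: scaled preset
  n <- cohort_spec$n_patients
  ids <- sprintf("LC%04d", seq_len(n))
  index_dates <- as.Date("2001-01-01") +
    sample.int(as.integer(as.Date("2007-12-31") - as.Date("2001-01-01")),
               n, replace = TRUE)
  rows <- list(new_claims(ids, index_dates, "162.9", "outpatient"))
  for (i in seq_len(n)) {
    dep_case <- (i %% 5L) == 0L
    anx_case <- (i %% 7L) == 0L
    near_miss <- (i %% 5L) == 2L    # only 2 depression visits
    gaps <- cumsum(30L + sample.int(30L, 3L, replace = TRUE))
    if (dep_case)
      rows[[length(rows) + 1L]] <- new_claims(
        rep(ids[i], 3), index_dates[i] + gaps, "311.0", rep("outpatient", 3))
    if (near_miss)
      rows[[length(rows) + 1L]] <- new_claims(
        rep(ids[i], 2), index_dates[i] + gaps[1:2], "311",
        rep("outpatient", 2))
    if (anx_case)
      rows[[length(rows) + 1L]] <- new_claims(
        rep(ids[i], 3), index_dates[i] + gaps + 7L, "300.00",
        rep("outpatient", 3))
  }
  cl <- do.call(rbind, rows)
  cl <- cl[order(cl$patient_id, cl$visit_date), ]
  rownames(cl) <- NULL
  ## ages 20-39 at index
  ages <- 20L + sample.int(19L, n, replace = TRUE)
  attr(cl, "birthdates") <- stats::setNames(
    index_dates - round(ages * 365.25), ids)
  cl
}

#' Birthdates attached to a generated claims table
#' @param claims Output of [generate_claims()].
#' @return Named `Date` vector (patient id -> birthdate).
#' @export
claims_birthdates <- function(claims) attr(claims, "birthdates")

## ---------------------------------------------------------------------
## CSV interchange

#' Write / read a categorical cohort as CSV
#'
#' Header row carries variable names; cells carry level labels.
#' @param cohort Data frame of factors.
#' @param path File path.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = TRUE,
                        check.names = FALSE, colClasses = "character")
  df[] <- lapply(df, factor)
  df
}

#' Write / read a claims table as CSV
#' @param claims Claims data frame.
#' @param path File path.
#' @export
write_claims_csv <- function(claims, path) {
  out <- claims
  out$visit_date <- format(out$visit_date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_claims_csv
#' @export
read_claims_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  new_claims(df$patient_id, as.Date(df$visit_date), df$icd9, df$setting)
}
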