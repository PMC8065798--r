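## Claims-based cohort construction.
##
## Implements the study-population rules: newly diagnosed young
## lung-cancer patients (index diagnosis inside the 2001--2007 window,
## aged 20-39 at index), baseline psychiatric exclusions during calendar
## 2001, and outcome confirmation by repeated distinct-date diagnoses.

#' Compile an ICD-9-CM code set
#'
#' Patterns use claims-register conventions: a trailing `X` is a
#' wildcard character (so `"162.XX"` covers every code under 162), a
#' bare prefix matches all of its extensions, and `"A-B"` (or an en-dash)
#' denotes an inclusive range over the final digit, e.g.
#' `"296.2X-296.3X"` expands to the prefixes 296.2 and 296.3.  Matching
#' ignores the dot separator.
#'
#' @param name Code-set name (e.g. `"depression"`).
#' @param patterns Character vector of patterns; validated and expanded
#'   at construction time.
#' @return A `code_set` with the expanded prefix list.
#' @export
code_set <- function(name, patterns) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!length(patterns) || any(!nzchar(patterns)))
    stop(sprintf("code set '%s': empty pattern list or blank pattern", name),
         call. = FALSE)
  prefixes <- unlist(lapply(patterns, expand_icd9_pattern))
  structure(list(name = name, patterns = patterns,
                 prefixes = unique(prefixes)),
            class = "code_set")
}

normalize_icd9 <- function(code) toupper(gsub(".", "", code, fixed = TRUE))

## one pattern -> character vector of normalized match prefixes
expand_icd9_pattern <- function(pattern) {
  p <- gsub("–", "-", trimws(pattern))   # en-dash ranges
  expand_one <- function(tok) {
    tok <- normalize_icd9(tok)
    tok <- sub("X+$", "", tok)                # trailing wildcards -> prefix
    if (!grepl("^[VE]?[0-9]+$", tok))
      stop(sprintf("malformed ICD-9 pattern '%s'", pattern), call. = FALSE)
    tok
  }
  if (grepl("-", p, fixed = TRUE)) {
    ends <- strsplit(p, "-", fixed = TRUE)[[1L]]
    if (length(ends) != 2L)
      stop(sprintf("malformed ICD-9 range '%s'", pattern), call. = FALSE)
    lo <- expand_one(ends[1L]); hi <- expand_one(ends[2L])
    stem_lo <- substr(lo, 1L, nchar(lo) - 1L)
    stem_hi <- substr(hi, 1L, nchar(hi) - 1L)
    d_lo <- substr(lo, nchar(lo), nchar(lo))
    d_hi <- substr(hi, nchar(hi), nchar(hi))
    if (nchar(lo) != nchar(hi) || stem_lo != stem_hi ||
        !grepl("^[0-9]$", d_lo) || !grepl("^[0-9]$", d_hi) ||
        as.integer(d_lo) > as.integer(d_hi))
      stop(sprintf("malformed ICD-9 range '%s'", pattern), call. = FALSE)
    paste0(stem_lo, seq.int(as.integer(d_lo), as.integer(d_hi)))
  } else {
    expand_one(p)
  }
}

#' Match an ICD-9-CM code against a code set
#'
#' Prefix semantics are half-open: the set `{"162.XX"}` matches
#' `"162"`, `"162.3"` and `"162.31"`.
#'
#' @param code Character vector of codes (dots optional).
#' @param codeset A [code_set()].
#' @return Logical vector.
#' @export
match_code <- function(code, codeset) {
  stopifnot(inherits(codeset, "code_set"))
  if (!length(code)) return(logical(0))
  if (any(!nzchar(code))) stop("empty code", call. = FALSE)
  norm <- normalize_icd9(code)
  out <- rep(FALSE, length(norm))
  for (p in codeset$prefixes) out <- out | startsWith(norm, p)
  out
}

#' The packaged ICD-9-CM code-set registry
#'
#' Loads the study definitions shipped with the package: lung cancer
#' (162.XX), depression (296.2X--296.3X, 300.4, 311.X), anxiety
#' (300.XX, 291.89, 292.89), bipolar disorders and alcohol-induced
#' mental disorders.
#'
#' @param path Optional path to an alternative JSON registry with the
#'   same layout (`{name: {patterns: [...]}}`).
#' @return Named list of [code_set()] objects.
#' @export
default_code_sets <- function(path = system.file("extdata", "code_sets.json",
                                                 package = "mcakm")) {
  reg <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(names(reg), function(nm) code_set(nm, reg[[nm]]$patterns))
  stats::setNames(out, names(reg))
}

#' Cohort eligibility criteria
#'
#' @param age_range Inclusive age range in whole years at the index
#'   (first lung-cancer) visit.
#' @param index_window Date range in which the index visit must fall.
#' @param exclusion_window Date range scanned for baseline psychiatric
#'   exclusion codes.
#' @param min_confirmations Distinct-date diagnosis count required to
#'   code an outcome as present (default 3).
#' @param max_gap_days Maximum gap in days allowed between successive
#'   confirmation visits; `Inf` (default) imposes no gap limit, i.e. the
#'   confirmations need only total `min_confirmations`.
#' @return A `cohort_criteria` list.
#' @export
cohort_criteria <- function(age_range = c(20L, 39L),
                            index_window = as.Date(c("2001-01-01", "2007-12-31")),
                            exclusion_window = as.Date(c("2001-01-01", "2001-12-31")),
                            min_confirmations = 3L,
                            max_gap_days = Inf) {
  index_window <- as.Date(index_window)
  exclusion_window <- as.Date(exclusion_window)
  stopifnot(length(age_range) == 2L, age_range[1L] <= age_range[2L],
            length(index_window) == 2L, index_window[1L] <= index_window[2L],
            length(exclusion_window) == 2L,
            exclusion_window[1L] <= exclusion_window[2L],
            min_confirmations >= 1L, max_gap_days > 0)
  structure(list(age_range = as.integer(age_range),
                 index_window = index_window,
                 exclusion_window = exclusion_window,
                 min_confirmations = as.integer(min_confirmations),
                 max_gap_days = max_gap_days),
            class = "cohort_criteria")
}

## whole years elapsed from birth to 'at'
age_at <- function(birth, at) {
  yrs <- as.integer(format(at, "%Y")) - as.integer(format(birth, "%Y"))
  before_bday <- format(at, "%m%d") < format(birth, "%m%d")
  yrs - as.integer(before_bday)
}

## TRUE iff >= m distinct sorted dates exist with a run of m whose
## successive gaps are all <= max_gap
confirmed <- function(dates, m, max_gap) {
  d <- sort(unique(dates))
  if (length(d) < m) return(FALSE)
  if (!is.finite(max_gap)) return(TRUE)
  gaps <- diff(as.numeric(d))
  ok <- gaps <= max_gap
  if (m == 1L) return(TRUE)
  run <- rle(ok)
  any(run$values & run$lengths >= (m - 1L))
}

#' Build an analysis cohort from claims records
#'
#' Applies, per patient: index selection (first lung-cancer-coded visit
#' must fall in `criteria$index_window` with age in `criteria$age_range`),
#' baseline exclusions (any visit in `criteria$exclusion_window` matching
#' one of `exclusion_sets`), optional death/withdrawal censoring, and
#' outcome confirmation (at least `min_confirmations` matching visits on
#' distinct dates strictly after the index date).  Every input patient
#' lands either in the cohort or in the exclusion log with one reason.
#'
#' @param claims Claims data frame (`patient_id, visit_date, icd9`, and
#'   optionally `setting`); row order is irrelevant.
#' @param birthdates Named `Date` vector, patient id -> birthdate.
#' @param criteria A [cohort_criteria()].
#' @param codesets Named list of [code_set()]s; must contain `index_set`,
#'   every `exclusion_sets` entry and every `outcome_sets` entry.
#' @param index_set Name of the case-defining code set.
#' @param exclusion_sets Names of baseline exclusion code sets.
#' @param outcome_sets Named character vector: output column name ->
#'   code-set name.
#' @param covariate_sets Optional named character vector of comorbidity
#'   code sets; each yields a Yes/No column flagging at least one
#'   matching visit at any time.
#' @param censor_dates Optional named `Date` vector of death/withdrawal
#'   dates; a censor date inside the index window excludes the patient.
#' @return List with `cohort` (data frame of factors, rownames = patient
#'   ids) and `log` (data frame `patient_id, reason`).
#' @export
build_cohort <- function(claims, birthdates, criteria = cohort_criteria(),
                         codesets = default_code_sets(),
                         index_set = "lung_cancer",
                         exclusion_sets = c("depression", "anxiety",
                                            "bipolar", "alcohol_induced"),
                         outcome_sets = c(Depression = "depression",
                                          Anxiety = "anxiety"),
                         covariate_sets = NULL,
                         censor_dates = NULL) {
  stopifnot(inherits(criteria, "cohort_criteria"))
  needed <- c(index_set, exclusion_sets, outcome_sets, covariate_sets)
  missing_sets <- setdiff(needed, names(codesets))
  if (length(missing_sets))
    stop("code sets not in registry: ", paste(missing_sets, collapse = ", "),
         call. = FALSE)

  empty_log <- data.frame(patient_id = character(), reason = character(),
                          stringsAsFactors = FALSE)
  outcome_cols <- names(outcome_sets)
  empty_cohort <- as.data.frame(
    stats::setNames(rep(list(factor(character(), levels = c("No", "Yes"))),
                        length(outcome_cols) + length(covariate_sets)),
                    c(outcome_cols, names(covariate_sets))))
  if (!nrow(claims)) return(list(cohort = empty_cohort, log = empty_log))

  claims <- claims[order(claims$patient_id, claims$visit_date), , drop = FALSE]
  by_pat <- split(claims, claims$patient_id)

  keep <- character(0)
  rows <- list()
  log_id <- character(0); log_reason <- character(0)
  drop <- function(id, reason) {
    log_id <<- c(log_id, id); log_reason <<- c(log_reason, reason)
  }

  for (id in names(by_pat)) {
    cl <- by_pat[[id]]
    if (!id %in% names(birthdates)) { drop(id, "missing_birthdate"); next }

    is_index_code <- match_code(cl$icd9, codesets[[index_set]])
    if (!any(is_index_code)) { drop(id, "no_index_diagnosis"); next }
    index_date <- min(cl$visit_date[is_index_code])
    if (index_date < criteria$index_window[1L] ||
        index_date > criteria$index_window[2L]) {
      drop(id, "index_outside_window"); next
    }
    age <- age_at(birthdates[[id]], index_date)
    if (age < criteria$age_range[1L] || age > criteria$age_range[2L]) {
      drop(id, "age_out_of_range"); next
    }

    baseline <- cl$visit_date >= criteria$exclusion_window[1L] &
                cl$visit_date <= criteria$exclusion_window[2L]
    excluded <- FALSE
    for (es in exclusion_sets) {
      if (any(baseline & match_code(cl$icd9, codesets[[es]]))) {
        drop(id, paste0("baseline_", es)); excluded <- TRUE; break
      }
    }
    if (excluded) next

    if (!is.null(censor_dates) && id %in% names(censor_dates) &&
        !is.na(censor_dates[[id]]) &&
        censor_dates[[id]] <= criteria$index_window[2L]) {
      drop(id, "died_or_withdrew"); next
    }

    vals <- character(0)
    for (oc in outcome_cols) {
      hits <- match_code(cl$icd9, codesets[[outcome_sets[[oc]]]]) &
        cl$visit_date > index_date
      vals <- c(vals, if (confirmed(cl$visit_date[hits],
                                    criteria$min_confirmations,
                                    criteria$max_gap_days)) "Yes" else "No")
    }
    for (cv in names(covariate_sets)) {
      vals <- c(vals,
                if (any(match_code(cl$icd9, codesets[[covariate_sets[[cv]]]])))
                  "Yes" else "No")
    }
    keep <- c(keep, id)
    rows[[id]] <- vals
  }

  cohort <- if (length(keep)) {
    m <- do.call(rbind, rows)
    df <- as.data.frame(m, stringsAsFactors = FALSE)
    names(df) <- c(outcome_cols, names(covariate_sets))
    df[] <- lapply(df, factor, levels = c("No", "Yes"))
    rownames(df) <- keep
    df
  } else empty_cohort

  list(cohort = cohort,
       log = data.frame(patient_id = log_id, reason = log_reason,
                        stringsAsFactors = FALSE))
}
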