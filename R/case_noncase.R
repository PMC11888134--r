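# Case/non-case classification and contingency-table assembly.

#' Classify reports as cases
#'
#' A report is a case iff at least one of its reaction terms canonically
#' equals a term of the vocabulary's event (SMQ-style) term set.
#' Classification is at report level: multiple matching terms still count
#' the report once.
#'
#' @param db an [icsr_db()].
#' @param vocabulary a [vocabulary()] with non-empty `smq_terms`.
#' @return named logical vector over `db$reports$report_id`.
#' @export
classify_case <- function(db, vocabulary) {
  stopifnot(inherits(db, "icsr_db"), inherits(vocabulary, "pv_vocabulary"))
  if (!length(vocabulary$smq_terms))
    stop("validation error: smq_terms must be non-empty")
  hit <- canonical_term(db$reactions$term) %in% vocabulary$smq_terms
  ids <- db$reports$report_id
  setNames(ids %in% unique(db$reactions$report_id[hit]), ids)
}

#' Classify reports as exposed to a drug-code set
#'
#' A report is exposed iff it carries at least one drug entry whose ATC code
#' prefix-matches `drug_codes` and whose role is admitted by `role_policy`
#' (`any_role`: suspect, concomitant or interacting; `suspect_only`: suspect
#' entries only).
#'
#' @param db an [icsr_db()].
#' @param drug_codes character vector of ATC codes/prefixes.
#' @param role_policy `"any_role"` or `"suspect_only"`.
#' @return named logical vector over `db$reports$report_id`.
#' @export
classify_exposure <- function(db, drug_codes,
                              role_policy = c("any_role", "suspect_only")) {
  stopifnot(inherits(db, "icsr_db"))
  role_policy <- match.arg(role_policy)
  ok <- atc_match(db$drugs$drug_code, drug_codes)
  if (role_policy == "suspect_only") ok <- ok & db$drugs$role == "suspect"
  ids <- db$reports$report_id
  setNames(ids %in% unique(db$drugs$report_id[ok]), ids)
}

# highest recorded daily dose among a report's matching entries, per report
# id (max is order-invariant under entry shuffling); reports without a dosed
# matching entry get NA
dose_by_report <- function(db, drug_codes, role_policy) {
  ok <- atc_match(db$drugs$drug_code, drug_codes)
  if (role_policy == "suspect_only") ok <- ok & db$drugs$role == "suspect"
  ok <- ok & !is.na(db$drugs$daily_dose_mg)
  d <- db$drugs[ok, c("report_id", "daily_dose_mg")]
  if (!nrow(d)) return(setNames(numeric(0), character(0)))
  v <- tapply(d$daily_dose_mg, d$report_id, max)
  setNames(as.numeric(v), names(v))
}

#' Build the case/non-case analytic dataset
#'
#' Restricts to reports with known (adult) age band, classifies case status
#' against the vocabulary's event term set and exposure per target drug under
#' the chosen role policy, and computes covariate flags: concurrent
#' antihypertensive (C02-style codes), concurrent known
#' hypertension-inducing drug, and membership in the comparator population
#' (N06A-style codes). Covariate flags are computed from entries whose code
#' does not match any target drug, so a target is never counted in its own
#' adjustment covariate. With `population_filter = "antidepressant_only"`,
#' only reports in the comparator population are retained.
#'
#' @param db an [icsr_db()].
#' @param vocabulary a [vocabulary()].
#' @param role_policy exposure role policy, `"any_role"` (default) or
#'   `"suspect_only"`.
#' @param population_filter `"whole_database"` (default) or
#'   `"antidepressant_only"`.
#' @return data frame of class `analytic_records`: one row per retained
#'   report with `report_id`, `is_case`, `age_group`, `sex`,
#'   `has_antihypertensive`, `has_hypertensive_inducer`, `in_comparator`,
#'   one `exposed_<drug>` logical and one `dose_<drug>` numeric column per
#'   target drug, and `exposed_any` (class-level exposure). The target drug
#'   labels are attached as attribute `"drugs"`.
#' @export
build_analytic_dataset <- function(db, vocabulary,
                                   role_policy = c("any_role", "suspect_only"),
                                   population_filter = c("whole_database",
                                                         "antidepressant_only")) {
  stopifnot(inherits(db, "icsr_db"), inherits(vocabulary, "pv_vocabulary"))
  role_policy <- match.arg(role_policy)
  population_filter <- match.arg(population_filter)

  keep <- db$reports$age_group != "unknown"
  rec <- data.frame(report_id = db$reports$report_id[keep],
                    age_group = db$reports$age_group[keep],
                    sex = db$reports$sex[keep],
                    stringsAsFactors = FALSE)
  rec$is_case <- unname(classify_case(db, vocabulary)[keep])

  target_union <- unique(unlist(vocabulary$target_drugs))
  non_target <- !atc_match(db$drugs$drug_code, target_union)
  flag_from_codes <- function(code_set) {
    if (!length(code_set)) return(rep(FALSE, nrow(rec)))
    hit <- atc_match(db$drugs$drug_code, code_set) & non_target
    rec$report_id %in% unique(db$drugs$report_id[hit])
  }
  rec$has_antihypertensive <- flag_from_codes(vocabulary$antihypertensive_codes)
  rec$has_hypertensive_inducer <- flag_from_codes(vocabulary$hypertensive_inducer_codes)
  comp <- vocabulary$comparator_population_codes
  rec$in_comparator <- if (length(comp)) {
    hit <- atc_match(db$drugs$drug_code, comp)
    rec$report_id %in% unique(db$drugs$report_id[hit])
  } else rep(FALSE, nrow(rec))

  labels <- names(vocabulary$target_drugs)
  any_exp <- rep(FALSE, nrow(rec))
  for (lab in labels) {
    exp_l <- unname(classify_exposure(db, vocabulary$target_drugs[[lab]],
                                      role_policy)[keep])
    rec[[paste0("exposed_", lab)]] <- exp_l
    doses <- dose_by_report(db, vocabulary$target_drugs[[lab]], role_policy)
    rec[[paste0("dose_", lab)]] <- unname(doses[rec$report_id])
    rec[[paste0("dose_", lab)]][!exp_l] <- NA_real_
    any_exp <- any_exp | exp_l
  }
  rec$exposed_any <- any_exp

  if (population_filter == "antidepressant_only") {
    if (!length(comp))
      stop("validation error: comparator_population_codes is empty but ",
           "population_filter = 'antidepressant_only' was requested")
    rec <- rec[rec$in_comparator, , drop = FALSE]
    rownames(rec) <- NULL
  }
  if (!nrow(rec))
    warning("analytic dataset is empty under the requested filter")
  structure(rec, class = c("analytic_records", "data.frame"),
            drugs = labels, role_policy = role_policy,
            population_filter = population_filter)
}

exposure_column <- function(records, drug) {
  col <- if (identical(drug, "class")) "exposed_any" else paste0("exposed_", drug)
  if (!col %in% names(records))
    stop("drug '", drug, "' not present in the analytic dataset")
  records[[col]]
}

#' Case/non-case contingency table for one drug
#'
#' Cross-classifies the analytic records by case status and exposure to
#' `drug`: `a` exposed cases, `b` exposed non-cases, `c` unexposed cases,
#' `d` unexposed non-cases. `drug = "class"` pools exposure to any target
#' drug (a co-exposed report counts once).
#'
#' @param records an `analytic_records` data frame.
#' @param drug target drug label, or `"class"`.
#' @return list of class `contingency_table` with fields `a`, `b`, `c`, `d`.
#' @export
contingency <- function(records, drug) {
  exp <- exposure_column(records, drug)
  case <- records$is_case
  structure(list(a = sum(exp & case), b = sum(exp & !case),
                 c = sum(!exp & case), d = sum(!exp & !case)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("2x2 case/non-case table: a=", x$a, " b=", x$b, " c=", x$c,
      " d=", x$d, "\n", sep = "")
  invisible(x)
}
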