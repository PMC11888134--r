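# Cohort characterization, time to onset, and dechallenge/rechallenge counts.

#' Extract the case cohort of a database
#'
#' One row per adult case report (known age band, at least one event-matching
#' reaction term) with demographics, seriousness, the `;`-joined seriousness
#' criteria, and flags for concomitant stroke / myocardial infarction
#' reactions and antihypertensive / hypertension-inducing co-medication.
#'
#' @param db an [icsr_db()].
#' @param vocabulary a [vocabulary()].
#' @return data frame of cases, attribute `"n_reports"` carrying the adult
#'   database size (the prevalence denominator).
#' @export
case_cohort <- function(db, vocabulary) {
  stopifnot(inherits(db, "icsr_db"), inherits(vocabulary, "pv_vocabulary"))
  adult <- db$reports$age_group != "unknown"
  is_case <- classify_case(db, vocabulary) & adult
  cases <- db$reports[is_case, , drop = FALSE]
  term_flag <- function(terms) {
    hit <- canonical_term(db$reactions$term) %in% terms
    cases$report_id %in% unique(db$reactions$report_id[hit])
  }
  cases$stroke <- term_flag(vocabulary$stroke_terms)
  cases$mi <- term_flag(vocabulary$mi_terms)
  target_union <- unique(unlist(vocabulary$target_drugs))
  non_target <- !atc_match(db$drugs$drug_code, target_union)
  code_flag <- function(code_set) {
    if (!length(code_set)) return(rep(FALSE, nrow(cases)))
    hit <- atc_match(db$drugs$drug_code, code_set) & non_target
    cases$report_id %in% unique(db$drugs$report_id[hit])
  }
  cases$antihypertensive <- code_flag(vocabulary$antihypertensive_codes)
  cases$inducer <- code_flag(vocabulary$hypertensive_inducer_codes)
  rownames(cases) <- NULL
  structure(cases, n_reports = sum(adult))
}

has_criterion <- function(criteria, token) {
  vapply(strsplit(criteria, ";", fixed = TRUE),
         function(x) token %in% trimws(x), logical(1))
}

#' Summarize the case cohort
#'
#' Counts and percentages characterizing the cases: sex, age bands,
#' seriousness (denominator: reports with known seriousness), seriousness
#' criteria (denominator: serious reports; criteria can co-occur, and serious
#' reports without a recorded criterion are counted as `criteria_missing`),
#' and concomitant stroke / myocardial infarction / antihypertensive /
#' hypertension-inducing-drug flags (denominator: all cases). The `n_cases`
#' row's percentage is the case prevalence in the database. Percentages are
#' `100 * count / denominator` rounded half-up to 1 decimal in rendered
#' output; this summary keeps full precision.
#'
#' @param cases a [case_cohort()] data frame (non-empty).
#' @param n_reports total number of (adult) reports, the prevalence
#'   denominator; defaults to the cohort's `n_reports` attribute.
#' @return data frame of class `cohort_summary` with columns `field`,
#'   `count`, `denominator`, `percent`.
#' @export
summarize_cohort <- function(cases, n_reports = attr(cases, "n_reports")) {
  cases <- as.data.frame(cases)
  if (!nrow(cases)) stop("case cohort is empty")
  if (is.null(n_reports)) stop("n_reports denominator is required")
  n <- nrow(cases)
  serious_known <- sum(cases$serious != "unknown")
  n_serious <- sum(cases$serious == "yes")
  crit <- cases$seriousness_criteria[cases$serious == "yes"]
  rows <- list(c("n_cases", n, n_reports))
  rows <- c(rows, list(c("female", sum(cases$sex == "female"), n)))
  for (band in AGE_BANDS)
    rows <- c(rows, list(c(paste0("age_", band),
                           sum(cases$age_group == band), n)))
  rows <- c(rows, list(c("serious", n_serious, serious_known)))
  for (tok in CRITERIA_LEVELS)
    rows <- c(rows, list(c(paste0("criteria_", tok),
                           sum(has_criterion(crit, tok)), n_serious)))
  rows <- c(rows, list(
    c("criteria_missing", sum(trimws(crit) == ""), n_serious),
    c("stroke", sum(cases$stroke), n),
    c("mi", sum(cases$mi), n),
    c("cvd", sum(cases$stroke | cases$mi), n),
    c("antihypertensive", sum(cases$antihypertensive), n),
    c("inducer", sum(cases$inducer), n)))
  out <- data.frame(field = vapply(rows, `[`, character(1), 1),
                    count = as.numeric(vapply(rows, `[`, character(1), 2)),
                    denominator = as.numeric(vapply(rows, `[`, character(1), 3)),
                    stringsAsFactors = FALSE)
  out$percent <- 100 * out$count / out$denominator
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' Time to onset of the event after drug start
#'
#' Per case report exposed to the drug, TTO = earliest event-matching
#' reaction onset date minus the drug's earliest start date, in whole days,
#' computed only when both dates are present and the difference is
#' non-negative (negative differences indicate data errors and are excluded,
#' not clamped). Median and quartiles use the midpoint-interpolation
#' convention (`quantile` type 2). With no informative report all summaries
#' are `NA`.
#'
#' @param db an [icsr_db()].
#' @param vocabulary a [vocabulary()].
#' @param drug target drug label (a name of `vocabulary$target_drugs`).
#' @return list of class `tto_summary`: `drug`, `n_available`,
#'   `median_days`, `iqr_low_days`, `iqr_high_days`.
#' @export
time_to_onset <- function(db, vocabulary, drug) {
  codes <- vocabulary$target_drugs[[drug]]
  if (is.null(codes)) stop("drug '", drug, "' not in vocabulary")
  adult <- db$reports$age_group != "unknown"
  case_ids <- db$reports$report_id[classify_case(db, vocabulary) & adult]

  rx <- db$reactions
  rx <- rx[rx$report_id %in% case_ids &
             canonical_term(rx$term) %in% vocabulary$smq_terms &
             !is.na(rx$onset_date), , drop = FALSE]
  onset <- tapply(as.numeric(rx$onset_date), rx$report_id, min)

  de <- db$drugs
  de <- de[de$report_id %in% case_ids & atc_match(de$drug_code, codes) &
             !is.na(de$start_date), , drop = FALSE]
  start <- tapply(as.numeric(de$start_date), de$report_id, min)

  shared <- intersect(names(onset), names(start))
  tto <- onset[shared] - start[shared]
  tto <- tto[tto >= 0]
  if (!length(tto)) {
    return(structure(list(drug = drug, n_available = 0L,
                          median_days = NA_real_, iqr_low_days = NA_real_,
                          iqr_high_days = NA_real_), class = "tto_summary"))
  }
  q <- unname(quantile(tto, c(0.25, 0.5, 0.75), type = 2))
  structure(list(drug = drug, n_available = length(tto),
                 median_days = q[2], iqr_low_days = q[1],
                 iqr_high_days = q[3]), class = "tto_summary")
}

#' Positive dechallenge and rechallenge counts
#'
#' Among adult case reports exposed to the drug, counts of reports carrying
#' at least one matching drug entry with a positive dechallenge and,
#' separately, a positive rechallenge (a report counts once per field).
#'
#' @param db an [icsr_db()].
#' @param vocabulary a [vocabulary()].
#' @param drug target drug label.
#' @return list with `drug`, `n_positive_dechallenge`,
#'   `n_positive_rechallenge`.
#' @export
challenge_counts <- function(db, vocabulary, drug) {
  codes <- vocabulary$target_drugs[[drug]]
  if (is.null(codes)) stop("drug '", drug, "' not in vocabulary")
  adult <- db$reports$age_group != "unknown"
  case_ids <- db$reports$report_id[classify_case(db, vocabulary) & adult]
  de <- db$drugs
  de <- de[de$report_id %in% case_ids & atc_match(de$drug_code, codes), ,
           drop = FALSE]
  list(drug = drug,
       n_positive_dechallenge =
         length(unique(de$report_id[de$dechallenge == "positive"])),
       n_positive_rechallenge =
         length(unique(de$report_id[de$rechallenge == "positive"])))
}

#' Time-to-onset table over all target drugs
#'
#' @param db an [icsr_db()].
#' @param vocabulary a [vocabulary()].
#' @return data frame in the `tto_table` schema (drugs alphabetical).
#' @export
tto_table <- function(db, vocabulary) {
  drugs <- sort(names(vocabulary$target_drugs))
  rows <- lapply(drugs, function(d) as.data.frame(unclass(
    time_to_onset(db, vocabulary, d)), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Dechallenge/rechallenge table over all target drugs
#'
#' @param db an [icsr_db()].
#' @param vocabulary a [vocabulary()].
#' @return data frame in the `challenge_table` schema (drugs alphabetical).
#' @export
challenge_table <- function(db, vocabulary) {
  drugs <- sort(names(vocabulary$target_drugs))
  rows <- lapply(drugs, function(d) as.data.frame(
    challenge_counts(db, vocabulary, d), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
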