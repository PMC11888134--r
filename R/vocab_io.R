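# Relational ICSR database container, vocabulary loader, and table writers.

REPORT_COLS <- c("report_id", "age_group", "sex", "serious", "seriousness_criteria")
DRUG_COLS <- c("report_id", "drug_code", "role", "daily_dose_mg",
               "start_date", "stop_date", "dechallenge", "rechallenge")
REACTION_COLS <- c("report_id", "term", "onset_date")

#' Construct an ICSR database
#'
#' An `icsr_db` bundles the three relational tables of a spontaneous-report
#' database: one row per report (demographics, seriousness), one row per drug
#' entry on a report (ATC code, role, daily dose, dates,
#' dechallenge/rechallenge outcome), and one row per reported reaction
#' (term, onset date). `report_id` keys the drugs and reactions tables to the
#' reports table.
#'
#' @param reports data frame with columns `report_id`, `age_group`
#'   (`18-44`/`45-64`/`65-74`/`75plus`/`unknown`), `sex`
#'   (`female`/`male`/`unknown`), `serious` (`yes`/`no`/`unknown`),
#'   `seriousness_criteria` (`;`-joined tokens among
#'   `hospitalization`, `congenital_anomaly`, `death`, `disabling`,
#'   `life_threatening`, `other`; empty when none recorded).
#' @param drugs data frame with columns `report_id`, `drug_code` (ATC),
#'   `role` (`suspect`/`concomitant`/`interacting`), `daily_dose_mg`
#'   (non-negative or `NA`), `start_date`, `stop_date` (ISO dates or `NA`),
#'   `dechallenge` (`positive`/`negative`/`unknown`), `rechallenge`
#'   (`positive`/`negative`/`not_done`/`unknown`).
#' @param reactions data frame with columns `report_id`, `term` (non-empty
#'   reaction term), `onset_date` (ISO date or `NA`).
#' @param validate check invariants (unique report ids, referential
#'   integrity, non-negative doses, `stop_date >= start_date`).
#' @return object of class `icsr_db` (a list of the three data frames).
#' @export
icsr_db <- function(reports, drugs, reactions, validate = TRUE) {
  reports <- as.data.frame(reports, stringsAsFactors = FALSE)
  drugs <- as.data.frame(drugs, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)

  check_cols(reports, REPORT_COLS, "reports")
  check_cols(drugs, DRUG_COLS, "drugs")
  check_cols(reactions, REACTION_COLS, "reactions")

  reports$report_id <- as.character(reports$report_id)
  drugs$report_id <- as.character(drugs$report_id)
  reactions$report_id <- as.character(reactions$report_id)
  reports$age_group <- coerce_enum(reports$age_group, AGE_LEVELS)
  reports$sex <- coerce_enum(reports$sex, SEX_LEVELS)
  reports$serious <- coerce_enum(reports$serious, SERIOUS_LEVELS)
  crit <- as.character(reports$seriousness_criteria)
  crit[is.na(crit)] <- ""
  reports$seriousness_criteria <- crit
  drugs$drug_code <- trimws(as.character(drugs$drug_code))
  drugs$role <- coerce_enum(drugs$role, ROLE_LEVELS, fallback = "concomitant")
  drugs$daily_dose_mg <- suppressWarnings(as.numeric(drugs$daily_dose_mg))
  drugs$start_date <- as_iso_date(drugs$start_date)
  drugs$stop_date <- as_iso_date(drugs$stop_date)
  drugs$dechallenge <- coerce_enum(drugs$dechallenge, DECHALLENGE_LEVELS)
  drugs$rechallenge <- coerce_enum(drugs$rechallenge, RECHALLENGE_LEVELS)
  reactions$term <- as.character(reactions$term)
  reactions$onset_date <- as_iso_date(reactions$onset_date)

  if (validate) {
    if (anyDuplicated(reports$report_id))
      stop("integrity error: duplicate report_id in reports table: ",
           paste(head(unique(reports$report_id[duplicated(reports$report_id)]), 3),
                 collapse = ", "))
    bad_d <- !(drugs$report_id %in% reports$report_id)
    if (any(bad_d))
      stop("integrity error: drugs rows reference absent report_id: ",
           paste(head(unique(drugs$report_id[bad_d]), 3), collapse = ", "))
    bad_r <- !(reactions$report_id %in% reports$report_id)
    if (any(bad_r))
      stop("integrity error: reactions rows reference absent report_id: ",
           paste(head(unique(reactions$report_id[bad_r]), 3), collapse = ", "))
    if (any(!is.na(drugs$daily_dose_mg) & drugs$daily_dose_mg < 0))
      stop("domain error: daily_dose_mg must be non-negative")
    both <- !is.na(drugs$start_date) & !is.na(drugs$stop_date)
    if (any(both & drugs$stop_date < drugs$start_date))
      stop("domain error: stop_date earlier than start_date")
    if (any(is.na(reactions$term) | trimws(reactions$term) == ""))
      stop("domain error: reaction term must be non-empty")
  }
  structure(list(reports = reports[REPORT_COLS],
                 drugs = drugs[DRUG_COLS],
                 reactions = reactions[REACTION_COLS]),
            class = "icsr_db")
}

check_cols <- function(df, cols, table) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("schema error: table '", table, "' is missing column(s): ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' @export
print.icsr_db <- function(x, ...) {
  cat("<icsr_db> ", nrow(x$reports), " reports, ", nrow(x$drugs),
      " drug entries, ", nrow(x$reactions), " reactions\n", sep = "")
  invisible(x)
}

# bin a raw age (years) into the adult analysis bands
bin_age <- function(age_years) {
  age <- suppressWarnings(as.numeric(age_years))
  out <- rep("unknown", length(age))
  out[!is.na(age) & age >= 18 & age < 45] <- "18-44"
  out[!is.na(age) & age >= 45 & age < 65] <- "45-64"
  out[!is.na(age) & age >= 65 & age < 75] <- "65-74"
  out[!is.na(age) & age >= 75] <- "75plus"
  out
}

#' Read an ICSR database from three CSV files
#'
#' Reads the relational reports/drugs/reactions layout and returns a joined,
#' validated [icsr_db()]. Unknown enum values are mapped to `unknown`
#' (invalid drug roles to `concomitant`). The reports file may carry either a
#' pre-binned `age_group` column or a raw `age_years` column, which is binned
#' at load time with boundaries 18/45/65/75 (values below 18 or missing map
#' to `unknown`).
#'
#' @param reports_path,drugs_path,reactions_path paths to the three CSV files.
#' @return an `icsr_db`.
#' @export
read_icsr_db <- function(reports_path, drugs_path, reactions_path) {
  reports <- read.csv(reports_path, stringsAsFactors = FALSE,
                      colClasses = "character")
  drugs <- read.csv(drugs_path, stringsAsFactors = FALSE,
                    colClasses = "character")
  reactions <- read.csv(reactions_path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!("age_group" %in% names(reports)) && "age_years" %in% names(reports)) {
    reports$age_group <- bin_age(reports$age_years)
    reports$age_years <- NULL
  }
  icsr_db(reports, drugs, reactions)
}

#' Write an ICSR database to a directory
#'
#' Writes `reports.csv`, `drugs.csv` and `reactions.csv` in the layout read by
#' [read_icsr_db()]; dates are written ISO-8601 and missing values as empty
#' fields, so `read_icsr_db(write_icsr_db(db))` is the identity.
#'
#' @param db an `icsr_db`.
#' @param dir output directory (created if absent).
#' @return named character vector of the three file paths, invisibly.
#' @export
write_icsr_db <- function(db, dir) {
  stopifnot(inherits(db, "icsr_db"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(reports = file.path(dir, "reports.csv"),
             drugs = file.path(dir, "drugs.csv"),
             reactions = file.path(dir, "reactions.csv"))
  dr <- db$drugs
  dr$start_date <- as.character(dr$start_date)
  dr$stop_date <- as.character(dr$stop_date)
  re <- db$reactions
  re$onset_date <- as.character(re$onset_date)
  write.csv(db$reports, paths["reports"], row.names = FALSE, na = "")
  write.csv(dr, paths["drugs"], row.names = FALSE, na = "")
  write.csv(re, paths["reactions"], row.names = FALSE, na = "")
  invisible(paths)
}

#' Construct a controlled vocabulary
#'
#' A vocabulary carries the flat term list defining the event of interest
#' (an SMQ-style set of preferred terms), the target drugs (label -> set of
#' ATC codes), and the ATC code sets used as covariates and population
#' filters. Code sets are matched by ATC prefix, so `"C02"` covers the whole
#' antihypertensive class. Terms are canonicalized (trim + case-fold) and
#' de-duplicated.
#'
#' @param smq_terms character vector of event-defining reaction terms
#'   (non-empty).
#' @param target_drugs named list: drug label -> character vector of ATC
#'   codes.
#' @param antihypertensive_codes ATC codes/prefixes for the antihypertensive
#'   covariate (typically `"C02"`).
#' @param hypertensive_inducer_codes ATC codes/prefixes for drugs known to
#'   induce hypertension (editable list; no licensed content shipped).
#' @param comparator_population_codes ATC codes/prefixes defining the
#'   comparator population for the sensitivity analysis (typically `"N06A"`).
#' @param stroke_terms,mi_terms reaction-term sets used by the cohort
#'   descriptives to flag concomitant stroke / myocardial infarction.
#' @return object of class `pv_vocabulary`.
#' @export
vocabulary <- function(smq_terms,
                       target_drugs = list(),
                       antihypertensive_codes = character(),
                       hypertensive_inducer_codes = character(),
                       comparator_population_codes = character(),
                       stroke_terms = c("Cerebrovascular accident",
                                        "Ischaemic stroke",
                                        "Haemorrhagic stroke"),
                       mi_terms = c("Myocardial infarction",
                                    "Acute myocardial infarction")) {
  smq_terms <- unique(canonical_term(as.character(smq_terms)))
  smq_terms <- smq_terms[smq_terms != ""]
  if (!length(smq_terms))
    stop("validation error: smq_terms must be non-empty")
  if (length(target_drugs)) {
    if (is.null(names(target_drugs)) || any(names(target_drugs) == ""))
      stop("validation error: target_drugs must be a named list")
    target_drugs <- lapply(target_drugs, function(x) unique(trimws(as.character(x))))
  }
  structure(list(
    smq_terms = smq_terms,
    target_drugs = target_drugs,
    antihypertensive_codes = unique(trimws(as.character(antihypertensive_codes))),
    hypertensive_inducer_codes = unique(trimws(as.character(hypertensive_inducer_codes))),
    comparator_population_codes = unique(trimws(as.character(comparator_population_codes))),
    stroke_terms = unique(canonical_term(as.character(stroke_terms))),
    mi_terms = unique(canonical_term(as.character(mi_terms)))
  ), class = "pv_vocabulary")
}

#' @export
print.pv_vocabulary <- function(x, ...) {
  cat("<pv_vocabulary> ", length(x$smq_terms), " event terms, ",
      length(x$target_drugs), " target drugs\n", sep = "")
  invisible(x)
}

#' Load a vocabulary from a YAML file
#'
#' The file carries the sections `smq_terms`, `target_drugs` (map of drug
#' label to ATC code list), `antihypertensive_codes`,
#' `hypertensive_inducer_codes` and `comparator_population_codes`, plus
#' optional `stroke_terms` / `mi_terms`. An empty or missing `smq_terms`
#' section is an error; other missing code sections load as empty sets with
#' a warning (the corresponding analysis then cannot be requested).
#'
#' @param path path to the YAML vocabulary file.
#' @return a `pv_vocabulary`.
#' @export
load_vocabulary <- function(path) {
  v <- yaml::read_yaml(path)
  if (is.null(v$smq_terms) || !length(v$smq_terms))
    stop("validation error: vocabulary file has an empty smq_terms section")
  for (sec in c("antihypertensive_codes", "hypertensive_inducer_codes",
                "comparator_population_codes")) {
    if (is.null(v[[sec]])) {
      warning("vocabulary section '", sec, "' missing; loaded as an empty set")
      v[[sec]] <- character()
    }
  }
  args <- list(smq_terms = unlist(v$smq_terms),
               target_drugs = lapply(v$target_drugs %||% list(), unlist),
               antihypertensive_codes = unlist(v$antihypertensive_codes),
               hypertensive_inducer_codes = unlist(v$hypertensive_inducer_codes),
               comparator_population_codes = unlist(v$comparator_population_codes))
  if (!is.null(v$stroke_terms)) args$stroke_terms <- unlist(v$stroke_terms)
  if (!is.null(v$mi_terms)) args$mi_terms <- unlist(v$mi_terms)
  do.call(vocabulary, args)
}

# output table schemas: stable column order + rendering rules.
# ROR-like columns render with 2 decimals, percentages and doses/days with 1;
# a machine-readable companion (<stem>.full.csv) retains full precision.
.schemas <- list(
  signal_table = list(
    cols = c("drug", "a", "b", "ror", "ci_low", "ci_high",
             "aror", "aci_low", "aci_high", "signal"),
    round2 = c("ror", "ci_low", "ci_high", "aror", "aci_low", "aci_high")),
  dose_table = list(
    cols = c("drug", "median_dose_mg",
             "low_a", "low_b", "low_ror", "low_ci_low", "low_ci_high",
             "low_aror", "low_aci_low", "low_aci_high",
             "high_a", "high_b", "high_ror", "high_ci_low", "high_ci_high",
             "high_aror", "high_aci_low", "high_aci_high",
             "trend_p", "evaluated"),
    round2 = c("low_ror", "low_ci_low", "low_ci_high", "low_aror",
               "low_aci_low", "low_aci_high", "high_ror", "high_ci_low",
               "high_ci_high", "high_aror", "high_aci_low", "high_aci_high",
               "trend_p"),
    round1 = "median_dose_mg"),
  tto_table = list(
    cols = c("drug", "n_available", "median_days", "iqr_low_days",
             "iqr_high_days"),
    round1 = c("median_days", "iqr_low_days", "iqr_high_days")),
  challenge_table = list(
    cols = c("drug", "n_positive_dechallenge", "n_positive_rechallenge")),
  cohort_summary = list(
    cols = c("field", "count", "denominator", "percent"),
    round1 = "percent")
)

#' Write an analysis output table
#'
#' Writes `rows` as a CSV with the stable column order of the named schema.
#' In the rendered file, odds-ratio columns are rounded to 2 decimals and
#' percentage/dose/day columns to 1 (half-up); undefined values render as
#' `"NA"`. Full precision is retained in a machine-readable companion file
#' `<stem>.full.csv`.
#'
#' @param rows data frame conforming to the schema (zero rows allowed).
#' @param path output CSV path.
#' @param schema_name one of `"signal_table"`, `"dose_table"`, `"tto_table"`,
#'   `"challenge_table"`, `"cohort_summary"`.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(rows, path, schema_name) {
  sch <- .schemas[[schema_name]]
  if (is.null(sch))
    stop("unknown schema_name: ", schema_name)
  if (is.null(rows) || !nrow(as.data.frame(rows))) {
    rows <- as.data.frame(setNames(rep(list(logical(0)), length(sch$cols)),
                                   sch$cols))
  }
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  check_cols(rows, sch$cols, schema_name)
  rows <- rows[sch$cols]
  write.csv(rows, sub("\\.csv$", ".full.csv", path), row.names = FALSE, na = "NA")
  rendered <- rows
  fmt <- function(x, digits) {
    out <- ifelse(is.na(x), "NA",
                  formatC(round_half_up(x, digits), format = "f", digits = digits))
    out
  }
  for (col in sch$round2 %||% character()) rendered[[col]] <- fmt(rows[[col]], 2)
  for (col in sch$round1 %||% character()) rendered[[col]] <- fmt(rows[[col]], 1)
  write.csv(rendered, path, row.names = FALSE, na = "NA")
  invisible(path)
}
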