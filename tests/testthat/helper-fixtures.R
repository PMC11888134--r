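# Fixture builders shared across the test files. All fixtures are built in
# code; nothing is read from disk except files the tests themselves write.

report_row <- function(report_id, age_group = "45-64", sex = "female",
                       serious = "no", seriousness_criteria = "") {
  data.frame(report_id = report_id, age_group = age_group, sex = sex,
             serious = serious, seriousness_criteria = seriousness_criteria,
             stringsAsFactors = FALSE)
}

drug_row <- function(report_id, drug_code, role = "suspect",
                     daily_dose_mg = NA_real_, start_date = NA,
                     stop_date = NA, dechallenge = "unknown",
                     rechallenge = "not_done") {
  data.frame(report_id = report_id, drug_code = drug_code, role = role,
             daily_dose_mg = daily_dose_mg,
             start_date = as.Date(start_date), stop_date = as.Date(stop_date),
             dechallenge = dechallenge, rechallenge = rechallenge,
             stringsAsFactors = FALSE)
}

reaction_row <- function(report_id, term = "Hypertension", onset_date = NA) {
  data.frame(report_id = report_id, term = term,
             onset_date = as.Date(onset_date), stringsAsFactors = FALSE)
}

tiny_vocab <- function() {
  vocabulary(
    smq_terms = c("Hypertension", "Blood pressure increased"),
    target_drugs = list(sertraline = "N06AB06", fluoxetine = "N06AB03"),
    antihypertensive_codes = "C02",
    hypertensive_inducer_codes = "M01AE01",
    comparator_population_codes = "N06A"
  )
}

# 10 adult reports: 3 cases (P01-P03), 4 sertraline-exposed (P01, P02, P04,
# P05); hand enumeration gives a=2, b=2, c=1, d=5 for sertraline.
fixture_db_10 <- function() {
  reports <- do.call(rbind, lapply(sprintf("P%02d", 1:10), report_row))
  drugs <- rbind(
    drug_row("P01", "N06AB06"), drug_row("P02", "N06AB06"),
    drug_row("P04", "N06AB06"), drug_row("P05", "N06AB06"),
    drug_row("P06", "A02BC01"))
  reactions <- rbind(
    reaction_row("P01"), reaction_row("P02"), reaction_row("P03"),
    reaction_row("P06", term = "Nausea"))
  icsr_db(reports, drugs, reactions)
}

# analytic-records frame built directly, for dose/trend unit tests
make_records <- function(is_case, exposed, dose = NA_real_,
                         age_group = "45-64", sex = "female",
                         has_antihypertensive = FALSE,
                         has_hypertensive_inducer = FALSE,
                         drug = "drugA") {
  n <- length(is_case)
  rec <- data.frame(
    report_id = sprintf("T%05d", seq_len(n)),
    age_group = rep_len(age_group, n), sex = rep_len(sex, n),
    is_case = is_case,
    has_antihypertensive = rep_len(has_antihypertensive, n),
    has_hypertensive_inducer = rep_len(has_hypertensive_inducer, n),
    in_comparator = TRUE, stringsAsFactors = FALSE)
  rec[[paste0("exposed_", drug)]] <- exposed
  rec[[paste0("dose_", drug)]] <- rep_len(dose, n)
  rec$exposed_any <- exposed
  structure(rec, class = c("analytic_records", "data.frame"), drugs = drug,
            role_policy = "any_role", population_filter = "whole_database")
}

# single-drug generator config used by calibration-style tests
one_drug_config <- function(n_reports, log_or = 0, prevalence = 0.1,
                            base_rate = 0.02, confounding = 0, seed = 1,
                            ...) {
  synthetic_config(
    n_reports = n_reports,
    baseline_event_logit = qlogis(base_rate),
    drug_specs = data.frame(drug = "drugA", code = "N06AB99",
                            exposure_prevalence = prevalence,
                            log_or = log_or, dose_median_mg = 50,
                            dose_dispersion = 0.4),
    confounder_specs = default_confounders(confounding),
    seed = seed, ...)
}
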