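# Synthetic ICSR database generator with planted effects and confounding.

INDUCER_POOL <- c("H02AB04", "M01AE01", "R01BA02", "L04AD01", "G03AA07")
ANTIHYPERTENSIVE_POOL <- c("C02AC01", "C02AB02", "C02CA01")
BACKGROUND_POOL <- c("A02BC01", "A10BA02", "J01CA04", "C10AA01", "B01AC06")
OTHER_ANTIDEPRESSANT <- "N06AA09"
NONCASE_TERMS <- c("Nausea", "Headache", "Dizziness", "Rash", "Insomnia")

#' Configure the synthetic ICSR generator
#'
#' Defines a spontaneous-report database with known ground truth: per-drug
#' exposure prevalences and planted log reporting odds ratios, a logistic
#' event model with demographic and co-medication covariate effects, and an
#' exposure-confounding term that shifts each drug's exposure logit by
#' `exposure_confounding_log_or` times the (centered) covariate score, so
#' that crude RORs are biased away from the planted effect while adjusted
#' RORs recover it.
#'
#' @param n_reports number of reports (0 allowed: empty database).
#' @param baseline_event_logit log-odds of the event term on an unexposed
#'   report with reference covariates (18-44, female, no flagged
#'   co-medication).
#' @param drug_specs data frame with columns `drug` (label), `code` (ATC),
#'   `exposure_prevalence` in (0,1), `log_or`, `dose_median_mg` > 0,
#'   `dose_dispersion` > 0 (log-normal sdlog).
#' @param confounder_specs list with `age_distribution` (probabilities over
#'   the four adult bands, summing to 1), `p_female`, `p_antihypertensive`,
#'   `p_hypertensive_inducer`, `log_or_age` (length 4, reference band 18-44),
#'   `log_or_sex_male`, `log_or_antihypertensive`, `log_or_inducer`, and
#'   `exposure_confounding_log_or`.
#' @param tto_mean_days mean of the exponential time-to-onset (days).
#' @param p_dechallenge_positive,p_rechallenge_positive probability that a
#'   target-drug entry on an event report carries a positive dechallenge /
#'   rechallenge outcome.
#' @param p_serious probability a report with known seriousness is serious.
#' @param seed integer master seed; the generator is a pure function of the
#'   config including the seed.
#' @param p_age_unknown,p_sex_unknown,p_serious_unknown fractions with
#'   missing demographics / seriousness.
#' @param p_dose_missing probability an exposed entry has no recorded daily
#'   dose (dose availability in spontaneous reports is sparse).
#' @param p_onset_missing probability an event report has no onset date.
#' @param p_suspect probability a target-drug entry is coded suspect (others
#'   concomitant).
#' @param p_other_antidepressant probability a report carries a non-target
#'   antidepressant entry (keeps the N06A comparator population non-trivial).
#' @param event_term reaction term written on event reports.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_reports,
                             baseline_event_logit,
                             drug_specs,
                             confounder_specs = default_confounders(),
                             tto_mean_days = 10,
                             p_dechallenge_positive = 0.07,
                             p_rechallenge_positive = 0.003,
                             p_serious = 0.75,
                             seed = 1L,
                             p_age_unknown = 0.05,
                             p_sex_unknown = 0.03,
                             p_serious_unknown = 0.1,
                             p_dose_missing = 0.8,
                             p_onset_missing = 0.9,
                             p_suspect = 0.7,
                             p_other_antidepressant = 0.2,
                             event_term = "Hypertension") {
  drug_specs <- as.data.frame(drug_specs, stringsAsFactors = FALSE)
  check_cols(drug_specs, c("drug", "code", "exposure_prevalence", "log_or",
                           "dose_median_mg", "dose_dispersion"), "drug_specs")
  if (!is.numeric(n_reports) || length(n_reports) != 1 || is.na(n_reports) ||
      n_reports < 0 || n_reports != floor(n_reports))
    stop("config error: n_reports must be a non-negative integer")
  if (anyDuplicated(drug_specs$code) || anyDuplicated(drug_specs$drug))
    stop("config error: drug labels and codes must be unique")
  if (any(drug_specs$exposure_prevalence <= 0 | drug_specs$exposure_prevalence >= 1))
    stop("config error: exposure_prevalence must lie in (0, 1)")
  if (any(drug_specs$dose_median_mg <= 0) || any(drug_specs$dose_dispersion <= 0))
    stop("config error: dose parameters must be positive")
  if (tto_mean_days <= 0)
    stop("config error: tto_mean_days must be positive")
  cs <- confounder_specs
  probs <- c(cs$p_female, cs$p_antihypertensive, cs$p_hypertensive_inducer,
             p_dechallenge_positive, p_rechallenge_positive, p_serious,
             p_age_unknown, p_sex_unknown, p_serious_unknown, p_dose_missing,
             p_onset_missing, p_suspect, p_other_antidepressant)
  if (any(!is.finite(probs)) || any(probs < 0 | probs > 1))
    stop("config error: probabilities must lie in [0, 1]")
  if (cs$p_female <= 0 || cs$p_female >= 1)
    stop("config error: p_female must lie in (0, 1)")
  if (length(cs$age_distribution) != 4 ||
      abs(sum(cs$age_distribution) - 1) > 1e-8 || any(cs$age_distribution < 0))
    stop("config error: age_distribution must be 4 probabilities summing to 1")
  if (length(cs$log_or_age) != 4)
    stop("config error: log_or_age must have one entry per adult age band")
  structure(list(
    n_reports = as.integer(n_reports),
    baseline_event_logit = baseline_event_logit,
    drug_specs = drug_specs,
    confounder_specs = cs,
    tto_mean_days = tto_mean_days,
    p_dechallenge_positive = p_dechallenge_positive,
    p_rechallenge_positive = p_rechallenge_positive,
    p_serious = p_serious,
    seed = as.integer(seed),
    p_age_unknown = p_age_unknown,
    p_sex_unknown = p_sex_unknown,
    p_serious_unknown = p_serious_unknown,
    p_dose_missing = p_dose_missing,
    p_onset_missing = p_onset_missing,
    p_suspect = p_suspect,
    p_other_antidepressant = p_other_antidepressant,
    event_term = event_term
  ), class = "synthetic_config")
}

#' Default confounder structure
#'
#' Reporting-age skews middle-aged, reports skew female, and hypertension
#' reporting odds rise with age and with antihypertensive / known
#' hypertension-inducing co-medication. `exposure_confounding_log_or = 0`
#' gives an unconfounded database.
#'
#' @param exposure_confounding_log_or strength of exposure-covariate
#'   confounding on the logit scale.
#' @return list suitable for `confounder_specs`.
#' @export
default_confounders <- function(exposure_confounding_log_or = 0.4) {
  list(
    age_distribution = setNames(c(0.42, 0.36, 0.13, 0.09), AGE_BANDS),
    p_female = 0.62,
    p_antihypertensive = 0.06,
    p_hypertensive_inducer = 0.35,
    log_or_age = setNames(log(c(1, 1.8, 2.0, 2.2)), AGE_BANDS),
    log_or_sex_male = log(1 / 1.4),
    log_or_antihypertensive = log(1.5),
    log_or_inducer = log(1.3),
    exposure_confounding_log_or = exposure_confounding_log_or
  )
}

# analytic expectation of the covariate score (used to center the
# confounding shift so configured exposure prevalences stay calibrated)
mean_covariate_score <- function(config) {
  cs <- config$confounder_specs
  (1 - config$p_age_unknown) * sum(cs$age_distribution * cs$log_or_age) +
    (1 - config$p_sex_unknown) * (1 - cs$p_female) * cs$log_or_sex_male +
    cs$p_antihypertensive * cs$log_or_antihypertensive +
    cs$p_hypertensive_inducer * cs$log_or_inducer
}

#' Generate a synthetic ICSR database
#'
#' Draws covariates, confounded drug exposures, logistic event indicators,
#' log-normal daily doses, exponential onset times and dechallenge /
#' rechallenge outcomes per the config, and assembles an [icsr_db()]. The
#' result is a pure function of the config (same config, same seed:
#' byte-identical database); random-number streams are split per component
#' so adding a drug spec does not perturb other draws.
#'
#' @param config a [synthetic_config()].
#' @return an `icsr_db`; the generating config is attached as attribute
#'   `"config"`.
#' @export
generate_database <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_reports
  cs <- config$confounder_specs
  if (n == 0) {
    return(icsr_db(
      data.frame(report_id = character(), age_group = character(),
                 sex = character(), serious = character(),
                 seriousness_criteria = character()),
      data.frame(report_id = character(), drug_code = character(),
                 role = character(), daily_dose_mg = numeric(),
                 start_date = as.Date(character()),
                 stop_date = as.Date(character()),
                 dechallenge = character(), rechallenge = character()),
      data.frame(report_id = character(), term = character(),
                 onset_date = as.Date(character()))))
  }
  ids <- sprintf("R%07d", seq_len(n))

  # --- covariates --------------------------------------------------------
  set.seed(mix_seed(config$seed, 11))
  age <- sample(AGE_LEVELS, n, replace = TRUE,
                prob = c((1 - config$p_age_unknown) * cs$age_distribution,
                         config$p_age_unknown))
  sex <- sample(SEX_LEVELS, n, replace = TRUE,
                prob = c((1 - config$p_sex_unknown) * cs$p_female,
                         (1 - config$p_sex_unknown) * (1 - cs$p_female),
                         config$p_sex_unknown))
  has_ah <- runif(n) < cs$p_antihypertensive
  has_ind <- runif(n) < cs$p_hypertensive_inducer
  lor_age <- c(cs$log_or_age, unknown = 0)
  score <- unname(lor_age[age]) + (sex == "male") * cs$log_or_sex_male +
    has_ah * cs$log_or_antihypertensive + has_ind * cs$log_or_inducer
  centered <- score - mean_covariate_score(config)

  # --- exposures (one independent stream per drug) -----------------------
  specs <- config$drug_specs
  k <- nrow(specs)
  expo <- matrix(FALSE, n, k, dimnames = list(NULL, specs$drug))
  conf <- cs$exposure_confounding_log_or
  for (j in seq_len(k)) {
    set.seed(mix_seed(config$seed, 20, code_hash(specs$code[j])))
    p <- plogis(qlogis(specs$exposure_prevalence[j]) + conf * centered)
    expo[, j] <- runif(n) < p
  }

  # --- event indicator ---------------------------------------------------
  set.seed(mix_seed(config$seed, 31))
  eta <- config$baseline_event_logit + score +
    as.vector(expo %*% specs$log_or)
  is_event <- runif(n) < plogis(eta)

  # --- seriousness -------------------------------------------------------
  set.seed(mix_seed(config$seed, 41))
  serious <- sample(SERIOUS_LEVELS, n, replace = TRUE,
                    prob = c((1 - config$p_serious_unknown) * config$p_serious,
                             (1 - config$p_serious_unknown) * (1 - config$p_serious),
                             config$p_serious_unknown))
  crit <- rep("", n)
  ser_idx <- which(serious == "yes")
  if (length(ser_idx)) {
    crit_p <- c(hospitalization = 0.45, congenital_anomaly = 0.001,
                death = 0.08, disabling = 0.03, life_threatening = 0.06,
                other = 0.35)
    hit <- matrix(runif(length(ser_idx) * length(crit_p)),
                  ncol = length(crit_p))
    hit <- sweep(hit, 2, crit_p, "<")
    parts <- lapply(seq_along(crit_p),
                    function(j) ifelse(hit[, j], names(crit_p)[j], ""))
    s <- do.call(paste, c(parts, sep = ";"))
    s <- gsub(";{2,}", ";", s)
    s <- gsub("^;|;$", "", s)
    crit[ser_idx] <- s
  }

  # --- dates -------------------------------------------------------------
  set.seed(mix_seed(config$seed, 51))
  date_pool <- seq(as.Date("2000-01-01"), as.Date("2024-06-30"), by = "day")
  bg_start <- sample(date_pool, n, replace = TRUE)

  # --- drug entries ------------------------------------------------------
  d_rid <- character(0); d_code <- character(0); d_role <- character(0)
  d_dose <- numeric(0); d_start <- as.Date(character(0))
  d_dech <- character(0); d_rech <- character(0)
  first_target_start <- rep(as.Date(NA), n)

  for (j in seq_len(k)) {
    idx <- which(expo[, j])
    m <- length(idx)
    if (!m) next
    set.seed(mix_seed(config$seed, 60, code_hash(specs$code[j])))
    role <- ifelse(runif(m) < config$p_suspect, "suspect", "concomitant")
    dose <- round(rlnorm(m, log(specs$dose_median_mg[j]),
                         specs$dose_dispersion[j]), 1)
    dose[runif(m) < config$p_dose_missing] <- NA_real_
    start <- sample(date_pool, m, replace = TRUE)
    ev <- is_event[idx]
    dech <- rep("unknown", m)
    rech <- rep("not_done", m)
    if (any(ev)) {
      u1 <- runif(sum(ev)); u2 <- runif(sum(ev))
      dech[ev] <- ifelse(u1 < config$p_dechallenge_positive, "positive",
                         ifelse(u1 < config$p_dechallenge_positive + 0.2,
                                "negative", "unknown"))
      rech[ev] <- ifelse(u2 < config$p_rechallenge_positive, "positive",
                         ifelse(u2 < config$p_rechallenge_positive + 0.05,
                                "negative", "not_done"))
    }
    d_rid <- c(d_rid, ids[idx]); d_code <- c(d_code, rep(specs$code[j], m))
    d_role <- c(d_role, role); d_dose <- c(d_dose, dose)
    d_start <- c(d_start, start)
    d_dech <- c(d_dech, dech); d_rech <- c(d_rech, rech)
    upd <- is.na(first_target_start[idx]) | start < first_target_start[idx]
    first_target_start[idx[upd]] <- start[upd]
  }

  set.seed(mix_seed(config$seed, 65))
  bg_code <- sample(BACKGROUND_POOL, n, replace = TRUE)
  other_ad <- runif(n) < config$p_other_antidepressant
  ah_code <- sample(ANTIHYPERTENSIVE_POOL, n, replace = TRUE)
  ind_code <- sample(INDUCER_POOL, n, replace = TRUE)

  add_entries <- function(sel, codes) {
    m <- sum(sel)
    d_rid <<- c(d_rid, ids[sel])
    d_code <<- c(d_code, codes[sel])
    d_role <<- c(d_role, rep("concomitant", m))
    d_dose <<- c(d_dose, rep(NA_real_, m))
    d_start <<- c(d_start, bg_start[sel])
    d_dech <<- c(d_dech, rep("unknown", m))
    d_rech <<- c(d_rech, rep("not_done", m))
  }
  add_entries(rep(TRUE, n), bg_code)
  if (any(has_ah)) add_entries(has_ah, ah_code)
  if (any(has_ind)) add_entries(has_ind, ind_code)
  if (any(other_ad)) add_entries(other_ad, rep(OTHER_ANTIDEPRESSANT, n))

  drugs <- data.frame(report_id = d_rid, drug_code = d_code, role = d_role,
                      daily_dose_mg = d_dose, start_date = d_start,
                      stop_date = as.Date(NA), dechallenge = d_dech,
                      rechallenge = d_rech, stringsAsFactors = FALSE)

  # --- reactions ---------------------------------------------------------
  set.seed(mix_seed(config$seed, 71))
  anchor <- first_target_start
  anchor[is.na(anchor)] <- bg_start[is.na(anchor)]
  delay <- floor(rexp(n, rate = 1 / config$tto_mean_days))
  onset <- anchor + delay
  onset[runif(n) < config$p_onset_missing] <- NA
  term <- sample(NONCASE_TERMS, n, replace = TRUE)
  term[is_event] <- config$event_term
  onset[!is_event] <- NA
  reactions <- data.frame(report_id = ids, term = term, onset_date = onset,
                          stringsAsFactors = FALSE)

  reports <- data.frame(report_id = ids, age_group = age, sex = sex,
                        serious = serious, seriousness_criteria = crit,
                        stringsAsFactors = FALSE)
  db <- icsr_db(reports, drugs, reactions, validate = FALSE)
  attr(db, "config") <- config
  db
}

#' Vocabulary matching a synthetic configuration
#'
#' Builds the [vocabulary()] under which analyses of a [generate_database()]
#' output see the planted structure: the event term as the SMQ set, the
#' config's drugs as targets, and the generator's fixed C02 / inducer / N06A
#' code conventions.
#'
#' @param config a [synthetic_config()].
#' @return a `pv_vocabulary`.
#' @export
synthetic_vocabulary <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  vocabulary(
    smq_terms = config$event_term,
    target_drugs = setNames(as.list(config$drug_specs$code),
                            config$drug_specs$drug),
    antihypertensive_codes = "C02",
    hypertensive_inducer_codes = INDUCER_POOL,
    comparator_population_codes = "N06A"
  )
}

#' Write the planted ground truth of a config
#'
#' Records every generator parameter (including planted log odds ratios) in a
#' YAML file alongside a simulated database, for audit of calibration runs.
#'
#' @param config a [synthetic_config()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  x <- unclass(config)
  x$drug_specs <- lapply(seq_len(nrow(config$drug_specs)), function(i)
    as.list(config$drug_specs[i, ]))
  x$confounder_specs <- lapply(x$confounder_specs, function(v)
    if (is.null(names(v))) v else as.list(v))
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

# exact marginal P(case | exposed to >= 1 target, adult) implied by a config:
# enumeration over covariate cells and drug-exposure subsets.
implied_exposed_case_rate <- function(config, baseline = config$baseline_event_logit) {
  cs <- config$confounder_specs
  specs <- config$drug_specs
  k <- nrow(specs)
  if (k > 12) stop("enumeration supports at most 12 drugs")
  cells <- expand.grid(age = AGE_BANDS, sex = SEX_LEVELS, ah = 0:1, ind = 0:1,
                       stringsAsFactors = FALSE)
  p_sex <- c(female = (1 - config$p_sex_unknown) * cs$p_female,
             male = (1 - config$p_sex_unknown) * (1 - cs$p_female),
             unknown = config$p_sex_unknown)
  p_cell <- cs$age_distribution[cells$age] * p_sex[cells$sex] *
    ifelse(cells$ah == 1, cs$p_antihypertensive, 1 - cs$p_antihypertensive) *
    ifelse(cells$ind == 1, cs$p_hypertensive_inducer, 1 - cs$p_hypertensive_inducer)
  score <- cs$log_or_age[cells$age] +
    (cells$sex == "male") * cs$log_or_sex_male +
    cells$ah * cs$log_or_antihypertensive + cells$ind * cs$log_or_inducer
  centered <- score - mean_covariate_score(config)
  subsets <- as.matrix(expand.grid(rep(list(0:1), k)))
  subset_lor <- as.vector(subsets %*% specs$log_or)
  exposed_any <- rowSums(subsets) > 0
  num <- 0; den <- 0
  for (i in seq_len(nrow(cells))) {
    pd <- plogis(qlogis(specs$exposure_prevalence) +
                   cs$exposure_confounding_log_or * centered[i])
    lp <- as.vector(subsets %*% log(pd) + (1 - subsets) %*% log(1 - pd))
    ps <- exp(lp)
    pev <- plogis(baseline + score[i] + subset_lor)
    den <- den + p_cell[i] * sum(ps[exposed_any])
    num <- num + p_cell[i] * sum(ps[exposed_any] * pev[exposed_any])
  }
  num / den
}

#' Study-scale default configuration
#'
#' Returns a config whose per-drug exposure prevalences reproduce, at
#' `n_reports = scale * 1e6`, the exposed-report counts of a worldwide
#' SRI-hypertension case/non-case evaluation (nine serotonin reuptake
#' inhibitors from alaproclate to zimeldine), with planted per-drug effects
#' equal to the adjusted estimates of that evaluation, positive confounding
#' on top, and the baseline event logit calibrated deterministically so the
#' implied case rate among adult exposed reports is 2.2%. The default
#' `scale = 0.1` (100,000 reports) is the desk-scale working size.
#'
#' @param scale database size as a fraction of the full 10^6-report scale;
#'   must be positive.
#' @param seed master seed.
#' @return a [synthetic_config()].
#' @export
vigibase_like_config <- function(scale = 0.1, seed = 20240729L) {
  if (!is.numeric(scale) || length(scale) != 1 || is.na(scale) || scale <= 0)
    stop("config error: scale must be a positive number")
  specs <- data.frame(
    drug = c("alaproclate", "citalopram", "escitalopram", "etoperidone",
             "fluoxetine", "fluvoxamine", "paroxetine", "sertraline",
             "zimeldine"),
    code = c("N06AB01", "N06AB04", "N06AB10", "N06AX09", "N06AB03",
             "N06AB08", "N06AB05", "N06AB06", "N06AB02"),
    exposure_prevalence = c(1, 115516, 111746, 34, 128104, 12874, 101345,
                            169663, 918) / 1e6,
    log_or = log(c(1, 1.16, 1.25, 1, 1.29, 0.99, 1.40, 1.30, 0.59)),
    dose_median_mg = c(400, 20, 10, 100, 20, 100, 20, 50, 200),
    dose_dispersion = rep(0.4, 9),
    stringsAsFactors = FALSE
  )
  cfg <- synthetic_config(
    n_reports = round(1e6 * scale),
    baseline_event_logit = -4,   # placeholder, calibrated below
    drug_specs = specs,
    confounder_specs = default_confounders(0.4),
    seed = seed
  )
  target <- 0.022
  f <- function(b) implied_exposed_case_rate(cfg, baseline = b) - target
  cfg$baseline_event_logit <- uniroot(f, c(-12, 0), tol = 1e-9)$root
  cfg
}
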