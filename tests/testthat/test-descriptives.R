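cohort_value <- function(summ, field, what = "percent") {
  summ[[what]][summ$field == field]
}

test_that("a single-case cohort reports 100% in its own fields", {
  cases <- data.frame(report_id = "S1", age_group = "18-44", sex = "female",
                      serious = "yes", seriousness_criteria = "hospitalization",
                      stroke = FALSE, mi = FALSE, antihypertensive = FALSE,
                      inducer = FALSE)
  summ <- summarize_cohort(cases, n_reports = 50)
  expect_equal(cohort_value(summ, "female"), 100)
  expect_equal(cohort_value(summ, "age_18-44"), 100)
  expect_equal(cohort_value(summ, "serious"), 100)
  expect_equal(cohort_value(summ, "criteria_hospitalization"), 100)
  expect_equal(cohort_value(summ, "n_cases"), 2)   # 1 of 50 reports
})

test_that("cohort percentages recompute from counts and denominators", {
  set.seed(101)
  n <- 400
  cases <- data.frame(
    report_id = sprintf("C%03d", 1:n),
    age_group = sample(c("18-44", "45-64", "65-74", "75plus"), n, TRUE),
    sex = sample(c("female", "male", "unknown"), n, TRUE, c(.6, .35, .05)),
    serious = rep(c("yes", "no", "unknown"), c(250, 100, 50)),
    seriousness_criteria = c(rep("hospitalization;death", 50),
                             rep("hospitalization", 100),
                             rep("other", 60), rep("", 40),
                             rep("", 150)),
    stroke = rep(c(TRUE, FALSE), c(30, n - 30)),
    mi = rep(c(FALSE, TRUE, FALSE), c(30, 20, n - 50)),
    antihypertensive = FALSE, inducer = FALSE)
  summ <- summarize_cohort(cases, n_reports = 10000)
  expect_equal(summ$percent, 100 * summ$count / summ$denominator)
  expect_equal(cohort_value(summ, "serious", "count"), 250)
  expect_equal(cohort_value(summ, "serious", "denominator"), 350)
  # criteria are counted over serious reports and may co-occur
  expect_equal(cohort_value(summ, "criteria_hospitalization", "count"), 150)
  expect_equal(cohort_value(summ, "criteria_death", "count"), 50)
  expect_equal(cohort_value(summ, "criteria_missing", "count"), 40)
  expect_equal(cohort_value(summ, "criteria_death", "denominator"), 250)
  # stroke and MI here are disjoint, so CVD-linked reports add up
  expect_equal(cohort_value(summ, "cvd", "count"), 50)
  # age-band counts sum to the cohort size
  age_counts <- summ$count[grepl("^age_", summ$field)]
  expect_equal(sum(age_counts), n)
})

test_that("case_cohort flags stroke, MI and co-medication from the database", {
  reports <- rbind(report_row("T1", serious = "yes",
                              seriousness_criteria = "death"),
                   report_row("T2"),
                   report_row("T3", age_group = "unknown"))
  drugs <- rbind(drug_row("T1", "N06AB06"), drug_row("T1", "C02AC01"),
                 drug_row("T2", "M01AE01"), drug_row("T3", "N06AB06"))
  reactions <- rbind(reaction_row("T1"), reaction_row("T1", term = "Myocardial infarction"),
                     reaction_row("T2"), reaction_row("T3"))
  db <- icsr_db(reports, drugs, reactions)
  cases <- case_cohort(db, tiny_vocab())
  expect_equal(nrow(cases), 2L)         # T3 has unknown age
  expect_equal(attr(cases, "n_reports"), 2L)
  expect_equal(cases$mi[cases$report_id == "T1"], TRUE)
  expect_equal(cases$antihypertensive, c(TRUE, FALSE))
  expect_equal(cases$inducer, c(FALSE, TRUE))
})

test_that("time to onset uses earliest dates, whole days, and exclusions", {
  vocab <- tiny_vocab()
  mk <- function(id, start, onset, extra_onset = NULL) {
    list(report_row(id),
         drug_row(id, "N06AB06", start_date = start),
         if (is.null(extra_onset)) reaction_row(id, onset_date = onset) else
           rbind(reaction_row(id, onset_date = onset),
                 reaction_row(id, onset_date = extra_onset)))
  }
  parts <- list(
    mk("Z1", "2020-01-01", "2020-01-02"),                 # TTO 1
    mk("Z2", "2020-01-01", "2020-01-02"),                 # TTO 1
    mk("Z3", "2020-01-01", "2020-01-05"),                 # TTO 4
    mk("Z4", "2020-01-01", "2020-01-10", "2020-01-02"),   # earliest onset: 1
    mk("Z5", "2020-01-01", "2020-01-06"),                 # TTO 5
    mk("Z6", "2020-03-01", "2020-01-01"),                 # negative: excluded
    mk("Z7", NA, "2020-01-01"))                           # no start: excluded
  db <- icsr_db(do.call(rbind, lapply(parts, `[[`, 1)),
                do.call(rbind, lapply(parts, `[[`, 2)),
                do.call(rbind, lapply(parts, `[[`, 3)))
  tto <- time_to_onset(db, vocab, "sertraline")
  # values [1, 1, 4, 1, 5]: median 1, quartiles (1, 4) under midpoint rule
  expect_equal(tto$n_available, 5L)
  expect_equal(tto$median_days, 1)
  expect_equal(tto$iqr_low_days, 1)
  expect_equal(tto$iqr_high_days, 4)

  # start = onset gives 0 days; no informative report gives NA
  db0 <- icsr_db(report_row("Y1"),
                 drug_row("Y1", "N06AB06", start_date = "2020-05-05"),
                 reaction_row("Y1", onset_date = "2020-05-05"))
  tto0 <- time_to_onset(db0, vocab, "sertraline")
  expect_equal(tto0$median_days, 0)
  expect_equal(time_to_onset(db0, vocab, "fluoxetine")$n_available, 0L)
  expect_true(is.na(time_to_onset(db0, vocab, "fluoxetine")$median_days))
})

test_that("challenge counts tally positive outcomes once per report", {
  vocab <- tiny_vocab()
  reports <- rbind(report_row("K1"), report_row("K2"), report_row("K3"))
  drugs <- rbind(
    drug_row("K1", "N06AB06", dechallenge = "positive", rechallenge = "positive"),
    # two entries of the same drug on K2, one positive in each field
    drug_row("K2", "N06AB06", dechallenge = "positive"),
    drug_row("K2", "N06AB06", rechallenge = "positive"),
    drug_row("K3", "N06AB06", dechallenge = "negative"))
  reactions <- rbind(reaction_row("K1"), reaction_row("K2"), reaction_row("K3"))
  db <- icsr_db(reports, drugs, reactions)
  cc <- challenge_counts(db, vocab, "sertraline")
  expect_equal(cc$n_positive_dechallenge, 2L)   # K1 and K2, each once
  expect_equal(cc$n_positive_rechallenge, 2L)
  # zero exposed cases for the other drug
  cc0 <- challenge_counts(db, vocab, "fluoxetine")
  expect_equal(c(cc0$n_positive_dechallenge, cc0$n_positive_rechallenge),
               c(0L, 0L))
})

test_that("TTO summaries ignore non-case reports", {
  vocab <- tiny_vocab()
  db <- icsr_db(
    rbind(report_row("L1"), report_row("L2")),
    rbind(drug_row("L1", "N06AB06", start_date = "2020-01-01"),
          drug_row("L2", "N06AB06", start_date = "2020-01-01")),
    rbind(reaction_row("L1", onset_date = "2020-01-08"),
          reaction_row("L2", term = "Nausea", onset_date = "2020-01-02")))
  tto <- time_to_onset(db, vocab, "sertraline")
  expect_equal(tto$n_available, 1L)
  expect_equal(tto$median_days, 7)
})
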