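test_that("read_icsr_db joins the three tables and validates integrity", {
  dir <- withr::local_tempdir()
  reports <- do.call(rbind, lapply(c("A1", "A2", "A3"), report_row))
  drugs <- rbind(drug_row("A1", "N06AB06", daily_dose_mg = 50),
                 drug_row("A1", "C02AC01", role = "concomitant"),
                 drug_row("A2", "N06AB03"),
                 drug_row("A3", "A02BC01"))
  reactions <- rbind(reaction_row("A1"), reaction_row("A2", term = "Nausea"),
                     reaction_row("A3", term = "Headache"))
  write.csv(reports, file.path(dir, "reports.csv"), row.names = FALSE, na = "")
  write.csv(drugs, file.path(dir, "drugs.csv"), row.names = FALSE, na = "")
  write.csv(reactions, file.path(dir, "reactions.csv"), row.names = FALSE, na = "")
  db <- read_icsr_db(file.path(dir, "reports.csv"), file.path(dir, "drugs.csv"),
                     file.path(dir, "reactions.csv"))
  counts <- table(db$drugs$report_id)
  expect_equal(as.integer(counts[c("A1", "A2", "A3")]), c(2L, 1L, 1L))
  expect_equal(nrow(db$reports), 3L)

  # degenerate input: header-only drugs and reactions files
  write.csv(drugs[0, ], file.path(dir, "d0.csv"), row.names = FALSE)
  write.csv(reactions[0, ], file.path(dir, "r0.csv"), row.names = FALSE)
  db0 <- read_icsr_db(file.path(dir, "reports.csv"), file.path(dir, "d0.csv"),
                      file.path(dir, "r0.csv"))
  expect_equal(nrow(db0$drugs), 0L)
  expect_equal(nrow(db0$reactions), 0L)

  # referential violation: drugs row pointing at an absent report
  bad <- rbind(drugs, drug_row("X9", "N06AB06"))
  write.csv(bad, file.path(dir, "bad.csv"), row.names = FALSE, na = "")
  expect_error(read_icsr_db(file.path(dir, "reports.csv"),
                            file.path(dir, "bad.csv"),
                            file.path(dir, "r0.csv")),
               "integrity error.*X9")

  # duplicate report id and missing column
  dup <- rbind(reports, report_row("A1"))
  write.csv(dup, file.path(dir, "dup.csv"), row.names = FALSE, na = "")
  expect_error(read_icsr_db(file.path(dir, "dup.csv"), file.path(dir, "d0.csv"),
                            file.path(dir, "r0.csv")),
               "integrity error.*duplicate")
  noage <- reports[, setdiff(names(reports), "age_group")]
  write.csv(noage, file.path(dir, "noage.csv"), row.names = FALSE, na = "")
  expect_error(read_icsr_db(file.path(dir, "noage.csv"),
                            file.path(dir, "d0.csv"), file.path(dir, "r0.csv")),
               "schema error.*age_group")
})

test_that("write_icsr_db then read_icsr_db is the identity", {
  reports <- rbind(report_row("B1", serious = "yes",
                              seriousness_criteria = "death;hospitalization"),
                   report_row("B2", age_group = "unknown", sex = "unknown"))
  drugs <- rbind(drug_row("B1", "N06AB06", daily_dose_mg = 37.5,
                          start_date = "2020-01-05", stop_date = "2020-03-01",
                          dechallenge = "positive", rechallenge = "positive"),
                 drug_row("B2", "C02AC01", role = "interacting"))
  reactions <- rbind(reaction_row("B1", onset_date = "2020-01-20"),
                     reaction_row("B2", term = "Nausea"))
  db <- icsr_db(reports, drugs, reactions)
  dir <- withr::local_tempdir()
  paths <- write_icsr_db(db, dir)
  back <- read_icsr_db(paths["reports"], paths["drugs"], paths["reactions"])
  expect_equal(back$reports, db$reports)
  expect_equal(back$drugs, db$drugs)
  expect_equal(back$reactions, db$reactions)
})

test_that("raw ages are binned into the adult bands at load time", {
  expect_equal(pvror:::bin_age(c(18, 44.9, 45, 64, 65, 74.5, 75, 90, 17, NA)),
               c("18-44", "18-44", "45-64", "45-64", "65-74", "65-74",
                 "75plus", "75plus", "unknown", "unknown"))
  dir <- withr::local_tempdir()
  reports <- data.frame(report_id = c("C1", "C2"), age_years = c(50, 16),
                        sex = "female", serious = "no",
                        seriousness_criteria = "")
  write.csv(reports, file.path(dir, "reports.csv"), row.names = FALSE)
  empty_drugs <- drug_row("C1", "X")[0, ]
  write.csv(empty_drugs, file.path(dir, "drugs.csv"), row.names = FALSE)
  write.csv(reaction_row("C1")[0, ], file.path(dir, "reactions.csv"),
            row.names = FALSE)
  db <- read_icsr_db(file.path(dir, "reports.csv"), file.path(dir, "drugs.csv"),
                     file.path(dir, "reactions.csv"))
  expect_equal(db$reports$age_group, c("45-64", "unknown"))
})

test_that("domain invariants on drug entries are enforced", {
  r <- report_row("D1")
  expect_error(icsr_db(r, drug_row("D1", "X", daily_dose_mg = -5),
                       reaction_row("D1")[0, ]),
               "non-negative")
  expect_error(icsr_db(r, drug_row("D1", "X", start_date = "2020-05-01",
                                   stop_date = "2020-01-01"),
                       reaction_row("D1")[0, ]),
               "stop_date")
})

test_that("vocabulary canonicalizes, de-duplicates, and validates", {
  v <- vocabulary(smq_terms = c(" Hypertension ", "HYPERTENSION", "BP up"))
  expect_equal(sort(v$smq_terms), c("bp up", "hypertension"))
  expect_identical(canonical_term(canonical_term(" HyPerTension ")),
                   canonical_term(" HyPerTension "))
  expect_error(vocabulary(smq_terms = character()), "smq_terms")
  expect_error(vocabulary("x", target_drugs = list("N06AB06")), "named")
})

test_that("vocabulary files load with section validation", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("smq_terms:", "  - Hypertension",
               "  - Blood pressure increased", "  - hypertension",
               "target_drugs:", "  sertraline: [N06AB06]",
               "antihypertensive_codes: [C02]",
               "hypertensive_inducer_codes: [M01AE01]"), path)
  expect_warning(v <- load_vocabulary(path), "comparator_population_codes")
  expect_length(v$smq_terms, 2)   # duplicate folds into one, set semantics
  expect_length(v$comparator_population_codes, 0)

  empty <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("smq_terms: []", "target_drugs: {}"), empty)
  expect_error(load_vocabulary(empty), "empty smq_terms")

  pkg_vocab <- load_vocabulary(system.file("extdata",
                                           "vocabulary_synthetic.yaml",
                                           package = "pvror"))
  expect_length(pkg_vocab$target_drugs, 9)
})

test_that("result tables render with stable order, rounding, and NA policy", {
  row <- data.frame(drug = "sertraline", a = 10L, b = 90L, ror = 1.4449,
                    ci_low = 1.0349, ci_high = 2.01732, aror = NA_real_,
                    aci_low = NA_real_, aci_high = NA_real_, signal = TRUE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_result_table(row, path, "signal_table")
  rendered <- read.csv(path, colClasses = "character", na.strings = NULL)
  expect_equal(names(rendered),
               c("drug", "a", "b", "ror", "ci_low", "ci_high", "aror",
                 "aci_low", "aci_high", "signal"))
  expect_equal(rendered$ror, "1.44")
  expect_equal(rendered$ci_low, "1.03")
  expect_equal(rendered$aror, "NA")
  full <- read.csv(sub("\\.csv$", ".full.csv", path))
  expect_equal(full$ror, 1.4449)

  write_result_table(NULL, path, "signal_table")
  expect_equal(nrow(read.csv(path)), 0L)
  expect_error(write_result_table(row, path, "nope"), "unknown schema")
})
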