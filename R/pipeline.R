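# Config-driven orchestration of the full analysis set, plus the simulation
# calibration harness.

ANALYSES <- c("main", "suspect_only", "n06a_population", "dose", "descriptives")

# weak but deterministic fingerprint for the run manifest
fingerprint <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  sprintf("%08x", sum(as.numeric(raw) * (seq_along(raw) %% 251 + 1)) %% 2^31)
}

#' Run the full case/non-case analysis set
#'
#' Executes the requested analyses on a database + vocabulary and writes one
#' CSV per output table (each with a full-precision companion) plus a YAML
#' run manifest (package version, input fingerprints, analyses, row counts,
#' number of disproportionality tests performed; no multiplicity correction
#' is applied across drugs). Signal tables carry per-drug rows in
#' alphabetical order with the pooled class row last. Any stage failure
#' aborts with a stage-named error and removes partial outputs.
#'
#' @param db an [icsr_db()], or a length-3 character vector of paths
#'   (reports, drugs, reactions CSVs).
#' @param vocabulary a [vocabulary()], or the path to a YAML vocabulary file.
#' @param analyses subset of `"main"`, `"suspect_only"`, `"n06a_population"`,
#'   `"dose"`, `"descriptives"`.
#' @param out_dir output directory (created if needed).
#' @return named list of the computed tables, invisibly.
#' @export
run_analysis <- function(db, vocabulary, analyses = ANALYSES, out_dir) {
  if (is.character(db) && length(db) == 3)
    db <- read_icsr_db(db[1], db[2], db[3])
  if (is.character(vocabulary))
    vocabulary <- load_vocabulary(vocabulary)
  stopifnot(inherits(db, "icsr_db"), inherits(vocabulary, "pv_vocabulary"))
  bad <- setdiff(analyses, ANALYSES)
  if (length(bad))
    stop("unknown analyses requested: ", paste(bad, collapse = ", "))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  written <- character(0)
  tables <- list()
  emit <- function(rows, file, schema) {
    path <- file.path(out_dir, file)
    write_result_table(rows, path, schema)
    written <<- c(written, path, sub("\\.csv$", ".full.csv", path))
    rows
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  records_main <- NULL
  if (any(c("main", "dose", "descriptives") %in% analyses))
    records_main <- stage("build_analytic_dataset", build_analytic_dataset(
      db, vocabulary, role_policy = "any_role",
      population_filter = "whole_database"))

  if ("main" %in% analyses)
    tables$signal_table <- stage("main", emit(
      signal_table(records_main), "signal_table.csv", "signal_table"))
  if ("suspect_only" %in% analyses) {
    rec <- stage("suspect_only", build_analytic_dataset(
      db, vocabulary, role_policy = "suspect_only",
      population_filter = "whole_database"))
    tables$signal_table_suspect_only <- stage("suspect_only", emit(
      signal_table(rec), "signal_table_suspect_only.csv", "signal_table"))
  }
  if ("n06a_population" %in% analyses) {
    rec <- stage("n06a_population", build_analytic_dataset(
      db, vocabulary, role_policy = "any_role",
      population_filter = "antidepressant_only"))
    tables$signal_table_n06a <- stage("n06a_population", emit(
      signal_table(rec), "signal_table_n06a.csv", "signal_table"))
  }
  if ("dose" %in% analyses)
    tables$dose_table <- stage("dose", emit(
      dose_table(records_main), "dose_table.csv", "dose_table"))
  if ("descriptives" %in% analyses) {
    tables$cohort_summary <- stage("descriptives", emit(
      summarize_cohort(case_cohort(db, vocabulary)),
      "cohort_summary.csv", "cohort_summary"))
    tables$tto_table <- stage("descriptives", emit(
      tto_table(db, vocabulary), "tto_table.csv", "tto_table"))
    tables$challenge_table <- stage("descriptives", emit(
      challenge_table(db, vocabulary), "challenge_table.csv",
      "challenge_table"))
  }

  n_tests <- sum(grepl("^signal_table", names(tables))) *
    (length(vocabulary$target_drugs) + 1)
  manifest <- list(
    package = "pvror",
    version = as.character(packageVersion("pvror")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    analyses = as.list(analyses),
    input = list(n_reports = nrow(db$reports),
                 n_drug_entries = nrow(db$drugs),
                 n_reactions = nrow(db$reactions),
                 reports_fingerprint = fingerprint(db$reports),
                 drugs_fingerprint = fingerprint(db$drugs),
                 reactions_fingerprint = fingerprint(db$reactions),
                 vocabulary_fingerprint = fingerprint(unclass(vocabulary))),
    n_disproportionality_tests = n_tests,
    multiplicity_correction = "none",
    tables = lapply(tables, nrow)
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(tables)
}

#' Simulation-based calibration of the pipeline
#'
#' Repeatedly generates a synthetic database from `config` (one derived seed
#' per replicate) and runs the case/non-case analysis on it, recording per
#' drug and replicate the contingency cells, crude ROR and CI, the signal
#' flag, optionally the adjusted ROR, the planted odds ratio, and whether the
#' crude CI covers it. The attached `"summary"` attribute reports the
#' empirical signal rate, CI coverage, and mean crude/adjusted estimates per
#' drug.
#'
#' @param config a [synthetic_config()].
#' @param n_replicates number of simulated databases (>= 1).
#' @param seed integer; replicate r uses a seed derived from `seed` and `r`.
#' @param adjust fit the adjusted model per replicate (set `FALSE` for large
#'   crude-only sweeps).
#' @return data frame with one row per replicate x drug; attribute
#'   `"summary"` holds the per-drug calibration summary.
#' @export
simulate_and_validate <- function(config, n_replicates, seed = config$seed,
                                  adjust = TRUE) {
  stopifnot(inherits(config, "synthetic_config"), n_replicates >= 1)
  vocab <- synthetic_vocabulary(config)
  specs <- config$drug_specs
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- mix_seed(seed, r)
    db <- generate_database(cfg)
    rec <- build_analytic_dataset(db, vocab)
    drug_rows <- lapply(seq_len(nrow(specs)), function(j) {
      drug <- specs$drug[j]
      tab <- contingency(rec, drug)
      crude <- compute_ror(tab)
      planted <- exp(specs$log_or[j])
      adj <- if (adjust) adjusted_ror(rec, drug) else
        list(aror = NA_real_, aci_low = NA_real_, aci_high = NA_real_)
      data.frame(replicate = r, drug = drug, planted_or = planted,
                 a = tab$a, b = tab$b, c = tab$c, d = tab$d,
                 ror = crude$ror, ci_low = crude$ci_low,
                 ci_high = crude$ci_high,
                 signal = signal_flag(crude$ror, crude$ci_low),
                 covered = !is.na(crude$ci_low) & crude$ci_low <= planted &
                   planted <= crude$ci_high,
                 aror = adj$aror, aci_low = adj$aci_low,
                 aci_high = adj$aci_high,
                 stringsAsFactors = FALSE)
    })
    rows[[r]] <- do.call(rbind, drug_rows)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  summ <- do.call(rbind, lapply(split(out, out$drug), function(g) {
    data.frame(drug = g$drug[1], planted_or = g$planted_or[1],
               n_replicates = nrow(g),
               signal_rate = mean(g$signal, na.rm = TRUE),
               coverage = mean(g$covered, na.rm = TRUE),
               mean_ror = mean(g$ror, na.rm = TRUE),
               mean_aror = mean(g$aror, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  attr(out, "summary") <- summ
  out
}
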