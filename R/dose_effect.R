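# Median-split dose-effect analysis and linear trend test.

#' Median daily dose among exposed records
#'
#' Median over the drug's exposed analytic records (cases and non-cases) with
#' a recorded daily dose; with an even count, the mean of the two central
#' values. `NA` when no exposed record carries a dose (the dose analysis is
#' then skipped for that drug).
#'
#' @param records an `analytic_records` data frame.
#' @param drug target drug label.
#' @return median dose in mg, or `NA`.
#' @export
median_dose <- function(records, drug) {
  exp <- exposure_column(records, drug)
  doses <- records[[paste0("dose_", drug)]][exp]
  doses <- doses[!is.na(doses)]
  if (!length(doses)) return(NA_real_)
  median(doses)
}

empty_stratum <- function(a = NA_integer_, b = NA_integer_) {
  list(a = a, b = b, ror = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
       aror = NA_real_, aci_low = NA_real_, aci_high = NA_real_)
}

stratum_estimates <- function(records, drug, in_stratum, adjust = TRUE) {
  exp_col <- exposure_column(records, drug)
  keep <- in_stratum | !exp_col     # stratum exposed + all unexposed
  sub <- records[keep, , drop = FALSE]
  exp_sub <- in_stratum[keep]
  a <- sum(exp_sub & sub$is_case)
  b <- sum(exp_sub & !sub$is_case)
  cc <- sum(!exp_sub & sub$is_case)
  dd <- sum(!exp_sub & !sub$is_case)
  crude <- compute_ror(a, b, cc, dd)
  out <- list(a = a, b = b, ror = crude$ror, ci_low = crude$ci_low,
              ci_high = crude$ci_high, aror = NA_real_, aci_low = NA_real_,
              aci_high = NA_real_)
  if (adjust && a > 0) {
    x <- adjustment_design(sub, exp_sub)
    fit <- fit_logistic(as.numeric(sub$is_case), x)
    if (fit$converged && !is.na(fit$se["exposure"])) {
      bhat <- fit$coefficients["exposure"]; s <- fit$se["exposure"]
      out$aror <- unname(exp(bhat))
      out$aci_low <- unname(exp(bhat - Z975 * s))
      out$aci_high <- unname(exp(bhat + Z975 * s))
    }
  }
  out
}

#' Linear trend test across dose strata
#'
#' Ordinary least-squares regression of case status (0/1) on the stratum
#' indicator (0 = dose at or below the median, 1 = above) over the drug's
#' exposed, dose-recorded records; returns the two-sided p-value of the
#' slope. Undefined when the stratum indicator has no variance.
#'
#' @param records an `analytic_records` data frame.
#' @param drug target drug label.
#' @return p-value in `[0, 1]`, or `NA`.
#' @export
trend_test <- function(records, drug) {
  exp <- exposure_column(records, drug)
  dose <- records[[paste0("dose_", drug)]]
  keep <- exp & !is.na(dose)
  if (!any(keep)) return(NA_real_)
  med <- median_dose(records, drug)
  y <- as.numeric(records$is_case[keep])
  x <- as.numeric(dose[keep] > med)
  if (length(unique(x)) < 2) return(NA_real_)
  fit <- summary(lm(y ~ x))
  unname(fit$coefficients["x", "Pr(>|t|)"])
}

#' Dose-stratified disproportionality analysis for one drug
#'
#' Splits the drug's exposed, dose-recorded records at the median daily dose
#' (ties to the low stratum), computes crude and adjusted RORs per stratum
#' against the same unexposed comparator cells as the main analysis, and the
#' linear trend test. The analysis is only evaluated when each stratum holds
#' at least 5 exposed cases; otherwise all stratum estimates and the trend
#' p-value are `NA`.
#'
#' @param records an `analytic_records` data frame.
#' @param drug target drug label.
#' @param adjust compute adjusted per-stratum estimates.
#' @return list of class `dose_effect_result`: `drug`, `median_dose_mg`,
#'   `low`, `high` (each with `a`, `b`, `ror`, `ci_low`, `ci_high`, `aror`,
#'   `aci_low`, `aci_high`), `trend_p`, `evaluated`.
#' @export
stratified_analysis <- function(records, drug, adjust = TRUE) {
  med <- median_dose(records, drug)
  exp <- exposure_column(records, drug)
  dose <- records[[paste0("dose_", drug)]]
  if (is.na(med)) {
    return(structure(list(drug = drug, median_dose_mg = NA_real_,
                          low = empty_stratum(), high = empty_stratum(),
                          trend_p = NA_real_, evaluated = FALSE),
                     class = "dose_effect_result"))
  }
  low_in <- exp & !is.na(dose) & dose <= med
  high_in <- exp & !is.na(dose) & dose > med
  a_low <- sum(low_in & records$is_case)
  a_high <- sum(high_in & records$is_case)
  evaluated <- a_low >= 5 && a_high >= 5
  if (!evaluated) {
    return(structure(list(drug = drug, median_dose_mg = med,
                          low = empty_stratum(a_low, sum(low_in & !records$is_case)),
                          high = empty_stratum(a_high, sum(high_in & !records$is_case)),
                          trend_p = NA_real_, evaluated = FALSE),
                     class = "dose_effect_result"))
  }
  structure(list(drug = drug, median_dose_mg = med,
                 low = stratum_estimates(records, drug, low_in, adjust),
                 high = stratum_estimates(records, drug, high_in, adjust),
                 trend_p = trend_test(records, drug),
                 evaluated = TRUE),
            class = "dose_effect_result")
}

#' Dose-effect table over all target drugs
#'
#' One row per drug with both strata's crude/adjusted RORs and CIs, the
#' trend p-value and the evaluation flag, in the `dose_table` schema.
#'
#' @param records an `analytic_records` data frame.
#' @param drugs drug labels (default: all drugs of the dataset).
#' @param adjust compute adjusted per-stratum estimates.
#' @return data frame in the `dose_table` schema.
#' @export
dose_table <- function(records, drugs = NULL, adjust = TRUE) {
  drugs <- sort(drugs %||% attr(records, "drugs"))
  rows <- lapply(drugs, function(drug) {
    r <- stratified_analysis(records, drug, adjust = adjust)
    data.frame(drug = drug, median_dose_mg = r$median_dose_mg,
               low_a = r$low$a, low_b = r$low$b, low_ror = r$low$ror,
               low_ci_low = r$low$ci_low, low_ci_high = r$low$ci_high,
               low_aror = r$low$aror, low_aci_low = r$low$aci_low,
               low_aci_high = r$low$aci_high,
               high_a = r$high$a, high_b = r$high$b, high_ror = r$high$ror,
               high_ci_low = r$high$ci_low, high_ci_high = r$high$ci_high,
               high_aror = r$high$aror, high_aci_low = r$high$aci_low,
               high_aci_high = r$high$aci_high,
               trend_p = r$trend_p, evaluated = r$evaluated,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
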