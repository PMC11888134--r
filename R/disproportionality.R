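# Crude and adjusted reporting odds ratios, the signal rule, and the IRLS
# logistic fitter behind the adjusted estimates.

#' Crude reporting odds ratio with Woolf confidence interval
#'
#' ROR = (a d)/(b c), with a 95% CI on the log scale:
#' exp(ln ROR +- 1.959964 sqrt(1/a + 1/b + 1/c + 1/d)). If any cell is zero
#' while the drug has at least one exposed report (`a + b > 0`), the
#' Haldane-Anscombe continuity correction adds 0.5 to all four cells first.
#' With no exposed cases (`a = 0`) or no exposed reports at all the estimate
#' is undefined and all three values are `NA` (rendered `"NA"` in tables).
#'
#' @param a,b,c,d cell counts: exposed cases, exposed non-cases, unexposed
#'   cases, unexposed non-cases. `a` may also be a `contingency_table`.
#' @return list with `ror`, `ci_low`, `ci_high`.
#' @export
compute_ror <- function(a, b = NULL, c = NULL, d = NULL) {
  if (inherits(a, "contingency_table")) {
    tab <- a; a <- tab$a; b <- tab$b; c <- tab$c; d <- tab$d
  }
  cells <- c(a, b, c, d)
  if (length(cells) != 4 || any(is.na(cells)))
    stop("domain error: four cell counts required")
  if (any(cells < 0))
    stop("domain error: cell counts must be non-negative")
  if (a == 0 || (a + b) == 0)
    return(list(ror = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
  if (any(cells == 0)) cells <- cells + 0.5
  lror <- log(cells[1]) + log(cells[4]) - log(cells[2]) - log(cells[3])
  se <- sqrt(sum(1 / cells))
  list(ror = exp(lror),
       ci_low = exp(lror - Z975 * se),
       ci_high = exp(lror + Z975 * se))
}

#' Disproportionality signal rule
#'
#' A safety signal is flagged when the ROR exceeds 1 and the lower 95% CI
#' bound exceeds 1, both strictly. Undefined inputs give an undefined flag.
#'
#' @param ror point estimate.
#' @param ci_low lower 95% confidence bound.
#' @return logical (`NA` when either input is `NA`).
#' @export
signal_flag <- function(ror, ci_low) {
  ifelse(is.na(ror) | is.na(ci_low), NA, ror > 1 & ci_low > 1)
}

#' Maximum-likelihood logistic regression by IRLS
#'
#' Fits case status on a complete design matrix (including any intercept
#' column) by iteratively reweighted least squares. Convergence is declared
#' when the largest absolute coefficient change falls below `tol` (default
#' 1e-8) within `max_iter` (default 50) iterations. Standard errors come from
#' the inverse observed information. Complete or quasi-complete separation
#' (a fitted probability within 1e-10 of 0 or 1 alongside a diverging
#' coefficient) is flagged; downstream adjusted estimates then render `"NA"`.
#'
#' @param y 0/1 (or logical) outcome vector.
#' @param x numeric design matrix, `length(y)` rows, full rank.
#' @param tol convergence tolerance on coefficient changes.
#' @param max_iter iteration cap.
#' @return list with `coefficients`, `se`, `converged`, `separation`,
#'   `n_iter`.
#' @export
fit_logistic <- function(y, x, tol = 1e-8, max_iter = 50L) {
  y <- as.numeric(y)
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  p <- ncol(x)
  beta <- rep(0, p)
  converged <- FALSE
  iter <- 0L
  info <- NULL
  mu <- rep(0.5, length(y))
  for (iter in seq_len(max_iter)) {
    eta <- as.vector(x %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    xw <- x * w
    info <- crossprod(x, xw)
    step <- tryCatch(solve(info, crossprod(xw, z)),
                     error = function(e) NULL)
    if (is.null(step)) break
    delta <- max(abs(step - beta))
    beta <- as.vector(step)
    if (delta < tol) { converged <- TRUE; break }
  }
  eta <- as.vector(x %*% beta)
  mu <- plogis(eta)
  boundary <- any(mu < 1e-10 | mu > 1 - 1e-10)
  separation <- boundary && max(abs(beta)) > 10
  se <- rep(NA_real_, p)
  if (!is.null(info)) {
    vc <- tryCatch(solve(info), error = function(e) NULL)
    if (!is.null(vc)) se <- sqrt(diag(vc))
  }
  names(beta) <- colnames(x)
  names(se) <- colnames(x)
  list(coefficients = beta, se = se,
       converged = converged && !separation,
       separation = separation, n_iter = iter)
}

# design matrix for the adjustment model: intercept, exposure, age dummies
# (reference 18-44), sex dummies (reference female; unknown kept as its own
# level), antihypertensive flag, inducer flag. Constant covariate columns
# (levels absent from the data) are dropped.
adjustment_design <- function(records, exposure) {
  n <- nrow(records)
  cols <- list("(Intercept)" = rep(1, n), exposure = as.numeric(exposure))
  for (band in AGE_BANDS[-1])
    cols[[paste0("age_", band)]] <- as.numeric(records$age_group == band)
  for (s in c("male", "unknown"))
    cols[[paste0("sex_", s)]] <- as.numeric(records$sex == s)
  cols$antihypertensive <- as.numeric(records$has_antihypertensive)
  cols$inducer <- as.numeric(records$has_hypertensive_inducer)
  x <- do.call(cbind, cols)
  keep <- c(TRUE, TRUE, apply(x[, -(1:2), drop = FALSE], 2,
                              function(v) length(unique(v)) > 1))
  x[, keep, drop = FALSE]
}

#' Covariate-adjusted reporting odds ratio
#'
#' Fits case status on the exposure indicator plus age-band dummies
#' (reference 18-44), sex dummies (reference female, unknown retained as its
#' own level), the concurrent-antihypertensive flag and the
#' hypertension-inducing-drug flag, over the identical record set as the
#' crude analysis. The aROR is the exponentiated exposure coefficient with a
#' Wald 95% CI. Degenerate covariates (constant in the data) are dropped, so
#' with all covariates degenerate the model reduces to the crude 2x2 fit.
#' Non-convergence or separation yields `NA`s.
#'
#' @param records an `analytic_records` data frame.
#' @param drug target drug label or `"class"`.
#' @return list with `aror`, `aci_low`, `aci_high`, `converged`.
#' @export
adjusted_ror <- function(records, drug) {
  exposure <- exposure_column(records, drug)
  if (!any(exposure & records$is_case))
    return(list(aror = NA_real_, aci_low = NA_real_, aci_high = NA_real_,
                converged = FALSE))
  x <- adjustment_design(records, exposure)
  fit <- fit_logistic(as.numeric(records$is_case), x)
  if (!fit$converged || is.na(fit$se["exposure"]))
    return(list(aror = NA_real_, aci_low = NA_real_, aci_high = NA_real_,
                converged = FALSE))
  b <- fit$coefficients["exposure"]
  s <- fit$se["exposure"]
  list(aror = unname(exp(b)),
       aci_low = unname(exp(b - Z975 * s)),
       aci_high = unname(exp(b + Z975 * s)),
       converged = TRUE)
}

#' Per-drug signal table
#'
#' One row per target drug (alphabetical) plus a pooled `"class"` row last:
#' exposed case/non-case counts, crude ROR with Woolf 95% CI, adjusted ROR
#' with Wald 95% CI, and the signal flag (on the crude estimate, the
#' screening statistic). The pooled row's `a` counts records exposed to at
#' least one target drug, not the sum of per-drug counts.
#'
#' @param records an `analytic_records` data frame.
#' @param drugs drug labels (default: all drugs of the dataset).
#' @param adjust compute adjusted estimates (set `FALSE` to skip the
#'   logistic fits in large calibration sweeps).
#' @return data frame in the `signal_table` schema.
#' @export
signal_table <- function(records, drugs = NULL, adjust = TRUE) {
  drugs <- sort(drugs %||% attr(records, "drugs"))
  rows <- lapply(c(drugs, "class"), function(drug) {
    tab <- contingency(records, drug)
    crude <- compute_ror(tab)
    adj <- if (adjust) adjusted_ror(records, drug) else
      list(aror = NA_real_, aci_low = NA_real_, aci_high = NA_real_)
    data.frame(drug = drug, a = tab$a, b = tab$b,
               ror = crude$ror, ci_low = crude$ci_low, ci_high = crude$ci_high,
               aror = adj$aror, aci_low = adj$aci_low, aci_high = adj$aci_high,
               signal = signal_flag(crude$ror, crude$ci_low),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
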