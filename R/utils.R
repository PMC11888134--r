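# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# 97.5% normal quantile used for all Woolf/Wald intervals
Z975 <- 1.959964

AGE_BANDS <- c("18-44", "45-64", "65-74", "75plus")
AGE_LEVELS <- c(AGE_BANDS, "unknown")
SEX_LEVELS <- c("female", "male", "unknown")
SERIOUS_LEVELS <- c("yes", "no", "unknown")
ROLE_LEVELS <- c("suspect", "concomitant", "interacting")
DECHALLENGE_LEVELS <- c("positive", "negative", "unknown")
RECHALLENGE_LEVELS <- c("positive", "negative", "not_done", "unknown")
CRITERIA_LEVELS <- c("hospitalization", "congenital_anomaly", "death",
                     "disabling", "life_threatening", "other")

#' Canonicalize reaction terms
#'
#' Term comparison throughout the package is exact-string after trimming
#' whitespace and case-folding; there is no hierarchy traversal.
#' Canonicalization is idempotent.
#'
#' @param x character vector of terms.
#' @return canonicalized character vector.
#' @export
canonical_term <- function(x) tolower(trimws(x))

# round half away from zero (printed tables use conventional rounding,
# not banker's rounding)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# prefix match of drug codes against an ATC code set (a set entry such as
# "C02" matches every code in that class)
atc_match <- function(codes, code_set) {
  codes[is.na(codes)] <- ""
  out <- rep(FALSE, length(codes))
  for (s in code_set) out <- out | startsWith(codes, s)
  out
}

# deterministic per-component RNG sub-seeds: streams are split per component
# (covariates, exposures, outcomes, doses, ...) so that adding a drug to a
# config does not perturb the draws of other components
mix_seed <- function(...) {
  parts <- as.numeric(c(...))
  h <- 104729
  for (p in parts) h <- (h * 69069 + abs(p) + 1) %% 2147483647
  as.integer(h)
}

code_hash <- function(x) {
  u <- utf8ToInt(x)
  sum(u * seq_along(u)) %% 999983
}

# map values not in `levels` to `fallback`
coerce_enum <- function(x, levels, fallback = "unknown") {
  x <- trimws(as.character(x))
  x[is.na(x) | x == "" | !(x %in% levels)] <- fallback
  x
}

as_iso_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  x[!is.na(x) & trimws(x) == ""] <- NA_character_
  as.Date(x, format = "%Y-%m-%d")
}
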