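#' @importFrom stats pnorm qnorm rbinom rmultinom runif setNames uniroot
#' @importFrom utils head
NULL

#' Closed category sets of the analysis
#'
#' `GLP1_DRUGS`: codes of the seven GLP-1 receptor agonists (albiglutide,
#' dulaglutide, exenatide, liraglutide, lixisenatide, semaglutide,
#' tirzepatide). `POOLED_CODE`: pseudo-drug code for the pooled group of all
#' comparators. `HLT_LEVELS`: the four analysis high level terms in display
#' order. `OUTCOME_LEVELS`: the seven case-outcome categories.
#' `STRAT_DIMENSIONS`: the five stratification dimensions of the
#' characteristics tables.
#'
#' @name enums
NULL

#' @rdname enums
#' @export
GLP1_DRUGS <- c("ALB", "DUL", "EXE", "LIR", "LIX", "SEM", "TIR")

#' @rdname enums
#' @export
POOLED_CODE <- "ALL_OTHER"

#' @rdname enums
#' @export
HLT_LEVELS <- c("modified_dose", "overdose", "underdose", "off_label_use")

# "modified dose" and "improper dose" are the same group under two names.
HLT_DISPLAY <- c(
  modified_dose = "modified dose (improper dose)",
  overdose      = "overdose",
  underdose     = "underdose",
  off_label_use = "off-label use"
)

#' @rdname enums
#' @export
OUTCOME_LEVELS <- c(
  "fatal", "not_recovered", "recovered_with_sequelae",
  "recovering", "recovered", "not_specified", "unknown"
)

# Stratification dimensions and their closed level sets.
AGE_LEVELS    <- c("NS", "m0_1", "m2_y2", "y3_11", "y12_17", "y18_64", "y65_85", "over85")
SEX_LEVELS    <- c("female", "male", "NS")
REGION_LEVELS <- c("EEA", "non_EEA", "NS")
REPORTER_LEVELS    <- c("HP", "NHP", "NS")
SERIOUSNESS_LEVELS <- c("serious", "non_serious", "NS")

#' @rdname enums
#' @export
STRAT_DIMENSIONS <- c("age", "sex", "region", "reporter", "seriousness")

strat_levels <- function(dimension) {
  switch(dimension,
    age = AGE_LEVELS,
    sex = SEX_LEVELS,
    region = REGION_LEVELS,
    reporter = REPORTER_LEVELS,
    seriousness = SERIOUSNESS_LEVELS,
    stop("unknown stratification dimension: ", dimension)
  )
}

#' Round half away from zero at a fixed number of decimals
#'
#' Commercial ("half-up") rounding, as used for every printed percentage and
#' ratio in the outputs; base [round()] uses round-half-to-even and would
#' disagree on exact .5 ties.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Normalize a preferred-term label for matching: trim, collapse internal
# whitespace, lower-case.
normalize_term <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

assert_drug_code <- function(drug) {
  if (!is.character(drug) || length(drug) != 1L || !nzchar(drug)) {
    stop("`drug` must be a single non-empty drug code", call. = FALSE)
  }
  invisible(drug)
}
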