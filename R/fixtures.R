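#' Packaged published summary tables
#'
#' The package bundles the published per-drug summary counts so the
#' descriptive layer can be exercised without the (undeposited) source
#' extract: stratified ICSR counts with their printed one-decimal
#' percentages, the published reporting odds ratios with confidence
#' intervals and stated signal directions, and the related-search-query
#' table.
#'
#' @name fixtures
NULL

fixture_path <- function(name) {
  system.file("extdata", name, package = "glp1signal", mustWork = TRUE)
}

#' Published stratified ICSR counts
#'
#' One row per (drug, dimension, level); `dimension = "total"` rows carry the
#' per-drug ICSR totals (SEM 21,012; ALB 384; DUL 17,332; EXE 12,926;
#' LIR 18,149; LIX 412; TIR 2,333; pooled comparators 51,536).
#' `pct_printed` is the published one-decimal percentage, reproduced
#' verbatim (including one cell, TIR age 12-17, whose printed 0.0 is
#' inconsistent with its own printed count; see the methods vignette).
#'
#' @return tibble `drug`, `dimension`, `level`, `count`, `pct_printed`.
#' @export
table3_counts <- function() {
  readr::read_csv(fixture_path("table3_counts.csv"), col_types = readr::cols(
    drug = readr::col_character(),
    dimension = readr::col_character(),
    level = readr::col_character(),
    count = readr::col_integer(),
    pct_printed = readr::col_double()
  ), progress = FALSE)
}

#' Per-drug ICSR totals from the packaged counts
#'
#' @param include_pooled keep the pooled `ALL_OTHER` row (default `FALSE`,
#'   since the pooled total duplicates the six comparators).
#' @return named integer vector of ICSR totals.
#' @export
fixture_totals <- function(include_pooled = FALSE) {
  tab <- table3_counts()
  tot <- tab[tab$dimension == "total", ]
  if (!include_pooled) tot <- tot[tot$drug != POOLED_CODE, ]
  setNames(tot$count, tot$drug)
}

#' Published reporting odds ratios with stated directions
#'
#' The ROR/95% CI pairs printed for the semaglutide-versus-comparator
#' disproportionality analysis, with the direction stated alongside each
#' (`higher`/`lower` probability of reporting).
#'
#' @return tibble `hlt`, `comparator`, `ror`, `ci_low`, `ci_high`,
#'   `direction`.
#' @export
reported_rors <- function() {
  readr::read_csv(fixture_path("reported_ror.csv"), col_types = readr::cols(
    hlt = readr::col_character(),
    comparator = readr::col_character(),
    ror = readr::col_double(),
    ci_low = readr::col_double(),
    ci_high = readr::col_double(),
    direction = readr::col_character()
  ), progress = FALSE)
}

#' Published related search queries per drug
#'
#' The weight-loss and side-effect related queries reported among the top
#' searches for each GLP-1 receptor agonist.
#'
#' @return tibble `drug`, `term`.
#' @export
related_queries <- function() {
  readr::read_csv(fixture_path("related_queries.csv"), col_types = readr::cols(
    drug = readr::col_character(),
    term = readr::col_character()
  ), progress = FALSE)
}
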