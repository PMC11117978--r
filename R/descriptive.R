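#' Descriptive analysis of ICSR datasets
#'
#' Reproduces the descriptive layer of the analysis: per-drug shares of all
#' reports, ADR-per-report ratios, stratified characteristics tables,
#' SOC distributions, the four HLT reporting frequencies, and outcome
#' distributions within an HLT. Percentages over case strata use the drug's
#' ICSR total as denominator; SOC/HLT/outcome percentages use ADR-record
#' totals. All printed values are rounded half-up at the conventional
#' precision (1 decimal for percentages, 2 for ADR-per-ICSR ratios).
#'
#' @name descriptive
NULL

#' Shares of total ICSRs per drug
#'
#' @param per_drug_totals named non-negative numeric vector of ICSR totals.
#' @return named numeric vector of percentage shares, rounded half-up to one
#'   decimal. Unrounded shares sum to 100 exactly.
#' @export
icsr_shares <- function(per_drug_totals) {
  if (length(per_drug_totals) == 0L || any(per_drug_totals < 0)) {
    stop("totals must be non-negative and non-empty", call. = FALSE)
  }
  grand <- sum(per_drug_totals)
  if (grand == 0) stop("all totals are zero; shares undefined", call. = FALSE)
  round_half_up(per_drug_totals / grand * 100, 1)
}

#' ADR records per ICSR for one drug
#'
#' @param ds an `icsr_dataset`.
#' @param drug a study drug code, or `"ALL_OTHER"` for the pooled group of
#'   all study drugs except `pool_excluding`.
#' @param pool_excluding drug excluded from the pooled group (default SEM).
#' @return the ratio of ADR records to ICSRs, rounded half-up to 2 decimals.
#' @export
adr_per_icsr <- function(ds, drug, pool_excluding = "SEM") {
  stopifnot(inherits(ds, "icsr_dataset"))
  drugs <- if (identical(drug, POOLED_CODE)) setdiff(GLP1_DRUGS, pool_excluding) else drug
  ids <- case_ids_for(ds, drugs)
  if (length(ids) == 0L) {
    stop("no cases for drug ", drug, "; ratio undefined", call. = FALSE)
  }
  n_adr <- sum(ds$adrs$case_id %in% ids)
  round_half_up(n_adr / length(ids), 2)
}

# Shared core: counts per stratum level -> table with half-up percentages.
strat_percentages <- function(counts, levels) {
  counts <- counts[levels]
  counts[is.na(counts)] <- 0L
  total <- sum(counts)
  pct <- if (total > 0) round_half_up(counts / total * 100, 1) else rep(NA_real_, length(counts))
  tibble::tibble(level = levels, count = as.integer(counts), pct = unname(pct))
}

#' Stratified characteristics table for one drug
#'
#' Counts the drug's ICSRs by one stratification dimension (age group, sex,
#' geographic origin, reporter type, or seriousness). "Not specified" strata
#' stay in the denominator. `drug = "ALL_OTHER"` pools every study drug
#' except `pool_excluding`.
#'
#' @inheritParams adr_per_icsr
#' @param dimension one of `"age"`, `"sex"`, `"region"`, `"reporter"`,
#'   `"seriousness"`.
#' @return tibble with columns `dimension`, `level`, `count`, `pct`; counts
#'   partition the drug's ICSRs.
#' @export
characteristics_table <- function(ds, drug, dimension, pool_excluding = "SEM") {
  stopifnot(inherits(ds, "icsr_dataset"))
  if (!dimension %in% STRAT_DIMENSIONS) {
    stop("`dimension` must be one of: ", paste(STRAT_DIMENSIONS, collapse = ", "),
         call. = FALSE)
  }
  drugs <- if (identical(drug, POOLED_CODE)) setdiff(GLP1_DRUGS, pool_excluding) else drug
  ids <- case_ids_for(ds, drugs)
  cases <- ds$cases[ds$cases$case_id %in% ids, , drop = FALSE]
  column <- switch(dimension, age = "age_group", sex = "sex", region = "region",
                   reporter = "reporter", seriousness = "seriousness")
  levels <- strat_levels(dimension)
  counts <- table(factor(cases[[column]], levels = levels))
  out <- strat_percentages(setNames(as.integer(counts), names(counts)), levels)
  tibble::tibble(dimension = dimension, out)
}

#' Characteristics table from a printed-counts fixture
#'
#' Recomputes stratum percentages from per-level counts (e.g. the packaged
#' published counts loaded by [table3_counts()]), using the same rounding as
#' [characteristics_table()].
#'
#' @param counts tibble with columns `level` and `count` for one
#'   (drug, dimension) block.
#' @param dimension the stratification dimension of the block.
#' @return tibble with columns `dimension`, `level`, `count`, `pct`.
#' @export
characteristics_from_counts <- function(counts, dimension) {
  levels <- strat_levels(dimension)
  v <- setNames(counts$count, counts$level)
  tibble::tibble(dimension = dimension, strat_percentages(v, levels))
}

#' ADR distribution across system organ classes
#'
#' @inheritParams adr_per_icsr
#' @param vocab a `glp1_vocabulary`; every ADR's SOC must be in its
#'   `soc_list`.
#' @return tibble `soc`, `count`, `pct` (percent of the drug's total ADR
#'   records, half-up to 1 decimal), one row per SOC in `vocab$soc_list`.
#' @export
soc_distribution <- function(ds, drug, vocab = load_vocabulary(),
                             pool_excluding = "SEM") {
  stopifnot(inherits(ds, "icsr_dataset"))
  drugs <- if (identical(drug, POOLED_CODE)) setdiff(GLP1_DRUGS, pool_excluding) else drug
  adrs <- drug_adrs(ds, drugs)
  unknown <- setdiff(unique(adrs$soc), vocab$soc_list)
  if (length(unknown)) {
    stop("ADR with SOC outside the vocabulary: ",
         paste(head(unknown, 3), collapse = "; "), call. = FALSE)
  }
  total <- nrow(adrs)
  counts <- table(factor(adrs$soc, levels = vocab$soc_list))
  pct <- if (total > 0) round_half_up(as.numeric(counts) / total * 100, 1) else NA_real_
  tibble::tibble(soc = vocab$soc_list, count = as.integer(counts), pct = pct)
}

#' Reporting frequency of the four analysis HLTs
#'
#' Counts the drug's ADR records mapping to each of the four analysis HLTs;
#' ADRs outside the groups count only in the denominator (the drug's total
#' ADR records).
#'
#' @inheritParams soc_distribution
#' @return tibble `drug`, `hlt`, `adr_count`, `pct_of_total_adrs` (half-up to
#'   2 decimals), one row per HLT in display order.
#' @export
hlt_frequencies <- function(ds, drug, vocab = load_vocabulary(),
                            pool_excluding = "SEM") {
  stopifnot(inherits(ds, "icsr_dataset"))
  drugs <- if (identical(drug, POOLED_CODE)) setdiff(GLP1_DRUGS, pool_excluding) else drug
  adrs <- drug_adrs(ds, drugs)
  total <- nrow(adrs)
  hlt <- map_pt(vocab, adrs$pt)
  counts <- table(factor(hlt, levels = HLT_LEVELS))
  pct <- if (total > 0) round_half_up(as.numeric(counts) / total * 100, 2) else rep(0, length(HLT_LEVELS))
  tibble::tibble(
    drug = drug,
    hlt = HLT_LEVELS,
    adr_count = as.integer(counts),
    pct_of_total_adrs = as.numeric(pct)
  )
}

#' Outcome distribution of one HLT's ADRs
#'
#' Tallies the seven outcome categories over the ADR records of `drug` that
#' map to `hlt`, and reports the unfavorable fraction (fatal plus not
#' recovered/not resolved). For an empty HLT all counts are zero and
#' percentages are `NA`.
#'
#' @inheritParams soc_distribution
#' @param hlt one of the four analysis HLT codes.
#' @return list with elements `drug`, `hlt`, `table` (tibble `outcome`,
#'   `count`, `pct`, half-up to 1 decimal of the HLT's ADR count),
#'   `fatal_pct`, `not_recovered_pct`, and `unfavorable_pct`.
#' @export
outcome_distribution <- function(ds, drug, hlt, vocab = load_vocabulary(),
                                 pool_excluding = "SEM") {
  stopifnot(inherits(ds, "icsr_dataset"))
  if (!hlt %in% HLT_LEVELS) {
    stop("`hlt` must be one of: ", paste(HLT_LEVELS, collapse = ", "),
         call. = FALSE)
  }
  drugs <- if (identical(drug, POOLED_CODE)) setdiff(GLP1_DRUGS, pool_excluding) else drug
  adrs <- drug_adrs(ds, drugs)
  in_hlt <- adrs[!is.na(map_pt(vocab, adrs$pt)) & map_pt(vocab, adrs$pt) == hlt, , drop = FALSE]
  total <- nrow(in_hlt)
  counts <- table(factor(in_hlt$outcome, levels = OUTCOME_LEVELS))
  pct <- if (total > 0) round_half_up(as.numeric(counts) / total * 100, 1) else rep(NA_real_, length(OUTCOME_LEVELS))
  tab <- tibble::tibble(outcome = OUTCOME_LEVELS, count = as.integer(counts),
                        pct = as.numeric(pct))
  unfav <- function(oc) if (total > 0) round_half_up(sum(counts[oc]) / total * 100, 1) else NA_real_
  list(
    drug = drug, hlt = hlt, table = tab,
    fatal_pct = unfav("fatal"),
    not_recovered_pct = unfav("not_recovered"),
    unfavorable_pct = unfav(c("fatal", "not_recovered"))
  )
}
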