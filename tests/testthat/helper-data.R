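# Small in-code builders for hand-constructed datasets.

mk_cases <- function(ids, drugs = "SEM", combination = "", age = "y18_64",
                     sex = "female", region = "EEA", reporter = "HP",
                     seriousness = "serious", date = "2023-06-01") {
  tibble::tibble(
    case_id = ids, drugs = drugs, combination = combination,
    age_group = age, sex = sex, region = region, reporter = reporter,
    seriousness = seriousness, report_date = as.Date(date)
  )
}

mk_adrs <- function(ids, pt = "Nausea", soc = "Gastrointestinal disorders",
                    outcome = "recovered") {
  tibble::tibble(case_id = ids, pt = pt, soc = soc, outcome = outcome)
}

# One-call dataset: one case per id with one ADR each unless overridden.
mk_ds <- function(cases, adrs) new_icsr_dataset(cases, adrs)

# A small two-drug configuration derived from the default calibration,
# keeping only the named drugs at the given case counts.
shrink_config <- function(drugs_keep, n_cases, seed = 1L) {
  cfg <- default_config(scale = 0.1, seed = seed)
  counts <- setNames(rep(0L, length(cfg$case_counts)), names(cfg$case_counts))
  counts[drugs_keep] <- as.integer(n_cases)
  cfg$case_counts <- counts
  cfg
}
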