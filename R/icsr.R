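#' Individual Case Safety Report datasets
#'
#' A dataset holds spontaneous adverse-event reports (ICSRs) as two linked
#' tables: `cases` (one row per report: suspected drugs, demographics,
#' reporter, seriousness, report date) and `adrs` (one row per reported
#' adverse drug reaction: preferred term, system organ class, outcome).
#' Cases are the counting unit for characteristics tables; ADR records are
#' the counting unit for SOC/HLT frequencies and contingency tables.
#'
#' @name icsr_dataset
NULL

LISTING_COLUMNS <- c("case_id", "drug", "combination", "age_group", "sex",
                     "region", "reporter", "seriousness", "report_date",
                     "pt", "outcome")

split_codes <- function(x) strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE)

#' Construct an ICSR dataset
#'
#' @param cases tibble with columns `case_id`, `drugs` (";"-joined suspected
#'   drug codes), `combination` (";"-joined fixed-combination markers, may be
#'   empty), `age_group`, `sex`, `region`, `reporter`, `seriousness`
#'   (closed category sets), `report_date` (`Date`).
#' @param adrs tibble with columns `case_id`, `pt`, `soc`, `outcome`.
#' @param cutoff_date optional `Date`; when given, all cases must have
#'   `report_date <= cutoff_date`.
#' @return an object of class `icsr_dataset`.
#' @export
new_icsr_dataset <- function(cases, adrs, cutoff_date = NULL) {
  cases <- tibble::as_tibble(cases)
  adrs <- tibble::as_tibble(adrs)
  need_cases <- c("case_id", "drugs", "combination", "age_group", "sex",
                  "region", "reporter", "seriousness", "report_date")
  need_adrs <- c("case_id", "pt", "soc", "outcome")
  stopifnot(all(need_cases %in% names(cases)), all(need_adrs %in% names(adrs)))

  if (anyDuplicated(cases$case_id)) {
    stop("duplicate case_id in dataset: ",
         paste(unique(cases$case_id[duplicated(cases$case_id)]), collapse = ", "),
         call. = FALSE)
  }
  orphan <- setdiff(adrs$case_id, cases$case_id)
  if (length(orphan)) {
    stop("ADR records reference unknown case_id: ",
         paste(head(orphan, 3), collapse = ", "), call. = FALSE)
  }
  no_adr <- setdiff(cases$case_id, adrs$case_id)
  if (length(no_adr)) {
    stop("ICSR without any ADR record: ",
         paste(head(no_adr, 3), collapse = ", "), call. = FALSE)
  }
  check_enum <- function(values, levels, what) {
    bad <- setdiff(unique(values), levels)
    if (length(bad)) {
      stop("invalid ", what, " value(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  check_enum(cases$age_group, AGE_LEVELS, "age_group")
  check_enum(cases$sex, SEX_LEVELS, "sex")
  check_enum(cases$region, REGION_LEVELS, "region")
  check_enum(cases$reporter, REPORTER_LEVELS, "reporter")
  check_enum(cases$seriousness, SERIOUSNESS_LEVELS, "seriousness")
  check_enum(adrs$outcome, OUTCOME_LEVELS, "outcome")
  if (any(!nzchar(cases$drugs) | is.na(cases$drugs))) {
    stop("every case must carry at least one suspected drug", call. = FALSE)
  }
  if (!is.null(cutoff_date)) {
    cutoff_date <- as.Date(cutoff_date)
    if (any(cases$report_date > cutoff_date)) {
      stop("case report_date later than cutoff_date", call. = FALSE)
    }
  }
  structure(
    list(cases = cases[need_cases], adrs = adrs[need_adrs],
         cutoff_date = cutoff_date),
    class = "icsr_dataset"
  )
}

#' @export
print.icsr_dataset <- function(x, ...) {
  cat("<icsr_dataset>", nrow(x$cases), "ICSRs,", nrow(x$adrs), "ADR records")
  if (!is.null(x$cutoff_date)) cat("; cutoff", format(x$cutoff_date))
  cat("\n")
  invisible(x)
}

#' Number of ICSRs for a drug
#'
#' @param ds an `icsr_dataset`.
#' @param drug a drug code, or [POOLED_CODE]/`"ALL_OTHER"` handled by callers.
#' @return integer count of cases suspecting `drug`.
#' @export
n_cases <- function(ds, drug = NULL) {
  stopifnot(inherits(ds, "icsr_dataset"))
  if (is.null(drug)) return(nrow(ds$cases))
  sum(vapply(split_codes(ds$cases$drugs), function(d) drug %in% d, logical(1)))
}

# Case ids of cases suspecting any of `drugs`.
case_ids_for <- function(ds, drugs) {
  keep <- vapply(split_codes(ds$cases$drugs),
                 function(d) any(d %in% drugs), logical(1))
  ds$cases$case_id[keep]
}

# ADR records attached to cases suspecting any of `drugs`.
drug_adrs <- function(ds, drugs) {
  ds$adrs[ds$adrs$case_id %in% case_ids_for(ds, drugs), , drop = FALSE]
}

#' Read an ICSR line listing
#'
#' The line-listing dialect is a UTF-8 CSV with header
#' `case_id,drug,combination,age_group,sex,region,reporter,seriousness,report_date,pt,outcome`
#' and one row per reported reaction; `drug` and `combination` may carry
#' several ";"-joined entries, and rows sharing a `case_id` are assembled
#' into one ICSR with multiple ADR records. The number of ADR records in the
#' returned dataset equals the number of data rows. Identical
#' (case, PT, outcome) rows are retained as distinct ADRs: spontaneous
#' reporting can legitimately repeat a reaction.
#'
#' @param path path to the listing CSV.
#' @param vocab a `glp1_vocabulary` used to attach SOCs to registered PTs;
#'   unregistered PTs keep the SOC column of the file (or `NA`).
#' @return an `icsr_dataset`.
#' @export
read_line_listing <- function(path, vocab = load_vocabulary()) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing_cols <- setdiff(setdiff(LISTING_COLUMNS, "soc"), names(raw))
  if (length(missing_cols)) {
    stop("line listing is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- nrow(raw)
  fail <- function(what, rows) {
    stop("invalid ", what, " at data row(s) ",
         paste(head(rows, 5), collapse = ", "), call. = FALSE)
  }
  check_enum <- function(values, levels, what) {
    bad <- which(!(values %in% levels))
    if (length(bad)) fail(what, bad)
  }
  check_enum(raw$age_group, AGE_LEVELS, "age_group")
  check_enum(raw$sex, SEX_LEVELS, "sex")
  check_enum(raw$region, REGION_LEVELS, "region")
  check_enum(raw$reporter, REPORTER_LEVELS, "reporter")
  check_enum(raw$seriousness, SERIOUSNESS_LEVELS, "seriousness")
  check_enum(raw$outcome, OUTCOME_LEVELS, "outcome")
  dates <- as.Date(raw$report_date, format = "%Y-%m-%d")
  if (anyNA(dates)) fail("report_date", which(is.na(dates)))
  if (any(is.na(raw$pt) | !nzchar(raw$pt))) fail("pt", which(is.na(raw$pt) | !nzchar(raw$pt)))

  # case-level attributes must agree across a case's rows
  attrs <- c("drug", "combination", "age_group", "sex", "region",
             "reporter", "seriousness", "report_date")
  raw$combination[is.na(raw$combination)] <- ""
  per_case <- raw[!duplicated(raw$case_id), c("case_id", attrs)]
  consistent <- nrow(unique(raw[, c("case_id", attrs)])) == nrow(per_case)
  if (!consistent) {
    stop("case-level attributes differ across rows of the same case_id",
         call. = FALSE)
  }

  cases <- tibble::tibble(
    case_id = per_case$case_id,
    drugs = per_case$drug,
    combination = per_case$combination,
    age_group = per_case$age_group,
    sex = per_case$sex,
    region = per_case$region,
    reporter = per_case$reporter,
    seriousness = per_case$seriousness,
    report_date = as.Date(per_case$report_date)
  )
  soc <- if ("soc" %in% names(raw)) raw$soc else NA_character_
  vocab_soc <- pt_soc(vocab, raw$pt)
  adrs <- tibble::tibble(
    case_id = raw$case_id,
    pt = raw$pt,
    soc = ifelse(is.na(vocab_soc), soc, vocab_soc),
    outcome = raw$outcome
  )
  new_icsr_dataset(cases, adrs)
}

#' Write an ICSR dataset as a line listing
#'
#' @param ds an `icsr_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_line_listing <- function(ds, path) {
  stopifnot(inherits(ds, "icsr_dataset"))
  rows <- dplyr::left_join(ds$adrs, ds$cases, by = "case_id")
  out <- tibble::tibble(
    case_id = rows$case_id,
    drug = rows$drugs,
    combination = rows$combination,
    age_group = rows$age_group,
    sex = rows$sex,
    region = rows$region,
    reporter = rows$reporter,
    seriousness = rows$seriousness,
    report_date = format(rows$report_date, "%Y-%m-%d"),
    pt = rows$pt,
    soc = rows$soc,
    outcome = rows$outcome
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Apply the study's case-level filters
#'
#' Retains cases that (i) suspect at least one drug of `target_class`,
#' (ii) carry no excluded fixed-combination marker (the study excluded
#' liraglutide + insulin degludec combination reports), and (iii) were
#' reported on or before `cutoff` (the cutoff is inclusive). Filtering is
#' idempotent and leaves the input unmodified.
#'
#' @param ds an `icsr_dataset`.
#' @param target_class non-empty character vector of drug codes to retain.
#' @param excluded_combinations character vector of combination markers to
#'   drop (default `"LIR+degludec"`).
#' @param cutoff inclusive report-date cutoff (default 2024-03-31).
#' @return a filtered `icsr_dataset` with `cutoff_date` set.
#' @export
apply_study_filters <- function(ds, target_class = GLP1_DRUGS,
                                excluded_combinations = "LIR+degludec",
                                cutoff = as.Date("2024-03-31")) {
  stopifnot(inherits(ds, "icsr_dataset"))
  if (length(target_class) == 0L) {
    stop("`target_class` must contain at least one drug code", call. = FALSE)
  }
  cutoff <- as.Date(cutoff)
  drug_sets <- split_codes(ds$cases$drugs)
  comb_sets <- split_codes(ds$cases$combination)
  keep <- vapply(drug_sets, function(d) any(d %in% target_class), logical(1)) &
    !vapply(comb_sets, function(cb) any(cb %in% excluded_combinations), logical(1)) &
    ds$cases$report_date <= cutoff
  cases <- ds$cases[keep, , drop = FALSE]
  adrs <- ds$adrs[ds$adrs$case_id %in% cases$case_id, , drop = FALSE]
  new_icsr_dataset(cases, adrs, cutoff_date = cutoff)
}

#' Split a dataset into target and comparator subsets
#'
#' The target subset holds every case suspecting `target`; the comparator
#' subset holds every case suspecting at least one other study drug. A case
#' suspecting both appears in both subsets, mirroring drug-centric database
#' queries; the synthetic generator emits single-suspect cases, under which
#' the two subsets are disjoint and their union is the whole dataset.
#'
#' @param ds an `icsr_dataset`.
#' @param target a study drug code.
#' @param study_drugs the full set of study drug codes.
#' @return list with elements `target` and `comparator`, both `icsr_dataset`.
#' @export
split_by_drug <- function(ds, target, study_drugs = GLP1_DRUGS) {
  stopifnot(inherits(ds, "icsr_dataset"))
  if (!target %in% study_drugs) {
    stop("unknown target drug code: ", target, call. = FALSE)
  }
  subset_for <- function(drugs) {
    ids <- case_ids_for(ds, drugs)
    cases <- ds$cases[ds$cases$case_id %in% ids, , drop = FALSE]
    adrs <- ds$adrs[ds$adrs$case_id %in% ids, , drop = FALSE]
    if (nrow(cases) == 0L) {
      return(structure(list(cases = cases, adrs = adrs,
                            cutoff_date = ds$cutoff_date),
                       class = "icsr_dataset"))
    }
    new_icsr_dataset(cases, adrs, cutoff_date = ds$cutoff_date)
  }
  list(
    target = subset_for(target),
    comparator = subset_for(setdiff(study_drugs, target))
  )
}
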