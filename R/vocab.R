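#' MedDRA-style vocabulary for the dose-error and off-label analysis
#'
#' The analysis groups reported preferred terms (PTs) into four high level
#' terms (HLTs): modified dose (also displayed as "improper dose"), overdose,
#' underdose, and off-label use. The bundled study registry holds the 35 PTs
#' used for the GLP-1 receptor agonist analysis: 11 modified-dose, 5 overdose,
#' 10 underdose and 9 off-label-use terms, of which 8 had no reports in the
#' study window (`observed = FALSE`).
#'
#' Only term labels ship with the package; the licensed MedDRA dictionary is
#' not included. The system organ class (SOC) attached to each study PT is a
#' mock assignment consistent with the observation that dose and off-label
#' reactions are coded under "Injury, poisoning and procedural complications"
#' and "Surgical and medical procedures".
#'
#' @name vocabulary
NULL

# The 27 system organ class labels (labels only; no hierarchy content).
MEDDRA_SOCS <- c(
  "Blood and lymphatic system disorders",
  "Cardiac disorders",
  "Congenital, familial and genetic disorders",
  "Ear and labyrinth disorders",
  "Endocrine disorders",
  "Eye disorders",
  "Gastrointestinal disorders",
  "General disorders and administration site conditions",
  "Hepatobiliary disorders",
  "Immune system disorders",
  "Infections and infestations",
  "Injury, poisoning and procedural complications",
  "Investigations",
  "Metabolism and nutrition disorders",
  "Musculoskeletal and connective tissue disorders",
  "Neoplasms benign, malignant and unspecified (incl cysts and polyps)",
  "Nervous system disorders",
  "Pregnancy, puerperium and perinatal conditions",
  "Product issues",
  "Psychiatric disorders",
  "Renal and urinary disorders",
  "Reproductive system and breast disorders",
  "Respiratory, thoracic and mediastinal disorders",
  "Skin and subcutaneous tissue disorders",
  "Social circumstances",
  "Surgical and medical procedures",
  "Vascular disorders"
)

#' Construct a vocabulary object
#'
#' @param terms tibble with columns `pt` (character), `hlt` (one of the four
#'   analysis HLT codes or `NA` for terms outside the groups), `soc`
#'   (character SOC label) and `observed` (logical).
#' @param soc_list ordered character vector of SOC labels (at most 27).
#' @return an object of class `glp1_vocabulary`.
#' @export
new_vocabulary <- function(terms, soc_list = MEDDRA_SOCS) {
  stopifnot(is.data.frame(terms))
  required <- c("pt", "hlt", "soc", "observed")
  missing_cols <- setdiff(required, names(terms))
  if (length(missing_cols)) {
    stop("vocabulary terms are missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  terms <- tibble::as_tibble(terms)[required]
  terms$hlt[!is.na(terms$hlt) & terms$hlt == ""] <- NA_character_

  bad_hlt <- setdiff(unique(terms$hlt[!is.na(terms$hlt)]), HLT_LEVELS)
  if (length(bad_hlt)) {
    stop("unknown HLT label(s): ", paste(bad_hlt, collapse = ", "), call. = FALSE)
  }
  key <- normalize_term(terms$pt)
  if (anyDuplicated(key)) {
    dup <- unique(terms$pt[duplicated(key)])
    stop("duplicate preferred term(s) in vocabulary: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (length(soc_list) > 27L) {
    stop("soc_list may have at most 27 entries", call. = FALSE)
  }
  unknown_soc <- setdiff(unique(terms$soc), soc_list)
  if (length(unknown_soc)) {
    stop("term SOC not in soc_list: ", paste(unknown_soc, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(terms = terms, soc_list = soc_list),
    class = "glp1_vocabulary"
  )
}

#' @export
print.glp1_vocabulary <- function(x, ...) {
  n_by_hlt <- table(factor(x$terms$hlt, levels = HLT_LEVELS))
  cat("<glp1_vocabulary>", nrow(x$terms), "preferred terms;",
      sum(!is.na(x$terms$hlt)), "in the four analysis HLTs\n")
  for (h in HLT_LEVELS) cat("  ", HLT_DISPLAY[[h]], ": ", n_by_hlt[[h]], " PTs\n", sep = "")
  invisible(x)
}

#' Load a vocabulary from file or the bundled study registry
#'
#' @param source path to a vocabulary CSV (header `pt,hlt,soc,observed`), or
#'   `"study"` for the bundled 35-term registry.
#' @return a `glp1_vocabulary`.
#' @export
load_vocabulary <- function(source = "study") {
  if (identical(source, "study")) {
    source <- system.file("extdata", "study_vocabulary.csv",
                          package = "glp1signal", mustWork = TRUE)
  }
  if (!file.exists(source)) {
    stop("vocabulary file not found: ", source, call. = FALSE)
  }
  terms <- tryCatch(
    readr::read_csv(source, col_types = readr::cols(
      pt = readr::col_character(),
      hlt = readr::col_character(),
      soc = readr::col_character(),
      observed = readr::col_logical()
    ), progress = FALSE),
    error = function(e) stop("malformed vocabulary file '", source, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  problems <- readr::problems(terms)
  if (nrow(problems)) {
    stop("malformed vocabulary file '", source, "', first problem at line ",
         problems$row[1], ": ", problems$expected[1], call. = FALSE)
  }
  bad_row <- which(is.na(terms$pt) | !nzchar(terms$pt))
  if (length(bad_row)) {
    stop("malformed vocabulary file '", source, "': empty PT at data line ",
         bad_row[1], call. = FALSE)
  }
  new_vocabulary(terms)
}

#' Write a vocabulary to a CSV file
#'
#' Inverse of [load_vocabulary()]; a written vocabulary reloads
#' field-for-field.
#'
#' @param vocab a `glp1_vocabulary`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "glp1_vocabulary"))
  readr::write_csv(vocab$terms, path, progress = FALSE)
  invisible(path)
}

#' Map a preferred term to its analysis high level term
#'
#' Matching is case-insensitive after trimming and collapsing whitespace,
#' since spontaneous-report extracts vary in casing. A PT outside the four
#' analysis groups (or absent from the vocabulary) maps to `NA`: it counts as
#' an "other ADR" rather than being an error.
#'
#' @param vocab a `glp1_vocabulary`.
#' @param pt_name character vector of preferred-term labels.
#' @return character vector of HLT codes (`NA` where unmapped).
#' @export
map_pt <- function(vocab, pt_name) {
  stopifnot(inherits(vocab, "glp1_vocabulary"))
  idx <- match(normalize_term(pt_name), normalize_term(vocab$terms$pt))
  vocab$terms$hlt[idx]
}

#' Look up the SOC of a preferred term
#'
#' @inheritParams map_pt
#' @return character vector of SOC labels (`NA` where the PT is unregistered).
#' @export
pt_soc <- function(vocab, pt_name) {
  stopifnot(inherits(vocab, "glp1_vocabulary"))
  idx <- match(normalize_term(pt_name), normalize_term(vocab$terms$pt))
  vocab$terms$soc[idx]
}
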