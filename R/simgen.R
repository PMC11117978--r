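#' Seeded synthetic ICSR generator
#'
#' Generates line listings with the statistical structure the analysis
#' assumes: per-drug case volumes, zero-truncated Poisson ADR multiplicities
#' targeting the published ADR-per-ICSR ratios, independent per-ADR
#' Bernoulli membership in the four analysis HLTs at per-drug probabilities,
#' demographic strata drawn from the published per-drug distributions, and
#' per-(drug, HLT) outcome multinomials. True reporting odds ratios can be
#' planted by odds inversion, so the full generate -> count -> ROR pipeline
#' is testable without any database extract.
#'
#' @name simgen
NULL

# Non-study preferred terms used for ADRs outside the four analysis HLTs.
# Weights loosely follow the published semaglutide SOC shares (gastro-
# intestinal disorders dominating); they are renormalized at draw time.
NONSTUDY_PTS <- tibble::tibble(
  pt = c(
    "Nausea", "Vomiting", "Diarrhoea", "Abdominal pain", "Pancreatitis",
    "Fatigue", "Injection site pain", "Malaise",
    "Weight decreased", "Blood glucose increased",
    "Headache", "Dizziness",
    "Decreased appetite", "Hypoglycaemia",
    "Acute kidney injury", "Hypersensitivity", "Rash", "Dyspnoea",
    "Anxiety", "Palpitations", "Vision blurred", "Arthralgia",
    "Cholelithiasis", "Urinary tract infection", "Deep vein thrombosis",
    "Tinnitus", "Goitre", "Fall", "Device malfunction",
    "Thyroid neoplasm", "Exposure during pregnancy", "Drug abuser",
    "Congenital anomaly"
  ),
  soc = c(
    rep("Gastrointestinal disorders", 5),
    rep("General disorders and administration site conditions", 3),
    rep("Investigations", 2),
    rep("Nervous system disorders", 2),
    rep("Metabolism and nutrition disorders", 2),
    "Renal and urinary disorders", "Immune system disorders",
    "Skin and subcutaneous tissue disorders",
    "Respiratory, thoracic and mediastinal disorders",
    "Psychiatric disorders", "Cardiac disorders", "Eye disorders",
    "Musculoskeletal and connective tissue disorders",
    "Hepatobiliary disorders", "Infections and infestations",
    "Vascular disorders", "Ear and labyrinth disorders",
    "Endocrine disorders", "Injury, poisoning and procedural complications",
    "Product issues",
    "Neoplasms benign, malignant and unspecified (incl cysts and polyps)",
    "Pregnancy, puerperium and perinatal conditions", "Social circumstances",
    "Congenital, familial and genetic disorders"
  ),
  weight = c(
    0.10, 0.06, 0.05, 0.03, 0.02,
    0.04, 0.03, 0.03,
    0.05, 0.05,
    0.05, 0.04,
    0.03, 0.03,
    0.02, 0.02, 0.03, 0.02,
    0.02, 0.02, 0.01, 0.03,
    0.02, 0.02, 0.01,
    0.01, 0.01, 0.02, 0.01,
    0.01, 0.005, 0.005,
    0.005
  )
)

outcome_vector <- function(fatal = 0, not_recovered = 0.05) {
  rest <- 1 - fatal - not_recovered
  c(
    fatal = fatal,
    not_recovered = not_recovered,
    recovered_with_sequelae = rest * 0.02 / 0.82,
    recovering = rest * 0.15 / 0.82,
    recovered = rest * 0.40 / 0.82,
    not_specified = rest * 0.20 / 0.82,
    unknown = rest * 0.05 / 0.82
  )
}

#' Default simulator configuration
#'
#' Calibrated to the published study profile. Per-drug case counts are the
#' published ICSR totals scaled by `scale` (default 1/10, keeping full
#' pipeline runs fast); ADR-per-ICSR means are the published ratios
#' (SEM 1.99, ALB 2.85, DUL 1.90, EXE 2.72, LIR 1.81, LIX 2.08, TIR 1.98);
#' semaglutide HLT probabilities are the published frequencies (modified
#' dose 0.79%, overdose 0.59%, underdose 0.33%, off-label use 6.16%);
#' comparator HLT probabilities use published frequencies where printed and
#' are otherwise derived by odds inversion from the published RORs against
#' the semaglutide values (see the methods vignette); demographic strata use
#' the published per-drug distributions.
#'
#' @param scale factor applied to the published per-drug ICSR totals.
#' @param seed integer root seed; per-drug substreams are derived from it by
#'   stable hashing of the drug code, so adding a drug does not perturb the
#'   draws of the others.
#' @return an object of class `sim_config`.
#' @export
default_config <- function(scale = 0.1, seed = 1L) {
  totals <- fixture_totals()
  case_counts <- setNames(as.integer(round(totals * scale)), names(totals))

  adr_mean <- c(SEM = 1.99, ALB = 2.85, DUL = 1.90, EXE = 2.72,
                LIR = 1.81, LIX = 2.08, TIR = 1.98)

  hlt_probs <- list(
    # published frequencies
    SEM = c(modified_dose = 0.0079, overdose = 0.0059,
            underdose = 0.0033, off_label_use = 0.0616),
    # modified dose / overdose / off-label published or ROR-derived;
    # underdose and the ALB/LIX dose groups are uncalibrated defaults
    ALB = c(modified_dose = 0.0100, overdose = 0.0030,
            underdose = 0.0050, off_label_use = 0.01458),
    DUL = c(modified_dose = 0.0068, overdose = 0.0066,
            underdose = 0.0050, off_label_use = 0.00777),
    EXE = c(modified_dose = 0.0190, overdose = 0.00245,
            underdose = 0.0080, off_label_use = 0.02212),
    LIR = c(modified_dose = 0.0049, overdose = 0.00339,
            underdose = 0.0032, off_label_use = 0.02261),
    LIX = c(modified_dose = 0.0100, overdose = 0.0030,
            underdose = 0.0050, off_label_use = 0.00995),
    TIR = c(modified_dose = 0.0052, overdose = 0.00175,
            underdose = 0.0045, off_label_use = 0.0608)
  )

  tab <- table3_counts()
  demographic_probs <- lapply(setNames(nm = names(totals)), function(dg) {
    lapply(setNames(nm = STRAT_DIMENSIONS), function(dim) {
      block <- tab[tab$drug == dg & tab$dimension == dim, ]
      p <- setNames(block$count / sum(block$count), block$level)
      p[strat_levels(dim)]
    })
  })

  generic <- outcome_vector()
  outcome_probs <- lapply(setNames(nm = names(totals)), function(dg) {
    list(
      modified_dose = generic, overdose = generic, underdose = generic,
      off_label_use = generic, other = generic
    )
  })
  # published unfavorable-outcome points
  outcome_probs$SEM$modified_dose <- outcome_vector(0, 0.070)
  outcome_probs$SEM$overdose      <- outcome_vector(0.016, 0.037)
  outcome_probs$SEM$underdose     <- outcome_vector(0, 0.066)
  outcome_probs$SEM$off_label_use <- outcome_vector(0, 0.072)
  outcome_probs$LIR$overdose      <- outcome_vector(0.027, 0.05)
  outcome_probs$LIR$underdose     <- outcome_vector(0, 0.068)
  outcome_probs$EXE$modified_dose <- outcome_vector(0, 0.084)
  outcome_probs$EXE$overdose      <- outcome_vector(0, 0.082)
  outcome_probs$EXE$underdose     <- outcome_vector(0, 0.097)
  outcome_probs$EXE$off_label_use <- outcome_vector(0, 0.178)

  new_sim_config(
    case_counts = case_counts,
    adr_mean = adr_mean,
    hlt_probs = hlt_probs,
    demographic_probs = demographic_probs,
    outcome_probs = outcome_probs,
    combination_fraction = 0.05,
    date_range = as.Date(c("2019-01-01", "2024-03-31")),
    seed = seed
  )
}

#' Construct and validate a simulator configuration
#'
#' @param case_counts named integer vector, cases per drug.
#' @param adr_mean named numeric vector, target ADR-per-ICSR ratio per drug
#'   (>= 1; the multiplicity model is a zero-truncated Poisson).
#' @param hlt_probs named list per drug of probabilities over the four HLTs;
#'   the residual mass goes to non-study PTs across SOCs.
#' @param demographic_probs named list per drug of per-dimension categorical
#'   distributions over the stratum levels.
#' @param outcome_probs named list per drug of categorical distributions over
#'   the seven outcomes, one per HLT plus `"other"`.
#' @param combination_fraction probability that a liraglutide case carries
#'   the insulin-degludec fixed-combination marker.
#' @param date_range length-2 `Date` vector; report dates are uniform on it.
#' @param seed integer root seed.
#' @return an object of class `sim_config`.
#' @export
new_sim_config <- function(case_counts, adr_mean, hlt_probs,
                           demographic_probs, outcome_probs,
                           combination_fraction = 0, date_range,
                           seed = 1L) {
  drugs <- names(case_counts)
  if (is.null(drugs) || any(!nzchar(drugs))) {
    stop("`case_counts` must be a named vector of drug codes", call. = FALSE)
  }
  if (any(case_counts < 0) || any(case_counts != floor(case_counts))) {
    stop("case counts must be non-negative integers", call. = FALSE)
  }
  for (dg in drugs) {
    if (is.na(adr_mean[dg]) || adr_mean[dg] < 1) {
      stop("adr_mean for ", dg, " must be >= 1", call. = FALSE)
    }
    p <- hlt_probs[[dg]]
    if (is.null(p) || !all(HLT_LEVELS %in% names(p))) {
      stop("hlt_probs for ", dg, " must cover all four HLTs", call. = FALSE)
    }
    if (any(p < 0) || sum(p[HLT_LEVELS]) > 1 + 1e-9) {
      stop("hlt_probs for ", dg, " must be non-negative with mass <= 1",
           call. = FALSE)
    }
    for (dim in STRAT_DIMENSIONS) {
      q <- demographic_probs[[dg]][[dim]]
      if (is.null(q) || abs(sum(q) - 1) > 1e-9 || any(q < 0)) {
        stop("demographic_probs[", dg, "][", dim, "] must sum to 1",
             call. = FALSE)
      }
    }
    for (grp in c(HLT_LEVELS, "other")) {
      q <- outcome_probs[[dg]][[grp]]
      if (is.null(q) || !all(OUTCOME_LEVELS %in% names(q)) ||
          abs(sum(q[OUTCOME_LEVELS]) - 1) > 1e-9 || any(q < 0)) {
        stop("outcome_probs[", dg, "][", grp, "] must sum to 1 over the ",
             "seven outcomes", call. = FALSE)
      }
    }
  }
  if (combination_fraction < 0 || combination_fraction > 1) {
    stop("combination_fraction must be in [0, 1]", call. = FALSE)
  }
  date_range <- as.Date(date_range)
  stopifnot(length(date_range) == 2L, date_range[1] <= date_range[2])
  structure(
    list(case_counts = case_counts, adr_mean = adr_mean,
         hlt_probs = hlt_probs, demographic_probs = demographic_probs,
         outcome_probs = outcome_probs,
         combination_fraction = combination_fraction,
         date_range = date_range, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", sum(x$case_counts), "cases over",
      length(x$case_counts), "drugs; seed", x$seed, "\n")
  invisible(x)
}

# Solve the zero-truncated Poisson rate whose truncated mean is `m`.
ztp_lambda <- function(m) {
  if (m <= 1 + 1e-12) return(0)
  uniroot(function(l) l / (1 - exp(-l)) - m,
          interval = c(1e-9, m + 10), tol = 1e-12)$root
}

# Draw n zero-truncated Poisson variates by CDF inversion.
ztp_sample <- function(n, m) {
  lambda <- ztp_lambda(m)
  if (lambda == 0) return(rep(1L, n))
  u <- runif(n, min = exp(-lambda), max = 1)
  stats::qpois(u, lambda)
}

# Deterministic per-drug substream seed from the root seed; arithmetic kept
# within double precision and the 32-bit integer range.
drug_substream <- function(seed, drug) {
  h <- 0
  for (cd in utf8ToInt(drug)) h <- (h * 131 + cd) %% 1000003
  as.integer(((abs(seed) %% 2147483647) * 16807 + h * 2143) %% 2147483647)
}

#' Generate a synthetic ICSR dataset
#'
#' Deterministic given the configuration and its seed: the same config
#' yields a byte-identical line listing. Drugs are generated on independent
#' substreams in code order of the drug name.
#'
#' @param config a `sim_config`.
#' @param path optional path; when given, the listing CSV is also written.
#' @param vocab vocabulary supplying the study PT registry; HLT-member PTs
#'   are drawn uniformly from the registry terms observed in the study.
#' @return an `icsr_dataset`.
#' @export
generate <- function(config, path = NULL, vocab = load_vocabulary()) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)

  ns_prob <- NONSTUDY_PTS$weight / sum(NONSTUDY_PTS$weight)
  n_days <- as.integer(config$date_range[2] - config$date_range[1])
  all_cases <- list()
  all_adrs <- list()

  for (dg in sort(names(config$case_counts))) {
    n <- config$case_counts[[dg]]
    if (n == 0L) next
    set.seed(drug_substream(config$seed, dg))

    mult <- ztp_sample(n, config$adr_mean[[dg]])
    dem <- config$demographic_probs[[dg]]
    draw_cat <- function(p) sample(names(p), n, replace = TRUE, prob = p)
    comb <- if (dg == "LIR" && config$combination_fraction > 0) {
      ifelse(runif(n) < config$combination_fraction, "LIR+degludec", "")
    } else rep("", n)

    case_id <- sprintf("%s%06d", dg, seq_len(n))
    cases <- tibble::tibble(
      case_id = case_id,
      drugs = dg,
      combination = comb,
      age_group = draw_cat(dem$age),
      sex = draw_cat(dem$sex),
      region = draw_cat(dem$region),
      reporter = draw_cat(dem$reporter),
      seriousness = draw_cat(dem$seriousness),
      report_date = config$date_range[1] + sample.int(n_days + 1L, n, replace = TRUE) - 1L
    )

    n_adr <- sum(mult)
    p_hlt <- config$hlt_probs[[dg]][HLT_LEVELS]
    group <- sample(c(HLT_LEVELS, "other"), n_adr, replace = TRUE,
                    prob = c(p_hlt, 1 - sum(p_hlt)))
    pt <- character(n_adr)
    soc <- character(n_adr)
    for (h in HLT_LEVELS) {
      sel <- which(group == h)
      if (!length(sel)) next
      pool <- vocab$terms[!is.na(vocab$terms$hlt) & vocab$terms$hlt == h &
                            vocab$terms$observed, ]
      idx <- sample.int(nrow(pool), length(sel), replace = TRUE)
      pt[sel] <- pool$pt[idx]
      soc[sel] <- pool$soc[idx]
    }
    sel <- which(group == "other")
    if (length(sel)) {
      idx <- sample.int(nrow(NONSTUDY_PTS), length(sel), replace = TRUE,
                        prob = ns_prob)
      pt[sel] <- NONSTUDY_PTS$pt[idx]
      soc[sel] <- NONSTUDY_PTS$soc[idx]
    }
    outcome <- character(n_adr)
    op <- config$outcome_probs[[dg]]
    for (grp in c(HLT_LEVELS, "other")) {
      sel <- which(group == grp)
      if (!length(sel)) next
      q <- op[[grp]][OUTCOME_LEVELS]
      outcome[sel] <- sample(OUTCOME_LEVELS, length(sel), replace = TRUE, prob = q)
    }
    adrs <- tibble::tibble(
      case_id = rep(case_id, mult),
      pt = pt, soc = soc, outcome = outcome
    )
    all_cases[[dg]] <- cases
    all_adrs[[dg]] <- adrs
  }

  ds <- new_icsr_dataset(dplyr::bind_rows(all_cases), dplyr::bind_rows(all_adrs),
                         cutoff_date = config$date_range[2])
  if (!is.null(path)) write_line_listing(ds, path)
  ds
}

#' Plant a true reporting odds ratio in a configuration
#'
#' Adjusts the target drug's probability for one HLT so that its odds against
#' the (fixed) comparator odds equal `true_or`. The comparator probability is
#' the ADR-weighted mean of the comparator drugs' probabilities, matching the
#' pooled comparator of the disproportionality sweep. Inversion:
#' `p_t = OR * o_c / (1 + OR * o_c)` with `o_c = p_c / (1 - p_c)`.
#'
#' @param config a `sim_config`.
#' @param hlt one of the four analysis HLT codes.
#' @param target target drug code.
#' @param true_or positive true odds ratio to plant.
#' @param comparators comparator drug codes (default all other configured
#'   drugs).
#' @return a new `sim_config` with the target probability adjusted.
#' @export
plant_odds_ratio <- function(config, hlt, target, true_or,
                             comparators = setdiff(names(config$case_counts), target)) {
  stopifnot(inherits(config, "sim_config"))
  if (!hlt %in% HLT_LEVELS) stop("unknown HLT: ", hlt, call. = FALSE)
  if (!isTRUE(true_or > 0)) stop("true_or must be positive", call. = FALSE)
  w <- config$case_counts[comparators] * config$adr_mean[comparators]
  p_c <- sum(vapply(comparators, function(dg) config$hlt_probs[[dg]][[hlt]],
                    numeric(1)) * w) / sum(w)
  o_c <- p_c / (1 - p_c)
  p_t <- true_or * o_c / (1 + true_or * o_c)
  probs <- config$hlt_probs[[target]]
  probs[[hlt]] <- p_t
  if (sum(probs[HLT_LEVELS]) > 1) {
    stop("infeasible parameter: planting OR ", true_or,
         " requires target probability ", signif(p_t, 4),
         " exceeding the available probability mass", call. = FALSE)
  }
  config$hlt_probs[[target]] <- probs
  config
}

#' True pooled-comparator odds ratio implied by a configuration
#'
#' @inheritParams plant_odds_ratio
#' @return the odds ratio of the target's HLT probability against the
#'   ADR-weighted pooled comparator probability.
#' @export
implied_odds_ratio <- function(config, hlt, target,
                               comparators = setdiff(names(config$case_counts), target)) {
  stopifnot(inherits(config, "sim_config"))
  w <- config$case_counts[comparators] * config$adr_mean[comparators]
  p_c <- sum(vapply(comparators, function(dg) config$hlt_probs[[dg]][[hlt]],
                    numeric(1)) * w) / sum(w)
  p_t <- config$hlt_probs[[target]][[hlt]]
  (p_t / (1 - p_t)) / (p_c / (1 - p_c))
}

#' Serialize a simulator configuration to YAML
#'
#' @param config a `sim_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  obj <- list(
    case_counts = as.list(config$case_counts),
    adr_mean = as.list(config$adr_mean),
    hlt_probs = lapply(config$hlt_probs, as.list),
    demographic_probs = lapply(config$demographic_probs, function(d) lapply(d, as.list)),
    outcome_probs = lapply(config$outcome_probs, function(d) lapply(d, as.list)),
    combination_fraction = config$combination_fraction,
    date_range = format(config$date_range, "%Y-%m-%d"),
    seed = config$seed
  )
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' Read a simulator configuration from YAML
#'
#' @param path YAML path written by [write_sim_config()].
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  obj <- yaml::read_yaml(path)
  new_sim_config(
    case_counts = unlist(obj$case_counts),
    adr_mean = unlist(obj$adr_mean),
    hlt_probs = lapply(obj$hlt_probs, unlist),
    demographic_probs = lapply(obj$demographic_probs, function(d) lapply(d, unlist)),
    outcome_probs = lapply(obj$outcome_probs, function(d) lapply(d, unlist)),
    combination_fraction = obj$combination_fraction,
    date_range = as.Date(obj$date_range),
    seed = obj$seed
  )
}
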