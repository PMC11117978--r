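#' Disproportionality analysis: reporting odds ratios
#'
#' For a target drug and one comparator, the 2x2 contingency table counts
#' ADR records (not cases):
#'
#' \preformatted{
#'                     target HLT ADRs   other ADRs
#'   target drug             a               b
#'   comparator              c               d
#' }
#'
#' The reporting odds ratio is ROR = (a*d)/(b*c), with the Woolf (log-scale
#' normal approximation) 95% confidence interval
#' exp(log(ROR) +/- z*sqrt(1/a + 1/b + 1/c + 1/d)), z = 1.959964. A signal
#' of disproportionate reporting requires at least 5 target-HLT ADRs and a
#' CI lower bound above 1; the symmetric reading (CI entirely below 1) is
#' classified as a lower reporting probability.
#'
#' @name signal
NULL

Z_95 <- 1.959964

#' Build an ADR-level 2x2 contingency table
#'
#' @param target_ds `icsr_dataset` for the target drug (from
#'   [split_by_drug()]).
#' @param comparator_ds `icsr_dataset` for the comparator side.
#' @param hlt one of the four analysis HLT codes.
#' @param vocab a `glp1_vocabulary`.
#' @return object of class `contingency_table` with integer cells
#'   `a`, `b`, `c`, `d`.
#' @export
build_table <- function(target_ds, comparator_ds, hlt,
                        vocab = load_vocabulary()) {
  stopifnot(inherits(target_ds, "icsr_dataset"),
            inherits(comparator_ds, "icsr_dataset"))
  if (!hlt %in% HLT_LEVELS) {
    stop("`hlt` must be one of: ", paste(HLT_LEVELS, collapse = ", "),
         call. = FALSE)
  }
  count_side <- function(ds) {
    h <- map_pt(vocab, ds$adrs$pt)
    in_hlt <- sum(!is.na(h) & h == hlt)
    c(in_hlt, nrow(ds$adrs) - in_hlt)
  }
  t_side <- count_side(target_ds)
  c_side <- count_side(comparator_ds)
  contingency_table(t_side[1], t_side[2], c_side[1], c_side[2])
}

#' @rdname build_table
#' @param a,b,c,d non-negative integer cell counts: target-HLT and other
#'   ADRs for the target drug (`a`, `b`) and the comparator (`c`, `d`).
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != floor(cells))) {
    stop("contingency cells must be non-negative integers", call. = FALSE)
  }
  structure(as.list(setNames(as.integer(cells), names(cells))),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("<contingency_table> a =", x$a, " b =", x$b, " c =", x$c, " d =", x$d, "\n")
  invisible(x)
}

#' Reporting odds ratio with Woolf 95% confidence interval
#'
#' Estimates, CI bounds and the two-sided Wald p-value (normal test of
#' log(ROR)/SE) are reported rounded half-up to 4 decimals. By default a
#' table with `b*c = 0` (or any zero cell) is a degenerate-table error;
#' `haldane = TRUE` opts in to the Haldane-Anscombe correction (+0.5 to all
#' cells), flagged in the result, which changes the estimate and should not
#' be silent.
#'
#' @param table a `contingency_table`.
#' @param haldane apply the +0.5 continuity correction to all cells.
#' @return object of class `ror_result`: `ror`, `ci_low`, `ci_high`,
#'   `n_target` (= a), `p_value`, `stars`, `signal`, `haldane`.
#' @export
ror <- function(table, haldane = FALSE) {
  stopifnot(inherits(table, "contingency_table"))
  cells <- c(table$a, table$b, table$c, table$d)
  if (any(cells == 0) && !haldane) {
    stop("degenerate contingency table (zero cell); ",
         "set haldane = TRUE to apply the +0.5 correction", call. = FALSE)
  }
  x <- cells + if (haldane) 0.5 else 0
  est <- (x[1] * x[4]) / (x[2] * x[3])
  se <- sqrt(sum(1 / x))
  lo <- exp(log(est) - Z_95 * se)
  hi <- exp(log(est) + Z_95 * se)
  p <- 2 * pnorm(-abs(log(est) / se))
  res <- structure(
    list(
      ror = round_half_up(est, 4),
      ci_low = round_half_up(lo, 4),
      ci_high = round_half_up(hi, 4),
      n_target = table$a,
      p_value = p,
      stars = p_stars(p),
      signal = NA_character_,
      haldane = haldane
    ),
    class = "ror_result"
  )
  res$signal <- classify(res)
  res
}

#' @export
print.ror_result <- function(x, ...) {
  cat(sprintf("<ror_result> ROR %.4f (95%% CI %.4f-%.4f), n = %d, p = %.3g %s-> %s%s\n",
              x$ror, x$ci_low, x$ci_high, x$n_target, x$p_value,
              if (nzchar(x$stars)) paste0(x$stars, " ") else "",
              x$signal, if (x$haldane) " [Haldane-Anscombe corrected]" else ""))
  invisible(x)
}

#' Significance stars for a p-value
#'
#' Tiers as used in the published forest plots: `*` p < 0.05, `***`
#' p <= 0.001, `****` p <= 0.0001 (no `**` tier is used).
#'
#' @param p numeric vector of p-values.
#' @return character vector of star strings (empty where p >= 0.05).
#' @export
p_stars <- function(p) {
  ifelse(p <= 1e-4, "****", ifelse(p <= 1e-3, "***", ifelse(p < 0.05, "*", "")))
}

#' Classify a reporting odds ratio as a signal
#'
#' `insufficient` when fewer than 5 target-HLT ADRs; otherwise `higher` when
#' the CI lower bound exceeds 1, `lower` when the CI upper bound is below 1,
#' `none` when the CI spans 1.
#'
#' @param result a `ror_result`, or anything with fields `n_target`,
#'   `ci_low`, `ci_high` (a one-row list works).
#' @return one of `"higher"`, `"lower"`, `"none"`, `"insufficient"`.
#' @export
classify <- function(result) {
  classify_signal(result$n_target, result$ci_low, result$ci_high)
}

#' @rdname classify
#' @param n_target number of target-HLT ADRs for the target drug (cell a).
#' @param ci_low,ci_high 95% CI bounds of the ROR.
#' @export
classify_signal <- function(n_target, ci_low, ci_high) {
  ifelse(n_target < 5, "insufficient",
         ifelse(ci_low > 1, "higher",
                ifelse(ci_high < 1, "lower", "none")))
}

#' Disproportionality sweep of one target against all comparators
#'
#' One ROR per (HLT, comparator), where the comparators are each drug in
#' `others` plus the pooled group of all of them. Output rows are ordered
#' deterministically: HLTs in display order, comparators alphabetically,
#' pooled last.
#'
#' @param ds an `icsr_dataset` covering all drugs.
#' @param target target drug code (default `"SEM"`).
#' @param others comparator drug codes (default all other study drugs).
#' @param vocab a `glp1_vocabulary`.
#' @param haldane passed to [ror()] for zero-cell tables.
#' @return tibble `hlt`, `comparator`, `a`, `b`, `c`, `d`, `ror`, `ci_low`,
#'   `ci_high`, `p_value`, `stars`, `signal`.
#' @export
comparison_sweep <- function(ds, target = "SEM",
                             others = setdiff(GLP1_DRUGS, target),
                             vocab = load_vocabulary(), haldane = FALSE) {
  stopifnot(inherits(ds, "icsr_dataset"))
  if (target %in% others) {
    stop("`target` must not be among `others`", call. = FALSE)
  }
  target_adrs <- drug_adrs(ds, target)
  target_hlt <- map_pt(vocab, target_adrs$pt)
  comparators <- c(sort(others), POOLED_CODE)
  rows <- list()
  for (h in HLT_LEVELS) {
    a <- sum(!is.na(target_hlt) & target_hlt == h)
    b <- nrow(target_adrs) - a
    for (cmp in comparators) {
      cmp_drugs <- if (cmp == POOLED_CODE) others else cmp
      cmp_adrs <- drug_adrs(ds, cmp_drugs)
      cmp_hlt <- map_pt(vocab, cmp_adrs$pt)
      cc <- sum(!is.na(cmp_hlt) & cmp_hlt == h)
      dd <- nrow(cmp_adrs) - cc
      res <- ror(contingency_table(a, b, cc, dd), haldane = haldane)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        hlt = h, comparator = cmp, a = a, b = b, c = cc, d = dd,
        ror = res$ror, ci_low = res$ci_low, ci_high = res$ci_high,
        p_value = res$p_value, stars = res$stars, signal = res$signal
      )
    }
  }
  dplyr::bind_rows(rows)
}
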