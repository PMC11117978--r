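#' Relative search volume utilities
#'
#' Search-interest tools mirror the relative scale of trend exports: values
#' are rescaled so the series (or regional) maximum equals 100, with 50
#' meaning half the peak popularity. Scaling raw inputs by any positive
#' constant leaves the outputs unchanged; cross-term comparisons therefore
#' require jointly normalized input (see the methods vignette).
#'
#' @name trends
NULL

#' Normalize a raw search-interest series to the 0-100 relative scale
#'
#' Each value is scaled by `100 / max(raw)` and rounded to the nearest
#' integer (display convention of trend tools); internal computation is at
#' full precision. An all-zero series maps to all zeros.
#'
#' @param raw data frame with columns `date` and `value` (non-negative), or
#'   a bare numeric vector.
#' @return tibble `date`, `value` with integer values in \[0, 100\]; for a
#'   bare vector, an integer vector.
#' @export
normalize_rsv <- function(raw) {
  vec_in <- !is.data.frame(raw)
  if (vec_in) raw <- tibble::tibble(date = seq_along(raw), value = raw)
  if (nrow(raw) == 0L) stop("empty series", call. = FALSE)
  if (any(raw$value < 0)) stop("search-interest values must be non-negative", call. = FALSE)
  m <- max(raw$value)
  scaled <- if (m > 0) as.integer(round(raw$value * 100 / m)) else rep(0L, nrow(raw))
  if (vec_in) return(scaled)
  tibble::tibble(date = raw$date, value = scaled)
}

#' Scale regional popularity so the top region scores 100
#'
#' @param raw named non-negative numeric vector, one entry per region, with
#'   at least one positive value.
#' @return named integer vector: 100 for the most popular region, others
#'   proportional, rounded to the nearest integer.
#' @export
regional_popularity <- function(raw) {
  if (length(raw) == 0L || is.null(names(raw))) {
    stop("`raw` must be a named vector of regional values", call. = FALSE)
  }
  if (any(raw < 0)) stop("regional values must be non-negative", call. = FALSE)
  m <- max(raw)
  if (m == 0) stop("all regional values are zero", call. = FALSE)
  setNames(as.integer(round(raw * 100 / m)), names(raw))
}

DEFAULT_QUERY_KEYWORDS <- list(
  weight_loss = c("weight loss"),
  side_effects = c("side effect")
)

#' Classify related search queries into topic buckets
#'
#' Case-insensitive substring matching against per-bucket keyword lists; the
#' first matching bucket in fixed order (`weight_loss`, then `side_effects`)
#' wins, and unmatched queries fall into `other`.
#'
#' @param queries character vector of related queries.
#' @param keywords named list of keyword vectors per bucket, tried in list
#'   order.
#' @return list with `queries` (tibble `term`, `bucket`) and `counts` (named
#'   integer vector per bucket, including `other`).
#' @export
classify_related_queries <- function(queries,
                                     keywords = DEFAULT_QUERY_KEYWORDS) {
  if (any(!lengths(keywords))) stop("keyword lists must be non-empty", call. = FALSE)
  lowq <- tolower(queries)
  bucket <- rep("other", length(queries))
  for (b in rev(names(keywords))) {
    hit <- Reduce(`|`, lapply(tolower(keywords[[b]]),
                              function(k) grepl(k, lowq, fixed = TRUE)))
    bucket[hit] <- b
  }
  levels <- c(names(keywords), "other")
  counts <- table(factor(bucket, levels = levels))
  list(
    queries = tibble::tibble(term = queries, bucket = bucket),
    counts = setNames(as.integer(counts), levels)
  )
}
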