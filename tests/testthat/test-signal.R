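test_that("ROR and Woolf interval match hand-computed values", {
  # frozen oracle: ROR = 50*3900/(950*100); CI = exp(log ROR -+ 1.959964 * SE),
  # SE = sqrt(1/50 + 1/950 + 1/100 + 1/3900), computed independently beforehand
  res <- ror(contingency_table(50, 950, 100, 3900))
  expect_equal(res$ror, 2.0526)
  expect_equal(res$ci_low, 1.4511)
  expect_equal(res$ci_high, 2.9035)
  expect_equal(res$signal, "higher")
  expect_equal(res$n_target, 50L)
  expect_equal(res$stars, "****")
})

test_that("a balanced table gives ROR 1 with a CI spanning 1", {
  res <- ror(contingency_table(10, 10, 10, 10))
  expect_equal(res$ror, 1.0000)
  expect_lt(res$ci_low, 1)
  expect_gt(res$ci_high, 1)
  expect_equal(res$signal, "none")
})

test_that("fewer than five target ADRs is insufficient regardless of the CI", {
  res <- ror(contingency_table(4, 100, 4, 100))
  expect_equal(res$signal, "insufficient")
  strong <- ror(contingency_table(4, 10, 40, 4000))
  expect_gt(strong$ci_low, 1)
  expect_equal(strong$signal, "insufficient")
})

test_that("zero cells raise a degenerate-table error unless Haldane-Anscombe is enabled", {
  expect_error(ror(contingency_table(5, 10, 0, 10)), "degenerate")
  res <- ror(contingency_table(5, 10, 0, 10), haldane = TRUE)
  expect_true(res$haldane)
  expect_true(is.finite(res$ror))
  # correction matches the +0.5 formula
  expect_equal(res$ror, round_half_up((5.5 * 10.5) / (10.5 * 0.5), 4))
})

test_that("classification reproduces every published ROR/CI direction", {
  fix <- reported_rors()
  # published signals all had at least five target ADRs
  got <- classify_signal(n_target = rep(5L, nrow(fix)),
                         ci_low = fix$ci_low, ci_high = fix$ci_high)
  expect_equal(got, fix$direction)
  # the worked examples
  expect_equal(classify_signal(5, 1.3379, 1.9542), "higher")
  expect_equal(classify_signal(5, 0.3579, 0.4667), "lower")
  expect_equal(classify_signal(5, 0.9, 1.6), "none")
})

test_that("swapping table rows inverts the ROR and mirrors the CI", {
  set.seed(101)
  for (i in 1:25) {
    cells <- rpois(4, lambda = c(40, 900, 60, 1200)) + 1L
    fwd <- ror(contingency_table(cells[1], cells[2], cells[3], cells[4]))
    rev <- ror(contingency_table(cells[3], cells[4], cells[1], cells[2]))
    expect_equal(rev$ror, round_half_up(1 / ((cells[1] * cells[4]) / (cells[2] * cells[3])), 4))
    expect_equal(rev$ci_low, round_half_up(1 / exp(log((cells[1] * cells[4]) / (cells[2] * cells[3])) +
                                                     1.959964 * sqrt(sum(1 / cells))), 4))
    expect_equal(fwd$p_value, rev$p_value, tolerance = 1e-12)
  }
})

test_that("the ROR is scale-free in the comparator and monotone in cell a", {
  base <- ror(contingency_table(30, 970, 50, 1950))
  for (k in c(2L, 5L, 10L)) {
    scaled <- ror(contingency_table(30, 970, 50 * k, 1950 * k))
    expect_equal(scaled$ror, base$ror)
    # CI narrows as the comparator grows
    expect_gte(scaled$ci_low, base$ci_low)
    expect_lte(scaled$ci_high, base$ci_high)
  }
  estimates <- vapply(c(10, 20, 40, 80),
                      function(a) ror(contingency_table(a, 970, 50, 1950))$ror,
                      numeric(1))
  expect_true(all(diff(estimates) > 0))
})

test_that("build_table counts ADRs at the HLT level via the vocabulary", {
  v <- load_vocabulary()
  target <- mk_ds(
    mk_cases(c("T1", "T2")),
    tibble::tibble(case_id = c("T1", "T1", "T2"),
                   pt = c("Overdose", "Nausea", "Overdose"),
                   soc = c("Injury, poisoning and procedural complications",
                           "Gastrointestinal disorders",
                           "Injury, poisoning and procedural complications"),
                   outcome = "recovered")
  )
  comparator <- mk_ds(mk_cases("K1", drugs = "LIR"), mk_adrs("K1", pt = "Nausea"))
  tab <- build_table(target, comparator, "overdose", v)
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(2L, 1L, 0L, 1L))

  empty <- mk_ds(mk_cases(character()), mk_adrs(character()))
  tab2 <- build_table(target, empty, "overdose", v)
  expect_equal(c(tab2$c, tab2$d), c(0L, 0L))
})

test_that("build_table equals a naive per-record scan on generated data", {
  cfg <- shrink_config(c("SEM", "EXE"), c(500, 500), seed = 17L)
  ds <- generate(cfg)
  v <- load_vocabulary()
  halves <- split_by_drug(ds, "SEM")
  for (h in HLT_LEVELS) {
    tab <- build_table(halves$target, halves$comparator, h, v)
    naive <- function(sub) {
      hits <- 0L
      for (i in seq_len(nrow(sub$adrs))) {
        m <- map_pt(v, sub$adrs$pt[i])
        if (!is.na(m) && m == h) hits <- hits + 1L
      }
      c(hits, nrow(sub$adrs) - hits)
    }
    expect_equal(c(tab$a, tab$b), naive(halves$target))
    expect_equal(c(tab$c, tab$d), naive(halves$comparator))
  }
})

test_that("comparison_sweep yields one ordered result per HLT and comparator", {
  cfg <- default_config(scale = 0.02, seed = 23L)
  ds <- generate(cfg)
  sw <- comparison_sweep(ds, haldane = TRUE)
  expect_equal(nrow(sw), 4L * 7L)
  expect_equal(unique(sw$hlt), HLT_LEVELS)
  per_hlt <- sw$comparator[sw$hlt == "overdose"]
  expect_equal(per_hlt, c(sort(setdiff(GLP1_DRUGS, "SEM")), POOLED_CODE))
  # cells are consistent: a+b constant per target, c+d = comparator totals
  expect_equal(length(unique(sw$a + sw$b)), 1L)
})

test_that("the signal rule keeps its nominal one-sided type-I error under the null", {
  # direct binomial tables at the null odds ratio; 500 replicates
  set.seed(77)
  n1 <- 20000L; n2 <- 20000L; p <- 0.01
  higher <- logical(500)
  for (i in 1:500) {
    a <- rbinom(1, n1, p); c <- rbinom(1, n2, p)
    if (a == 0 || c == 0) { higher[i] <- FALSE; next }
    res <- ror(contingency_table(a, n1 - a, c, n2 - c))
    higher[i] <- identical(res$signal, "higher")
  }
  bound <- 0.025 + 3 * sqrt(0.025 * 0.975 / 500)
  expect_lte(mean(higher), bound)
})
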