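test_that("icsr_shares reproduces the published shares from the fixture totals", {
  shares <- icsr_shares(fixture_totals())
  expect_equal(shares[["SEM"]], 29.0)
  expect_equal(shares[["LIR"]], 25.0)
  expect_equal(shares[["DUL"]], 23.9)
  expect_equal(shares[["EXE"]], 17.8)
  expect_equal(shares[["TIR"]], 3.2)
  expect_equal(shares[["LIX"]], 0.6)
  expect_equal(shares[["ALB"]], 0.5)
  # unrounded shares sum to 100 exactly
  tot <- fixture_totals()
  expect_equal(sum(tot / sum(tot) * 100), 100)
})

test_that("icsr_shares handles degenerate inputs", {
  expect_equal(unname(icsr_shares(c(A = 7))), 100.0)
  expect_equal(unname(icsr_shares(c(A = 1, B = 1))), c(50.0, 50.0))
  expect_error(icsr_shares(c(A = 0, B = 0)), "zero")
})

test_that("adr_per_icsr is the ADR-record to case ratio at two decimals", {
  ids <- c("C1", "C2", "C3")
  ds <- mk_ds(mk_cases(ids), mk_adrs(rep(ids, times = c(1, 2, 3))))
  expect_equal(adr_per_icsr(ds, "SEM"), 2.00)
  one <- mk_ds(mk_cases(ids), mk_adrs(ids))
  expect_equal(adr_per_icsr(one, "SEM"), 1.00)
  expect_error(adr_per_icsr(ds, "TIR"), "undefined")
})

test_that("characteristics_table partitions cases and matches a brute-force tally", {
  one <- mk_ds(mk_cases("C1", sex = "female"), mk_adrs("C1"))
  tab <- characteristics_table(one, "SEM", "sex")
  expect_equal(tab$count[tab$level == "female"], 1L)
  expect_equal(tab$pct[tab$level == "female"], 100.0)
  expect_equal(tab$pct[tab$level == "male"], 0.0)

  cfg <- shrink_config("SEM", 200, seed = 5L)
  ds <- generate(cfg)
  for (dim in STRAT_DIMENSIONS) {
    tab <- characteristics_table(ds, "SEM", dim)
    expect_equal(sum(tab$count), 200L)
    col <- switch(dim, age = "age_group", sex = "sex", region = "region",
                  reporter = "reporter", seriousness = "seriousness")
    brute <- table(ds$cases[[col]])
    for (lev in names(brute)) {
      expect_equal(tab$count[tab$level == lev], as.integer(brute[[lev]]))
    }
    expect_equal(tab$pct, round_half_up(tab$count / 200 * 100, 1))
  }
  expect_error(characteristics_table(ds, "SEM", "height"), "dimension")
})

test_that("published stratified percentages recompute from the packaged counts", {
  tab <- table3_counts()
  block <- tab[tab$drug == "SEM" & tab$dimension == "seriousness", ]
  out <- characteristics_from_counts(block, "seriousness")
  expect_equal(out$count[out$level == "serious"], 12029L)
  expect_equal(out$pct[out$level == "serious"], 57.2)
  block <- tab[tab$drug == POOLED_CODE & tab$dimension == "seriousness", ]
  out <- characteristics_from_counts(block, "seriousness")
  expect_equal(out$pct[out$level == "serious"], 74.2)
})

test_that("soc_distribution partitions ADR records over the SOC list", {
  v <- load_vocabulary()
  ds <- mk_ds(mk_cases(c("C1", "C2")),
              mk_adrs(c("C1", "C2", "C2"), pt = "Nausea",
                      soc = "Gastrointestinal disorders"))
  out <- soc_distribution(ds, "SEM", v)
  expect_equal(out$pct[out$soc == "Gastrointestinal disorders"], 100.0)
  expect_equal(sum(out$count), 3L)

  bad <- mk_ds(mk_cases("C1"), mk_adrs("C1", soc = "Imaginary disorders"))
  expect_error(soc_distribution(bad, "SEM", v), "SOC outside")

  cfg <- shrink_config("SEM", 300, seed = 9L)
  sim <- generate(cfg)
  out <- soc_distribution(sim, "SEM", v)
  brute <- table(factor(sim$adrs$soc, levels = v$soc_list))
  expect_equal(out$count, as.integer(brute))
  expect_equal(sum(out$count), nrow(sim$adrs))
})

test_that("hlt_frequencies counts mapped ADRs against the total-ADR denominator", {
  v <- load_vocabulary()
  # 10,000 ADRs of which 59 overdose PTs -> 0.59%
  ids <- sprintf("C%05d", 1:10000)
  pt <- rep("Nausea", 10000)
  pt[1:59] <- "Overdose"
  ds <- mk_ds(mk_cases(ids), mk_adrs(ids, pt = pt))
  out <- hlt_frequencies(ds, "SEM", v)
  expect_equal(out$adr_count[out$hlt == "overdose"], 59L)
  expect_equal(out$pct_of_total_adrs[out$hlt == "overdose"], 0.59)
  expect_equal(out$adr_count[out$hlt == "off_label_use"], 0L)
  expect_equal(out$pct_of_total_adrs[out$hlt == "off_label_use"], 0.00)
})

test_that("hlt_frequencies is invariant to case order and to split-and-recombine", {
  cfg <- shrink_config("SEM", 400, seed = 13L)
  ds <- generate(cfg)
  v <- load_vocabulary()
  base <- hlt_frequencies(ds, "SEM", v)

  perm <- sample(nrow(ds$cases))
  shuffled <- new_icsr_dataset(ds$cases[perm, ], ds$adrs[sample(nrow(ds$adrs)), ])
  expect_equal(hlt_frequencies(shuffled, "SEM", v)$adr_count, base$adr_count)

  half <- ds$cases$case_id[1:200]
  d1 <- new_icsr_dataset(ds$cases[ds$cases$case_id %in% half, ],
                         ds$adrs[ds$adrs$case_id %in% half, ])
  d2 <- new_icsr_dataset(ds$cases[!ds$cases$case_id %in% half, ],
                         ds$adrs[!ds$adrs$case_id %in% half, ])
  recombined <- hlt_frequencies(d1, "SEM", v)$adr_count +
    hlt_frequencies(d2, "SEM", v)$adr_count
  expect_equal(recombined, base$adr_count)
})

test_that("outcome_distribution reports counts, percentages and the unfavorable share", {
  v <- load_vocabulary()
  n <- c(fatal = 4, not_recovered = 9, recovered = 234)
  ids <- sprintf("C%03d", seq_len(sum(n)))
  ds <- mk_ds(mk_cases(ids),
              mk_adrs(ids, pt = "Overdose",
                      soc = "Injury, poisoning and procedural complications",
                      outcome = rep(names(n), n)))
  out <- outcome_distribution(ds, "SEM", "overdose", v)
  expect_equal(sum(out$table$count), 247L)
  expect_equal(out$fatal_pct, 1.6)  # 4/247
  expect_equal(out$not_recovered_pct, 3.6)
  expect_equal(out$unfavorable_pct, 5.3)  # 13/247

  empty <- outcome_distribution(ds, "SEM", "underdose", v)
  expect_equal(sum(empty$table$count), 0L)
  expect_true(all(is.na(empty$table$pct)))
  expect_true(is.na(empty$unfavorable_pct))
  expect_error(outcome_distribution(ds, "SEM", "bad_hlt", v), "hlt")
})

test_that("outcome tallies on generated data match a brute-force scan", {
  cfg <- shrink_config("SEM", 1500, seed = 21L)
  ds <- generate(cfg)
  v <- load_vocabulary()
  out <- outcome_distribution(ds, "SEM", "off_label_use", v)
  hlt <- map_pt(v, ds$adrs$pt)
  brute <- table(factor(ds$adrs$outcome[!is.na(hlt) & hlt == "off_label_use"],
                        levels = OUTCOME_LEVELS))
  expect_equal(out$table$count, as.integer(brute))
})

test_that("pooled ALL_OTHER aggregates every drug except the excluded one", {
  cfg <- shrink_config(c("SEM", "LIR", "DUL"), c(100, 100, 100), seed = 3L)
  ds <- generate(cfg)
  pooled <- characteristics_table(ds, POOLED_CODE, "sex")
  by_hand <- table(factor(ds$cases$sex[!grepl("SEM", ds$cases$drugs)],
                          levels = c("female", "male", "NS")))
  expect_equal(pooled$count, as.integer(by_hand))
  expect_equal(sum(pooled$count), 200L)
})
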