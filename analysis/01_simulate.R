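#!/usr/bin/env Rscript
# Generate the synthetic ICSR line listing used by the downstream analyses.
#
# The default configuration encodes the study conditions: per-drug case
# volumes at 1/10 of the published totals, published ADR-per-ICSR ratios,
# published (or ROR-derived) HLT reporting probabilities, and the published
# demographic strata. The listing, the serialized configuration and a brief
# summary table are written under results/.

suppressMessages(library(glp1signal))
dir.create("results", showWarnings = FALSE)

cfg <- default_config(scale = 0.1, seed = 20240331)
write_sim_config(cfg, "results/sim_config.yaml")

ds <- generate(cfg, path = "results/sim_listing.csv")
ds <- apply_study_filters(ds)  # no-op on generated data unless LIR+degludec planted

summary_tab <- data.frame(
  drug = names(cfg$case_counts),
  n_cases = vapply(names(cfg$case_counts), function(d) n_cases(ds, d), integer(1)),
  adr_per_icsr = vapply(names(cfg$case_counts), function(d) {
    if (n_cases(ds, d) > 0) adr_per_icsr(ds, d) else NA_real_
  }, numeric(1))
)
write.csv(summary_tab, "results/01_simulated_volumes.csv", row.names = FALSE)

cat("Simulated", nrow(ds$cases), "ICSRs carrying", nrow(ds$adrs),
    "ADR records across", sum(summary_tab$n_cases > 0), "drugs.\n")
cat("Excluded", sum(read_line_listing("results/sim_listing.csv")$cases$combination != ""),
    "liraglutide + degludec combination reports via the study filter.\n")
print(summary_tab, row.names = FALSE)
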