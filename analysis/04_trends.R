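#!/usr/bin/env Rscript
# Search-interest layer: relative-search-volume normalization, regional
# popularity scaling, and classification of related queries into the
# weight-loss / side-effects buckets.

suppressMessages(library(glp1signal))
dir.create("results", showWarnings = FALSE)

# A synthetic monthly interest series with a late peak, mimicking the surge
# in semaglutide searches: normalization pins the peak month at 100.
months <- seq(as.Date("2021-01-01"), as.Date("2024-03-01"), by = "month")
raw <- tibble::tibble(
  date = months,
  value = 5 + 95 * pmax(0, as.numeric(months - as.Date("2021-06-01"))) /
    as.numeric(as.Date("2024-03-01") - as.Date("2021-06-01"))
)
rsv <- normalize_rsv(raw)
write.csv(as.data.frame(rsv), "results/04_rsv_series.csv", row.names = FALSE)
cat("RSV series: peak", max(rsv$value), "at", format(rsv$date[which.max(rsv$value)]),
    "; first month", rsv$value[1], "\n")

# Regional scaling from raw proportional inputs reproduces the published
# ordering (Puerto Rico 100, United States 71, ...).
reg <- regional_popularity(c(PR = 1.00, US = 0.71, AU = 0.32, UK = 0.26,
                             IE = 0.22, CA = 0.22) * 5000)
write.csv(data.frame(region = names(reg), rsv = unname(reg)),
          "results/04_regional_popularity.csv", row.names = FALSE)
cat("Regional popularity:", paste(names(reg), reg, collapse = " | "), "\n")

fix <- related_queries()
cls <- classify_related_queries(fix$term)
out <- data.frame(drug = fix$drug, cls$queries)
write.csv(out, "results/04_related_queries.csv", row.names = FALSE)
cat("Related queries: ", cls$counts[["weight_loss"]], " weight-loss vs ",
    cls$counts[["side_effects"]], " side-effect terms across ",
    length(unique(fix$drug)), " drugs.\n", sep = "")
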