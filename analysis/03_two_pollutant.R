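#!/usr/bin/env Rscript
# Two-pollutant models on the city-merged series: ozone adjusted for each
# co-pollutant, and NO2/PM10 adjusted for ozone. Pairs whose lag 1-2 mean
# concentrations correlate at |r| >= 0.6 are refused (collinearity rule).

source(file.path("analysis", "common.R"))

study <- load_study_data()
merged <- study$merged
pairs <- list(c("o3_8h", "pm10"), c("o3_8h", "no2"), c("o3_8h", "so2"),
              c("o3_8h", "co"), c("no2", "o3_8h"), c("no2", "pm10"),
              c("pm10", "o3_8h"), c("pm10", "no2"))

rows <- list(); refusals <- character(0)
for (cause in c("total", "cvd", "resp")) for (pr in pairs) {
  res <- tryCatch(
    run_two_pollutant(merged, pr[1], pr[2], cause, scope = "merged"),
    error = function(e) conditionMessage(e))
  if (is.character(res)) {
    if (cause == "total") {
      refusals <- c(refusals, sprintf("%s adjusted for %s: %s", pr[1], pr[2], res))
      cat(sprintf("REFUSED %s ~ %s: %s\n", pr[1], pr[2], res))
    }
  } else {
    rows <- c(rows, list(as.data.frame(res)))
    if (cause == "total")
      cat(sprintf("%s adjusted for %-6s: ER %.2f%% (%.2f, %.2f)\n",
                  pr[1], pr[2], res$er, res$lo, res$hi))
  }
}

tab <- do.call(rbind, rows)
tab$er_ci <- sprintf("%.2f (%.2f, %.2f)", tab$er, tab$lo, tab$hi)
save_table(tab, "two_pollutant_er.tsv")
writeLines(refusals, file.path(TABLE_DIR, "two_pollutant_refusals.txt"))
cat(sprintf("\n%d model(s) refused by the |r| < 0.6 rule (see %s)\n",
            length(refusals), file.path(TABLE_DIR, "two_pollutant_refusals.txt")))
cat("Ozone estimates barely move under adjustment here because only ozone\n")
cat("carries an injected effect and its synthetic correlation with the\n")
cat("primary pollutants is weak, mirroring its distinct formation pathway.\n")
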