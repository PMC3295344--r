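#!/usr/bin/env Rscript
# Ozone effects stratified by exposure period: peak (September-November,
# the autumn ozone maximum) vs nonpeak (December-August), with 2-df and
# 6-df time-trend splines respectively, with and without PM10 adjustment,
# plus the z-based between-stratum difference test.

source(file.path("analysis", "common.R"))

study <- load_study_data()

rows <- list()
for (cause in c("total", "cvd", "resp")) for (adj in c(FALSE, TRUE)) {
  st <- run_stratified_o3(study$merged, cause, adjust_pm10 = adj)
  for (side in c("peak", "nonpeak")) {
    r <- as.data.frame(st[[side]])
    r$model <- if (adj) "pm10_adjusted" else "single"
    r$diff_z <- round(st$difference[["z"]], 3)
    r$diff_p <- signif(st$difference[["p"]], 3)
    rows <- c(rows, list(r))
  }
  cat(sprintf("%-5s (%s): peak %.2f%% (%.2f, %.2f) vs nonpeak %.2f%% (%.2f, %.2f), diff p = %.3f\n",
              cause, if (adj) "PM10-adj" else "single",
              st$peak$er, st$peak$lo, st$peak$hi,
              st$nonpeak$er, st$nonpeak$lo, st$nonpeak$hi,
              st$difference[["p"]]))
}

tab <- do.call(rbind, rows)
tab$er_ci <- sprintf("%.2f (%.2f, %.2f)", tab$er, tab$lo, tab$hi)
save_table(tab, "stratified_o3_er.tsv")

cat("\nThe generator injects a common ozone effect in both periods, so no\n")
cat("systematic peak/nonpeak difference is expected here; the difference\n")
cat("test should reject at roughly its nominal rate under these conditions.\n")
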