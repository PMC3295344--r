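# Shared by the numbered analysis drivers: simulate (or reload) the default
# four-city study data at the study seed, prepared for regression.

library(prdmort)

STUDY_SEED <- 42L
RESULTS <- file.path("results")
DATA_DIR <- file.path(RESULTS, "data")
TABLE_DIR <- file.path(RESULTS, "tables")
dir.create(DATA_DIR, recursive = TRUE, showWarnings = FALSE)
dir.create(TABLE_DIR, recursive = TRUE, showWarnings = FALSE)

load_study_data <- function(seed = STUDY_SEED) {
  holidays <- read_holidays()
  files <- file.path(DATA_DIR, paste0(names(prd_city_profiles()), ".csv"))
  if (all(file.exists(files))) {
    cities <- lapply(files, read_daily_csv)
    names(cities) <- names(prd_city_profiles())
  } else {
    cities <- simulate_prd(simulation_config(seed = seed))
  }
  cities <- lapply(cities, prepare_series, holidays = holidays)
  list(cities = cities,
       merged = prepare_series(merge_cities(cities), holidays = holidays),
       holidays = holidays)
}

save_table <- function(df, name) {
  path <- file.path(TABLE_DIR, name)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  cat(sprintf("  -> %s\n", path))
}
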