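#' Read a daily city series CSV
#'
#' Reads the packaged per-city CSV schema (`date, pm10, no2, o3_8h, so2,
#' co, temp, rh, deaths_total, deaths_cvd, deaths_resp`, ISO-8601 dates).
#' Unknown columns are ignored with a warning; non-integer death counts
#' are an error naming the first offending row.
#'
#' @param path CSV file path.
#' @return daily series data frame with a `Date` date column.
#' @export
read_daily_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  known <- c("date", "pm10", "no2", "o3_8h", "so2", "co", "temp", "rh",
             "deaths_total", "deaths_cvd", "deaths_resp", "flu", "period",
             "holiday")
  extra <- setdiff(names(df), known)
  if (length(extra)) {
    warning(sprintf("ignoring unknown column(s): %s",
                    paste(extra, collapse = ", ")))
    df <- df[, setdiff(names(df), extra), drop = FALSE]
  }
  if (!"date" %in% names(df)) stop("CSV must have a 'date' column")
  df$date <- as.Date(df$date)
  if (any(is.na(df$date))) stop("unparseable dates (expect ISO-8601)")
  for (cc in grep("^deaths_", names(df), value = TRUE)) {
    v <- df[[cc]]
    bad <- which(!is.na(v) & (v < 0 | v != round(v)))
    if (length(bad))
      stop(sprintf("column '%s' has a non-integer or negative death count at row %d",
                   cc, bad[1]))
    df[[cc]] <- as.integer(v)
  }
  df[order(df$date), , drop = FALSE]
}

#' Write a daily city series CSV
#'
#' Lossless round-trip companion of [read_daily_csv()].
#'
#' @param series daily series data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_daily_csv <- function(series, path) {
  out <- series
  out$date <- format(as.Date(out$date), "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Effect-estimate tables in the layout of the published result tables:
# raw columns plus a 2-decimal "ER (lo, hi)" presentation column.
format_er_table <- function(df) {
  df$er_ci <- sprintf("%.2f (%.2f, %.2f)", df$er, df$lo, df$hi)
  df
}

write_tsv_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Assembles (or reads from a flat YAML file) the configuration of the
#' end-to-end analysis pipeline. All module-level switches with defaults
#' documented in their functions (influenza window mode, overdispersion
#' threshold, df grids, ozone window convention) live here.
#'
#' @param seed global integer seed.
#' @param outdir output directory for data and tables.
#' @param n_days,start_date simulation window.
#' @param pollutants exposure columns to analyse.
#' @param causes outcome causes to analyse.
#' @param two_pollutant run co-pollutant adjustments of ozone, NO2 and
#'   PM10 (pairs failing the correlation rule are refused and logged).
#' @param stratified run the peak/nonpeak ozone analysis.
#' @param sensitivity run the 10-row sensitivity suite on the merged
#'   ozone/total model.
#' @param simulate generate synthetic data (`TRUE`) or read per-city CSVs
#'   from `data_files` (named list city -> path).
#' @param data_files named list of existing per-city CSV paths when
#'   `simulate = FALSE`.
#' @param config_overrides named list passed to [simulation_config()].
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L, outdir = tempfile("prdmort_run_"),
                            n_days = 1096L, start_date = "2006-01-01",
                            pollutants = c("o3_8h", "no2", "pm10"),
                            causes = c("total", "cvd", "resp"),
                            two_pollutant = TRUE, stratified = TRUE,
                            sensitivity = FALSE, simulate = TRUE,
                            data_files = NULL, config_overrides = list()) {
  if (!simulate) {
    if (is.null(data_files) || !length(data_files))
      stop("simulate = FALSE requires 'data_files'")
    missing_files <- !vapply(data_files, file.exists, logical(1))
    if (any(missing_files))
      stop("data files not found: ",
           paste(unlist(data_files[missing_files]), collapse = ", "))
  }
  supported <- c("pm10", "no2", "o3_8h", "so2", "co")
  if (!all(pollutants %in% supported))
    stop("unsupported pollutant(s): ",
         paste(setdiff(pollutants, supported), collapse = ", "))
  structure(list(seed = as.integer(seed), outdir = outdir,
                 n_days = as.integer(n_days), start_date = start_date,
                 pollutants = pollutants, causes = causes,
                 two_pollutant = two_pollutant, stratified = stratified,
                 sensitivity = sensitivity, simulate = simulate,
                 data_files = data_files,
                 config_overrides = config_overrides),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a flat YAML file
#'
#' @param path YAML file with the fields of [pipeline_config()].
#' @return a `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Run the end-to-end multicity analysis pipeline
#'
#' Executes the full analysis plan on synthetic or user data:
#' per-city single-pollutant models, Cochran's Q homogeneity tests across
#' cities, city-merged single- and two-pollutant models (two-pollutant
#' pairs failing the |r| < 0.6 rule are refused and logged), the
#' stratified peak/nonpeak ozone analysis with difference tests, and
#' optionally the sensitivity suite. Deterministic given the
#' configuration seed; every table row records its model provenance
#' (stratum, co-pollutant, time df, n). Tables are written as TSV under
#' `outdir/tables`, per-city data under `outdir/data`, and a run log to
#' `outdir/run.log`.
#'
#' @param config a [pipeline_config()] or path to its YAML form.
#' @return invisibly, a list with the per-city, merged, homogeneity,
#'   stratified and sensitivity tables plus the refusal log.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(file.path(config$outdir, "tables"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(config$outdir, "data"), showWarnings = FALSE)
  logfile <- file.path(config$outdir, "run.log")
  logcon <- file(logfile, open = "wt")
  on.exit(close(logcon), add = TRUE)
  say <- function(...) {
    msg <- sprintf(...)
    writeLines(msg, logcon)
    message(msg)
  }

  holidays <- read_holidays()
  if (config$simulate) {
    sim_args <- c(list(n_days = config$n_days, start_date = config$start_date,
                       seed = config$seed), config$config_overrides)
    sim_cfg <- do.call(simulation_config, sim_args)
    cities <- simulate_prd(sim_cfg)
    say("simulated %d cities x %d days (seed %d)", length(cities),
        config$n_days, config$seed)
    for (nm in names(cities))
      write_daily_csv(cities[[nm]],
                      file.path(config$outdir, "data", paste0(nm, ".csv")))
  } else {
    cities <- lapply(config$data_files, read_daily_csv)
    say("read %d city series", length(cities))
  }
  cities <- lapply(cities, prepare_series, holidays = holidays)
  merged <- prepare_series(merge_cities(cities), holidays = holidays)

  # per-city single-pollutant table + homogeneity tests
  city_rows <- list(); homo_rows <- list()
  for (cause in config$causes) for (pol in config$pollutants) {
    ests <- lapply(names(cities), function(nm)
      run_single_pollutant(cities[[nm]], pol, cause, scope = nm))
    city_rows <- c(city_rows, lapply(ests, as.data.frame))
    if (length(ests) >= 2) {
      hr <- cochran_q(vapply(ests, `[[`, numeric(1), "beta"),
                      vapply(ests, `[[`, numeric(1), "se"),
                      labels = names(cities))
      homo_rows[[paste(cause, pol, sep = "_")]] <-
        data.frame(cause = cause, pollutant = pol, Q = hr$Q, df = hr$df,
                   p = hr$p, pooled_beta = hr$pooled_beta)
      say("homogeneity %s/%s: Q = %.3f, p = %.3f", cause, pol, hr$Q, hr$p)
    }
  }
  city_tab <- format_er_table(do.call(rbind, city_rows))
  homo_tab <- do.call(rbind, homo_rows)

  # merged single- and two-pollutant models
  merged_rows <- list(); refusals <- character(0)
  copollutants <- list(o3_8h = c("pm10", "no2", "so2", "co"),
                       no2 = c("o3_8h", "pm10"), pm10 = c("o3_8h", "no2"))
  for (cause in config$causes) for (pol in config$pollutants) {
    est <- run_single_pollutant(merged, pol, cause, scope = "merged")
    merged_rows <- c(merged_rows, list(as.data.frame(est)))
    if (config$two_pollutant) {
      for (cop in copollutants[[pol]]) {
        if (!cop %in% names(merged)) next
        res <- tryCatch(
          run_two_pollutant(merged, pol, cop, cause, scope = "merged"),
          error = function(e) conditionMessage(e))
        if (is.character(res)) {
          refusals <- c(refusals, sprintf("%s/%s adj %s: %s", cause, pol,
                                          cop, res))
          say("REFUSED %s/%s adjusted for %s: %s", cause, pol, cop, res)
        } else merged_rows <- c(merged_rows, list(as.data.frame(res)))
      }
    }
  }
  merged_tab <- format_er_table(do.call(rbind, merged_rows))

  strat_tab <- NULL
  if (config$stratified && "o3_8h" %in% config$pollutants) {
    rows <- list()
    for (cause in config$causes) for (adj in c(FALSE, TRUE)) {
      st <- run_stratified_o3(merged, cause, adjust_pm10 = adj)
      for (side in c("peak", "nonpeak")) {
        r <- as.data.frame(st[[side]])
        r$model <- if (adj) "pm10_adjusted" else "single"
        r$diff_z <- st$difference["z"]; r$diff_p <- st$difference["p"]
        rows <- c(rows, list(r))
      }
      say("stratified o3/%s (%s): peak %.2f%%, nonpeak %.2f%%, diff p = %.4f",
          cause, if (adj) "pm10-adjusted" else "single",
          st$peak$er, st$nonpeak$er, st$difference["p"])
    }
    strat_tab <- format_er_table(do.call(rbind, rows))
  }

  sens_tab <- NULL
  if (config$sensitivity) {
    sens_tab <- sensitivity_suite(merged, model_spec(), holidays = holidays)
    say("sensitivity suite: %d perturbations, max |%% change in beta| = %.1f",
        nrow(sens_tab), max(abs(sens_tab$pct_change_beta)))
  }

  tables_dir <- file.path(config$outdir, "tables")
  write_tsv_report(city_tab, file.path(tables_dir, "city_single_pollutant.tsv"))
  write_tsv_report(homo_tab, file.path(tables_dir, "homogeneity.tsv"))
  write_tsv_report(merged_tab, file.path(tables_dir, "merged_models.tsv"))
  if (!is.null(strat_tab))
    write_tsv_report(strat_tab, file.path(tables_dir, "stratified_o3.tsv"))
  if (!is.null(sens_tab))
    write_tsv_report(sens_tab, file.path(tables_dir, "sensitivity.tsv"))
  say("wrote tables to %s", tables_dir)

  invisible(list(cities = city_tab, homogeneity = homo_tab,
                 merged = merged_tab, stratified = strat_tab,
                 sensitivity = sens_tab, refusals = refusals,
                 outdir = config$outdir))
}
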