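#' Read patient records from CSV
#'
#' One row per patient. Required columns: `patient_id`, `arm` (`tdm` /
#' `non_tdm`), `baseline_freq` (> 0), `freq_6m`, `freq_12m` (empty when
#' the patient discontinued before the visit), `discontinued_cycle` (1, 2
#' or empty), `tdm_count`, and ten period-cost columns
#' `cost<1|2>_<per|other_asm|tdm|outpatient|hospitalization>`. Invariants
#' are validated row by row: non-monitored patients must have zero
#' monitoring counts and costs, frequencies must be absent exactly when
#' the patient had discontinued, and costs must be non-negative. All
#' violations are collected and reported together.
#'
#' @param path CSV file path.
#' @return a validated patient-record data frame.
#' @export
read_patient_records <- function(path) {
  .assert(file.exists(path), "no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  cats <- c("per", "other_asm", "tdm", "outpatient", "hospitalization")
  need <- c("patient_id", "arm", "baseline_freq", "freq_6m", "freq_12m",
            "discontinued_cycle", "tdm_count",
            paste0("cost1_", cats), paste0("cost2_", cats))
  .assert(all(need %in% names(df)), "missing columns: ",
          paste(setdiff(need, names(df)), collapse = ", "))
  errs <- character()
  bad <- function(i, msg) errs <<- c(errs, sprintf("row %d (%s): %s", i, df$patient_id[i], msg))
  for (i in seq_len(nrow(df))) {
    if (!df$arm[i] %in% ARMS) bad(i, paste("unknown arm", df$arm[i]))
    if (!is.finite(df$baseline_freq[i]) || df$baseline_freq[i] <= 0)
      bad(i, "baseline_freq must be positive")
    dc <- df$discontinued_cycle[i]
    if (!is.na(dc) && !dc %in% c(1, 2)) bad(i, "discontinued_cycle must be 1, 2 or empty")
    if (!is.na(dc) && dc <= 1 && !is.na(df$freq_6m[i]))
      bad(i, "freq_6m present although discontinued in cycle 1")
    if (is.na(dc) && is.na(df$freq_6m[i])) bad(i, "freq_6m absent without discontinuation")
    if (!is.na(dc) && dc <= 2 && !is.na(df$freq_12m[i]))
      bad(i, "freq_12m present although discontinued")
    if (is.na(dc) && is.na(df$freq_12m[i])) bad(i, "freq_12m absent without discontinuation")
    costs <- unlist(df[i, c(paste0("cost1_", cats), paste0("cost2_", cats))])
    if (any(costs < 0, na.rm = TRUE)) bad(i, "negative cost")
    if (df$arm[i] == "non_tdm") {
      if (df$tdm_count[i] != 0) bad(i, "non-monitored arm with tdm_count != 0")
      if (any(c(df$cost1_tdm[i], df$cost2_tdm[i]) != 0, na.rm = TRUE))
        bad(i, "non-monitored arm with monitoring costs")
    }
  }
  if (length(errs))
    stop("invalid patient records:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  df
}

#' Write patient records to CSV
#'
#' Writes the same dialect [read_patient_records] reads.
#'
#' @param records patient-record data frame.
#' @param path output CSV path.
#' @export
write_patient_records <- function(records, path) {
  write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Run the full analysis pipeline and write a report bundle
#'
#' Executes calibration, the base case, the one-way and probabilistic
#' sensitivity analyses and the configured scenarios, writes the result
#' tables (base-case and scenario results, tornado, acceptability curve)
#' as CSV plus a JSON run manifest recording the configuration, seeds and
#' output inventory. Deterministic outputs are reproducible bit-exactly
#' from the manifest's seed.
#'
#' @param params,config model inputs.
#' @param out_dir output directory (created if needed).
#' @param seed seed for the probabilistic analysis.
#' @param n_draws probabilistic draws (default 10,000).
#' @param horizons scenario time horizons in years.
#' @return the manifest (invisibly), of class `run_manifest`.
#' @export
run_all <- function(params = load_parameter_tables(), config = model_config(),
                    out_dir, seed, n_draws = 10000, horizons = c(1, 5, 10)) {
  .assert(!missing(out_dir), "out_dir is required")
  .assert(!missing(seed), "seed is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  emit <- function(df, name) {
    fp <- file.path(out_dir, name)
    write.csv(df, fp, row.names = FALSE)
    files <<- c(files, name)
    fp
  }
  cal <- calibrate_config(params)
  emit(as.data.frame(cal), "calibration.csv")
  base_fit <- cea(params, config)
  res_rows <- list(cbind(analysis = "base", as.data.frame(base_fit$ce)))
  for (h in horizons) {
    sc <- run_scenario(params, config, "time_horizon", horizon_years = h)
    res_rows[[length(res_rows) + 1L]] <-
      cbind(analysis = sprintf("horizon_%gy", h), as.data.frame(sc$ce))
  }
  sc1 <- run_scenario(params, config, "one_year_tdm")
  res_rows[[length(res_rows) + 1L]] <- cbind(analysis = "one_year_tdm",
                                             as.data.frame(sc1$ce))
  res <- do.call(rbind, res_rows)
  # negative monetary values rendered in parentheses, as in the published table
  res_fmt <- res
  for (cc in c("incremental_cost", "icer"))
    res_fmt[[cc]] <- .fmt_money(res[[cc]])
  emit(res_fmt, "results.csv")
  reg <- build_param_registry(params, config)
  ow <- one_way_sa(params, config, reg)
  emit(as.data.frame(ow), "tornado.csv")
  psa <- run_psa(params, config, n_draws = n_draws, seed = seed, registry = reg)
  emit(psa$ceac, "ceac.csv")
  emit(psa$draws, "psa_draws.csv")
  manifest <- list(
    package = "tdmcea",
    version = as.character(utils::packageVersion("tdmcea")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed, n_draws = n_draws,
    config = unclass(config),
    calibration_selected = as.data.frame(cal)[1, , drop = FALSE],
    registry_size = nrow(reg),
    p_high_ce = psa$p_high_ce,
    base_icer = base_fit$ce$icer,
    files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  class(manifest) <- "run_manifest"
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Run manifest:", x$timestamp, "\n")
  cat(sprintf("  base ICER %.2f; P(highly CE) %.2f%%; registry %d; seed %s\n",
              x$base_icer, 100 * x$p_high_ce, x$registry_size, format(x$seed)))
  cat("  files:", paste(x$files, collapse = ", "), "\n")
  invisible(x)
}
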