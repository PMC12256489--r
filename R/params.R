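#' Load the packaged model parameter tables
#'
#' Reads the parameter fixture files (transition rows, per-state per-cycle
#' costs and their components, utilities, adverse-event inputs, drug
#' combination profiles and unit prices, monitoring inputs, and the
#' published cost/QALY reference totals used for calibration) and validates
#' them. Validation failures that contradict hard invariants (a transition
#' row not summing to 1, a negative cost, a utility outside \[0, 1\])
#' abort the load with an itemised report; soft inconsistencies that are
#' present in the published tables themselves (hospitalization component
#' products that disagree with the printed totals by more than 1%) are
#' collected in `validation$warnings` instead.
#'
#' @param path directory containing the CSV tables; defaults to the copies
#'   shipped with the package.
#' @return a `cea_params` object (see Details).
#' @details The returned list holds: `pooled` (the printed first-cycle and
#'   subsequent-cycle transition rows), `or` (odds ratio with 95% CI),
#'   `arms$tdm` / `arms$non_tdm` (per-state cost totals and components,
#'   hospitalization and outpatient unit inputs, adverse-event profile,
#'   combination profile), `utilities`, `ae_disutility`, `drug_prices`,
#'   `misc` (monitoring count and unit cost, test/exam costs, discount
#'   rate, thresholds), `reference` (published totals for calibration) and
#'   `validation`.
#' @export
load_parameter_tables <- function(path = system.file("extdata", package = "tdmcea")) {
  .assert(nzchar(path) && dir.exists(path), "fixture directory not found: ", path)
  rd <- function(f) {
    fp <- file.path(path, f)
    .assert(file.exists(fp), "missing fixture file: ", f)
    read.csv(fp, stringsAsFactors = FALSE)
  }
  need <- function(df, cols, f)
    .assert(all(cols %in% names(df)), "fixture ", f, " lacks columns: ",
            paste(setdiff(cols, names(df)), collapse = ", "))

  errs <- character(); warns <- character()

  tr <- rd("transitions.csv"); need(tr, c("phase", "from", "to", "prob"), "transitions.csv")
  row_of <- function(phase, from) {
    v <- setNames(rep(0, 4), STATES)
    sel <- tr$phase == phase & tr$from == from
    v[tr$to[sel]] <- tr$prob[sel]
    v
  }
  pooled <- list(first = row_of("first", "no_response"),
                 sub_no_response = row_of("subsequent", "no_response"),
                 sub_response = row_of("subsequent", "response"))
  for (nm in names(pooled))
    if (abs(sum(pooled[[nm]]) - 1) > 1e-9)
      errs <- c(errs, paste0("transition row '", nm, "' sums to ",
                             sum(pooled[[nm]]), ", not 1"))

  sc <- rd("state_costs.csv"); need(sc, c("arm", "state", "category", "value"), "state_costs.csv")
  if (any(sc$value < 0)) errs <- c(errs, "negative state cost entries")
  hosp <- rd("hospitalization.csv")
  need(hosp, c("arm", "state", "p_hosp", "n_hosp", "days", "daily_cost", "total"),
       "hospitalization.csv")
  for (i in seq_len(nrow(hosp))) {
    prod <- hosp$p_hosp[i] * hosp$n_hosp[i] * hosp$days[i] * hosp$daily_cost[i]
    if (abs(prod - hosp$total[i]) / hosp$total[i] > 0.01)
      warns <- c(warns, sprintf(
        "hospitalization %s/%s: component product %.2f differs from printed total %.2f by %.1f%%",
        hosp$arm[i], hosp$state[i], prod, hosp$total[i],
        100 * abs(prod - hosp$total[i]) / hosp$total[i]))
  }
  outp <- rd("outpatient.csv")
  need(outp, c("arm", "state", "n_outpatient", "n_low", "n_high", "consult_cost"),
       "outpatient.csv")
  ae <- rd("adverse_events.csv")
  need(ae, c("arm", "event", "prob", "prob_low", "prob_high",
             "cost", "cost_low", "cost_high"), "adverse_events.csv")
  if (any(ae$prob < 0 | ae$prob > 1)) errs <- c(errs, "adverse-event probability outside [0,1]")
  disu <- rd("ae_disutility.csv"); need(disu, c("event", "disutility", "low", "high"), "ae_disutility.csv")
  ut <- rd("utilities.csv"); need(ut, c("state", "utility", "low", "high"), "utilities.csv")
  if (any(ut$utility < 0 | ut$utility > 1)) errs <- c(errs, "utility outside [0,1]")
  comb <- rd("combinations.csv"); need(comb, c("arm", "state", "drug", "prob", "low", "high"), "combinations.csv")
  if (any(comb$low > comb$high))
    errs <- c(errs, paste0("inverted combination range for ",
      paste(comb$arm[comb$low > comb$high], comb$state[comb$low > comb$high],
            comb$drug[comb$low > comb$high], sep = "/", collapse = "; ")))
  prices <- rd("drug_prices.csv"); need(prices, c("drug", "unit_price"), "drug_prices.csv")
  misc_df <- rd("misc.csv"); need(misc_df, c("key", "value", "low", "high"), "misc.csv")
  misc <- setNames(misc_df$value, misc_df$key)
  misc_rng <- misc_df
  outc <- rd("outcomes_12m.csv")
  need(outc, c("arm", "uncontrolled", "response", "seizure_free", "discontinued"),
       "outcomes_12m.csv")
  ref <- rd("reference_results.csv")
  need(ref, c("analysis", "cost_non_tdm", "cost_tdm", "qaly_non_tdm",
              "qaly_tdm", "icer"), "reference_results.csv")

  if (length(errs))
    stop("parameter tables failed validation:\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)

  getv <- function(df, arm, state, col = "value", key = "category", what = "total") {
    sel <- df$arm == arm & df$state == state & df[[key]] == what
    if (!any(sel)) NA_real_ else df[[col]][sel][1]
  }
  arm_block <- function(a) {
    costm <- sapply(c("total", "hospitalization", "outpatient", "per", "other_asm"),
                    function(cc) vapply(STATES, function(s) getv(sc, a, s, what = cc), 0))
    rownames(costm) <- STATES
    list(arm = a,
         state_cost = costm[, "total"],
         cost_components = costm,
         hosp = hosp[hosp$arm == a, , drop = FALSE],
         outpatient = outp[outp$arm == a, , drop = FALSE],
         ae = ae[ae$arm == a, , drop = FALSE],
         combos = comb[comb$arm == a, , drop = FALSE])
  }
  arms <- list(tdm = arm_block("tdm"), non_tdm = arm_block("non_tdm"))
  # utility lookup in state order
  u <- setNames(ut$utility[match(STATES, ut$state)], STATES)

  structure(list(
    pooled = pooled,
    or = list(value = unname(misc["or"]),
              low = misc_df$low[misc_df$key == "or"],
              high = misc_df$high[misc_df$key == "or"]),
    arms = arms,
    utilities = u, utilities_rng = ut,
    ae_disutility = disu,
    drug_prices = prices,
    misc = misc, misc_rng = misc_rng,
    outcomes_12m = outc,
    reference = ref,
    validation = list(errors = character(), warnings = warns)),
    class = "cea_params")
}

#' @export
print.cea_params <- function(x, ...) {
  cat("Model parameter tables\n")
  cat(sprintf("  odds ratio %s (%s-%s); %d adverse events/arm; utilities %s\n",
              x$or$value, x$or$low, x$or$high, nrow(x$arms$tdm$ae),
              paste(sprintf("%s=%.3f", substr(STATES, 1, 4), x$utilities),
                    collapse = " ")))
  cat(sprintf("  per-cycle state cost totals (tdm): %s\n",
              paste(sprintf("%.2f", x$arms$tdm$state_cost), collapse = ", ")))
  cat(sprintf("  per-cycle state cost totals (non-tdm): %s\n",
              paste(sprintf("%.2f", x$arms$non_tdm$state_cost), collapse = ", ")))
  if (length(x$validation$warnings))
    cat("  validation warnings:", length(x$validation$warnings),
        "(printed-table inconsistencies; see $validation$warnings)\n")
  invisible(x)
}

# discontinue-state per-cycle cost for one arm under a config
.dc_cost <- function(arm_block, mode) {
  if (mode == "printed") return(arm_block$state_cost[["discontinue"]])
  comp <- arm_block$cost_components["discontinue", c("hospitalization", "outpatient", "other_asm")]
  sum(comp)
}
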