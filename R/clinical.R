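#' Classify a follow-up seizure outcome
#'
#' Orders a patient's follow-up seizure frequency against baseline into the
#' three ordered clinical categories used throughout the analysis:
#' `uncontrolled` (< 50% reduction), `response` (>= 50% but < 100% reduction)
#' and `seizure_free` (100% reduction, i.e. a follow-up frequency of zero).
#' A missing follow-up frequency marks a patient who stopped perampanel
#' before the visit and is returned as `"discontinued"`.
#'
#' A reduction of exactly 50% counts as response. The comparison is done as
#' `2 * followup <= baseline`, which is exact in floating point for the
#' half-frequency boundary and avoids a division.
#'
#' @param baseline_freq seizures per 28 days at enrolment; must be > 0
#'   (a zero baseline makes "percentage reduction" undefined and flags an
#'   invalid enrolment record).
#' @param followup_freq seizures per 28 days at the visit, or `NA` if the
#'   patient discontinued before the visit.
#' @return one of `"uncontrolled"`, `"response"`, `"seizure_free"`,
#'   `"discontinued"`.
#' @examples
#' classify_outcome(8, 0) # seizure_free
#' classify_outcome(8, 4) # response (exactly 50%)
#' classify_outcome(8, 5) # uncontrolled
#' @export
classify_outcome <- function(baseline_freq, followup_freq) {
  .assert(is.numeric(baseline_freq) && length(baseline_freq) == 1L &&
            is.finite(baseline_freq) && baseline_freq > 0,
          "baseline_freq must be a single positive number; ",
          "a zero baseline leaves the percentage reduction undefined")
  if (length(followup_freq) != 1L) stop("followup_freq must be length 1")
  if (is.na(followup_freq)) return("discontinued")
  .assert(is.numeric(followup_freq) && followup_freq >= 0,
          "followup_freq must be >= 0 when present")
  if (followup_freq == 0) return("seizure_free")
  if (2 * followup_freq <= baseline_freq) return("response")
  "uncontrolled"
}

#' Tabulate outcomes by arm
#'
#' Counts completers at a visit in each arm by ordered outcome category.
#' Patients who discontinued before the visit are excluded from the counts
#' (and reported in the `discontinued` attribute), matching the convention of
#' analysing only children who stayed on perampanel for the full follow-up.
#'
#' @param records a patient-record data frame as produced by
#'   [generate_cohort] or [read_patient_records].
#' @param visit `"6m"` or `"12m"`.
#' @return an `outcome_table`: a 2 x 3 integer matrix (rows `tdm`,
#'   `non_tdm`; columns `uncontrolled`, `response`, `seizure_free`) with a
#'   `discontinued` attribute giving per-arm dropout counts. If every record
#'   discontinued the table is all-zero and carries `empty = TRUE`.
#' @export
build_outcome_table <- function(records, visit = c("12m", "6m")) {
  visit <- match.arg(visit)
  .assert(is.data.frame(records) && nrow(records) > 0, "records must be non-empty")
  fcol <- if (visit == "6m") "freq_6m" else "freq_12m"
  tab <- matrix(0L, 2, 3, dimnames = list(ARMS, OUTCOME_LEVELS))
  disc <- c(tdm = 0L, non_tdm = 0L)
  for (i in seq_len(nrow(records))) {
    arm <- as.character(records$arm[i])
    cls <- classify_outcome(records$baseline_freq[i], records[[fcol]][i])
    if (cls == "discontinued") disc[arm] <- disc[arm] + 1L
    else tab[arm, cls] <- tab[arm, cls] + 1L
  }
  structure(tab, discontinued = disc, visit = visit,
            empty = all(tab == 0L), class = c("outcome_table", "matrix"))
}

#' @export
print.outcome_table <- function(x, ...) {
  cat("Outcome table at", attr(x, "visit"), "visit",
      if (isTRUE(attr(x, "empty"))) "(no completers)" else "", "\n")
  print(unclass(x)[, , drop = FALSE])
  cat("discontinued before visit:",
      paste(names(attr(x, "discontinued")), attr(x, "discontinued"),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Seizure-free and responder rates with exact binomial intervals
#'
#' The responder rate counts both `response` and `seizure_free` (at least a
#' 50% reduction); the seizure-free rate counts only complete seizure
#' freedom. Intervals are Clopper-Pearson 95% limits.
#'
#' @param table an [build_outcome_table] result (completers only).
#' @return a data frame with one row per arm and columns `n`,
#'   `seizure_free_rate`, `sf_low`, `sf_high`, `responder_rate`, `resp_low`,
#'   `resp_high`.
#' @export
outcome_rates <- function(table) {
  .assert(inherits(table, "outcome_table") || (is.matrix(table) && ncol(table) == 3),
          "table must be an outcome table")
  if (is.null(colnames(table))) colnames(table) <- OUTCOME_LEVELS
  if (is.null(rownames(table))) rownames(table) <- ARMS
  n <- rowSums(table)
  .assert(all(n >= 1), "every arm needs at least one completer; got zero in: ",
          paste(rownames(table)[n < 1], collapse = ", "))
  ci <- function(k, n) as.numeric(binom.test(k, n)$conf.int)
  out <- lapply(rownames(table), function(a) {
    sf <- table[a, "seizure_free"]
    rs <- sf + table[a, "response"]
    data.frame(arm = a, n = n[a],
               seizure_free_rate = sf / n[a],
               sf_low = ci(sf, n[a])[1], sf_high = ci(sf, n[a])[2],
               responder_rate = rs / n[a],
               resp_low = ci(rs, n[a])[1], resp_high = ci(rs, n[a])[2],
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' Dose-adjustment recommendation from a monitoring result
#'
#' Encodes the concentration-guided dosing rules of the monitored arm. The
#' therapeutic range for perampanel used here is 100-1000 ng/mL. The five
#' published rules cover every combination except "below range and seizure
#' free"; that cell returns `MAINTAIN`, since dose escalation has no clinical
#' driver in a patient who is already seizure free (logged as an explicit
#' sixth rule in the rationale).
#'
#' @param concentration trough plasma concentration, ng/mL (>= 0).
#' @param seizure_free logical flag: is the patient currently seizure free?
#' @param range therapeutic range, ng/mL, as `c(low, high)` with low < high.
#' @return a `dose_action` list with `action` (one of `INCREASE_BY_TDM`,
#'   `MAINTAIN`, `INCREASE_2MG_PER_DAY`, `DECREASE_BY_TDM`,
#'   `CONSIDER_OTHER_THERAPY`) and a text `rationale`.
#' @examples
#' recommend_dose_action(50, FALSE)   # INCREASE_BY_TDM
#' recommend_dose_action(500, TRUE)   # MAINTAIN
#' recommend_dose_action(1200, FALSE) # CONSIDER_OTHER_THERAPY
#' @export
recommend_dose_action <- function(concentration, seizure_free,
                                  range = c(100, 1000)) {
  .assert(is.numeric(concentration) && length(concentration) == 1L &&
            is.finite(concentration) && concentration >= 0,
          "concentration must be a single non-negative number (ng/mL)")
  .assert(isTRUE(seizure_free) || isFALSE(seizure_free),
          "seizure_free must be TRUE or FALSE")
  .assert(length(range) == 2L && range[1] < range[2], "range must be (low, high)")
  pos <- if (concentration < range[1]) "below"
         else if (concentration <= range[2]) "within" else "above"
  key <- paste(pos, if (seizure_free) "sf" else "nsf", sep = "_")
  rule <- switch(key,
    below_nsf  = list("INCREASE_BY_TDM",
                      "below therapeutic range without seizure freedom: increase dose guided by the measured concentration (rule 1)"),
    within_sf  = list("MAINTAIN",
                      "within therapeutic range with seizure freedom: maintain dosage (rule 2)"),
    within_nsf = list("INCREASE_2MG_PER_DAY",
                      "within therapeutic range without seizure freedom: increase by 2 mg/day per step (rule 3)"),
    above_sf   = list("DECREASE_BY_TDM",
                      "above therapeutic range with seizure freedom: decrease dose guided by the measured concentration (rule 4)"),
    above_nsf  = list("CONSIDER_OTHER_THERAPY",
                      "above therapeutic range without seizure freedom: consider other therapies (rule 5)"),
    below_sf   = list("MAINTAIN",
                      "below therapeutic range with seizure freedom: no clinical driver for escalation, maintain dosage (rule 6, house convention)"))
  structure(list(action = rule[[1]], rationale = rule[[2]]),
            class = "dose_action")
}

#' @export
print.dose_action <- function(x, ...) {
  cat(x$action, "-", x$rationale, "\n"); invisible(x)
}

#' Inflate a cost to a later price year
#'
#' @param amount cost in USD.
#' @param years number of years of inflation to apply.
#' @param rate annual inflation rate; the packaged analysis uses the average
#'   Chinese healthcare inflation rate of 1.48%/yr to express costs in 2022
#'   dollars.
#' @return `amount * (1 + rate)^years`.
#' @export
inflate_cost <- function(amount, years, rate = 0.0148) {
  .assert(rate > -1, "rate must exceed -1")
  amount * (1 + rate)^years
}

#' Convert RMB to USD
#'
#' @param amount_rmb amount in RMB.
#' @param rate RMB per USD; default 6.73, the 2022 average exchange rate.
#' @export
convert_currency <- function(amount_rmb, rate = 6.73) {
  .assert(rate > 0, "exchange rate must be positive")
  amount_rmb / rate
}

# states occupied by all patients in a follow-up period (1: 0-6m, 2: 6-12m),
# vectorized counterpart of classify_outcome with discontinuation handling
.states_at <- function(records, period) {
  f <- if (period == 1L) records$freq_6m else records$freq_12m
  disc <- !is.na(records$discontinued_cycle) & records$discontinued_cycle <= period
  st <- rep("discontinue", nrow(records))
  act <- !disc & !is.na(f)
  st[act & f == 0] <- "seizure_free"
  st[act & f > 0 & 2 * f <= records$baseline_freq] <- "response"
  st[act & 2 * f > records$baseline_freq] <- "no_response"
  st
}

#' Estimate transition rows from patient records
#'
#' First-cycle rows describe movement from enrolment (everyone starts in
#' `no_response`) to the 6-month state. Subsequent-cycle rows condition on
#' the 6-month state and describe movement to the 12-month state; patients
#' discontinuing during a cycle are assigned the `discontinue` destination
#' for that cycle. A conditioning state with no patients yields a row of
#' `NA` (flagged in `missing_rows`), never a silent zero row.
#'
#' @param records patient-record data frame.
#' @param cycle `"first"` or `"subsequent"`.
#' @return a `transition_estimate` list with per-arm matrices `rows`
#'   (origin x destination proportions), per-arm origin counts `n`, and
#'   `missing_rows`.
#' @export
estimate_transitions <- function(records, cycle = c("first", "subsequent")) {
  cycle <- match.arg(cycle)
  .assert(is.data.frame(records) && nrow(records) > 0, "records must be non-empty")
  res <- list(); miss <- character()
  for (arm in ARMS) {
    ra <- records[records$arm == arm, , drop = FALSE]
    rows <- matrix(NA_real_, 4, 4, dimnames = list(STATES, STATES))
    n <- setNames(integer(4), STATES)
    if (cycle == "first") {
      origins <- "no_response"
      dest <- .states_at(ra, 1L)
      n["no_response"] <- nrow(ra)
      if (nrow(ra) > 0)
        rows["no_response", ] <- as.numeric(table(factor(dest, STATES))) / nrow(ra)
    } else {
      s6 <- .states_at(ra, 1L)
      s12 <- .states_at(ra, 2L)
      origins <- c("no_response", "response", "seizure_free")
      for (o in origins) {
        sel <- s6 == o
        n[o] <- sum(sel)
        if (n[o] > 0)
          rows[o, ] <- as.numeric(table(factor(s12[sel], STATES))) / n[o]
      }
      rows["discontinue", ] <- c(0, 0, 0, 1) # absorbing by construction
      n["discontinue"] <- sum(s6 == "discontinue")
    }
    for (o in origins) if (n[o] == 0)
      miss <- c(miss, paste(arm, o, sep = "/"))
    res[[arm]] <- list(rows = rows, n = n)
  }
  structure(list(tdm = res$tdm, non_tdm = res$non_tdm, cycle = cycle,
                 missing_rows = miss),
            class = "transition_estimate")
}

#' Mean 6-month costs per health state from patient records
#'
#' Assigns each follow-up period's costs to the state the patient occupied
#' in that period and averages by arm, state and cost category.
#'
#' @param records patient-record data frame.
#' @return a `state_cost_estimate` list with per-arm matrices `mean`
#'   (state x category, plus a `total` column equal to the category sum),
#'   observation counts `n`, and `missing` (arm/state cells never observed).
#' @export
estimate_state_costs <- function(records) {
  .assert(is.data.frame(records) && nrow(records) > 0, "records must be non-empty")
  cats <- c("per", "other_asm", "tdm", "outpatient", "hospitalization")
  out <- list(); miss <- character()
  for (arm in ARMS) {
    ra <- records[records$arm == arm, , drop = FALSE]
    acc <- matrix(0, 4, length(cats), dimnames = list(STATES, cats))
    n <- setNames(integer(4), STATES)
    for (p in 1:2) {
      st <- factor(.states_at(ra, p), STATES)
      cm <- as.matrix(ra[, paste0("cost", p, "_", cats), drop = FALSE])
      .assert(all(cm >= 0, na.rm = TRUE), "negative costs in records")
      sums <- rowsum(cm, st, na.rm = TRUE)
      acc[rownames(sums), ] <- acc[rownames(sums), ] + sums
      tab <- table(st)
      n <- n + as.integer(tab[STATES])
    }
    m <- sweep(acc, 1, pmax(n, 1L), "/")
    m[n == 0L, ] <- NA_real_
    miss <- c(miss, paste(arm, STATES[n == 0L], sep = "/"))
    out[[arm]] <- list(mean = cbind(m, total = rowSums(m)), n = n)
  }
  structure(list(tdm = out$tdm, non_tdm = out$non_tdm, missing = miss),
            class = "state_cost_estimate")
}
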