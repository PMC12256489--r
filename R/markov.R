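#' Shift a transition row by an odds ratio on the cumulative-logit scale
#'
#' Applies a proportional-odds shift to the ordered destination distribution
#' of a transition row: for every cumulative cut j,
#' `odds'(dest > j) = or_value * odds(dest > j)`. Two variants are
#' supported:
#'
#' * `cuts = "on_per"`: the discontinuation probability is held fixed and
#'   the shift acts on the conditional distribution over the on-treatment
#'   destinations no_response < response < seizure_free (two cuts), which is
#'   then rescaled back so the row sums to one.
#' * `cuts = "four_state"`: discontinuation is treated as the worst ordered
#'   outcome (discontinue < no_response < response < seizure_free) and the
#'   shift acts on all three cuts, so the discontinuation probability moves
#'   too. This is the variant the calibrated configuration uses.
#'
#' `or_value = 1` returns the row unchanged; as `or_value` tends to 0 the
#' mass in the highest category tends to 0. A structurally zero cumulative
#' probability (for example no seizure-freedom destination) stays zero.
#'
#' @param reference_row probability vector over the four destinations, in
#'   state order (no_response, response, seizure_free, discontinue).
#' @param or_value odds ratio (> 0) for reaching higher destinations.
#' @param cuts `"on_per"` or `"four_state"`.
#' @return the adjusted row (sums to 1).
#' @export
apply_or_adjustment <- function(reference_row, or_value,
                                cuts = c("on_per", "four_state")) {
  cuts <- match.arg(cuts)
  row <- as.numeric(reference_row)
  .assert(.is_prob_row(row), "reference_row must be a probability vector over the 4 states")
  .assert(is.numeric(or_value) && length(or_value) == 1L && or_value > 0,
          "or_value must be a single positive number")
  shift <- function(p) {
    # p: probabilities over ordered categories (low -> high)
    cg <- rev(cumsum(rev(p)))[-1]          # P(dest > j), j = 1..K-1
    odds <- ifelse(cg >= 1, Inf, cg / (1 - cg))
    cg2 <- ifelse(is.infinite(odds), 1, or_value * odds / (1 + or_value * odds))
    cg2[cg == 0] <- 0
    c(1 - cg2[1], if (length(cg2) > 1) -diff(cg2) else numeric(0),
      cg2[length(cg2)])
  }
  if (cuts == "on_per") {
    dc <- row[4]
    on <- 1 - dc
    if (on <= 0)
      stop("reference row has zero on-treatment mass; ordinal adjustment undefined",
           call. = FALSE)
    p <- row[1:3] / on
    q <- shift(p)
    out <- c(q * on, dc)
  } else {
    p <- c(row[4], row[1], row[2], row[3]) # discontinue is the lowest category
    q <- shift(p)
    out <- c(q[2], q[3], q[4], q[1])
  }
  out <- out / sum(out)
  names(out) <- STATES
  out
}

#' Build per-arm, per-phase transition matrices
#'
#' Constructs the 4 x 4 first-cycle and subsequent-cycle matrices for both
#' arms from the printed transition rows and the odds ratio, under the
#' configured `or_mode` / `or_cuts` / `or_scope` (see [model_config]).
#' Seizure freedom and discontinuation rows are unit vectors (absorbing) in
#' every case.
#'
#' @param params a [load_parameter_tables] object (or any list with
#'   `pooled` rows and `or$value`).
#' @param config a [model_config].
#' @param or_value override for the odds ratio (defaults to the table value).
#' @return `list(tdm = list(first, subsequent), non_tdm = ...)` of
#'   row-stochastic matrices.
#' @export
build_arm_matrices <- function(params, config = model_config(),
                               or_value = params$or$value) {
  .assert(inherits(config, "cea_config"), "config must be a model_config()")
  .assert(or_value > 0, "or_value must be positive")
  p <- params$pooled
  fac <- switch(config$or_mode,
    printed_is_pooled = c(tdm = 1 / sqrt(or_value), non_tdm = sqrt(or_value)),
    printed_is_tdm    = c(tdm = 1, non_tdm = or_value),
    printed_is_nontdm = c(tdm = 1 / or_value, non_tdm = 1))
  adj <- function(row, f) if (f == 1) setNames(as.numeric(row), STATES)
                          else apply_or_adjustment(row, f, config$or_cuts)
  mk <- function(nr, r) {
    m <- rbind(no_response = nr, response = r,
               seizure_free = c(0, 0, 1, 0), discontinue = c(0, 0, 0, 1))
    colnames(m) <- STATES
    m
  }
  out <- lapply(ARMS, function(a) {
    f <- fac[[a]]
    first_nr <- adj(p$first, f)
    if (config$or_scope == "both_phases") {
      sub_nr <- adj(p$sub_no_response, f)
      sub_r <- adj(p$sub_response, f)
    } else {
      sub_nr <- setNames(as.numeric(p$sub_no_response), STATES)
      sub_r <- setNames(as.numeric(p$sub_response), STATES)
    }
    list(first = mk(first_nr, sub_r), subsequent = mk(sub_nr, sub_r))
  })
  names(out) <- ARMS
  out
}

#' Run the cohort through the Markov chain
#'
#' Starts the whole cohort in the no-response state and propagates the
#' occupancy vector through the first-cycle matrix once and the
#' subsequent-cycle matrix thereafter:
#' `occupancy_{t} = occupancy_{t-1} P_phase(t)`.
#'
#' @param matrices `list(first, subsequent)` of 4 x 4 row-stochastic
#'   matrices (one arm), or a function `f(t)` returning the matrix for
#'   cycle `t` (used by the monitoring-switch scenario).
#' @param n_cycles number of transitions to run.
#' @return a `cohort_trace`: an `(n_cycles + 1) x 4` matrix of state
#'   occupancies whose first row is the entry distribution (1, 0, 0, 0).
#' @export
run_cohort <- function(matrices, n_cycles) {
  .assert(n_cycles >= 1, "n_cycles must be >= 1")
  get_P <- if (is.function(matrices)) matrices
           else function(t) if (t == 1L) matrices$first else matrices$subsequent
  s <- c(1, 0, 0, 0)
  trace <- matrix(NA_real_, n_cycles + 1L, 4L,
                  dimnames = list(0:n_cycles, STATES))
  trace[1L, ] <- s
  for (t in seq_len(n_cycles)) {
    P <- get_P(t)
    .assert(is.matrix(P) && all(dim(P) == 4L) &&
              all(abs(rowSums(P) - 1) <= 1e-9) && all(P >= -1e-12 & P <= 1 + 1e-12),
            "non-stochastic transition matrix at cycle ", t)
    s <- as.numeric(s %*% P)
    trace[t + 1L, ] <- s
  }
  structure(trace, class = c("cohort_trace", "matrix"))
}

#' Discount factor for a model cycle
#'
#' The textbook convention: the first reward is undiscounted and cycle `t`
#' is discounted by `(1 + rate)^(-(t - 1) * cycle_length_years)`. With
#' `basis = "per_cycle"` the exponent is `-(t - 1)` regardless of cycle
#' length, i.e. the rate is applied once per cycle; the calibrated
#' configuration uses this basis (see [model_config]).
#'
#' @param cycle_index 1-based reward index (cycle 1 is undiscounted).
#' @param annual_rate discount rate (>= 0).
#' @param cycle_length_years cycle length in years.
#' @param basis `"annual"` or `"per_cycle"`.
#' @return a factor in (0, 1].
#' @examples
#' discount_factor(1, 0.05)        # 1
#' discount_factor(3, 0.05, 0.5)   # 1/1.05
#' @export
discount_factor <- function(cycle_index, annual_rate,
                            cycle_length_years = 0.5,
                            basis = c("annual", "per_cycle")) {
  basis <- match.arg(basis)
  .assert(all(cycle_index >= 1), "cycle_index starts at 1")
  .assert(annual_rate >= 0, "rate must be >= 0")
  expo <- if (basis == "annual") (cycle_index - 1) * cycle_length_years
          else (cycle_index - 1)
  (1 + annual_rate)^(-expo)
}

# expected per-cycle adverse-event cost and QALY decrement per person in an
# AE-eligible state
.ae_load <- function(arm_block, disu_tab) {
  p <- arm_block$ae$prob
  cost <- sum(p * arm_block$ae$cost)
  d <- disu_tab$disutility[match(arm_block$ae$event, disu_tab$event)]
  list(cost = cost, disutility = sum(p * abs(d)))
}

#' Accumulate discounted costs and QALYs over a cohort trace
#'
#' Per occupancy point, cost is the occupancy-weighted state cost plus the
#' adverse-event layer (occupancy in AE-eligible states times the expected
#' per-cycle event cost), and the QALY contribution is the
#' occupancy-weighted utility (scaled per `qaly_scale`) minus the expected
#' adverse-event disutility, which is a per-event decrement not scaled by
#' cycle length. Rewards are discounted with [discount_factor] under the
#' configured basis; when `include_entry_cycle` is set the entry
#' distribution earns the first (undiscounted) reward. The optional
#' half-cycle correction replaces each occupancy row by the average of
#' adjacent rows.
#'
#' @param trace a [run_cohort] trace.
#' @param arm_values realized per-arm inputs: a list with `state_cost`
#'   (length-4), `ae_cost` and `ae_disutility` (expected per-cycle values
#'   per person at risk), and `utilities` (length-4). [cea] builds this
#'   from the parameter tables.
#' @param config a [model_config].
#' @return an `arm_result`: `total_cost`, `total_qalys`, and a per-cycle
#'   breakdown data frame.
#' @export
accumulate <- function(trace, arm_values, config) {
  .assert(inherits(config, "cea_config"), "config must be a model_config()")
  u <- arm_values$utilities
  .assert(all(u >= 0 & u <= 1), "utilities must lie in [0, 1]")
  .assert(all(arm_values$state_cost >= 0), "state costs must be >= 0")
  occ <- unclass(trace)
  if (!config$include_entry_cycle) occ <- occ[-1L, , drop = FALSE]
  if (config$half_cycle_correction && nrow(occ) > 1L)
    occ <- (occ[-nrow(occ), , drop = FALSE] + occ[-1L, , drop = FALSE]) / 2
  t_idx <- seq_len(nrow(occ))
  dfc <- discount_factor(t_idx, config$cost_discount_rate,
                         config$cycle_length_years, config$discount_basis)
  dfe <- discount_factor(t_idx, config$effect_discount_rate,
                         config$cycle_length_years, config$discount_basis)
  at_risk <- as.numeric(occ[, config$ae_states, drop = FALSE] %*%
                          rep(1, length(config$ae_states)))
  qs <- if (config$qaly_scale == "per_year") config$cycle_length_years else 1
  cost_t <- as.numeric(occ %*% arm_values$state_cost) + at_risk * arm_values$ae_cost
  qaly_t <- as.numeric(occ %*% u) * qs - at_risk * arm_values$ae_disutility
  per_cycle <- data.frame(
    cycle = t_idx, cost = cost_t, qaly = qaly_t,
    disc_cost = cost_t * dfc, disc_qaly = qaly_t * dfe)
  structure(list(total_cost = sum(per_cycle$disc_cost),
                 total_qalys = sum(per_cycle$disc_qaly),
                 per_cycle = per_cycle),
            class = "arm_result")
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("discounted totals: cost %.2f USD, %.4f QALYs over %d reward points\n",
              x$total_cost, x$total_qalys, nrow(x$per_cycle)))
  invisible(x)
}

# realized inputs for one arm under a config
.arm_values <- function(params, arm, config) {
  blk <- params$arms[[arm]]
  sc <- blk$state_cost
  sc[["discontinue"]] <- .dc_cost(blk, config$dc_cost_mode)
  ae <- .ae_load(blk, params$ae_disutility)
  list(state_cost = sc, ae_cost = ae$cost, ae_disutility = ae$disutility,
       utilities = params$utilities)
}

#' Run the full two-arm cost-effectiveness model
#'
#' Builds the per-arm transition matrices, runs the cohort over the
#' configured horizon, accumulates discounted costs and QALYs for both
#' arms, and computes the incremental cost-effectiveness result of
#' monitoring versus no monitoring.
#'
#' @param params parameter tables from [load_parameter_tables].
#' @param config run configuration from [model_config].
#' @return a `tdm_cea` object with elements `arms` (per-arm `arm_result`),
#'   `traces`, `matrices`, `ce` (a `ce_result`, see [icer]), `params`,
#'   `config`. Methods: `print`, `summary`, `plot`, `simulate` (PSA draws).
#' @examples
#' \donttest{
#' fit <- cea(load_parameter_tables(), model_config())
#' fit
#' }
#' @export
cea <- function(params = load_parameter_tables(), config = model_config()) {
  .assert(inherits(params, "cea_params"), "params must come from load_parameter_tables()")
  mats <- build_arm_matrices(params, config)
  traces <- lapply(mats, run_cohort, n_cycles = config$n_cycles)
  arms <- lapply(ARMS, function(a)
    accumulate(traces[[a]], .arm_values(params, a, config), config))
  names(arms) <- ARMS
  ce <- icer(arms$tdm$total_cost, arms$tdm$total_qalys,
             arms$non_tdm$total_cost, arms$non_tdm$total_qalys,
             thresholds = config$wtp_thresholds)
  structure(list(arms = arms, traces = traces, matrices = mats,
                 ce = ce, params = params, config = config),
            class = "tdm_cea")
}

#' @export
print.tdm_cea <- function(x, ...) {
  cat("Two-arm four-state Markov cost-effectiveness model\n")
  cat(sprintf("  horizon %g y (%d cycles), OR %s applied as %s/%s/%s\n",
              x$config$horizon_years, x$config$n_cycles, x$params$or$value,
              x$config$or_mode, x$config$or_cuts, x$config$or_scope))
  cat(sprintf("  monitored:     cost %10.2f  QALYs %7.4f\n",
              x$arms$tdm$total_cost, x$arms$tdm$total_qalys))
  cat(sprintf("  non-monitored: cost %10.2f  QALYs %7.4f\n",
              x$arms$non_tdm$total_cost, x$arms$non_tdm$total_qalys))
  print(x$ce)
  invisible(x)
}

#' @export
summary.tdm_cea <- function(object, ...) {
  tr <- object$traces
  end <- lapply(tr, function(m) m[nrow(m), ])
  out <- list(ce = object$ce,
              final_occupancy = do.call(rbind, end),
              config = object$config)
  class(out) <- "summary.tdm_cea"
  out
}

#' @export
print.summary.tdm_cea <- function(x, ...) {
  print(x$ce)
  cat("final-cycle state occupancy:\n")
  print(round(x$final_occupancy, 4))
  invisible(x)
}

#' @export
plot.tdm_cea <- function(x, arm = c("tdm", "non_tdm"), ...) {
  arm <- match.arg(arm)
  tr <- x$traces[[arm]]
  matplot_args <- list(...)
  old <- par(no.readonly = TRUE); on.exit(par(old))
  plot(NA, xlim = c(0, nrow(tr) - 1), ylim = c(0, 1),
       xlab = "cycle", ylab = "occupancy",
       main = paste("State occupancy,", arm, "arm"))
  for (j in 1:4) lines(0:(nrow(tr) - 1), tr[, j], lty = j, lwd = 2)
  legend("right", legend = STATES, lty = 1:4, lwd = 2, bty = "n")
  invisible(x)
}

#' @export
simulate.tdm_cea <- function(object, nsim = 1000, seed = NULL, ...) {
  .assert(!is.null(seed), "simulate() needs an explicit seed")
  psa <- run_psa(object$params, object$config, n_draws = nsim, seed = seed, ...)
  psa$draws
}
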