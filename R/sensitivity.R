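#' Build a sampler for one uncertain parameter
#'
#' Parameterizes the registry entry's distribution family by method of
#' moments from the base value and a standard error taken as
#' `(high - low) / (2 * 1.96)` when an interval exists and `0.2 * base`
#' otherwise. The lognormal family is parameterized on the log scale
#' (`meanlog = log(base)`, `sdlog` from the log-scale interval). A zero
#' standard error, or a base value on the boundary of the family's
#' support, yields a point mass.
#'
#' @param spec a single registry row (see [build_param_registry]).
#' @return a `param_sampler` list with `family`, `pars`, and `sample(n)`;
#'   the sampler draws from the current RNG stream (seed it with
#'   `set.seed`).
#' @export
fit_distribution <- function(spec) {
  .assert(is.data.frame(spec) && nrow(spec) == 1L, "spec must be a single registry row")
  m <- spec$base
  # an explicit degenerate interval (low == high) means a known zero spread;
  # only a missing interval falls back to the 20%-of-mean rule
  se <- if (!is.na(spec$low) && !is.na(spec$high))
    (spec$high - spec$low) / (2 * 1.96) else 0.2 * abs(m)
  fam <- spec$dist
  point <- function() list(family = "point", pars = c(value = m),
                           sample = function(n) rep(m, n))
  out <- switch(fam,
    beta = {
      if (se <= 0 || m <= 0 || m >= 1) point()
      else {
        vmax <- m * (1 - m)
        s2 <- min(se^2, 0.95 * vmax) # keep the moment solution feasible
        k <- vmax / s2 - 1
        a <- m * k; b <- (1 - m) * k
        list(family = "beta", pars = c(shape1 = a, shape2 = b),
             sample = function(n) rbeta(n, a, b))
      }
    },
    gamma = {
      if (se <= 0 || m <= 0) point()
      else {
        shape <- m^2 / se^2; rate <- m / se^2
        list(family = "gamma", pars = c(shape = shape, rate = rate),
             sample = function(n) rgamma(n, shape, rate))
      }
    },
    normal = {
      if (se <= 0) point()
      else list(family = "normal", pars = c(mean = m, sd = se),
                sample = function(n) rnorm(n, m, se))
    },
    lognormal = {
      .assert(m > 0, "lognormal base must be positive")
      sdlog <- if (!is.na(spec$low) && spec$low > 0)
        (log(spec$high) - log(spec$low)) / (2 * 1.96) else 0.2
      list(family = "lognormal", pars = c(meanlog = log(m), sdlog = sdlog),
           sample = function(n) rlnorm(n, log(m), sdlog))
    },
    stop("unknown distribution family: ", fam))
  structure(out, class = "param_sampler")
}

#' One-way (tornado) sensitivity analysis
#'
#' Reruns the model with each registry parameter set to its low and high
#' value in turn, everything else at base, and records the two ICERs. The
#' result is sorted by descending spread `|icer_high - icer_low|`. A
#' parameter whose extremes crash the model run is kept with `NA` ICERs
#' and flagged, never dropped silently.
#'
#' @param params,config model inputs.
#' @param registry optionally a prebuilt [build_param_registry].
#' @return a `tdm_owsa` data frame (`id`, `low`, `high`, `icer_at_low`,
#'   `icer_at_high`, `spread`, `failed`) with the base-case ICER in
#'   `attr(, "icer_base")`. `plot()` draws the tornado.
#' @export
one_way_sa <- function(params, config = model_config(),
                       registry = build_param_registry(params, config)) {
  mb <- .model_base(params, config, registry)
  base_out <- .eval_model(mb, mb$base)
  icer_of <- function(o) (o[3] - o[1]) / (o[4] - o[2])
  icer_base <- icer_of(base_out)
  n <- nrow(registry)
  lo <- hi <- rep(NA_real_, n); failed <- logical(n)
  for (i in seq_len(n)) {
    for (side in c("low", "high")) {
      v <- mb$base
      v[i] <- registry[[side]][i]
      o <- tryCatch(.eval_model(mb, v), error = function(e) NULL)
      if (is.null(o)) failed[i] <- TRUE
      else if (side == "low") lo[i] <- icer_of(o) else hi[i] <- icer_of(o)
    }
  }
  out <- data.frame(id = registry$id, low = registry$low, high = registry$high,
                    icer_at_low = lo, icer_at_high = hi,
                    spread = abs(hi - lo), failed = failed,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$spread), ]
  rownames(out) <- NULL
  structure(out, icer_base = icer_base, class = c("tdm_owsa", "data.frame"))
}

#' @export
print.tdm_owsa <- function(x, n = 10, ...) {
  cat(sprintf("One-way sensitivity analysis: %d parameters, base ICER %.2f\n",
              nrow(x), attr(x, "icer_base")))
  print(head(as.data.frame(x)[, c("id", "icer_at_low", "icer_at_high", "spread")], n))
  if (any(x$failed)) cat("failed runs:", sum(x$failed), "\n")
  invisible(x)
}

#' @export
plot.tdm_owsa <- function(x, n = 15, ...) {
  top <- head(x, n)
  base <- attr(x, "icer_base")
  old <- par(no.readonly = TRUE); on.exit(par(old))
  par(mar = c(4, 16, 2, 1))
  ylim <- c(0.5, n + 0.5)
  xlim <- range(c(top$icer_at_low, top$icer_at_high, base), na.rm = TRUE)
  plot(NA, xlim = xlim, ylim = ylim, yaxt = "n", xlab = "ICER (USD/QALY)",
       ylab = "", main = "Tornado diagram")
  for (i in seq_len(nrow(top))) {
    y <- n + 1 - i
    lines(c(top$icer_at_low[i], top$icer_at_high[i]), c(y, y), lwd = 8, col = "grey60")
    points(base, y, pch = "|")
  }
  axis(2, at = n:1, labels = top$id, las = 2, cex.axis = 0.6)
  abline(v = base, lty = 2)
  invisible(x)
}

#' Probabilistic sensitivity analysis
#'
#' Draws every sampled registry parameter from its fitted distribution
#' (see [fit_distribution]), renormalizes each sampled transition row,
#' recomputes the odds-ratio-derived first-cycle rows from the sampled
#' reference row and sampled odds ratio, reruns both arms per draw and
#' records the incremental cost and QALYs. Utilities are truncated to
#' `[0, 1]` and outpatient counts to non-negative values by resampling
#' (the number of resampled values is reported). The cost-effectiveness
#' acceptability curve gives, for each willingness-to-pay, the fraction of
#' draws with positive net monetary benefit.
#'
#' Identical seeds give bit-identical draws and curves.
#'
#' @param params,config model inputs.
#' @param n_draws number of Monte Carlo draws (10,000 in the published
#'   analysis).
#' @param seed integer seed (required).
#' @param wtp_grid willingness-to-pay grid for the acceptability curve.
#' @param registry optionally a prebuilt registry.
#' @return a `tdm_psa` list: `draws` (data frame with `dc`, `de`), `ceac`
#'   (data frame `wtp`, `p_ce`), `p_high_ce` (probability highly
#'   cost-effective at the GDP-per-capita threshold), `n_resampled`,
#'   `seed`.
#' @export
run_psa <- function(params, config = model_config(), n_draws = 10000, seed,
                    wtp_grid = seq(0, 50000, by = 500),
                    registry = build_param_registry(params, config)) {
  .assert(!missing(seed) && length(seed) == 1L && is.finite(seed),
          "run_psa needs an explicit integer seed")
  .assert(n_draws >= 1, "n_draws must be >= 1")
  mb <- .model_base(params, config, registry)
  set.seed(as.integer(seed))
  n_resampled <- 0L
  D <- matrix(rep(mb$base, each = n_draws), nrow = n_draws)
  for (i in seq_len(nrow(registry))) {
    if (registry$derived[i]) next
    smp <- fit_distribution(registry[i, ])
    x <- smp$sample(n_draws)
    if (registry$group[i] == "utility") {
      bad <- which(x < 0 | x > 1)
      for (it in 1:50) {
        if (!length(bad)) break
        n_resampled <- n_resampled + length(bad)
        x[bad] <- smp$sample(length(bad))
        bad <- which(x < 0 | x > 1)
      }
      x <- pmin(pmax(x, 0), 1)
    } else if (registry$dist[i] == "normal") {
      bad <- which(x < 0)
      for (it in 1:50) {
        if (!length(bad)) break
        n_resampled <- n_resampled + length(bad)
        x[bad] <- smp$sample(length(bad))
        bad <- which(x < 0)
      }
      x <- pmax(x, 0)
    }
    D[, i] <- x
  }
  dc <- de <- numeric(n_draws)
  for (k in seq_len(n_draws)) {
    o <- .eval_model(mb, D[k, ])
    dc[k] <- o[3] - o[1]
    de[k] <- o[4] - o[2]
  }
  ceac <- data.frame(wtp = wtp_grid,
                     p_ce = vapply(wtp_grid, function(l) mean(l * de - dc > 0), 0))
  p_high <- mean(config$wtp_thresholds[1] * de - dc > 0)
  structure(list(draws = data.frame(dc = dc, de = de), ceac = ceac,
                 p_high_ce = p_high, n_resampled = n_resampled,
                 seed = seed, n_draws = n_draws,
                 wtp_threshold = config$wtp_thresholds[1]),
            class = "tdm_psa")
}

#' @export
print.tdm_psa <- function(x, ...) {
  cat(sprintf("Probabilistic sensitivity analysis: %d draws (seed %s)\n",
              x$n_draws, format(x$seed)))
  cat(sprintf("  P(highly cost-effective at %s USD/QALY) = %.2f%%\n",
              format(x$wtp_threshold, big.mark = ","), 100 * x$p_high_ce))
  cat(sprintf("  mean increments: cost %.2f USD, %.4f QALYs; %d values resampled\n",
              mean(x$draws$dc), mean(x$draws$de), x$n_resampled))
  invisible(x)
}

#' @export
plot.tdm_psa <- function(x, which = c("ceac", "plane"), ...) {
  which <- match.arg(which)
  old <- par(no.readonly = TRUE); on.exit(par(old))
  if (which == "ceac") {
    plot(x$ceac$wtp, x$ceac$p_ce, type = "l", lwd = 2, ylim = c(0, 1),
         xlab = "willingness to pay (USD/QALY)",
         ylab = "P(cost-effective)", main = "Acceptability curve")
    abline(v = x$wtp_threshold, lty = 2)
  } else {
    plot(x$draws$de, x$draws$dc, pch = ".", cex = 2,
         xlab = "incremental QALYs", ylab = "incremental cost (USD)",
         main = "Cost-effectiveness plane")
    abline(h = 0, v = 0, lty = 3)
    abline(0, x$wtp_threshold, lty = 2)
  }
  invisible(x)
}

#' Scenario analysis
#'
#' Three scenario families:
#'
#' * `"time_horizon"`: rerun the calibrated model with only the horizon
#'   changed (`horizon_years`).
#' * `"one_year_tdm"`: monitoring guides dosing for the first year only.
#'   The monitored arm keeps its own matrices, costs and adverse-event
#'   profile for cycles 1-2, then switches to the non-monitored arm's
#'   matrices, state costs (monitoring testing cost dropped with them) and
#'   adverse-event profile while retaining its accumulated state occupancy.
#' * `"override"`: substitute user-supplied arm parameters (the vehicle
#'   for subgroup analyses whose inputs are not published). `overrides`
#'   must carry complete replacement blocks.
#'
#' @param params,config model inputs.
#' @param name scenario name.
#' @param horizon_years horizon for `"time_horizon"`.
#' @param overrides for `"override"`: a list that may contain `arms`
#'   (complete per-arm blocks as in [load_parameter_tables]), `or`, or
#'   `pooled`.
#' @return a `cea_scenario` list with `scenario`, `ce`, `arms`.
#' @export
run_scenario <- function(params, config = model_config(),
                         name = c("time_horizon", "one_year_tdm", "override"),
                         horizon_years = NULL, overrides = NULL) {
  name <- match.arg(name)
  if (name == "time_horizon") {
    .assert(!is.null(horizon_years) && horizon_years >= config$cycle_length_years,
            "time_horizon scenario needs horizon_years of at least one cycle")
    cfg <- config; cfg$horizon_years <- horizon_years
    cfg$n_cycles <- as.integer(round(horizon_years / cfg$cycle_length_years))
    .assert(abs(horizon_years / cfg$cycle_length_years - cfg$n_cycles) < 1e-9,
            "horizon must be a whole number of cycles")
    fit <- cea(params, cfg)
    return(structure(list(scenario = name, horizon_years = horizon_years,
                          ce = fit$ce, arms = fit$arms), class = "cea_scenario"))
  }
  if (name == "override") {
    .assert(is.list(overrides), "override scenario needs an overrides list")
    p2 <- params
    if (!is.null(overrides$arms)) {
      need <- c("state_cost", "cost_components", "ae")
      for (a in names(overrides$arms)) {
        miss <- setdiff(need, names(overrides$arms[[a]]))
        .assert(!length(miss), "override arm '", a, "' lacks fields: ",
                paste(miss, collapse = ", "))
        p2$arms[[a]] <- utils::modifyList(p2$arms[[a]], overrides$arms[[a]])
      }
    }
    if (!is.null(overrides$or)) p2$or <- utils::modifyList(p2$or, overrides$or)
    if (!is.null(overrides$pooled)) p2$pooled <- utils::modifyList(p2$pooled, overrides$pooled)
    fit <- cea(p2, config)
    return(structure(list(scenario = name, ce = fit$ce, arms = fit$arms),
                     class = "cea_scenario"))
  }
  # one_year_tdm: switch the monitored arm to non-monitored behaviour after
  # cycle 2 (month 12)
  mats <- build_arm_matrices(params, config)
  switch_cycle <- 2L
  P_fun <- function(t) {
    if (t <= switch_cycle) (if (t == 1L) mats$tdm$first else mats$tdm$subsequent)
    else mats$non_tdm$subsequent
  }
  trace_td <- run_cohort(P_fun, config$n_cycles)
  trace_nt <- run_cohort(mats$non_tdm, config$n_cycles)
  av_td <- .arm_values(params, "tdm", config)
  av_nt <- .arm_values(params, "non_tdm", config)
  res_nt <- accumulate(trace_nt, av_nt, config)
  # split the monitored arm's rewards at the switch point
  occ <- unclass(trace_td)
  pts <- if (config$include_entry_cycle) 0:config$n_cycles else 1:config$n_cycles
  use_tdm <- pts <= switch_cycle
  acc_piece <- function(rows, av, offset) {
    if (!length(rows)) return(c(0, 0))
    t_idx <- rows + offset
    expo <- if (config$discount_basis == "annual")
      (t_idx - 1) * config$cycle_length_years else t_idx - 1
    sub <- occ[rows, , drop = FALSE]
    at_risk <- rowSums(sub[, match(config$ae_states, STATES), drop = FALSE])
    qs <- if (config$qaly_scale == "per_year") config$cycle_length_years else 1
    cost_t <- as.numeric(sub %*% av$state_cost) + at_risk * av$ae_cost
    qaly_t <- as.numeric(sub %*% av$utilities) * qs - at_risk * av$ae_disutility
    c(sum(cost_t * (1 + config$cost_discount_rate)^(-expo)),
      sum(qaly_t * (1 + config$effect_discount_rate)^(-expo)))
  }
  ridx <- seq_along(pts) + (if (config$include_entry_cycle) 0L else 1L)
  a1 <- acc_piece(ridx[use_tdm], av_td, 0L)
  a2 <- acc_piece(ridx[!use_tdm], av_nt, 0L)
  # NOTE: reward index continues across the switch, so discounting is by the
  # global cycle position
  tot_td <- a1 + a2
  ce <- icer(tot_td[1], tot_td[2], res_nt$total_cost, res_nt$total_qalys,
             thresholds = config$wtp_thresholds)
  structure(list(scenario = name, ce = ce,
                 arms = list(tdm = list(total_cost = tot_td[1],
                                        total_qalys = tot_td[2]),
                             non_tdm = res_nt)),
            class = "cea_scenario")
}

#' @export
print.cea_scenario <- function(x, ...) {
  cat("Scenario:", x$scenario,
      if (!is.null(x$horizon_years)) paste0("(", x$horizon_years, " y)"), "\n")
  print(x$ce)
  invisible(x)
}

#' Calibrate the model conventions against the published totals
#'
#' The published tables do not state which arm the transition rows
#' describe, how the odds ratio was applied, or the exact reward and
#' discounting conventions. This routine runs every candidate combination
#' (odds-ratio mode / cut set / scope, effect-discount rate, and reward
#' convention) over the base case and the 1-, 5- and 10-year horizons,
#' scores each by its worst relative error against the published per-arm
#' cost and QALY totals and the published ICERs, and reports all candidates
#' with the best one flagged. The shipped [model_config] defaults equal the winner.
#'
#' @param params parameter tables (including the `reference` totals).
#' @return a `cea_calibration` data frame of candidates sorted by error,
#'   with the selected configuration in `attr(, "best_config")`.
#' @export
calibrate_config <- function(params) {
  ref <- params$reference
  refrow <- function(a) unlist(ref[ref$analysis == a,
    c("cost_non_tdm", "qaly_non_tdm", "cost_tdm", "qaly_tdm")])
  horizons <- list(base = 15, horizon_1y = 1, horizon_5y = 5, horizon_10y = 10)
  conventions <- list(
    per_cycle_entry = list(discount_basis = "per_cycle",
                           include_entry_cycle = TRUE, qaly_scale = "per_cycle"),
    annual_no_entry = list(discount_basis = "annual",
                           include_entry_cycle = FALSE, qaly_scale = "per_year"))
  rows <- list(); cfgs <- list()
  for (conv in names(conventions)) for (om in c("printed_is_pooled", "printed_is_tdm", "printed_is_nontdm"))
    for (oc in c("four_state", "on_per")) for (os in c("first_cycle", "both_phases"))
      for (ed in c(0.05, 0)) {
        cv <- conventions[[conv]]
        cfg <- model_config(or_mode = om, or_cuts = oc, or_scope = os,
                            effect_discount_rate = ed,
                            discount_basis = cv$discount_basis,
                            include_entry_cycle = cv$include_entry_cycle,
                            qaly_scale = cv$qaly_scale)
        errs <- c(); icer15 <- NA
        for (h in names(horizons)) {
          cfg_h <- cfg
          cfg_h$horizon_years <- horizons[[h]]
          cfg_h$n_cycles <- as.integer(horizons[[h]] / cfg$cycle_length_years)
          fit <- cea(params, cfg_h)
          got <- c(fit$arms$non_tdm$total_cost, fit$arms$non_tdm$total_qalys,
                   fit$arms$tdm$total_cost, fit$arms$tdm$total_qalys)
          errs <- c(errs, abs(got - refrow(h)) / refrow(h))
          ref_icer <- ref$icer[ref$analysis == h]
          errs <- c(errs, abs(fit$ce$icer - ref_icer) / ref_icer)
          if (h == "base") icer15 <- fit$ce$icer
        }
        rows[[length(rows) + 1L]] <- data.frame(
          convention = conv, or_mode = om, or_cuts = oc, or_scope = os,
          effect_discount = ed, icer_base = icer15,
          max_rel_error = max(errs), stringsAsFactors = FALSE)
        cfgs[[length(cfgs) + 1L]] <- cfg
      }
  out <- do.call(rbind, rows)
  ord <- order(out$max_rel_error)
  out <- out[ord, ]; cfgs <- cfgs[ord]
  out$selected <- seq_len(nrow(out)) == 1L
  rownames(out) <- NULL
  structure(out, best_config = cfgs[[1L]],
            reference_icer = ref$icer[ref$analysis == "base"],
            class = c("cea_calibration", "data.frame"))
}

#' @export
print.cea_calibration <- function(x, n = 8, ...) {
  cat("Calibration against published cost/QALY totals (best first)\n")
  print(head(as.data.frame(x), n), digits = 4)
  b <- attr(x, "best_config")
  cat(sprintf("selected: %s / %s / %s, effect discount %g, basis %s (published base ICER %.2f)\n",
              b$or_mode, b$or_cuts, b$or_scope, b$effect_discount_rate,
              b$discount_basis, attr(x, "reference_icer")))
  invisible(x)
}
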