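#' Build the uncertain-parameter registry
#'
#' Enumerates every uncertain input of the model as one `ParamSpec` row:
#' identifier, location (arm/state/item), base value, one-way range,
#' distribution family and whether the entry is derived (recomputed from
#' the odds ratio rather than sampled independently). Printed 95% intervals
#' are used verbatim as the one-way range; where no interval is printed the
#' range is `base +/- 1.96 * 0.2 * base` (a standard error of 20% of the
#' mean), clipped to `[0, 1]` for probabilities.
#'
#' Families follow the published assignment: gamma for costs (and, on its
#' magnitude, the adverse-event disutility and the monitoring count), beta
#' for probabilities, normal for utilities and outpatient counts, lognormal
#' for the odds ratio.
#'
#' Under the default configuration the registry on the packaged tables has
#' 240 rows: per arm the 4 adverse-event probabilities and 4 costs, 4
#' per-state cost totals, 12 hospitalization components, the
#' discontinue-state hospitalization total, 4 outpatient counts, 4
#' consultation costs, 4 outpatient totals, 3 perampanel costs, 4 other-ASM
#' costs, 52 drug-combination probabilities and the 4 derived first-cycle
#' transition probabilities (plus monitoring count and unit cost in the
#' monitored arm); 12 pooled transition probabilities; and the shared odds
#' ratio, 4 utilities, 4 adverse-event disutilities, test and examination
#' costs, 14 drug unit prices and the discount rate.
#'
#' @param params a [load_parameter_tables] object.
#' @param config a [model_config]; decides how transition entries are laid
#'   out (reference rows vs derived rows).
#' @return a `param_registry` data frame with columns `id`, `group`,
#'   `arm`, `state`, `item`, `base`, `low`, `high`, `dist`, `derived`.
#' @export
build_param_registry <- function(params, config = model_config()) {
  rows <- list()
  add <- function(group, arm, state, item, base, low = NA, high = NA,
                  dist, derived = FALSE) {
    if (is.na(low) || is.na(high)) {
      half <- 1.96 * 0.2 * abs(base)
      low <- base - half; high <- base + half
      if (dist == "beta") { low <- max(0, low); high <- min(1, high) }
      if (dist == "gamma") low <- max(0, low)
    }
    .assert(low <= high, "inverted range for ", group, "/", arm, "/", state, "/", item,
            ": low ", low, " > high ", high)
    .assert(low <= base && base <= high || (low == high),
            "base outside range for ", paste(group, arm, state, item))
    id <- paste(c(group, arm, state, item)[c(TRUE, !is.na(arm), !is.na(state), !is.na(item))],
                collapse = ".")
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, group = group, arm = ifelse(is.na(arm), "", arm),
      state = ifelse(is.na(state), "", state), item = ifelse(is.na(item), "", item),
      base = base, low = low, high = high, dist = dist, derived = derived,
      stringsAsFactors = FALSE)
  }

  # shared block
  add("or", NA, NA, NA, params$or$value, params$or$low, params$or$high, "lognormal")
  for (s in STATES) {
    i <- match(s, params$utilities_rng$state)
    add("utility", NA, s, NA, params$utilities_rng$utility[i],
        params$utilities_rng$low[i], params$utilities_rng$high[i], "normal")
  }
  for (i in seq_len(nrow(params$ae_disutility)))
    add("ae_disutility", NA, NA, params$ae_disutility$event[i],
        params$ae_disutility$disutility[i], params$ae_disutility$low[i],
        params$ae_disutility$high[i], "gamma")
  add("outp_unit", NA, NA, "test_cost", unname(params$misc["test_cost"]), dist = "gamma")
  add("outp_unit", NA, NA, "exam_cost", unname(params$misc["exam_cost"]), dist = "gamma")
  for (i in seq_len(nrow(params$drug_prices)))
    add("drug_price", NA, NA, params$drug_prices$drug[i],
        params$drug_prices$unit_price[i], dist = "gamma")
  add("discount_rate", NA, NA, NA, unname(params$misc["discount_rate"]), dist = "beta")

  # reference (pooled) transition rows
  ref_rows <- list(first = params$pooled$first,
                   sub_no_response = params$pooled$sub_no_response,
                   sub_response = params$pooled$sub_response)
  for (ph in names(ref_rows))
    for (s in STATES)
      add("trans_ref", "pooled", ph, s, unname(ref_rows[[ph]][s]), dist = "beta")

  # per-arm blocks
  mats <- build_arm_matrices(params, config)
  for (a in ARMS) {
    blk <- params$arms[[a]]
    for (i in seq_len(nrow(blk$ae))) {
      add("ae_prob", a, NA, blk$ae$event[i], blk$ae$prob[i],
          blk$ae$prob_low[i], blk$ae$prob_high[i], "beta")
      add("ae_cost", a, NA, blk$ae$event[i], blk$ae$cost[i],
          blk$ae$cost_low[i], blk$ae$cost_high[i], "gamma")
    }
    for (s in STATES)
      add("state_cost_total", a, s, NA, unname(blk$state_cost[s]), dist = "gamma")
    for (i in seq_len(nrow(blk$hosp))) {
      s <- blk$hosp$state[i]
      add("hosp_p", a, s, NA, blk$hosp$p_hosp[i], dist = "beta")
      add("hosp_n", a, s, NA, blk$hosp$n_hosp[i], dist = "gamma")
      add("hosp_days", a, s, NA, blk$hosp$days[i], dist = "gamma")
      add("hosp_daily_cost", a, s, NA, blk$hosp$daily_cost[i], dist = "gamma")
    }
    add("hosp_dc_total", a, "discontinue", NA,
        blk$cost_components["discontinue", "hospitalization"], dist = "gamma")
    for (i in seq_len(nrow(blk$outpatient))) {
      s <- blk$outpatient$state[i]
      add("outp_n", a, s, NA, blk$outpatient$n_outpatient[i],
          blk$outpatient$n_low[i], blk$outpatient$n_high[i], "normal")
      add("consult_cost", a, s, NA, blk$outpatient$consult_cost[i], dist = "gamma")
      add("outp_total", a, s, NA, blk$cost_components[s, "outpatient"], dist = "gamma")
    }
    for (s in STATES[1:3])
      add("per_cost", a, s, NA, blk$cost_components[s, "per"], dist = "gamma")
    for (s in STATES)
      add("other_asm", a, s, NA, blk$cost_components[s, "other_asm"], dist = "gamma")
    for (i in seq_len(nrow(blk$combos)))
      add("combo", a, blk$combos$state[i], blk$combos$drug[i],
          blk$combos$prob[i], blk$combos$low[i], blk$combos$high[i], "beta")
    # discontinue-state combination profile: not printed; mirrors the
    # no-response profile like the other discontinue-state rows do
    nr <- blk$combos[blk$combos$state == "no_response", , drop = FALSE]
    for (i in seq_len(nrow(nr)))
      add("combo", a, "discontinue", nr$drug[i], nr$prob[i], nr$low[i], nr$high[i], "beta")
    # per-arm first-cycle rows are always recomputed from the reference rows
    # and the odds ratio (identity transform for a reference arm), so they
    # are one-way targets but never sampled independently
    for (s in STATES)
      add("trans_first", a, "first", s, unname(mats[[a]]$first["no_response", s]),
          dist = "beta", derived = TRUE)
    if (a == "tdm") {
      add("tdm_count", a, NA, NA, unname(params$misc["tdm_count"]),
          params$misc_rng$low[params$misc_rng$key == "tdm_count"],
          params$misc_rng$high[params$misc_rng$key == "tdm_count"], "gamma")
      add("tdm_unit_cost", a, NA, NA, unname(params$misc["tdm_unit_cost"]), dist = "gamma")
    }
  }
  reg <- do.call(rbind, rows)
  .assert(!anyDuplicated(reg$id), "duplicate registry ids")
  class(reg) <- c("param_registry", "data.frame")
  reg
}

#' @export
print.param_registry <- function(x, ...) {
  cat("Uncertain-parameter registry:", nrow(x), "entries (",
      sum(x$derived), "derived )\n")
  print(table(x$group))
  invisible(x)
}

# ---- fast model evaluation under parameter overrides -----------------------

# Precompute everything .eval_model needs. `reg` fixes the parameter order.
.model_base <- function(params, config, reg = build_param_registry(params, config)) {
  idx <- function(...) {
    sel <- rep(TRUE, nrow(reg))
    crit <- list(...)
    for (nm in names(crit)) sel <- sel & reg[[nm]] == crit[[nm]]
    which(sel)
  }
  one <- function(...) { i <- idx(...); .assert(length(i) == 1L, "registry lookup"); i }
  arm_idx <- function(a) list(
    ae_prob = idx(group = "ae_prob", arm = a),
    ae_cost = idx(group = "ae_cost", arm = a),
    state_total = vapply(STATES, function(s) one(group = "state_cost_total", arm = a, state = s), 1L),
    hosp = lapply(c("seizure_free", "response", "no_response"), function(s)
      c(p = one(group = "hosp_p", arm = a, state = s),
        n = one(group = "hosp_n", arm = a, state = s),
        d = one(group = "hosp_days", arm = a, state = s),
        c = one(group = "hosp_daily_cost", arm = a, state = s))),
    hosp_dc = one(group = "hosp_dc_total", arm = a),
    outp = lapply(STATES, function(s)
      c(n = one(group = "outp_n", arm = a, state = s),
        cc = one(group = "consult_cost", arm = a, state = s),
        tot = one(group = "outp_total", arm = a, state = s))),
    per = vapply(STATES[1:3], function(s) one(group = "per_cost", arm = a, state = s), 1L),
    other = vapply(STATES, function(s) one(group = "other_asm", arm = a, state = s), 1L),
    combo = lapply(STATES, function(s) idx(group = "combo", arm = a, state = s)),
    first = vapply(STATES, function(s) one(group = "trans_first", arm = a, item = s), 1L),
    tdm = if (a == "tdm") c(count = one(group = "tdm_count"),
                            unit = one(group = "tdm_unit_cost")) else NULL)
  list(
    params = params, config = config, reg = reg, base = reg$base,
    i_or = one(group = "or"),
    i_util = vapply(STATES, function(s) one(group = "utility", state = s), 1L),
    i_disu = idx(group = "ae_disutility"),
    i_test = one(group = "outp_unit", item = "test_cost"),
    i_exam = one(group = "outp_unit", item = "exam_cost"),
    i_price = idx(group = "drug_price"),
    price_names = reg$item[idx(group = "drug_price")],
    i_disc = one(group = "discount_rate"),
    i_ref = list(first = vapply(STATES, function(s) one(group = "trans_ref", state = "first", item = s), 1L),
                 sub_nr = vapply(STATES, function(s) one(group = "trans_ref", state = "sub_no_response", item = s), 1L),
                 sub_r = vapply(STATES, function(s) one(group = "trans_ref", state = "sub_response", item = s), 1L)),
    arm = list(tdm = arm_idx("tdm"), non_tdm = arm_idx("non_tdm")))
}

# renormalize a row; if exactly one cell moved, keep it and rescale the rest
.row_renorm <- function(row, base_row) {
  row[row < 0] <- 0
  moved <- which(abs(row - base_row) > 1e-12)
  if (length(moved) == 1L && row[moved] <= 1) {
    rest <- sum(base_row[-moved])
    if (rest > 0) row[-moved] <- base_row[-moved] * (1 - row[moved]) / rest
    else row[moved] <- 1
  }
  s <- sum(row)
  .assert(s > 0, "transition row degenerated to zero mass")
  row / s
}

# Evaluate both arms under a full parameter vector v (registry order).
# Returns c(cost_non_tdm, qaly_non_tdm, cost_tdm, qaly_tdm).
.eval_model <- function(mb, v, n_cycles = mb$config$n_cycles) {
  cfg <- mb$config
  or_v <- v[mb$i_or]
  ref_first <- .row_renorm(v[mb$i_ref$first], mb$base[mb$i_ref$first])
  sub_nr <- .row_renorm(v[mb$i_ref$sub_nr], mb$base[mb$i_ref$sub_nr])
  sub_r <- .row_renorm(v[mb$i_ref$sub_r], mb$base[mb$i_ref$sub_r])
  fac <- switch(cfg$or_mode,
    printed_is_pooled = c(tdm = 1 / sqrt(or_v), non_tdm = sqrt(or_v)),
    printed_is_tdm    = c(tdm = 1, non_tdm = or_v),
    printed_is_nontdm = c(tdm = 1 / or_v, non_tdm = 1))
  util <- pmin(pmax(v[mb$i_util], 0), 1)
  disu <- abs(v[mb$i_disu])
  prices <- v[mb$i_price]
  base_prices <- mb$base[mb$i_price]
  names(prices) <- names(base_prices) <- mb$price_names
  rate <- v[mb$i_disc]

  out <- numeric(4)
  for (a in ARMS) {
    ai <- mb$arm[[a]]
    f <- fac[[a]]
    first <- if (f == 1) ref_first else apply_or_adjustment(ref_first, f, cfg$or_cuts)
    if (cfg$or_scope == "both_phases" && f != 1) {
      s_nr <- apply_or_adjustment(sub_nr, f, cfg$or_cuts)
      s_r <- apply_or_adjustment(sub_r, f, cfg$or_cuts)
    } else { s_nr <- sub_nr; s_r <- sub_r }
    # direct perturbation of the derived first-cycle row (one-way analysis)
    dv <- v[ai$first]
    if (any(abs(dv - mb$base[ai$first]) > 1e-12))
      first <- .row_renorm(ifelse(abs(dv - mb$base[ai$first]) > 1e-12, dv, first),
                           first)
    P1 <- rbind(first, s_r, c(0, 0, 1, 0), c(0, 0, 0, 1))
    P2 <- rbind(s_nr, s_r, c(0, 0, 1, 0), c(0, 0, 0, 1))

    # state costs: totals plus component deltas
    sc <- v[ai$state_total]
    names(sc) <- STATES
    if (cfg$dc_cost_mode == "components") {
      blk <- mb$params$arms[[a]]
      sc[["discontinue"]] <- sum(blk$cost_components["discontinue",
                                 c("hospitalization", "outpatient", "other_asm")])
    }
    hs <- c("seizure_free", "response", "no_response")
    for (k in seq_along(hs)) {
      ii <- ai$hosp[[k]]
      sc[hs[k]] <- sc[hs[k]] + prod(v[ii]) - prod(mb$base[ii])
    }
    sc["discontinue"] <- sc["discontinue"] + v[ai$hosp_dc] - mb$base[ai$hosp_dc]
    for (k in seq_along(STATES)) {
      ii <- ai$outp[[k]]
      f_now <- v[ii["n"]] * v[ii["cc"]] + v[mb$i_test] + v[mb$i_exam]
      f_base <- mb$base[ii["n"]] * mb$base[ii["cc"]] + mb$base[mb$i_test] + mb$base[mb$i_exam]
      sc[STATES[k]] <- sc[STATES[k]] + (f_now - f_base) + (v[ii["tot"]] - mb$base[ii["tot"]])
    }
    for (k in 1:3) {
      i <- ai$per[k]
      scale <- prices["PER"] / base_prices["PER"]
      sc[STATES[k]] <- sc[STATES[k]] + v[i] * scale - mb$base[i]
    }
    for (k in seq_along(STATES)) {
      i <- ai$other[k]
      ci <- ai$combo[[k]]
      dn <- mb$reg$item[ci]
      w_base <- sum(mb$base[ci] * base_prices[dn])
      w_now <- sum(v[ci] * prices[dn])
      scale <- if (w_base > 0) w_now / w_base else 1
      sc[STATES[k]] <- sc[STATES[k]] + v[i] * scale - mb$base[i]
    }
    if (!is.null(ai$tdm)) {
      d_tdm <- v[ai$tdm["count"]] * v[ai$tdm["unit"]] -
               mb$base[ai$tdm["count"]] * mb$base[ai$tdm["unit"]]
      sc[STATES[1:3]] <- sc[STATES[1:3]] + d_tdm
    }
    sc <- pmax(sc, 0)

    ae_cost <- sum(v[ai$ae_prob] * v[ai$ae_cost])
    ae_disu <- sum(v[ai$ae_prob] * disu)

    res <- .accum_core(P1, P2, n_cycles, sc, ae_cost, ae_disu, util, cfg,
                       rate_cost = rate, rate_eff = rate)
    if (a == "non_tdm") out[1:2] <- res else out[3:4] <- res
  }
  out
}

# lean trace + reward accumulation shared by accumulate() and .eval_model()
.accum_core <- function(P1, P2, n_cycles, state_cost, ae_cost, ae_disu, util,
                        cfg, rate_cost = cfg$cost_discount_rate,
                        rate_eff = cfg$effect_discount_rate) {
  occ <- matrix(NA_real_, n_cycles + 1L, 4L)
  s <- c(1, 0, 0, 0)
  occ[1L, ] <- s
  for (t in seq_len(n_cycles)) {
    s <- as.numeric(s %*% (if (t == 1L) P1 else P2))
    occ[t + 1L, ] <- s
  }
  if (!cfg$include_entry_cycle) occ <- occ[-1L, , drop = FALSE]
  if (cfg$half_cycle_correction && nrow(occ) > 1L)
    occ <- (occ[-nrow(occ), , drop = FALSE] + occ[-1L, , drop = FALSE]) / 2
  t_idx <- seq_len(nrow(occ))
  expo <- if (cfg$discount_basis == "annual") (t_idx - 1) * cfg$cycle_length_years
          else t_idx - 1
  at_risk <- rowSums(occ[, match(cfg$ae_states, STATES), drop = FALSE])
  qs <- if (cfg$qaly_scale == "per_year") cfg$cycle_length_years else 1
  cost_t <- as.numeric(occ %*% state_cost) + at_risk * ae_cost
  qaly_t <- as.numeric(occ %*% util) * qs - at_risk * ae_disu
  c(sum(cost_t * (1 + rate_cost)^(-expo)),
    sum(qaly_t * (1 + rate_eff)^(-expo)))
}
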