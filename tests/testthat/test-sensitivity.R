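registry <- build_param_registry(params, base_config)

test_that("the registry enumerates the study's uncertain inputs", {
  expect_equal(nrow(registry), 240)
  expect_true(all(registry$low <= registry$base & registry$base <= registry$high))
  # the key published specs are present with their printed ranges
  or_row <- registry[registry$group == "or", ]
  expect_equal(or_row$base, 0.461)
  expect_equal(c(or_row$low, or_row$high), c(0.220, 0.965))
  expect_identical(or_row$dist, "lognormal")
  dz <- registry[registry$id == "ae_prob.non_tdm.dizziness", ]
  expect_equal(c(dz$base, dz$low, dz$high), c(0.091, 0.073, 0.109))
  expect_identical(dz$dist, "beta")
  # a cost with no printed interval gets the 20%-of-mean standard error rule
  sf <- registry[registry$id == "state_cost_total.tdm.seizure_free", ]
  expect_equal(sf$low, 609.16 * (1 - 1.96 * 0.2))
  expect_equal(sf$high, 609.16 * (1 + 1.96 * 0.2))
  # families by role
  expect_true(all(registry$dist[registry$group %in%
    c("state_cost_total", "ae_cost", "tdm_count")] == "gamma"))
  expect_true(all(registry$dist[registry$group %in% c("ae_prob", "combo")] == "beta"))
  expect_true(all(registry$dist[registry$group == "utility"] == "normal"))
})

test_that("fitted samplers reproduce their moments", {
  set.seed(31)
  # method-of-moments beta example: mean 0.091, SE 0.00918
  spec <- registry[registry$id == "ae_prob.non_tdm.dizziness", ]
  s <- fit_distribution(spec)
  expect_identical(s$family, "beta")
  m <- spec$base; se <- (spec$high - spec$low) / (2 * 1.96)
  expect_equal(unname(s$pars["shape1"] / sum(s$pars)), m)
  expect_equal(unname(s$pars["shape1"] * s$pars["shape2"] /
                        (sum(s$pars)^2 * (sum(s$pars) + 1))), se^2, tolerance = 1e-9)
  # degenerate spread collapses to a point mass
  pm <- fit_distribution(data.frame(base = 5, low = 5, high = 5, dist = "gamma"))
  expect_identical(pm$family, "point")
  expect_equal(pm$sample(3), rep(5, 3))
  # lognormal is parameterized on the log scale: exp(mean log) ~ base
  orspec <- registry[registry$group == "or", ]
  so <- fit_distribution(orspec)
  draws <- so$sample(1e5)
  expect_equal(exp(mean(log(draws))), orspec$base, tolerance = 0.01)
  # every sampled family's first moment matches its target at 1e5 draws
  set.seed(32)
  for (i in sample(nrow(registry), 40)) {
    s <- fit_distribution(registry[i, ])
    if (s$family %in% c("point", "lognormal")) next
    x <- s$sample(1e5)
    mc_se <- stats::sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - registry$base[i]), 3 * mc_se + 1e-12)
  }
  expect_error(fit_distribution(data.frame(base = 1.4, low = 1, high = 2,
                                           dist = "beta"))$sample,
               NA) # mean outside (0,1) collapses via the guard below
  pm2 <- fit_distribution(data.frame(base = 1.4, low = 1, high = 2, dist = "beta"))
  expect_identical(pm2$family, "point")
})

test_that("one-way analysis reproduces the base ICER at degenerate ranges", {
  reg0 <- registry
  reg0$low <- reg0$base
  reg0$high <- reg0$base
  ow0 <- one_way_sa(params, base_config, reg0)
  base_icer <- attr(ow0, "icer_base")
  expect_equal(ow0$icer_at_low, rep(base_icer, nrow(ow0)))
  expect_equal(ow0$icer_at_high, rep(base_icer, nrow(ow0)))
  expect_false(any(ow0$failed))
})

test_that("one-way cost perturbations act linearly through discounted occupancy", {
  mb <- tdmcea:::.model_base(params, base_config, registry)
  i <- which(registry$id == "hosp_daily_cost.non_tdm.no_response")
  v <- mb$base
  delta_c <- 50
  hosp <- params$arms$non_tdm$hosp
  hrow <- hosp[hosp$state == "no_response", ]
  v[i] <- v[i] + delta_c
  out <- tdmcea:::.eval_model(mb, v)
  base_out <- tdmcea:::.eval_model(mb, mb$base)
  # expected cost change: component delta x discounted no-response occupancy
  m <- build_arm_matrices(params, base_config)
  tr <- run_cohort(m$non_tdm, base_config$n_cycles)
  disc <- (1 + base_config$cost_discount_rate)^-(0:base_config$n_cycles)
  occ_weight <- sum(tr[, "no_response"] * disc)
  expected <- hrow$p_hosp * hrow$n_hosp * hrow$days * delta_c * occ_weight
  expect_equal(out[1] - base_out[1], expected, tolerance = 1e-9)
  expect_equal(out[3], base_out[3]) # other arm untouched
  # QALYs untouched by a pure cost parameter
  expect_equal(out[c(2, 4)], base_out[c(2, 4)])
})

test_that("probabilistic analysis is seed-deterministic with coherent draws", {
  psa1 <- run_psa(params, base_config, n_draws = 400, seed = 77, registry = registry)
  psa2 <- run_psa(params, base_config, n_draws = 400, seed = 77, registry = registry)
  expect_identical(psa1$draws, psa2$draws)
  expect_identical(psa1$ceac, psa2$ceac)
  psa3 <- run_psa(params, base_config, n_draws = 400, seed = 78, registry = registry)
  expect_false(identical(psa1$draws, psa3$draws))
  # acceptability boundaries: at zero the curve counts cost savings; at a
  # huge willingness-to-pay it counts effect gains
  de <- psa1$draws$de; dc <- psa1$draws$dc
  expect_equal(psa1$ceac$p_ce[psa1$ceac$wtp == 0], mean(dc < 0))
  expect_equal(mean(1e12 * de - dc > 0), mean(de > 0) )
  # conditional monotonicity: restricted to effect-positive draws the curve
  # cannot decrease
  pos <- de > 0
  ceac_pos <- vapply(psa1$ceac$wtp, function(l) mean(l * de[pos] - dc[pos] > 0), 0)
  expect_true(all(diff(ceac_pos) >= 0))
})

test_that("degenerate distributions make the acceptability curve a step function", {
  reg0 <- registry
  reg0$low <- reg0$base
  reg0$high <- reg0$base
  psa <- run_psa(params, base_config, n_draws = 20, seed = 5, registry = reg0)
  base_icer <- attr(one_way_sa(params, base_config, reg0), "icer_base")
  expect_true(all(psa$ceac$p_ce %in% c(0, 1)))
  expect_true(all(psa$ceac$p_ce[psa$ceac$wtp < base_icer] == 0))
  expect_true(all(psa$ceac$p_ce[psa$ceac$wtp > base_icer] == 1))
})

test_that("scenarios change exactly what they claim to change", {
  # horizon scenarios only shorten the run
  sc10 <- run_scenario(params, base_config, "time_horizon", horizon_years = 10)
  direct <- cea(params, model_config(horizon_years = 10))
  expect_equal(sc10$ce$icer, direct$ce$icer, tolerance = 1e-12)
  expect_error(run_scenario(params, base_config, "time_horizon",
                            horizon_years = 0), "at least one cycle")
  # the monitoring-switch arm matches the comparator's per-cycle cost and
  # event load once switched, given equal occupancy: with identical
  # transition rows everywhere the arms coincide exactly after the switch
  p2 <- params
  p2$or$value <- 1
  sc <- run_scenario(p2, base_config, "one_year_tdm")
  m <- build_arm_matrices(p2, base_config)
  tr <- run_cohort(m$non_tdm, base_config$n_cycles)
  av_nt <- tdmcea:::.arm_values(p2, "non_tdm", base_config)
  av_td <- tdmcea:::.arm_values(p2, "tdm", base_config)
  ref <- accumulate(tr, av_nt, base_config)
  # difference arises only in the first two cycles (plus entry point)
  pts <- 0:2
  disc <- (1 + base_config$cost_discount_rate)^-(pts)
  occ <- tr[pts + 1, , drop = FALSE]
  at_risk <- rowSums(occ[, 1:3])
  dcost <- sum((as.numeric(occ %*% (av_td$state_cost - av_nt$state_cost)) +
                  at_risk * (av_td$ae_cost - av_nt$ae_cost)) * disc)
  expect_equal(sc$arms$tdm$total_cost - ref$total_cost, dcost, tolerance = 1e-9)
  # override scenario swaps whole parameter blocks and validates them
  expect_error(run_scenario(params, base_config, "override",
                            overrides = list(arms = list(tdm = list(state_cost = 1)))),
               "lacks fields")
  ov <- list(arms = list(tdm = params$arms$non_tdm))
  ov$arms$tdm$arm <- "tdm"
  sc_ov <- run_scenario(params, base_config, "override", overrides = ov)
  expect_s3_class(sc_ov, "cea_scenario")
})

test_that("calibration reports all candidates and flags a single winner", {
  cal <- calibrate_config(params)
  expect_equal(nrow(cal), 48)
  expect_equal(sum(cal$selected), 1)
  expect_true(all(diff(cal$max_rel_error) >= 0))
  best <- attr(cal, "best_config")
  expect_s3_class(best, "cea_config")
  # the shipped defaults are the calibration winner
  expect_identical(best$or_mode, base_config$or_mode)
  expect_identical(best$or_cuts, base_config$or_cuts)
  expect_identical(best$or_scope, base_config$or_scope)
  expect_identical(best$discount_basis, base_config$discount_basis)
  expect_equal(best$effect_discount_rate, base_config$effect_discount_rate)
})
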