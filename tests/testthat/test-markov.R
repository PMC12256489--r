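test_that("odds-ratio row adjustment has the required fixed points and limits", {
  first <- params$pooled$first
  # identity at OR = 1 under both cut conventions
  for (cuts in c("on_per", "four_state"))
    expect_equal(apply_or_adjustment(first, 1, cuts), first,
                 tolerance = 1e-12, ignore_attr = TRUE)
  # on-treatment variant: discontinuation held fixed, seizure freedom shrinks
  adj <- apply_or_adjustment(first, 0.461, "on_per")
  expect_equal(unname(adj["discontinue"]), unname(first["discontinue"]))
  expect_lt(adj["seizure_free"], first["seizure_free"])
  expect_equal(sum(adj), 1, tolerance = 1e-12)
  # closed-form check of the two-cut system against a direct computation
  on <- first[1:3] / (1 - first[4])
  cg <- c(on[2] + on[3], on[3])
  odds2 <- 0.461 * cg / (1 - cg)
  cg2 <- odds2 / (1 + odds2)
  expect_equal(unname(adj[1:3]),
               unname(c(1 - cg2[1], cg2[1] - cg2[2], cg2[2]) * (1 - first[4])),
               tolerance = 1e-12)
  # vanishing odds ratio sends the top category to zero
  expect_lt(apply_or_adjustment(first, 1e-12, "on_per")["seizure_free"], 1e-9)
  # four-state variant moves discontinuation (worst category) up when OR < 1
  adj4 <- apply_or_adjustment(first, 0.461, "four_state")
  expect_gt(adj4["discontinue"], first["discontinue"])
  # structural zeros stay zero
  znr <- apply_or_adjustment(params$pooled$sub_no_response, 0.5, "on_per")
  expect_equal(unname(znr["seizure_free"]), 0)
  expect_error(apply_or_adjustment(c(0, 0, 0, 1), 0.5, "on_per"), "on-treatment")
})

test_that("arm matrices are row-stochastic with absorbing states in every mode", {
  sub_r <- params$pooled$sub_response
  expect_equal(sum(sub_r), 1, tolerance = 1e-12) # printed row reordered to state order
  for (om in c("printed_is_pooled", "printed_is_tdm", "printed_is_nontdm"))
    for (os in c("first_cycle", "both_phases")) {
      cfg <- model_config(or_mode = om, or_scope = os)
      m <- build_arm_matrices(params, cfg)
      for (a in c("tdm", "non_tdm")) for (ph in c("first", "subsequent")) {
        P <- m[[a]][[ph]]
        expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-9)
        expect_equal(unname(P["seizure_free", ]), c(0, 0, 1, 0))
        expect_equal(unname(P["discontinue", ]), c(0, 0, 0, 1))
      }
    }
  # OR of one makes the arms identical
  m1 <- build_arm_matrices(params, model_config(), or_value = 1)
  expect_equal(m1$tdm, m1$non_tdm, tolerance = 1e-12)
  # the monitored arm must dominate in long-run seizure freedom
  m <- build_arm_matrices(params, base_config)
  occ_t <- run_cohort(m$tdm, 30); occ_n <- run_cohort(m$non_tdm, 30)
  expect_gt(occ_t[31, "seizure_free"], occ_n[31, "seizure_free"])
})

test_that("the cohort engine conserves mass and matches hand matrix products", {
  m <- build_arm_matrices(params, base_config)
  tr <- run_cohort(m$tdm, 30)
  expect_equal(unname(tr[1, ]), c(1, 0, 0, 0))
  expect_equal(unname(rowSums(tr)), rep(1, 31), tolerance = 1e-9)
  # absorbing occupancy never decreases
  absorbed <- tr[, "seizure_free"] + tr[, "discontinue"]
  expect_true(all(diff(absorbed) >= -1e-12))
  # cycle-1 occupancy equals the first-cycle row
  cfg_tdm <- model_config(or_mode = "printed_is_tdm")
  mt <- build_arm_matrices(params, cfg_tdm)$tdm
  expect_equal(unname(run_cohort(mt, 2)[2, ]),
               unname(params$pooled$first), tolerance = 1e-12)
  # three-cycle hand computation
  s <- c(1, 0, 0, 0)
  s1 <- s %*% mt$first; s2 <- s1 %*% mt$subsequent; s3 <- s2 %*% mt$subsequent
  tr3 <- run_cohort(mt, 3)
  expect_equal(unname(tr3[4, ]), as.numeric(s3), tolerance = 1e-12)
  # identity matrices freeze the cohort
  id <- list(first = diag(4), subsequent = diag(4))
  expect_equal(unname(run_cohort(id, 5)[6, ]), c(1, 0, 0, 0))
  # non-stochastic input is rejected
  bad <- m$tdm; bad$first[1, 1] <- bad$first[1, 1] + 0.2
  expect_error(run_cohort(bad, 3), "stochastic")
})

test_that("trace conservation holds for a thousand random stochastic matrices", {
  set.seed(99)
  for (i in 1:1000) {
    mats <- list(first = rand_stochastic(), subsequent = rand_stochastic())
    tr <- run_cohort(mats, 6)
    expect_true(all(abs(rowSums(tr) - 1) <= 1e-9))
  }
})

test_that("discounting follows its closed form and is monotone in the rate", {
  expect_equal(discount_factor(1, 0.05), 1)
  expect_equal(discount_factor(3, 0.05, 0.5), 1 / 1.05)
  expect_equal(discount_factor(7, 0, 0.5), 1)
  expect_equal(discount_factor(3, 0.05, 0.5, basis = "per_cycle"), 1.05^-2)
  # higher discounting never increases totals
  m <- build_arm_matrices(params, base_config)
  tr <- run_cohort(m$tdm, 30)
  av <- tdmcea:::.arm_values(params, "tdm", base_config)
  totals <- sapply(c(0, 0.03, 0.05, 0.1), function(r) {
    cfg <- base_config
    cfg$cost_discount_rate <- r; cfg$effect_discount_rate <- r
    res <- accumulate(tr, av, cfg)
    c(res$total_cost, res$total_qalys)
  })
  expect_true(all(diff(totals[1, ]) < 0))
  expect_true(all(diff(totals[2, ]) < 0))
})

test_that("reward accumulation matches hand-computed single-cycle values", {
  # one cycle entirely seizure-free, utility 0.650, no adverse events,
  # no discounting, yearly QALY scaling: 0.650 * 0.5 = 0.325
  trace <- structure(matrix(c(0, 0, 1, 0, 0, 0, 1, 0), 2, 4, byrow = TRUE,
                            dimnames = list(0:1, tdmcea:::STATES)),
                     class = c("cohort_trace", "matrix"))
  cfg <- model_config(horizon_years = 0.5, cost_discount_rate = 0,
                      effect_discount_rate = 0, qaly_scale = "per_year",
                      include_entry_cycle = FALSE, discount_basis = "annual")
  av <- list(state_cost = c(0, 0, 100, 0), ae_cost = 0, ae_disutility = 0,
             utilities = c(0.5, 0.597, 0.650, 0.5))
  res <- accumulate(trace, av, cfg)
  expect_equal(res$total_qalys, 0.325)
  expect_equal(res$total_cost, 100)
  # zero utilities and costs give zero totals
  av0 <- list(state_cost = rep(0, 4), ae_cost = 0, ae_disutility = 0,
              utilities = rep(0, 4))
  res0 <- accumulate(trace, av0, cfg)
  expect_equal(res0$total_cost, 0); expect_equal(res0$total_qalys, 0)
  # totals equal the sum of the per-cycle breakdown
  fit <- cea(params, base_config)
  for (a in c("tdm", "non_tdm")) {
    expect_equal(fit$arms[[a]]$total_cost,
                 sum(fit$arms[[a]]$per_cycle$disc_cost), tolerance = 1e-9)
    expect_equal(fit$arms[[a]]$total_qalys,
                 sum(fit$arms[[a]]$per_cycle$disc_qaly), tolerance = 1e-9)
  }
  expect_error(accumulate(trace, list(state_cost = c(0, 0, 1, 0), ae_cost = 0,
                                      ae_disutility = 0,
                                      utilities = c(0, 0, 1.2, 0)), cfg),
               "utilities")
})

test_that("equal odds make the arms differ only through costs and events", {
  # with OR = 1 and the non-monitored arm's cost/event profile cloned into
  # the monitored arm, the two arms are identical
  p2 <- params
  p2$or$value <- 1
  p2$arms$tdm <- p2$arms$non_tdm
  p2$arms$tdm$arm <- "tdm"
  fit <- cea(p2, base_config)
  expect_equal(fit$arms$tdm$total_cost, fit$arms$non_tdm$total_cost, tolerance = 1e-9)
  expect_equal(fit$arms$tdm$total_qalys, fit$arms$non_tdm$total_qalys, tolerance = 1e-9)
  expect_false(fit$ce$icer_defined)
})
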