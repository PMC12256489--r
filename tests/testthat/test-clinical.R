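test_that("outcome classification respects the 50% and 100% reduction boundaries", {
  cases <- list(
    list(8, 0, "seizure_free"),      # 100% reduction
    list(8, 4, "response"),          # exactly 50% counts as response
    list(8, 5, "uncontrolled"),      # 37.5% < 50%
    list(8, NA, "discontinued"),
    list(3, 1.5, "response"),        # half-frequency boundary, non-integer
    list(7, 3.5, "response"),
    list(7, 3.51, "uncontrolled"),
    list(1, 8, "uncontrolled"))      # worsening stays uncontrolled
  for (cs in cases)
    expect_identical(classify_outcome(cs[[1]], cs[[2]]), cs[[3]])
  expect_error(classify_outcome(0, 1), "positive")
  expect_error(classify_outcome(8, -1), ">= 0")
})

test_that("outcome tables count only completers and partition them", {
  recs <- rbind(
    make_record("a", "tdm", 8, 0, 0),
    make_record("b", "tdm", 8, 4, 6),          # response then uncontrolled
    make_record("c", "tdm", 8, NA, NA, disc = 1L),
    make_record("d", "non_tdm", 10, 5, NA, disc = 2L),
    make_record("e", "non_tdm", 10, 2, 2))
  tab <- build_outcome_table(recs, "12m")
  expect_identical(sum(tab), 3L)               # 2 discontinued excluded
  expect_identical(unname(tab["tdm", ]), c(1L, 0L, 1L))
  expect_identical(unname(attr(tab, "discontinued")), c(1L, 1L))
  tab6 <- build_outcome_table(recs, "6m")
  expect_identical(sum(tab6), 4L)              # only the cycle-1 dropout missing
  # all-discontinued cohort is flagged, not mis-counted
  all_disc <- rbind(make_record("x", "tdm", 8, NA, NA, disc = 1L),
                    make_record("y", "non_tdm", 8, NA, NA, disc = 1L))
  expect_true(attr(build_outcome_table(all_disc, "12m"), "empty"))
})

test_that("rates reproduce hand-computed proportions with exact intervals", {
  tab <- structure(study_table, class = c("outcome_table", "matrix"))
  r <- outcome_rates(tab)
  tdm <- r[r$arm == "tdm", ]; nt <- r[r$arm == "non_tdm", ]
  expect_equal(tdm$seizure_free_rate, 26 / 54)
  expect_equal(tdm$responder_rate, 45 / 54)
  expect_equal(nt$seizure_free_rate, 4 / 24)
  expect_equal(nt$responder_rate, 14 / 24)
  # Clopper-Pearson agrees with stats::binom.test by construction; check the
  # interval brackets the point estimate and a degenerate single-category arm
  expect_true(tdm$sf_low < tdm$seizure_free_rate &&
                tdm$seizure_free_rate < tdm$sf_high)
  one_cat <- structure(matrix(c(0L, 0L, 7L, 0L, 0L, 3L), 2, byrow = TRUE,
                              dimnames = dimnames(study_table)),
                       class = c("outcome_table", "matrix"))
  expect_equal(outcome_rates(one_cat)$seizure_free_rate, c(1, 1))
  zero_arm <- structure(matrix(c(1L, 0L, 0L, 0L, 0L, 0L), 2, byrow = TRUE,
                               dimnames = dimnames(study_table)),
                        class = c("outcome_table", "matrix"))
  expect_error(outcome_rates(zero_arm), "zero")
})

test_that("dose recommendations are total over all six concentration cells", {
  expect_identical(recommend_dose_action(50, FALSE)$action, "INCREASE_BY_TDM")
  expect_identical(recommend_dose_action(500, TRUE)$action, "MAINTAIN")
  expect_identical(recommend_dose_action(500, FALSE)$action, "INCREASE_2MG_PER_DAY")
  expect_identical(recommend_dose_action(1200, TRUE)$action, "DECREASE_BY_TDM")
  expect_identical(recommend_dose_action(1200, FALSE)$action, "CONSIDER_OTHER_THERAPY")
  expect_identical(recommend_dose_action(50, TRUE)$action, "MAINTAIN")
  # deterministic and pure in its inputs
  expect_identical(recommend_dose_action(50, TRUE), recommend_dose_action(50, TRUE))
  expect_error(recommend_dose_action(-1, TRUE), "non-negative")
})

test_that("currency helpers follow their closed forms", {
  expect_equal(inflate_cost(100, 0), 100)
  expect_equal(inflate_cost(100, 1), 101.48)
  expect_equal(inflate_cost(100, 2), 100 * 1.0148^2) # 102.98...
  expect_equal(convert_currency(6.73), 1)
  expect_equal(convert_currency(0), 0)
  expect_equal(convert_currency(673), 100)
  expect_error(convert_currency(1, 0), "positive")
})

test_that("transition estimation recovers generator rows and flags empty cells", {
  gs <- generator_spec(n_per_arm = 10000, seed = 11, params = params)
  recs <- generate_cohort(gs)
  est1 <- estimate_transitions(recs, "first")
  est2 <- estimate_transitions(recs, "subsequent")
  for (a in c("tdm", "non_tdm")) {
    expect_lt(max(abs(est1[[a]]$rows["no_response", ] -
                        gs$transitions[[a]]$first["no_response", ])), 0.01)
    for (o in c("no_response", "response"))
      expect_lt(max(abs(est2[[a]]$rows[o, ] -
                          gs$transitions[[a]]$subsequent[o, ])), 0.02)
    expect_equal(sum(est1[[a]]$rows["no_response", ]), 1, tolerance = 1e-12)
  }
  # a cohort where everyone stays uncontrolled
  stuck <- do.call(rbind, lapply(1:6, function(i)
    make_record(paste0("s", i), if (i <= 3) "tdm" else "non_tdm", 8, 7, 7)))
  est <- estimate_transitions(stuck, "first")
  expect_equal(unname(est$tdm$rows["no_response", ]), c(1, 0, 0, 0))
  # missing conditioning cells are explicit
  est_sub <- estimate_transitions(stuck, "subsequent")
  expect_true("tdm/response" %in% est_sub$missing_rows)
  expect_true(all(is.na(est_sub$tdm$rows["response", ])))
})

test_that("state cost estimation averages by occupied state", {
  zero <- rbind(make_record("a", "tdm", 8, 0, 0),
                make_record("b", "non_tdm", 8, 0, 0))
  z <- estimate_state_costs(zero)
  expect_equal(unname(z$tdm$mean["seizure_free", "total"]), 0)
  # known per-state means recovered within 2 SE on a sampled cohort
  gs <- generator_spec(n_per_arm = 3000, seed = 5, params = params)
  recs <- generate_cohort(gs)
  est <- estimate_state_costs(recs)
  # 12 simultaneous cells: bound each standardized error and their average
  zs <- c()
  for (a in c("tdm", "non_tdm")) {
    true_tot <- rowSums(gs$cost_means[[a]])
    for (s in c("no_response", "response", "seizure_free")) {
      n <- est[[a]]$n[s]
      se <- gs$cost_cv * sqrt(sum(gs$cost_means[[a]][s, ]^2)) / sqrt(n)
      zs <- c(zs, (est[[a]]$mean[s, "total"] - true_tot[s]) / se)
    }
  }
  expect_lt(max(abs(zs)), 4)
  expect_lt(mean(abs(zs)), 1.5)
  expect_true(all(est$tdm$mean[!is.na(est$tdm$mean)] >= 0))
})
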