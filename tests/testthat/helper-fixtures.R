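# Shared fixtures: load the packaged parameter tables once per run.
params <- load_parameter_tables()
base_config <- model_config()

# published 12-month outcome counts (uncontrolled, response, seizure_free)
study_table <- local({
  oc <- params$outcomes_12m
  m <- as.matrix(oc[, c("uncontrolled", "response", "seizure_free")])
  rownames(m) <- oc$arm
  m[c("tdm", "non_tdm"), ]
})

# independent grid-search oracle for the cumulative-logit likelihood:
# coarse-to-fine search over (slope, cutpoint1, cutpoint2)
po_grid_oracle <- function(tab, stages = 6, span = 4, k = 15) {
  centre <- c(0, -1, 1)
  width <- rep(span, 3)
  best <- c(-Inf, centre)
  for (s in seq_len(stages)) {
    g1 <- seq(centre[1] - width[1], centre[1] + width[1], length.out = k)
    g2 <- seq(centre[2] - width[2], centre[2] + width[2], length.out = k)
    g3 <- seq(centre[3] - width[3], centre[3] + width[3], length.out = k)
    for (b in g1) for (a1 in g2) for (a2 in g3) {
      if (a2 <= a1) next
      ll <- tdmcea:::.po_loglik(b, c(a1, a2), tab)
      if (ll > best[1]) best <- c(ll, b, a1, a2)
    }
    centre <- best[2:4]
    width <- width * 0.25
  }
  list(loglik = best[1], beta = best[2], cutpoints = best[3:4])
}

# random row-stochastic 4x4 matrix
rand_stochastic <- function() {
  m <- matrix(rexp(16), 4, 4)
  m / rowSums(m)
}

# tiny record builder for hand-made cohorts
make_record <- function(id, arm, baseline, f6, f12, disc = NA_integer_,
                        costs1 = rep(0, 5), costs2 = rep(0, 5), tdm_count = 0L) {
  cats <- c("per", "other_asm", "tdm", "outpatient", "hospitalization")
  df <- data.frame(patient_id = id, arm = arm, baseline_freq = baseline,
                   freq_6m = f6, freq_12m = f12, discontinued_cycle = disc,
                   tdm_count = tdm_count, stringsAsFactors = FALSE)
  for (i in seq_along(cats)) {
    df[[paste0("cost1_", cats[i])]] <- costs1[i]
    df[[paste0("cost2_", cats[i])]] <- costs2[i]
  }
  df
}
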