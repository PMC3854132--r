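# Trajectory integration, apoptosis accumulation and condition panels.

test_that("the untreated baseline stays constant over long horizons", {
  tr <- simulate_trajectory(ref, treatment_condition(horizon = 24),
                            times = seq(0, 24, 4))
  drift <- sweep(tr$states, 2, baseline_state())
  expect_lt(max(abs(drift)), 1e-10)
})

test_that("EGF drives a transient ERK peak that declines within the hour scale", {
  tr <- simulate_trajectory(ref, treatment_condition(egf = 1, horizon = 3),
                            times = seq(0, 3, 0.05))
  erk <- tr$states[, "ERK"]
  t_peak <- tr$times[which.max(erk)]
  expect_lt(t_peak, 1)
  expect_gt(max(erk), 0.5)
  expect_lt(erk[length(erk)], 0.5 * max(erk)) # clear decline by 3 h
})

test_that("LY294002 pre-treatment suppresses pAKT while EGF-driven pERK stays transient", {
  cond <- treatment_condition(egf = 1, egf_onset = 2,
                              inhibitors = list(LY294002 = 10), horizon = 6)
  tr <- simulate_trajectory(ref, cond, times = seq(0, 6, 0.1))
  akt <- tr$states[, "AKT"]
  expect_lt(akt[length(akt)], 0.15)             # suppressed
  erk <- tr$states[, "ERK"]
  expect_gt(max(erk[tr$times > 2]), 0.5)        # delayed EGF still fires ERK
  expect_lt(erk[length(erk)], 0.3)              # and stays transient
  # steady pAKT is monotone in LY dose
  steady_akt <- vapply(c(0, 0.5, 1, 2, 10),
                       function(u) endpoint_state(ref, ly_cond(u))$state[["AKT"]],
                       numeric(1))
  expect_true(all(diff(steady_akt) < 0))
})

test_that("each inhibitor lowers the steady level of its immediate target", {
  targets <- c(AG1478 = "EGFR", C4BRaf = "Raf", `DN-MEK1` = "ERK",
               N17Rac = "Rac", `DN-PAK1` = "PAK", LY294002 = "PI3K",
               `PKI-GFP` = "PKA", BADS112A = "pS112BAD")
  # background with active stimuli so the upstream branches are on
  for (drug in names(targets)) {
    lev <- vapply(c(0, 0.5, 1, 2, 10), function(u) {
      cond <- treatment_condition(egf = 1, stress = 100,
                                  inhibitors = setNames(list(u), drug),
                                  horizon = 24)
      endpoint_state(ref, cond)$state[[targets[[drug]]]]
    }, numeric(1))
    expect_true(all(diff(lev) <= 1e-10), label = drug)
  }
})

test_that("fixed-step RK4 converges and matches the adaptive cross-check", {
  cond <- treatment_condition(egf = 1, stress = 10,
                              inhibitors = list(LY294002 = 1, BADS112A = 1),
                              horizon = 2)
  t1 <- simulate_trajectory(ref, cond, times = c(0, 1, 2), step = 0.005)
  t2 <- simulate_trajectory(ref, cond, times = c(0, 1, 2), step = 0.0025)
  expect_lt(max(abs(cbind(t1$states, t1$apoptosis) -
                    cbind(t2$states, t2$apoptosis))), 1e-8)
  ta <- simulate_trajectory(ref, cond, times = c(0, 1, 2), method = "adaptive")
  expect_lt(max(abs(t1$states - ta$states)), 1e-6)
})

test_that("state contract violations are rejected", {
  expect_error(model_rhs(rep(0.5, 10), 0, ref, treatment_condition(horizon = 1)),
               "13 species")
  s <- baseline_state(); s[3] <- -0.2
  expect_error(model_rhs(s, 0, ref, treatment_condition(horizon = 1)),
               "non-negative")
  expect_error(simulate_trajectory(ref, treatment_condition(horizon = 1),
                                   times = c(0, 2)), "horizon")
  expect_error(treatment_condition(inhibitors = list(FOO = 1)),
               "unknown inhibitor")
})

test_that("apoptosis accumulates monotonically and respects the percentage scale", {
  for (cond in list(ly_cond(1), ly_cond(1, stress = 100),
                    treatment_condition(egf = 1, horizon = 48))) {
    tr <- simulate_trajectory(ref, cond, times = seq(0, 48, 2), step = 0.05)
    expect_true(all(diff(tr$apoptosis) >= -1e-12))
    expect_true(all(tr$apoptosis <= 100))
    expect_equal(tr$apoptosis + tr$survival, rep(100, length(tr$times)))
  }
})

test_that("the apoptosis rate is anti-correlated with BAD phosphorylation and CREB", {
  s <- baseline_state()
  # saturated anti-apoptotic limit: full phosphorylation + high CREB
  s_max <- s; s_max[c("pS112BAD", "pS136BAD")] <- 2.5; s_max["CREB"] <- 1
  expect_lt(apoptosis_rate(s_max, t = 10, ref), 0.05 * apoptosis_rate(
    `[<-`(s, c("pS112BAD", "pS136BAD"), 0), t = 10, ref))
  # rate decreases as pBAD rises
  rates <- vapply(seq(0, 2.4, 0.4), function(b) {
    si <- s; si["pS112BAD"] <- b; si["pS136BAD"] <- 0
    apoptosis_rate(si, t = 10, ref)
  }, numeric(1))
  expect_true(all(diff(rates) < 0))
  expect_error(apoptosis_rate(s, t = 1, ref, ca = 150), "\\[0, 100\\]")
})

test_that("the Mcl-1 model nests the BAD-only model", {
  p_nested <- update_parameters(ref, c(beta_mcl = 1e-10))
  cond <- ly_cond(1, stress = 100)
  t1 <- simulate_trajectory(ref, cond, times = c(0, 24, 48), step = 0.05,
                            variant = "bad_only")
  t2 <- simulate_trajectory(p_nested, cond, times = c(0, 24, 48), step = 0.05,
                            variant = "bad_mcl1")
  expect_equal(t1$apoptosis, t2$apoptosis, tolerance = 1e-6)
  # with CREB == 0 (no stress) both variants give identical rates
  s <- baseline_state()
  expect_identical(apoptosis_rate(s, 5, ref, variant = "bad_only"),
                   apoptosis_rate(s, 5, ref, variant = "bad_mcl1"))
})

test_that("stress antagonizes drug-induced apoptosis monotonically", {
  for (inh in list(list(LY294002 = 1), list(LY294002 = 1, BADS112A = 1),
                   list(`DN-PAK1` = 1))) {
    ca <- vapply(c(0, 1, 10, 100), function(s)
      endpoint_apoptosis(ref, treatment_condition(
        stress = s, inhibitors = inh, horizon = 48)), numeric(1))
    expect_true(all(diff(ca) < 0))
  }
})

test_that("the condition panel reproduces the expected treatment ranking", {
  d <- 48
  panel <- run_condition_panel(ref, list(
    parse_schedule("LY294002:1@0", d, "LY"),
    parse_schedule("LY294002:1@0+C4BRaf:1@0", d, "LY+C4BRaf"),
    parse_schedule("LY294002:1@0+DN-PAK1:1@0", d, "LY+DNPAK1"),
    parse_schedule("LY294002:1@0+DN-PAK1:1@0+C4BRaf:1@0", d, "LY+DNPAK1+C4B")))
  # without EGF/stress these combinations act through the same active branch
  expect_lt(diff(range(panel$apoptosis_pct)), 1)
  # LY294002 + BADS112A is the strongest pair at dose 1 each
  pairs <- utils::combn(inhibitor_names(), 2)
  eff <- apply(pairs, 2, function(pr) endpoint_apoptosis(
    ref, treatment_condition(inhibitors = setNames(list(1, 1), pr),
                             horizon = d)))
  best <- pairs[, which.max(eff)]
  expect_setequal(best, c("LY294002", "BADS112A"))
  # stress = 100 lowers every pairwise-combination endpoint
  eff_s <- apply(pairs, 2, function(pr) endpoint_apoptosis(
    ref, treatment_condition(stress = 100,
                             inhibitors = setNames(list(1, 1), pr),
                             horizon = d)))
  expect_true(all(eff_s < eff))
})

test_that("stress rescues pS112-BAD and CREB under the LY + BADS112A combination", {
  no_stress <- endpoint_state(ref, ly_cond(1, BADS112A = 1))
  stress <- endpoint_state(ref, ly_cond(1, stress = 100, BADS112A = 1))
  expect_gt(stress$state[["pS112BAD"]], no_stress$state[["pS112BAD"]] + 0.2)
  expect_gt(stress$state[["CREB"]], no_stress$state[["CREB"]] + 0.2)
  expect_lt(stress$ca, no_stress$ca)
})

test_that("trajectories export tidily and panels are deterministic", {
  cond <- ly_cond(1, horizon = 24)
  df <- as.data.frame(simulate_trajectory(ref, cond, times = seq(0, 24, 6),
                                          step = 0.05))
  expect_setequal(unique(df$variable), c(species_names(), "apoptosis_pct"))
  expect_identical(nrow(df), 5L * 14L)
  p1 <- run_condition_panel(ref, list(cond, ly_cond(2, horizon = 24)))
  p2 <- run_condition_panel(ref, list(cond, ly_cond(2, horizon = 24)))
  expect_identical(p1, p2)
})
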