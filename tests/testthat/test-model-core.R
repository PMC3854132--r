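# Kinetics primitives, parameter container and steady-state closure.

test_that("Hill activation has the saturation kinetics contract", {
  expect_identical(hill_activation(0, v = 3, k = 0.4, n = 2), 0)
  expect_equal(hill_activation(0.5, v = 2, k = 0.5, n = 1), 1) # half-saturation
  expect_equal(hill_activation(1e9, v = 3, k = 0.4, n = 2), 3, tolerance = 1e-6)
  x <- seq(0, 5, 0.1)
  y <- hill_activation(x, v = 2, k = 0.7, n = 3)
  expect_true(all(diff(y) >= 0))        # monotone
  expect_true(all(y <= 2))              # bounded by v
  expect_error(hill_activation(1, v = -1, k = 1, n = 1), "must be > 0")
  expect_error(hill_activation(1, v = 1, k = 1, n = 0.5), ">= 1")
  expect_error(hill_activation(-1, v = 1, k = 1, n = 1), ">= 0")
})

test_that("drug factor halves the velocity at unit normalized dose", {
  expect_identical(drug_factor(0), 1)
  expect_identical(drug_factor(1), 0.5)
  expect_identical(drug_factor(3), 0.25)
  u <- seq(0, 10, 0.5)
  expect_true(all(diff(drug_factor(u)) < 0))
  expect_error(drug_factor(-0.1), ">= 0")
})

test_that("BADS112A raises the pS112 dephosphorylation rate monotonically", {
  expect_identical(bads112a_decay(0.05, 0), 0.05)
  u <- c(0, 0.5, 1, 2, 10)
  r <- bads112a_decay(0.05, u)
  expect_true(all(diff(r) > 0))
  expect_true(all(r >= 0.05))
  expect_error(bads112a_decay(-1, 0), "> 0")
  expect_error(bads112a_decay(1, -1), ">= 0")
})

test_that("expressing BADS112A lowers the steady pS112 level", {
  base <- endpoint_state(ref, ly_cond(dose = 0, horizon = 72))
  mut <- endpoint_state(ref, treatment_condition(
    inhibitors = list(BADS112A = 1), horizon = 72))
  expect_lt(mut$state[["pS112BAD"]], base$state[["pS112BAD"]])
})

test_that("parameter set exposes 37 signaling and 7 apoptosis free parameters", {
  counts <- count_free_parameters(ref)
  expect_identical(counts[["signaling"]], 37L)
  expect_identical(counts[["apoptosis"]], 7L)
  expect_length(free_parameter_names("signaling"), 37)
  expect_length(free_parameter_names("apoptosis"), 7)
  # derived decays are exactly the four closed species
  expect_named(ref$decay_derived,
               c("d_PI3K", "d_AKT", "d_pS112BAD", "d_pS136BAD"))
})

test_that("parameter validation rejects non-positive and unknown entries", {
  expect_error(update_parameters(ref, c(V_akt = -1)), "positive")
  expect_error(update_parameters(ref, c(nonsense = 1)), "unknown")
  expect_error(update_parameters(ref, c(d_PI3K = 1)), "unknown|non-free")
  bad <- flatten_parameters(ref, include_derived = FALSE)
  bad[["beta_mcl"]] <- 1.5
  expect_error(unflatten_parameters(bad), "\\[0, 1\\]")
})

test_that("steady-state closure makes the baseline a fixed point", {
  for (seed in 1:5) {
    p <- random_parameters(seed)
    dy <- model_rhs(baseline_state(), 0, p, treatment_condition(horizon = 1))
    expect_lt(max(abs(dy)), 1e-12)
  }
})

test_that("closure formula equals baseline activation flux over baseline level", {
  d_pi3k <- hill_activation(1, ref$vmax[["pi3k"]], ref$km[["pi3k"]],
                            ref$hill_n[["pi3k"]]) / baseline_state()[["PI3K"]]
  expect_equal(ref$decay_derived[["d_PI3K"]], d_pi3k)
})

test_that("perturbing one activation velocity only re-closes the decays it feeds", {
  p2 <- update_parameters(ref, c(V_akt = ref$vmax[["akt"]] * 2))
  changed <- names(which(abs(p2$decay_derived - ref$decay_derived) > 1e-15))
  expect_identical(changed, "d_AKT")
  p3 <- update_parameters(ref, c(V_bad112 = ref$vmax[["bad112"]] * 3))
  changed <- names(which(abs(p3$decay_derived - ref$decay_derived) > 1e-15))
  expect_identical(changed, "d_pS112BAD")
})

test_that("flatten/unflatten round-trips a random parameter set", {
  p <- random_parameters(7)
  q <- unflatten_parameters(flatten_parameters(p, include_derived = FALSE))
  expect_equal(flatten_parameters(p), flatten_parameters(q))
})

test_that("wiring YAML maps every inhibitor to exactly one target", {
  doc <- yaml::yaml.load(wiring_yaml())
  expect_setequal(names(doc$inhibitor_targets), inhibitor_names())
  expect_length(unique(unlist(doc$inhibitor_targets)), 8)
  # BADS112A is the only inhibitor acting on a dephosphorylation rate
  on_decay <- grepl("^decay:", unlist(doc$inhibitor_targets))
  expect_identical(names(doc$inhibitor_targets)[on_decay], "BADS112A")
})
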