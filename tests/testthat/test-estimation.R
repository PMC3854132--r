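# Objective, dataset scaling, GA fitting and model selection wiring.

noiseless_tc <- generate_observations(generator_config(
  "ly_egf_timecourse", noise_lognorm_sd = 0, seed = 11))

test_that("the objective is an MSE with exact self-fit and offset behaviour", {
  expect_equal(objective(ref, noiseless_tc), 0, tolerance = 1e-12)
  shifted <- as.data.frame(noiseless_tc)
  shifted$value <- shifted$value + 0.1
  expect_equal(objective(ref, observation_table(shifted)), 0.01,
               tolerance = 1e-9)
  # invariant to row order
  perm <- observation_table(shifted[sample.int(nrow(shifted)), ])
  expect_equal(objective(ref, perm), 0.01, tolerance = 1e-9)
})

test_that("apoptosis residuals enter the objective on the fractional scale", {
  tab <- generate_observations(generator_config(
    "apoptosis_panel", noise_lognorm_sd = 0, seed = 3))
  shifted <- as.data.frame(tab)
  shifted$value <- shifted$value + 10 # +10 percentage points = 0.1 fractional
  expect_equal(objective(ref, observation_table(shifted), step = 0.05), 0.01,
               tolerance = 1e-9)
})

test_that("un-mappable conditions are reported by name", {
  bad <- as.data.frame(noiseless_tc)
  bad$schedule[bad$condition_id == "TC_LY"] <- "NOTADRUG:1@0"
  expect_error(objective(ref, observation_table(bad)), "TC_LY")
})

test_that("apoptosis dataset scaling equalizes the anchor treatments", {
  tab <- generate_observations(generator_config(
    "apoptosis_panel", noise_lognorm_sd = 0, seed = 4))
  same <- scale_apoptosis_datasets(tab, tab)
  expect_equal(same$scale_factor, 1)
  expect_identical(nrow(same$merged), 2L * nrow(tab))
  doubled <- as.data.frame(tab); doubled$value <- doubled$value * 2
  res <- scale_apoptosis_datasets(tab, observation_table(doubled))
  expect_equal(res$scale_factor, 0.5)
  # proportional tables match exactly after scaling; rescaling is idempotent
  expect_equal(sort(res$merged$value), sort(rep(tab$value, 2)))
  again <- scale_apoptosis_datasets(tab, observation_table(
    as.data.frame(res$merged)[res$merged$condition_id %in%
                                paste0(tab$condition_id, "_b"), ]))
  expect_equal(again$scale_factor, 1)
  no_anchor <- observation_table(as.data.frame(tab)[tab$schedule == "control", ])
  expect_error(scale_apoptosis_datasets(tab, no_anchor), "anchor")
})

test_that("the GA respects bounds, is seed-deterministic and improves the fit", {
  free <- c("V_akt", "K_akt")
  truth_vals <- flatten_parameters(ref)[free]
  bounds <- cbind(lo = truth_vals / 4, hi = truth_vals * 4)
  start <- update_parameters(ref, truth_vals * 2.5)
  cfg <- fit_config(free, bounds, pop_size = 24, generations = 12, seed = 99,
                    step = 0.05, polish = TRUE)
  rep1 <- fit_parameters(noiseless_tc, cfg, template = start)
  rep2 <- fit_parameters(noiseless_tc, cfg, template = start)
  expect_identical(rep1$mse, rep2$mse)
  expect_equal(flatten_parameters(rep1$parameters),
               flatten_parameters(rep2$parameters))
  got <- flatten_parameters(rep1$parameters)[free]
  expect_true(all(got >= bounds[, "lo"] & got <= bounds[, "hi"]))
  expect_true(rep1$improved)
  expect_lt(rep1$mse, 1e-4)
  # recovered parameters land near the generating truth
  expect_equal(unname(got), unname(truth_vals), tolerance = 0.2)
})

test_that("model selection splits, fits both variants and reports holdout MSE", {
  tab <- generate_observations(generator_config(
    "apoptosis_panel", noise_lognorm_sd = 0, seed = 5))
  cfg <- tiny_fit_config(free_parameter_names("apoptosis"), seed = 2)
  sel <- model_select(tab, signaling = ref, cfg = cfg)
  expect_true(sel$choice %in% c("bad_only", "bad_mcl1"))
  expect_true(all(is.finite(sel$holdout_mse)))
  expect_identical(sort(unique(sel$train$schedule)),
                   sort(c("LY294002:1@0", "LY294002:1@0+EGF:1@0",
                          "LY294002:1@0+STRESS:10@0")))
  expect_gt(nrow(sel$holdout), 0)
  expect_error(model_select(tab, signaling = ref,
                            train_schedules = unique(tab$schedule),
                            cfg = cfg), "holdout")
})
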