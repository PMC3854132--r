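# Shared fixtures: the reference calibration and a few treatment builders.

ref <- reference_parameters()

ly_cond <- function(dose = 1, stress = 0, horizon = 48, ...) {
  treatment_condition(stress = stress,
                      inhibitors = c(list(LY294002 = dose), list(...)),
                      horizon = horizon)
}

endpoint_state <- function(p, cond, variant = "bad_mcl1") {
  tr <- simulate_trajectory(p, cond, times = c(0, cond$horizon), step = 0.05,
                            variant = variant)
  list(state = tr$states[2, ], ca = tr$apoptosis[2])
}

# tiny GA budget for wiring-level tests (recovery power is exercised in the
# acceptance suite at the documented reduced budget)
tiny_fit_config <- function(free, seed = 1, ...) {
  fit_config(free, pop_size = 20, generations = 10, seed = seed, step = 0.05,
             ...)
}
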