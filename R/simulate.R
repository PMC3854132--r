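# Integration of the ODE system over treatment schedules.

.cond_inputs_at <- function(cond, t) {
  eps <- 1e-12
  list(egf = if (cond$egf_onset <= t + eps) cond$egf else 0,
       stress = if (cond$stress_onset <= t + eps) cond$stress else 0,
       u = ifelse(cond$onset <= t + eps, cond$dose, 0))
}

#' Right-hand side of the signaling + apoptosis ODE system
#'
#' Time derivative of the 14-component state (13 species plus apoptosis
#' percentage) under a treatment condition, with the piecewise schedule
#' evaluated at time `t`. EGFR-branch species decay as `d * tb * x` with the
#' desensitization clock `tb = max(t - egf_onset, 0)` (phenomenological
#' short-term receptor signaling); all other species have
#' constant decay; inhibitor doses scale their target velocity by
#' [drug_factor()], except BADS112A which acts through [bads112a_decay()].
#'
#' @param state Numeric vector of length 13 (species) or 14 (with apoptosis
#'   percentage appended); entries must be non-negative.
#' @param t Time (h, >= 0).
#' @param p A `parameter_set`.
#' @param cond A `treatment_condition`.
#' @param variant Apoptosis model: `"bad_mcl1"` (model 2, default) or
#'   `"bad_only"` (model 1).
#' @return Named numeric vector of derivatives, same length as `state`.
#' @export
model_rhs <- function(state, t, p, cond, variant = "bad_mcl1") {
  n_in <- length(state)
  if (!n_in %in% c(13, 14))
    stop("`state` must have 13 species (plus optional apoptosis %)")
  if (any(state < 0)) stop("`state` entries must be non-negative")
  if (t < 0) stop("`t` must be >= 0")
  y <- c(unname(state), if (n_in == 13) 0)
  inp <- .cond_inputs_at(cond, t)
  dy <- cpp_rhs(y, t, unname(p$vmax), unname(p$km), unname(p$hill_n),
                unname(decay_rates(p)), unname(p$apoptosis),
                .variant_code(variant), inp$egf, inp$stress, unname(inp$u),
                cond$egf_onset)
  names(dy) <- c(species_names(), "apoptosis_pct")
  dy[seq_len(n_in)]
}

.variant_code <- function(variant) {
  switch(match.arg(variant, c("bad_mcl1", "bad_only")),
         bad_only = 1L, bad_mcl1 = 2L)
}

#' Simulate a trajectory under a treatment schedule
#'
#' Integrates the network with a fixed-step 4th-order Runge-Kutta scheme,
#' splitting the integration at every stimulus/inhibitor onset so the
#' right-hand side is smooth within each segment. The `"adaptive"` method
#' (deSolve's lsoda) is provided as an independent cross-check of the
#' default integrator.
#'
#' @param p A `parameter_set`.
#' @param cond A `treatment_condition`.
#' @param times Strictly increasing output time grid starting at 0 (h);
#'   defaults to 201 points over `[0, horizon]`.
#' @param step RK4 step size (h); default 0.01.
#' @param variant Apoptosis model variant, see [model_rhs()].
#' @param method `"rk4"` (default) or `"adaptive"`.
#' @return An object of class `trajectory`: list with `times`, `states`
#'   (matrix, 13 named columns), `apoptosis` (percentage, non-decreasing),
#'   `survival` (100 - apoptosis), `condition`, `variant`.
#' @export
simulate_trajectory <- function(p, cond, times = NULL, step = 0.01,
                                variant = "bad_mcl1", method = c("rk4", "adaptive")) {
  method <- match.arg(method)
  stopifnot(inherits(p, "parameter_set"), inherits(cond, "treatment_condition"))
  if (is.null(times)) times <- seq(0, cond$horizon, length.out = 201)
  if (times[1] != 0 || any(diff(times) <= 0))
    stop("`times` must be strictly increasing and start at 0")
  if (max(times) > cond$horizon + 1e-9)
    stop("`times` must not exceed the condition horizon")
  y0 <- c(unname(baseline_state()), 0)
  vc <- .variant_code(variant)
  if (method == "adaptive") {
    states <- .integrate_adaptive(p, cond, times, y0, vc)
  } else {
    states <- .integrate_rk4(p, cond, times, y0, vc, step)
  }
  colnames(states) <- c(species_names(), "apoptosis_pct")
  structure(list(times = times,
                 states = states[, 1:13, drop = FALSE],
                 apoptosis = states[, 14],
                 survival = 100 - states[, 14],
                 condition = cond, variant = variant),
            class = "trajectory")
}

.integrate_rk4 <- function(p, cond, times, y0, vc, step) {
  onsets <- sort(unique(c(0, cond$egf_onset, cond$stress_onset,
                          cond$onset[cond$dose > 0])))
  onsets <- onsets[onsets <= max(times)]
  breaks <- sort(unique(c(onsets, max(times))))
  out <- matrix(NA_real_, length(times), 14)
  y <- y0
  if (times[1] == 0) out[1, ] <- y0
  first <- if (times[1] == 0) 2L else 1L
  rec_idx <- seq_along(times) >= first
  d <- decay_rates(p)
  branch_max <- max(d[.egfr_branch_species])
  for (s in seq_len(length(breaks) - 1)) {
    t0 <- breaks[s]; t1 <- breaks[s + 1]
    sel <- which(rec_idx & times > t0 + 1e-12 & times <= t1 + 1e-12)
    inp <- .cond_inputs_at(cond, t0)
    # linear-stability cap: the fastest decay eigenvalue must stay inside
    # the RK4 stability interval (lambda * h < 2.5)
    lam <- max(d[!names(d) %in% .egfr_branch_species],
               branch_max * max(t1 - cond$egf_onset, 0),
               d[["pS112BAD"]] * (1 + inp$u[["BADS112A"]]))
    seg_step <- min(step, 2.5 / lam)
    res <- cpp_integrate_segment(y, t0, t1, seg_step, times[sel],
                                 unname(p$vmax), unname(p$km),
                                 unname(p$hill_n), unname(decay_rates(p)),
                                 unname(p$apoptosis), vc,
                                 inp$egf, inp$stress, unname(inp$u),
                                 cond$egf_onset)
    if (length(sel)) out[sel, ] <- res$states
    y <- res$yend
  }
  out
}

.integrate_adaptive <- function(p, cond, times, y0, vc) {
  deriv <- function(t, y, parms) {
    inp <- .cond_inputs_at(cond, t)
    y <- pmax(y, 0)
    list(cpp_rhs(y, t, unname(p$vmax), unname(p$km), unname(p$hill_n),
                 unname(decay_rates(p)), unname(p$apoptosis), vc,
                 inp$egf, inp$stress, unname(inp$u), cond$egf_onset))
  }
  onsets <- sort(unique(c(cond$egf_onset, cond$stress_onset,
                          cond$onset[cond$dose > 0])))
  onsets <- onsets[onsets > 0 & onsets < max(times)]
  sol <- deSolve::ode(y = y0, times = sort(unique(c(times, onsets))),
                      func = deriv, parms = NULL, method = "lsoda",
                      rtol = 1e-9, atol = 1e-10)
  sol <- sol[match(times, sol[, 1]), -1, drop = FALSE]
  pmax(sol, 0)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s; %d time points over [0, %g] h; endpoint apoptosis %.2f%%\n",
              format_schedule(x$condition), length(x$times), max(x$times),
              x$apoptosis[length(x$apoptosis)]))
  invisible(x)
}

#' Tidy data frame of a trajectory (time, variable, value)
#' @param x A `trajectory`.
#' @param ... Unused.
#' @return A long-format `data.frame` with `time`, `variable`, `value` and
#'   `condition_id` columns.
#' @export
as.data.frame.trajectory <- function(x, ...) {
  id <- if (is.null(x$condition$id)) format_schedule(x$condition) else x$condition$id
  m <- cbind(x$states, apoptosis_pct = x$apoptosis)
  data.frame(time = rep(x$times, ncol(m)),
             variable = rep(colnames(m), each = nrow(m)),
             value = as.vector(m),
             condition_id = id,
             stringsAsFactors = FALSE)
}

#' Instantaneous apoptosis accumulation rate
#'
#' Evaluates `dCa/dt` of the chosen apoptosis model at a given signaling
#' state: the rate is proportional to elapsed time, to the unphosphorylated
#' (pro-apoptotic) BAD fraction, under model 2 to the CREB/Mcl-1 de-protection
#' factor, and to the surviving fraction `(100 - Ca)`.
#'
#' @param state Numeric vector of 13 species levels.
#' @param t Time (h).
#' @param p A `parameter_set`.
#' @param ca Current apoptosis percentage in \[0, 100\].
#' @param variant `"bad_mcl1"` or `"bad_only"`.
#' @return Non-negative rate (percentage points per hour).
#' @export
apoptosis_rate <- function(state, t, p, ca = 0, variant = "bad_mcl1") {
  if (ca < 0 || ca > 100) stop("`ca` must lie in [0, 100]")
  if (p$apoptosis[["bad_total"]] <= 0) stop("`bad_total` must be > 0")
  dy <- model_rhs(c(unname(state), ca), t, p,
                  treatment_condition(horizon = max(t, 1)), variant)
  unname(dy["apoptosis_pct"])
}

#' Endpoint apoptosis for a panel of conditions
#'
#' Simulates each condition to its horizon and reports the endpoint apoptosis
#' percentage, one row per condition.
#'
#' @param p A `parameter_set`.
#' @param conditions List of `treatment_condition` objects (shared horizon).
#' @param variant Apoptosis model variant.
#' @param step RK4 step (h); the 0.05 default resolves the slow apoptosis
#'   accumulation accurately (see the methods vignette).
#' @return `data.frame` with `condition_id`, `treatment`, `apoptosis_pct`.
#' @export
run_condition_panel <- function(p, conditions, variant = "bad_mcl1", step = 0.05) {
  stopifnot(length(conditions) > 0)
  horizons <- vapply(conditions, function(cc) cc$horizon, numeric(1))
  if (length(unique(horizons)) != 1)
    stop("all panel conditions must share one horizon")
  rows <- lapply(seq_along(conditions), function(i) {
    cond <- conditions[[i]]
    tr <- simulate_trajectory(p, cond, times = c(0, cond$horizon),
                              step = step, variant = variant)
    data.frame(condition_id = if (is.null(cond$id)) paste0("cond", i) else cond$id,
               treatment = format_schedule(cond),
               apoptosis_pct = tr$apoptosis[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Endpoint apoptosis for one condition
#' @inheritParams run_condition_panel
#' @param cond A `treatment_condition`.
#' @return Apoptosis percentage at the horizon.
#' @export
endpoint_apoptosis <- function(p, cond, variant = "bad_mcl1", step = 0.05) {
  tr <- simulate_trajectory(p, cond, times = c(0, cond$horizon), step = step,
                            variant = variant)
  unname(tr$apoptosis[2])
}
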