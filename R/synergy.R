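# Drug-combination synergy: Loewe isobologram index, total-dose combination
# index, dose-grid synergy maps and the stress-triggered pattern switch.

#' Single-agent dose-response function
#'
#' Builds the monotone mapping from the normalized dose of one inhibitor to
#' endpoint apoptosis percentage, on top of a fixed background condition
#' (stimuli and other drugs).
#'
#' @param p A `parameter_set`.
#' @param drug An inhibitor name from [inhibitor_names()].
#' @param background A `treatment_condition` giving stimuli/co-treatments;
#'   defaults to no treatment with a 48 h horizon.
#' @param dose_max Largest evaluable dose (default 100).
#' @param variant Apoptosis model variant.
#' @param step RK4 step (h).
#' @return An object of class `dose_response`: callable as `dr(dose)`.
#' @export
dose_response <- function(p, drug, background = NULL, dose_max = 100,
                          variant = "bad_mcl1", step = 0.05) {
  drug <- match.arg(drug, inhibitor_names())
  if (is.null(background)) background <- treatment_condition(horizon = 48)
  f <- function(dose) {
    stopifnot(all(dose >= 0))
    vapply(dose, function(d) {
      cond <- background
      cond$dose[drug] <- cond$dose[drug] + d
      endpoint_apoptosis(p, cond, variant = variant, step = step)
    }, numeric(1))
  }
  structure(f, class = c("dose_response", "function"), drug = drug,
            dose_max = dose_max)
}

#' Invert a dose-response: dose achieving a requested effect
#'
#' Returns the smallest dose `D_x` whose endpoint apoptosis matches the
#' requested effect `x`, solved by bisection to an absolute effect tolerance.
#' An effect below the zero-dose response returns dose 0; an effect above the
#' response at `dose_max` raises an `unreachable_effect` error (distinct from
#' numerical failure).
#'
#' @param dr A `dose_response`.
#' @param x Target apoptosis percentage.
#' @param tol Absolute effect tolerance (percentage points), default 1e-4.
#' @return The dose `D_x`.
#' @export
invert_dose_response <- function(dr, x, tol = 1e-4) {
  stopifnot(inherits(dr, "dose_response"))
  dmax <- attr(dr, "dose_max")
  e0 <- dr(0)
  if (x <= e0 + tol) return(0)
  emax <- dr(dmax)
  if (x > emax + tol)
    stop(structure(class = c("unreachable_effect", "error", "condition"),
                   list(message = sprintf(
                     "effect %.4g%% unreachable: response at max dose %g is %.4g%%",
                     x, dmax, emax), call = NULL)))
  lo <- 0; hi <- dmax
  repeat {
    mid <- (lo + hi) / 2
    em <- dr(mid)
    if (abs(em - x) < tol || (hi - lo) < 1e-10) return(mid)
    if (em < x) lo <- mid else hi <- mid
  }
}

#' Loewe combination index on an isobologram
#'
#' For a dose pair `(d1, d2)` producing combined effect `x`, the Loewe index
#' is the total effective dose ratio `d1 / D_x1 + d2 / D_x2`, where `D_xi` is
#' the single-agent dose of drug `i` achieving the same effect `x`. Values
#' below 1 indicate Loewe synergy, above 1 antagonism, 1 additivity.
#'
#' @param d1,d2 Doses of drugs 1 and 2 in the combination.
#' @param dr1,dr2 Single-agent `dose_response` objects.
#' @param combo Function `(d1, d2) -> effect` giving the combined endpoint
#'   apoptosis; see [combination_effect()].
#' @param tol Inversion tolerance passed to [invert_dose_response()].
#' @return `CI_Loewe` (scalar).
#' @export
loewe_index <- function(d1, d2, dr1, dr2, combo, tol = 1e-4) {
  x <- combo(d1, d2)
  D1 <- invert_dose_response(dr1, x, tol = tol)
  D2 <- invert_dose_response(dr2, x, tol = tol)
  if (d1 > 0 && D1 == 0) stop("effect reachable at zero dose of drug 1; Loewe index undefined")
  if (d2 > 0 && D2 == 0) stop("effect reachable at zero dose of drug 2; Loewe index undefined")
  (if (d1 > 0) d1 / D1 else 0) + (if (d2 > 0) d2 / D2 else 0)
}

#' Combined-effect function for a drug pair
#'
#' @param p A `parameter_set`.
#' @param drug1,drug2 Inhibitor names.
#' @param background Background `treatment_condition` (stimuli, horizon).
#' @param variant Apoptosis model variant.
#' @param step RK4 step (h).
#' @return Function `(d1, d2) -> endpoint apoptosis %`.
#' @export
combination_effect <- function(p, drug1, drug2, background = NULL,
                               variant = "bad_mcl1", step = 0.05) {
  drug1 <- match.arg(drug1, inhibitor_names())
  drug2 <- match.arg(drug2, inhibitor_names())
  if (is.null(background)) background <- treatment_condition(horizon = 48)
  function(d1, d2) {
    cond <- background
    cond$dose[drug1] <- cond$dose[drug1] + d1
    cond$dose[drug2] <- cond$dose[drug2] + d2
    endpoint_apoptosis(p, cond, variant = variant, step = step)
  }
}

#' Total-dose combination index
#'
#' A combination index built on equal-total-dose comparison: with
#' `E1`, `E2` the single-agent effects at the total dose `d1 + d2` and `E12`
#' the combined effect at `(d1, d2)`,
#' `CI = max(E1, E2) / E12`.
#' The index is below 1 exactly when the combination produces a greater
#' effect than both single agents at the same total dose (synergism), above 1
#' for antagonism, and 1 for additivity; a drug "combined" with itself at any
#' split scores exactly 1.
#'
#' @param d1,d2 Doses (>= 0, not both 0).
#' @param dr1,dr2 Single-agent `dose_response` objects (same background).
#' @param combo Combined-effect function from [combination_effect()].
#' @return `CI` (scalar).
#' @export
combination_index <- function(d1, d2, dr1, dr2, combo) {
  if (d1 < 0 || d2 < 0) stop("doses must be >= 0")
  if (d1 == 0 && d2 == 0) stop("at least one dose must be positive")
  ci_from_effects(dr1(d1 + d2), dr2(d1 + d2), combo(d1, d2))
}

#' Combination index from precomputed effects
#' @param e1,e2 Single-agent effects at the total dose.
#' @param e12 Combined effect at the dose split.
#' @return `CI = max(e1, e2) / e12`.
#' @export
ci_from_effects <- function(e1, e2, e12) {
  if (e12 <= 0) return(Inf)
  max(e1, e2) / e12
}

#' Synergy map over a 2-D dose grid
#'
#' Evaluates the total-dose combination index of a drug pair over a
#' log-spaced dose grid under a given background stress level, and labels
#' each cell `synergy` (CI < 1), `additivity` (CI = 1 within 1e-6) or
#' `antagonism` (CI > 1). Cells whose simulation fails are flagged `failed`
#' and the map completes.
#'
#' @param p A `parameter_set`.
#' @param drug1,drug2 Inhibitor names (default the BADS112A + LY294002 pair).
#' @param stress Background stress level (epinephrine/VIP scale).
#' @param n Grid points per axis (default 20).
#' @param dose_range Dose interval, default `c(0.01, 100)`.
#' @param horizon Assay horizon (h).
#' @param variant Apoptosis model variant.
#' @param step RK4 step (h).
#' @return A `synergy_map` `data.frame` with columns `d1`, `d2`, `ci`,
#'   `label`, `stress`; attribute `grid` holds the dose axis.
#' @export
synergy_map <- function(p, drug1 = "BADS112A", drug2 = "LY294002", stress = 0,
                        n = 20, dose_range = c(0.01, 100), horizon = 48,
                        variant = "bad_mcl1", step = 0.05) {
  doses <- 10^seq(log10(dose_range[1]), log10(dose_range[2]), length.out = n)
  bg <- treatment_condition(stress = stress, horizon = horizon)
  dr1 <- dose_response(p, drug1, bg, dose_max = 2 * max(doses),
                       variant = variant, step = step)
  dr2 <- dose_response(p, drug2, bg, dose_max = 2 * max(doses),
                       variant = variant, step = step)
  combo <- combination_effect(p, drug1, drug2, bg, variant = variant, step = step)
  # single-agent effects cached per distinct total dose
  totals <- unique(as.vector(outer(doses, doses, `+`)))
  e1 <- setNames(dr1(totals), as.character(totals))
  e2 <- setNames(dr2(totals), as.character(totals))
  grid <- expand.grid(d1 = doses, d2 = doses)
  ci <- numeric(nrow(grid)); lab <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    key <- as.character(grid$d1[i] + grid$d2[i])
    val <- tryCatch(
      ci_from_effects(e1[[key]], e2[[key]], combo(grid$d1[i], grid$d2[i])),
      error = function(e) NA_real_)
    ci[i] <- val
    lab[i] <- if (is.na(val)) "failed"
    else if (val < 1 - 1e-6) "synergy"
    else if (val > 1 + 1e-6) "antagonism"
    else "additivity"
  }
  out <- data.frame(grid, ci = ci, label = lab, stress = stress,
                    stringsAsFactors = FALSE)
  attr(out, "grid") <- doses
  class(out) <- c("synergy_map", "data.frame")
  out
}

#' Count contiguous CI-sign regions of a synergy map
#'
#' Flood-fills the dose grid over 4-neighbour adjacency on the binary
#' synergy/non-synergy labelling and returns the number of connected
#' regions (used to detect the stress-induced two-region pattern).
#'
#' @param map A `synergy_map`.
#' @return Integer region count.
#' @export
count_ci_regions <- function(map) {
  doses <- attr(map, "grid")
  n <- length(doses)
  lab <- matrix(!is.na(map$ci) & map$ci < 1, n, n) # d1 varies fastest
  seen <- matrix(FALSE, n, n)
  regions <- 0L
  for (j in seq_len(n)) for (i in seq_len(n)) {
    if (seen[i, j]) next
    regions <- regions + 1L
    queue <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        a <- cur[1] + d[1]; b <- cur[2] + d[2]
        if (a >= 1 && a <= n && b >= 1 && b <= n && !seen[a, b] &&
            lab[a, b] == lab[cur[1], cur[2]]) {
          seen[a, b] <- TRUE
          queue[[length(queue) + 1]] <- c(a, b)
        }
      }
    }
  }
  regions
}

#' Isobologram of a drug pair at a fixed effect level
#'
#' Sweeps `d1` over a log-spaced grid and solves for the `d2` completing the
#' requested combined effect by bisection; grid points where no such `d2`
#' exists are excluded.
#'
#' @param p A `parameter_set`.
#' @param effect Target apoptosis percentage (default 25).
#' @param drug1,drug2 Inhibitor names.
#' @param background Background condition.
#' @param n Number of `d1` grid points.
#' @param dose_range `d1` range.
#' @param variant,step Passed to the simulations.
#' @return `data.frame` with `effect_pct`, `d1`, `d2`.
#' @export
isobologram <- function(p, effect = 25, drug1 = "BADS112A", drug2 = "LY294002",
                        background = NULL, n = 12, dose_range = c(0.01, 100),
                        variant = "bad_mcl1", step = 0.05) {
  if (is.null(background)) background <- treatment_condition(horizon = 48)
  combo <- combination_effect(p, drug1, drug2, background, variant = variant,
                              step = step)
  d1s <- 10^seq(log10(dose_range[1]), log10(dose_range[2]), length.out = n)
  rows <- list()
  for (d1 in d1s) {
    partial <- structure(function(d) combo(d1, d),
                         class = c("dose_response", "function"),
                         dose_max = dose_range[2])
    d2 <- tryCatch(invert_dose_response(partial, effect, tol = 1e-4),
                   error = function(e) NA_real_)
    if (!is.na(d2) && d2 > 0)
      rows[[length(rows) + 1]] <- data.frame(effect_pct = effect, d1 = d1, d2 = d2)
  }
  do.call(rbind, rows)
}

#' Endpoint-apoptosis surface over a dose grid for several stress levels
#'
#' Raw apoptosis percentages (no index) over the `(d1, d2)` grid, one layer
#' per background stress level; quantifies stress-induced drug resistance.
#'
#' @inheritParams synergy_map
#' @param stress_levels Numeric vector of stress levels.
#' @return `data.frame` with `d1`, `d2`, `stress`, `apoptosis_pct`.
#' @export
resistance_surface <- function(p, drug1 = "BADS112A", drug2 = "LY294002",
                               stress_levels = c(0, 100), n = 10,
                               dose_range = c(0.01, 100), horizon = 48,
                               variant = "bad_mcl1", step = 0.05) {
  doses <- 10^seq(log10(dose_range[1]), log10(dose_range[2]), length.out = n)
  out <- list()
  for (s in stress_levels) {
    bg <- treatment_condition(stress = s, horizon = horizon)
    combo <- combination_effect(p, drug1, drug2, bg, variant = variant,
                                step = step)
    grid <- expand.grid(d1 = doses, d2 = doses)
    grid$stress <- s
    grid$apoptosis_pct <- mapply(combo, grid$d1, grid$d2)
    out[[length(out) + 1]] <- grid
  }
  do.call(rbind, out)
}
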