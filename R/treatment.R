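# Treatment schedules: piecewise-constant stimulus and inhibitor inputs.

#' Construct a treatment condition
#'
#' A treatment condition is a piecewise-constant schedule of stimulus levels
#' and inhibitor doses. Each input switches on at its onset time and stays on
#' until the simulation horizon. Epinephrine and VIP act through the same
#' beta2-adrenergic/cAMP entry point and share the single `stress` channel.
#'
#' @param egf EGF stimulus level (dimensionless, >= 0; 1 = standard stimulus).
#' @param egf_onset Onset time of the EGF step (h).
#' @param stress Stress (epinephrine/VIP) level (>= 0; 100 = high stress).
#' @param stress_onset Onset time of the stress step (h).
#' @param inhibitors Named list or vector. Either `name = dose` (onset 0) or
#'   `name = c(dose, onset)`. Names must be among [inhibitor_names()]; doses
#'   are normalized so that dose 1 gives half-maximal inhibition.
#' @param horizon Simulation end time (h).
#' @param id Optional condition identifier.
#' @return An object of class `treatment_condition`.
#' @export
treatment_condition <- function(egf = 0, egf_onset = 0, stress = 0,
                                stress_onset = 0, inhibitors = list(),
                                horizon = 48, id = NULL) {
  if (egf < 0 || stress < 0) stop("stimulus levels must be >= 0")
  dose <- setNames(numeric(8), inhibitor_names())
  onset <- setNames(numeric(8), inhibitor_names())
  if (length(inhibitors)) {
    nm <- names(inhibitors)
    if (is.null(nm) || any(nm == ""))
      stop("`inhibitors` must be a named list")
    bad <- setdiff(nm, inhibitor_names())
    if (length(bad))
      stop("unknown inhibitor(s): ", paste(bad, collapse = ", "),
           "; valid names: ", paste(inhibitor_names(), collapse = ", "))
    for (i in seq_along(inhibitors)) {
      v <- inhibitors[[i]]
      dose[nm[i]] <- v[1]
      onset[nm[i]] <- if (length(v) > 1) v[2] else 0
    }
  }
  if (any(dose < 0)) stop("inhibitor doses must be >= 0")
  ons <- c(egf_onset, stress_onset, onset)
  if (any(ons < 0) || any(ons > horizon))
    stop("onset times must lie in [0, horizon]")
  structure(list(egf = egf, egf_onset = egf_onset, stress = stress,
                 stress_onset = stress_onset, dose = dose, onset = onset,
                 horizon = horizon, id = id),
            class = "treatment_condition")
}

#' @export
print.treatment_condition <- function(x, ...) {
  cat("<treatment_condition>", format_schedule(x), sprintf("(horizon %g h)\n", x$horizon))
  invisible(x)
}

#' Format a treatment condition as a compact schedule string
#'
#' The schedule descriptor used in observation tables:
#' tokens `NAME:dose@onset` joined by `+`, e.g.
#' `"LY294002:1@0+EGF:1@2"`; the empty schedule is `"control"`.
#' @param cond A `treatment_condition`.
#' @return A single string.
#' @export
format_schedule <- function(cond) {
  tok <- character(0)
  if (cond$egf > 0)
    tok <- c(tok, sprintf("EGF:%g@%g", cond$egf, cond$egf_onset))
  if (cond$stress > 0)
    tok <- c(tok, sprintf("STRESS:%g@%g", cond$stress, cond$stress_onset))
  on <- which(cond$dose > 0)
  for (i in on)
    tok <- c(tok, sprintf("%s:%g@%g", names(cond$dose)[i], cond$dose[i],
                          cond$onset[i]))
  if (!length(tok)) "control" else paste(tok, collapse = "+")
}

#' Parse a schedule string back into a treatment condition
#' @param x Schedule string as produced by [format_schedule()].
#' @param horizon Simulation end time (h).
#' @param id Optional condition identifier.
#' @return A `treatment_condition`.
#' @export
parse_schedule <- function(x, horizon = 48, id = NULL) {
  x <- trimws(x)
  if (identical(x, "control") || x == "")
    return(treatment_condition(horizon = horizon, id = id))
  egf <- 0; egf_onset <- 0; stress <- 0; stress_onset <- 0
  inh <- list()
  for (tok in strsplit(x, "+", fixed = TRUE)[[1]]) {
    m <- regmatches(tok, regexec("^([^:]+):([0-9.eE+-]+)@([0-9.eE+-]+)$", tok))[[1]]
    if (length(m) != 4)
      stop("malformed schedule token: '", tok, "' (expected NAME:dose@onset)")
    nm <- m[2]; lev <- as.numeric(m[3]); ons <- as.numeric(m[4])
    if (nm == "EGF") { egf <- lev; egf_onset <- ons }
    else if (nm %in% c("STRESS", "EPI", "VIP")) { stress <- lev; stress_onset <- ons }
    else inh[[nm]] <- c(lev, ons)
  }
  treatment_condition(egf = egf, egf_onset = egf_onset, stress = stress,
                      stress_onset = stress_onset, inhibitors = inh,
                      horizon = horizon, id = id)
}

#' Export the network wiring and inhibitor-target map as YAML
#'
#' Writes an auditable YAML document describing each species, each activation
#' reaction (upstream input, decay form) and the inhibitor-target map.
#' @param path File to write; `NULL` returns the YAML text.
#' @return The YAML string, invisibly when written to a file.
#' @export
wiring_yaml <- function(path = NULL) {
  wiring <- list(
    species = as.list(setNames(seq_along(species_names()), species_names())),
    initial_state = as.list(baseline_state()),
    reactions = list(
      egfr = list(input = "EGF", decay = "d_EGFR * t"),
      raf = list(input = "EGFR", decay = "d_Raf * t"),
      erk = list(input = "Raf", decay = "d_ERK * t"),
      kinasex = list(input = "ERK", decay = "d_KinaseX * t"),
      rac = list(input = "EGF", decay = "d_Rac"),
      pak = list(input = "Rac", decay = "d_PAK"),
      pi3k = list(input = "basal (constant 1)", decay = "d_PI3K (derived)"),
      akt = list(input = "PI3K", decay = "d_AKT (derived)"),
      camp = list(input = "stress", decay = "d_cAMP"),
      pka = list(input = "cAMP", decay = "d_PKA"),
      creb = list(input = "PKA", decay = "d_CREB"),
      bad112 = list(input = "KinaseX + PKA + 0.5 * AKT",
                    decay = "d_pS112BAD * (1 + u_BADS112A) (derived)"),
      bad136_pak = list(input = "PAK", decay = "d_pS136BAD (derived, shared)"),
      bad136_akt = list(input = "AKT", decay = "d_pS136BAD (derived, shared)")),
    inhibitor_targets = as.list(inhibitor_target_map()))
  txt <- yaml::as.yaml(wiring)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
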