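# Local relative sensitivity of model variables to parameters.

.sensitivity_states <- function(p, cond, times, variant, step) {
  tr <- simulate_trajectory(p, cond, times = times, step = step,
                            variant = variant)
  cbind(tr$states, apoptosis_pct = tr$apoptosis)
}

#' Relative sensitivity coefficient of one variable to one parameter
#'
#' Percentage change of a model variable per percentage change of a
#' parameter at time `t`, computed by a one-sided forward finite difference
#' (the parameter is increased by `perturbation`):
#' `S = ((x' - x) / x) / perturbation`.
#'
#' @param p A `parameter_set`.
#' @param variable One of [species_names()] or `"apoptosis_pct"`.
#' @param parameter A free parameter name in flattened notation.
#' @param t Evaluation time (h).
#' @param cond Treatment condition under which sensitivity is evaluated;
#'   defaults to the central fitted scenario (LY294002 dose 1, no stress).
#' @param perturbation Relative parameter increase (default 0.01 = 1%).
#' @param variant Apoptosis model variant.
#' @param step RK4 step (h).
#' @return The dimensionless coefficient, or `NA` when the unperturbed
#'   variable is below 1e-8 at `t` (relative change undefined at zero).
#' @export
relative_sensitivity <- function(p, variable, parameter, t,
                                 cond = NULL, perturbation = 0.01,
                                 variant = "bad_mcl1", step = 0.05) {
  if (is.null(cond))
    cond <- treatment_condition(inhibitors = list(LY294002 = 1), horizon = max(t, 1))
  times <- sort(unique(c(0, t)))
  base <- .sensitivity_states(p, cond, times, variant, step)
  flat <- flatten_parameters(p, include_derived = FALSE)
  if (!parameter %in% names(flat))
    stop("unknown free parameter '", parameter, "'")
  pert <- update_parameters(p, setNames(flat[[parameter]] * (1 + perturbation),
                                        parameter))
  up <- .sensitivity_states(pert, cond, times, variant, step)
  i <- match(t, times)
  x0 <- base[i, variable]
  if (abs(x0) < 1e-8) return(NA_real_)
  ((up[i, variable] - x0) / x0) / perturbation
}

#' Time-averaged sensitivity matrix
#'
#' For every model variable (13 proteins plus apoptosis percentage) and every
#' analyzed parameter, the absolute relative sensitivity coefficients are
#' averaged over the `n`-point equal partition of `[0, T]` (partition points
#' `T/n, 2T/n, ..., T`; the origin is excluded since most variables start at
#' 0). Partition points where the unperturbed variable is below 1e-8 are
#' skipped for that variable and recorded in the metadata. Entries are the
#' time-averaged percentage change of the variable under the stated
#' perturbation: with the default 1% increase an entry of 1 means the
#' variable moves by 1% of itself (relative coefficient 1).
#'
#' @param p A `parameter_set`.
#' @param parameters Parameter names to analyze; defaults to all 37 + 7 free
#'   parameters.
#' @param cond Condition during the run; defaults to LY294002 dose 1,
#'   no stress (the central fitted scenario). Required and recorded.
#' @param perturbation Relative increase per parameter (default 1%).
#' @param T Averaging horizon (h), default 100.
#' @param n Partition count, default 10.
#' @param variant Apoptosis model variant.
#' @param step RK4 step (h).
#' @return A `sensitivity_matrix`: matrix (14 variables x parameters, in %)
#'   with attributes `perturbation`, `T`, `n`, `condition`, `skipped`
#'   (points excluded per variable).
#' @export
time_averaged_sensitivity <- function(p, parameters = NULL, cond = NULL,
                                      perturbation = 0.01, T = 100, n = 10,
                                      variant = "bad_mcl1", step = 0.05) {
  if (is.null(parameters))
    parameters <- c(free_parameter_names("signaling"),
                    free_parameter_names("apoptosis"))
  if (is.null(cond))
    cond <- treatment_condition(inhibitors = list(LY294002 = 1), horizon = T)
  if (cond$horizon < T) stop("condition horizon must cover [0, T]")
  tpts <- T / n * seq_len(n)
  times <- sort(unique(c(0, tpts)))
  vars <- c(species_names(), "apoptosis_pct")
  base <- .sensitivity_states(p, cond, times, variant, step)
  ii <- match(tpts, times)
  flat <- flatten_parameters(p, include_derived = FALSE)
  bad <- setdiff(parameters, names(flat))
  if (length(bad))
    stop("unknown free parameter(s): ", paste(bad, collapse = ", "))
  S <- matrix(0, length(vars), length(parameters),
              dimnames = list(vars, parameters))
  usable <- abs(base[ii, vars, drop = FALSE]) >= 1e-8
  skipped <- setNames(as.integer(n - colSums(usable)), vars)
  for (j in seq_along(parameters)) {
    pj <- parameters[j]
    pert <- update_parameters(p, setNames(flat[[pj]] * (1 + perturbation), pj))
    up <- tryCatch(
      .sensitivity_states(pert, cond, times, variant, step),
      error = function(e)
        stop("integration failed for perturbed parameter '", pj, "': ",
             conditionMessage(e)))
    for (v in seq_along(vars)) {
      ok <- usable[, v]
      if (!any(ok)) next
      x0 <- base[ii[ok], vars[v]]
      x1 <- up[ii[ok], vars[v]]
      S[v, j] <- mean(abs((x1 - x0) / x0)) * 100
    }
  }
  structure(S, class = c("sensitivity_matrix", "matrix", "array"),
            perturbation = perturbation, T = T, n = n,
            condition = format_schedule(cond), skipped = skipped)
}

#' @export
print.sensitivity_matrix <- function(x, ...) {
  cat(sprintf("<sensitivity_matrix> %d variables x %d parameters; max |S| = %.4f%% (T = %g, n = %d, %g%% perturbation)\n",
              nrow(x), ncol(x), max(x), attr(x, "T"), attr(x, "n"),
              100 * attr(x, "perturbation")))
  invisible(x)
}

#' Write a sensitivity matrix as CSV plus JSON metadata
#' @param S A `sensitivity_matrix`.
#' @param path CSV output path; metadata goes to `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_sensitivity_matrix <- function(S, path) {
  write.csv(as.data.frame(unclass(S)), path, row.names = TRUE)
  meta <- list(perturbation = attr(S, "perturbation"), T = attr(S, "T"),
               n = attr(S, "n"), condition = attr(S, "condition"),
               skipped_points = as.list(attr(S, "skipped")))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
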