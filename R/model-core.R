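# Kinetics primitives and the parameter-set container.

#' Hill activation rate
#'
#' Rate contribution of an upstream regulator at activity `x` on its target:
#' `v * x^n / (k^n + x^n)`. Monotone non-decreasing in `x`, bounded above
#' by `v`, half-maximal at `x = k` for any exponent.
#'
#' @param x Upstream activity (dimensionless, >= 0).
#' @param v Maximal activation velocity (1/h, > 0).
#' @param k Michaelis activation coefficient (dimensionless, > 0).
#' @param n Hill exponent (>= 1).
#' @return Rate contribution in (0, v].
#' @examples
#' hill_activation(0.5, v = 2, k = 0.5, n = 1) # half-saturation: 1
#' @export
hill_activation <- function(x, v, k, n = 1) {
  if (any(x < 0)) stop("upstream activity `x` must be >= 0")
  if (any(v <= 0) || any(k <= 0)) stop("`v` and `k` must be > 0")
  if (any(n < 1)) stop("Hill exponent `n` must be >= 1")
  xn <- x^n
  v * xn / (k^n + xn)
}

#' Multiplicative drug factor on a maximal velocity
#'
#' Inhibition Hill factor `1 / (1 + u)` applied to the targeted reaction's
#' maximal velocity. Doses are normalized to the half-inhibition
#' concentration, so `u = 1` halves the velocity and no additional parameters
#' enter the model.
#'
#' @param u Normalized inhibitor dose (>= 0).
#' @return Factor in (0, 1].
#' @examples
#' drug_factor(0) # 1
#' drug_factor(1) # 0.5
#' @export
drug_factor <- function(u) {
  if (any(u < 0)) stop("normalized dose `u` must be >= 0")
  1 / (1 + u)
}

#' Effective pS112-BAD dephosphorylation rate under BADS112A
#'
#' The phosphorylation-deficient mutant BADS112A lowers the steady fraction of
#' phosphorylated S112-BAD; it is modelled on the dephosphorylation rate of
#' pS112-BAD as `d_base * (1 + u)`, the mirror image of [drug_factor()] under
#' the same dose normalization.
#'
#' @param d_base Baseline pS112 dephosphorylation rate (1/h, > 0).
#' @param u Normalized BADS112A expression level (>= 0).
#' @return Effective rate >= `d_base`, increasing in `u`.
#' @export
bads112a_decay <- function(d_base, u) {
  if (any(d_base <= 0)) stop("`d_base` must be > 0")
  if (any(u < 0)) stop("normalized dose `u` must be >= 0")
  d_base * (1 + u)
}

#' Construct a model parameter set
#'
#' Bundles the kinetic parameters of the 13-species signaling network and the
#' 7 apoptosis-model parameters, and closes the four derivable
#' dephosphorylation rates so that [baseline_state()] is a fixed point of the
#' drug- and stimulus-free system (see [derive_decay_rates()]).
#'
#' The free (fittable) parameters are the 14 maximal velocities, the 14
#' Michaelis coefficients, the four EGFR-branch dephosphorylation coefficients
#' and the five decay rates of species whose baseline is zero (Rac, PAK, cAMP,
#' PKA, CREB) - 37 in total - plus the 7 apoptosis parameters. Hill exponents
#' are fixed structural constants.
#'
#' @param vmax Named numeric vector of 14 maximal velocities (see
#'   [reaction_names()]), all > 0.
#' @param km Named numeric vector of 14 Michaelis coefficients, all > 0.
#' @param hill_n Named numeric vector of 14 Hill exponents, all >= 1.
#' @param decay_free Named numeric vector of 9 free dephosphorylation rates:
#'   `d_EGFR, d_Raf, d_ERK, d_KinaseX` (time-dependent branch) and
#'   `d_Rac, d_PAK, d_cAMP, d_PKA, d_CREB` (zero-baseline species), all > 0.
#' @param apoptosis Named numeric vector of the 7 apoptosis parameters
#'   (`k_a, bad_total, K_bad, n_bad, K_mcl, n_mcl, beta_mcl`); `beta_mcl` in
#'   \[0, 1\] switches the Mcl-1/CREB term (0 disables it).
#' @return An object of class `parameter_set` with an additional
#'   `decay_derived` component holding the closed rates for PI3K, AKT,
#'   pS112-BAD and pS136-BAD.
#' @export
parameter_set <- function(vmax, km, hill_n, decay_free, apoptosis) {
  vmax <- .check_named(vmax, reaction_names(), "vmax")
  km <- .check_named(km, reaction_names(), "km")
  hill_n <- .check_named(hill_n, reaction_names(), "hill_n")
  decay_free <- .check_named(
    decay_free,
    paste0("d_", c(.egfr_branch_species, .zero_baseline_species)),
    "decay_free")
  apoptosis <- .check_named(apoptosis, apoptosis_parameter_names(), "apoptosis")
  if (any(vmax <= 0)) stop("all `vmax` must be strictly positive")
  if (any(km <= 0)) stop("all `km` must be strictly positive")
  if (any(hill_n < 1)) stop("all Hill exponents must be >= 1")
  if (any(decay_free <= 0)) stop("all free decay rates must be strictly positive")
  if (any(apoptosis[c("k_a", "bad_total", "K_bad", "n_bad", "K_mcl", "n_mcl")] <= 0))
    stop("apoptosis parameters must be strictly positive")
  if (apoptosis[["beta_mcl"]] < 0 || apoptosis[["beta_mcl"]] > 1)
    stop("`beta_mcl` must lie in [0, 1]")
  p <- structure(
    list(vmax = vmax, km = km, hill_n = hill_n, decay_free = decay_free,
         decay_derived = NULL, apoptosis = apoptosis),
    class = "parameter_set")
  p$decay_derived <- derive_decay_rates(p)
  p
}

.check_named <- function(x, expected, what) {
  if (is.null(names(x))) {
    if (length(x) != length(expected))
      stop(sprintf("`%s` must have %d entries", what, length(expected)))
    names(x) <- expected
  }
  if (!setequal(names(x), expected))
    stop(sprintf("`%s` must be named exactly: %s", what,
                 paste(expected, collapse = ", ")))
  x[expected]
}

#' Steady-state closure of the derivable dephosphorylation rates
#'
#' For each species with a non-zero baseline among the constant-decay
#' equations (PI3K, AKT, pS112-BAD, pS136-BAD), the decay rate is set to the
#' baseline activation flux divided by the baseline level, which makes
#' [baseline_state()] an exact fixed point of the stimulus- and drug-free
#' system. These rates are recomputed deterministically from `(vmax, km,
#' hill_n)` and are never fitted. Species whose baseline level and baseline
#' production are both zero (Rac, PAK, cAMP, PKA, CREB) have a degenerate
#' closure; their rates are free parameters held in `decay_free`.
#'
#' @param p A `parameter_set` (the `decay_derived` component is ignored).
#' @return Named numeric vector: `d_PI3K, d_AKT, d_pS112BAD, d_pS136BAD`.
#' @export
derive_decay_rates <- function(p) {
  v <- p$vmax; k <- p$km; n <- p$hill_n
  s0 <- baseline_state()
  # baseline input of the pS112 reaction: KinaseX + PKA + 0.5 * AKT
  s112_in0 <- s0[["KinaseX"]] + s0[["PKA"]] + .akt_s112_weight * s0[["AKT"]]
  c(d_PI3K = hill_activation(1, v[["pi3k"]], k[["pi3k"]], n[["pi3k"]]) / s0[["PI3K"]],
    d_AKT = hill_activation(s0[["PI3K"]], v[["akt"]], k[["akt"]], n[["akt"]]) / s0[["AKT"]],
    d_pS112BAD = hill_activation(s112_in0, v[["bad112"]], k[["bad112"]],
                                 n[["bad112"]]) / s0[["pS112BAD"]],
    d_pS136BAD = (hill_activation(s0[["PAK"]], v[["bad136_pak"]], k[["bad136_pak"]],
                                  n[["bad136_pak"]]) +
                  hill_activation(s0[["AKT"]], v[["bad136_akt"]], k[["bad136_akt"]],
                                  n[["bad136_akt"]])) / s0[["pS136BAD"]])
}

#' Full per-species decay vector (free + derived), in species order
#' @param p A `parameter_set`.
#' @return Named numeric vector of length 13.
#' @export
decay_rates <- function(p) {
  d <- setNames(numeric(13), species_names())
  free <- p$decay_free
  names(free) <- sub("^d_", "", names(free))
  d[names(free)] <- free
  der <- p$decay_derived
  names(der) <- sub("^d_", "", names(der))
  d[names(der)] <- der
  d
}

#' Number of free parameters in each submodel
#' @param p A `parameter_set`.
#' @return Named integer vector with components `signaling` and `apoptosis`.
#' @export
count_free_parameters <- function(p) {
  c(signaling = length(p$vmax) + length(p$km) + length(p$decay_free),
    apoptosis = length(p$apoptosis))
}

#' @export
print.parameter_set <- function(x, ...) {
  nf <- count_free_parameters(x)
  cat("<parameter_set>\n")
  cat(sprintf("  signaling: %d free (14 V + 14 K + %d d), %d derived decay rates\n",
              nf[["signaling"]], length(x$decay_free), length(x$decay_derived)))
  cat(sprintf("  apoptosis: %d free\n", nf[["apoptosis"]]))
  invisible(x)
}

#' Flatten a parameter set to a named numeric vector
#'
#' Names follow the CSV convention: `V_<reaction>`, `K_<reaction>`,
#' `n_<reaction>`, `d_<species>`, and the apoptosis parameter names.
#' @param p A `parameter_set`.
#' @param include_derived Include the derived decay rates (default TRUE).
#' @return Named numeric vector.
#' @export
flatten_parameters <- function(p, include_derived = TRUE) {
  out <- c(setNames(p$vmax, paste0("V_", names(p$vmax))),
           setNames(p$km, paste0("K_", names(p$km))),
           setNames(p$hill_n, paste0("n_", names(p$hill_n))),
           p$decay_free,
           p$apoptosis)
  if (include_derived) out <- c(out, p$decay_derived)
  out
}

#' Rebuild a parameter set from a named numeric vector
#'
#' Inverse of [flatten_parameters()]; derived decay rates are always
#' recomputed by closure, never taken from the vector.
#' @param x Named numeric vector.
#' @return A `parameter_set`.
#' @export
unflatten_parameters <- function(x) {
  pick <- function(prefix, names) {
    got <- x[paste0(prefix, names)]
    setNames(as.numeric(got), names)
  }
  parameter_set(
    vmax = pick("V_", reaction_names()),
    km = pick("K_", reaction_names()),
    hill_n = pick("n_", reaction_names()),
    decay_free = x[paste0("d_", c(.egfr_branch_species, .zero_baseline_species))],
    apoptosis = x[apoptosis_parameter_names()])
}

#' Update selected free parameters of a parameter set
#'
#' @param p A `parameter_set`.
#' @param values Named numeric vector in [flatten_parameters()] notation;
#'   only free parameters may be updated.
#' @return A new `parameter_set` with the derived decays re-closed.
#' @export
update_parameters <- function(p, values) {
  flat <- flatten_parameters(p, include_derived = FALSE)
  unknown <- setdiff(names(values), names(flat))
  if (length(unknown))
    stop("unknown or non-free parameter(s): ", paste(unknown, collapse = ", "))
  flat[names(values)] <- values
  unflatten_parameters(flat)
}
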