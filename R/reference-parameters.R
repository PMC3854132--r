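# Synthetic reference parameter set.
#
# No externally fitted estimates for this network ship with the package; this set was calibrated once, by simulation, to reproduce the
# qualitative behaviour of the modelled system: a transient ERK peak under
# EGF within the first hour, suppression of pAKT and BAD phosphorylation by
# LY294002, stress-driven (cAMP/PKA) rescue of pS112-BAD and CREB, a maximal
# pro-apoptotic effect of the LY294002 + BADS112A combination, and the
# stress-induced synergism-pattern switch. It is the ground truth of the
# synthetic-data generator and the default for sensitivity and synergy runs.

#' Synthetic reference parameter set
#'
#' A fixed, fully documented `parameter_set` used as the package's default
#' model calibration and as the ground truth of the synthetic-data generator.
#' It is a synthetic, documented stand-in for an experimentally fitted table.
#'
#' @return A `parameter_set`.
#' @export
reference_parameters <- function() {
  rn <- reaction_names()
  parameter_set(
    vmax = setNames(c(
      6.0,   # egfr   EGF -> EGFR (fast receptor activation)
      6.0,   # raf
      4.0,   # erk (pERK/total ERK peaks just below 1 under EGF)
      3.0,   # kinasex
      2.0,   # rac
      2.0,   # pak
      1.0,   # pi3k (constitutive)
      1.0,   # akt
      2.0,   # camp
      2.0,   # pka
      1.0,   # creb
      0.1,   # bad112 (slow pS112 turnover, ~20 h residence)
      0.1,   # bad136_pak
      0.2),  # bad136_akt
      rn),
    km = setNames(c(
      0.5,   # egfr
      0.5,   # raf
      0.5,   # erk
      0.5,   # kinasex
      0.5,   # rac
      0.5,   # pak
      0.5,   # pi3k
      0.7,   # akt
      10.0,  # camp (stress scale runs to ~100)
      0.5,   # pka
      0.5,   # creb
      0.5,   # bad112
      0.5,   # bad136_pak
      0.7),  # bad136_akt
      rn),
    hill_n = setNames(c(2, 2, 2, 2, 2, 2, 1, 2, 1, 2, 2, 2, 2, 2), rn),
    decay_free = c(d_EGFR = 5, d_Raf = 5, d_ERK = 5, d_KinaseX = 5,
                   d_Rac = 2, d_PAK = 2, d_cAMP = 1, d_PKA = 1, d_CREB = 1),
    apoptosis = c(k_a = 1e-3, bad_total = 2.5, K_bad = 0.25, n_bad = 2,
                  K_mcl = 0.3, n_mcl = 2, beta_mcl = 0.5))
}

#' Draw a random valid parameter set
#'
#' Log-uniform draws of all free parameters inside the default fit bounds;
#' used by property-style tests. Hill exponents are kept at the reference
#' structural values.
#' @param seed Optional integer seed.
#' @return A `parameter_set`.
#' @export
random_parameters <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ref <- reference_parameters()
  loguni <- function(n, lo, hi) 10^runif(n, log10(lo), log10(hi))
  parameter_set(
    vmax = setNames(loguni(14, 0.1, 10), reaction_names()),
    km = setNames(loguni(14, 0.1, 10), reaction_names()),
    hill_n = ref$hill_n,
    decay_free = setNames(loguni(9, 0.1, 5), names(ref$decay_free)),
    apoptosis = c(k_a = loguni(1, 1e-4, 1e-2), bad_total = loguni(1, 2, 4),
                  K_bad = loguni(1, 0.1, 1), n_bad = runif(1, 1, 4),
                  K_mcl = loguni(1, 0.1, 1), n_mcl = runif(1, 1, 4),
                  beta_mcl = runif(1, 0, 1)))
}
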