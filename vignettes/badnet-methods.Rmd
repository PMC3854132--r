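---
title: "Modeling stress-mediated BAD phosphorylation and drug-combination synergy"
author: "badnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling stress-mediated BAD phosphorylation and drug-combination synergy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(badnet)
```

## The biological problem

BAD is a BH3-only pro-apoptotic protein whose killing activity is neutralized
by phosphorylation at Ser112 and Ser136. In prostate cancer cells three
signaling routes converge on these sites: EGF drives Ser112 through
EGFR-Raf-MEK/ERK and a downstream kinase (here called KinaseX) and Ser136
through Rac-PAK; constitutive PI3K-AKT signaling phosphorylates Ser136 and
partially Ser112; and psychological-stress hormones (epinephrine or VIP,
acting through the beta2-adrenergic receptor) raise cAMP, activate PKA and
phosphorylate Ser112 while also activating CREB, a proxy for stabilization of
the anti-apoptotic protein Mcl-1. Because dephosphorylated BAD promotes
apoptosis, drugs that cut these kinase routes (the PI3K inhibitor LY294002,
the phosphorylation-deficient mutant BADS112A, and six further pathway
inhibitors) push cells toward death, and stress signaling antagonizes them.
`badnet` implements this network as a quantitative pipeline: ODE simulation,
parameter estimation, sensitivity analysis, and drug-combination synergy
scoring, including the stress-induced switch of the synergy pattern.

## The dynamical model

The state is a vector of 13 dimensionless activity levels (normalized to the
untreated control): EGFR\*, Raf\*, ERK\*, KinaseX\*, Rac\*, PAK\*, PI3K\*,
AKT\*, cAMP, PKA\*, CREB\*, pS112-BAD and pS136-BAD. Every activation is a
Hill term $v\,x^n/(k^n + x^n)$ of the upstream regulator. Dephosphorylation
is linear, with two structural exceptions:

* **EGFR-branch species** (EGFR, Raf, ERK, KinaseX) decay as
  $d_i \, t_b \, x_i$, where $t_b$ is the time since EGF exposure. The
  growing decay coefficient is a phenomenological surrogate for short-term
  receptor signaling (internalization/desensitization): it produces the
  observed transient - pERK peaks below one hour after EGF and then declines
  - without modeling receptor trafficking. Anchoring the clock at the EGF
  onset rather than at absolute time matters: a stimulus applied after a 2 h
  pre-treatment must still fire the cascade.
* **pS112-BAD** has its dephosphorylation rate scaled by $(1+u)$ when the
  BADS112A mutant is expressed at normalized level $u$, the mirror image of
  the inhibitor convention below.

The untreated cell is the initial state $(0,0,0,0,0,0,1,1,0,0,0,1,1)$:
PI3K, AKT and both BAD phospho-sites are constitutively on. For every species
with a non-zero baseline and constant decay (PI3K, AKT, pS112, pS136) the
decay rate is not fitted but *closed*: it is set to the baseline activation
flux divided by the baseline level, which makes the untreated state an exact
fixed point. A useful consequence (and a good unit test) is that a maximal
velocity has no steady-state effect on its own species - the closure absorbs
it - so steady responses to drugs are controlled by the Michaelis constants
and the drug factors. Species whose baseline level *and* baseline production
are both zero (Rac, PAK, cAMP, PKA, CREB) have a degenerate closure; their
decay rates are ordinary fitted parameters.

Eight inhibitors enter multiplicatively on the maximal velocity of exactly
one reaction each (`inhibitor_target_map()`), via the factor $1/(1+u)$ with
the dose $u$ normalized to the half-inhibition concentration - dose 1 halves
the velocity and no new parameters are introduced. BADS112A is the one
exception, acting on a dephosphorylation rate as described above.

The free parameters of the signaling stage are the 14 maximal velocities,
the 14 Michaelis coefficients, the four EGFR-branch decay coefficients and
the five degenerate-closure decay rates: 37 in total, matched to a 56-point
observation set. Hill exponents are fixed structural constants (1 for the
graded cAMP and basal-PI3K inputs, 2 elsewhere); keeping cooperativity modest
is also what keeps the model robust (see the sensitivity section). The pS112
equation takes its three kinase inputs as a weighted sum
$\mathrm{KinaseX} + \mathrm{PKA} + 0.5\,\mathrm{AKT}$ inside a single Hill
term; the fixed weight 0.5 encodes the partial AKT dependence of Ser112
without adding parameters.

## Apoptosis readout

Apoptosis percentage $C_a \in [0,100]$ accumulates as

$$\frac{dC_a}{dt} = k_a \, t \,
  \Big(1 - H\big(\tfrac{\mathrm{pS112}+\mathrm{pS136}}{\mathrm{BAD}_T};
  K_{bad}, n_{bad}\big)\Big)\,
  \Big(1 - \beta\, H(\mathrm{CREB}; K_{mcl}, n_{mcl})\Big)\,(100 - C_a),$$

with survival $C_s = 100 - C_a$. The additive pS112+pS136 argument encodes
that phosphorylation of either site suffices to neutralize BAD; the explicit
$t$ factor reproduces the accelerating time course of apoptosis assays; the
$(100-C_a)$ factor is the surviving pool and saturates the percentage
smoothly (a hard clip at 100 remains as a guard). **Model 1** (BAD-only) is
the nested case $\beta = 0$; **model 2** adds the CREB/Mcl-1 anti-apoptotic
term. The 7 free parameters are $k_a$, $\mathrm{BAD}_T$, $K_{bad}$,
$n_{bad}$, $K_{mcl}$, $n_{mcl}$ and $\beta$, fitted to a 27-point panel.
The default assay horizon is 48 h; it is a configurable argument of every
panel and synergy function and is recorded in outputs.

## Numerical integration

The system is integrated with a fixed-step 4th-order Runge-Kutta scheme
(default step 0.01 h; 0.05 h for 48 h apoptosis endpoints, where the dynamics
are slow). Two details matter:

* **Discontinuities.** Stimuli and drugs are step functions. Integration is
  split at every onset so the right-hand side is smooth within segments;
  step-halving then converges at the expected 4th order (endpoint changes
  below 1e-8), and the independent adaptive cross-check (deSolve's lsoda)
  agrees to better than 1e-6.
* **Stiffness.** The $d\,t_b$ decay grows linearly in time, and high BADS112A
  doses scale the pS112 decay by $(1+u)$; both can push the fastest
  eigenvalue beyond the nominal step's stability limit. Each segment
  therefore caps its step at $2.5/\lambda_{\max}$, estimated from the decay
  rates, before integrating.

Trajectories are clipped at 0 for excursions smaller than 1e-9 (float noise);
larger negative values raise an integration error naming the first offending
time, so genuine model errors are never silently repaired.

## The synthetic reference calibration and data generator

No experimentally fitted estimates or quantified blot tables ship with the
package;
`reference_parameters()` is a synthetic stand-in calibrated once, by forward
simulation, to reproduce the qualitative behaviour of the modelled system:
the sub-hour pERK transient; strong pAKT and BAD-site suppression under
high-dose LY294002; stress rescue of pS112 and CREB under combination
therapy; LY294002 + BADS112A as the strongest of the 28 inhibitor pairs
under all stimulus backgrounds; monotone stress antagonism of apoptosis;
an inward-bowing 25% Loewe isobologram; and the two-region combination-index
map under high stress. A deliberate kinetic choice is the slow turnover of
the BAD phospho-sites (residence times of hours to tens of hours): LY294002
only stops pS112 *production*, while BADS112A accelerates its *removal*, so
the combination clears the site much faster than either agent alone - this
complementarity is what makes the pair synergistic in the model.

`generate_observations()` drives this ground truth through the three
experimental designs and applies the measurement conventions: an epinephrine
dose series (8 conditions; pS112 normalized to control, pCREB to its
maximum), an LY/EGF time course (10 conditions; pAKT, pS112, pS136 to
control, pERK to total ERK), and a 9-treatment apoptosis panel with 3
replicates (27 points). In the two blot designs LY294002 is applied at
normalized dose 10, reflecting the strongly saturating concentrations used
in such experiments, while the apoptosis panel and all synergy analyses use
the dose-1 convention under which every inhibitor sits at half-inhibition.
Nanomolar epinephrine maps to the dimensionless stress input through a
saturating log transform with unit EC50, reaching the high-stress level 100
at 1 uM. Densitometry noise is multiplicative lognormal (default sd 0.1, a
typical western-blot quantification scale); apoptosis noise is binomial
counting over 350 cells, so replicate scatter shrinks as
$1/\sqrt{n_{cells}}$. What passing tests on these tables shows is that the
pipeline is *self-consistent* - it recovers the parameters and model variant
that generated the data; it cannot show that the calibration equals the
biological truth, and features of real blots such as loading artifacts,
saturation nonlinearity or between-batch drift are not emulated.

## Parameter estimation and model selection

The objective is the mean squared error between predicted and observed
normalized values over all table rows, with apoptosis percentages rescaled
to fractions so both data types carry comparable weight; max-normalized
readouts are renormalized on the predicted side exactly as in the data. The
optimizer is an in-package real-coded genetic algorithm searched in log10
space: tournament selection (size 3), uniform crossover (0.8), per-gene
Gaussian mutation (rate 0.1, sd 0.15 of the log-range), elitism 2, all
individuals clamped to the bounds, defaults of population 100 over 200
generations sized to the 37-dimensional stage. An optional Nelder-Mead
polish (derivative-free, bound-clamped) follows the GA; every fit report
records the seed, configuration and per-generation best error. Fitting is
staged: the signaling stage first, then the 7
apoptosis parameters with the signaling stage frozen.

`model_select()` fits both apoptosis variants on the training treatments
(LY294002, LY+EGF, LY+stress) and compares them on the held-out panel,
choosing the lower holdout MSE with ties broken toward the parsimonious
BAD-only model. The mechanism that makes this work is that the BAD-only
model can only absorb the stress-protected training treatment by distorting
its shared parameters, which degrades its held-out predictions.

The tests and the acceptance script run reduced problem sizes chosen to
exercise the full machinery: recovery fits free 8 influential signaling
parameters at population 60 over 40 generations with bounds bracketing the
generating values at a factor of 5, and model selection runs population 40
over 30 generations. These reach MSE below 1e-3 on noiseless data and
recover the generating variant.

## Sensitivity analysis

`time_averaged_sensitivity()` perturbs each free parameter upward by 1% (a
one-sided forward difference, matching how such analyses are usually run)
and averages the absolute relative change of all 14 variables (13 proteins
plus apoptosis percentage) over the 10-point equal partition of [0, 100] h.
The default evaluation condition - LY294002 at dose 1, no stress, the
model's central fitted scenario - is a required, recorded field, because a
local sensitivity is only meaningful for a stated trajectory. Partition
points where the unperturbed variable is below 1e-8 are skipped (relative
change is undefined at zero) and the skip counts are reported in the
metadata. Under the reference calibration the largest entry is about 1.2%,
i.e. the system is conserved under modest parameter changes.

## Synergy quantification

Two complementary indices are computed for a drug pair:

* **Loewe isobologram index.** For a combination $(d_1, d_2)$ achieving
  effect $x$, $CI_{Loewe} = d_1/D_{x,1} + d_2/D_{x,2}$, where $D_{x,i}$ is
  the single-agent dose achieving $x$, obtained by bisection to an absolute
  effect tolerance of 1e-4 (an effect above the single-agent plateau raises
  a typed `unreachable_effect` error). A sham combination of a drug with
  itself scores exactly 1 at every split - the canonical consistency check.
* **Total-dose combination index.** $CI = \max(E_1, E_2)/E_{12}$, where
  $E_i$ is the single-agent effect at the *total* dose $d_1 + d_2$ and
  $E_{12}$ the combined effect at the split. $CI < 1$ exactly when the
  combination beats both single agents at equal total dose; a self-combination
  again scores 1. This max-ratio form is the sharpest index with that sign
  semantics; note that it is intrinsically conservative at extreme dose
  asymmetry - when almost all of the total dose is the weaker agent, the
  stronger single agent at the full total dose is a hard comparator, so maps
  over the full dose grid retain an antagonistic band along the weaker
  drug's axis even for genuinely cooperative pairs.

`synergy_map()` evaluates the combination index over a log-spaced dose grid
(default 20x20 over [0.01, 100], the stated dose range) with single-agent
effects cached per distinct total dose; `count_ci_regions()` segments the
grid at the CI = 1 threshold by flood fill. Under the reference calibration
the no-stress map is synergistic wherever the LY294002 component is at or
above its half-inhibition dose, while at stress 100 the map splits into
exactly two contiguous regions with synergy only at high doses - the
stress-triggered synergism-pattern switch. `resistance_surface()` reports
the raw apoptosis surface instead, showing stress-induced resistance:
without stress the surface sits in a high band at active doses, and under
stress even maximal BADS112A requires high LY doses to kill.

## Design choices where the design was open

* Epinephrine and VIP share one stress input channel with identical
  downstream parameters; they act through the same receptor class and are
  used interchangeably in the modelled experiments.
* The cAMP -> PKA ordering follows second-messenger biology (cAMP is species
  9, PKA species 10), consistent with the initial-state positions.
* The AKT contribution to pS112 is additive inside one Hill term with fixed
  weight 0.5, not a separate fitted term: a separate term would inflate the
  free-parameter count beyond the 37 the staged design prescribes.
* Degenerate-closure decay rates are fitted rather than fixed by convention,
  reconciling the free count to 37 while keeping closure exact.
* The apoptosis-panel VIP treatment uses stress level 10 (a solidly
  activating dose); the synergy switch experiment uses 100.
* The sensitivity condition defaults to LY294002 dose 1 without stress, and
  absolute coefficient values are averaged (magnitudes are what robustness
  statements are about).

## Known limitations

* The time-dependent EGFR-branch decay is phenomenological; there is no
  mechanistic receptor internalization, and species downstream of BAD
  (BclXL, BAX, BAK) are not modelled.
* Apoptosis is a population percentage; no stochastic single-cell model.
* The reference calibration reproduces the documented qualitative
  behaviours, not any externally fitted parameter values; quantities that
  depend on such external estimates (for example their fit errors) are not
  reproduced by construction, and the package reports its own values for
  them.
* The combination index's max-ratio semantics makes whole-grid synergy
  claims unattainable for pairs with unequal single-agent plateaus (see
  above); conclusions about synergy regions should be read with the
  comparator in mind.
* Local, one-sided sensitivity only; no global (Sobol/Morris) analysis.
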