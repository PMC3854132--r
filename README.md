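# badnet

Dynamic network modeling of stress-mediated anti-apoptotic signaling in
prostate cancer cells.

Prostate cancer cells escape apoptosis when the BH3-only protein BAD is
phosphorylated at Ser112 or Ser136. Three signaling routes converge there -
EGF through EGFR-Raf-MEK/ERK (Ser112) and Rac-PAK (Ser136), constitutive
PI3K-AKT (Ser136 and partially Ser112), and stress hormones
(epinephrine/VIP) through the beta2-adrenergic receptor, cAMP and PKA
(Ser112), with PKA-activated CREB standing in for stabilization of the
anti-apoptotic protein Mcl-1. `badnet` implements this 13-protein network as
a system of Hill-kinetics ODEs

$$\dot x_i \;=\; V_i\,\frac{x_{up}^{\,n_i}}{K_i^{\,n_i} + x_{up}^{\,n_i}}
\;-\; d_i\,x_i,$$

with a time-growing decay $d_i\,t_b\,x_i$ on the EGFR branch (the short-term
receptor-signaling transient), steady-state-closed decay rates that make the
untreated state an exact fixed point, and eight targeted inhibitors entering
as the factor $1/(1+u)$ on the velocity they inhibit (dose $u = 1$ is
half-inhibition; the BADS112A mutant instead scales the pS112
dephosphorylation rate by $1+u$). Apoptosis percentage accumulates as

$$\dot C_a = k_a\,t\,\big(1 - H(\mathrm{pBAD}/\mathrm{BAD}_T)\big)\,
\big(1 - \beta\,H(\mathrm{CREB})\big)\,(100 - C_a),$$

where $\beta = 0$ gives the BAD-only model 1 and $\beta > 0$ the BAD+Mcl-1
model 2. On top of the simulator the package provides a genetic-algorithm
fitting stage (37 free signaling + 7 apoptosis parameters), holdout model
selection between the two apoptosis variants, local time-averaged
sensitivity analysis, and drug-combination synergy scoring with both the
Loewe isobologram index and a total-dose combination index
$CI = \max(E_1, E_2)/E_{12}$. A synthetic-data generator reproduces the
statistical structure of the underlying experiments (epinephrine dose
series, LY294002/EGF time courses, apoptosis panels with binomial counting
noise), so the entire pipeline is testable without external data. The
shipped calibration is a documented synthetic reference, not an
experimentally fitted parameter table.

## Worked example

Endpoint apoptosis for the strongest drug pair, with and without stress, and
the stress-triggered synergy switch:

```r
library(badnet)
p <- reference_parameters()

run_condition_panel(p, list(
  parse_schedule("control", 48, "control"),
  parse_schedule("LY294002:1@0", 48, "LY"),
  parse_schedule("LY294002:1@0+BADS112A:1@0", 48, "LY+BADS112A"),
  parse_schedule("LY294002:1@0+BADS112A:1@0+STRESS:100@0", 48, "LY+BADS112A+stress")))
#>         condition_id                              treatment apoptosis_pct
#> 1            control                                control          9.74
#> 2                 LY                           LY294002:1@0         24.58
#> 3        LY+BADS112A              LY294002:1@0+BADS112A:1@0         35.30
#> 4 LY+BADS112A+stress STRESS:100@0+LY294002:1@0+BADS112A:1@0          8.99
```

The PI3K inhibitor LY294002 roughly doubles spontaneous apoptosis at 48 h,
adding BADS112A raises it further (the best of all 28 inhibitor pairs), and
high stress collapses the combination back to near-control level - the
modeled basis of stress-induced therapy resistance. The synergy landscape
switches accordingly:

```r
m0 <- synergy_map(p, stress = 0, n = 10)
m1 <- synergy_map(p, stress = 100, n = 10)
#> no stress:  44% of the dose grid synergistic (CI < 1), 2 regions
#> stress 100: 52% synergistic, 2 contiguous regions; CI at (100, 100) = 0.35
```

Without stress the combination is synergistic wherever the LY294002
component reaches its half-inhibition dose; under high stress synergy
survives only at high doses. Robustness of the calibration:

```r
max(time_averaged_sensitivity(p))
#> [1] 1.19  # max % change of any variable per 1% parameter increase
```

A command-line workflow over the same functions lives in
`inst/cli/badnet.R` (subcommands `simulate`, `fit`, `validate`,
`sensitivity`, `synergy`, `generate-data`, configured by YAML).

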