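# beclinduality

Systems-biology analysis of the dual role of Beclin-1 in ischemic stroke.

Beclin-1 initiates autophagy and, through it, mitophagy — the clearance of
damaged mitochondria that keeps stressed neurons alive. The same protein
feeds three death routes: Caspase-3 cleaves it into the pro-apoptotic
fragment Beclin-1C, accumulating autophagosomes activate Caspase directly,
and autophagic degradation of IAPs (inhibitor-of-apoptosis proteins)
weakens Caspase inactivation. Whether more Beclin-1 saves a neuron or
kills it therefore depends on the stress level, the expression rate, and
the balance of these mechanisms. This package implements that balance as a
five-state ODE model and runs the analyses that quantify it.

## The model

States B (Beclin-1), Bc (Beclin-1C), A (autophagosomes), M (damaged
mitochondria), C (active Caspase-3), under piecewise-constant ischemic
stress S(t):

    dB/dt  = alpha_B (1 + u_B S) - beta_B C B - gamma_B B
    dBc/dt = beta_B C B - gamma_BC Bc
    dA/dt  = alpha_A B - J,     J = beta_A A / (1 + A / phi_A)
    dM/dt  = alpha_M (1 + u_M S) + sigma_M Bc - gamma_M J M
    dC/dt  = (alpha_C M + sigma_C A + mu_C C / (phi_C + 1 - C)) (1 - C)
             - gamma_C C / (phi_C + sigma_J J + C)

The saturable Caspase activation/inactivation pair gives zero-order
ultrasensitivity: C is a bistable switch whose survival state is destroyed
— via a saddle-node bifurcation — by either the mitochondrial damage drive
`alpha_C M + sigma_C A` or the IAP-depletion drive `sigma_J J`. A cell is
apoptotic when C > 0.5 at the 48-hour read-out.

## Worked example

The "golden hour": how long can severe ischemic stress (S = 8) last before
the representative cell is irreversibly committed to apoptosis, and which
interventions extend that window?

```r
library(beclinduality)

duration_threshold(r_variant(), S = 8)
#> <golden_hour> S = 8: T* = 4.66 h

panel <- intervention_panel(S = 8)
panel[!panel$raise_phi_A, c("intervention", "t_star", "fold")]
#>                  intervention    t_star     fold
#> 1                    baseline  4.664062 1.000000
#> 2            halve-expression  8.695312 1.864322
#> 4                 no-cleavage  8.601562 1.844221
#> 6                     flux-5x 10.148438 2.175879
#> 8 no-autophagosome-activation 10.804688 2.316583
#> 10            iap-sparing-10x 10.710938 2.296482
```

Stress removed within ~4.7 h leaves only a transient Caspase rise; beyond
it the switch commits. Halving Beclin-1 expression roughly doubles the
window; so do blocking its cleavage, boosting autophagic flux, or sparing
IAPs from autophagic degradation. Combining IAP sparing with an
unsaturable flux (`raise_phi_A = TRUE` rows) protects past the whole 48 h
horizon (fold reported censored at ~10x).

The population-level analyses live in `analysis/` as numbered stages:

1. `01_caspase_switch.R` — bistability arithmetic and bifurcation
   diagrams of the Caspase switch,
2. `02_scenario_ensemble.R` — a paired Latin-hypercube ensemble across
   eight saturation-by-knockout scenarios with chi-square comparisons,
3. `03_viability_windows.R` — the survival window (theta_L, theta_H) of
   Beclin-1 expression versus stress, and its parameter sensitivity,
4. `04_perturbation.R` — noise-perturbed knockdown/overexpression
   populations under mild and severe stress,
5. `05_golden_hour.R` — the intervention panel above.

Each stage prints its findings and writes tidy CSV/JSON under `results/`.
For example, `Rscript analysis/02_scenario_ensemble.R 2000 1234` simulates
all eight scenarios on a shared 2,000-variant population: the wild type is
~88% apoptotic; each mechanism knockout lowers that to ~73–75%; preventing
flux saturation alone gives ~85%, and combined with the IAP knockout ~46%
— every knockout-versus-wild-type contrast is significant at Bonferroni-
adjusted p < 0.001, while the mechanism-2 and mechanism-3 knockouts are
statistically indistinguishable.

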