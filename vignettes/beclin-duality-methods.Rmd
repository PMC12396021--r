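---
title: "Modeling the dual role of Beclin-1 in ischemic stroke"
author: "beclinduality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the dual role of Beclin-1 in ischemic stroke}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beclinduality)
```

## The model

Beclin-1 sits at the crossroads of autophagy and apoptosis in the ischemic
penumbra. It initiates autophagosome formation and thereby mitophagy — the
clearance of damaged mitochondria, the main cytoprotective response to
ischemic stress — but it also promotes death through three routes:
active Caspase-3 cleaves Beclin-1 into the fragment Beclin-1C, which
permeabilizes the mitochondrial outer membrane; accumulating autophagosomes
act as a platform for Caspase activation; and autophagic degradation of
inhibitor-of-apoptosis proteins (IAPs) weakens Caspase-3 inactivation.

The package implements a five-state ODE system in the variables
B (Beclin-1), Bc (Beclin-1C), A (autophagosomes), M (damaged mitochondria)
and C (active Caspase-3), driven by a piecewise-constant ischemic stress
S(t):

$$\dot B = \alpha_B (1 + u_B S) - \beta_B C B - \gamma_B B$$
$$\dot{B_c} = \beta_B C B - \gamma_{BC} B_c$$
$$\dot A = \alpha_A B - J, \qquad J = \frac{\beta_A A}{1 + A/\varphi_A}$$
$$\dot M = \alpha_M (1 + u_M S) + \sigma_M B_c - \gamma_M J M$$
$$\dot C = \Big(\alpha_C M + \sigma_C A +
  \frac{\mu_C C}{\varphi_C + 1 - C}\Big)(1 - C) -
  \frac{\gamma_C C}{\varphi_C + \sigma_J J + C}$$

Most reactions are mass action. The autophagic flux J saturates at
$\beta_A \varphi_A$ (limited lysosomal capacity), and both the Caspase
activation and inactivation terms are Michaelis–Menten in C: their shared
saturation produces zero-order ultrasensitivity, so C behaves as a
bistable switch between a survival state (low C) and an apoptotic state
(high C). Abundances are normalized so that unstressed steady levels are
of order one; rates are per hour. A simulated cell is *apoptotic* when
C exceeds 0.5 at the 48-hour read-out (strictly greater: `classify_apoptosis`
breaks the tie downward).

## The Caspase switch in isolation

Freezing the slow variables lumps their influence into two drives: an
activation drive $\alpha_1 = \alpha_C M + \sigma_C A$ and an IAP-depletion
drive $\alpha_2 = \sigma_J J$. For $\alpha_1 = \alpha_2 = 0$ the net
Caspase rate factorises as $g_1(C)\,g_2(C)$ with $g_1 < 0$ on (0, 1] and
$g_2$ quadratic, so the switch is bistable exactly when $g_2$ has two roots
in (0, 1] — positive discriminant and $g_2(0) > 0$. The fixed constants
$\mu_C = 1$, $\gamma_C = 0.3$, $\varphi_C = 0.15$ give
$g_2(0) = 0.195$ and half-discriminant $0.27125$, hence critical points at
0 (stable), $\gamma_1 \approx 0.207$ (unstable threshold) and
$\gamma_2 \approx 0.943$ (stable, apoptotic):

```{r cond1}
caspase_cond1(switch_params())
```

For nonzero drives the critical points are found numerically (dense sign
scan over 400 subintervals of [0, 1], bisection refinement to 1e-10);
growing either drive annihilates the survival state in a saddle-node
bifurcation. `caspase_bifurcation` locates the fold by bisection on
"the low-C stable branch exists"; `caspase_fold_tangency` solves the
tangency condition independently by exploiting that the net rate is linear
in the drive. The two agree to 1e-6, which the test suite asserts.

These three constants are excluded from ensemble sampling precisely
because the analysis depends on the switch staying bistable.

## Resting states and initial conditions

The study conditions never state initial conditions explicitly, so the
package makes them a first-class design decision. Every simulation starts
from the variant's own unstressed steady state, computed by fixed-point
iteration on C (each remaining state has a closed form given C, and C is
updated to the lowest stable root of the Caspase balance under the frozen
drives). Near the resting saddle-node the fixed-point map can cycle; those
rare variants are finished by relaxation integration of the unstressed
system, and any state whose right-hand side exceeds 1e-8 per component is
rejected loudly.

Two special cases arise in wide parameter ranges:

* **Flux-degenerate variants** — when $\alpha_A B > \beta_A \varphi_A$ at
  rest, autophagosome formation outruns the flux supremum and no resting
  balance exists. These variants (about 3% of the default ensemble) are
  excluded from ensemble analyses, identically across paired scenarios,
  with counts reported.
* **Basin-less variants** — the cleavage feedback C → Bc → M can destroy
  the survival root, leaving only the apoptotic branch. Roughly half the
  sampled variants rest there: they are intrinsically doomed cells, *kept*
  in the ensembles and simulated from their (apoptotic) resting state.
  Excluding them instead would depress the wild-type apoptotic fraction by
  roughly ten percentage points, far from the values this pipeline
  reproduces — the published fractions require counting them.

Intervention experiments (the golden-hour panel and the
knockdown/overexpression populations) start from the resting state of the
*untreated base variant*, with the parameter override acting from stress
onset: the in-silico analogue of administering a treatment to a resting
cell at the moment of the insult. Re-equilibrating each intervention to its
own steady state before stressing it changes the measured fold-extensions
substantially (e.g. 1.55 instead of 1.9 for halved expression) and does not
correspond to the acute-treatment narrative.

## The virtual population

`sample_ensemble` draws Latin-hypercube variants: each sampled parameter's
unit interval is split into n equal strata holding exactly one draw
(`lhs::randomLHS` under a fixed seed, default 1234), mapped linearly onto
the parameter ranges. Sampling is uniform on the linear scale for every
parameter — no log transformation — matching the linear-interpolation
description of the sampling procedure.

Fourteen parameters are sampled: S ∈ [0, 10], α_B ∈ [0.1, 5], and the
rates β_B, γ_B, γ_BC, α_A, β_A ∈ [0.5, 2], φ_A ∈ [5, 20],
α_M, γ_M ∈ [0.5, 2], σ_M ∈ [25, 100], α_C ∈ [0.0025, 0.01],
σ_C ∈ [0.0005, 0.002], σ_J ∈ [0.005, 0.02]. The stress sensitivities
u_B and u_M are held at their representative value 1: the study's stated
count of varied parameters is fourteen even though its symbol list and
range table include the sensitivities, and the paired-design attribution
(below) corroborates the fourteen-parameter reading — with sixteen sampled,
the knockout-scenario fractions sit systematically three to five points
above the published values across seeds, while with fourteen every scenario
lands within about one point. `sampling_ranges(include_stress_sensitivities
= TRUE)` restores the sixteen-parameter design for exploration.

The exact draws of the original analysis are not portable across samplers
(a seed pins a specific library's stream), so ensemble results carry
Monte-Carlo plus sampler-implementation uncertainty; the acceptance
tolerances are set accordingly (±2 percentage points at n = 10,000).

The stress level S is sampled per variant and drives that variant's
protocol (stress on [0, 24] h of a 48 h simulation). For the
stratified summaries it is binned into mild (0, 1], moderate (1, 2.5] and
severe (2.5, 5] bands, with variants above 5 reported in an extra band
rather than dropped. Expression bins are log-spaced over the sampled
α_B range — it spans almost two decades — and bins with fewer than five
variants are reported as missing rather than as zero.

## The eight scenarios and attribution

The scenario grid crosses flux saturation (sampled φ_A versus φ_A = 10^6,
which removes saturation for any reachable A) with knockouts of the three
pro-apoptotic mechanisms: β_B = 0 (no cleavage), σ_C = 0 (no
autophagosome-mediated activation), σ_J = 0 (no IAP degradation). All
eight scenarios run on the *same* variants, so every contrast decomposes
exactly into per-variant rescues and losses; `scenario_fractions` retains
the per-variant outcome matrix, and the test suite asserts that the
fraction gap equals the net flip rate and that knockouts essentially only
rescue (< 1% adverse flips). This paired attribution is also the
instrument used to diagnose any systematic miss of the published
fractions — it is how the fourteen-parameter sampling question was
settled.

Scenario comparisons use Pearson chi-square tests on the 2×2 tables
without continuity correction (immaterial at these sample sizes) and
Bonferroni adjustment with the family size of the reference analysis (six
pairwise tests among the four saturated-family conditions). Proportions
carry Wald 95% intervals, as in the reference analysis, despite the Wald
form's boundary degeneracy (a score interval is deliberately not
substituted — the reporting convention is part of what is being
reproduced).

## Golden hour and censoring

`duration_threshold` bisects the stress duration d (stress on [0, d],
horizon 48 h) for the boundary of the 48-h apoptosis classification, to a
resolution of 0.05 h; commitment is monotone in d because the switch is
bistable, which a 0.1 h sweep in the test suite confirms. For the
representative variant at S = 8 the threshold is ≈ 4.7 h.

One intervention — ten-fold lower IAP-degradation efficiency combined with
a ten-fold higher saturation threshold — never commits within the 48 h
horizon at any duration: sustained stress parks C at ≈ 0.03, below the
fold. Its threshold is therefore *censored at the horizon* and its fold
(≈ 10×) is a lower bound read at 48 h. The corresponding published
fold (9.9) equals the largest duration testable inside the horizon in
units of the baseline threshold, i.e. the same censoring expressed on a
scan grid; the panel flags such entries rather than pretending the
threshold is interior.

The mechanism-2 entry of the intervention panel is five-fold flux
enhancement (β_A × 5), the intervention the reference analysis actually ran; a σ_C = 0 entry is provided alongside, but its
fold-extension (≈ 2.4 alone, ≈ 2.7 with raised φ_A) does not match the
published 2.2/2.3 pair, while β_A × 5 does.

## Numerical choices

* Integration: `deSolve::lsoda` on a compiled right-hand side, rtol 1e-8,
  atol 1e-10; the integration restarts at stress onset/offset so the
  solver never steps across a discontinuity. An R-level right-hand side
  provides an independent route, and a fixed-step RK4 oracle at dt = 1e-3 h
  agrees with the adaptive solution to 1e-3 on random variants.
* State box: components are clipped only for sub-tolerance negative
  excursions; any trajectory leaving B, Bc, A, M ≥ 0 or 0 ≤ C ≤ 1 beyond
  1e-6 aborts (it would signal a solver problem, not model behaviour).
* Thresholds: viability windows scan 100 log-spaced expression rates on
  [0.1, 10] with bisection refinement to 1e-3; a non-contiguous survival
  set is an error (none has been observed), not silently hulled.
* Ties: apoptosis is a strict inequality at C = 0.5; the end-point and
  ever-crossed readings coincide away from a measure-zero band because the
  switch is bistable.

## Problem sizes

The analysis scripts default to 2,000-variant ensembles — at that size
every published fraction is reproduced within about one point (the
acceptance tests allow ±3 at n = 2,000) — and the acceptance script runs
the two headline scenarios at the full 10,000. Windows, sensitivity scans
and perturbation populations use the grid sizes quoted above; the
knockdown/overexpression populations default to 1,000 cells per fold.

## What the generator does not emulate

The virtual population varies kinetic parameters cell-to-cell but keeps
the model structure fixed: no spatial stress gradients across the
penumbra, no reperfusion injury or hemorrhagic-transformation risk, no
cell-type heterogeneity beyond parameter spread, and no upstream
regulators (mTORC1, AMPK, BNIP3/Bcl-2 binding). Passing tests therefore
certify the pipeline against its own model assumptions — not against
neuronal biology, which the accompanying wet-lab literature addresses.
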