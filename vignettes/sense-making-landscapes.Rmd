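---
title: "Sense-making landscapes of symptom perception: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sense-making landscapes of symptom perception: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sensescape)
```

## The model

`sensescape` analyses a Landau-type free-energy model of the automatic
perception of a persistent symptom (pain, fatigue, dizziness, ...). The
order parameter $\phi$ is the automatic perception: $\phi < 0$ is a
survival-oriented, alert-protection reading of the symptom, $\phi > 0$ a
liveliness-oriented, trust-explore reading, $\phi = 0$ neutral. The
organism's sense-making $S$ is modelled as minus a free energy,

$$F(\phi) = -h_{\mathrm{ext}}\,\phi + \frac{a}{2}\phi^2 +
  \frac{h_{\mathrm{int}}}{3}\phi^3 + \frac{b}{4}\phi^4,
  \qquad a = a_0\,(T - T_0),$$

so minima of $F$ are the most likely perceptions. The control parameters
are all dimensionless embodied information:

* $T \ge 0$ — information from the senses about the context ($T = 0$ means
  complete absence of sensory information);
* $T_0$ — the innate critical context below which a neutral perception is
  no longer tenable;
* $h_{\mathrm{int}}$ — historical information about the symptom; positive
  values are alarming learned rules;
* $h_{\mathrm{ext}}$ — information from the expert culture; negative values
  act as nocebo messages, positive values as trustworthy neurobiological
  education (NBE);
* $a_0, b > 0$ — innate constants. The model gives no ranges for them
  beyond positivity; the package defaults $a_0 = b = 1$ are a toolkit
  choice, not a model prescription, and every function takes them
  explicitly.

Stationary perceptions solve the cubic $F'(\phi) = 0$,
$h_{\mathrm{ext}} = a\phi + h_{\mathrm{int}}\phi^2 + b\phi^3$. With $b > 0$
there are one to three stationary points and at most two minima (wells).

Two derived quantities summarise a two-well landscape: the perception bias
$\Delta\phi = |\phi_{t\text{-}e}| - |\phi_{a\text{-}p}|$ and the
sense-making bias $\Delta F = |F(\phi_{t\text{-}e})| -
|F(\phi_{a\text{-}p})|$, where $\phi_{a\text{-}p}$ and $\phi_{t\text{-}e}$
are the negative and positive wells. $F(\phi_{a\text{-}p})$ is termed
hypervigilance and $F(\phi_{t\text{-}e})$ curiosity. When one of the two
states does not exist, the biases are reported as `NA` — flagged, never
silently zero. In the catastrophizing landscape the neutral well stands in
for the absent trust-explore state, so the curiosity value is exactly 0
there; this is surfaced explicitly rather than folded into $\Delta F$.

## Regime taxonomy

With no historical bias ($h_{\mathrm{int}} = 0$) the transition at
$T = T_0$ is second order: Zen (one neutral well) above, uncertainty at the
critical context, and the balanced "baby" double well below, with
$\Delta\phi = \Delta F = 0$. Alarming history makes the transition first
order and shifts the onset of uncertainty to

$$T^* = T_0 + \frac{2\,h_{\mathrm{int}}^2}{9\,a_0 b},$$

i.e. the perceived critical context depends on personal history. For
$h_{\mathrm{int}} > 0$: Zen for $T > T^*$, uncertainty with pessimistic
bias exactly at $T^*$ (degenerate wells at $\phi = 0$ and
$\phi = -2h_{\mathrm{int}}/3b$, both at $F = 0$), catastrophizing for
$T_0 < T < T^*$ (global alert-protection well, neutral well marginal), and
the hypervigilance-bias mixed state for $T < T_0$. Negating
$h_{\mathrm{int}}$ (and $h_{\mathrm{ext}}$) mirrors every landscape:
catastrophizing becomes communicative, hypervigilance bias becomes
curiosity bias.

`classify_regime()` is deliberately structural — it reads the well count,
the well signs and the degeneracy of their energies, not parameter
inequalities — so it extends to tilted landscapes
($h_{\mathrm{ext}} \ne 0$), where only qualitative guidance exists. The
parameter bands above are cross-checked against the structural labels in
the test suite at $h_{\mathrm{ext}} = 0$. Two boundary choices were
genuinely open and are resolved as follows:

* a two-well landscape whose *metastable* well lies above $F = 0$ while the
  neutral well is global is labelled ZEN, matching the convention that the
  Zen landscape extends down to $T^*$;
* a *monostable* landscape with a nonzero well (possible only under tilt)
  inherits the label of the family whose dominant state it is the limit of:
  CATASTROPHIZING when the well is negative, COMMUNICATIVE when positive.
  This keeps the mirror symmetry exact and gives tilted scenario endpoints
  a meaningful label.

The description of the uncertainty-pessimistic landscape as having
"multiple" minima is schematic — a quartic supports at most two — and is
implemented literally with two.

## Numerical choices

* **Stationary points.** The gradient cubic is solved analytically
  (trigonometric branch for three real roots, Cardano for one) and each
  root is polished with guarded Newton steps to gradient tolerance
  $10^{-10}$. Double roots are detected on a *relative* discriminant scale
  $\max(|p|^3, q^2)$ of the depressed cubic — an absolute threshold would
  misread three small symmetric roots near $a \approx 0$ as degenerate —
  and reported once, as inflections. Roots closer than
  $10^{-6}(1 + |\phi|)$ are merged. Curvature within $10^{-9}$ of zero is
  classified as an inflection.
* **Degeneracy tolerance.** Landscape classification uses an energy
  tolerance of $10^{-6}$ (configurable). Exactly degenerate regimes
  (uncertainty, $T = T^*$) are measure-zero; the tolerance makes them
  reachable.
* **Numeric degeneracy context.** `degeneracy_context_numeric()`
  generalises the closed form to $h_{\mathrm{ext}} \ne 0$: it scans the
  well-energy gap over a $T$ grid, bisects any sign change to tolerance
  $10^{-8}$, and — because the bistable window in $T$ can be narrower than
  any fixed grid — refines the upper boundary of bistability and bisects
  toward it, accepting the limit only if the gap actually closes there.
  Gaps below the floating-point noise floor of $F$ are treated as exact
  degeneracy; the fully symmetric family ($h_{\mathrm{int}} =
  h_{\mathrm{ext}} = 0$), degenerate everywhere it is bistable, returns the
  upper boundary $T_0$.
* **Basin tracking.** Quasi-static sweeps and scenarios identify the well
  continuously connected to the previous perception by the exact watershed
  criterion on a 1-D landscape — a well is reachable if no maximum lies
  strictly between — rather than a nearest-minimum radius heuristic. A
  transition counts as a jump (basin annihilation) exactly when the path
  from the previous perception to the new well crosses the
  negative-curvature band of the new landscape, the region a continuously
  drifting well can never enter.
* **Hysteresis loop area.** Branch differences are integrated by the
  trapezoidal rule. The sweep grid is augmented with the exact spinodal
  fields, and at a spinodal the occupied state passes through the
  degenerate shoulder before falling, so jump verticals sit exactly at
  $h_{\mathrm{ext}}^{\uparrow\!/\!\downarrow}$; the area is then stable to
  better than $10^{-3}$ relative between 200- and 2000-point grids.

## Attention and occupancy

Automatic attention sits in the global minimum; at a degeneracy the tie is
broken by policy (default: the trust-explore side, matching the usual
depiction; `keep_previous` is used inside scenarios to preserve
hysteresis). Conscious attention may be placed on any extremum regardless
of depth. The model itself only *orders* states — deeper sense-making
minima are more likely — and defers metastable-state probabilities to a
microscopic treatment; the Gibbs weighting
$p_i \propto e^{-F_i/\tau}$ over wells implemented by
`occupancy_probabilities()` is therefore an implementation choice. Its
fluctuation scale $\tau$ (default 0.05, dimensionless like $F$) is echoed
in every output so results are never presented as model-prescribed. As
$\tau \to 0^+$ the weight concentrates on the global minimum, recovering
automatic attention.

How conscious attention interacts with subsequent automatic attention
across scenario steps is unspecified in the model; the package keeps them
independent (a conscious placement only sets the starting state).

## Hysteresis and the biopsychosocial loop

Sweeping expert information $h_{\mathrm{ext}}$ quasi-statically with an
alarming history present ($h_{\mathrm{int}}^2 > 3ab$) produces a
first-order hysteresis loop: the occupied basin persists until it
annihilates at a spinodal field, where gradient and curvature vanish
simultaneously. The zero-fluctuation (deterministic) jump policy is the
only construction the static model supports — thermally activated switching
before the spinodal would require non-equilibrium dynamics, which are out
of scope. For $h_{\mathrm{int}} > 0$ the loop is asymmetric,
$h^{\uparrow} > |h^{\downarrow}|$: trustworthy positive information must be
large to counteract the learned bias, which is the model's reading of a
biopsychosocial loop (bio: symptom; psycho: perception; social: expert
information). The middle, negative-slope branch is excluded from the loop
and drawn dashed. `detect_hysteretic_cycle()` flags the operational loop
signature in a scenario — parameters revisit an earlier record while the
occupied role differs — and reports the signed shoelace area of the
enclosing $(h_{\mathrm{ext}}, \phi)$ cycle, which for a closed path
crossing both spinodals reproduces the quasi-static loop area.

The "Phoenix" narrative — a new perception emerging from deep suffering
once sensory information is allowed back in — is represented only by the
monotonicity of the alert state's depth in $T$ (the catastrophizing well is
closer to neutral than the hypervigilance one), not as a distinct
mechanism.

## The packaged scenario and the parameter sampler

The neckache scenario shipped in
`inst/extdata/neckache_scenario.yaml` is synthetic and illustrative: the
narrative sequence (neutral context, uncertainty with survival bias,
catastrophizing, hypervigilance, nocebo deepening, NBE, belief revision,
communicative landscape) is qualitative in the model, and the packaged
numbers ($a_0 = b = 1$, $T_0 = 5$, steps `T: 8 -> 7 -> 6 -> 4`,
`h_int: 0 -> 3 -> -1`, `h_ext: 0 -> -0.5 -> 0 -> 0.5`, final `T: 6`) were
chosen once to satisfy the regime inequalities, and are documented as a
toolkit choice. Scenario steps are additive deltas by default, matching
the model's description of learning as variations $\delta h$, $\delta T$;
absolute overrides exist for fixtures.

`sample_random_parameters()` draws uniform parameter sets for property
testing over $a_0, b \in [0.2, 5]$, $h_{\mathrm{int}}, h_{\mathrm{ext}} \in
[-5, 5]$, $T_0 \in [0.5, 10]$, $T \in [0, 12]$ — ranges wide enough to
cover every named regime and both spinodal phases, chosen once and kept
fixed. What passing property tests show is that the analytic machinery is
exact and self-consistent across this space; the generator emulates no
empirical data, and nothing here validates the model *as psychology* —
there is no inference from patient data, and none is attempted.

## Worked example

```{r example}
p <- model_parameters(h_int = 1, T = 5.1, T0 = 5)
an <- analyze_landscape(p)
an
occupancy_probabilities(an, tau = 0.01)
```

Problem sizes used throughout the documentation and tests (grids of a few
hundred to a few thousand points, property suites of 100 seeded draws) keep
every computation well under a second while leaving the reported digits
converged; they are stated where used.

## Limitations

Static, equilibrium model only: no time-dependent feedback between agent
and organism, no stochastic switching before the spinodal, no $\phi^6$
extensions, and no mapping from regime labels to clinical recommendations.
The toolkit computes exactly what the model defines — landscapes, regimes,
critical contexts, spinodals, loops and scenario trajectories — and nothing
beyond it.
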