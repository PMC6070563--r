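---
title: "Modeling the Twist1-Prrx1-TNC switch: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the Twist1-Prrx1-TNC switch: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pflswitch)
```

## The model

Activated fibroblasts are maintained by a three-gene positive feedback
loop: Twist1 activates Prrx1, Prrx1 activates tenascin-C (TNC), and
secreted TNC feeds back onto Twist1 production. `pflswitch` models the
loop with three state variables (Twist1 $Tw$, Prrx1 $P$, TNC $T$, all in
arbitrary units) driven by Hill-type activation and first-order decay:

$$
\begin{aligned}
\frac{dTw}{dt} &= b_{Tw} + V_{dox}\, h(D; K_{dox}, n_{dox})
  + V_{fb}\, h(T_{sensed}; K_{m1}, n_{fb}) - k_{Tw} Tw,\\
\frac{dP}{dt} &= b_P + V_{TwP}\, h(Tw; K_{TwP}, n_{TwP}) - k_P P,\\
\frac{dT}{dt} &= b_T + V_{PT}\, h(P; K_{PT}, n_{PT}) - k_T T,
\end{aligned}
\qquad h(x; K, n) = \frac{x^n}{K^n + x^n}.
$$

Two stimulus modes cover the two experimental situations. In **dox mode**
the external input $D$ is the doxycycline level of a Tet-ON Twist1
induction and the feedback senses endogenous TNC only
($T_{sensed} = T$). In **injection mode** there is no doxycycline
($D = 0$) and the feedback senses endogenous plus exogenous TNC
($T_{sensed} = T + s$), which is how a recombinant-TNC treatment enters
the loop.

This is deliberately a minimal essential model: each regulatory arrow in
the loop is a single saturating term, decay is linear, and no
intermediate species are resolved. The canonical form has 18 constants;
the shipped configurations keep the effective count at 16 by fixing
$n_{dox} = 1$ (the induction input is Michaelis-Menten) and tying
$n_{TwP} = n_{PT}$ (a single cascade cooperativity). Both constraints are
plain parameter choices, not code restrictions.

Time is measured in days — the natural scale of the induction
experiments, where Prrx1 follows Twist1 within a day but TNC needs
several days to come up — and all concentrations are in arbitrary units,
as appropriate for immunoblot fold-change data.

## Steady states, sweeps, and why there are two engines

At equilibrium $P$ and $T$ are explicit functions of $Tw$, so all fixed
points solve a scalar self-consistency equation in $Tw$ on the a-priori
bracket $[0, (b_{Tw} + V_{dox} + V_{fb})/k_{Tw}]$. `find_fixed_points()`
scans this bracket on a log-spaced grid (2000 points by default), polishes
every sign change with Brent's method (`eps_root = 1e-9`), merges
duplicates closer than `eps_dup = 1e-6` (relative), and classifies
stability from the eigenvalues of the analytic 3x3 Jacobian. Because the
scan is exhaustive on the bracket, the method finds all one-to-three
roots of the monotone cascade.

Quasi-static stimulus sweeps — step the stimulus, let the system settle,
seed the next step with the settled state — come in two interchangeable
engines:

* `method = "relax"` integrates the ODE (`deSolve::lsoda`, analytic
  Jacobian, `rtol = 1e-8`, `atol = 1e-10`) in growing chunks until
  $\max |dx/dt| < 10^{-8}$ a.u./day or a 5000-day horizon is reached
  (non-convergence is flagged, not raised). This is the literal
  quasi-static protocol.
* `method = "continuation"` follows the stable equilibrium branch through
  the root scan, picking at each grid point the stable fixed point
  nearest the previous state (in log-Twist1). After a saddle-node the
  nearest surviving branch is the one the flow reaches, so the two
  engines agree; the test suite asserts this, and also checks both
  against a genuinely slow ODE ramp.

Phase diagrams add a third, still faster route. The loop has a single
fold: an up-then-down excursion changes the final state if and only if
(i) the system is bistable at zero stimulus and (ii) the low branch has
vanished by the sweep maximum. Both conditions are two root scans, so a
cell's ΔTNC is `TNC_high(0) - TNC_low(0)` when they hold and zero
otherwise. A 40x40 diagram takes on the order of ten seconds this way; the
equivalence with the sweep engines is again under test.

## Switching metrics

`hysteresis()` reports the activation threshold `theta_on` (up-sweep
jump), deactivation threshold `theta_off` (down-sweep fall), their
difference (the hysteresis width), and the irreversibility measure
`delta_tnc` = TNC at zero stimulus after the excursion minus before it,
with `eps_rev = 1e-3` a.u. separating "reversible" (ΔTNC = 0, Phase I)
from "irreversible" (ΔTNC > 0, Phase II). Thresholds are quoted as the
midpoint of the bracketing grid interval, so the grid spacing is their
uncertainty.

Jumps are detected by an adjacent-point TNC ratio. The package default is
2, not higher, and this is a considered choice: a parameterization that is
reversible at its default feedback strength necessarily has its active
TNC state sitting near the feedback threshold $K_{m1}$ (were it far above,
the loop would self-sustain at zero stimulus), which caps the contrast
between the last low-branch point and the first high-branch point at
roughly 2.5-fold. Ratios of 5 or more only occur in irreversible regimes.
The threshold is a reporting convention and is exposed as `jump_ratio`.

Ultrasensitivity is summarized by the classic effective Hill exponent
$n_{eff} = \log 81 / \log(EC_{90}/EC_{10})$ of the up-sweep TNC branch,
with the matched $V_{fb} = 0$ cascade as control (dox mode only — in
injection mode the ablated loop has no stimulus route at all and the
control is undefined). When both crossings fall in one grid interval the
response is flagged discontinuous and $n_{eff} = \infty$.

## The calibrated presets

Four parameter files ship in `inst/extdata/` (see
`inst/scripts/tune_presets.R`, which regenerates them and records the
tuning targets). They were tuned once, before the test suite was written,
against the qualitative and kinetic anchors of the underlying study:

* **dox_reference / mrc5** (identical): bistable for dox between about
  1.8 and 6.6 a.u., reversible hysteresis at the default feedback
  strength $V_{fb} = 40$, irreversible at $V_{fb} = 80$. The Prrx1 and
  TNC timescales (9 and 3 days) and the Prrx1-to-TNC threshold
  ($K_{PT} = 9$, near the Prrx1 plateau of ~10) put the noise-free TNC
  2-fold induction delay at 8.1 days under a saturating dox step, with
  activation order Twist1 (0.2 d), Prrx1 (0.9 d), TNC — the slow TNC
  onset is a genuine threshold-crossing delay, not merely a slow decay
  constant.
* **imr90**: the same equilibrium structure with faster Prrx1/TNC
  turnover (3.5 and 1.5 days), giving a 4-day TNC delay.
* **dermal_injection**: the exogenous-TNC variant, with a stronger basal
  cascade (unit decay rates, $K_{TwP} = K_{PT} = 5$, $n_{TwP} = n_{PT} =
  2$) and feedback $(K_{m1}, V_{fb}) = (5, 30)$. At these values the loop
  is bistable at zero stimulus, so a pulse of amplitude 3 latches it on
  (ΔTNC ≈ 4.5); at $(10, 15)$ the zero-stimulus state is unique and any
  pulse is reversible. The dose-to-stimulus scale is 0.6 a.u. per
  microgram, placing the switching threshold between the 2 and 5 ug doses
  so that, of the panel {0, 0.1, 1, 2, 5} ug, only 5 ug activates Twist1
  and endogenous TNC beyond 2-fold.

## Synthetic data: what it emulates, and what it does not

`generate_timecourse()` simulates an induction protocol from the basal
steady state, converts to log2 fold change over that baseline (the
immunoblot normalization), and adds i.i.d. Gaussian noise on the log2
scale — i.e., log-normal multiplicative error, defaulting to
$\sigma = 0.2$, a typical densitometry error scale. Default sample days
are {0, 1, 2, 3, 5, 8, 11, 15}. `generate_dose_response()` reads out
steady-state (or fixed-horizon) Twist1 and endogenous-TNC fold changes
per dose with the same noise model. `generate_single_cell_snapshot()`
draws each cell ON with a set probability, places it at the corresponding
stable fixed point, and applies independent log-normal cell-to-cell
factors, producing the concordant, bimodal triple-positive/triple-negative
mixtures seen in tissue snapshots of a bistable population.

Every generator is a pure function of its arguments and seed, and
noise-free output scores exactly the likelihood constant under the
estimation objective.

These generators emulate the *shape* of the measured data, not its full
error structure: real immunoblots have shared per-blot normalization
error, saturation, and background subtraction; real single-cell stains
have segmentation error and spatial correlation; dose-response wells
share batch effects. Passing tests therefore demonstrate that the
pipeline recovers truth under the stated noise model, not that it is
robust to every artifact of the original assays.

## Parameter estimation

The objective is the Gaussian negative log-likelihood of the observed
log2 fold changes,
$\sum_i (y_i - \hat y_i(\theta))^2 / 2\sigma^2 + n \log(\sigma\sqrt{2\pi})$,
with $\sigma$ fixed by the caller (homoscedastic on the log2 scale, the
natural scale of fold-change data). Candidates whose simulation fails are
scored $+\infty$ and thereby rejected rather than raising.

The global search is a generational genetic algorithm over log10
parameter space within bounds (default two decades either side of the
base values): tournament selection (size 3), uniform crossover (rate
0.8), Gaussian mutation (per-gene rate 0.1, step 0.15 of the log-range),
and elitism (2), followed by a Nelder-Mead polish of the best individual.
Elitism makes the best-objective trace non-increasing, and the entire fit
is a deterministic function of the configuration seed. The defaults
(population 100, 200 generations) suit overnight fitting; the test suite
and examples use smaller, documented configurations (population 24-48,
25-48 generations) that already recover a single free parameter from
noise-free data to well under 1%.

Parameter recovery has one structural caveat worth knowing about. When
the active-state TNC level stays below $K_{m1}$, the feedback term is
effectively $V_{fb}(T/K_{m1})^{n}$ and only the ratio $V_{fb}/K_{m1}^{n}$
is constrained — $V_{fb}$ and $K_{m1}$ individually slide along a ridge.
The packaged recovery benchmark therefore uses an IMR90-like truth with
$K_{m1} = 2.5$, placing the ON state in the saturating part of the
feedback curve where both parameters are identifiable; with
$\sigma = 0.2$ noise, three replicates and eight sample days, the
four-parameter fit ($V_{fb}$, $K_{m1}$, $k_{Tw}$, $V_{dox}$) recovers
each parameter with a median relative error well inside 30% across ten
seeds. `recovery_experiment()` flags parameters whose median error
exceeds 100% as non-identifiable.

## Numerical choices and degenerate inputs

* Stiff-safe integration: `lsoda` with the analytic Jacobian; protocol
  discontinuities coincide with solver restarts (piecewise integration).
* States are floored at zero before evaluating the right-hand side, so
  solver undershoot within `atol` cannot trip the non-negativity domain
  checks; trajectories are reported clipped at zero.
* `hill()` works on the ratio $(x/K)^n$ and maps overflow to 1, so very
  large inputs and exponents stay finite; its derivative is defined at
  $x = 0$ (equal to $1/K$ for $n = 1$, zero otherwise).
* Fold-change baselines are floored at $10^{-6}$ a.u. (`induction_delay`)
  or $10^{-12}$ (log2 conversion) to guard division by a near-zero basal
  level; induction delays interpolate linearly between samples, and a
  trajectory that never crosses threshold reports `NA` with a `crossed`
  flag rather than an error.
* Ties in `activation_order()` are broken by the loop order Twist1,
  Prrx1, TNC.
* A monostable up-sweep reports thresholds as `NA`, width 0 and
  ΔTNC = 0 by construction; an irreversible sweep reports `theta_off =
  NA` and, in `hysteresis_width_curve()`, the open-ended width equal to
  `theta_on` with an `open_ended` flag.

## Problem sizes

The shipped analyses are sized for a single CPU: hysteresis sweeps use
41-51 grid points, phase diagrams 40x40 cells via the two-scan fast
engine, the oracle cross-checks use 10 random parameter draws with a
27-point initial-condition grid, and the recovery benchmark runs ten
seeds at population 48 for 48 generations. All of these are arguments,
not constants; larger grids and populations simply take proportionally
longer.

## Known limitations

* The exact supplementary equations of the original study are not
  reproduced; the model here is the canonical Hill cascade consistent
  with the loop's published structure (induction input, two activation
  steps, saturating feedback, linear decay). Conclusions that depend on
  finer mechanistic detail (e.g., explicit secretion or matrix binding of
  TNC) are out of scope.
* ΔTNC is computed for quasi-static excursions; fast pulses that outrun
  the slow Prrx1/TNC timescales can fail to latch the loop even in the
  irreversible regime. Use `simulate_pfl()` with an explicit
  `tnc_pulse()` when pulse kinetics matter.
* The likelihood assumes independent homoscedastic log2 errors;
  correlated blot-level error is not modeled, so confidence in fitted
  parameters is optimistic for real data.
* The $(V_{fb}, K_{m1})$ ridge described above means those two parameters
  should not be fitted jointly from a single sub-saturating time course.
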