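---
title: "Models and methods: bistability in tumor-immune dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: bistability in tumor-immune dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cisim)
```

## The scientific problem

Immunotherapy works, when it works, by tipping a tumor out of a stable
state. `cisim` implements a family of deterministic cancer-immune
interaction models whose common feature is *bistability*: for the same
parameters the system supports both a cancer-free state and a
macroscopic tumor near carrying capacity, separated by an unstable
interior equilibrium — the *immunological barrier*. The package provides
the full analytic apparatus around these equilibria, a discrete-event
stochastic simulator for the small-number regime where eradication is
actually decided, and treatment experiments that exploit the bistability
(checkpoint-blockade-style killing-efficacy ramps, adoptive effector
transfer, and dose grids of the two combined).

## The three models

**Base model.** Tumor cells $T$ grow logistically and are lysed by
effector cells $E$ under mass action; effectors are replenished at a
constant rate, die, and are net-stimulated or net-suppressed by tumor
contact at a single signed rate $m$:

$$\dot T = aT(1-bT) - kTE, \qquad \dot E = \sigma - dE + mET.$$

Collapsing stimulation and suppression into one net rate is the model's
deliberate simplification: the sign of $m$ is then the interesting
object. $(0, \sigma/d)$ is always a fixed point; interior equilibria
solve a quadratic, $T^*_{2,3} = [a(m+bd) \pm \sqrt{\Delta_s}]/(2abm)$
with $\Delta_s = (a(m+bd))^2 - 4abm(ad-k\sigma)$. Requiring both roots
positive — the only arrangement compatible with an immunological
barrier — forces $m < 0$ (immunosuppression dominates) and brackets the
killing efficacy between closed-form thresholds

$$k_l = \frac{ad}{\sigma}, \qquad
  k_u = k_l - \frac{(a(m+bd))^2}{4abm}\cdot\frac1\sigma,$$

computed by `base_k_thresholds()`. Below $k_l$ a single macroscopic
attractor exists (case ii); between $k_l$ and $k_u$ the system is
bistable (case iii); above $k_u$ only the cancer-free state survives
(case i). `sweep_branches()` + `detect_bifurcations()` reproduce this
diagram numerically and the two routes are cross-checked in the test
suite.

**Saturation model.** Effector proliferation and exhaustion respond to
tumor load through Michaelis–Menten terms ($b_e, \kappa_e$ and
$d_e, \kappa_d$). Interior equilibria become roots of a cubic
$AT^3+BT^2+CT+D$ (`saturation_cubic_coeffs()`). Bistability (exactly
two positive roots) is decided by the cubic discriminant together with
trigonometric root-location inequalities; three positive roots add a
*microscopic stable state* interpretable as tumor dormancy
(`saturation_multistability()`). The analogue of $m<0$ is
$A = ab(b_e - d_e - d) < 0$: exhaustion plus natural death outweigh
proliferation.

**NK/CTL model.** The effector pool is split into constantly-supplied
natural killer cells $N$ and tumor-primed cytotoxic T cells $E$ (no
constant supply; source term $\omega N T$). Interior equilibria reduce
to roots of a quintic in $T$, for which no closed form exists; the
plausibility analogue of $m<0$ is
$-ab\,(b_e-d_e-d)(b_n-d_n-\mu) - k\sigma\omega < 0$, notably
independent of all four saturation constants.

## Numerical choices

**Cubic/quintic root handling.** Roots are computed with `polyroot`.
For cubics the *discriminant* decides how many roots are real:
`polyroot` alone can attach spurious relative imaginary parts of order
$10^{-7}$ when the leading coefficient is many orders smaller than the
others (near-degenerate cubics arise routinely for extreme parameter
draws), which would miscount real roots. The closed-form
bistability/multistability conditions are evaluated exactly as written;
when the trigonometric branch is indeterminate (non-real roots, or an
arccos argument outside $[-1,1]$ beyond tolerance) the numeric count is
used, and on any determinate disagreement the numeric verdict wins with
a warning.

**Quintic reduction.** Rather than multi-start root searching in three
dimensions, the NK/CTL fixed points are found by eliminating $N$ and
$E$ through their nullclines and assembling the quintic's coefficients
by polynomial convolution. Nullcline poles (where the effective NK or
CTL loss rate crosses zero) are filtered by a residual check on the
recovered three-dimensional state; every reported equilibrium satisfies
$\lVert f(x^*)\rVert < 10^{-6}\,\max(1, \lVert x^*\rVert)$.

**Stability.** `stability_of()` linearizes by central finite
differences with per-component steps and classifies by eigenvalue real
parts with a dead band of $10^{-10}\,\mathrm{day}^{-1}$: `stable`,
`unstable`, or `marginal`. For the base model a closed-form Jacobian is
kept alongside as an oracle. Stability labels for the bistable presets
are additionally confirmed in the tests by long forward integration
from states bracketing the barrier. Equilibria closer than $10^{-4}$
relative are deduplicated; roots within rounding of zero are identified
with the cancer-free state.

**ODE integration.** No ODE-solver package is assumed at run time, so
the package carries a Dormand–Prince 5(4) adaptive integrator
(`ode_integrate()`). The systems are mildly stiff near carrying
capacity (effector turnover $\sim |m|T \approx 10^3\,\mathrm{day}^{-1}$
against tumor relaxation $\sim a$); the step controller simply takes
small steps there, which is acceptable at desk scale.

## The stochastic simulator

Eradication is a small-number event, so treatment is simulated with
integer counts. The base model's net logistic growth is decomposed into
the simplest nonnegative birth-death split — birth at rate $aT$ and
crowding death at rate $abT^2$ — plus killing $k(t)TE$, supply
$\sigma$, effector death $dE$, and signed modulation $|m|TE$
(decrementing $E$ for $m<0$). The propensity-weighted drift equals the
deterministic right-hand side identically, which the tests assert
state-by-state.

Leaping follows the species-based bound of Cao, Gillespie & Petzold
(2006): each leap limits the expected relative change of every species
to `eps` (default **0.03**, an explicit package convention — the
original experiments deferred this choice to a library default). Leaps
that would drive a count negative are rejected and retried at half the
step; when the candidate leap is smaller than ten expected reaction
times the engine switches to exact SSA steps. All randomness comes from
R's RNG, so a run is bit-reproducible from its seed. "Cleared" always
means the integer count $T = 0$, which is absorbing by construction —
no threshold is involved.

One property of tau-leaping matters for validation: the *mean* of
leaped trajectories follows an Euler-type path with relative step
`eps`, so it carries an $O(\mathrm{eps})$ systematic bias that is
largest at the knee of the growth curve (about 1.5% of carrying
capacity at `eps = 0.03`) and that does **not** shrink with system
size, while the replicate-mean fluctuation band does. The
stochastic-vs-ODE consistency check therefore runs at `eps = 0.005`,
where the bias sits well inside the $3\,\mathrm{sd}/\sqrt{n}$ band;
the default `eps = 0.03` trades that bias for speed in the treatment
experiments, where outcomes are bimodal (cleared vs persisting) and a
percent-level transient bias is immaterial.

## Treatment model

Two modalities, combinable with independent timing
(`treatment_schedule()`):

* **Killing-efficacy ramp** (antibody/checkpoint blockade): starting at
  $\tau_k$, $k$ increases by $\Delta k/\Delta\tau_k$ at the end of each
  of $\Delta\tau_k$ treatment days and stays at $k+\Delta k$ forever
  (the alteration is permanent). The end-of-day convention is the one
  consistent with "increased by $\Delta k/\Delta\tau_k$ every day,
  reaching $k+\Delta k$ at course end": after 10.5 days of a 21-day
  course, 10 increments have been applied.
* **Adoptive transfer**: integer boluses of
  $\mathrm{round}(\Delta E/\Delta\tau_E)$ cells at days
  $\tau_E, \tau_E+1, \dots$, the last adjusted so the total is exactly
  $\Delta E$ (exact for integer doses; non-integer totals are first
  rounded to whole cells). Transferred cells are ordinary effectors:
  against a macroscopic tumor they are suppressed at rate $|m|T \approx
  10^3\,\mathrm{day}^{-1}$ and survive only hours — which is precisely
  why timing against the efficacy ramp matters.

**Dose-grid timing.** For the single-day combination grid
(`combination_grid()`), the default template administers the antibody
dose during day 50 (efficacy raised from day 51 under the end-of-day
rule) and the transfer bolus on day 51, as the ramp completes. This
sequencing is a deliberate design choice: with both doses nominally "at
day 50", the bolus would be exhausted hours before the efficacy
increase exists, and the grid would show no combination benefit at all.
Administering the bolus under the already-raised efficacy produces the
synergy the model family predicts — the minimal clearing transfer dose
drops by roughly one grid decade per decade of antibody dose, a
monotone trade-off frontier. Both timings remain expressible through
`tau_k`/`tau_E`.

## Default parameterizations

The base-model defaults (`param_preset("table1")`) are the standard
literature-derived set: $a = 0.514\,\mathrm{day}^{-1}$,
$b = 1.02\times10^{-9}\,\mathrm{cells}^{-1}$ (carrying capacity
$\approx 9.8\times10^8$ cells), $k = 10^{-4}$, $\sigma = 10$,
$d = 10^{-2}$, $m = -10^{-6}$. The bifurcation-diagram preset
(`"fig2"`) differs only in $d = 2\times10^{-2}$; the two are shipped as
distinct presets because both values appear in the source material and
silently reconciling them would change $k_l$ by a factor of two. Note
that $m$ multiplies $ET$ and therefore carries units
$\mathrm{cells}^{-1}\mathrm{day}^{-1}$ even though it is sometimes
quoted as a plain rate.

The saturation and NK/CTL defaults are **synthetic**: no canonical
printed set exists for these variants. They were chosen once, on
biological grounds, to sit in the regime the analysis identifies as
interesting, and then frozen: exhaustion dominating proliferation
($b_e = 0.1 < d + d_e = 2.01\,\mathrm{day}^{-1}$), half-saturations at
$10^4$–$10^5$ cells (well below carrying capacity), and — for the
NK/CTL model — baseline NK surveillance strong enough to clear
microscopic tumors ($c\sigma/\mu > a$) while established tumors exhaust
both effector types. Under these defaults the NK/CTL model shows the
same barrier structure as the base model (tumor-free state stable,
barrier at $T \approx 94$, macroscopic attractor at
$T \approx 9.5\times10^8$). Users with measured parameters should
override them.

## What the tests establish, and what they do not

The synthetic experiments emulate a *systemic, well-mixed* cancer with
demographic stochasticity only. A green suite establishes internal
consistency — analytic roots against independent numeric oracles over
thousands of random parameter draws, stochastic drift against the ODE,
threshold formulas against grid-detected bifurcations, dose bookkeeping
exact, growth and clearance endpoints inside their stated bands — not
biological truth. Spatial structure, cytokine dynamics,
immunoediting/mutational escape, fractional-kill laws and environmental
fluctuations are all outside the model family, and the transfer
experiments assume transferred cells behave identically to endogenous
effectors. The growth endpoint (95% of carrying capacity in roughly 41
days from $T_0 = 100$ under the standard preset) sits at the lower edge
of the "around 45 days" reference because reaching *visual* carrying
capacity takes a few additional days beyond the 95% crossing.

## Known limitations

* The closed-form trig conditions presume three real cubic roots;
  their indeterminate branch falls back to numeric counting (observed
  on none of $10^3$ random draws, but the path exists and is tested).
* The explicit integrator is not suited to genuinely stiff
  parameterizations ($|m|T \gg 10^3$); swap in an implicit solver if
  you push the rates.
* The stochastic engine handles propensities up to $10^{25}$; more
  extreme dose combinations abort cleanly rather than losing precision.
* `mean_trajectory()` at the default `eps` carries the knee bias
  discussed above; use a smaller `eps` when comparing means against
  deterministic solutions.
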