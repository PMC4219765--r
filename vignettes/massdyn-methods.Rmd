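---
title: "Methods: two-compartment energy-balance dynamics with social noise"
author: "massdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-compartment energy-balance dynamics with social noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(massdyn)
```

## The model

An individual's body mass $m = F + L$ is partitioned into fat mass $F$ and
lean mass $L$ (kg), with fixed energy densities $\rho_F = 9400$ and
$\rho_L = 1800$ kcal/kg (the standard Chow--Hall values; both configurable
through `energy_densities()`). The daily energy imbalance between caloric
intake $I$ and total expenditure $E$ is stored in the two compartments,

$$\rho_L \frac{dL}{dt} = p\,(I - E), \qquad
  \rho_F \frac{dF}{dt} = (1 - p)\,(I - E),$$

which is energy conservation by construction:
$\rho_F\,\Delta F + \rho_L\,\Delta L = (I - E)\,\Delta t$ holds exactly at
every step, and `audit_conservation()` verifies it on any simulated
trajectory.

### The partition fraction: two rules

**Forbes.** $p = C/(C+F)$ with the Forbes constant
$C = 10.4\,\rho_L/\rho_F \approx 1.99$ kg, the energy-partition form of the
empirical lean--fat companionship curve $L = 10.4\ln F + \text{const}$
(originally fitted to adult women; used here for both sexes as an
approximation). As fat depletes, $p \to 1$ and the remaining imbalance is
drawn from lean tissue, so $F \ge 0$ is structurally protected. As a belt
and braces, a step that would still empty a compartment (possible only
under extreme synthetic inputs, e.g. a pinned-zero intake) clamps it at
zero, flags the record, and stops the run.

**Hall (first-difference).** The alternative rule defines $p$ through
realized mass changes, $p(t) = \Delta L / \Delta M$ over the previous day,
with the first step (and any step after a numerically degenerate
$|\Delta M| < 10^{-9}$ kg) seeded by a Forbes-consistent step. The ratio is
deliberately *not* clamped to $[0,1]$.

A subtlety decided here: a ratio of mass changes is a *mass share*, not an
energy share, and the two readings produce qualitatively different
dynamics. If the realized ratio is fed back as the energy fraction $p$ in
the equations above, the one-step update becomes the autonomous map
$p' = p\rho_F / (p\rho_F + (1-p)\rho_L)$, whose fixed point $p = 1$ attracts
the whole interval $(0,1)$: within about ten days all imbalance is routed to
lean tissue, fat freezes, and the two rules become indistinguishable in
every respect that matters — the comparison would be empty. We therefore
apply the ratio self-consistently as
the lean share of the day's mass change,

$$\Delta M = \frac{(I-E)\,\Delta t}{p\,\rho_L + (1-p)\,\rho_F}, \qquad
  \Delta L = p\,\Delta M, \qquad \Delta F = (1-p)\,\Delta M,$$

which still conserves energy exactly (the denominator is the effective
energy density of the tissue mix). Under this reading the ratio reproduces
itself day after day, so the rule freezes the *initial* companionship ratio
($\approx 0.445$ for a man with 13 kg of fat) and extrapolates it linearly:
during sustained weight loss fat keeps absorbing its initial share of the
mass change even as the compartment empties, and crosses zero — the
first-difference rule ignores the curvature of the Forbes curve. The
simulator records this as a `negative_fat` flag and keeps running; hiding or
clamping it would defeat the purpose of the comparison, which is precisely
that the Forbes rule is the better-behaved description. The mass-share
update is singular at $p = \rho_F/(\rho_F-\rho_L) \approx 1.24$, where the
effective density changes sign; the step refuses such values with an error
rather than integrating through the singularity.

### Dynamic intake

The intake law is a modelling commitment of this package:

$$I(t) = I(t_0)\,\bigl(m(t)/m(t_0)\bigr)^{\gamma},$$

the simplest law satisfying all the qualitative constraints the parameter
$\gamma$ is meant to encode: $I(m_0) = I_0$ (fixed point at the initial
state), intake rises with mass, $\gamma = 0$ decouples intake from mass, and
larger $\gamma$ makes intake chase the shrinking gap so equilibration slows
down. Individuals draw $\gamma$ uniformly from $(0.1, 0.5)$ (grid sweeps use
steps of 0.05; 0.3, the interval mean, is the conventional single value for
the social experiments). The law is isolated in `intake_update()` so an
alternative (e.g. linear in relative mass) can be swapped in.

One consequence worth stating plainly: the equilibrium mass $m^*$ solves
$(1-\beta) I_0 (m/m_0)^\gamma = B(m) + \delta m$, which **does** depend on
$\gamma$ — for the 99.5 kg example man, $m^*$ moves from 98.46 kg at
$\gamma = 0.1$ to 96.57 kg at $\gamma = 0.5$. $\gamma$ mainly shapes the
path, but it also tilts the balance point slightly; the property tests
therefore compare each run against its own analytic root
(`equilibrium_mass()`, an independent `uniroot` computation) rather than
assuming a shared limit. For $\gamma \gtrsim 0.4$ the balance function
acquires a second, low-mass root; `equilibrium_mass()` walks from $m_0$
toward the sign change so it always reports the root the dynamics actually
approach.

### Expenditure decomposition and calibration

$$E(t) = B(\text{sex}, \text{age}, m) + \beta I(t) + \delta\, m(t).$$

* $B$: FAO/WHO/UNU (Schofield) weight-based adult equations, brackets 18–30
  and 30–60 by sex (`fao_bmr_table()`, replaceable via config). Ages outside
  the table raise an error listing the supported brackets; ages are treated
  as fixed over a run (a few simulated years at most).
* $\beta = 0.10$: diet-induced thermogenesis as a fraction of intake — the
  usual convention; configurable in $[0, 0.3)$.
* $\delta$: activity cost per kg per day, obtained once from the initial
  conditions, $\delta = (E_0 - B_0 - \beta I_0)/m_0$, so that the model
  reproduces $E_0$ exactly at $t_0$ and only known quantities are used.
  Initial conditions implying $\delta < 0$ are rejected as inconsistent. A
  constant-activity alternative ($A = E_0 - B_0 - \beta I_0$) is selectable.

### Social interactions as energy noise

Each day a signed perturbation $\pm\,\alpha_s\,\varepsilon$ (social
proximity $\times$ social influence, kcal/day) is added to the personal
balance $I - E$ as a single net term — the approximation in which the
socially induced intake and expenditure differences collapse into one
energetic difference. Three cases: (i) $\alpha_s$ fixed at 0.5 with
$\varepsilon$ swept over 20–150 kcal/day; (ii) $\varepsilon$ fixed at
$\pm 50$ kcal/day with $\alpha_s$ swept over $[0,1]$; (iii) both random,
$\alpha_s \sim U(0,1)$, $\varepsilon \sim U(0,300)$, sign equiprobable. The
300 kcal/day cap corresponds to 10–20 % of a typical daily intake. Redraw
cadence is a genuine design choice: proximity,
influence and sign are all redrawn independently *each day* in case iii,
which makes the noise white; a per-individual fixed draw would instead shift
the equilibrium run by run. Splitting the term between intake and
expenditure (rather than applying the net term to the balance) would change
thermogenesis by $\beta$ times the intake part — a sub-kcal effect at the
default cap, which is why the net-term approximation is the default.

## Synthetic populations

`generate_population()` emulates survey-style adult energy distributions so
every scenario runs without external data: expenditure is built as
BMR $\times$ PAL with PAL $\sim U(1.4, 2.0)$ (sedentary-to-active adults),
and intake as expenditure plus a symmetric $U(-300, 300)$ kcal/day gap —
matching the observed spread of individual energy gaps. Anthropometrics are
height $\sim N(1.76, 0.07)$ m for men and $N(1.62, 0.07)$ m for women, BMI
$\sim$ truncated $N(26, 5)$ on $[16, 45]$, mass $= \text{BMI}\cdot h^2$, and
fat fraction truncated normal by sex ($0.25 \pm 0.08$ men,
$0.33 \pm 0.08$ women, bounded to $[0.05, 0.55]$). These are deliberately
generic placeholder distributions — plausible for a broad adult population,
tied to no country — and every one of them is overridable through
`pop_config()`. With PAL $\ge 1.4$ the activity calibration is feasible by
construction (the implied $\delta$ is always $\ge 0$), and the generator's
outputs satisfy every profile invariant (mass closure to $10^{-9}$, bounded
energy gap, $\gamma$ in range) for all draws, which the tests check on
$10^4$ profiles.

What passing tests on these populations do **not** show: real populations
have correlated age–mass–activity structure, measurement error, and
non-uniform $\gamma$; the generator has none of these, so results on it
validate the machinery, not demographic realism.

## Numerics

* **Integration**: explicit Euler with $\Delta t = 1$ day, matching the
  model's native daily cadence. No adaptive stepping. The discretization is
  benign at physiological rates — a 10× finer step changes a one-year
  endpoint by $\sim 4\times10^{-6}$ relative — because the per-day
  contraction factor of the balance is $\ll 1$.
* **Horizons** (package defaults, chosen to reach the regime each experiment
  needs): 1500 days for noise experiments, 2500 for the Forbes/Hall
  comparisons, 3000 for the convergence runs, 6000 for the $\gamma$ sweep
  (the $\gamma = 0.5$ run needs $\approx 3700$ days to stabilize).
* **Stability criteria**: $|I - E| < 0.5$ kcal/day (`stable_day()`) or mass
  within 0.1 kg of its target (`time_to_stability()`).
* **Tolerances**: Hall degeneracy fallback at $|\Delta M| < 10^{-9}$ kg;
  conservation audited at $10^{-8}$ relative; equilibrium roots to
  $10^{-10}$ kg.
* **Reproducibility**: every stochastic entry point takes a seed and
  restores the caller's RNG state; scenario run $k$ uses sub-seed
  $\text{seed} + k$, so matched noise-on/off pairs and repeated suite runs
  are byte-identical.
* **$\gamma$ recovery** (`estimate_gamma()`): grid least squares over the
  daily mass series against re-simulated candidates. On clean trajectories
  the SSE is sharply convex in $\gamma$ and recovery is exact at the grid
  resolution.

## Known limitations

* Two compartments only: no glycogen/water dynamics, so short-term mass
  fluctuations are purely energetic.
* The Forbes relation is applied to both sexes; the Hall first-difference
  rule is included as a comparison object, not as a recommended model — its
  negative-fat behaviour is the point of the comparison.
* The fat-mass record of a Hall run is physically meaningless once negative;
  total mass remains well-behaved because the balance law does not read the
  composition.
* Social noise is independent across days and individuals; no network
  structure, partner choice, or persistent social environment.
* Adult BMR brackets only (18–60); ages are frozen during a run.
* One preset stores an initial expenditure corrected from an implausible
  printed value (29991.30 → 2999.13 kcal/day); the original is preserved in
  the profile metadata.
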