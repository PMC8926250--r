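---
title: "From molecular exchange to community steady states: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From molecular exchange to community steady states: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paircomm)
```

`paircomm` models spatially structured communities of two cell types that
affect each other's growth across a finite interaction range — the motivating
case being mutualistic cross-feeding between two auxotrophic bacteria, each
leaking an amino acid the other cannot synthesize. The package connects three
levels of description:

1. **Biophysics.** Diffusion, uptake and leakage rates of each exchanged
   molecule, plus cell geometry and density, determine two *local interaction
   rules* per type: the neighborhood size $r$ (how many cells it exchanges
   metabolites with) and the maximum growth rate $\hat\mu$ (its growth when
   completely surrounded by partners).
2. **Community.** A pair approximation on a directed regular graph turns the
   four numbers $(r_A, r_B, \hat\mu_A, \hat\mu_B)$ into closed-form
   steady-state predictions: global composition, local spatial structure,
   community productivity, and the conditions under which the community
   collapses.
3. **Simulation.** A stochastic cellular automaton on a periodic lattice
   implements the same birth–replacement process without the moment-closure
   assumptions, serving as the validation oracle and covering regimes where
   the closure degrades.

This vignette records the model assumptions, the numerical choices, and the
design decisions that were genuinely open.

## The biophysical layer

For a molecule with diffusion coefficient $D$, uptake rate $r_u$ and leakage
rate $r_l$, exchanged in a community occupying volume fraction $\rho$, the
interaction range is

$$R = \frac{\beta}{2(1-\rho)}\sqrt{\frac{2D}{\rho(2+\rho)(r_u+r_l)}}
\;\ln\!\left[\frac{r_l}{\gamma}\Big(1+\sqrt{1+\tfrac{4\gamma}{r_l}}\Big)+4\right],$$

and the maximum cross-feeding growth rate is
$\hat\mu = \mu_{wt}\,\frac{r_l}{\gamma}\big(\sqrt{1+2\gamma/r_l}-1\big)$,
bounded by the wild-type rate $\mu_{wt}$. Here $\beta$ is a dimensionless
calibration constant and $\gamma = 2\mu_{wt}K/I_C$ is a composite rate
(Monod constant $K$, internal concentration $I_C$). Two transcription
cross-checks are enforced by the test suite: as $r_l \to 0$ the logarithm
tends to $\ln 4$, and as $r_l/\gamma \to \infty$ the growth rate saturates
at $\mu_{wt}$. The uptake rate dominates the range; the leakage rate
dominates the growth rate — the two local rules are tuned by different
molecular knobs.

When uptake and leakage differ between the producing and the non-producing
type, the same formulas hold with $r_l/\gamma$ replaced by the constants
$\theta$ (growth) and $\delta$ (range) built from the per-type rates; both
reduce exactly to $r_l/\gamma$ at equal rates, which the suite asserts to
machine precision over random parameter draws.

Neighborhood sizes follow from geometry: in 2D, the number of cells in the
stadium-shaped shell of width $R$ around a rod of length $l$ and width $w$,
$r = [2R(l-w) + \pi(R+w/2)^2 - \pi(w/2)^2]\,\rho_{2D}$; in 3D, the volume of
the shell around a spherocylinder times $\rho_{3D}$. The 3D form is the
natural analog of the 2D one and is checked against Monte-Carlo rejection
sampling (1% and 2% tolerances at $10^6$ samples) rather than against an
external reference. Because $r \propto R^2$ in monolayers but
$r \propto R^3$ in three-dimensional structures, dimensionality changes the
neighbor count — and hence the community predictions — even when $R$ itself
barely changes.

**Design choices.** $\beta$ has no hidden default; it must be supplied.
$\gamma$ is stored in composite form (the generalized parameter set stores
the decomposition). Neighborhood sizes are kept continuous: the closed-form
equilibria below are smooth in $r$, so rounding happens only at the lattice
boundary, where an extended Moore range must be an integer. Units are
declared once in the configuration (`units:` block) and never converted.

## The community layer: pair approximation on a directed graph

Both types fully occupy a regular graph; type A interacts with its $r_A$
in-neighbors, type B with $r_B \ge r_A$ (the labeling convention; builders
swap labels and record the swap). Because the two neighborhood sizes differ,
links are *directed*: $X \leftarrow Y$ means focal cell $X$ receives building
blocks from $Y$. The growth rate of a cell rises linearly with the partner
frequency in its own neighborhood, reaching $\hat\mu$ at full partner
surround. Reproduction is proportional to growth rate; the offspring
replaces a uniformly chosen neighbor within the *replication neighborhood*,
taken equal to the smaller interaction neighborhood ($r_R = r_A$).

The dynamical state is the vector of directed link counts
$N_{X\leftarrow Y}$; with a constant population, three variables remain:
the global frequency $P(A)$ and the local partner frequencies
$P(B|A,r_A)$ and $P(A|B,r_B)$. Two events change them: an A replaces a B
(rate $T^+$) or a B replaces an A (rate $T^-$), with

$$T^+ = P(A)\,P(B|A)\,\frac{1+P(B|A)(r_A-1)}{r_A}\,\hat\mu_A, \qquad
T^- = P(B)\,P(A|B)\,\frac{1+P(A|B)(r_B-1)}{r_B}\,\hat\mu_B\,\kappa,$$

where $\kappa$ corrects for the replaced A having to lie inside the
*smaller* replication window of the reproducing B.

**The closure (an open design point).** The event bookkeeping needs the
neighborhood composition around one site evaluated at *both* window sizes,
but only the own-window conditionals are state variables. We translate
across windows with a single community-wide clustering intensity $s$:
writing the partner deficit of a focal with $r$ neighbors as $s/(r-1)$ —
the $1/(r-1)$ shape arises because exactly one neighbor slot is held by the
focal's parent or offspring — we estimate $s$ from both conditionals and
average with composition weights, $\bar s = P(A)s_B + P(B)s_A$. Two
properties recommend this closure, and both are enforced by tests:

* the interior fixed point of the resulting link dynamics is **unique**, with
  $s_A = s_B = 1$, landing exactly on the closed forms below (the suite
  requires agreement within $10^{-6}$ across a parameter grid);
* at that fixed point $\kappa$ reduces to the ratio of enrichment factors
  $\frac{(r_A-2)/(r_A-1)}{(r_B-2)/(r_B-1)}$.

A simpler $\kappa = 1$ closure fails the first property and was rejected.
The per-event link-change vectors are derived by first-principles
bookkeeping (guaranteed parent, re-typed in/out links) and conserve
out-degree regularity exactly — each A-replaces-B event adds $r_A$ incoming
links and removes $r_B$; the cellular automaton's event-type frequencies
independently validate the rates.

**Closed forms.** Solving the dynamics at steady state:

$$P(A) = \frac{\hat\mu_A\frac{r_A-2}{r_A} +
\big(\frac{\hat\mu_A}{r_A}-\frac{\hat\mu_B}{r_B}\big)}
{\hat\mu_A\frac{r_A-2}{r_A} + \hat\mu_B\frac{r_B-2}{r_B}},
\qquad
P(A)_{WM} = \frac{\hat\mu_A}{\hat\mu_A+\hat\mu_B},$$

$$\frac{P(B|A,r_A)}{P(B)} = \frac{r_A-2}{r_A-1}, \qquad
\frac{P(A|B,r_B)}{P(A)} = \frac{r_B-2}{r_B-1}.$$

Values of the first expression outside $(0,1)$ are reported as fixation
(`collapsed` flag) with zero productivity: the constant-population model
persists as a monoculture without turnover. Solving for the boundary gives
the coexistence interval of the ratio $\hat\mu_A/\hat\mu_B$:
$\big(\tfrac{r_A}{r_B(r_A-1)},\ \tfrac{r_A(r_B-1)}{r_B}\big)$ — at
$r_A=r_B=3$, $(1/2,\,2)$: spatial structure can destroy a cross-feeding
community that would coexist well-mixed at any ratio.

Community productivity is the mean birth rate
$P(A)\hat\mu_A P(B|A) + P(B)\hat\mu_B P(A|B)$, evaluated at the spatial
equilibrium with the steady-state local frequencies and compared with the
same expression at the well-mixed equilibrium with global frequencies. For
cross-feeding the ratio never exceeds 1.

```{r closed-forms}
rules <- local_rules(10, 130, 0.22, 0.78)
steady_state_frequency(rules)
productivity(rules)
```

**Generalized growth models.** When growth scales with the partner *count*
(`density_linear`, e.g. sensed but not consumed growth factors), the
balance criterion becomes the product $\hat\mu r$; when the types inhibit
each other (`inhibition_linear`), clustering shelters cells and the spatial
community grows at least as fast as its well-mixed counterpart. Arbitrary
growth functions are handled by root finding on $P(A)$ using exact binomial
expectations over the neighborhood composition; the steady-state
local-to-global relation above holds for every growth model and is reused
there. Root brackets scan $(10^{-9}, 1-10^{-9})$; among multiple sign
changes the bracket containing 0.5 is preferred (the solution reachable
from a balanced start).

**Numerical choices.** Integration uses `deSolve` (lsoda) with relative
tolerance $10^{-8}$ and absolute $10^{-10}$ for trajectories; equilibrium
location integrates in doubling chunks at $10^{-10}/10^{-12}$ until
$\max|dN/dt| < 10^{-9}$ per unit time. $r$ is continuous in all closed
forms; conditionals at absent focal types are defined as 0.

## The simulation layer

The cellular automaton places the two types on a fully occupied periodic
lattice (default $100\times100$). A cell of type $X$ interacts within an
extended Moore neighborhood of range $d_X$ — $(2d_X+1)^2-1$ neighbors — and
grows according to the configured growth model. One *event* selects a
reproducing cell with probability proportional to its growth rate and
overwrites a uniformly chosen neighbor within the replication range $d_R$
(default: the smaller interaction range).

Three points were genuinely open and are resolved as follows:

* **Time step semantics.** One step is one replacement event (sequential
  update), so "100,000 steps" means 100,000 events; composition changes by
  at most one cell per event.
* **Same-type replacement.** The target may be of the reproducer's own
  type: the event consumes a step but leaves the composition unchanged.
  Excluding such targets would bias event rates relative to the pair
  approximation's bookkeeping.
* **Replication-range robustness.** Varying $d_R$ between the two
  interaction ranges shifts the equilibrium composition by only a few
  percentage points; the suite asserts this boundedness rather than any
  specific value.

The engine (C++, incremental partner-count updates, two-level weighted
sampling by row) simulates $10^5$ events on a $100\times100$ lattice in a
fraction of a second, and uses R's RNG so that a configuration plus a seed
reproduces a trajectory bit for bit. Absorbing states (zero total growth)
terminate a run early with a flag.

```{r ca, eval = FALSE}
cfg <- ca_config(d_A = 1, d_B = 5, mu_hat_A = 0.22, mu_hat_B = 0.78,
                 d_R = 1, seed = 100, n_events = 100000)
ca_ensemble(cfg, n_replicates = 20)$summary
```

## Observables and the randomization experiment

`snapshot_stats()` reports, for any lattice snapshot, the global
composition, the mean partner frequency within each type's own interaction
range (undefined — `NA` — when a type is absent, never silently 0), and the
community mean growth rate. `clustered_vs_randomized()` re-hosts the
in-silico productivity experiment on lattices: the mean growth rate of a
snapshot is divided by its average over 20 label permutations that preserve
composition exactly. On equilibrated cross-feeding lattices the ratio falls
below 1 (clustering starves cells of partners); on freshly randomized
lattices it is statistically 1; the lattice growth model plays the role of
the growth predictor, so the ratio isolates the effect of spatial
arrangement alone. Pixel-weighted frequency estimation is out of scope:
lattice cells are uniform, so cell-count and area-based estimates coincide
here.

## What the synthetic conditions do and do not show

The study conditions generated by the package — independently seeded random
lattices, linear growth responses, constant population, sequential
replacement — match the model's own assumptions, so agreement between the
closed forms and the simulations validates the moment closure, not the
model's fidelity to any particular experimental system. Real monolayer
communities differ in known ways: cells are rods that push rather than
replace neighbors, growth responses saturate, and boundaries exchange cells
with the environment. Against the one experimental community the framework
was built around, the same parameterization used throughout
($r_A = 10$, $r_B = 130$, ratio $0.22/0.78$; lattice ranges $d = 1$ and
$d = 5$) the model reproduces composition well but is known to
underestimate spatial effects (local-frequency deficit, productivity loss)
by about a factor of 2 — the package reproduces the model-side predictions,
and nothing here should be read as a data analysis.

Problem sizes used by the test-suite and acceptance computations —
$100\times100$ lattices, $10^5$ events, 6–20 replicates, $10^6$ Monte-Carlo
samples — were chosen so that closed-form checks are exact, stochastic
checks have confidence intervals a few times tighter than their tolerances,
and the whole suite runs in well under a minute of simulation time.

## Known limitations

* Two types only; no mutation, no empty sites, no varying population size.
* The pair approximation degrades for strongly asymmetric communities
  (growth ratios far from 1) and small neighborhoods; the lattice simulator
  is the fallback there.
* The closure's cross-window translation is exact at steady state but
  approximate in transients; temporal dynamics are qualitative (time is
  measured in events or units of $1/\hat\mu$, not calibrated to wall-clock
  hours).
* The biophysical layer returns closed-form endpoints; it does not solve
  the underlying reaction–diffusion problem, fit parameters from data, or
  ship molecule-specific parameter tables.
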