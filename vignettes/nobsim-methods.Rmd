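---
title: "Trait-based modeling of soil nitrite oxidizers: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait-based modeling of soil nitrite oxidizers: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nobsim)
```

## The problem

Soil nitrite-oxidizing bacteria (NOB) carry out the second step of
nitrification, NO2- to NO3-. Two genera dominate in soil: *Nitrospira*,
K-strategists with high affinity (low half-saturation constants) for nitrite
and oxygen, and *Nitrobacter*, r-strategists that grow fast when nitrite and
oxygen are abundant; some *Nitrobacter* (e.g. relatives of
*N. hamburgensis*) additionally grow mixotrophically on organic carbon (OC).
`nobsim` represents this guild as a small number of functional types defined
by kinetic and growth traits, simulates their competition to steady state
under prescribed nitrite/OC/oxygen supply, and uses the resulting community
composition and nitrite-oxidation flux to interpret and predict NOB
responses to multifactorial global-change treatments (CO2 enrichment,
nitrogen addition, altered precipitation, and their combinations).

## The dynamical model

Each functional type $i$ carries a biomass pool $B_i$ (M biomass-C) and
cellular stores of carbon and nitrogen expressed as quotas $q_{C,i}$,
$q_{N,i}$ (mol per mol biomass-C). Energy acquisition follows dual-Monod
kinetics in the oxidized substrate ($S$ = NO2-, and OC for mixotrophs) and
oxygen:

$$V_i^S = V^S_{\max,i}\,
  \frac{[S]}{K^S_{M,i}+[S]}\,\frac{[O_2]}{K^{O_2}_{M,i}+[O_2]}\,B_i$$

Carbon assimilation is Michaelis–Menten in the available carbon (CO2 for
chemolithotrophs; CO2 + OC for mixotrophs) with an effective maximal rate
proportional to the energy currently yielded by oxidation:
$V^C_i = y_i\,(V^{NO_2}_i + V^{OC}_i)\,[C]/(K^C_M+[C])$, where $y_i$ is the
growth yield (mol biomass-C per mol substrate oxidized). Assimilated C and N
(a fixed fraction $f_N$ of the oxidized nitrite-N) feed the quotas, which
are diluted by growth; growth follows a Droop law,

$$\mu_i = \mu_{\max,i}\,\min_e\left(1 - \frac{q^{\min}_e}{q_{e,i}}\right),
  \qquad e \in \{C, N\},$$

and biomass obeys
$\dot B_i = (\mu_i - \Delta_i - m_q B_{g(i)})\,B_i$, with first-order
mortality $\Delta_i$ and a density-dependent loss discussed below.

Two traits of the mixotrophic *Nitrobacter* type are *flexible*, i.e.
respond to the ambient environment: $\mu_{\max}$ rises piecewise-linearly
with OC from 6.9e-6 s^-1 (no OC) to 27.8e-6 s^-1 at 150 ppm CH2O
(5e-3 M), and $K_M(O_2)$ rises from 25.1 uM at ~3.2 ppm O2 (1e-4 M) to
125 uM at >= 200 ppm (6.25e-3 M), constant beyond the anchors. Linear
interpolation between the two reported endpoints is the simplest monotone
choice. The ppm-molar bridge treats ppm as mg per liter of soil solution
with molar masses 30 (CH2O) and 32 (O2) g mol^-1, which reproduces both
correspondences above exactly.

### Boundary conditions and steady state

`nob_integrate()` offers three resource boundary conditions:

* **clamped** — substrate concentrations pinned at the prescribed values; a
  pure forcing used for analytic limits (e.g. exponential growth at
  $\mu_{\max}$).
* **renewal** (used by `run_to_steady_state()`) — a semi-chemostat: ambient
  pools relax toward the prescribed environment at rate $\rho$ (default
  1e-3 s^-1) while being depleted by consumption, so the prescribed
  concentrations act as constant supply points. At equilibrium a surviving
  type's realized growth balances its losses, and with purely first-order
  mortality the winner of competition for one substrate is the type with the
  lowest break-even concentration $S^\* = \Delta K_M/(\mu_{\max}-\Delta)$ —
  the classical R\* result, which the test suite verifies against the
  simulator on randomized two-type contests.
* **batch** — closed system used for stoichiometric conservation checks
  (oxidized NO2--N = accumulated NO3--N + assimilated N).

A literal reading of "steady state under constant concentrations" with
substrates *clamped* admits no non-trivial equilibrium: per-capita rates are
then density-independent, so biomass either grows without bound or washes
out. The renewal closure is the standard way to make the prescribed
environment a supply condition rather than a forcing, and is what the
package's steady states mean.

### Density-dependent loss and coexistence

With a single depletable resource and linear mortality, equilibrium
competition is winner-takes-all: the lowest-$S^\*$ type (the K-strategist)
would exclude all others everywhere, and no r-strategist niche could exist
at equilibrium. Real soil NOB coexist, and trait-based community models
conventionally close this gap with a quadratic (self-limiting) loss term
representing aggregated predation, viral lysis and microhabitat saturation.
`nobsim` applies the quadratic loss *within crowding guilds* — the two
K-strategist (*Nitrospira*-like) types share one guild, every other strategy
class is its own guild — so that ecologically redundant types partition,
rather than inflate, their guild's biomass. The coefficient
(`density_mortality`, default 0.003 per M biomass-C per s) was chosen once so
that simulated soil-level nitrite oxidation falls in the tens of ng-N g^-1
h^-1, the magnitude observed for actual (not potential) oxidation in
grassland soils. Setting it to 0 recovers the pure first-order mortality of
the growth equation, which is how the R\*-theory checks are run.

## Functional types and trait defaults

The reference community has three types; ablation variants collapse or
extend it (`build_type_set(1:4)`).

| Trait | *Nitrospira* | chemolitho. *Nitrobacter* | mixo. *Nitrobacter* |
|---|---|---|---|
| $K_M(NO_2^-)$, uM | 15 | 500 | 500 |
| $K_M(O_2)$, uM | 10 | 60 | 25.1–125 (flexible) |
| $\mu_{\max}$, s^-1 | 7e-6 | 1.6e-5 | 6.9e-6–2.78e-5 (flexible) |
| yield, mol/mol | 0.10 | 0.02 | 0.02 |
| $\Delta$, s^-1 | 3e-7 | 3e-7 | 3e-7 |

Maximal oxidation rates are not free knobs: each type's $V_{\max}$ is sized
so that `yield * V_max` matches the C demand of growth at its maximum rate
(`mu_max * q_min_c`). This energetic consistency keeps the realized
growth-substrate response Monod-like with effective half-saturations
proportional to the quoted $K_M$ values — preserving the K/r contrast the
types are defined by — and it makes the quota model's break-even ordering
match the analytic Monod R\* ordering away from near-ties. Two deliberate
departures from the plain rule encode ecophysiology: the K-strategist's
oxidation machinery is over-provisioned twofold relative to its growth
demand (its growth response saturates at very low nitrite, the essence of a
K-strategist), and the mixotroph's NO2- capacity is sized for the mid-range
of its OC-flexible growth rate, with the OC-supported increment carried by
its OC-oxidation capacity. The resulting specific nitrite-oxidation
activities are roughly 6–7-fold higher for *Nitrobacter* than for
*Nitrospira*, consistent with the view that rare *Nitrobacter* can dominate
function while *Nitrospira* dominates abundance.

These defaults are calibration anchors, not measurements: they reproduce the
documented qualitative niche structure (see below) and the two printed
flexible-trait anchor pairs, and they can be overridden wholesale through
YAML/JSON trait configurations (`load_trait_config()`; the packaged copy is
`inst/extdata/traits_reference.yaml`).

## From field drivers to soil environments

The soil is represented by two homogeneous compartments: a *hotspot*
(5.5% of soil mass) holding the resource-rich microhabitats, and a *bulk*
compartment prescribed at low nitrite and oxygen (1e-5 M and 5e-4 M) with no
OC, suitable at best for *Nitrospira* — a property that is emergent (all
types are seeded everywhere), not hard-coded. Hotspot concentrations follow
measured drivers:

* NO2- (M) = 2e-16 x ammonification^5.35 (ammonification in ng-N g^-1 h^-1);
* O2 (M) = -0.019 ln(respiration) + 0.0137, clamped into [1e-4, 1e-2] M;
* OC: the reported relation (10 x respiration - 15.5) is dimensionally
  implausible read in M — it exceeds the whole simulated OC domain
  (0–5e-3 M) for any realistic respiration rate, which would erase all
  OC contrasts between treatments. The default mapping therefore keeps the
  relation's linear shape and zero crossing (1.55 mg-C g^-1 h^-1) but
  rescales the slope so the observed respiration range (up to
  ~2.7 mg-C g^-1 h^-1) spans [0, 5e-3] M. The literal form, clamped, is
  available via `oc_mapping = "literal"`.

Dissolved CO2 is fixed at a non-limiting 1e-5 M: no CO2 concentration is
reported, and chemolithotrophic C fixation must not be artificially
limiting.

## Niche reconstruction and scenarios

`niche_sweep()` runs every cell of a NO2- x OC x O2 grid (defaults: NO2-
7.4e-6–3.7e-2 M log-spaced, OC 0–5e-3 M linear, O2 1e-4–1e-2 M log-spaced,
12 points per axis) to steady state independently, and
`classify_dominance()` labels each cell with its biomass argmax (ties broken
by listed order and flagged; all-extinct cells labelled "none"). The
reconstructed niches show *Nitrospira* dominant at low NO2-/low O2,
chemolithotrophic *Nitrobacter* dominant at high NO2-/high O2 without OC,
and a mixotroph share that rises monotonically with OC at high NO2- while
staying below half the community at the lowest NO2- level — there its
N supply (a fraction $f_N$ of oxidized nitrite-N, default 2%) starves it
regardless of OC energy.

`run_scenarios()` maps one driver row per treatment through the
two-compartment environment, runs both compartments to steady state,
aggregates per-type biomass weighted by compartment mass fraction, and
converts total NO2- oxidation to ng-N g^-1 dry soil h^-1 using the
incubation moisture (0.21 L per kg dry soil). Relative abundances are
biomass-based. `complexity_ablation()` repeats this under 1-, 2-, 3- and
4-type configurations: the 1-type "average NOB" collapses at low resources
(oxidation well under 20 ng-N g^-1 h^-1 where the 3-type community sustains
~20), and the 4-type run (adding a near-neutral mixotrophic *Nitrospira*
that shares the K-strategist crowding guild) reproduces the 3-type
predictions to well within 5 percentage points of relative abundance. One
reported contrast is not reproduced: under the guild closure the 2-type
(genus-level) configuration predicts slightly *lower*, not higher, nitrite
oxidation than the reference under the CO2NW-like treatment, because
averaging the two *Nitrobacter* types merges their guilds; the ablation's
composition-distance ordering (2-type far from, 4-type close to, the
reference) is unaffected.

## Synthetic field datasets

`generate_drivers()` emulates the field study's split-plot 2x2x2 factorial
(CO2 at plot level, N and precipitation at quadrant level, 6 blocks, 48
units) with a multiplicative effect model on two baseline drivers
(ammonification 100 ng-N g^-1 h^-1, respiration 1.8 mg-C g^-1 h^-1;
N x1.8 on ammonification, W x1.15 on respiration and x0.9 on
ammonification, CO2 x1.3 on respiration) and unit-mean lognormal noise.
These multipliers are illustrative — per-treatment driver values were never
published — and were fixed once to reproduce the observed effect
*directions* (N raises *Nitrobacter*, precipitation lowers it, CO2 raises
nitrite oxidation). `generate_observations()` forward-simulates the
pipeline's true outputs per unit, then corrupts them the way the assays
would: lognormal noise on potential-nitrite-oxidation (PNO) measurements and
qPCR-like abundances, and 30-clone multinomial libraries over the
*Nitrobacter* types. Truth is retained, so `recovery_report()` can quantify
bias, RMSE and percent-effect recovery; noise-free datasets recover truth
exactly, and at 20% observation noise the observed-on-predicted PNO
regression slope is statistically indistinguishable from 1 across 100 noise
realizations.

What the generator does *not* emulate: within-treatment driver correlation
across years, spatial autocorrelation between quadrants, PCR/primer bias in
clone libraries, and qPCR efficiency drift. Passing recovery tests therefore
demonstrates the pipeline's internal consistency, not robustness to those
real-data artifacts.

## Numerical choices

* Solver: `deSolve::lsoda`, absolute tolerance 1e-14 M, relative 1e-8;
  step budget 1e5 per stage, with partial progress accepted and resumed if
  the budget is exhausted (persistent exhaustion returns
  `converged = FALSE`, never a silent answer).
* Steady state: staged integration with geometrically growing horizons
  (from 4e6 s, x4 per stage) until the per-capita biomass rate of change of
  every surviving type falls below 1e-10 s^-1, capped at 10 simulated
  years.
* Extinction threshold 1e-12 M biomass-C; equal initial seeding at 1e-6 M
  per type; quotas start at twice their minima.
* Degenerate inputs: zero substrate, oxygen or biomass give zero rates; a
  zero community is absorbing; quota excursions below the minima are
  clamped; negative-state excursions are clipped to zero with a warning.
* Problem sizes in the test suite are chosen for a single CPU: niche
  dominance checks run on a 6x5x4 grid (the full 12^3 default remains the
  user-facing sweep), oracle comparisons use 2e5-s horizons, and the
  recovery experiment reuses one deterministic truth across 100 noise
  realizations.

## Known limitations

* The two-compartment soil is homogeneous by construction; no diffusion,
  spatial gradients, or transient (seasonal) dynamics — every prediction is
  an equilibrium property.
* The nitrogen source for biomass is tied to nitrite oxidation ($f_N$);
  there is no NH4+ pool, no ammonia-oxidizer coupling, and no NO3-
  feedback.
* Mortality losses leave the system (no recycling to OC or N pools).
* The quadratic-loss closure is phenomenological; its coefficient shifts
  absolute biomass and flux scales (relative structure is insensitive).
* Trait values are literature-anchored calibration defaults, not fitted
  estimates; conclusions about absolute rates should be read as order of
  magnitude.
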