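---
title: "Methods: community dynamic FBA, cross-feeding statistics, and the synthetic ground truth"
author: "fluxarena"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community dynamic FBA and cross-feeding statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxarena)
```

# The model

## Flux balance analysis

Each species is a stoichiometric network with boxed fluxes. A steady
state is a flux vector $v$ (mmol·gDW$^{-1}$·h$^{-1}$) with $S v = 0$ and
$lb \le v \le ub$; `solveFBA()` maximises the biomass flux, whose value
is the specific growth rate $\mu$ (h$^{-1}$). The central modelling
assumptions inherited from FBA are (i) optimality — cells maximise
biomass production, although real organisms can run sub-optimally — and
(ii) the absence of kinetics: bounds, not enzyme saturation, limit
fluxes.

Exchange reactions are boundary passages with exactly one (external)
metabolite at coefficient $-1$; **positive exchange flux is secretion,
negative is uptake**. This sign convention is enforced by the model
validity check and is what gives the cross-feeding statistic its sign
semantics.

## Solver numerics

No LP backend is assumed: the package compiles its own dense two-phase
primal simplex (`src/simplex.cpp`). Numerical choices:

* variables are shifted to $y = v - lb \ge 0$ and upper bounds become
  explicit slack rows, so the tableau is in standard form;
* feasibility/optimality tolerance $10^{-9}$;
* Bland's smallest-index rule for entering and leaving variables. This
  is the tie-break policy: it is cycle-proof and fully deterministic,
  so a fixed model yields a bit-identical flux vector on every call —
  degenerate alternative optima are resolved the same way every time,
  which the downstream flux statistics rely on;
* infeasibility is not an error but a biological state: an agent whose
  steady-state problem is infeasible neither grows nor exchanges in
  that step (`status = "infeasible"`, $\mu = 0$, empty fluxes);
* an optional second lexicographic stage (`pfba = TRUE`) re-solves at
  the pinned optimum minimising $\sum_j |v_j|$, which removes futile
  cycles from reported flux vectors. It is off by default because the
  dynamic simulation only consumes exchange fluxes of toy networks
  without cycles; it exists to stabilise flux reports on degenerate
  networks.

Units are fixed globally: flux mmol·gDW$^{-1}$·h$^{-1}$, biomass pg
(1 pg = $10^{-12}$ gDW), time h, per-cell substrate amounts fmol. These
choices make the bookkeeping numerically convenient: the amount moved by
an agent in one step is exactly `flux * biomass_pg * dt` femtomoles, and
the availability bound is `amount_fmol / (biomass_pg * dt)`.

# The arena

`runSimulation()` advances an agent population on a `rows x cols` grid.
One step, in a freshly reshuffled agent order (re-randomised each step
from the arena RNG, so no agent has a systematic first-mover advantage):

1. uptake bounds are tightened to $-\min(|lb|, \text{amount}/(m\,dt))$
   per exchange, so an agent can never take up more than its cell holds
   — this is also the only mechanism that keeps amounts non-negative;
   amounts are never clipped after the fact (a $10^{-12}$-scale guard
   absorbs float roundoff only);
2. FBA is solved for the agent;
3. biomass grows multiplicatively, $m \leftarrow m\,e^{\mu\,dt}$,
   truncated at twice the division threshold. Exponential rather than
   Euler integration is exact for constant $\mu$ and stable at the
   default $dt$ = 1 h;
4. the agent's cell gains $v_{ex}\, m\, dt$ of each exchanged
   metabolite (secretion adds, uptake subtracts);
5. an agent at or above the division threshold splits into two
   half-biomass agents, the child placed uniformly at random on a free
   von Neumann neighbour; with no free neighbour the division is
   deferred, not forfeited — this makes the capacity derivation below
   exact;
6. each substrate field mixes: every cell sends a `diffusionRate`
   fraction of its content in equal parts to its von Neumann neighbours
   (closed boundaries), which conserves totals exactly; replenished
   fields are then reset to their initial concentration.

## Capacity

The arena imposes a hard total-biomass capacity (default 750 pg). The
documented derivation is `capacity = rows x cols x divisionThreshold`:
a full grid of agents sitting at the division threshold. Because
truncation alone (step 3) would let a full grid of deferred dividers
reach twice that, the capacity is enforced globally: an agent's growth
in a step is clipped to the remaining headroom, in the shuffled
processing order, and its recorded exchange fluxes are scaled by the
realised/intended gain ratio so that the metabolite accounting
invariant — total amount change equals $\sum v_{ex}\, m\, dt$ over the
recorded series — holds exactly even in the saturated regime. Headroom
is symmetric in expectation across identical species because the order
is reshuffled every step.

## Defaults and their rationale

The spatial parameters are deliberately desk-scale; all are overridable
in `arenaConfig()`.

| parameter | default | rationale |
|---|---|---|
| grid | 20 × 20 | enough agents (400) for spatial competition, small enough for thousands of LP solves per run |
| total volume | 1 µL | per-cell volume follows as `totalVolume/(rows*cols)` |
| dt | 1 h | matches the hourly resolution of the growth curves |
| horizon | 45 h | standard growth-experiment duration |
| capacity | 750 pg | the conventional arena biomass ceiling; bins at 250/500/750 pg refer to it |
| division threshold | capacity/(rows·cols) = 1.875 pg | makes capacity exact (see above) |
| initial agent biomass | half the threshold | a fresh cell is mid-cycle |
| diffusion rate | 0.5 | fast but not instantaneous mixing at dt = 1 h |
| oxygen | 0.1 mM, replenished | constant microaerobic environment |

Oxygen is treated as an ordinary replenished substrate: held at 0.1 mM
by per-step reset. A one-shot (non-replenished) bolus is available by
configuration (`oxygenReplenished = FALSE`), since either reading of a
constant-oxygen setting is defensible; the toy species are
oxygen-indifferent, so for the shipped scenarios the choice is inert.

Replicates: growth curves are reported as means of 12 seeded runs
(`runReplicates()`, seeds `baseSeed..baseSeed+11`); metabolite
production profiling conventionally uses 100.

# Cross-feeding statistics

For one exchange reaction at one timepoint the two species'
population-level fluxes (biomass-weighted means, i.e. populations rather
than single agents) form the ratio $r = v_A/v_B$. When $-1 < r < 1$ the
reciprocal is reported instead, so the magnitude always highlights the
larger flux and $|value| \ge 1$. This reciprocal rule is the entire
normalisation — no further scaling is applied. The sign equals
$\mathrm{sign}(v_A)\cdot\mathrm{sign}(v_B)$: negative means opposite
transport directions, the signature of an exchanged metabolite. A flux
below $10^{-8}$ counts as "not transported" (the tolerance exists so LP
solver noise cannot create spurious sharing), and the metabolite is
*not shared* at that timepoint.

The ratio is not symmetric in its inputs, only its magnitude and sign
are; outputs therefore record which species was the numerator. Swapping
the species maps $r \mapsto 1/r$, which the reciprocal rule sends to the
same reported magnitude and sign, so the orientation choice cannot
change any call.

`detectExchanged()` calls a metabolite exchanged when its ratio is
negative in at least 80% of the timepoints where it is shared, with at
least 3 shared timepoints. The two numbers are package choices — they
encode "consistently negative over the time course" while tolerating
brief sign flips around growth-phase transitions and refusing to call
one-timepoint coincidences; both are arguments.

# Cumulative flux between media

Per reaction, fluxes are summed over all recorded timepoints on each
medium ($v_{Sum}$), the media are compared by $d = v_{Sum,base} -
v_{Sum,comp}$, and the magnitude is compressed as $\log(|d|+1)$. Two
genuinely open choices are pinned and flagged in the output metadata:

* **log base** — natural log (`log10` by flag). The transform's unit
  statement is log(mmol·gDW$^{-1}$·h$^{-1}$) and the test suite pins
  $value(e-1) = 1$.
* **group aggregation** — a reaction group sums the signed $d$ first and
  transforms once. The transform is defined on sums, so aggregation
  belongs on the signed scale; the consequence (opposite rerouting
  within a group cancels) is intended and tested.
* **summation window** — the sum runs over the full series once rather
  than being re-evaluated per timepoint; per-timepoint prefixes can be
  recomputed from the stored series if needed.

# Screens

The growth grid simulates every singleton and unordered cross-genus
pair (all pairs by flag) on every medium and bins the total final
biomass at the fixed edges weak [0, 250), intermediate [250, 500),
strong [500, 750] pg.

`classifyInteraction()` compares co-culture to mono-culture finals per
species: stimulation at $\ge 2\times$ mono, inhibition at
$\le 0.5\times$ mono while the partner is not decreased, competition
when both decrease, otherwise neutral. The thresholds are arguments;
the classification is invariant to relabelling the pair.

The supplementation screen adds one candidate metabolite at one dose
(default 10 mM; the dose-response ladder is 10 nM, 0.1 µM, 0.1 mM,
1 mM, 100 mM) and calls a candidate *promoting* at fold change
$\ge 2$ **and** absolute gain $\ge 10$ pg. No printed criterion exists
for "promoting", so both thresholds are explicit arguments and echoed
into the output attributes; the absolute-gain guard stops 2× rescues of
numerically tiny baselines from counting. Candidates unknown to both
the medium and the model are recorded as not applicable rather than
failing the screen.

# Synthetic ground truth

The generators produce the smallest models whose behaviour is known in
closed form, so every pipeline stage has an exact oracle:

* `makeChainSpecies()` — exchange → transport → biomass on one
  substrate; $\mu = v_{max} \cdot yield$ exactly (default
  $10 \times 0.1 = 1$ h$^{-1}$).
* `makeCrossfeedingPair()` — the producer co-secretes `cpd_M`
  *stoichiometrically with biomass* (5 mmol/gDW formed). Obligate
  coupling, rather than optional overflow, is deliberate: with optional
  secretion an alternate FBA optimum could silently drop the secretion
  and make every cross-feeding test flaky. The consumer requires
  1 mmol/gDW of `cpd_M` in its biomass and cannot synthesise it, so its
  growth on a `cpd_M`-free medium is exactly 0. The construction-time
  check `.verifyGroundTruth()` re-derives all closed-form growth rates
  with `solveFBA()` to $10^{-8}$.
* `makeCompetitorPair()` — two label-distinct copies of one chain
  species: pure space/resource competition with an expected 50/50
  split by symmetry.
* `makeHeterolacticSpecies()` — biomass-coupled co-secretion of lactate
  (4 mmol/gDW) and acetate (2 mmol/gDW); the 1:2 acetate:lactate flux
  ratio is exact at any optimum.

The media suite fixes the scenario: `rich` (20 mM substrates, 10 mM
`cpd_M`) saturates the arena; `limiting` zeroes `cpd_M` and supplies
glucose at only 2 µM. That glucose pool is sized so the producer's
final biomass stays well below both the capacity and the grid size —
otherwise the producer would fill the arena before the consumer's
rescue could express itself, confounding cross-feeding with space
competition. `limitingM` is `limiting` plus 10 mM `cpd_M`, the rescue
control. All three hold oxygen at 0.1 mM replenished.

## What the toys do and do not show

Passing the suite demonstrates that the machinery — solver, spatial
accounting, statistics, screens — is correct on networks whose truth is
known. The toys do **not** emulate genome-scale properties: thousands of
reactions with degenerate optima, realistic biomass stoichiometries,
condition-dependent secretion, or quantitatively meaningful growth
magnitudes. Results on real reconstructions inherit all the usual FBA
caveats (optimality assumption, unknown uptake kinetics, no growth
inhibition by toxic products such as H₂O₂/H₂S, no pH) and should be read
as qualitative predictions of interaction structure, not growth
magnitudes.

# Problem sizes

The shipped tests run the default 20 × 20 arena only where the claim is
about the default arena (competitor saturation, 12 replicates); all
other scenario tests use 6–10 cell grids and 10–45 h horizons, which
keeps the entire suite in the tens of seconds while exercising identical
code paths — grid geometry changes per-cell amounts but not totals,
because the total arena volume is held at 1 µL.

# Known limitations

* The dense simplex is sized for small and mid-sized models; genome
  scale (~2,000 reactions) works through the same interface but is slow
  and is not what the shipped scenarios exercise.
* Biomass growth uses $e^{\mu dt}$ while substrate drawdown uses the
  start-of-step biomass linearly; over one step the two disagree at
  order $(\mu\,dt)^2$. The metabolite accounting invariant is defined
  against the recorded series and holds exactly; the
  substrate-per-biomass yield over a trajectory is discretisation-
  dependent, as in any explicit dFBA.
* The SBML reader covers the FBC-v2 constructs that constraint-based
  models actually use (species, charge/formula annotations, bound
  parameters, the active objective); it is not a general SBML parser.
* No host compartment, chemotaxis, pH, or toxicity feedback.
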