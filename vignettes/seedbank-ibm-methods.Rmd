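---
title: "Methods: an encounter-limited individual-based model of microbial seed banks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an encounter-limited individual-based model of microbial seed banks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedbankIBM)
```

## The model

`seedbankIBM` simulates heterotrophic microbial communities as
individuals in a cubic arena, at the spatial and temporal scale of the
cells themselves.  The arena side is **43,200 µm** and one time step is
**1200 s**: 1200 s is an *E. coli*-scale minimum doubling time, and
36 µm/s an *E. coli*-scale maximal swimming speed, so in one step the
fastest species can double at most once and the fastest swimmer can
cross the arena at most once.  This space–time equivalency puts
reproduction and dispersal on a common footing.

Each cell carries a **relative quota** $Q \in (0, 1]$ — its endogenous
resource store as a fraction of the species maximum.  Quota is
proportional to cell volume, so diameter follows a cube-root law,
$d = 1.25\,Q^{1/3}$ µm; immigrants arrive with $Q \sim U(0.5, 1)$,
i.e. diameters of roughly 1–1.25 µm.  Resource particles are spheres
whose content (1000–10,000 mass units on supply) maps to diameter by
the same volume-proportional law anchored at content 1000 ↦ 4000 µm
(hence supplied diameters of 4000–8600 µm).

Consumption is **encounter-limited**: a cell can only consume a
particle whose sphere it physically touches and whose type its species
can use.  Each consumption event strips at most a species-specific
fraction of the particle's content (and never more than the cell's
remaining headroom $1-Q$), after which the remainder is broken into
two fragments with a uniform random content split.  Fragmentation
conserves mass exactly; repeated breakdown produces cascades of
ever-smaller "crumbs" whose tiny collision cross-sections make them
increasingly hard to re-encounter — dilute resources resistant to
consumption, and a pool whose emergent size distribution is one of the
model's diagnostic outputs.

Physiology is a quota ledger.  Per step, an active cell pays its
species maintenance $m_s \in [0.001, 0.01]$; it reproduces by clonal
binary fission with probability $g_s Q$, paying a growth cost
$c_g\,g_s\,Q$ before the remaining quota is halved between mother and
daughter; it dies when $Q < m_s$.  A cell whose quota falls to
$\theta_d\,m_s$ (with $\theta_d = 50$) enters **dormancy**: it stops
moving, consuming, and reproducing, and its maintenance drops by the
species factor $f_s \in [10, 100]$.  Dormant cells resuscitate at
random with species probability $\rho_s \in [0.001, 0.01]$ per step.
The dormant fraction of the community is the **seed bank**; nothing in
the model imposes its size — it emerges from the energetics.

## The complexity regimes

A model runs under one of $4 \times 3 \times 3 \times 2 = 72$ regimes
(`enumerate_regimes()`):

* **Trophic**: plain consumer–resource; *scavenging* (dead cells leave
  a universally consumable necromass particle worth a sampled 1–100 %
  of their quota); *cross-feeding*, one-way or two-way (consumption
  releases a metabolite particle of a species-specific product type,
  with yield $\beta$ per unit consumed; two-way permits reciprocal
  producer–consumer pairs, one-way forbids them).
* **Resource**: labile monoculture (one supplied type, usable by all);
  labile polyculture (several supplied types, each usable only by its
  specialist consumers); *lock-and-key* recalcitrance (breakdown of a
  supplied particle succeeds only with a per-type sampled probability
  0.01–1.0, and each attempt costs the handler energy), combined at
  random with a mono- or polyculture supply.
* **Dispersal**: passive (free); *run-and-tumble* (straight swimming
  with random reorientation at walls, up to the species fraction
  $\delta_s \in [0.01, 1]$ of the arena side per step, at cost
  $c_d\,(\text{dist}/L)\,Q$); *chemotaxis* (straight pursuit of the
  nearest consumable particle, at twice the run-and-tumble cost — the
  price of sense perception).
* **Mixing**: well-mixed (every entity relocated uniformly each step)
  or spatially structured (particles and non-swimming cells move only
  by Brownian jitter, $\sigma_B$ per axis; fragments land within
  $\epsilon$ of their parent, so broken-down resources aggregate).

Each step executes the nine process blocks (supply, immigration,
mixing, dispersal, consumption, reproduction, maintenance, death,
dormancy) in a freshly shuffled order, which prevents fixed-order
artifacts; within the consumption block, when several cells contact
the same particle the winner is drawn by a uniform shuffle and one
consumption per cell and per particle is allowed per step.

## Parameters

Sampled per model, uniformly within their ranges
(`sample_params()`, `sample_species_traits()`):

| parameter | range | units |
|---|---|---|
| resource supply rate | 0.1–1.0 | probability/step |
| inflowing resource diversity | 1–10 | types |
| supplied particle content | 1000–10,000 | mass units |
| lock-and-key breakdown probability | 0.01–1.0 | per attempt, per type |
| necromass value | 1–100 | % of dead cell quota |
| immigration rate | 0.01–0.1 | probability/step |
| log-series shape α (founders) | 0.95–0.99 | – |
| specific maintenance $m_s$ | 0.001–0.01 | quota/step |
| dispersal fraction $\delta_s$ | 0.01–1.0 | of 43,200 µm/step |
| growth rate $g_s$ | 0.1–1.0 | probability scale |
| resuscitation $\rho_s$ | 0.001–0.01 | probability/step |
| maintenance reduction $f_s$ | 10–100 | divisor while dormant |
| consumption rate | 0.1–1.0 | fraction of particle/encounter |

Constants with no published value are declared in one block
(`DEFAULT_CONSTANTS`) and documented as design choices:

* $\kappa = 0.001$ quota per mass unit.  This makes one full cell
  equivalent to 1000 mass units, so a supplied particle holds 1–10
  cells' worth of energy — the same unit system in which a maximum
  quota is "1000".
* $c_g = 0.1$ (growth cost) and $c_d = 0.05$ (dispersal cost
  coefficient): a fast swimmer crossing the arena spends 5 % of its
  quota per step (10 % under chemotaxis), enough to make foraging
  strategy consequential without dwarfing maintenance.
* $\beta = 0.1$ metabolite yield; $\theta_d = 50$ (dormancy begins
  with ~50 steps of active maintenance left in reserve);
  $\sigma_B = 10$ µm; $\epsilon = 100$ µm.
* Content floor $10^{-6}$ mass units: fragments below a ~4 µm diameter
  are dropped from the ledger.  The floor is set at the micron scale
  of the smallest emergent aggregates rather than at one mass unit
  (≈ 400 µm diameter), which would amputate the crumb cascade the
  model is meant to exhibit.
* Particle ceiling 10,000: beyond it the smallest crumbs are culled
  (their content booked as removed).  Particle totals stay below
  10,000 — a practical bound on computational overhead; cross-feeding
  regimes would otherwise accumulate metabolite crumbs without limit.
* Species pool $S = 100$; founders' species are drawn from a
  log-series with the sampled α truncated to the pool (a realistic
  commonness/rarity mix), while immigrant species are uniform.

## Workflow and problem sizes

`run_model()` steps a model until its total-abundance series
mean-reverts — the means of the last two non-overlapping 100-step
windows within 0.1 pooled SD of each other, checked every 25 steps
after step 500, capped at 10,000 steps (capped runs are flagged, not
discarded) — then discards the burn-in and records every 10th step of
a 2000-step production phase.  One step is one "generation" (the time
step *is* the minimum doubling time).  Extinction (N = 0 with
immigration disabled) terminates a run early.

The packaged experiments run at desk scale, tens of runs rather than
the >10,000-model sweeps of a cluster campaign; their sizes are stated
here as the package's own defaults:

* `ensemble_emergent_sizes()` / `correlation_encounter_dormancy()`:
  20–30 runs, burn-in capped at 500 steps plus 1500 recorded steps
  (~2000 steps per run), each run drawing its own parameters and one
  of the 72 regimes from its seed.
* `contrast_dispersal_encounters()`: 10 matched pairs
  (chemotaxis vs passive, structured monoculture), 1000 steps, total
  encounters compared without discarding a burn-in since the response
  is cumulative.
* `contrast_dormancy_presets()`: 10 matched pairs under the strong
  ($f_s = 100$, $\rho_s = 0.001$) vs weak ($f_s = 10$, $\rho_s = 0.1$;
  deliberately outside the sampled resuscitation range) dormancy
  presets, immigration off so extinction is absorbing, 2500 steps.
* `contrast_lock_key_stability()`: 10 matched pairs, labile vs
  lock-and-key monoculture in a structured run-and-tumble setting
  (the stabilizing influence of recalcitrance is a
  structured-environment time-series result), 1000 steps.

## The log-series fit

`logseries_r2()` scores an observed species abundance distribution
against the Fisher log-series fitted through its richness $S$ and
abundance $N$: the shape $x$ solves
$S/N = \frac{1-x}{x}\,(-\ln(1-x))$ (equivalently Fisher's
$\alpha_F = N(1-x)/x$), expected rank abundances are the log-series
quantiles at rank midpoints, and the statistic is a modified $r^2$ on
rank-matched *log* abundances, $1 - \sum(\ln o_i - \ln p_i)^2 /
\sum(\ln o_i - \overline{\ln o})^2$ — it can be negative for poor
fits.  Log scale is the convention of the macroecology literature this
check belongs to; the self-consistency test draws SADs from a
log-series and verifies the fit recovers them (median $r^2 > 0.8$).

## Numerical choices

Boundaries reflect (entities "hit the edge and turn"; a periodic wrap
would make edges undetectable).  Encounter detection is exact
sphere–sphere contact with ties to the lowest particle id; the
spatial-grid index inside the C++ kernel is an internal acceleration
with a contract identical to the brute-force all-pairs scan, and the
test suite holds it to that oracle.  Maintenance, handling, and
dispersal deductions are capped at the current quota, so quota never
goes negative; a fully drained cell dies at its next death check.
Conservation is audited, not assumed: cumulative ledgers of content
(supplied + spawned − consumed − removed) and quota (founding +
immigration + consumption − maintenance − growth − dispersal −
handling − death) must balance the standing totals to a relative
$10^{-9}$ over any run, and the tests enforce this.

## What the generator emulates, and what it does not

The randomized generator reproduces the *conditions* of the study —
parameter ranges, the 72-regime factorial, 100-cell founding
communities — so that passing tests demonstrate the mechanisms
(encounter limitation, energetic trade-offs, emergent dormancy) under
those conditions.  It does not emulate real microbial data:
there is no mutation or evolution (reproduction is clonal), no
hydrodynamics or chemoattractant gradients (chemotactic sensing is
geometric and unlimited in range, offset by its energetic cost), no
explicit enzymes (recalcitrance is a Bernoulli gate), and trophic
structure is limited to scavenging and cross-feeding — no predation
or parasitism.  Conclusions about real communities rest on the
paper-scale reasoning, not on these desk-scale ensembles.

## Known limitations

* Emergent statistics at desk scale are noisy; the packaged ensembles
  use tens of seeds and inherit that variance.
* The dormancy entry rule (deterministic threshold $\theta_d m_s$) is
  the simplest depletion trigger consistent with the narrative that
  energetically depleted cells go dormant; other plausible rules
  (stochastic entry, resource-cue entry) are not implemented.
* Under monoculture supply, cross-feeding relies on the extra
  metabolite-acceptance type each species receives; without it no
  species could consume any metabolite and the regime would be inert.
* The particle ceiling makes extreme crumb-accumulation regimes
  (notably cross-feeding with high encounter rates) slightly lossy;
  the culled content is booked in the ledger, so conservation audits
  still balance.
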