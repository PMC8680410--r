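---
title: "Modelling self-oxygenating implants: oxygen-generating beads, hypoxia-driven VEGF, and sprouting angiogenesis"
author: "oxybeads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling self-oxygenating implants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxybeads)
```

## The problem

A clinically sized engineered tissue implanted without vasculature relies
on diffusion from the host during its prevascular phase. Oxygen falls
first into hypoxia (below 5% dissolved oxygen) and then anoxia (below
0.5%), killing the encapsulated cells and, with them, the production of
the angiogenic factors (chiefly VEGF) needed to attract host vessels.
Oxygen-generating micromaterials aim to break this deadlock: calcium
peroxide (CPO) hydrolyses to oxygen in a short burst of a few days,
while CPO encapsulated in hydrophobic polycaprolactone microparticles
(hydrophobic oxygen generators, HOGs) releases oxygen for roughly two
weeks. The interesting regime is *mild* oxygenation: enough to prevent
anoxic death, little enough that the tissue stays hypoxic and keeps
signalling for vessels.

`oxybeads` implements a hybrid in-silico model of this system: a
tissue-level taxis-diffusion-reaction description of oxygen, VEGF,
progenitor cells, fibroblasts and fibrous matrix, coupled to a discrete
endothelial-cell model of sprouting angiogenesis with Dll4-Notch
lateral inhibition, with beads acting as decaying, oxygen-gated point
sources.

## Unit conventions

* Oxygen is nondimensional with 1.0 = 21% dissolved oxygen
  (atmospheric normoxia). The anoxia and hypoxia thresholds are
  0.5/21 and 5/21; the implant initializes at 3.7/21. Under this
  convention the release half-saturation 0.11 corresponds to about
  2.3% oxygen — inside the hypoxic band, which is what makes the bead
  field self-limiting: release shuts down as tissue approaches the
  hypoxic set point rather than driving it to normoxia.
* One time unit is one day. The HOG decay rate 0.05/day then gives a
  release half-life of ~13.9 days (a two-week sustained release) and
  the CPO rate 0.5/day a ~1.4-day burst, matching the qualitative
  kinetics of the two materials.
* One lattice site is `dx` = 0.04 mm; the default 100 × 100 lattice is
  a 4 mm implant cross-section, followed for 7 days (the implantation
  window used for the in vivo comparison).

## The bead release law

Each bead releases oxygen at

$$r(c, t) = G_n \, \frac{H_n^{6}}{c^{6} + H_n^{6}} \; e^{-\tau t},$$

with peak rate $G_n = 2.2$, half-saturation $H_n = 0.11$, Hill
coefficient 6, and $\tau$ = 0.5/day (CPO) or 0.05/day (HOGs); the two
bead types share $G_n$ and $H_n$ and differ only in their decay clock.
At zero oxygen the cumulative release has the closed form
$(G_n/\tau)(1 - e^{-\tau t})$, so a HOG bead carries a tenfold total
oxygen budget. `fitReleaseParams()` recovers $(G_n, \tau)$ from sampled
release curves by Levenberg-Marquardt least squares with a
deterministic initialization ($G$ from the curve maximum, $\tau$ from
the end-point log-slope). Note that at zero ambient oxygen the Hill
gate is identically 1, so $H_n$ is structurally unidentifiable from the
standard nitrogen-purged release protocol; estimating it requires a
curve recorded at non-zero oxygen (`fixH = FALSE`).

## The continuum tissue model

Five fields evolve on the lattice by explicit finite differences
(five-point Laplacian, ghost-cell mirroring for zero-flux boundaries):

* **Oxygen** diffuses, is consumed by cells with Michaelis-Menten
  kinetics $k_c \,(m+f)\, c/(c+K_c)$, is injected at bead sites through
  the release law, and relaxes towards a capillary tension at perfused
  vessel sites.
* **VEGF** diffuses, decays, is taken up at endothelial sites, and is
  produced by cells at rate $(p\,m + 10\,p\,f)\,\varphi(c)$ — the
  fibroblast rate is ten times the progenitor rate — where
  $\varphi(c) = 1 + (\varphi_{max}-1) K_\varphi^{q} / (c^{q} +
  K_\varphi^{q})$ amplifies production under hypoxia, capturing the
  inverse correlation between oxygen tension and total secreted VEGF.
  Dead tissue produces nothing: anoxia ultimately silences the implant.
* **Progenitors and fibroblasts** diffuse slowly, proliferate
  logistically with an oxygen-limited rate $\propto c/(c+K_c)$, die at
  rate $d_a$ where oxygen is anoxic, and enter over the boundary at a
  Dirichlet density of 0.01 during the first 3 days.
* **Fibrous matrix** is deposited by cells, saturating at 1.

Initial state: oxygen 3.7%, matrix 0.1, progenitors 0.1, no
fibroblasts, no VEGF. The boundary oxygen is clamped to the host
tension (set equal to the initial 3.7%, as no host value is stated for
this system), and the original model's ten continuum variables are
reduced here to the five that the reported simulation outputs (oxygen
state, VEGF, cellularity, vascularization) actually exercise; the
reduction is deliberate and documented rather than silent.

## The vascular agent model

Endothelial agents occupy lattice sites and carry the eight-species
intracellular state VEGFR-2, active VEGFR-2, effective active VEGFR-2,
Notch1, active Notch1, effective active Notch1, Dll4 and actin.
The lateral-inhibition causal chain is: local VEGF activates VEGFR-2;
effective receptor activity is algebraically attenuated by effective
Notch, $V_e = V_a/(1 + (N_e/K)^2)$; $V_e$ drives sigmoidal Dll4
production; a cell's Notch1 is activated by the mean Dll4 of its
lattice neighbours; actin relaxes towards $V_e$ and confers tip
competence above a threshold. Receptor and Notch production are
VEGF-gated, so the all-zero state at zero VEGF is a fixed point, and
"effective active" species implement inhibition as algebraic
attenuation where no dynamics are specified. Two adjacent cells under
uniform VEGF break symmetry towards whichever started with more
VEGFR-2; a row relaxes to the classic salt-and-pepper pattern with no
two adjacent tips.

Sprouts seed as quiescent agents every 10 sites around the full
perimeter (vessels can invade from all sides). Selection makes an
agent a tip when its actin exceeds the threshold and strictly exceeds
every lattice-neighbour agent's actin (id tie-break); tip role then
persists while actin stays above threshold, at most one tip leads each
sprout, and only the free end of a sprout can lead — sprouts are
unbranched chains, matching the sprouting → growth → anastomosis
sequence. Every 0.1 day a tip advances to the unoccupied neighbour
site with the highest VEGF (deterministic N, E, S, W tie order), the
vacated site keeping a newborn stalk cell. Two modelling choices keep
the advancing front coherent: enclosed stalk cells (two or more vessel
connections) sense a fraction (0.2) of the local VEGF, concentrating
Dll4 expression in the filopodia-bearing head, and the newborn stalk
inherits no accumulated Dll4, so the tip it trails is not transiently
self-inhibited by its own daughter. A tip arriving adjacent to a
different sprout fuses with it (anastomosis); the shortest
root-to-root path through the fused network is then flagged perfused,
and perfused sites deliver oxygen. Unfused sprouts deliver nothing.

## Parameter choices and calibration

The release constants, the VEGF-rate multiplier, the initial and
boundary conditions and the classification thresholds are fixed by the
system being modelled (values above). The remaining rate constants are
not published for this system; they were chosen once, by scale
analysis, and are all exposed in `ModelParameters`:

* `D_oxygen` = 0.05 mm²/day with `k_consume` = 2/day and `K_consume` =
  0.2 puts the oxygen diffusion-consumption length
  $\sqrt{D(c+K)/(k\,m)}$ near 0.3 mm — between the ~0.28 mm bead
  spacing at 2% area fraction and the 2 mm implant half-width. This is
  the regime the system lives in: a bead-free implant develops an
  anoxic core behind a thin oxygenated rim within ~2 days, while a 2%
  HOG lattice holds the bulk hypoxic, because each bead's oxygenated
  neighbourhood overlaps the next. At 1% the neighbourhoods no longer
  tile (the benefit erodes); at 4% they saturate (little is added).
  The same balance makes the mean 2% HOG supply (0.02 × 2.2 ≈
  0.044/day) sit just above consumption at hypoxic tensions, so the
  tissue equilibrates inside the hypoxic band instead of racing to
  normoxia.
* VEGF: production 1/day per unit progenitor density, decay 1/day,
  `phi_max` = 5 with half-effect at 2.5% oxygen and Hill 4 — the
  steep amplification centred in the HIF-response range is what makes
  the hypoxic (living) core the VEGF source and gives tips an inward
  gradient to climb; endothelial uptake 3/day carves the field down
  behind the vascular front without starving the front itself.
* Notch constants (production 5/day, decay 5/day, activation rates
  10/day, inhibition scale 0.1, Dll4 half-max 0.3) give the
  intracellular species sub-day relaxation times, so that two-cell
  competition seeded by a 0.1% receptor asymmetry resolves decisively
  within a few simulated days (faster for the larger asymmetries real
  VEGF gradients provide), with the winner's actin near its
  isolated-cell value and the loser suppressed more than tenfold.
  The tip threshold 0.15 sits between those two levels across the
  VEGF range the tissue actually produces (~0.3-1).
* Growth cadence 0.1 day (a maximum tip speed of 0.4 mm/day, the
  order of endothelial migration speeds) lets a sprout cross the 2 mm
  half-width within the 7-day window only if its VEGF supply is
  sustained — which is exactly the discriminator between bead
  conditions.

No parameter differs between the control, CPO and HOG conditions
except the bead type and fraction themselves.

## Numerical choices

* Explicit Euler with `dt` = 0.002 day; `validateConfig()` enforces
  the diffusion stability bound `dt <= dx²/(4 max D)` (0.008 day at
  the defaults) and a run aborts with a stability error naming `dt`
  if any field goes non-finite.
* Negative field values produced by the explicit step are clipped to
  zero; with a valid `dt` this is a guard, not a correction.
* Dirichlet conditions are applied by overwriting boundary rings
  before each step; everything else is zero-flux by ghost mirroring,
  under which pure diffusion conserves each field to 1e-10 over 1000
  steps (a property the test suite asserts).
* All stochasticity (bead placement, synthetic noise) runs under
  private, seeded RNG streams that restore the caller's state, so a
  scenario is bit-reproducible from its configuration and seed, and
  replicate k of a sweep uses seed `base_seed + k - 1`.
* Ties in tip advancement resolve in fixed N, E, S, W order; ties in
  tip selection resolve towards the smaller agent id.
* Degenerate inputs fail loudly: all-zero release curves, fewer than
  5 fit points, `tau` = 0 in the cumulative closed form, spacing
  wider than the domain edge, and H-estimation from zero-oxygen
  curves are all errors, not silent results.

## What the synthetic generator emulates — and what it does not

`makeReleaseCurve()` reproduces the *shape* of measured release
kinetics (a CPO-like burst, a HOG-like two-week sustained release)
with additive, homoscedastic, seeded Gaussian noise clipped at zero;
real sensor traces have drift and heteroscedastic error the generator
does not attempt. `makeVegfGradient()` and `makeEcRow()` are clean
fixtures for tip migration and lateral inhibition. Passing tests on
these fixtures demonstrates the mechanisms (parameter recovery,
symmetry breaking, gradient climbing), not agreement with any
particular measured dataset. Likewise the model omits the hydrogen
peroxide intermediate of CPO hydrolysis and its cytotoxicity, blood
flow and vessel regression, implant mechanics, pH effects and any
immune field — its anoxic-death term is the only toxicity in play, so
CPO's in-silico disadvantage (early burnout) understates its measured
one (peroxide toxicity).

## Problem sizes used by the tests

Unit tests run on 21 × 21 lattices for speed. The acceptance suite
runs the full study conditions — 100 × 100 sites, 7 simulated days,
five bead conditions (control, CPO 2%, HOG 1/2/4%) × 5 placement
seeds — and asserts the predicted contrasts: anoxic fraction ordered
control > CPO-2% > HOG-2%, penetration depth ordered the other way,
4% HOG adding little over 2% and 1% eroding the benefit. Each full
run takes on the order of 15 s on one CPU.

## Known limitations

* The five-field continuum reduction and the concrete Notch ODE forms
  are declared stand-ins for model components whose full equations are
  not published for this system; their constants are calibration
  knobs, exposed in `ModelParameters`, not measurements.
* Perfusion is binary (a loop either connects two boundary roots or
  not) and oxygen delivery is a relaxation towards a fixed capillary
  tension rather than a flow computation.
* The lattice is 2D; a 4 mm cross-section stands in for a volumetric
  implant, which overstates boundary access relative to a true 3D
  core.
* The stated initial progenitor density is taken at its explicit
  value (0.1) where the surrounding prose ("10% of 10% of carrying
  capacity") is self-contradictory.
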