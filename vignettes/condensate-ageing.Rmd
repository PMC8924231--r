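---
title: "Modelling condensate ageing with a sticker-spacer polymer model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling condensate ageing with a sticker-spacer polymer model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Biomolecular condensates formed by liquid-liquid phase separation (LLPS)
start out as liquids: proteins diffuse freely inside them, droplets fuse and
relax to spheres. Over time many condensates *mature* (age): protein
mobility decays by orders of magnitude, droplets stop coalescing, and
solid-like, often aspherical aggregates appear. A leading molecular
explanation is the progressive strengthening of a subset of inter-protein
interactions - for instance through inter-protein beta-sheet formation in
LARKS-containing low-complexity domains, post-translational modification, or
changing solution conditions.

`agedrop` implements a minimal coarse-grained model to study exactly this
coupling between interaction strengthening, protein mobility, and condensate
shape, together with the simulation protocols and observables needed to map
its consequences.

## The model

Each protein is a fully flexible bead-spring heteropolymer of 39 beads (a
bead is roughly 6-8 residues, so a chain represents a 234-312 residue
disordered region). Two bead classes exist:

* **spacers** (34 beads) interact with everything *weakly*, with
  Lennard-Jones well depth $\varepsilon_D$;
* **stickers** (3 of type A, 2 of type B) interact weakly with everything
  *except* their complementary sticker type: A-B pairs bind *strongly* with
  $\varepsilon_S$. Homotypic A-A and B-B pairs stay weak - strong binding is
  meant to represent orientation-specific ordered contacts, which only
  complementary pairs can form.

The two depths are coupled, $\varepsilon_S = 10\,\varepsilon_D$, reflecting
the roughly order-of-magnitude strengthening measured for
disordered-to-ordered binding transitions. A homopolymer control (all beads
spacers) isolates the effect of the strong sticker network.

Interactions are truncated-and-shifted Lennard-Jones (cutoff $3.0\sigma$;
the truncation radius shifts the critical point, and with it the
phase-separation threshold, by up to $\sim$10% in $T^*$, so it is kept
generous). A Wang-Frenkel
variant (cutoff $1.5\sigma$, exactly finite-ranged) is available to probe
the effect of a much shorter attraction range; its prefactor is chosen so
the well depth is exactly $-\varepsilon$. Consecutive beads are joined by
harmonic springs ($k = 100\,\varepsilon_{\mathrm{ref}}/\sigma^2$,
$r_0 = \sigma$), which keeps bond-length fluctuations near $0.1\sigma$
while remaining integrable at the default timestep. Bonded 1-2 pairs are
excluded from nonbonded interactions.

**Units.** Lengths are in bead diameters $\sigma$, energies in units of
$k_BT$ at the simulation temperature, masses 1, time in
$\tau^* = \sigma\sqrt{m/\varepsilon_{\mathrm{ref}}}$. The thermostat is
always at $T^* = 1$; because only the ratio $\varepsilon/k_BT$ matters,
*rescaling the well depths is the model's way of changing temperature*
(lowering $\varepsilon$ is heating). All "thermal" protocols below are
implemented as interaction switches.

**Sticker placement.** Only the sticker counts and their qualitative
placement are physically meaningful. The `uniform` patterning interleaves A
and B along the whole chain (A at beads 5, 19, 33; B at 12, 26); the
`half_chain` variant packs all five stickers into the first twenty beads
(A at 3, 11, 19; B at 7, 15). Both are configurable.

## Dynamics

The engine integrates underdamped Langevin dynamics with the BAOAB
splitting; with friction set to zero it reduces to velocity Verlet, which
the test suite uses as an energy-conservation oracle. Defaults:

* $\gamma = 1\,/\tau^*$ - the conventional implicit-solvent friction for
  bead-spring models. Implicit solvent overestimates absolute diffusion, so
  only relative trends in $D$ are meaningful.
* $dt = 0.01\,\tau^*$ for weak couplings, $0.005\,\tau^*$ whenever any well
  depth reaches $2\,k_BT$ (the protocols switch automatically).

Nonbonded forces use a Verlet neighbor list built through a cell grid and
rebuilt whenever any bead has moved more than half the skin
($0.4\sigma$ default) since the last build, so no pair inside the cutoff
can be missed. Thermal noise comes from a counter-based generator
(a splitmix64 hash of seed, global step, bead and axis fed through
Box-Muller): a trajectory is a pure function of its seed and inputs,
continuations across checkpoints are bit-identical, and the engine's "RNG
state" is just the step counter.

Forces are capped per bead only during the initial relaxation of packed
random configurations; production runs are uncapped, and bead overlaps
closer than $0.5\sigma$ are counted and warned about.

## Observables

**Windowed diffusion coefficient.** Protein mobility is tracked through the
mean-square displacement (MSD) of each chain's central bead. The trajectory
is cut into consecutive windows, each expanded until the root MSD reaches a
set multiple (3-5, default 4) of the bead diameter, so that slowing
dynamics automatically produce longer windows; $D$ is the slope/6 of a
linear MSD fit over the window's diffusive tail. Arrested systems never
satisfy the displacement rule; `allow_partial = TRUE` then yields a final
flagged window, which is how quenched mobility is quantified at all.

**Kinetic threshold and regime labels.** A state point is *liquid* when its
terminal $D$ sits above a kinetic threshold and has plateaued (relative
change below 15% over the last three windows); otherwise it is *ageing* -
either $D$ has crossed below the threshold (the crossing time is the ageing
onset) or it is still decaying when the observation window ends. The
threshold defaults to $2\times10^{-4}\,\sigma^2/\tau^*$, i.e. 10% of the
weak-binding homopolymer liquid plateau measured in the same campaigns; a
relative definition survives parameter changes. For condensates that occupy
only part of the box (nucleation-and-growth, hysteresis legs), $D$ is
measured for the chains of the terminal largest cluster over the assembled
stretch of the trajectory, *relative to the cluster's centre of mass*: a
desk-scale aggregate of $M$ chains diffuses as a body with
$D \approx k_BT/(39 M \gamma)$, which would otherwise floor the estimate
above the kinetic threshold and hide the quench entirely.

**Strong contacts.** Inter-chain A-B pairs within $1.5\sigma$ (the
attractive well region). Chains sharing a strong contact form a graph whose
connected components are the strong-contact clusters. The per-volume count,
normalised by an arrest-threshold contact density, is the maturation
coordinate of the in-droplet ageing protocol.

**Condensate density.** Largest bead-graph cluster (cutoff $1.5\sigma$),
recentred through per-axis circular means, radial profile about its centre
of mass; the core density is read from the profile plateau and the
condensate volume from the equimolar radius. Clusters under 100 beads carry
a flag and use a gyration-equivalent volume. Because a percolating gas can
masquerade as "one big cluster" at finite density, phase-separation calls
additionally require liquid-like *inter-chain* packing: the mean density of
other-chain beads within $1.5\sigma$ of a cluster bead. Intra-chain
neighbours are excluded (an isolated chain is self-dense; counting its own
beads would make even a gas look condensed). Calibrated on reference
states, the statistic is sharply bimodal - gas and dispersing systems score
$0.02$-$0.03$ beads/$\sigma^3$, weak-liquid condensates (uniform
$\varepsilon = 0.66$) score $0.23$-$0.26$ - and the condensed-phase gate is
set at $0.12$, half the weakest liquid reference.

**Shape.** Gyration-tensor eigenvalues, asphericity, and relative shape
anisotropy $\kappa^2 \in [0, 1]$ ($0$ = sphere, $1$ = rod).

**Coalescence time.** For two tangent droplets, $\tau_c$ is the first time
the largest cluster holds $\ge 95\%$ of chains *and* $\kappa^2$ stays below
0.02 for a dwell period (10% of the censoring time). Pairs that never get
there are censored at the (stated, arbitrary) maximum simulated time;
losing more than half the chains is reported as evaporation instead.

**Border curve.** Intersecting each $D(t)$ curve with the kinetic threshold
gives, per $\varepsilon_S$, the time available before the condensate ages -
the kinetic border against which coalescence times compete.

**Real units.** With a typical in-condensate diffusion coefficient of
$1\,\mu m^2/s$, the Einstein relation $t = L^2/6D$ puts a $5\,\mu m$ journey
at $25/6 \approx 4.2$ s; the 2-3 orders of magnitude of deceleration
observed on maturation map the same journey to minutes-to-an-hour
(`deceleration_time()`).

## Protocols and study conditions

All drivers are desk-scale by default - chosen so a full campaign runs on
one CPU core in tens of minutes - and every record re-runs bit-identically
from its stored configuration and seed. The reference study conditions:

| quantity | value | note |
|---|---|---|
| chain length | 39 beads | 3 A + 2 B + 34 spacers |
| coupling | $\varepsilon_S = 10\,\varepsilon_D$ | single knob |
| liquid control | homopolymer, $\varepsilon_D = 0.66$ | plateaued liquid $D$ |
| LLPS threshold scan | $\varepsilon_D = 0.25 \ldots 0.50$, step $0.05$ | from dilute starts |
| ageing boundary | $\varepsilon_S = 5.0$ (liquid) vs $5.25$ (ageing) | bulk runs |
| dissolution point | $\varepsilon_S = 3.5$ | no LLPS |
| dilute-start density | $0.08$ beads/$\sigma^3$ | spinodal-ish, nucleates on desk timescales |
| bulk runs | self-measured coexistence density | from a droplet's radial profile |

Desk-scale sizes (30-50 chains for bulk and nucleation boxes, 12-50 chains
per droplet) were fixed from throughput measurements of the engine and from
the physical timescales involved - e.g. dilute-start aggregation needs
roughly the time for a chain to diffuse a few inter-chain spacings
($\sim 400\,\tau^*$ at density 0.08), and a bulk diffusion estimate needs a
handful of windows of $\sim 9/(6D)\,\tau^*$ each. Publication-scale sizes
(hundreds of chains, $10^5\,\tau^*$ horizons) are plain parameter changes.

The drivers:

* `run_bulk_diffusion_scan()` - condensed-phase NVT boxes across
  $\varepsilon_S$, with the homopolymer control; emits $D(t)$ series and
  regime labels.
* `run_nucleation_growth()` - dilute start; shape and diffusion series,
  nucleation flag, terminal $\kappa^2$ (liquid settings end near-spherical,
  ageing settings end arrested and aspherical).
* `run_hysteresis()` - a schedule of interaction switches on one system.
  Forming a condensate at $\varepsilon_S = 6.6$ and returning to $5.0$
  probes thermal hysteresis (the matured aggregate stays arrested even
  though a direct $5.0$ run is liquid); a final leg at $3.5$ dissolves the
  condensate completely (largest cluster below 10% of chains).
* `run_maturation_in_droplet()` - strong interactions switched on *inside*
  a preformed spherical droplet; tracks the normalised strong-contact
  density against droplet shape. The characteristic result: contacts cross
  the arrest threshold while the droplet stays nearly spherical.
* `run_coalescence_matrix()` - tangent droplet pairs across sizes and
  $\varepsilon_S$; fused cells report $\tau_c$, arrested cells censor.
* `scan_llps_threshold()` - the smallest interaction strength forming a
  persistent, liquid-dense condensate from a dilute start.

## Design choices where the design was open

* **Droplet preparation.** Droplets are grown inside a sphere at packing
  density $0.45$ beads/$\sigma^3$ and relaxed under *homogeneous weak*
  interactions (uniform $\varepsilon = 0.66$, a comfortably liquid state
  point) until compact and near-spherical ($\kappa^2 < 0.05$); the target
  interaction table is switched on afterwards. This yields a "preformed
  spherical condensate" without biasing its internal strong-contact
  structure.
* **Tangent placement.** Independently prepared droplets, random mutual
  orientation, surfaces brought to a $1.0\sigma$ gap along the line of
  centres; the box is three merged-droplet diameters per axis, keeping the
  system far from the density regime where slabs or cylinders become the
  free-energy minimum shape.
* **Contact-threshold normalisation.** The strong-contact density at the
  liquid-to-ageing crossover is described procedurally (contacts per volume
  where the diffusion curve meets the kinetic threshold) but has no
  printed value; the default normalisation is $0.01$ contacts/$\sigma^3$,
  configurable, and reported alongside the raw counts.
* **Windows.** Whether diffusion windows overlap and how $D$ is fit within
  a window are open choices; windows here are non-overlapping and $D$ is a
  tail slope fit (an endpoint estimator is available as `fit = "endpoint"`).
* **Degenerate inputs.** Zero separations raise divergence guards; clusters
  under four beads return reduced-rank shape results; static trajectories
  fail the displacement rule loudly unless partial windows are allowed.

## What the synthetic fixtures do and do not show

The analysis code is validated against generators with analytic ground
truth: Brownian walkers (known $D$), rigid rods and uniform balls (known
$\kappa^2$ and density), a scheduled two-sphere merge (known $\tau_c$), and
hand-built contact frames. These certify the estimators, not the physics:
they contain no hydrodynamics, no real contact kinetics, and no
interaction-dependent densification. Conversely, the engine-level physics
checks (free-particle diffusion, NVE conservation, force-oracle
equivalence, ideal-chain statistics) certify the dynamics independent of
the analysis stack. Passing both says the pipeline measures what it claims
to measure on systems where truth is known - the model's biological
fidelity is bounded by its coarse-graining assumptions (implicit solvent,
uniform bead size, static interaction strengths).

## Known limitations

* Absolute timescales are not comparable to experiment (implicit solvent,
  reduced units); only relative trends in $D$, density and shape are.
* Desk-scale horizons bias slow boundaries: near-critical state points have
  not finished condensing at $10^3\,\tau^*$ (the measured LLPS onset sits
  about one grid step above its long-horizon location), the gradual
  diffusion decay that distinguishes marginal ageing strengths from the
  liquid side develops only over $10^4$-$10^5\,\tau^*$, and dissolution or
  arrest of small matured aggregates is slower still. The corresponding
  checks in the test suite assert the full-scale expectations and fail
  honestly where the desk-scale conditions cannot meet them.
* Interaction strengths are static; the strengthening *rate* is emulated by
  protocol (switch inside a droplet vs present from nucleation), not by a
  time-dependent Hamiltonian.
* Desk-scale droplets (tens of chains) have large surface-to-volume ratios;
  size-dependent quantities ($\tau_c$, censoring patterns) are ordinal, not
  quantitative, at these sizes.
* No electrostatics, no sequence chemistry beyond the two-letter
  sticker/spacer alphabet, no rheology (viscosity, interfacial tension) -
  mobility is tracked through diffusion only.

## A minimal session

```{r}
library(agedrop)

model <- cg_model(make_sequence("uniform"), build_interaction_table(0.5))
state <- build_dilute(30, model, box = 53, seed = 1)
params <- engine_params(dt = 0.005, gamma = 1, seed = 1)
state <- advance(state, model, params, 20000, record_stride = 400)
traj <- attr(state, "trajectory")

shape_series(traj)                       # largest-cluster shape vs time
msd_windowed(traj, displacement_factor = 3, allow_partial = TRUE)
```
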