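---
title: "Methods: a hybrid cellular Potts model of invasion through fibrillar ECM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a hybrid cellular Potts model of invasion through fibrillar ECM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invadopotts)
```

## The model

`invadopotts` simulates the dissemination of a tumour cell aggregate
through a fibrillar extracellular matrix with a multiscale hybrid model:
a Graner–Glazier–Hogeweg (GGH, cellular Potts) lattice for cells coupled
to a reaction–diffusion field for matrix metalloproteinases (MMPs).

The arena is a 2D lattice of 500 × 500 pixels, 2 µm per pixel (1 × 1 mm).
Each pixel belongs to one of three entity classes — a **cell** (an
extended, deformable domain of pixels sharing a cell id), an ECM
**fibre** (static, impenetrable until degraded), or interstitial
**fluid**. Fibres are straight segments, one pixel (2 µm) thick and 30–40
µm long; a mesh is parameterized by the fibre count ξ and the orientation
mode ψ (isotropic angles, or all horizontal for a linearized, crosslinked
matrix). The initial condition is an aggregate of 69 square cells of 400
µm² placed at the lattice centre; the nominal population diameter is 200
µm, leaving a 400 µm margin to the boundary, twice the population length
scale.

The configuration energy is

$$
E = \sum_{\text{edges}} J_{\tau_1 \tau_2}
  + \sum_c \lambda_a \,(a(c) - a_0)^2
  + \sum_c \lambda_p \,(p(c) - p_0)^2
  + \sum_c w(c),
$$

with contact energies $J$ charged per first-order lattice edge between
pixels of different domains, quadratic area and perimeter constraints per
cell, and an active-motility work potential
$w(c) = -\mu_0\, \hat{p}_c \cdot \mathbf{r}_c$, where $\hat{p}_c$ is the
cell's polarity and $\mathbf{r}_c$ its centroid. Lower $J$ means stronger
adhesion. The dynamics are Metropolis pixel copies: a source pixel
(uniform among cell + fluid pixels) attempts to copy its id onto a
uniformly chosen 4-neighbour; attempts involving fibre pixels or within
one domain are aborted. Moves with $\Delta E < 0$ are always accepted,
otherwise with probability $e^{-\Delta E / T_m}$. One Monte Carlo step
(MCS) is $N$ attempts, $N$ being the number of evolvable pixels, and
corresponds to 36 s of real time; reference runs last 1800 MCS ≈ 18 h.

Polarity is adaptive: after every MCS, each cell's centroid displacement
is appended to a ring buffer of the last $\tau = 10$ displacements, and
$\hat{p}_c$ is their sum normalized to unit length (zero while the sum
vanishes; the partial history is used during the first $\tau$ steps).
This gives persistent, history-dependent migration and—in a confined,
non-degradable circular geometry—the collective rotation used below for
calibration.

MMPs live on a per-pixel scalar field. Whenever a fibre pixel has at
least one cell pixel among its 8 neighbours it receives secretion
$\lambda \Delta t$ per one-second substep; the field then diffuses
($D = 0.1\ \mu m^2/s$) and decays ($\delta = 0.002\,/s$) by forward
Euler with a 5-point Laplacian and zero-flux boundaries. The stability
number $D\,\Delta t/\Delta x^2 = 0.025$ is far inside the 2D bound 0.25.
Because every MMP rate is per second and one MCS is 36 s, the solver runs
36 substeps per MCS. Once per MCS, every fibre pixel whose MMP count
reaches 1 is converted to fluid and its count reduced by 1 — a
threshold rule standing in for the unresolved proteolysis reaction at the
scale of one pixel of higher-order ECM structure.

## Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| $J_{cc}$ | 1 / 16 / 40 | kT/edge | cell–cell contact energy (high/medium/low adhesion) |
| $J_{ce}, J_{cf}, J_{ef}, J_{ee}, J_{ff}$ | 16, 32, 35, 5, 35 | kT/edge | other contact energies |
| $\lambda_a$, $a_0$ | 1.0, 100 px² | kT/px⁴, px² | area constraint (400 µm² target) |
| $\lambda_p$, $p_0$ | 0.5, 17.5 px | kT/px², px | perimeter constraint (35 µm target) |
| $T_m$ | 12 | kT | noise strength (calibrated; see below) |
| $\mu_0$ | 600 | kT/px | motility strength (calibrated; see below) |
| $\tau$ | 10 | MCS | polarity memory |
| $D$, $\delta$, $\lambda$ | 0.1, 0.002, 0.01–0.1 | µm²/s, /s, /s | MMP transport, decay, secretion |
| ξ, ψ | 400–1000, random/aligned | — | fibre density and orientation |

Internally all energies are in kT and lengths in pixels; conversion to µm
happens only at I/O (trajectories, metrics).

### Why the noise and motility scales are calibrated, not copied

The literature values for this model family quote $T_m = 0.01$ kT and
$\mu_0 = 50$. Under a per-edge Hamiltonian these cannot be literal
Boltzmann scales: the cheapest boundary move of a cell in fluid costs
about $2 J_{cf} = 64$ kT of contact energy plus a perimeter penalty, so
at $T_m = 0.01$ the acceptance of any non-downhill move is
$e^{-6400}$ — the lattice freezes after smoothing its corners, no
migration, rotation or invasion can occur, and no unit convention we
could construct (pixels, µm, mm) restores consistency while preserving
the printed ratios. We therefore keep every printed contact, constraint
and MMP value and recalibrate only the two scales that were themselves
calibrated to phenomenology in the source model:

1. **Rotation**: $\mu_0$ must be strong enough that cells confined in a
   non-degradable circular enclosure exhibit persistent collective
   rotation — the time-averaged angular momentum of the centroids about
   the enclosure centre exceeds an isotropized-increment null at
   $p < 0.01$ (`calibrate_rotation()`).
2. **Speed**: cells migrating along pre-existing fibre-free paths must
   reach ≈ 23 µm/h, the experimental speed that fixes the 36 s/MCS time
   calibration (`calibrate_speed()`: mean per-MCS centroid displacement
   × 100 MCS/h, averaged over ≥ 3 seeds after discarding the first
   $\tau$ MCS while the polarity buffer fills).

A grid search over $(T_m, \mu_0)$ shows the two criteria intersect in a
band around $T_m \approx 12$ kT, $\mu_0 \approx 600$ kT/px (speed 25
µm/h, rotation $p = 0.01$ at 99 resamples); $\mu_0 \gtrsim 700$
overshoots the speed band at any temperature, and $T_m \gtrsim 30$ loses
rotation at the $\mu_0$ the speed band allows. These are the package
defaults; the printed pair remains loadable via
`energy_params(T_m = 0.01, mu0 = 50)` for the near-deterministic regime.

A note on the perimeter target: $p_0 = 35$ µm = 17.5 px lies *below* the
geometric minimum perimeter of a 400 µm² cell (70.9 µm for a disc, 80 µm
for the lattice square), so the perimeter term never reaches its
minimum and acts as a constant line tension of ≈ 22.5 kT per edge on top
of the contact energies. We considered re-expressing the target in
pixel units (35 px = 70 µm, the continuum circumference of the
target-area disc, which would make the constraint a mild shape
regularizer) but kept the literal 17.5 px: under the calibrated
$(T_m, \mu_0)$ it yields the better overall phenomenology, and the
alternative forces $\mu_0 \le 300$ through the speed calibration,
weakening aggregate fission.

## Geometry conventions

* Rasterization: fibres are 8-connected Bresenham chains, one pixel
  thick; overlapping fibres share pixels; segments are clipped at the
  lattice boundary so the count ξ is exact.
* Aggregate packing: cells are 10 × 10-px blocks on a grid whose central
  block is centred at pixel (250, 250); a block is a cell iff its centre
  lies within the aggregate disk. Scanning the radius in 1-px steps, 90
  µm is the smallest radius giving exactly 69 cells; the admitted blocks
  then lie within 100 µm of the centre along each axis, i.e. the nominal
  200-µm-diameter population. Fibre pixels under the initial aggregate
  are deleted (a pixel holds one entity class; the aggregate core starts
  fibre-free).
* Perimeters and contact energies use first-order (4-neighbour) edges;
  cell–fibre *secretion* contact uses the 8-neighbour Moore
  neighbourhood, one unit-rate per contacting fibre pixel regardless of
  multiplicity.
* Cluster analysis deems two cells adjacent when any of their pixels are
  4-neighbours; clusters are connected components of that graph.
* Fluid is one unconstrained domain (no area, perimeter or motility
  terms); fibre pixels do not block MMP diffusion; cell connectivity is
  not enforced (fragmentation is possible and logged implicitly through
  cluster statistics).

## Invasion metrics

Per replicate the package reports the population-mean total path length
$d_{total}$ (centroid displacements summed per MCS), net translocation
$d_{net}$ (straight-line displacement start → end; always
$\le d_{total}$), radius of gyration about the initial population centre
(scattering), percent ECM degradation (fibre pixels lost relative to the
initial count), and the cluster count / size distribution
(collective vs single-cell invasion).

## Scenario presets and replicate design

`preset()` returns the reference condition grids: the cell–cell adhesion
sweep at λ = 0.05 (`fig2`), the adhesion × secretion-rate grid (`fig3`),
the adhesion × fibre-density grid at λ = 0.05 and at the two-fold rate
0.1 (`fig4`, `fig4_high_lambda`), and the proteolysis-free random vs
aligned comparison (`fig5`), each with 1800 MCS and 10 replicates at full
scale. Replicate $r$ uses seed `base_seed + r`, so the same meshes recur
across conditions — a paired design that sharpens rank-based
comparisons (`compare_conditions()`, one-sided Mann–Whitney at α = 0.05,
matching the mean ± SEM reporting convention of this literature).

Desk-scale mode (`scale = 0.5`) shrinks the lattice to 250 × 250 px with
ξ scaled by the area ratio; the aggregate is kept at full size. The
package's stochastic regression tests run in this mode. Slow observables
need the full 18-h horizon: aggregate fission into clusters develops on
a ~1000-MCS timescale, so the adhesion sweep is tested at 1800 MCS with
5 replicates, while the secretion-rate and fibre-density sweeps run at
600 MCS. The proteolysis-free orientation comparison uses 900 MCS and 10
replicates: contact guidance needs travel time to separate the aligned
and random conditions at every point of the 3 × 3 grid. These problem
sizes are the package's test design, chosen so that each ordering is
measured in a regime where it is dynamically expressed while the suite
stays fast.

## What the generator emulates — and what it does not

The synthetic meshes emulate fibre density (via count), orientation
(random vs aligned) and steric hindrance; they do not model fibre
mechanics (bending, displacement, strain stiffening), crosslink density
as an explicit variable, 3D pore topology, or matrix heterogeneity.
Cells are a single phenotype: no division, no cell supply from a primary
site, no chemotaxis toward MMP gradients (the field acts only on ECM).
Passing tests therefore demonstrate the model's internal consistency and
the direction of parameter effects under these idealizations, not
quantitative agreement with any particular experimental matrix.

## Known limitations

* With the printed contact-energy table, cell–cell adhesion at
  $J_{cc} = 40$ is still below the dispersal threshold
  ($J_{cc} < 2 J_{cf}$), so aggregate break-up is motility-driven and
  slow (a few clusters by 18 h rather than full scattering). Orderings
  that depend on strong single-cell dispersal — most visibly
  "ECM degradation is maximal at the lowest cell–cell adhesion" — are
  only partially reproduced: medium adhesion ($J_{cc} = J_{ce} = 16$),
  where cells wet fibres maximally while staying connected, secretes and
  degrades the most in this implementation.
* Percent degradation saturates in λ beyond ≈ 0.05/s at fixed geometry,
  because secretion is limited by the cell–fibre contact area: once
  local fibre is consumed faster than cells advance, additional
  secretion rate adds little. The λ = 0.01 → 0.05 contrast is robust.
* Net translocation is only weakly sensitive to λ and to fibre density
  in this implementation: at the reference densities (ξ ≤ 1000, ~7 %
  pixel coverage) the calibrated cells are deformable enough to thread
  the pore network without proteolysis, so migration is not
  track-limited. Reproducing strong λ- and ξ-dependence of translocation
  would require a far stiffer/colder membrane regime, which the two
  calibration criteria above exclude (channel speed collapses below
  23 µm/h before the mesh becomes impassable). Density and proteolysis
  effects therefore appear mainly in the degradation and secretion
  observables, not in translocation.
* The acceptance temperature and motility strength are calibrated
  jointly (see above); absolute energies are therefore not comparable to
  other CPM implementations, only orderings and the calibrated speeds
  are.
* The forward-Euler solver requires $D\,\Delta t/\Delta x^2 \le 0.25$;
  `mmp_params()` enforces this at construction.

## Numerical details worth knowing

* Energies are evaluated locally per attempt and agree with a full
  recompute to < 1e-9 kT (property-tested), including across cell-death
  moves: a vanished cell keeps its constraint penalties in the total so
  that the energy stays a state function.
* The motility term is implemented as the exact centroid-shift work:
  gaining pixel $q$ moves the centroid by $(q - c)/(a + 1)$, losing it
  by $(c - q')/(a - 1)$; polarities are frozen between the per-MCS
  updates, which is what makes local/global consistency exact.
* All randomness flows through R's RNG (`set.seed` + the engine drawing
  from the same stream), so runs, sweeps and written CSVs are
  reproducible bit-for-bit given a configuration.
* CSV output is written at 6 significant digits for cross-platform byte
  stability.

## A worked micro-example

```{r example}
lat <- build_lattice(generate_fibre_mesh(150, "random", seed = 1,
                                         lattice_px = 250),
                     build_initial_aggregate(lattice_px = 250))
lat
st <- initialize_state(lat, energy_params(J_cc = 16),
                       mmp_params(lambda = 0.05))
res <- run_simulation(st, 25, seed = 1)
tail(res$series[, c("mcs", "n_accepted", "n_degraded", "fibre_px",
                    "mmp_total", "pde_substeps")], 3)
metrics_report(res, initial_fibre_px = sum(lat$sigma == -1L),
               centre_um = c(250, 250))
```
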