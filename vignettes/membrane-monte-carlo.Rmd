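---
title: "Coupled membrane and molecular Monte Carlo: model and methods"
author: "MembraneMC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled membrane and molecular Monte Carlo: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MembraneMC)
```

# Overview

MembraneMC couples two stochastic layers:

* **molecular dynamics** — ideal-gas point particles flying ballistically
  between specular reflections, and surface-bound molecules diffusing on
  triangulated membranes and binding across a small gap; and
* **membrane dynamics** — deformable triangulated meshes whose vertices
  move by Metropolis Monte Carlo under stretching elasticity, adhesion
  tethers and a volume-restoring pressure displacement.

The coupling runs in both directions. Particle collisions move a piston
membrane; receptor–ligand bonds tether a cell membrane to a surface and
bias its thermal moves; membrane shape in turn carries the molecules
that live on it. One iteration represents 1 µs; lengths are µm, areas
µm², volumes µm³, and all energies are expressed in units of kT
(`beta = 1`).

# Energies and the Metropolis rule

A proposed vertex move with energy change $\Delta E$ is accepted with
probability $\min(1, e^{-\Delta E})$; energy-lowering moves are always
accepted (`metropolisAccept()`). Moves are isotropic Gaussian
displacements of a single vertex (standard deviation `sigma` per axis),
attempted once per free vertex per iteration in a shuffled order.
Clamped boundary vertices and rigid meshes never move. Moves are
rejected outright when they leave the movement-space box, collapse an
incident face below `areaTol`, or would cross another mesh.

**Stretching elasticity.** Each face carries a quadratic penalty against
its frozen rest area $a_i$:

$$H_{el} = \sum_i \frac{\kappa}{2 a_i^2} (A_i - a_i)^2,$$

with $\kappa = \kappa_1 \kappa_2 / (\kappa_1 + \kappa_2)$ the series
("effective") rigidity of the two apposed membrane layers — when one is
much stiffer, the softer one dominates. Because each face's area
depends only on its three vertices, the energy change of a single-vertex
move is exactly local to the incident fan, which keeps sweeps cheap.

**Bending energy (optional, off by default).** A discrete Helfrich
energy is provided for analysis:
$2\kappa_B \sum_v |L\mathbf{x}_v|^2 / (4 A_v)$, where $L$ is the
cotangent Laplace–Beltrami operator applied to the coordinate field and
$A_v$ the barycentric one-ring area (one third of the incident face
area). The normalisation is fixed by two exact requirements: a flat
sheet scores zero, and a refining sphere converges to the smooth
Helfrich value $8\pi\kappa_B$ independent of radius (subdivision levels
1–4 of the unit icosphere give 23.41, 24.69, 25.02, 25.10 against
$8\pi \approx 25.13$). The membrane *dynamics* deliberately use
stretching only; the bending term errors unless explicitly enabled, so
it can never silently contribute.

**Pressure displacement.** Closed cells restore their enclosed volume:
once per iteration every free vertex is displaced by
$D_P = c\,(\Delta V)^2 / V_{int}$ along its normal — inward when the
volume grew beyond the initial $V_{int}$, outward when it shrank. This
is a deterministic restoring step, not a Metropolis move; `c` sets its
strength.

**Adhesion tethers.** A receptor–ligand bond is a quadratic spring
between the receptor's current embedded position and the ligand anchor:
$\tfrac12 k (d - d_0)^2$ with
$k = 2\,E_{bond}/\delta^2$, i.e. stretching a bond by the reference
extension $\delta$ beyond its rest length $d_0$ costs $E_{bond}$ kT.
Bond energies enter the Metropolis balance of the membrane, which is
what pulls the cell onto the surface.

# Molecular layers

**Ideal-gas particles.** Particles fly $v\,\Delta t$ with specular
reflections off the chamber walls and the piston plane, implemented by
coordinate folding so arbitrarily many reflections per step are exact.
Each piston hit transfers an impulse $2 m |v_z|$ to its side of the
piston. Velocities are resampled each iteration from a Maxwell-like
per-axis Gaussian, giving diffusive long-time behaviour with
well-defined per-collision momenta.

**The piston.** The piston is massless and overdamped: it translates by
`mobility × (impulseBottom − impulseTop)` per iteration. A deliberate
design point: per-compartment molecular *speeds* are configured
directly (`speedBottom`, `speedTop`), the way particle-based
reaction-diffusion simulators assign per-species diffusion speeds
independently of any bookkeeping mass. With equal speeds and unequal
masses, the heavy compartment transfers more momentum per collision at
the same collision rate, and the piston drifts away from it. Had we
instead drawn both compartments at equal *temperature*
($\sigma_v \propto m^{-1/2}$), equipartition would make the mean
impulse rate mass-independent and no drift would occur at all — the
equal-speed convention is what makes particle mass observable in this
experiment. With equal speeds *and* equal masses the piston performs an
unbiased random walk; the walk step is proportional to the mobility,
which is the one free constant to calibrate against a measured piston
diffusion coefficient.

**Surface molecules.** Molecules live on mesh faces in barycentric
coordinates. An unbound molecule takes an in-plane Gaussian step with
per-axis variance $2 D \Delta t$; a step crossing an edge is unfolded
into the adjacent face by rotating about the shared edge, so molecules
follow the curved surface exactly and never leave it (open boundaries
reflect specularly). Bound molecules are immobilised.

**Pairing and binding.** Candidate receptor–ligand pairs are all
unbound pairs within the pairing distance (an exact fixed-radius
neighbour query on a uniform grid), reduced to a one-to-one matching
greedily by increasing distance. Each matched pair binds with
probability $1 - e^{-k_{on}\Delta t}$; bonds are permanent by default
(`offRate = 0`), and both partners are immobilised.

# Scenarios

| scenario | driver | readout |
|---|---|---|
| `runPiston()` | collision impulses | piston height, work $nRT\ln(V_2/V_1)$ |
| `runFluctuatingMembrane()` | elastic relaxation of a spiked, perimeter-clamped sheet | peak height, elastic energy |
| `runCellSpreading()` | binding feedback between receptors and an activating surface | contact area, cumulative bonds |
| `runCellCell()` | rigid-sphere approach with plastic denting and pressure | contact area, minimum separation |

Cell spreading is the emergent centrepiece: nothing in the model
prescribes spreading. The ruffled cell hovers a small gap above the
surface; thermal membrane fluctuations bring patches within the capture
radius, local bonds form, tethers hold the membrane down, neighbouring
faces come into range, and the contact zone zippers outward while
pressure conserves cell volume. Removing the ligands
(`withLigands = FALSE`) removes spreading entirely, which is the
ablation control.

# Default parameters and their rationale

| parameter | default | rationale |
|---|---|---|
| chamber side | 0.5 µm | sub-cellular compartment scale |
| particles/compartment | 2000 | collision statistics at interactive cost |
| masses | 0.1 / 0.01 | 10× contrast makes the drift sign unambiguous |
| per-axis speed | 0.02 µm/µs | a few chamber crossings per 1000 iterations |
| piston mobility | 5×10⁻⁶ | drift resolvable in 5000 iterations but ≪ chamber |
| cell radius | 2 µm | lymphocyte scale |
| icosphere subdivisions | 4 (2562 vertices) | edge ≈ 0.09 µm, resolves the contact rim |
| ruffle amplitude | 0.05 µm | must stay comparable to the pairing distance: much larger ruffles reduce the initial contact to one spike whose area can never seed a bond, and spreading cannot nucleate |
| gap | 0.02 µm | within thermal-fluctuation reach of the capture radius |
| molecules/surface | 5000 | ≈ 100 µm⁻², high enough that the contact cap holds tens of receptors |
| receptor D | 5 µm²/s | membrane-protein mobility scale |
| on-rate | 2×10⁶ s⁻¹ | binds within a few µs of proximity |
| pairing distance | 0.05 µm | receptor–ligand capture radius |
| per-bond energy | 5 kT at 0.05 µm extension | bonds survive thermal kicks but single bonds can still break membrane moves |
| κ₁, κ₂ | 20–40, 10⁶ kT | soft membrane against a quasi-rigid partner; effective rigidity ≈ the soft value |
| sigma (node moves) | 0.006–0.012 µm | ≈ 10% of edge length; acceptance in the 30–70% band |
| areaTol, crossTol | 10⁻⁹ | numerical guards only |

Problem sizes (2562-vertex cells, 5000 molecules, 1000–5000 iterations)
are this package's own choice of a desk-scale configuration: every
scenario runs in seconds to tens of seconds on one CPU.

# Numerical verification

The test suite pins the implementation to independent references:
closed-form energies on hand-built meshes; a from-scratch cotangent
bending oracle; locality of the Metropolis $\Delta E$ against full-mesh
recomputation; single-vertex sampling variance against deterministic
3-D quadrature of $e^{-E}$ (agreement within a few percent at $10^5$
sweeps); neighbour search against $O(n^2)$ brute force; surface-walk
mean-squared displacement against $4Dt$; and bitwise seeded
reproducibility of every scenario.

# Limitations

* Bonds are permanent (`offRate` is accepted but only 0 is exercised);
  synapse patterns that need unbinding kinetics are out of scope.
* The membrane dynamics carry no bending stiffness — shapes are
  regularised by stretching against frozen rest areas, so the sheet has
  soft bending modes and relaxation of sharp features is near-linear
  rather than exponential.
* The piston experiences mean reversion through the volume dependence
  of the collision rate; at large mobility its trajectory is
  Ornstein–Uhlenbeck-like and only short-lag statistics are diffusive.
* Vertex connectivity is fixed (no remeshing, no fission/fusion), and
  the deterministic pressure step is a model of volume regulation, not
  a thermodynamically consistent barostat.
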