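---
title: "The coarse-grained brush/nanoparticle model and its analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The coarse-grained brush/nanoparticle model and its analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npbrush)
```

## The physical system

`npbrush` simulates a polymer brush — linear bead-spring chains end-grafted
to a surface densely enough that they stretch away from it — in contact with
a solution of spherical nanoparticles that bind to the polymer beads.  Two
geometries are supported: a planar slab (chains grafted on the bottom wall of
a box periodic in x and y) and an inside-grafted cylinder (a nanopore of
radius R whose axis lies along x, immersed in a fully periodic box).  The
motivating application is nanovalve-like gating: at low temperature the
nanoparticles partition into the brush and collapse it, opening the pore; at
higher temperature they desorb and the brush re-expands and closes it.

Everything is expressed in reduced Lennard-Jones units:
monomer diameter `sigma_m`, interaction scale `epsilon`, particle mass `m`
and Boltzmann's constant all equal 1, so time is measured in
`tau = sigma * sqrt(m / epsilon)` and temperature in `epsilon / kB`.

## Interactions

Three non-bonded pair potentials and one bond potential define the model:

* **monomer-monomer**: the purely repulsive truncated-and-shifted
  Lennard-Jones (WCA) form
  `U(r) = 4 eps [(sigma_m/r)^12 - (sigma_m/r)^6] + eps` for
  `r < 2^(1/6) sigma_m`, zero beyond.  This is the good-solvent (athermal)
  choice: there is no attractive well, so the pure brush's equilibrium
  structure is essentially independent of temperature.
* **bonded monomers**: the FENE spring
  `U(r) = -(k r0^2 / 2) ln[1 - (r/r0)^2]` with `k = 30`, `r0 = 1.5`,
  acting *in addition to* the WCA repulsion (the Kremer-Grest convention).
  A bond reaching `r0` is a hard error — the integrator aborts rather than
  clamp, because an overstretched bond means the time step no longer
  resolves the dynamics.
* **nanoparticle-nanoparticle**: the same WCA repulsion with
  `sigma_m -> sigma_n`.
* **monomer-nanoparticle**: a radially displaced Lennard-Jones potential
  `U(r) = 4 eps_b [(sigma_m/(r-Delta))^12 - (sigma_m/(r-Delta))^6]` for
  `r < 3 sigma_m`, with `Delta = (sigma_n - sigma_m)/2`.  Its well has depth
  exactly `eps_b`, attained at `r = Delta + 2^(1/6) sigma_m`; the offset
  makes the contact distance grow with the nanoparticle diameter while the
  well depth stays `eps_b`.

Because the repulsions are nearly hard-core and the only finite energy scale
is `eps_b`, every pairwise Boltzmann factor — and hence every equilibrium
property — depends on `eps_b` and `T` (approximately) only through the ratio
`eps_b / T`.  The package's `scaling_collapse()` quantifies how well h–c
curves at different `(eps_b, T)` pairs with equal ratio coincide.

Two numerical details are deliberate:

* The monomer-nanoparticle potential is *not* energy-shifted at its cutoff
  by default; the jump there is `4 eps_b (3^-12 - 3^-6) ~ -0.0055 eps_b`,
  far below thermal noise, and the unshifted form is the model's printed
  definition.  A `shift_nm` flag restores continuity if wanted.
* The cutoff stays `3 sigma_m` for both nanoparticle sizes, even though for
  `sigma_n = 3` the well is displaced outward; the tail beyond the cutoff is
  correspondingly larger there, which is part of the model definition, not
  an approximation we chose.

## Walls

Walls are smooth surface potentials of the same WCA form applied to the
particle's distance to the wall, rather than layers of explicit wall atoms.
In the slab both z-walls repel monomers and nanoparticles.  The cylinder
wall repels monomers only and exerts no force on nanoparticles at all — a
species-selective, perfectly permeable pore wall.  This is an idealization
of a porous wall built from explicit atoms; it keeps the contract (monomers
confined, nanoparticles exchanging freely with the outside solution) with
one fewer length scale to tune.

## Initial configurations

Graft points are drawn uniformly at random on the grafting surface with a
minimum separation of `sigma_m` (random sequential insertion).  Chains start
*fully stretched* with bond length `0.97 sigma_m` — near the minimum of the
combined FENE + WCA bond energy, so the start exerts no force spikes — which
prevents the brush from being trapped in entangled metastable states.

In the planar geometry stretched chains simply point along +z and
nanoparticles are inserted uniformly (again with minimum separation) in the
region above them.  In the cylinder, straight radial chains are impossible
at large N: all chains would have to converge on the axis, where there is
no volume.  Each chain is therefore grown as a nearly straight line that
descends radially while advancing along the axis, with a per-chain random
radial descent rate chosen so chain ends spread between the axis region and
mid-radius, small angular jitter, and hard rejection of any bead placed
within `0.85 sigma_m` of an existing one.  Chains remain fully extended
(every bond exactly `0.97 sigma_m`) and every freshly built configuration
satisfies a no-overlap bound (no single pair energy above `50 epsilon`).
Nanoparticles start in the solution annulus outside the cylinder and
equilibrate across the permeable wall during the run.

The first bead of each chain is *frozen* at its graft point: it exerts
forces but is never integrated or thermostatted.  Lz for the slab defaults
to `1.5 N sigma_m`, leaving a solution reservoir above the stretched chains.
The cylinder's box cross-section is `2R + 2 box_pad` with `box_pad = 10` by
default (so the published pore radius 45 gives a 110 x 110 cross-section);
the pad is recorded in the configuration, not hard-coded.

## Dynamics

The integrator is velocity-Verlet with a Langevin thermostat, implemented
as the BAOAB splitting: half kick, half drift, an exact Ornstein-Uhlenbeck
velocity refresh `v <- c1 v + sqrt(T (1 - c1^2)) xi` with
`c1 = exp(-Gamma dt)`, half drift, half kick.  With `Gamma = 0` the O-step
disappears and the scheme reduces to plain velocity-Verlet, which is how the
energy-conservation tests run.  Defaults are `dt = 0.005 tau` and
`Gamma = 1/tau`; the thermostat acts on all mobile particles (monomer beads
2..N and nanoparticles), not on frozen graft beads.  Each run draws its
noise from a dedicated 64-bit Mersenne Twister stream seeded from the run's
seed, so replicates are independent and a run is reproducible bit-for-bit
on a given platform.

Forces come from Verlet neighbor lists (pair-type-specific cutoffs plus a
`0.4 sigma` skin) built from a cell grid and rebuilt whenever any particle
has moved more than half the skin.  The engine aborts — with the step index
— on overstretched bonds, wall escapes, hard-core overlap or non-finite
coordinates.

## Observables

Density profiles are time-averaged histograms (default bin width
`0.25 sigma`, fine enough to resolve N = 30–100 brushes without excessive
noise) declared with an explicit normalization:

* planar monomer profile: `int_0^Lz psi(z) dz = sigma_g N`;
* planar nanoparticle profile: integral 1;
* cylindrical radial profile, with r measured from the grafting wall:
  `2 pi L int_0^R (R - r) psi(r) dr = N n_ch` (each bin divided by its
  shell volume; bins at the axis, where the Jacobian vanishes, are
  excluded with a warning);
* projection profile: each monomer's displacement from its own chain's
  anchor is projected on the anchor's inward surface normal and histogrammed
  like the planar profile (`int psi(s) ds = sigma_g N`).  Projections can
  exceed R, which is what makes this profile a meaningful height measure
  when chains pass the pore axis.

Profiles are treated as piecewise-constant in their bins, so the defining
integral is `sum(value * bin_width)` (with the shell-volume weight in the
radial case) and the cumulative distribution is piecewise linear.  The
**brush height** is the 0.995 quantile of that cumulative distribution,
linearly interpolated inside the straddling bin with ties broken toward
smaller h; the 0.995 convention follows the classic bead-spring brush
literature calibration.  The **solution concentration** is the time-averaged
number of nanoparticles in the solution region divided by its volume:
outside the cylinder (`V_box - pi R^2 L`) in the pore geometry, and above
the brush (`z > h`, computed self-consistently from the monomer profile of
the same trajectory) in the slab — the slab solution region is not part of
the model definition, so the package defines it to mirror the cylinder's
"outside the brush" rule.

`hc_diagram()` aggregates replicate state points into h-vs-c curves;
`scaling_collapse()` interpolates curves sharing an `eps_b/T` ratio onto the
overlap of their concentration ranges and reports the maximum and mean
absolute height discrepancies.

## Desk-scale study conditions

The published protocol (100 or 400 chains of 100 beads, 4e6 + 1e6 steps,
five replicates per state point) is a cluster workload; it ships as the
`paper-flat` / `paper-cylinder` presets.  The package's own experiments and
tests run a reduced desk protocol chosen once:

* flat brush: 16 chains of N = 40 at `sigma_g = 0.0625` (box 16 x 16 x 60),
  192 nanoparticles where present — the same 0.3 nanoparticle:monomer ratio
  as the published flat systems, which puts the equilibrium solution
  concentration on the compression branch of the h–c curve near T = 1;
* cylinder: 40 chains of N = 25 in a pore of radius 12 with a 6-sigma
  solution pad and 300 nanoparticles, so chains reach past the axis as in
  the published pore;
* pure-brush runs use 1.4e5 equilibration steps (9e4 at T >= 2, where the
  stretched start decays faster) plus 6e4 production steps.  Nanoparticle
  systems use 1.5e5 equilibration plus 6e4 production at T >= 1; below
  T = 1, where nanoparticle partitioning is slowest and the brush height
  fluctuates slowly near the collapse transition, they get 2.8e5
  equilibration plus 8e4 production.  Deeply collapsing state points
  (eps_b/T >= 1.4) nucleate their collapse slowly and irregularly across
  replicates, so they get 3.4e5 equilibration steps;
* five replicate seeds per state point, with the replicate standard
  deviation as the error estimate, as in the full-scale protocol.

At this scale the desk brush reproduces the full-scale phenomenology —
athermal pure brush, low-T collapse with nanoparticles, loss of the
collapse by T = 1.5, and the `eps_b/T` collapse of state points — at brush
heights around 18 sigma rather than 42.  What the reduced scale does *not*
reproduce are the published absolute numbers (pure heights ~42 flat / ~47
cylinder, minimum heights 24.31 and 36.87): those belong to the
100-bead-chain systems behind the `paper` presets.  The synthetic-data
builders likewise emulate only this model's idealizations — monodisperse
chains, implicit solvent, smooth walls — so passing tests say nothing about
polydispersity, hydrodynamics or explicit-atom wall effects in real
systems.

## Known limitations

* Dynamics are Langevin in an implicit solvent: no hydrodynamic
  interactions, so kinetics (equilibration times) are not those of a real
  solvated system, only the equilibria.
* The radial profile is meaningless once chains cross the pore axis (the
  Jacobian vanishes); the projection profile is the height measure there,
  and its per-chain inward-normal construction is this package's explicit
  operationalization of the projection method.
* At the desk scale the 0.995-quantile height carries a few tenths of a
  sigma of replicate noise; statements about temperature insensitivity are
  made on replicate means.
* Nanoparticle insertion assumes a dilute-enough solution region; random
  sequential insertion fails loudly (packing error) rather than degrade.
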