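# npbrush

Coarse-grained molecular dynamics of polymer brushes with attractive
nanoparticles, and the analysis needed to study their **temperature
response** — in R, with the force kernels in C++.

## The problem

A polymer brush is a layer of linear chains end-grafted to a surface at a
density high enough that the chains stretch away from it.  In a good
solvent a pure brush is *athermal*: its only interactions are effectively
hard-core repulsions, every pairwise Boltzmann factor is 0 or 1, and the
equilibrium structure barely changes with temperature.  Add spherical
nanoparticles that bind to the monomers with well depth `eps_b`, however,
and the structure becomes strongly temperature dependent: at low `T`
nanoparticles partition into the brush and collapse it; raising `T` drives
them back into solution and the brush re-expands.  Grafted inside a
cylindrical nanopore, this is a thermally gated nanovalve.  Because the
only finite energy scale is `eps_b`, equilibrium properties depend on
`eps_b` and `T` (to a good approximation) only through the ratio
`eps_b / T`.

`npbrush` is for anyone who wants to simulate and analyze these systems at
a scale from desk to cluster: it implements the model, the builders, the
dynamics, and the standard observables.

## The model

* **Monomer–monomer**: purely repulsive truncated-and-shifted LJ (WCA),
  `U(r) = 4ε[(σ/r)¹² − (σ/r)⁶] + ε` for `r < 2^{1/6}σ` (good solvent).
* **Bonds**: FENE, `U(r) = −(k r₀²/2) ln[1 − (r/r₀)²]`, `k = 30`,
  `r₀ = 1.5`, on top of the WCA repulsion (Kremer–Grest chains).
* **Nanoparticle–nanoparticle**: WCA with `σ → σ_n`.
* **Monomer–nanoparticle**: displaced LJ
  `U(r) = 4ε_b[(σ/(r−Δ))¹² − (σ/(r−Δ))⁶]` for `r < 3σ`,
  `Δ = (σ_n − σ)/2`; well depth exactly `ε_b` at `r = Δ + 2^{1/6}σ`.
* **Dynamics**: velocity-Verlet + Langevin thermostat (BAOAB splitting),
  `δt = 0.005τ`, damping `Γ = 1/τ`, NVT; Verlet neighbor lists; smooth
  WCA walls (the cylinder wall repels monomers and is transparent to
  nanoparticles — a permeable pore).
* **Observables**: density profiles with declared normalizations
  (`∫ψ(z)dz = σ_g N` flat; `2πL∫(R−r)ψ(r)dr = N n_ch` radial; projection
  onto each chain's inward anchor normal for brushes that cross the pore
  axis; nanoparticle profiles normalized to 1), brush height as the 0.995
  quantile of the cumulative profile, solution nanoparticle concentration,
  h–c diagrams with replicate spreads, and an `eps_b/T` collapse score.

All quantities are in reduced LJ units (`σ = ε = m = k_B = 1`).  See the
methods vignette (`vignettes/brush-nanoparticle-model.Rmd`) for the full
account, including every default and its rationale.

## Worked example

A desk-scale flat brush (16 chains of 40 beads at grafting density 0.0625)
with 192 attractive nanoparticles at `T = 1`, `eps_b = 1`:

```r
library(npbrush)
sys <- build_planar(n_chains = 16, N = 40, n_np = 192,
                    temperature = 1, seed = 1)
#> particle_system: 640 monomers in 16 chains, 192 nanoparticles
#> planar_slab geometry, box 16 x 16 x 60, sigma_g = 0.0625
ff <- force_field(sigma_n = 1, eps_b = 1)
tr <- run_md(sys, ff, md_params(temperature = 1, n_steps_equil = 1.8e5,
                                n_steps_prod = 4e4, snapshot_stride = 500,
                                seed = 1))
prof <- profile_flat(tr)
#> density_profile (flat_psi): 240 bins of width 0.25, integral = 2.5
h <- brush_height(prof)
cc <- solution_concentration(tr, h = h)
#> brush height h = 16.38 sigma
#> solution concentration c = 0.0091 sigma^-3
```

The profile integral is `σ_g · N = 0.0625 × 40 = 2.5`, as its
normalization demands.  The brush height 16.4σ is well below the pure
brush's ≈18σ at this temperature: with `eps_b/T = 1` the nanoparticles
have partitioned into the brush and compressed it.  Re-running at
`temperature = 1.5` (ratio 0.67) gives a brush back at its pure height —
the collapse is lost, which is the temperature-gating effect.  Sweeps over
`(T, n_np, seed)` with per-state-point directories, resumability and h–c
aggregation are handled by `cmd_run()` / `cmd_analyze()` (see
`preset_config("desk-flat")` and the CLI wrapper in `inst/cli/npbrush.R`);
the published full-scale protocols ship as the `paper-flat` and
`paper-cylinder` presets.

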