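# cgresin

Coarse-grained molecular simulation of photopolymerizable dental resins
in R.

Light-cured dental composites (and many 3D-printing resins) are based on
mixtures of the bulky dimethacrylate **Bis-GMA** and its low-viscosity
diluent **TEGDMA**. Their key engineering properties — density,
volumetric curing shrinkage, final double-bond conversion, glass
transition — are governed by the crosslinked network that forms during
radical photopolymerization, which no experiment observes directly.
`cgresin` is a self-contained simulator for this system at
Martini-3-style coarse-grained resolution, aimed at method development
and desk-scale numerical experiments:

* **Molecule templates**: Bis-GMA (15 beads, 37 heavy atoms; rigid
  3-bead aromatic rings held by SHAKE constraints) and TEGDMA (6 beads,
  20 heavy atoms), with the full tabulated set of harmonic bonds
  `V = k/2 (r - r0)^2`, harmonic angles `V = k/2 (θ - θ0)^2`, and
  periodic dihedrals/impropers `V = k (1 + cos(nφ - φ0))`.
* **System building**: formulation arithmetic from a Bis-GMA weight
  fraction, and random packing in the curing protocol's insertion order
  (initiators, then Bis-GMA, then the remaining TEGDMA).
* **MD engine**: velocity Verlet (20 fs default timestep), stochastic
  velocity-rescaling thermostat, isotropic weak-coupling barostat,
  SHAKE/RATTLE ring constraints, steepest-descent minimizer, and a
  temperature-sweep driver.
* **Simulated chain-growth polymerization**: bonds form between
  *active* (radical) and *reactive* (unreacted methacrylate) beads
  within a 0.55 nm cutoff; the active label transfers to the partner;
  the topology gains the backbone bond/angle terms; curing alternates
  bonding attempts with minimization and relaxation MD and stops after
  a budget of consecutive empty attempts (propagation only — no
  termination reactions).
* **Analyses**: density (real molar masses), volumetric shrinkage,
  double-bond conversion, glass-transition estimation by two-segment
  linear fits of density–temperature sweeps, bonded-distribution
  histograms, and centre-of-geometry mapping of all-atom trajectories.

The bundled nonbonded table is a clearly labelled synthetic stand-in in
the Martini 3 style (the published interaction matrix is not
redistributed here); swap in real parameters with
`load_forcefield("your.ff")`. See the methods vignette
(`vignettes/cgresin-methods.Rmd`) for the model, all numerical choices,
and limitations.

## Worked example

Fifty-fifty formulation arithmetic reproduces the study's molecule
counts exactly:

```r
library(cgresin)
formulation_counts(0.5)
#> Formulation: 500 TEGDMA + 279 Bis-GMA (requested 50 wt%, realized 50.0 wt% Bis-GMA)
```

A desk-scale version of the full curing pipeline (45 TEGDMA + 25
Bis-GMA, 645 beads, 4 initiators — minutes of runtime):

```r
ff  <- load_forcefield()
f   <- formulation_counts(0.5, mass_basis = 90)
sys <- pack_box(f, n_active = 4, target_density = 0.8, seed = 42)
st  <- minimize(sys$state, sys$topology, ff, force_tol = 50, max_steps = 800)

ens <- ensemble_spec(temperature = 298, pressure = 1,
                     timestep_fs = 10, tau_t = 0.2, tau_p = 3)
eq  <- run_md(st, sys$topology, ff, ens, 4000, seed = 1)
density_gcm3(eq$state, sys$topology)          # ~1.17 g/cm^3 at 298 K / 1 bar

sch  <- polymerization_schedule(bonding_cutoff = 0.55, relax_steps = 400,
                                retry_steps = 200, max_failed_attempts = 12,
                                seed = 7)
cure <- polymerization_run(eq$state, sys$topology, ff, sch, ens)
conversion(cure$topology)                     # fraction of C=C consumed
shrinkage(prod(eq$state$box), prod(cure$state$box))  # percent

sw  <- temperature_sweep(cure$state, cure$topology, ff, n_steps = 8000,
                         n_windows = 16, seed = 3, timestep_fs = 10,
                         tau_t = 0.2, tau_p = 3)
fit_tg(sw, min_points = 4)
```

At this reduced scale (seed 1 throughout) the pipeline prints a resin
density of 1.175 g/cm³, 47.1% conversion with 62 polymer bonds, 10.9%
volumetric shrinkage, a cured-network density of 1.318 g/cm³, and
two-segment fits placing the resin's glass transition near 237 K and the
cured network's above it near 253 K. Tiny boxes and short sweeps carry
tens-of-kelvin uncertainty on Tg — these runs demonstrate the machinery
and the physical orderings, not converged material predictions (see the
vignette).

A thin command-line wrapper over the same stages ships in
`inst/scripts/cgresin`:

```sh
Rscript inst/scripts/cgresin all --config inst/extdata/example_config.yaml
```

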