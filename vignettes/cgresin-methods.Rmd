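---
title: "Coarse-grained curing simulations of Bis-GMA/TEGDMA resins with cgresin"
author: "cgresin authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained curing simulations of Bis-GMA/TEGDMA resins with cgresin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`cgresin` simulates the photopolymerizable organic phase of dental
composites — mixtures of the bulky dimethacrylate Bis-GMA and its
low-viscosity diluent TEGDMA — at Martini-3-style coarse-grained
resolution, and generates crosslinked networks with a simulated
chain-growth polymerization algorithm. Groups of two, three or four heavy
atoms map onto tiny, small and regular beads (36, 54 and 72 amu for the
dynamics; real molar masses, 512.59 and 286.32 g/mol, whenever a density
is reported). Seven standard bead types are used: SC4 for the reactive
methacrylate groups, N4a for the ester groups, TP1 and TN2a on the
Bis-GMA arms, TC5 for the aromatic ring beads, SC2 for the isopropylidene
bridge, and SN3a for the glycol ethers of TEGDMA.

TEGDMA is a linear 6-bead chain (20 heavy atoms); Bis-GMA has 15 beads
(37 heavy atoms): two symmetric methacrylate arms, two aromatic rings of
three TC5 beads each, and one bridge bead. All bonded-term lists of
Bis-GMA are invariant under the arm-swapping permutation.

Bonded interactions are harmonic bonds `V = k/2 (r - r0)^2`, harmonic
angles `V = k/2 (theta - theta0)^2` (deviation in radians), and periodic
dihedrals/impropers `V = k (1 + cos(n phi - phi0))`. The harmonic
prefactor convention is a force-field switch (`harmonic_prefactor`,
`"half"` by default, `"full"` for the `k (x - x0)^2` convention); the
`"half"` convention is consistent with the kJ/mol/nm² and kJ/mol/rad²
units of the parameter tables and with the GROMACS-style run files this
class of models is distributed with. Nonbonded interactions are 12-6
Lennard-Jones pairs, potential-shifted to zero at a 1.1 nm cutoff, with
1-2 and 1-3 neighbors excluded.

### Rigid aromatic rings

Each three-bead ring is kept rigid by two constrained bonds plus one
constrained angle — a rigid triangle. The two constrained edge lengths
are 0.229 nm (the edge adjacent to the ring bead that binds the arm's
TN2a bead, the longer one) and 0.197 nm. The tables that define the
model give no equilibrium value for the internal ring angle, so the
package fixes it at 60° (a near-equilateral triangle); under SHAKE the
angle is enforced as the equivalent third distance by the law of
cosines (0.2148 nm). Two improper dihedrals per ring (0°/65 kJ/mol and
180°/100 kJ/mol, n = 1) keep the ring planar with its substituents, and
two periodic dihedrals per ring (phi0 = 313°, k = 8.46 kJ/mol, n = 2, on
the 3-4-5-5 quadruples at the arm attachment) govern ring rotation. The
second quadruple of each ring runs across the rigid triangle's implied
third edge; the package's connectivity checks treat constrained-angle
outer pairs as connected for this reason.

### The nonbonded table is a labelled stand-in

The published Martini 3 interaction matrix is not reprinted in this
package. The bundled file
`inst/extdata/nonbonded_synthetic_martini3_style.ff` is a synthetic
stand-in in the same format and style: sigmas follow the
regular/small/tiny size-pair convention (0.47/0.41/0.34 nm self-pairs),
epsilons are plausible-scale values graded by chemical-class polarity.
Substituting the published matrix is a one-file swap
(`load_forcefield(path)`); everything downstream is parameter-agnostic.
With the bundled table the equilibrated 50 wt% resin lands near
1.17 g/cm³ at 298 K/1 bar, in the right territory for these resins, but
absolute densities should not be over-interpreted.

## Simulated polymerization

All methacrylate (label-1) beads are reactive; the radical-bearing chain
ends carry an active label. A bond forms whenever an active and a
reactive bead come within the bonding cutoff (0.55 nm, the 5.5 Å
criterion; boundary inclusive); the active label then transfers to the
partner so the chain can propagate. Newly formed backbone bonds get
k = 35000 kJ/mol/nm² at r0 = 0.31 nm; a backbone angle (125°,
350 kJ/mol/rad²) is added across any bead holding two polymer bonds, and
backbone–sidechain angles (80°, 50 kJ/mol/rad²) connect the new bond to
each endpoint's ester-side bond. No backbone dihedrals are added, for
numerical stability of the strained network.

The schedule alternates bonding attempts with relaxation: after ten
accumulated bonds the system is energy-minimized and run for 40000 MD
steps; an attempt that forms no bond triggers a 20000-step run; the
simulation terminates after 40 *consecutive* empty attempts (the counter
resets on any success — an interpretation choice, flagged here). Two
implementation details matter in practice:

* **A minimization follows every successful attempt**, not only the
  ten-bond cycles, and velocities are re-drawn from the thermostat
  temperature afterwards. Bonds may form at up to the cutoff distance —
  75% beyond their equilibrium length — and the staged
  minimize-then-run structure of chain-growth curing workflows is what
  keeps that from crashing the dynamics. Without the fresh velocities,
  the potential energy released by successive bond formations
  accumulates as heat faster than the thermostat can drain it.
* **Matching is greedy nearest-first**; each active bead forms at most
  one bond per attempt, each reactive bead is consumed at most once, and
  ties break toward the lowest bead index. A monomer's two methacrylate
  beads cannot react with each other directly (a degenerate short loop);
  network-mediated cyclization remains possible. Both rules are
  configurable.

Initiators are drawn from TEGDMA when the formulation has any (they are
inserted into the box first, then Bis-GMA, then the remaining TEGDMA),
otherwise from Bis-GMA. One of the two methacrylate beads of each
initiator is activated at random, and initiator double bonds count as
consumed for conversion accounting by default
(`count_initiators_as_reacted = TRUE`), mirroring the radical mechanism;
the flag reports the other convention when needed.

## The engine and its numerical choices

Velocity-Verlet at a 20 fs default timestep, a stochastic
velocity-rescaling thermostat (tau 1.0 ps), and an isotropic
weak-coupling barostat (tau 12 ps, compressibility 4.5e-5 1/bar) — the
coupling schemes are the package's own defaults, as the source protocol
names neither. SHAKE enforces the ring constraints each step using the
classic pre-step reference directions (using current directions instead
dissipates energy at first order in the timestep — measurably so), with
a RATTLE velocity projection after the second half-kick; the barostat's
isotropic rescaling is followed by a re-projection so that every frame
satisfies the constraint tolerance (1e-4 relative by default).

**A genuine stiffness of this parameter set.** The ring-rotation
dihedrals sit across the soft 3-4-5 angle (130°, 40 kJ/mol/rad²), whose
barrier to collinearity is only ~15 kJ/mol. When a quadruple passes near
collinearity the analytic dihedral force diverges as 1/sin² of the
flanking angle; the passages are rare but inject discrete energy kicks
that do not vanish with the timestep. (The model's own authors dropped
*backbone* dihedrals for exactly this class of reason.) The package
bounds the damage with a per-quadruple force cap (default
1000 kJ/mol/nm, `dihedral_force_cap` on the force-field object) that
rescales the four force contributions of a degenerate quadruple as a
unit, preserving zero net force and torque; away from degeneracy forces
are the exact negative energy gradient, which the test suite verifies
against central differences at 1e-5 relative tolerance. TEGDMA-only
systems are cleanly conservative at 20 fs (NVE drift ~1e-6 relative);
for Bis-GMA-containing production runs the package's own runs use a
10 fs timestep and a 0.2 ps thermostat coupling, which keeps the
steady-state kinetic temperature within a few percent of the set point
at desk scale. The residual heating bias shrinks with system size as the
per-event kick is shared across more degrees of freedom.

Other numerical choices: angle cosines are clamped into [-1, 1] before
`acos`; neighbor lists use a 0.2 nm skin with displacement-triggered
rebuilds over a blocked O(N²) minimum-image scan (appropriate for the
desk-scale systems this package targets); minimization is adaptive-step
steepest descent with SHAKE projection after every accepted move;
positions are stored unwrapped and wrapped only on file output, so
shrinkage and diffusion remain well defined.

## Observables

* `density_gcm3()` — real molar masses by default; Martini masses on
  request.
* `conversion()` — fraction of methacrylate beads consumed.
* `shrinkage()` — percent volumetric decrease; the reference volume used
  by the pipeline is the time-average over the last quarter of the
  pre-cure NPT run (an averaging-window choice of this package).
* `fit_tg()` — two free straight lines, breakpoint chosen by scanning
  all interior split points (at least 3 points per side) for minimal
  total squared residual; the reported Tg is the intersection of the two
  lines. On noiseless piecewise-linear input the breakpoint is recovered
  exactly; collinear input raises a degenerate-fit warning.
* `bonded_distributions()` — normalized bond/angle/dihedral histograms
  with a prominence-based mode count for the bimodality of the ring
  dihedrals.
* `cg_map()` — centre-of-geometry mapping (unweighted atom means) of
  all-atom trajectories, with strict assignment validation.

## What the synthetic boxes do and do not show

The generator's defaults are the study conditions: formulation counts
from the nine-tuple table at a 1000-TEGDMA-equivalent mass basis (e.g.
50 wt% Bis-GMA is 500 TEGDMA + 279 Bis-GMA = 7185 beads), insertion
order initiators → Bis-GMA → remaining TEGDMA, a 0.25 nm packing
rejection distance and a 0.9 g/cm³ initial density guess (neither is
stated by the protocol; both are configurable), 298 K / 1 bar, bonding
cutoff 0.55 nm, 10 bonds per 40000-step relaxation, 20000-step retries,
termination after 40 empty attempts, and 150→500 K heating sweeps over
one million steps.

The test suite and the acceptance script run the same pipeline at
reduced size — a few hundred beads, 10³–10⁴ MD steps, sweeps of ~5·10³
steps in 12 windows — sizes chosen so the full workflow (pack, minimize,
equilibrate, cure, sweep, fit) completes in minutes in plain R. At that
scale the Tg fits carry tens-of-kelvin uncertainty and per-window
densities are noisy; what the passing tests demonstrate is the
correctness of the machinery (exact formulation arithmetic, table-exact
templates, gradient-exact forces, conservation and constraint
properties, audit-clean curing) and the right physical orderings
(density decreasing with temperature, cured network denser and stiffer
than the resin, polymer Tg above resin Tg) — not converged material
property predictions, which require the full-size, million-step
protocol and the published nonbonded matrix.

## Known limitations

* No termination reactions — propagation only; curing ends by the
  mobility criterion (the consecutive-failure budget).
* No reaction-probability or Arrhenius kinetics; bonding is purely
  geometric.
* Bead types are not changed by reaction (the underlying model is
  silent on this; types are retained).
* Orthorhombic boxes only; all beads uncharged; no parallel execution.
* The bundled nonbonded table is a synthetic stand-in (see above).
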