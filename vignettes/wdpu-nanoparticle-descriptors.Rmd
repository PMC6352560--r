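---
title: "Structural descriptors for WDPU nanoparticles: models, generators, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural descriptors for WDPU nanoparticles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wdpunano)
```

## Scope and model

`wdpunano` analyzes the structure of nanoparticles self-assembled from
waterborne biodegradable polyurethane (WDPU) chains — block copolymers
whose flexible soft segments are polyesters (poly(caprolactone), PCL, and
polylactide, PLA, mixed 3:1 by moles in the shipped presets) joined by
rigid urethane-bearing hard segments. The package has three layers:

1. **Topology** (`composition_preset()`, `build_chain_topology()`): a
   labeled bead model of one chain. Resolution is united-heavy-atom: each
   heavy atom of the polyester repeats is one bead with its hydrogens'
   mass folded in, except the urethane N–H hydrogens, which are explicit
   because hydrogen-bond geometry needs them. Every soft segment is
   flanked by two nitrogen junction beads; those nitrogens carry the
   donor role and serve as the end-to-end markers for chains and
   segments. The hard-segment interiors are *padding*: the package does
   not model the full hard-segment chemistry, only its bookkeeping (bead
   count, junction geometry, donor sites), and the builder pads each hard
   block with CH2-like beads so a chain meets an explicit particle-count
   target (3070 by default). Per-chain molar mass is therefore
   approximate (~43 kDa with CH2-like pads) and is not treated as a
   reproducible quantity.
2. **Generator** (`generator_config()`, `pack_assembly()`,
   `plant_hbond_geometries()`, `calibrate_preset()`): seeded synthetic
   assemblies with controllable chain stiffness, radial density profile,
   anisotropy, and planted hydrogen-bond geometries.
3. **Descriptors** (`radius_of_gyration()`, `eccentricity()`,
   `surface_area()`, `radial_density_profile()`,
   `end_to_end_distances()`, `rdf()`, `detect_hbonds()`,
   `classify_hbonds()`, `summarize_descriptors()`): the measurement
   suite, implemented independently of the generator so that
   generator-to-descriptor round trips are meaningful checks.

A CVFF-form potential evaluator (`evaluate_energy()`,
`evaluate_forces()`, `relax_system()`) completes the set; it consumes
user-supplied parameter tables and ships only a deliberately non-physical
toy table for tests.

## The chain sampler

Chain conformations come from a correlated random walk over the backbone
beads. Each step's bend-angle cosine is drawn uniformly from an interval
whose mean is the persistence parameter $c \in [-1, 1]$:

* $c = 0$: the bend cosine is uniform on $(-1, 1)$, i.e. each new
  direction is uniform on the sphere — exactly the freely-jointed chain,
  with $\langle R^2 \rangle = N b^2$;
* $c = 1$: the rigid rod, end-to-end equal to the contour length $Nb$;
* $c < 0$: anti-correlated, compact walks.

For independent bend cosines the mean-square end-to-end distance follows
the freely-rotating-chain law
$\langle R^2\rangle = N b^2\,\frac{1+c}{1-c}$ (with the usual finite-$N$
correction), strictly increasing in $c$; `mean_end_to_end()` exposes this
closed form and anchors calibration.

**Targeted mode (default).** Nanoparticle ensembles of the kind emulated
here report *very* narrow end-to-end dispersions — a few parts in ten
thousand relative — because they are time averages over an equilibrated
dense assembly, not independent coil draws. A free random walk at fixed
$c$ fluctuates at the ~40% level per chain, so no free-walk ensemble of
ten chains can reproduce that narrowness. The default sampler therefore
*bridges* each realization: after generating the free walk it applies a
uniform per-bond shear (of order $|\Delta R|/N \approx 0.01$ Å per bond,
far below the bond length) so the end-to-end distance equals a value
drawn from a tight distribution (relative sd `end_to_end_rel_sd`,
default 0.002) around the closed-form mean. Local conformational
statistics remain those of the correlated walk; only the global
end-to-end coordinate is pinned. `mode = "free"` disables the bridge and
is what the freely-jointed-chain and rigid-rod physics checks use. At
$c = 1$ the rod is deterministic and no noise is applied.

Excluded volume is soft: an optional `min_separation` check against a
window of preceding beads with bounded redraws (placement fails with a
congestion error naming the bead when even the best candidate has under
half the requested clearance). It is off by default — at desk scale the
descriptors under study are insensitive to local overlaps, and a strict
self-avoiding walk at compact $c$ is not samplable in reasonable time.

## Packing and the radial density profile

`pack_assembly()` places whole chains rigidly (rotation + translation
only), so per-chain end-to-end distances calibrated at the sampler level
survive packing *exactly*. Chain centers get stratified (quantile) radii
drawn from the target radial mass profile — a plateau of `core_density`
out to `core_radius`, decaying linearly to zero at `decay_radius` — along
quasi-uniform Fibonacci-lattice directions under a seeded random global
rotation; larger chains are assigned smaller radii and capped inside the
profile so the realized bead density vanishes just past `decay_radius`.
The stratification is a variance-reduction choice, made for the same
reason as the targeted sampler: replicate-to-replicate dispersions in the
emulated ensembles are tiny, and independent uniform placement of only
ten chain centers would swamp them. Anisotropy is applied as a final
per-axis scaling (the shipped calibrated workflows keep it isotropic,
since scaling deforms chains).

The realized bead density is the center distribution convolved with each
chain's own mass cloud: plateau and cutoff are reproduced up to that
convolution (a few tens of percent in 5 Å bins when chain extents are
comparable to the bin width), which the tests treat as binning error.
Density units are Da/Å³ throughout; a number-density profile is emitted
alongside the mass density. Feasibility is checked analytically (total
bead volume against random close packing of the profile volume) rather
than by per-bead rejection, which pure-R pairwise checks would make the
dominant cost for no measured benefit; `min_separation` remains available
at the sampler level.

## Calibration

`calibrate_preset()` tunes one monotone control per target: persistence
for the mean chain end-to-end distance, a radial scale factor on
`(core_radius, decay_radius)` for the assembly radius of gyration. Each
iterate is *measured* — generated over `n_seeds = 5` replicates and
evaluated with the descriptor code, never trusted from the closed form —
and iteration is bracketed secant, starting from the closed-form
inversion (end-to-end) or a proportional correction (Rg). Unreachable
targets (outside the collapsed-globule-to-rigid-rod range, measured at
the bracket ends) raise an error reporting the achievable range.
Convergence tolerance defaults to 0.5% relative.

## Descriptor conventions

* **Radius of gyration**: mass-weighted RMS distance from the center of
  mass (a `weighting = "number"` variant is available; the two differ
  by <1% for these bead masses). Scales linearly under uniform coordinate
  scaling.
* **Eccentricity**: $1 - I_{\min}/I_{\mathrm{avg}}$ over the principal
  moments of the mass-weighted inertia tensor — exactly this form, not
  the square-root variant used elsewhere. Zero for cubic or spherical
  symmetry; undefined (error) for collinear configurations, detected via
  rank of the gyration tensor. Rotation-, translation- and
  scale-invariant.
* **Surface area**: Shrake–Rupley point sampling on a deterministic
  Fibonacci lattice (default 960 points/particle) with particle radii
  extended by a 1.4 Å probe. The spherical reference $A_s$ is the area of
  the sphere of equal *accessible volume*, with the volume obtained from
  the same exposed points by the divergence theorem
  ($V = \tfrac13 \oint \mathbf{r}\cdot\mathbf{n}\, dA$) — so an isolated
  sphere gives a ratio of exactly 1 and any aspherical body a ratio > 1.
  The choice of reference sphere is recorded in the result object.
* **End-to-end distances**: Euclidean distances between the nitrogen
  junction markers for whole chains and per soft segment (grouped PCL vs
  PLA); contour lengths computed from realized coordinates bound them.
* **RDF**: pair-distance histogram in 0.5 Å bins (reported peak positions
  then sit at odd multiples of 0.25 Å), normalized by shell volume times
  the mean pair density inside the minimal enclosing sphere — the
  finite-cluster, non-periodic convention, under which uniform points
  give $g \approx 1$ well inside the cluster and raw counts are always
  retained so any renormalization is recoverable. Chain- and
  segment-centroid selections are the default inputs
  (`chain_centroids()`, `segment_centroids()`); atom-level point sets
  work unchanged. `peak` is the global-maximum bin center; `first_peak`
  the first local maximum above a configurable fraction (default 0.5) of
  the global maximum.
* **Hydrogen bonds**: donor–acceptor distance ≤ 3.0 Å *and* deviation of
  the D–H⋯A angle from 180° ≤ 30°, both boundaries inclusive; the angle
  convention is deviation-from-linearity and is configurable. Roles come
  from topology labels only (urethane N–H donors, carbonyl/ester oxygen
  acceptors), never element inference; acceptors within 3 covalent bonds
  of the donor are excluded (configurable), the usual convention that
  suppresses trivial adjacent-ester contacts. Detection is cell-list
  accelerated and exactly reproduces exhaustive search (tested against a
  triple-loop oracle). Categories (PCL–PCL, PLA–PLA, PCL–PLA) use a
  per-particle class label under which each hard-segment block inherits
  the class of the soft segment it precedes, making the three-way
  partition total; scope (intra- vs intermolecular) compares chain ids.
* **Ensembles**: averages are over independent seeded replicates
  (default 5), reported as mean ± sd, mirroring ensemble-averaged error
  bars; a single replicate reports sd 0.

## Hydrogen-bond planting

`plant_hbond_geometries()` turns an assembly into a detector test
harness: it repositions chosen donor-H/acceptor triples to exact
geometries (default 2.8 Å, 10° deviation), plants decoys violating
exactly one criterion (distance 5% over the cutoff, or deviation 25%
over), and then *sterilizes* accidental contacts — re-azimuthing triads
or pushing free acceptors outward in a bounded loop until the detected
set equals the planted set exactly. Ground truth is bookkeeping recorded
at planting time, never re-measured.

## CVFF evaluator

All terms of the consistent-valence functional form are implemented:
Morse bonds, harmonic angles, cosine torsions, a Wilson-angle
out-of-plane term ($\chi$ = angle between the central atom's third bond
and the plane of the first two), five cross terms (bond–bond and
bond–angle within each angle, angle–angle pairs sharing a central atom,
torsion with its two flanking angles, out-of-plane pairs with bonded
centers), Lennard–Jones in the $\varepsilon, r^*$ form, and Coulomb with
configurable dielectric. Nonbonded exclusions are 1–2 and 1–3, with 1–4
included at full weight (the CVFF-era convention). Forces are analytic
throughout — including the Wilson angle, differentiated via scalar
triple-product identities — and match central finite differences to
better than $10^{-6}$ relative. No cutoff is applied at desk scale.
Parameter values are not shipped; tables are user-supplied
(YAML/`ff_params()`), with a clearly labeled non-physical toy set bundled
for tests. `relax_system()` is a line-searched steepest-descent toy
relaxer with a guaranteed non-increasing energy sequence; it is a
convenience, not an equilibration protocol.

## Problem sizes and what the tests do (and do not) show

The shipped workflows run at desk scale: 10 chains of 3070 particles,
5 replicates, calibrations over ≤ 20 secant iterations — a full
calibrate-generate-measure cycle takes seconds to a couple of minutes on
one CPU. The synthetic generator emulates the *statistical targets* of
equilibrated nanoparticle ensembles (sizes, density-profile shape,
end-to-end statistics, planted hydrogen-bond counts); it does not
emulate thermodynamically faithful self-assembly, solvent, chain
entanglement, temperature, or the stereochemical (D,L- vs L-lactide)
mechanism — the two shipped presets differ only through their calibrated
stiffness/packing parameters, and the package makes no claim about *why*
the two chemistries differ. Passing round-trip tests therefore show that
the descriptor implementations are correct and that the generator can be
driven to stated conditions; they do not re-derive any
molecular-dynamics result.

## Other numerical choices

* Seeds: every stochastic function takes an explicit seed; child streams
  are derived arithmetically (all below $2^{31}$), and RNG state is
  always restored, so identical configurations are bitwise reproducible.
* Radial profiles: default 5 Å bins about the center of mass; the
  outermost bin is extended to the farthest particle so shell masses sum
  exactly to the total mass.
* Degenerate inputs: zero-mass systems, collinear clouds, empty
  selections, missing markers, missing radii, unresolvable force-field
  tuples and infeasible densities all raise targeted errors; boundary
  hydrogen-bond geometries are included (≤, not <).
* PDB chain ids wrap through a 62-character alphabet; full label
  fidelity across I/O comes from the JSON sidecar, with bonded tuples
  re-derived from the bond list on read.
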