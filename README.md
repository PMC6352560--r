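# wdpunano

Structural descriptors and synthetic configurations for waterborne
biodegradable polyurethane (WDPU) nanoparticles.

WDPU nanoparticles — self-assembled from block-copolymer chains whose
soft segments mix poly(caprolactone) (PCL) and polylactide (PLA) 3:1 by
moles around rigid urethane hard segments — are the building blocks of
injectable biodegradable hydrogels. Their material behaviour traces back
to structural quantities at the particle and chain level: how big and how
spherical the particle is, how mass is distributed radially, how extended
the chains are, how chains and segments pack, and how many hydrogen-bond
"physical crosslinks" hold the assembly together. `wdpunano` is for
researchers who need those quantities as reusable, tested code: it builds
labeled chain topologies, generates seeded synthetic nanoparticle
configurations with controllable statistics, and measures the full
descriptor suite with implementations that are independent of the
generator.

## What it computes

For a labeled particle configuration (generated, or read from
PDB/extended-XYZ):

* **Radius of gyration** — mass-weighted,
  `Rg² = Σ mᵢ|rᵢ − r_cm|² / Σ mᵢ`.
* **Eccentricity** — `1 − I_min/I_avg` over the principal moments of the
  inertia tensor (0 = spherically symmetric).
* **Accessible surface area** — Shrake–Rupley point sampling with a
  1.4 Å probe, plus the ratio `A_m/A_s` against the sphere of equal
  accessible volume.
* **Radial density profile** — shell mass / shell volume about the
  center of mass (Da/Å³), mass-conserving by construction.
* **End-to-end and segment-to-segment distances** — between the nitrogen
  junction markers delimiting chains and soft segments (N–C–C–N ends).
* **Radial distribution functions** — finite-cluster normalization, for
  chain centroids, PCL/PLA segment centroids, or atoms; 0.5 Å bins.
* **Hydrogen bonds** — geometric criterion `d(D,A) ≤ 3.0 Å` and D–H⋯A
  deviation from linearity `≤ 30°`, classified three ways
  (PCL–PCL / PLA–PLA / PCL–PLA) and by scope (intra-/intermolecular).
* **CVFF energies and forces** — Morse bonds, harmonic angles, cosine
  torsions, Wilson out-of-plane, five cross terms, LJ + Coulomb, over
  user-supplied parameter tables; analytic gradients and a toy relaxer.

The synthetic generator emulates the statistics of equilibrated
nanoparticle ensembles — target radial density profile (plateau core,
decaying shell), chain stiffness via a persistence parameter with exact
freely-jointed and rigid-rod limits, anisotropy, and planted
hydrogen-bond geometries with distance/angle decoys — and
`calibrate_preset()` tunes it to stated targets by measured secant
iteration. See the vignette in `vignettes/` for the model and every
numerical choice.

## Worked example

Calibrate the PCL75LL25 preset to a 54.99 Å mean chain end-to-end
distance, generate three replicate 10-chain assemblies (3070 particles
per chain), and summarize:

```r
library(wdpunano)

pre   <- composition_preset("PCL75LL25")
chain <- build_chain_topology(pre, seed = 1)
cal   <- calibrate_preset("mean_end_to_end", 54.99,
                          generator_config(seed = 1, preset = pre))
round(cal$persistence, 4)
#> [1] -0.3563

systems <- lapply(1:3, function(s) {
  cfg <- cal; cfg$seed <- s
  pack_assembly(chain, cfg)$system
})
summarize_descriptors(systems, include_surface = FALSE)
#> descriptor_report over 3 replicate(s)
#>   rg                       75.417 +/- 0.508
#>   eccentricity              0.143 +/- 0.052
#>   mean_end_to_end          54.976 +/- 0.049
#>   mean_seg_pcl             10.769 +/- 0.168
#>   mean_seg_pla              8.671 +/- 0.502
#>   hbond_total              21.000 +/- 4.359
#>   hbond_pcl_pcl            10.000 +/- 2.000
#>   hbond_pla_pla             4.667 +/- 0.577
#>   hbond_pcl_pla             6.333 +/- 3.055
#>   hbond_inter               0.000 +/- 0.000
#>   rdf_chain_peak           45.750 +/- 6.557
#>   rdf_pla_first_peak       13.583 +/- 7.320
```

Reading the output: the calibrated persistence of −0.36 makes chains
mildly anti-correlated (compact) walks whose measured mean end-to-end
distance (54.98 ± 0.05 Å) reproduces the calibration target on fresh
seeds; with the default density profile the 10-chain assembly has
Rg ≈ 75 Å; the ~21 detected hydrogen bonds per replicate here are
chance contacts of this loose synthetic packing, split by the three-way
donor/acceptor class partition. `calibrate_preset("rg", ...)` would
rescale the density profile to hit a target radius of gyration;
`plant_hbond_geometries()` plants exact hydrogen-bond counts for
detector validation.

The pipeline form of the same workflow —
`run_pipeline(run_config(generator_config(...)))` — writes
`report.json`, tidy CSVs, and a seeded, config-hashed log;
`inst/cli/wdpunano` wraps it for shell use
(`wdpunano generate --config run.yaml`).

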