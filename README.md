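# mc3ssm

Statistical shape and subchondral bone-mineral-density modeling of the
equine distal third metacarpal (MC3) epiphysis.

The fetlock is the most common site of catastrophic injury in Thoroughbred
racehorses, and both the geometry of the distal MC3 and the density of the
bone just beneath its articular surface shape the mechanical stresses that
precede condylar fracture. `mc3ssm` is for biomechanics and veterinary
imaging researchers who want a corresponded, quantitative description of
how MC3 shape and subchondral BMD vary together across a population of CT
scans — a point distribution model of shape and appearance.

## What it computes

Given segmented bone-surface point clouds and calibrated CT volumes, the
package:

1. registers a fixed-topology template surface (40 bicubic Lagrange
   patches, 361 nodes) to every cloud — coarse host-mesh (free-form
   deformation) fit, then a fine per-node fit with a bending penalty;
2. establishes population correspondence by rigid generalized Procrustes
   alignment plus an iterative shape-model-constrained refit;
3. samples subchondral bone 5 mm along each node's inward normal and
   converts mean Hounsfield units through the two-point phantom calibration

   ρ_HA = (CT_bone − CT_H2O) / (CT_HA − CT_H2O) · ρ_phantom

   and the empirical density–modulus law ρ_app = ρ_HA / 0.626,
   E = 2017.3 · ρ_app^2.46 (MPa);
4. trains principal-component models with the N×3n shape matrix
   (covariance PCA) and the N×4n combined shape+density matrix
   (correlation PCA, per-node x,y,z,I), x = x̄ + Σ ω_i φ_i, retaining
   components to 80% cumulative variance;
5. validates by leave-one-out reconstruction and interrogates modes through
   landmark morphometry at ±2 SD.

No imaging archive ships with the package. Instead a synthetic-data module
generates MC3-like populations (surfaces, point clouds, CT volumes with a
phantom) from three known latent modes — overall size, sagittal-ridge
prominence, condylar asymmetry — so every stage is testable against ground
truth. The generator is first-class, documented code, not a test fixture.

## Worked example

The `analysis/` directory holds the study drivers (`01_generate.R` …
`07_morphometry.R`); each is a thin script over the package functions and
writes its tables under `results/`. Running them on the packaged default
study (40 synthetic specimens, master seed 20260101) prints:

```
Generated 40 specimens; cloud sizes 1630-2367 points (median 1978).
Coarse fit: mean 0.351 mm (range 0.227-0.701); fine fit: mean 0.153 mm.
Correspondence loop: 1 round(s), mean RMS 0.148 mm (target 0.3 mm, met).
Sampled 40 x 361 node densities; 0 flagged rays; mean rho_HA 0.698 g/cm^3.
shape    :  3 components for 80% variance; leading fractions 45.9% 29.9% 14.9%
density  :  3 components for 80% variance; leading fractions 49.8% 28.0% 10.5%
combined :  3 components for 80% variance; leading fractions 44.4% 22.8% 13.5%
LOO geometric RMS: 1.81 mm at k=0 -> 0.52 mm at k=10; density RMS 0.074 -> 0.028 g/cm^3.
Mode 1 at +/-2 SD: total area +35.3%, dorsal BMD +48.3%, palmar BMD +51.4%.
Mode 3 lateral/medial condylar area ratio: 1.088 (-2 SD) -> 0.871 (+2 SD).
```

Read: the template registers to every cloud well below the voxel scale
(the fine-fit RMS sits at the 0.15 mm segmentation-jitter floor); the three
generative modes are recovered as the three leading components of each
model flavor, together explaining ~80% of the variance; reconstruction
error drops steeply once those modes are included; and the combined model's
first mode couples larger epiphyses with higher subchondral BMD — the
asymmetry mode trades lateral against medial condylar area — matching the
latent structure the generator planted.

The same machinery is exposed directly:

```r
library(mc3ssm)
pop    <- sample_population(default_synthetic_spec(n_specimens = 40))
cloud  <- export_point_cloud(pop$specimens[[1]], density = 0.25, seed = 1)
fit    <- fine_fit(host_mesh_fit(pop$base, cloud), cloud)
vol    <- voxelize(pop$specimens[[1]], pop$spec)
field  <- node_density_field(fit$mesh, vol)   # HU, rho_HA, rho_app, E per node
```

`vignettes/shape-density-modeling.Rmd` explains the models, parameters, and
design choices in detail.

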