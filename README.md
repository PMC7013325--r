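# ipdtsim

Simulation of treatment outcomes for **interstitial photodynamic therapy
(iPDT)** of malignant brain tumors with ALA-induced protoporphyrin IX
(PpIX). The package is aimed at treatment-planning and dosimetry work:
given a voxelized tissue model, a plan of cylindrical light diffusers and a
photophysical parameter set, it predicts which tissue dies.

The pipeline has four stages:

1. **Phantom** — a voxel model with per-tissue optical properties
   (μa, μs, g) and an initial PpIX concentration field C₀(x,y,z)
   (parametric uniform-tumor and ellipsoid-in-white-matter generators;
   NIfTI/JSON/YAML I/O).
2. **Transport** — Monte Carlo photon-packet propagation from the
   diffusers (Henyey–Greenstein scattering, absorption-weight fluence
   estimator, Russian roulette with an exactly conserved energy ledger),
   giving the fluence rate φ(x,y,z) in mW/cm².
3. **Dose** — accumulated singlet-oxygen concentration with photobleaching
   (β the bleaching fluence constant, Φ the singlet-oxygen quantum yield,
   A = 1000 ε ln10 λ / (h c N_A)):

       D_SO = A · Φ · C₀ · β · (1 − exp(−F/β)),   F = φ·T  [J/cm²]

   which saturates at A·Φ·C₀·β; without bleaching D_SO = A·Φ·C₀·F grows
   without bound. Closed-form inversions: required fluence for a
   threshold, minimum C₀, minimum β.
4. **Outcome** — cell-death mask where D_SO ≥ D_SO(th) (default 0.56 mM)
   and the plan metrics: treated volume (TV, killed tumor), damaged volume
   (DV, killed normal tissue), tumor coverage (TC = TV / tumor volume).

## Worked example

```r
library(ipdtsim)

p <- photophysical_params()          # epsilon 5000 /cm/M, 635 nm, Phi 0.77,
                                     # beta 13.5 J/cm^2, rounded h, c, N_A
dose_prefactor(p)                    # 61.3  (J/cm^2)^-1
1000 * saturation_dose(5.8e-6, p)    # 3.70  mM  — the most 5.8 uM PpIX can yield
required_fluence(0.56e-3, 5.8e-6, p) # 2.22  J/cm^2 to reach the 0.56 mM threshold
                                     # (1.55 / 2.93 for 0.4 / 0.72 mM)

# one 1.6 cm diffuser (200 mW/cm) in a 1.4 cm ellipsoidal tumor in white matter
cfg <- run_config(
  phantom   = list(type = "ellipsoid", dims = c(24, 24, 24),
                   spacing = rep(0.1, 3), center = rep(1.2, 3),
                   semi_axes = rep(0.7, 3), c0_tumor = 5.8e-6, tn_ratio = 95),
  diffusers = diffuser_spec(c(1.2, 1.2, 0.4), radiation_length = 1.6,
                            outer_diameter = 0.11, linear_power_density = 200),
  n_photons = 2e4, seed = 1)
res <- run_pipeline(cfg)
glance(res$report)
#>   threshold_mM tv_cm3 dv_cm3    tc tumor_volume_cm3 n_masked_voxels
#> 1         0.56   1.23      0 0.833             1.47            1226
```

Reading: one hour at 200 mW/cm treats 1.23 cm³ of the 1.47 cm³ tumor
(TC = 0.83) and no white matter at all — DV = 0 is structural here: at a
tumor-to-normal uptake ratio of 95 the normal-tissue saturation dose
(~0.04 mM) can never reach the 0.56 mM threshold, however much light is
delivered. `autoplot(radial_dose_profile(res$dose, cfg$diffusers[[1]]))`
shows the dose fall-off around the fiber, and
`scan_parameter("c0", ...)` / `plot_dose_fluence()` reproduce the
sensitivity analyses (dose saturation, the C₀ cutoff below which no light
suffices, the β dependence).

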