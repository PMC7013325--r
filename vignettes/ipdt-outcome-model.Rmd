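---
title: "Simulating interstitial PDT outcomes with a singlet-oxygen dose model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating interstitial PDT outcomes with a singlet-oxygen dose model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipdtsim)
```

## The problem

Interstitial photodynamic therapy (iPDT) for malignant brain tumors inserts
cylindrical fiber diffusers directly into the tumor and drives a
photosensitizer — protoporphyrin IX (PpIX), metabolically induced by
5-aminolevulinic acid (ALA) — with 635 nm light. The cytotoxic agent is
singlet oxygen generated by the excited photosensitizer. Whether a given
insertion plan actually kills the tumor, and whether it damages the
surrounding white matter, depends on the interplay of light transport,
photosensitizer concentration and photobleaching in a way that is hard to
intuit. `ipdtsim` simulates that interplay end to end:

1. **phantom** — a voxelized tissue model with per-tissue optical properties
   and a PpIX concentration field;
2. **transport** — Monte Carlo photon-packet propagation from the diffusers,
   giving the fluence-rate field $\varphi(x,y,z)$ (mW/cm²);
3. **dose** — conversion of fluence to accumulated singlet-oxygen
   concentration $D_{SO}(x,y,z)$ via a photobleaching-corrected quantum-yield
   model;
4. **outcome** — thresholding $D_{SO}$ into a cell-death mask and computing
   treated volume (TV), damaged volume (DV) and tumor coverage (TC = TV /
   tumor volume).

## The dose model

A photosensitizer at molar concentration $C$ under fluence rate $\varphi$
(W/cm²) absorbs photons at a rate proportional to
$A = 1000\,\varepsilon \ln(10)\, \lambda/(h c N_A)$ — moles of photons per
litre, per J/cm² of fluence, per mol/L of sensitizer (the factor 1000
converts cm³ to L). Each absorbed photon yields a singlet-oxygen molecule
with probability $\Phi$ (the singlet-oxygen quantum yield, SOQY).
Photobleaching destroys the sensitizer exponentially in delivered fluence
with fluence constant $\beta$ (J/cm²), so with constant $\varphi$ over
irradiation time $T$ and $F = \varphi T$:

$$
D_{SO} \;=\; \int_0^T A\,\Phi\,\varphi\,C_0\,
             e^{-\varphi t/\beta}\,\mathrm{d}t
       \;=\; A\,\Phi\,C_0\,\beta\,\bigl(1 - e^{-F/\beta}\bigr),
$$

and $D_{SO} = A\,\Phi\,C_0\,F$ with bleaching disabled. Two structural
consequences drive everything downstream:

* **Saturation.** $D_{SO} \le A\,\Phi\,C_0\,\beta$ no matter how much light
  is delivered ([saturation_dose()]): once the sensitizer is bleached away,
  further irradiation is wasted.
* **Reciprocity.** $D_{SO}$ depends on $\varphi$ and $T$ only through $F$.
  The model carries no explicit oxygen kinetics — $\Phi$ is constant,
  which is appropriate while tissue oxygenation stays above roughly 1%
  dissolved-oxygen saturation, and the same $\Phi$ is used for tumor and
  normal tissue.

The bleaching exponent is implemented as $e^{-\varphi t/\beta}$, i.e.
$\beta$ is a *fluence constant* in J/cm². This is the dimensionally
consistent form for the units $\beta$ is reported in, and it is what makes
the closed-form inversions below reproduce the model's published operating
points.

Closed-form inversions come with the model:

* [required_fluence()] — $F$ at which $D_{SO}$ reaches a cell-death
  threshold; unreachable thresholds (at or above saturation) return `Inf`
  rather than erroring, because unreachability is an informative answer.
* [min_initial_concentration()] — the smallest $C_0$ that can reach the
  threshold at a given $F$ (or ever, at $F = \infty$).
* [min_bleaching_coefficient()] — the smallest $\beta$ for which a given
  $F$ still suffices; found by bracketed bisection on $[10^{-6}, 10^6]$
  J/cm² to $10^{-6}$ relative width (the function
  $\beta(1 - e^{-F/\beta})$ is strictly increasing in $\beta$, so the root
  is unique whenever it exists).

A trapezoidal time-stepped integrator ([numeric_dose_integral()]) provides
an independent numerical check of the closed form; at $dt = T/10^4$ the two
agree to $10^{-4}$ relative over the clinically relevant fluence range
(up to a few tens of J/cm²). At extreme $F/\beta$ (thousands), where the
integrand decays within a handful of steps, the trapezoid rule needs a finer
grid — those exposures are far past saturation and carry no dosimetric
information.

### Default parameters

| parameter | default | units | meaning |
|---|---|---|---|
| $\varepsilon$ | 5000 | cm⁻¹ M⁻¹ | PpIX molar extinction at 635 nm |
| $\lambda$ | 635 | nm | excitation wavelength |
| $\Phi$ | 0.77 | — | singlet-oxygen quantum yield |
| $\beta$ | 13.5 | J/cm² | photobleaching fluence constant |
| $C_0$ | 5.8 | µM | initial tumor PpIX concentration |
| $D_{SO}(th)$ | 0.56 | mM | cell-death threshold |
| TN ratio | 95 | — | tumor-to-normal PpIX uptake |

Reported PpIX bleaching constants span roughly 4.5–33 J/cm² and measured
$C_0$ values 0–28 µM; $\beta$ and $C_0$ are therefore first-class scan
parameters ([scan_parameter()]), not constants. The physical constants are
deliberately the rounded values conventional for this model
($c = 3.0\times10^{10}$ cm/s, $N_A = 6.0\times10^{23}$ mol⁻¹) rather than
CODATA values; the difference is far below every tolerance in play. The TN
ratio for ALA-PpIX in brain has been reported in the low-90s to mid-90s
range; it is a configuration value here, never hard-coded.

## Monte Carlo transport

The kernel is a voxel Monte Carlo in the mcxyz tradition, written in C++:

* **Launch.** The diffuser's radiation section (default 40 mm long, 1.1 mm
  diameter) is modelled as a uniformly emitting lateral cylinder surface:
  launch points uniform along the length and in azimuth, launch directions
  uniform over the outward solid-angle hemisphere about the local surface
  normal; the end faces do not emit. This is the simplest source consistent
  with "uniform emission" and with the surface-fluence relation
  $\varphi_{sur} = $ linear power density $/(\pi d)$
  ([linear_to_surface_fluence()]). Whether packets should instead start in
  the diffuser interior is not settled; the surface launch is this package's
  choice, and at radii beyond a voxel or two from the surface the two are
  indistinguishable.
* **Propagation.** Dimensionless step $s = -\ln\xi$ consumed against the
  local $\mu_t = \mu_a + \mu_s$, with partial steps at voxel boundaries; at
  each interaction the packet deposits $W \mu_a/\mu_t$ in the current voxel
  and scatters through a Henyey–Greenstein angle with the voxel's $g$.
  Refractive-index boundaries are treated as matched (no Fresnel
  reflection/refraction), since the tissue indices involved are nearly
  equal; the diffuser volume itself is treated as tissue after launch.
* **Termination.** Russian roulette below weight $10^{-4}$ with survival
  probability 0.1. The ledger books the survivor boost *against* the
  discard tally (the tally is the net weight removed by roulette), which
  makes `deposited + escaped + discarded = launched` a floating-point
  identity rather than a statistical statement — [ledger_residual()] is
  ~$10^{-13}$ on every run, and the test suite asserts $<10^{-6}$.
  Packets leaving the grid or entering void (label 0) are tallied as
  escaped; the model does not describe what surrounds the tissue, so void
  terminates rather than reflects.
* **Estimator.** Fluence per voxel is the absorption-weight estimator
  $\varphi_v = D_v P/(n\,\mu_{a,v}\,V)$; voxels with $\mu_a = 0$ fall back
  to the track-length estimator, which is defined there.
* **Reproducibility.** The RNG is R's own, so `set.seed()` governs the
  kernel; each diffuser runs on its own substream
  (`seed + 7919 k mod 2³¹−1`), so adding a diffuser to a plan never
  perturbs the others, and fluence is exactly linear in each diffuser's
  power at fixed seed.

Validation is against the infinite-medium diffusion approximation for a
point source ([point_source_diffusion_fluence()]),
$\varphi(r) = P e^{-\mu_{eff} r}/(4\pi D r)$ with
$\mu_{eff} = \sqrt{3\mu_a(\mu_a + \mu_s')}$. For tumor optical properties
($\mu_a = 1.7$, $\mu_s = 365$ cm⁻¹, $g = 0.9$; $\mu_{eff} \approx 14$
cm⁻¹) the kernel agrees within 15% over $r = 0.3$–$0.8$ cm at $10^6$
packets, the expected level for diffusion theory in this regime — the
residual grows slowly with $r$ because the true transport decay constant
differs slightly from $\mu_{eff}$.

## Phantoms: what they emulate and what they do not

The clinical use case starts from a segmented MRI volume; those data are
patient-specific and not distributable, so the package generates parametric
stand-ins:

* [build_uniform_phantom()] — a tumor-only cube (the sensitivity-analysis
  geometry: defaults 512³ voxels at 100 µm are the full-scale version;
  tests use 48³–64³ at 400 µm, which is ample for closed-form work and for
  MC validation radii under 1 cm);
* [build_ellipsoid_phantom()] — an ellipsoidal tumor embedded in white
  matter ($\mu_a = 0.7$, $\mu_s = 951$ cm⁻¹, $g = 0.9$), with the
  normal-tissue PpIX scaled down by the TN ratio.

Voxels are half-open boxes addressed by 0-based indices in the C++ kernel
and 1-based arrays in R; anisotropic spacings (e.g. 468×468×417 µm³) are
stored per axis and never rounded to cubic. What these phantoms do *not*
reproduce: irregular tumor margins, heterogeneous PpIX uptake, per-patient
optical-property variation, and anatomy outside the white-matter
neighbourhood. Tests passing on them validate the physics and bookkeeping,
not the clinical volumes one would obtain from a real segmentation.

A consequence worth knowing: at TN ratio 95 the normal-tissue saturation
dose is $3.7\,\text{mM} / 95 \approx 0.04$ mM, far below the 0.56 mM
threshold — with photobleaching on, *no* fluence can damage white matter in
this model, so DV = 0 is structural, not a near-miss.

## Outcome metrics and numerical choices

* Thresholding is **inclusive** ($D_{SO} \ge$ threshold counts as death;
  configurable). The tie rule matters because dosing exactly to
  [required_fluence()] should count as treated under floating-point
  equality.
* A voxel is wholly killed or wholly spared; no partial-volume weighting,
  matching the voxel-counting definition of TV/DV/TC.
* The same threshold applies to tumor and normal tissue by default — a
  conservative choice for normal-tissue damage, overridable per call.
* [radial_dose_profile()] bins voxel centres by cylindrical radius about
  the diffuser axis over the radiation-section extent; empty bins are
  reported as `NA`, never as zero dose.
* Degenerate inputs: a model with no tumor reports `tc = NA` (not 0, not
  an error); an all-void model refuses to simulate; an ellipsoid without a
  single interior voxel centre is an error at construction.

## Problem sizes

The defaults aim at desk-scale reproducibility: $10^6$ packets per diffuser
(about three minutes on one core for the validation cube) rather than the
$10^7$ a production run would use; MC statistical error enters TV/DV only
through voxels near the threshold isosurface, and the closed-form layers are
exact, so the operating-point analyses are packet-count independent. The
test suite runs its MC checks at $10^4$–$10^6$ packets on 16³–64³ grids.

## Limitations

* No oxygen-depletion kinetics: $\Phi$ constant means the model is blind to
  transient hypoxia during irradiation.
* No thermal modelling: the 0.9 cm minimum interfiber spacing used in
  multi-diffuser plans encodes a temperature constraint that this package
  takes as given.
* No immune-response component; the outcome is the immediate photochemical
  kill volume.
* The diffusion-approximation oracle is a validation device, not a fluence
  engine; it is only meaningful in homogeneous, strongly scattering media.
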