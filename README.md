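# dotcal

Data self-calibration for high-density parallel-plate continuous-wave
diffuse optical tomography (DOT), with a complete simulate → calibrate →
reconstruct → unmix pipeline for breast-size slab phantoms.

## The problem

CW breast DOT measures one transmission amplitude Γ(rᵢˢ, rⱼᵈ) per
source–detector (SD) pair between two parallel plates. Before
reconstruction the data must be calibrated against a homogeneous
reference, conventionally by scanning a reference phantom and forming

    Γ* = (Γ_tsk / Γ_ref) · Γ_pre

which cancels per-channel gains exactly — but a phantom matching each
patient's breast cannot be made on site. In a high-density mirrored
layout many SD pairs share the same SD distance d_ij. Grouping the task
scan into distance classes Ω_k and taking each class maximum

    Γ_k^max = max Ω_k,     Γ_est(rᵢˢ, rⱼᵈ) = Γ_k^max  for d_ij = d_k

builds a **virtual homogeneous reference** directly from the task data:
the class maximum is the member whose sensitivity region best avoided the
absorbing lesion. Self-calibration then reads

    Γ** = (Γ_tsk / Γ_est) · Γ_pre.

The package implements this method end to end: probe geometry and
distance classes, coverage/110 mm exclusions and CoV-based ring peeling
of boundary pairs (threshold 0.3), an FEM diffusion forward solver with
Robin boundaries plus an exact analytic slab oracle, Tikhonov-regularized
Gauss–Newton absorption reconstruction (λ = 10, 6 iterations by default),
Hb/HbO₂ spectral unmixing, and a synthetic-data generator (deterministic
diffusion forward and a voxel Monte Carlo cross-check in compiled code).

## Worked example

The baseline two-target phantom: a 44 × 130 × 79 mm slab (μa = 0.004,
μs′ = 1 mm⁻¹) with two 3×-absorbing cylinders (R = 7.5 mm) at
(17, 45, 42) and (17, 85, 42) mm, measured by mirrored 3 × 4 arrays
(13/14 mm pitch, 144 SD pairs):

```r
library(dotcal)
sc <- scenario_presets("sim_baseline")
ph <- build_phantom(sc$phantom_spec)          # task mesh + homogeneous twin
ds <- simulate_dataset(ph, sc$probe)          # task / reference / predicted

est <- build_virtual_reference(ds$task)       # per-distance-class maxima
mean_relative_error(est, ds$reference)$overall
#> [1] 0.0273958

cal <- self_calibrate(ds$task, est, ds$predicted)
im  <- reconstruct_absorption(cal, build_phantom(sc$phantom_spec, h = 2)$reference,
                              sc$probe, recon_settings())
```

The first number is the fidelity of the virtual reference: its mean
relative deviation from a true homogeneous-reference scan is ~2.7% on
this phantom — the tumor-induced suppression that survives the class-max
construction. From the reconstruction,

```r
target_peak_ratio(im, split_y = 65)$ratio     # two equal targets -> ~1
line_profile_metrics(im, line = list(x = 17, z = 42))$peaks$fwhm
```

give the two-target peak ratio (0.9496 on this run; a perfect method
would give 1) and each target's full width at half maximum (14.9 and
14.4 mm for 15 mm-diameter targets). `run_pipeline()` wires all stages together from a YAML/JSON
config and writes measurement CSVs, calibration reports, NIfTI volumes
and a provenance manifest; `inst/cli/dotcal` is a thin command-line
wrapper around it.

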