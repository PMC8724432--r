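---
title: "Data self-calibration for high-density parallel-plate DOT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data self-calibration for high-density parallel-plate DOT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Continuous-wave diffuse optical tomography (CW-DOT) of the breast measures,
for every source-detector (SD) pair of a two-plate transmission system, a
single amplitude $\Gamma(r_i^s, r_j^d)$. Reconstruction inverts a diffusion
forward model, and any mismatch between that model and the hardware —
per-channel coupling, LED/photodiode gain spread, surface contact — corrupts
the result unless the data are first calibrated. The conventional remedy is a
*relative measurement*: scan a homogeneous reference phantom with the task's
shape and background optics and form

$$\Gamma^{*} = \frac{\Gamma_{tsk}}{\Gamma_{ref}}\,\Gamma_{pre},$$

where $\Gamma_{pre}$ is the model prediction for the homogeneous medium.
Multiplicative per-channel gains appear identically in numerator and
denominator and cancel exactly. The practical obstacle is clinical: a
reference phantom matching each patient's breast cannot be fabricated on the
spot.

# Data self-calibration

The package implements an alternative that needs no physical reference. In a
high-density mirrored layout, many SD pairs share the same SD distance
$d_{ij} = |r_i^s - r_j^d|$. For a large, mostly homogeneous medium, all pairs
of a distance class $\Omega_k$ would read the same amplitude; a localized
absorber (a tumor) only *suppresses* the subset of pairs whose sensitivity
region intersects it. The class maximum

$$\Gamma_k^{max} = \max\,\Omega_k$$

is therefore the member least affected by the heterogeneity, and serves as an
estimate of the homogeneous reading at that distance. Assigning
$\Gamma_{est} = \Gamma_k^{max}$ to every member of $\Omega_k$ builds a
*virtual homogeneous reference*, and

$$\Gamma^{**} = \frac{\Gamma_{tsk}}{\Gamma_{est}}\,\Gamma_{pre}$$

replaces the reference-phantom scan. Two algebraic facts are load-bearing and
are asserted by the test suite: a global scale on the task scan cancels
exactly (it passes into $\Gamma_{est}$), and $\Gamma_{est} \ge \Gamma_{tsk}$
pairwise, so the calibrated data never exceed the prediction. Per-channel
gains do *not* cancel exactly here — the method trades that exactness for
needing no second scan, and relies on the gain spread being modest relative
to the heterogeneity signal.

The method presumes that each distance class has enough members that at
least one avoids the absorber. It is therefore appropriate for breast-like
geometries (small tumor in a large quasi-homogeneous organ, dense SD
sampling) and inappropriate for sparse probes or media with extended
heterogeneity; `build_virtual_reference()` makes no attempt to detect the
latter.

## Exclusions and boundary pairs

Before the class maxima are taken, two exclusion rules run
(`apply_exclusions()`): pairs with an endpoint not covered by the imaging
object, and pairs with SD distance above 110 mm, whose transmission
amplitudes sit at the noise floor of a CW system. Additionally, pairs near
the lateral object boundary read systematically low even in homogeneous
media, which corrupts class maxima and injects artifacts. The package
follows a ring-peeling strategy (`select_non_boundary()`): the coefficient
of variation (CoV = sd/mean) of each class is computed on the task data,
and while any class exceeds the threshold (default 0.3) the outermost ring
of sources and detectors is removed, keeping the plates mirrored. On the
full 7x8 grids two peels yield the 3x4 core used throughout the simulation
study. The CoV is computed on the task scan because that is what exists
clinically; the selection report records which data were used.

# Forward model

Photon transport is modeled by the CW diffusion equation with Robin
boundaries,

$$-\nabla\!\cdot\!(\kappa \nabla \Phi) + \mu_a \Phi = q_0, \qquad
  \Phi + 2\kappa\zeta\, \hat s_n\!\cdot\!\nabla\Phi = 0 \ \text{on}\ \partial\Omega,$$

with $\kappa = 1/(3(\mu_a + \mu_s'))$, $\zeta = (1+R_f)/(1-R_f)$, and $R_f$
from the Groenhuis polynomial fit in the refractive index (0.472 at
$n = 1.33$). The speed of light is set to 1: every quantity the package
derives from CW amplitudes is a ratio in which it cancels. Sources are
isotropic points one transport mean free path ($1/\mu_s'$) beneath the
source plate; the detector reading is $\Phi/(2\zeta)$, the boundary flux
implied by the Robin condition — consistent on both sides of every
calibration ratio, and numerically stabler than differentiating $\Phi$.

`solve_cw()` discretizes the slab with P1 tetrahedra on a structured
lattice (six Kuhn tetrahedra per cell) and solves the SPD system with a
sparse Cholesky factorization, reusing the symbolic factorization across
Gauss-Newton iterations.

## The analytic oracle and mesh resolution

`analytic_slab_flux()` provides an independent solution for the infinite
homogeneous slab. It is built in the lateral Fourier domain, where the
depth profile is a closed-form sinh/cosh two-point boundary-value problem
with the *same* Robin condition and source model as the FEM, and inverted
by numerical Hankel quadrature. We use this exact form rather than the
common extrapolated-boundary image-source series deliberately: direct
comparison shows the image series is biased 0.6–2.7% (worst at small
lateral offsets) relative to the exact Robin solution, which would
contaminate a 5% solver-verification budget.

Against this oracle, interior pairs (both endpoints at least two grid
pitches from the lateral rim) agree with the FEM to within 5% at a 2.5 mm
nominal element size (~33k nodes for the 44 x 130 x 79 mm slab), which is
the package default. At 3 mm the worst interior pair reaches 5.2%, the
error being dominated by numerical dispersion of the discrete attenuation
over the 44 mm plate separation.

*Reconstruction* uses a finer 2 mm mesh. The Kuhn split is chiral: it
breaks the phantom's y-mirror symmetry, and the two-target peak-ratio
metric is sensitive to exactly that asymmetry. At 2.5 mm the spurious
asymmetry contributes several percent to the ratio; at 2 mm both
calibration routes give ratios within 2% of unity on the symmetric
two-target phantom. Amplitude-domain error metrics, by contrast, are
ratios of same-mesh quantities and are reported on the default mesh.

# Inverse problem

`reconstruct_absorption()` runs damped Gauss-Newton on log-amplitude
(Rytov-style) residuals — CW amplitudes span decades between 44 mm and
110 mm pairs, and the log transform equalizes their leverage. Each
iteration solves

$$(J^T J + \lambda \max(\mathrm{diag}(J^T J)) I)\,\delta = J^T r$$

via the algebraically identical data-space form
$\delta = J^T (J J^T + \alpha I)^{-1} r$ (the data space is tiny: one row
per retained pair). Scaling $\lambda$ by $\max(\mathrm{diag}(J^TJ))$ makes
the conventional dimensionless choice $\lambda = 10$ meaningful across mesh
resolutions; with 6 iterations these are the package defaults. The
Jacobian is recomputed every iteration (full Gauss-Newton) by the adjoint
method, with the exact P1 element mass so that it is the exact derivative
of the discrete forward model — the test suite verifies it against direct
perturbation to within finite-difference nonlinearity. Only $\mu_a$ is
reconstructed; $\mu_s'$ stays frozen at background. Nodal values are
clamped at a small positive floor, and the loop stops early (with a
warning, returning the best iterate) if the data residual rises on two
consecutive iterations.

Known behaviour, asserted rather than hidden by the tests: recovered peak
absorption underestimates the true 3x contrast (roughly 0.006 vs
0.012 mm^-1 at these settings — heavy regularization plus CW depth
ambiguity), and recovered targets are displaced in depth. Localization is
assessed on the above-half-maximum centroid: for reference-calibrated
data it lands within one target radius (7.5 mm) of the truth on the 2 mm
reconstruction. Self-calibrated images localize the targets equally well
along the profile axis but show a stronger depth bias (~10 mm centroid
offset): the class-constant virtual reference slightly overestimates the
homogeneous amplitude of pairs near the lateral boundary, and the
resulting spurious shallow absorption drags the half-max blob toward the
source plate. This is a property of the calibration, not of the
inversion, and it leaves the width and contrast-ratio metrics intact.

## Image metrics

`line_profile_metrics()` samples the nodal image along y at fixed (x, z) in
0.5 mm steps, finds the target peaks, sets the background to the median of
the profile more than 20 mm from every peak, and measures each target's
full width at half of (peak − background) with linear interpolation at the
crossings. `target_peak_ratio()` reports the ratio of the maximum
reconstructed absorption in the two domain halves split at the
inter-target midplane — the quantity conventionally quoted as the
two-target contrast ratio.

# Synthetic data

`scenario_presets()` encodes the simulation study: a 44 x 130 x 79 mm slab
(x = through-plate axis), background $\mu_a = 0.004$ mm$^{-1}$,
$\mu_s' = 1$ mm$^{-1}$, $n = 1.33$, $g = 0.9$; two cylindrical absorbers
(radius 7.5 mm, height 10 mm, $\mu_a$ three times background) centered at
(17, 45, 42) and (17, 85, 42) mm; mirrored 3x4 grids at 13 mm / 14 mm
pitch centered on the plates, 44 mm apart. The cylinder axis is not
uniquely determined by the published slice figures; we chose the
through-plate axis, which makes the central x-slice show two 15 mm
circles. The position-sweep presets (`position_1..3`) likewise had to be
chosen here: both targets shifted +10 mm in y, +14 mm in z, and +10 mm in
depth respectively — three displacements that keep the targets inside the
slab and under the probe footprint.

`simulate_dataset()` runs the diffusion forward model on the phantom and
its homogeneous twin and applies one shared channel-gain/noise realization
to both scans (log-normal per-channel gains, default sdlog 0.05 when
enabled; one realization per session, mirroring a single hardware state).
The acceptance computations use the deterministic noiseless defaults: the
quantities being reproduced are systematic (target-induced suppression of
class maxima), not noise-driven.

`voxel_monte_carlo()` is the physics cross-check: a weighted-photon random
walk on a 1 mm voxelization with Henyey-Greenstein scattering
($\mu_s = \mu_s'/(1-g)$), Fresnel reflection at the index-mismatched
surface, cone sources (120 degree divergence) and 1.5 mm-diameter detector
apertures, with Russian roulette below weight $10^{-4}$. Energy is
conserved to bookkeeping precision (the roulette's net weight
creation/destruction is tracked explicitly). Desk-scale photon budgets
($10^4$–$10^6$ per source) cannot populate 1.5 mm apertures across a 44 mm
slab, so the cross-check tests run thinner slabs and wider apertures and
compare distance-class *ratios* within Monte Carlo error bars —
variance-reduction choices, not physics changes.

## What the generator does not emulate

The synthetic data are diffusion-model data: passing the pipeline on them
shows the calibration algebra, selection rules and inversion behave as
designed, not that the diffusion model matches tissue. Real breasts add a
curved, partially-covered boundary (the slab plus coverage masks is an
approximation), chest-wall losses, physiological heterogeneity far from
the "single small absorber" idealization, and detector noise floors.
The reference values this package reproduces were themselves produced by
a Monte Carlo study; substituting the deterministic diffusion generator
shifts the virtual-reference fidelity metric by of order one percentage
point. That metric is also not fully mesh-converged: at the default
2.5 mm generator mesh the baseline error is 2.7% (vs 4.4% reported; the
finer 2 mm mesh gives 3.5%), and the R = 10 mm size variant gives 4.9%
(vs 3.3% reported). The reported size sweep *decreases* with radius,
which no noiseless diffusion generator can reproduce — a strictly larger
absorber suppresses strictly more — so the size-variant comparison should
be read as order-of-magnitude agreement under generator substitution.

# Numerical choices

- Distance-class grouping keys on the squared distance rounded to
  $10^{-6}$ mm$^2$: exact for integer-mm pitches, immune to float noise.
- Amplitudes below $10^{-30}$ in any calibration denominator raise a
  division-hazard error naming the pair, rather than producing silent
  huge ratios.
- The Hankel quadrature truncates at $k_{max} = \max(2, 40/L)$ mm$^{-1}$,
  where the integrand has decayed by $e^{-40}$ relative to its scale.
- Peak search requires a strict rise above the profile minimum, so flat
  profiles report a metric failure instead of fake peaks; ties on
  plateaus are resolved by the first sample.
- All randomness (gains, noise, photon paths) flows from explicit integer
  seeds; the Monte Carlo kernel consumes R's RNG stream, so `set.seed()`
  reproduces runs bit for bit.

# Problem sizes

The shipped tests and the acceptance script run the full study at desk
scale: default 2.5 mm generator meshes (~33k nodes), 2 mm reconstruction
meshes (~63k nodes, 6 Gauss-Newton iterations), 144-pair probe layouts,
and Monte Carlo budgets of $10^4$–$10^5$ photons per source on reduced
geometries. These sizes were chosen so the whole validation cycle runs on
a single CPU in tens of minutes while leaving every qualitative
conclusion, and the quantitative tolerances stated above, intact.

# Limitations

- Slab geometry only: no curved breast contours or mesh import beyond the
  package's own VTK writer/reader.
- $\mu_a$-only reconstruction with a single global Tikhonov weight; no
  spatially varying or spectrally constrained regularization.
- The virtual reference assumes absorbing (not scattering) perturbations
  that are small relative to the organ.
- Absolute recovered $\mu_a$ values depend on the (unpublished)
  normalization conventions of the reference implementation's inversion;
  ratios and widths are the quantitative outputs, absolute peaks are
  qualitative.
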