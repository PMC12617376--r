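---
title: "Comparing DCS analytical models on a layered head: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing DCS analytical models on a layered head: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: the models it
implements, the conventions and numerical choices behind them, what the
synthetic-data generator does and does not emulate, and the design decisions
taken where more than one reasonable convention exists.

## The physical problem

Diffuse correlation spectroscopy (DCS) shines long-coherence near-infrared
light into tissue and measures the normalized intensity autocorrelation
g2(τ) of the re-emerging speckle. Moving red blood cells decorrelate the
field; the decay rate of g2 therefore encodes microvascular flow. The field
autocorrelation G1(r, τ) obeys the correlation diffusion equation, a
Helmholtz-type equation in which flow appears as an extra, delay-dependent
absorption term ⅓ μs′ k₀² α⟨Δr²(τ)⟩, with ⟨Δr²(τ)⟩ = 6 D_B τ for diffusive
scatterer motion. The product α·D_B (mm²/s) is the blood flow index (BFi);
in the brain layer it is the cerebral index CBFi. The measured g2 connects
to the normalized field correlation g1 through the Siegert relation
g2 = 1 + β g1², with β set by the detection optics (0.5 throughout for the
synthetic data, emulating detection of two speckle modes).

The adult head is layered — scalp, skull, cerebrospinal fluid (CSF), brain —
and a detector at separation ρ on the scalp sees a mixture of all of them.
The package exists to compare, on known ground truth, how well three
inversion models recover cerebral flow from such mixed signals: the
homogeneous **semi-infinite** model, a **two-layer** model (extracerebral +
cerebral), and a **three-layer** model (scalp, skull, cerebral).

## The head model and delay grid

`four_layer_head()` returns the default truth: thicknesses 5 / 7 / 2 / ∞ mm,
absorption 0.019 / 0.014 / 0.001 / 0.020 mm⁻¹, scattering 6.6 / 8.6 / 0.002 /
11.0 mm⁻¹ with anisotropy g = 0.89 everywhere, Brownian coefficients
1e-6 / 8e-8 / 1e-8 / 6e-6 mm²/s, refractive index 1.37 in every layer,
wavelength 785 nm. The wavenumber k₀ = 2π n₀/λ uses the tissue index, not
air. Coordinates: z runs from the surface into the tissue; the source sits
at the origin; detectors at radius ρ on the surface. The model ships as a
YAML file (`inst/extdata/four_layer_head.yaml`); numbers serialize as
17-significant-digit strings so a write/read round trip is bit-exact.

`tau_grid()` reproduces a multi-tau correlator schedule: bin width 6.145 ns
for the first 16 channels, tripled every 16 channels. The default spans 14
groups (224 channels). Note the arithmetic: 14 tripling groups reach a
maximum delay of ~0.24 s, far beyond the ~10 ms needed for full decay at
ρ = 15–35 mm; the extra flat-tail channels carry g2 ≈ 1 in both data and
model and are harmless to the fits. The per-channel bin index used by the
noise model is m = τ/T_bin, a real number under the multi-tau cumulative
delay convention; channel-local T_bin also sets ⟨n⟩ = I·T_bin, so deeper
channels integrate more photons per bin.

## Analytical forward models

**Semi-infinite.** The classical two-source construction: an isotropic
source at depth z₀ = 1/μs′ and its image mirrored about the extrapolated
zero-fluence plane at z = −z_b, z_b = 2D(1+R_eff)/(1−R_eff), with R_eff
from the standard polynomial in the refractive index (R_eff ≈ 0.506 at
n = 1.37) and D = 1/(3μs′). The delay-dependent attenuation is
K(τ)² = 3μs′μa + 6μs′²k₀²αD_Bτ. For a homogeneous half-space the image
construction solves the extrapolated-boundary problem exactly, which the
test suite exploits: the layered solver in its homogeneous limit agrees
with the closed form to quadrature accuracy (~1e-10), far inside the 1%
assertion.

**Two and three layers.** In the radial spatial-frequency domain each layer
obeys a modified Helmholtz equation with pseudo-attenuation
αᵢ²(s, τ) = s² + (μ_{a,i} + 2μs′ᵢk₀²D_{B,i}τ)/Dᵢ. The surface field is
assembled by an admittance (transmission-line) recursion from the deepest
layer upward — flux and fluence continuous at interfaces, Dirichlet zero at
the extrapolated plane, the source again at z₀ = 1/μs′ of the first layer —
using only `tanh` and exponentials of negative arguments, so large αL
cannot overflow. The real-space solution is recovered by numerical Hankel
inversion: 8-point Gauss–Legendre panels of half a J₀ period each,
truncated where the e^{−s·z₀} envelope falls below ~1e-12 of its peak
(`smax_scale = 32`). Doubling the truncation or halving the panel width
changes g1 by < 1e-6 everywhere (asserted in the tests).

During fitting the layered model is evaluated exactly at 64 log-spaced
delay knots and interpolated to the 224-channel grid with a monotone cubic
spline in log τ; the interpolation error (< ~3e-5 in g2) is two orders of
magnitude below the noise floor of any fitted curve, and `knots = 0`
switches to exact per-channel evaluation. Inverse-crime recovery with the
knotted evaluator is within 0.01% of truth.

## The synthetic-data generator

`run_mc()` random-walks photons through the slab (200×200×200 mm box) and,
for every detected photon, tallies the per-layer momentum transfer
Yᵢ = Σ(1−cos θ) and pathlength Lᵢ. The field correlation follows as

g1(τ) ∝ Σ_n exp(−⅓ k₀² Σᵢ Y_{n,i} · 6D_{B,i}τ) · exp(−Σᵢ μ_{a,i} L_{n,i}),

normalized to its τ = 0 value. Two consequences shape the design:

* **Absorption is applied terminally**, never in flight, so the tallies are
  independent of every D_B and one transport run serves the entire
  perturbation grid (`generate_dataset()` re-weights the same tallies for
  each flow level). Re-evaluation is bit-reproducible.
* Because photons never die by absorption, a walk needs a stopping rule.
  Photons are discarded on geometric escape (side/bottom of the box, or
  surface escape outside any detector) and by a roulette on the
  *accumulated absorption optical depth* Σμ_{a,i}Lᵢ > 15: such photons
  would enter the estimator with weight < e⁻¹⁵ ≈ 3e-7, three or more orders
  below typical detected weights. Thresholding on optical depth rather than
  pathlength is deliberate — it treats low-absorption (CSF-heavy) paths
  fairly, where a pathlength cap would bias against them.

**Detectors** default to full annular rings (half-width 0.5 mm) centred on
the source, exploiting the slab's radial symmetry: a ring at ρ = 30 mm
collects ~200× the photons of a 1-mm disc, so ~10⁶–10⁷ launched photons
give tail statistics comparable to disc-detector runs of ~10⁹. Disc mode is
retained and the tests check ring and disc estimates agree within combined
Monte Carlo error. Per-channel uncertainties come from a block bootstrap
over photons (`tallies_to_g1(..., n_boot)`).

**Scattering sampling.** The default mode samples Henyey–Greenstein angles
with the per-layer g = 0.89 at the full scattering coefficient, i.e. the
anisotropy the head model states. An isotropic similarity mode (step on
μs′, isotropic angles, each event contributing 1−cos θ with mean 1) is
provided and tested against the anisotropic mode. The anisotropic mode is
the default for two reasons: it is the faithful representation of the
stated tissue anisotropy, and — perhaps counter-intuitively — it is also
the *faster* mode in the four-layer geometry, where per-photon cost is
dominated by deep-wandering photons that exhaust the roulette budget in
either mode. The similarity mode remains useful for homogeneous media,
where it is several times faster.

**Boundaries and source.** The external medium is air (n = 1): photons
reaching the surface undergo unpolarized Fresnel reflection or total
internal reflection at the n = 1.37 → 1.0 step; transmitted photons are
detected or lost. The source is a 1-mm-diameter disc launching a pencil
beam normally into the tissue; no specular launch loss is applied (the
beam enters from outside the medium). The transport RNG is a
self-contained xoshiro256++ generator, so identical seeds give identical
tallies on any platform, independent of R's RNG state.

**What the generator does and does not emulate.** It reproduces layered
partial-volume mixing, correlator channel spacing, shot/speckle noise
magnitudes, and count rates tied to separation. It does not emulate curved
or MRI-derived anatomy, probe-pressure effects, detector numerical
aperture, afterpulsing or dead time, correlated channel noise, or
voxelization of the geometry. Passing tests therefore demonstrate
correctness of the pipeline on an idealized slab, not performance on real
heads.

## The correlator noise model

Noise is zero-mean Gaussian per channel with standard deviation

σ(τ) = √(T_bin/T_int) · [ (β²(1+e^{−2ΓT_bin})(1+e^{−2Γτ}) +
2m(1−e^{−2ΓT_bin})e^{−2Γτ}) / (1−e^{−2ΓT_bin}) +
2β(1+e^{−2ΓT_bin})/⟨n⟩ + (1+βe^{−Γτ})/⟨n⟩² ]^{1/2},

evaluated per channel with that channel's T_bin and m. The grouping above —
the first fraction's denominator covering both speckle terms, the two
photon-count terms added inside the bracket — follows the standard
multi-tau noise model; a unit test pins four channels of σ against an
independent 50-digit transcription of the formula, so any silent regrouping
is caught. The decay rate Γ is extracted per clean curve by a
single-exponential fit g2 = 1 + β e^{−2Γτ} over the full grid. Operating
constants: count rates 686.1 / 142.8 / 35.1 / 10.0 / 3.4 kcps at
ρ = 15 / 20 / 25 / 30 / 35 mm (anchored at 10 kcps at 30 mm and scaled by
CW fluence; the printed values are shipped as constants because the exact
geometry behind the scaling is not uniquely determined), and T_int = 60 s.
Noisy curves are *not* clipped to [1, 1+β]; the fitting routines tolerate
early channels dipping below 1. σ scales exactly as 1/√T_int, which the
tests assert to machine precision.

## Fitting strategies

All inversions minimize an unweighted sum of squared g2 residuals over the
configured delay window with a bounded Nelder–Mead simplex; bounds are
enforced by the smooth sine-squared transform x = lb + (ub−lb)·sin²θ, the
construction used by bounded-simplex wrappers in other environments. Flow
coefficients are optimized in log₁₀ space (their bounds, [1e-9, 1e-4]
mm²/s, span five decades); β, when free, is bounded in [0, 1] and starts at
0.5. A small set of log-spaced start candidates (default 3) is screened and
the simplex runs from the best, guarding against local minima in
multi-layer fits at modest cost. Solutions pinned at a bound are flagged
not converged.

* **Semi-infinite ETLR**: brain optics assumed known; the fitted window is
  τ ≤ 30 µs (92 channels). The alternative early-range criterion
  g2 ≥ 1.25 used in some prior work can be emulated by passing a custom
  `etlr_cutoff`; the fixed 30-µs window is the default.
* **Single-exponential ETLR**: fits τ_c in g2 = 1 + βe^{−2τ/τ_c} on the
  same window; relative flow derives from the decorrelation speed as
  rCBFi = τ_c,baseline/τ_c (baseline = mean recovered τ_c).
* **Two-layer**: extracerebral layer = scalp optics, 12 mm thick (scalp +
  skull); CSF grouped with the brain. SD fits one curve with β fixed (0.5)
  or free; MD jointly fits a short (15 mm) and a long separation with one
  shared free β (the shared-β convention is an assumption, documented
  here).
* **Three-layer**: scalp and skull as in the truth table; CSF grouped with
  the brain; the skull coefficient is held at its assumed baseline
  (8e-8 mm²/s) — treating skull flow as static during fitting — so the
  fitted parameters are scalp flow, brain flow, and (MD) β.

A Levenberg–Marquardt backend (`backend = "lm"`, via minpack.lm) exists
solely for method-comparison experiments; the simplex is the default and
the one used everywhere else, as the least-squares backend shows larger
fluctuations on noisy early-lag windows.

## Metrics and experiment orchestration

rCBFi divides each recovered coefficient by the *global mean* recovered
baseline (not per-realization pairing). Sensitivity,
S = [(CBFi/CBFi₀) − 1]/[(D_B/D_{B,0}) − 1] × 100, is computed per
realization and then aggregated (mean for headline numbers, median for
crosstalk curves); the aggregation order is fixed. The unperturbed level
raises an error rather than being silently skipped. For skull-flow
crosstalk the zero-flow level against the 8e-8 baseline yields denominator
−1, flipping the sign convention for that cell — documented rather than
special-cased. `run_experiment()` drives the (ρ × level × realization)
grids: brain-flow perturbations ±25% / ±50% of 6e-6 mm²/s, scalp flow
2–18e-7 mm²/s, skull flow 0–1.6e-7 mm²/s (`perturbation_grid()`), with 20
noise realizations per condition by default. The parameter-mismatch
scenario perturbs the *assumed* absorption, reduced scattering and
thicknesses via `perturb_reduction()`; the tests assert its expected
signature — biased absolute flow, preserved relative flow.

## Problem sizes

The test suite and the acceptance script run at desk scale as a deliberate
package choice: 1.5–2×10⁶ launched photons per transport run with ring
detectors (tail standard errors of a few × 1e-3 per channel at
ρ = 30 mm), 10–20 noise realizations per condition, and 4–10 realizations
for the most expensive (three-layer MD) grids in the test suite. These
sizes put sampled quantities within a few percent of their large-sample
values while keeping a full run in minutes on one CPU.

## A finding on the CSF layer, and known limitations

With the stated parameters the CSF layer is nearly transparent
(μs′ = 2.2e-4 mm⁻¹) and two millimetres thick: in a continuous slab it acts
as a light guide. At ρ = 30 mm roughly 40% of detected photon weight
carries more than 10 mm of CSF path, photons reach the brain more
efficiently than any two- or three-layer diffusion model predicts, and the
layered inversions consequently *over-respond*: on clean four-layer data
the two-layer SD and three-layer MD brain-flow sensitivities run at
~115–140% rather than ~100%, and the three-layer MD absolute brain
coefficient lands near 1.0e-5 mm²/s against a 6e-6 truth. This is a
genuine property of the continuous four-layer geometry, not an inversion
defect: the identical pipeline applied to an exact three-layer truth (CSF
removed) recovers every fitted parameter within 0.5%, and the MC and
analytical forward models agree within Monte Carlo error wherever they
describe the same geometry. Voxelized transport, a more scattering
"effective" CSF, or a detector acceptance-angle cutoff would all temper
the channeling; none is adopted here because the package implements the
stated parameters literally. Semi-infinite results are essentially
unaffected (the ETLR window weights early decay), and relative-flow
tracking remains accurate for all models.

Other limitations worth restating: slab geometry only; up to three layers
analytically; Brownian-motion dynamics only (no random-flow term);
unweighted penalties (no σ-weighting across the two separations of an MD
fit — the convention matches the penalty definitions, but it does mean the
noisier long-separation curve carries equal nominal weight); and a single
count-rate/integration-time operating point per separation.
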