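---
title: "Models and methods: LET in dynamically collimated proton pencil beams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: LET in dynamically collimated proton pencil beams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dcslet)
```

## The problem

Energy-specific collimation in pencil beam scanning (PBS) proton therapy —
paired nickel trimmer blades driven to the edge of each beamlet — sharpens
the lateral penumbra, at the price of a low-energy proton scatter
population produced in the blades. Because the relative biological
effectiveness (RBE) of protons rises with linear energy transfer (LET),
that scatter changes not only the physical dose but also the RBE-weighted
dose. `dcslet` implements, at desk scale, the full computational chain
needed to study this: condensed-history proton transport with per-step
LET scoring, exit-plane spectral analysis, analytic surrogate beamlets,
composite-field plan optimization, and a phenomenological RBE model.

## Transport and scoring model

Protons are sampled from a divergent point source on the beam axis
(`source_model()`): a Gaussian-distributed aim point at the phantom
surface gives the configured spot sigma, and kinetic energies are
Normal(nominal, 0.7% of nominal). The transport kernel
(`transport()`, `simulate_beamlet()`) advances particles through vacuum,
the nickel trimmer blades and the voxelized water phantom with:

* mean energy loss by exact continuous-slowing-down (CSDA) range
  inversion on calibrated Bethe stopping tables,
* Gaussian (Bohr) energy-loss straggling, variance
  $0.1569\,(Z/A)\,\rho\,\Delta s$ MeV²,
* Highland multiple Coulomb scattering per step,
* a two-parameter nuclear-interaction surrogate (rate 1%/cm in unit
  density at ≥ 20 MeV; 60% of the interacting proton's energy deposited
  locally, one secondary proton with $E \sim U(5, 0.5E)$ emitted
  forward), and
* steps refined to ≤ 20% of the residual range so the Bragg peak is
  resolved; the above-cutoff track end is scored over the true residual
  range and the sub-cutoff remainder (< 8 µm of water) deposited as a
  point.

Each scored step adds $(\varepsilon_i, l_i, \varepsilon_i^2/l_i)$ to its
voxel, split exactly at voxel faces. The track-averaged and dose-averaged
LET of a voxel are

$$\mathrm{LET}_t = \frac{\sum_i \varepsilon_i}{\sum_i l_i}, \qquad
  \mathrm{LET}_d = \frac{\sum_i \varepsilon_i^2/l_i}{\sum_i \varepsilon_i},$$

which satisfy $\mathrm{LET}_d \ge \mathrm{LET}_t$ by the Cauchy–Schwarz
inequality — asserted over every simulation in the test suite. Point
deposits (cutoff kills, nuclear lumped energy) enter a separate dose
accumulator but are excluded from all three LET sums, since the
dose-averaged estimator is undefined at zero path length; diluting its
denominator with lumped pseudo-dose would bias the Bragg-peak LET
downward and couple it to nuclear-model noise.

## Stopping-power calibration

No measured stopping tables ship with the package. Tables are generated
from the Bethe formula (no shell or density corrections; I = 75 eV for
water, 311 eV for nickel) and calibrated against the only authoritative
anchors available: the simulated Bragg-peak depths 6.4 / 10.65 / 15.75 cm
at 90 / 120 / 150 MeV. The calibration targets the *simulated peak*, not
the CSDA range: with Bohr straggling plus the 0.7% energy spread, the
integral-depth-dose maximum sits 0.7–1.7 mm proximal to the range, and
the 1 mm binning plus parabolic refinement of the peak estimator shifts
the measured value by a further fraction of a millimetre. The calibration
therefore models the whole measurement chain (analytic Bragg curve from
the package's own stopping profile, Gaussian range spread, multiple
scattering detour, 1 mm binning, parabolic refinement) and solves for a
scale factor plus a small energy tilt $(E/100)^{\alpha}$, $\alpha \approx
0.007$, frozen below 20 MeV — a stand-in for the shell corrections plain
Bethe lacks. A single scale factor alone cannot put all three peaks
within 1 mm. The calibrated tables stay within 3% of the closed-form
Bethe oracle over 5–250 MeV, and the Monte Carlo peaks land within
±0.7 mm of the anchors across seeds.

## Beamline geometry

The X and Y trimmer pairs are centred 6.5 and 10.65 cm above the phantom
surface (the X pair's exit plane 5 cm above the surface, so the spectral
tally plane "5 cm below the X trimmers" is the surface itself; the Y pair
4.15 cm further upstream). Blade edges are focused along the ray from the
effective source (200 cm) through the edge. Blades are 3 cm thick: the
calibrated nickel range of a 160 MeV proton is ~2.9 cm, and a thinner
blade would leak punch-through protons with tens of MeV — the 2.5 cm
first draft flooded the exit plane with them. Spot sigmas at the surface
follow $0.37\,(E/150)^{-0.67}$ cm, the power law through the
90/120/150 MeV defaults.

## Spectral features and their limits

Exit-plane crossings are histogrammed in 0.1 MeV and 0.1 keV/µm bins.
The scatter fraction is the count fraction below the incident-spectrum
mean minus three of its sigmas (so a pure Gaussian beamlet gives the
Normal tail mass, ≈ 0.00135). All qualitative collimation behaviours
hold: X-only and Y-only spectra are statistically indistinguishable, the
scatter fraction falls monotonically with trimmer offset, grows with the
number of blades, and collimation raises the 99th-percentile track LET.
The *absolute* scatter fractions, however, are much larger than a
full beam-model Monte Carlo reports: a slab-geometry condensed-history
model with Highland scattering lets of order 1% of the beam escape
through the medial blade face, so enhancement ratios over the pure
Gaussian baseline come out orders of magnitude above the reference
factors (≈1.8 and ≈6.5). We report the model's ratios as computed; the
discrepancy is a documented limitation of the parameterized source (no
nozzle-scatter baseline) and the unbounded tally plane, not a property
the tests hide.

## Surrogate beamlets

`surrogate_params()` builds an analytic beamlet from the same physics as
the transport model: depth dose from the stopping profile convolved with
the combined Bortfeld-plus-beam range spread, primaries attenuated at the
nuclear surrogate rate with the interaction energy redeposited locally
(peak-to-entrance ratios agree with the Monte Carlo to a few per cent,
peak depths to better than 1 mm); Gaussian lateral profiles with
$\sigma(z)^2 = \sigma_0^2 + (0.11\sqrt{z})^2$; aperture truncation as an
erf penumbra (σ = 0.12 cm) re-blurred by in-water scattering; an optional
2% broad halo emulating trimmer scatter; and a dose-averaged LET model
anchored at entrance and peak values obtained from a deterministic
range-straggling quadrature over the package's stopping tables (no Monte
Carlo noise enters the anchors), with a Gaussian ridge of relative height
0.5 at collimated edges. `make_surrogate_scoremaps()` emits the same
accumulator container the Monte Carlo fills, so every downstream stage
accepts either.

## Planning

`spot_layout()` places energy layers at 4 MeV spacing spanning the target
depth extent and spots on a 0.25 cm lattice covering each layer's target
cross-section plus one spot margin. The cube target (4 cm deep, 5 × 5 cm)
uses a fixed aperture at the target boundary; the inverted pyramid
(5 × 5 cm base at the shallow face, 5 mm apex at the deep end) matches
each layer's aperture to its own cross-section, so the aperture expands
from the most distal layer upward — the orientation in which collimating
the distal layers shapes the LET environment of all shallower tissue.
Both targets default to a 2.5–6.5 cm depth extent: energy-specific
collimation is clinically aimed at shallow targets, and this is the
shallowest placement we model. For lattice layouts the surrogate maps are
separable, so the influence operator and the composite maps are computed
per layer as small matrix products — exact for the surrogate, with no
need to store thousands of voxel maps.

Weights are optimized by accelerated projected gradient (FISTA with
restart) on
$\sum_{\mathrm{target}} (D - p)^2 + \lambda \sum_{\mathrm{normal}} D^2$,
$\lambda = 0.05$, to a relative objective change of $10^{-6}$, and the
plan is normalized so the physical target D95 equals the prescription.
Composite LET_d is recombined from the weighted accumulator maps
($\sum_b w_b \Sigma\varepsilon$ and $\sum_b w_b \Sigma\varepsilon^2/l$),
never by averaging per-beamlet LET maps.

Two consequences of the study conditions are worth stating plainly.
First, with a flat 0.7% energy spread the Bragg-peak width at 50–90 MeV
(σ ≈ 0.07–0.10 cm) is smaller than the ~0.5 cm range step of a 4 MeV
layer spacing, so the optimized spread-out peak retains ±15–25% depth
ripple and the cube's D5/D95 sits near 1.4; a machine whose relative
energy spread grows toward low energies would flatten it. Second, the
half-prescription volume comparison is only sensitive to collimation for
shallow targets: at depth, the entrance column of the field already
exceeds half prescription everywhere inside the aperture projection, and
trimming outside it cannot change the 50% isodose.

## RBE model

`rbe()` implements the phenomenological linear-quadratic proton RBE
model with $\mathrm{RBE}_{max} = p_0 + p_1\,\mathrm{LET}_d/(\alpha/\beta)_x$
and $\mathrm{RBE}_{min} = p_2 + p_3 \sqrt{(\alpha/\beta)_x}\,\mathrm{LET}_d$
(defaults $p_0 = 0.99064$, $p_1 = 0.35605$, $p_2 = 1.1012$,
$p_3 = -0.0038703$, $(\alpha/\beta)_x = 3.49$ Gy):

$$\mathrm{RBE} = \frac{1}{2D}\left[\sqrt{(\alpha/\beta)_x^2
  + 4D(\alpha/\beta)_x\,\mathrm{RBE}_{max}
  + 4D^2\,\mathrm{RBE}_{min}^2} - (\alpha/\beta)_x\right],$$

with the continuous limit $\mathrm{RBE}_{max}$ at $D \to 0$. The
published typeset equation is garbled; this is the standard form of the
cited model, which the printed coefficient signs match. $D$ is the
per-voxel physical dose of the single delivered plan (25 Gy scale);
fractionation is not modelled.

## Analysis conventions

LET_d maps are median-filtered with a one-voxel span and optionally
Gaussian-smoothed (σ = 0.5 voxel, normalized convolution so masked
voxels neither leak nor vanish); dose maps are smoothed only. Planar
dose-weighted LET_d is $\sum \mathrm{LET}_d D / \sum D$ over the
unmasked voxels of a depth plane. Penumbra LET is interpolated at the
outermost 10%-of-peak dose crossing per side. Volume histograms are
cumulative volume-fraction-above-threshold curves; D95 is their inverse
at 95%. The "upper quartile" of a LET distribution is its 75th
percentile. Difference volume histograms use RBE-weighted minus physical
dose. Voxels with dose below $10^{-4}$ of the map maximum are masked in
LET maps (statistical noise floor).

## Problem sizes

The packaged analyses run at reduced statistics chosen for desk-scale
work: $10^5$ histories for spectra and range anchors, $2\times 10^5$
for per-beamlet LET maps (reference simulations used $10^6$–$10^7$), a
1 mm isotropic beamlet grid over a 10 × 10 × 20 cm phantom, and a
1.25 mm plan grid over 12 × 12 × 8 cm with ~5000 (cube) and ~2000
(pyramid) beamlets per delivery. Statistical error at the Bragg peak at
these counts is ~1–2%.

## Known limitations

* The parameterized divergent Gaussian source carries no beamline
  scatter baseline, so absolute scatter fractions (and their
  enhancement ratios) are not comparable to a full nozzle model.
* Highland/Bohr condensed history reproduces ranges and dose shapes
  well, but the Bragg-peak dose-averaged LET trend with energy is
  steeper than reference values (+15% at 90 MeV, −11% at 150 MeV under
  the flat 0.7% energy spread).
* No neutrons, photons, heavy fragments, or δ-ray transport; LET is
  proton LET.
* Surrogate beamlets are relative (no absolute output calibration), and
  beamlets are translated laterally rather than re-simulated off-axis.
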