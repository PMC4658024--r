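---
title: "Simulating and quantifying CT metal artefact reduction"
author: "marstreak"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and quantifying CT metal artefact reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`marstreak` rebuilds, at desk scale, the computational chain of a
clinical comparison of CT metal-artefact-reduction (MAR) methods: a
synthetic dual-energy acquisition of implant-bearing phantoms, four
reconstruction arms, a Fourier-based streak score, and nonparametric
arm comparisons. This vignette explains the models, the parameters that
matter, and the choices made where the design was genuinely open.

## The physics model

**Attenuation.** Every material is described by two coefficients in

$$\mu(E) = a_{pe}\,(E/70)^{-3} + a_c\, f_{KN}(E),$$

a photoelectric basis and the Klein–Nishina total-cross-section shape,
both normalized to 1 at the reference energy $E_0 = 70$ keV (the
conventional effective energy of ~120 kV imaging). Water is anchored at
$\mu(70) = 0.1928\ \mathrm{cm^{-1}}$, the standard narrow-beam value, so
Hounsfield calibration has a fixed point. A two-basis model rather than
tabulated cross sections keeps the package self-contained; it reproduces
the two phenomena that matter here — spectral decline (beam hardening)
and material-dependent decline rates (dual-energy contrast) — but it has
no absorption edges (see *Metals* below) and no coherent scatter.

**Metals.** The implant alloys of a clinical cohort are unknown in
practice, so the three tiers are stand-ins with deliberate spectral
personalities, tiered in density ($\mu(70)$: titanium 5.3 < steel 8.5 <
amalgam 22 cm⁻¹, each at least ten times cortical bone):

* *titanium* (4.0, 1.3) and *steel* (6.5, 2.0) are photoelectric-heavy:
  their attenuation falls steeply with energy, so the 100 kV channel
  starves behind the implant while the tin-filtered 140 kV channel keeps
  a usable signal. This is what lets monoenergetic extrapolation help
  hip cases: it re-weights towards the channel that can still see.
* *amalgam* (4.0, 18.0) is Compton-flat. Real dental amalgam is rich in
  mercury and silver, whose K edges (83 keV and 25.5 keV) sit in or
  below the imaging band, so the high-kV channel gains far less than a
  smooth $E^{-3}$ model would predict. The flat profile models that net
  effect within a monotone $\mu(E)$; with crown-sized implants both
  channels starve and extrapolation has nothing to recover — the
  mechanism behind the hip/dental divergence of the dual-energy arm.

**Spectra.** Kramers bremsstrahlung fluence $(kVp - E)/E$ on
$[20, kVp]$ keV, filtered by 2.5 mm aluminum-equivalent inherent
filtration and, for the high channel, 0.4 mm of tin. Only the *relative*
hardening between the channels matters to the artefact mechanisms, so no
attempt is made to match a manufacturer spectrum. Default 24 bins; the
mean-energy ordering (tin-filtered > 100 kV) holds for any binning.

**Acquisition.** 2D parallel beam, 180 views over 180°, detector pitch
equal to the pixel size, ray-driven (Joseph) forward projection with
half-pixel steps and bilinear sampling, compiled in C++. Detected
intensity per ray is $I = N_0 \sum_b w_b \exp(-\sum_m \mu_m(E_b) t_m)$;
noisy mode draws Poisson counts and floors them at one count before the
log (a detector electronic floor — this is what turns total absorption
into the characteristic starvation streaks). Noiseless all-absorbing
rays are clamped at a log attenuation of 60 with a warning.
Reconstruction is filtered back-projection with the classical discrete
Ram-Lak kernel (Shepp-Logan apodization available), pixel-driven linear
back-interpolation. On a 256² water disk with 180 views the chain
recovers $\mu_{water}$ to well under 1%.

**Fluence defaults** (`n0_low = 1e7`, `n0_high = 2e7` photons per ray):
chosen so that artefact-remote soft tissue reconstructs with clinically
plausible noise while every ray through an implant starves. At much
lower fluence the *whole* image is photon-limited and streaks are no
longer implant-specific — sinogram-domain MAR, which only alters rays in
the metal trace, then cannot show its effect, which contradicts the
clinical picture being emulated.

## The phantoms

Two geometry families at 256² (40 cm field of view for hips, 22 cm for
dental), with per-seed jitter so a cohort varies:

* **hip**: elliptical pelvis of soft tissue, sacral and iliac bone, two
  femoral heads of which one (`hip_unilateral`) or both
  (`hip_bilateral`) are replaced by a metal disc (diameter ≥ 10% of the
  grid) inside a bone annulus, plus two small iodinated vessels;
* **dental**: head-sized soft-tissue disc, mandibular bone arc, 2–6
  crown-sized amalgam implants (~1 cm) placed pseudo-randomly on the
  arc, plus two vessels.

Each phantom guarantees an artefact-remote soft-tissue patch of at least
20×20 px for the noise ROI, and carries its scoring polygon: a 16-gon in
the soft-tissue annulus just outside the implant-bearing bone (hip:
radius 0.11·n around the implant; dental: radius 0.365·n, between jaw
and skin). Placing the trace where only streaks — not anatomy edges —
cross it is what makes the Fourier score specific: on the metal-free
control the same trace is nearly flat.

Cohorts reproduce the study strata (default 20 hip, ~1 in 9 bilateral,
and 30 dental). Per-case seeds derive from the master seed by the
documented rule in `make_cohort()`, so cohorts are reproducible
element-wise.

## The four arms

* **NOMAR** — FBP of both channels, blended 50/50 into the 120
  kV-equivalent mixed image (the blend weight is configurable; vendors
  do not publish theirs).
* **IMAR** — per channel: segment metal (≥ 3000 HU, opening+closing),
  freeze the metal trace, then cycle *build prior → normalized
  interpolation (NMAR) → FBP → frequency-split recombination (FSMAR)*,
  the cycle count tied to the implant tier (titanium 3, steel 4,
  amalgam 6); corrected channels are then blended as above. Applied per
  kV channel before any mixing or decomposition — the vendor's internal
  order is unpublished, but the study's own arm description (source
  images with IMAR → mixed / monoenergetic) implies channel-wise
  correction.
* **DEMAR** — image-domain two-basis decomposition of the channel pair
  (closed-form 2×2 per pixel, using the same basis functions as the
  simulator, which makes noiseless decomposition exact and testable),
  virtual monoenergetic synthesis at 130 keV, then the frequency-split
  noise technique: low-pass of the 130 keV image plus high-pass of a
  70 keV reference from the same maps (σ = 2 px, λ = 1).
* **IMAR+DEMAR** — DEMAR computed from the IMAR-corrected channels.

## Numerical choices in the MAR loop

The NMAR prior is a three-plateau tissue model (air / soft / bone
medians, metal assigned the soft plateau, Gaussian-smoothed). Four
stabilizers keep the prior→inpaint→reconstruct loop convergent on noisy
data, where streaks would otherwise contaminate the prior and feed back
exponentially:

1. tissue classification runs on a 2 px median-filtered copy (thin
   impulsive streaks must not masquerade as bone);
2. the air class must be connected to the image border — enclosed dark
   bands around an implant are artefact, not anatomy, and stay soft;
3. plateau medians are clamped to physiological ranges (air −1100…−850,
   soft −150…250, bone 250…2200 HU) — the prior is a model, not a
   measurement;
4. inpainted rays are clamped to the measured sinogram's range.

Defaults `t_air = −500`, `t_bone = 500` HU, `sigma_prior = 6` px: the
bone threshold sits above the brightest common streaks, and the heavier
prior smoothing matters because the inpainted band inherits the prior
projection's fine structure — a rougher prior writes its own streaks
into the corrected image. FSMAR uses `sigma_split = 2` px, `r_edge = 6`
px, `w_edge = 1` (these have no published values; they are configurable
and their roles are: split scale, width of the edge-restoration zone,
and how much of the original's high band is restored there). The metal
mask and trace are frozen after the initial reconstruction —
re-segmenting each cycle risks oscillation. Views fully covered by the
trace are interpolated along the angle axis (a degenerate case the
sources are silent on). Rays outside the trace are returned bit-level
identical, and that invariant is tested.

## The streak metric

HU values are read by bilinear interpolation at 256 equally spaced
arc-length positions along the closed polygon (fixed sample count makes
band indices comparable across cases; nearest-neighbour sampling is
available for strict pixel-stepping). The unscaled one-sided DFT
magnitudes $|F_k|$, $k = 0..128$, are grouped into the bands {1,2},
{3,4}, {5–8}, {9–16}; the headline score is the total over k = 1…16.
The DC term is excluded everywhere — it encodes mean HU, not streaks.
Whether the source bands count from DC or from k = 1 is not stated in
the underlying method descriptions; this package counts from k = 1, and
whether the headline should be one band or their sum is equally
unstated — the sum is used, with all four bands always reported
alongside. Streaks crossing the trace appear at low k; uncorrelated
noise spreads to high k, and a k = 40 tone is provably invisible to the
score. Multi-slice scoring averages per-slice totals; since phantoms are
single 2D slices, "slices" in the cohort pipeline are independent noise
realizations, and the cohort default is one per case (five-realization
averaging is exercised through `score_case()` directly).

## Statistics

Paired arm contrasts use the Wilcoxon signed-rank test (same cases
across arms); Mann–Whitney U is exposed for unpaired stratum
comparisons. Both are implemented with an exact branch (shift-algorithm
convolution over mid-ranks, ties included; signed-rank up to 12
effective pairs, U when min(n, m) ≤ 8) and a normal approximation with
tie and continuity correction beyond; the branch is recorded in the
result. Two-sided p-values throughout, α = 0.05, no multiple-testing
correction. At n = 12 the exact two-sided p is a step function with
steps up to ~0.013, which bounds how closely any continuous
approximation can track it. Cohen's kappa is the unweighted 5×5
contingency form with the conventional interpretation bands
(lower-inclusive cut points at 0.21/0.41/0.61/0.81; values below 0 are
labelled "poor"); a degenerate single-category table returns 1 with a
warning. The reader simulator bins streak scores by quantiles of the
NOMAR distribution (defaults 0.1/0.35/0.65/0.9) into the 0–4 Likert
scale and perturbs a second reader by ±1 with probability 0.2 — the
calibration is arbitrary, exposed in the call, and exists so the
qualitative half of the pipeline (ratings → kappa) is testable end to
end.

Whether the underlying comparisons were computed per case or per slice
is not stated in the sources; this package compares per case.

## Problem sizes

The shipped conditions are 256² grids, 180 views, 24 spectrum bins,
cohorts of 20 hip + 30 dental cases with one noise realization per
case. The full cohort pipeline plus statistics runs in roughly five
minutes on one CPU; unit tests use 128² versions of the same phantoms.

## What the simulation does and does not show

The generator emulates the two artefact mechanisms named in the clinical
problem — beam hardening and photon starvation — in 2D parallel-beam
geometry with an idealized detector. It does **not** model spiral/cone
beam acquisition, scatter, detector cross-talk, automatic exposure
control, vendor reconstruction kernels, or real alloy compositions; the
absolute streak scores and percent reductions therefore characterize
*this simulator*, not any scanner. What the passing test suite shows is
directional and mechanistic: the simulator produces implant-specific
streaks (score ≥ 5× the metal-free control), the iterative loop removes
most of them while preserving implant edges and leaving out-of-trace
data untouched, 130 keV extrapolation helps where one channel retains
signal (hip tiers) and not where both starve (amalgam), and the combined
arm is best on hip cases — the qualitative pattern of the clinical
comparison, at cohort medians, under paired nonparametric tests.

Known limitations worth restating: monotone μ(E) cannot represent a
K edge (only its net flattening effect); the photon floor makes fully
starved rays deterministic rather than electronically noisy; the prior's
plateau clamps assume human-tissue HU ranges; and the polygon placement
is generator-provided, whereas clinical polygons are hand-drawn.
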