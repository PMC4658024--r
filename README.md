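# marstreak

Metal implants wreck CT images: the implant absorbs nearly all photons in
some projections (photon starvation) and preferentially absorbs the soft
end of the spectrum in others (beam hardening), so the reconstruction is
crossed by bright/dark streaks that can hide fractures, loosening or
tumours in exactly the tissue a radiologist needs to see. Two correction
families dominate clinical practice: **iterative sinogram-domain MAR**
(IMAR: normalized metal-trace interpolation plus frequency-split edge
restoration, cycled 3–6 times depending on implant density) and
**dual-energy virtual monoenergetic imaging** (DEMAR: a two-basis
decomposition of a 100 kV / tin-filtered 140 kV pair, extrapolated to
130 keV with a frequency-split noise technique) — and they can be
combined.

`marstreak` is a desk-scale, fully synthetic reimplementation of that
comparison for people studying MAR algorithms: it generates 2D phantoms
with hip-prosthesis or dental-implant geometry, simulates the dual-energy
polyenergetic acquisition with Poisson noise, reconstructs all four arms
(NOMAR, IMAR, DEMAR, IMAR+DEMAR), and quantifies residual streaks with a
polygon-trace Fourier metric:

* attenuation model: `μ(E) = a_pe (E/70)⁻³ + a_c f_KN(E)` per material
  (photoelectric + Klein–Nishina bases, water anchored at
  μ = 0.1928 cm⁻¹ at 70 keV for Hounsfield calibration);
* acquisition: `I = N₀ Σ_b w_b exp(−Σ_m μ_m(E_b) t_m)`, Poisson counts
  floored at 1 before the log; filtered back-projection (Ram-Lak or
  Shepp-Logan) behind a compiled parallel-beam projector pair;
* streak score: HU sampled at 256 equal arc-length points along a closed
  polygon, unscaled one-sided DFT, summed amplitudes of coefficients
  k = 1…16 (bands {1,2}, {3,4}, {5–8}, {9–16} reported alongside);
* statistics: exact-capable Wilcoxon signed-rank and Mann–Whitney U
  tests, Cohen's kappa with the conventional interpretation bands, and a
  seeded two-reader Likert simulator.

## Worked example

```r
library(marstreak)

phantom <- make_phantom("hip_unilateral", grid_size = 256, seed = 7)
phantom
#> <ct_phantom hip_unilateral: 256x256 px, 0.156 cm/px, metal titanium (0.94% of grid)>

scores <- run_case(phantom, mar_config(), seed = 11)
as.data.frame(scores[, c("arm", "mean_score", "band_1_2", "band_9_16")])
#>          arm mean_score band_1_2 band_9_16
#> 1      NOMAR     133179    63181     22767
#> 2       IMAR      36573    18153      6870
#> 3      DEMAR      61389     4436     29291
#> 4 IMAR+DEMAR      21879     4233      7315

round(percent_reduction(scores$mean_score,
                        scores$mean_score[scores$arm == "NOMAR"]), 1)
#> [1]   0.0 -72.5 -53.9 -83.6
```

`mean_score` is the sum of low-frequency DFT amplitudes along the case's
scoring polygon — higher means more streak. On this titanium hip case the
iterative correction removes ~73% of the streak signal, the 130 keV
extrapolation ~54% (mostly the lowest band: dark-band artefacts), and the
combination ~84%. `run_cohort()` repeats this over a 20-hip / 30-dental
cohort and returns per-stratum comparison tables (means ± SD, percent
change vs NOMAR, paired Wilcoxon p-values); `tidy()`, `glance()` and
`autoplot()` work on the comparison objects.

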