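---
title: "Dynamic ULM of functional hyperemia: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic ULM of functional hyperemia: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`fulm` turns ultrafast contrast-enhanced ultrasound frame stacks into
super-resolved microbubble (MB) count and velocity maps and extracts
stimulus-locked functional hyperemia from them. The processing chain is

1. SVD clutter filtering of each frame block (`svd_clutter_filter()`),
2. sub-pixel MB localization (`localize_block()`),
3. particle tracking (`assemble_tracks()`),
4. rasterization onto a 16x-super-resolved grid (`rasterize_tracks()`),
5. sliding-window and stimulation-pattern-averaged dynamic movies
   (`build_sliding_movie()`, `pattern_average()`),
6. Pearson-correlation and SVD activation analysis (`correlation_map()`,
   `svd_decompose()`, `select_stim_mode()`, `variation_map()`),
7. per-vessel quantification (`segment_compartments()`,
   `longitudinal_profile()`, `transversal_profile()`, `perfusion_area()`,
   `rest_stim_stats()`).

A ground-truthed synthetic phantom (`build_phantom()`,
`simulate_microbubbles()`, `render_frame_block()`) generates every input the
chain consumes, so each stage is testable without experimental data.

# The measurement model

**Acquisition geometry.** A linear probe with 110 um pitch images a coronal
plane at 1000 compounded frames/s in blocks of 400 frames; the axial
acquisition pixel is 100 um. Maps are reconstructed at 1/16 of the
acquisition pixel, i.e. 6.875 x 6.25 um (lateral x axial). Depth `z`
increases downward (matrix rows), `x` is lateral (columns); pixels are
half-open intervals, so a coordinate exactly on a boundary belongs to the
higher-index pixel — this is also the tie rule of `grid_snap()`.

**Clutter filtering.** Each block is reshaped to a Casorati matrix
(`Nz*Nx x Nf`) and the 10 leading singular values are zeroed (60 for the
200-frame Power Doppler blocks). No mean-centering is applied; the first
mode absorbs the temporal mean. Energy splits exactly across the removed and
retained subspaces (Parseval), which the tests assert.

**Localization.** The magnitude image is Lanczos-3 interpolated (factor 6),
candidate maxima are gated by a vesselness mask and by their Pearson
correlation with a Gaussian PSF model, then refined by a least-squares
paraboloid fit around the maximum. Two details matter:

* The PSF-shape check is evaluated on the *acquisition* grid, not on the
  interpolated one. Interpolated images are smooth by construction, so any
  local maximum of interpolated noise resembles a smooth blob; on the coarse
  grid, white noise decorrelates from the Gaussian spot model and the 0.7
  correlation threshold has its intended discriminating power (the false
  positive rate on MB-free noise is below 1 per 10^4 pixels in the tests).
* The paraboloid fit neighborhood follows the PSF footprint: the default
  5x5 neighborhood corresponds to a PSF of about 2.5 interpolated pixels
  (a wavelength-sized spot at interpolation factor 6); for wider PSFs the
  neighborhood grows proportionally (`0.85 * sigma` pixels half-width).
  With the default rendering PSF (sigma 80 um, i.e. ~190 um full width at
  half maximum, a realistic beamformed spot at 15 MHz), the localization
  RMSE at 20 dB SNR is ~0.14 acquisition pixels (~14 um), measured over
  1000 spots in `scripts/acceptance.R`.

**Tracking.** Frame-to-frame linking is a minimum-total-distance linear
assignment (Hungarian method via `clue::solve_LSAP`) gated at the distance a
bubble travels in one frame period at 100 mm/s; unmatched detections open or
close tracks (dummy nodes at gate cost). There is no gap filling and no
motion model; tracks shorter than 10 frames are discarded. Interframe
velocities are finite differences times the frame rate. Brute-force
enumeration on small instances is kept as an independent oracle in the test
suite.

**Rasterization.** Tracks are linearly interpolated so that each
super-resolved pixel crossed by a segment is counted exactly once per
traversal; a pixel revisited in a later pass counts again (the count map is
a passage count). Sampling is 1/8 of the smaller pitch, dense enough that
no crossed pixel is skipped; a brute-force supersampled rasterization is the
oracle.

# Dynamic movies

The sliding-window movie `M(z, x, t)` counts traversals per pixel in
half-open windows `[t - W/2, t + W/2)` centered at `(k - 1/2) * Step`,
`k = 1..Nt`, `Nt = Acq/Step` (defaults `W = 5 s`, `Step = 1 s`; the
`1 s / 0.5 s` variant is supported). Windows at the acquisition edges are
truncated, never wrapped. Window membership uses the interpolated traversal
timestamp. Note one consequence of the half-open rule: a detection at
exactly `t = 10 s` with `W = 5 s` belongs to the windows centered in
`(7.5, 12.5]`, i.e. the window centered exactly at 7.5 s does *not* contain
it.

Pattern averaging sums the counts of equivalent phase points across the
repetitions and divides by the window length, giving the MB flux `MB_F` in
MB/s (a pattern-summed flux: with 20 repetitions of a 70-s pattern and a
5-s window, each phase map accumulates 100 s of data). Velocities pool all
MBs across repetitions (population mean), not a mean of per-repetition
means. Count conservation between the absolute-time and pattern-phase
representations is exact and asserted.

**Drift correction.** Slow drift is estimated by translation-only
registration of 10-s MB count maps against the first chunk, using the FFT
cross-correlation peak with quadratic sub-pixel interpolation, and
subtracted from the MB coordinates of each chunk.

# Activation analysis

The Pearson correlation map correlates each pixel's pattern-averaged flux
signal with the stimulation boxcar A(t) (0 rest / 1 stimulation);
zero-variance pixels are assigned c = 0.

The SVD analysis decomposes the reshaped movie (`Nz*Nx x Nts`), without
mean-centering; pixels totalling fewer than 5 detections are zero-filled
(not dropped, preserving geometry). The stimulation mode is the temporal
singular vector with the largest |p|, where p is the scalar product of the
normalized (mean-removed, unit-norm) boxcar with each temporal vector; the
sign of the selected (U, V) pair is flipped so p > 0. The variation map is

```
MB_svd = lambda_istim * U_istim * (int_stim V_istim dt - int_base V_istim dt)
```

with equal-duration stimulation (30-60 s phase) and baseline (0-30 s)
windows and integrals taken as sums times the step. The relative-increase
map divides by the baseline map formed by the modes below `i_stim`; pixels
whose baseline magnitude is below `1e-6` of the maximum are masked rather
than producing unstable ratios, and the map is undefined (with a warning)
when `i_stim = 1`.

**When is a mode "stimulus-locked"?** The temporal singular vectors are an
orthonormal basis, so the p's satisfy `sum p_i^2 <= 1`. A mode is accepted
when `|p| >= 0.6`, i.e. when at least 36% of the stimulus-pattern energy
concentrates in a single mode; under the null the pattern spreads over all
`Nts` modes and the maximum rarely reaches that level (the null-calibration
acceptance check measures the spurious-selection rate at ~15-20%, which is
the price of a threshold low enough to catch weak activations). This
threshold is a package constant chosen once; it was not revisited.

**Exactness of the single-mode formula.** On a constructed rank-2 movie
(constant baseline map plus an activation map modulated by the mean-removed
boxcar, the two spatial maps orthogonal), the decomposition separates the
two components exactly and `MB_svd` recovers `amplitude x stimulation
duration` to machine precision — this closed form anchors the tests. With
an *uncentered* boxcar the stimulation contrast leaks partially into mode 1
and the single-mode map additionally carries a (typically negative) imprint
of the non-activated vasculature, because `U_istim` must be orthogonal to
the baseline mode. This imprint is intrinsic to the method, visible in real
activation maps as a faint vasculature print, and is why the phantom
recovery checks correlate the map with ground truth *within the activated
region* rather than over the whole image.

The single-trial variant applies the same machinery to the raw sliding
movie (no pattern summation), sums the per-trial stimulation/baseline
contrasts, and returns the per-trial time courses of `V_istim`.

# Vessel analytics

Compartments are segmented by Frangi vesselness (Hessian-eigenvalue ridge
filter, scales 1/2/4 pixels, Otsu threshold on the log-compressed count
map; both the filter and the Zhang-Suen skeletonization are implemented in
the package). Pial pixels come from a user-supplied seed mask; remaining
vessel pixels with |mean Vz| above 5 mm/s are split by flow direction
(descending = arteriole, ascending = venule), the rest are
intraparenchymal. Where penetrating vessels overlap, only downward-flowing
MBs are counted for the arteriolar compartment and upward for the venular
one.

Profiles are sampled every half pixel along an 80-um segment normal to the
local flow direction `theta = atan2(Vx, Vz)` (two-argument arctangent, so
vertical flow is safe); transversal profiles average a 50-um-wide slice
along the flow. Profile smoothing uses a running *median* of the stated
physical width (50 um transversal; 200-um boxcar for the per-depth metric
series, median for diameters): a boxcar of 50 um would wash out the
half-maximum edges of a 30-um vessel, while the median preserves them —
the rectangular-profile diameter is then exact to one pixel, which the
tests assert. The diameter is the profile width at half the *rest* profile
maximum, the same threshold being applied to the stimulation profile.

The perfusion/drainage area selects every track whose rasterized path
touches a seed segment and counts the distinct pixels those tracks visit,
times the pixel area (set semantics: duplicate passages do not add area).
Dilation/constriction maps subtract the binarized rest vasculature from the
stimulation one; the vesselness response of both conditions is normalized
by their *common* maximum and thresholded with a single pooled Otsu
threshold, so the subtraction reflects geometry rather than per-condition
normalization. Rest-vs-stimulation metrics are summarized by mean, s.e.m.
and a two-sided exact Wilcoxon signed-rank test (paired variant for depth
comparisons); the spatial-resolution check applies Welch t-tests between
the velocity samples of consecutive pixels across a vessel section.

# The synthetic phantom

The generator emulates the study conditions: a continuous MB infusion over
repeated stimulation patterns of 30 s rest, 30 s stimulation, 10 s rest
(20 repetitions by default).

* **Arrivals** per segment follow an inhomogeneous Poisson process at
  `rate * (1 + (flux_gain - 1) * m(t))`, where `m(t)` is the stimulation
  boxcar smoothed into a trapezoid with a 2-s linear ramp. The trapezoid
  (rather than a gamma-shaped response) reflects the plateau-like responses
  seen during sustained stimulation, and it conserves the boxcar integral,
  so closed-form expectations of arrival counts remain exact.
* **Advection** is plug flow along the centerline at the segment speed
  frozen at arrival time (transit times of ~0.1 s are short against the
  2-s hemodynamic ramp), with a constant lateral offset drawn uniformly
  within the modulated radius. No Poiseuille profile by default: plug flow
  keeps the per-track ground-truth speed exact. Hyperemia multiplies flux,
  speed and radius by `flux_gain`, `speed_gain`, `diameter_gain` (default
  1.5 / 1.2 / 1.2, the order of magnitude of sensory-evoked increases).
* **Rendering** adds a Gaussian echo per MB (sigma 80 um) on the
  acquisition grid, low-rank tissue clutter (smooth random spatial patterns
  with smooth temporal weights, 50x the MB amplitude), white noise, and
  optional rigid motion (linear drift plus axial pulsatility).

What the phantom does *not* emulate: speckle statistics of real tissue,
aberration and attenuation, out-of-plane motion, MB disruption and size
dispersion, and flow profiles within the lumen. Passing tests therefore
demonstrate the correctness of the *processing*, not the in vivo
performance of the method.

**Problem sizes in the checks.** The acceptance analyses are desk-scale by
design: single-vessel phantoms use 0.4-5 MB/s per vessel over 20 patterns
(a strongly perfused vessel carries several MB/s under continuous
infusion); the flux-gain slope is measured at 4 MB/s, where Poisson
scatter resolves it (at the 0.4 MB/s baseline condition the ratio of two
noisy means carries a ~13% standard error, so only the individual means
are compared there, each within 3 s.e.). The weak-activation
(repetition-dependence) phantom is a cortical patch of eight thin vessels
(radius 8 um, 2 MB/s), half of them activated at flux gain 1.2, with
fifteen repetitions and three replicate simulations: detection-and-location
below five patterns fails in the majority of replicates, succeeds reliably
from twelve, and the replicate-averaged map's ground-truth correlation
changes by less than 0.05 per added pattern beyond ten. Null calibration
runs twenty replicate unit-gain simulations.

# Numerical choices and degenerate inputs

* SVD: LAPACK via base `svd()`; reconstruction and orthonormality asserted
  to 1e-10. Ties in |p| (within 1e-12) resolve to the smaller mode index
  with a warning.
* Assignment ties are resolved deterministically by the LSAP solver; all
  randomness in the package flows from explicit seeds, and identical
  configurations reproduce byte-identical track CSVs.
* Empty vesselness responses (e.g. constant images) warn and pass through
  an all-true mask; flat 5x5 patches fall back to the integer maximum;
  registration of non-overlapping count maps warns and applies zero shift;
  an all-zero movie is rejected rather than decomposed.
* Frangi scales whose kernel would exceed the image are skipped; clutter
  fields clamp their smoothing kernel to the image size.
* Movie/frame TIFF I/O min-max-scales to the 32-bit range and stores the
  scale in the JSON sidecar (round trip to ~1e-9 relative error); velocity
  NA is encoded by a zero count.

# Known limitations

* The single-mode variation map carries the baseline-orthogonality imprint
  discussed above; quantitative per-pixel amplitudes are exact only when
  the activation is orthogonal to the baseline.
* `MBrelative_svd` is undefined when the stimulation mode is the first
  mode (no baseline modes below it); the package masks the map and warns
  rather than guessing.
* The mode-acceptance threshold trades sensitivity against a ~15-20%
  spurious-selection rate under the null; single-realization mode selection
  near the threshold is seed-dependent by nature.
* Compartment splitting relies on a |Vz| cutoff (5 mm/s default) that
  assumes penetrating vessels are faster than intraparenchymal ones;
  oblique fast vessels would need a manual label.
* The tracker is nearest-neighbor with a hard gate: crossing vessels with
  similar speeds can swap identities, as with any non-probabilistic
  linker.
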