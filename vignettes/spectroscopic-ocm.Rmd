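---
title: "Spectroscopic visible-light OCM: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectroscopic visible-light OCM: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specoct)
```

# The measurement and its reconstruction

Spectral-domain optical coherence microscopy (OCM) records, for every
lateral position, the spectrum of the interference between a reference
field and light backscattered from the sample. A scatterer at optical depth
$z$ contributes a fringe $\cos(2kz)$ across the detected wavenumbers
$k = 2\pi/\lambda$, so the Fourier transform of the spectrum is a depth
profile (A-scan). With a broadband visible source (here 425–685 nm,
centre $\lambda_c = 555$ nm, FWHM $\Delta\lambda_t = 156$ nm) the axial
resolution of a Gaussian band,

$$\Delta z = \frac{2\ln 2}{\pi}\,\frac{\lambda^2}{\Delta\lambda},$$

reaches below one micrometre in tissue ($1.2\,\mu m$ in air measures as
$1.2/1.36 = 0.88\,\mu m$ for a group index of 1.36), fine enough to resolve
amyloid-beta plaques of a few tens of micrometres.

`reconstruct()` implements the standard chain: background (reference
spectrum) removal, cubic-spline resampling from the wavelength grid onto a
uniform $k$ grid, polynomial dispersion correction, and an FFT normalized
so spectral energy is conserved. The depth pitch follows from the spanned
$k$ range, $\Delta = \pi/(P\,\mathrm{d}k)$, and the depth axis is optical
depth; division by the group index (1.36 for fixed brain tissue) converts
to geometric depth where a function needs it.

Dispersion mismatch between the interferometer arms blurs the axial
point-spread function. The correction phase is a polynomial in normalized
detuning $u = (k - k_0)/k_{half}$ with coefficients read as radians at the
band edge; `estimate_dispersion()` finds it by minimizing the Shannon
entropy of the normalized reconstructed intensity, seeding a Nelder-Mead
simplex from a fixed coarse grid over the quadratic term so the whole
search is deterministic. On seeded point-target phantoms an injected
mismatch of 50 rad at the band edge is recovered to a fraction of a radian
and the corrected PSF returns to within a few permille of the transform
limit.

# Constant-resolution spectroscopic windows

Multiplying the spectrum by a Gaussian window centred at $\lambda_i$ before
the FFT yields a tomogram that sees only that band. Because $\Delta z$
scales as $\lambda^2/\Delta\lambda$, equal-width windows would mix axial
resolutions across bands. `design_windows()` instead solves for bandwidths
that (i) share one $\Delta z$ and (ii) sum to the total FWHM
$\Delta\lambda_t$:

$$\Delta\lambda_1 =
  \frac{\Delta\lambda_t}{1 + \lambda_1^{-2}\sum_{i=2}^{N}\lambda_i^2},
  \qquad
  \Delta\lambda_{i+1} = \frac{\lambda_{i+1}^2}{\lambda_i^2}\Delta\lambda_i.$$

Both properties are algebraic identities and the package tests them to
$10^{-9}$ relative on randomized designs. The three designs used throughout
(three windows at 520/560/600 nm, two disjoint windows at 500/600 nm from a
55 nm band, and seven windows at 500–620 nm) follow directly:

```{r}
design_windows(156, c(520, 560, 600))
design_windows(55, c(500, 600))
```

Published tables print these bandwidths rounded to integer nanometres and
the resolution to one decimal; the package keeps full precision internally
and rounds only for display, which is also how the acceptance checks assert
agreement.

Sub-band handling (`apply_windows()`) equalizes the total spectral energy
of each windowed band — each windowed source profile is rescaled to the
area of the first window's, the natural anchor although any window would
do — so a spectrally neutral reflector responds equally in all bands.
Three bands compose into an RGB image (`compose_rgb()`; longest wavelength
to red) on a log scale clipped to a 40 dB dynamic range, chosen to match
typical OCM display practice; equal band intensities render grey/white.
Two bands whose $\pm 2\sigma$ supports are disjoint
(`split_channels()`) give fully independent images — the function rejects
overlapping supports because that independence is the point of the
two-window design. A Congo-red-like stain is modelled as a sigmoidal
spectral response that is near zero below ~540 nm, which makes stained
inclusions appear in the red channel and vanish in the green one.

# Attenuation estimation

Two estimators quantify how quickly light is lost with depth. The *global*
estimator fits $I(z) = I_0 e^{-\mu_t z}$ per A-scan over a window below the
surface (default 200 µm, configurable), seeded by a closed-form log-linear
regression and refined by Levenberg–Marquardt in the linear domain. The
*local* estimator assigns a coefficient to every pixel from the discrete
depth-resolved model

$$\mu_t[i] = \frac{1}{2\Delta}\,
  \ln\!\Big(1 + \frac{I[i]}{\sum_{j>i} I[j]}\Big),$$

exact for a geometric decay with a fully captured tail. The two formulas
carry different round-trip conventions (the fit has no factor 2, the
per-pixel model divides by $2\Delta$); both are implemented exactly as
written and a `roundtrip` flag on the fit converts its result to the
per-pixel convention for comparisons, rather than silently reconciling the
two.

Two practical points matter on real and simulated data alike:

* **Truncation bias.** The per-pixel model needs the decay essentially
  completed inside the recorded profile — the tail sum spans about
  $1/(2\mu\Delta)$ pixels, thousands at $\mu \approx 0.4\,mm^{-1}$ and
  sub-micrometre pitch, while visible-light penetration ends after a few
  hundred micrometres. Local maps at these depths therefore show relative
  contrast (white matter above grey matter) but not calibrated absolute
  values; the package validates their absolute accuracy on long synthetic
  profiles where the assumption holds, and validates *calibrated* recovery
  through the full pipeline with the global fit instead.
* **Speckle.** Per-A-line fits under fully developed speckle are noisy
  (single-line standard deviations exceed the WM/GM difference), so
  `fit_region_attenuation()` averages surface-aligned, roll-off-corrected
  intensity profiles over a region before fitting — the incoherent
  averaging every OCM practitioner applies — and recovers
  $0.35/0.39\,mm^{-1}$ ground truth within 10% on desk-scale volumes.

Sensitivity roll-off (24 dB/mm here) adds an apparent decay far larger than
tissue attenuation, so intensities are roll-off-compensated
(`compensate_rolloff()`) at their absolute optical depth before any
attenuation estimate.

# The synthetic instrument and phantoms

No public raw data accompany this kind of measurement, so the package
carries a seeded forward model in place of the instrument. Detected
spectra are $E(\lambda)\,|r + \sum_j a_j(\lambda) e^{i(2 k n z_j +
\phi_d(k))}|^2$: a Gaussian source envelope with optional camera
quantum-efficiency weighting; discrete scatterers on the phantom voxel
grid with Beer–Lambert path attenuation, power-law spectral slopes,
cumulative Gaussian absorption bands and spectrometer roll-off; an optional
polynomial dispersion phase; Gaussian shot, multiplicative excess-intensity
and additive read noise; and quantization to the 12-bit camera range. A
layer with attenuation $\mu$ produces reconstructed intensity decaying as
$e^{-2\mu z}$ in geometric depth, i.e. $\mu$ is defined in the round-trip
convention the per-pixel estimator recovers.

Choices a user should know about:

* **Speckle** is produced, when enabled, by summing several random-phase
  sub-resolution scatterers per voxel — fully developed (circular Gaussian)
  statistics without a wave simulation.
* **Axial jitter** offsets each A-line's origin by a seeded sub-voxel draw.
  Without it the regular scatterer grid aliases into laterally averaged
  profiles as a comb; with it the grid mimics the continuum of real tissue.
  Recovery tests switch it on.
* **Operating regime.** Defaults put the instrument in the
  reference-dominated regime (per-scatterer backscatter amplitudes of order
  $10^{-3}$–$10^{-2}$ of the reference). Strong scatterer fields add
  self-interference (autocorrelation) structure that contaminates deep
  signal — visible in simulation exactly as in a badly balanced
  interferometer.
* **Depth budget.** Cubic-spline resampling attenuates fringes near the
  Nyquist depth, mimicking (on top of the modelled roll-off) the finite
  spectral resolution of a real spectrometer. Quantitative phantoms keep
  the scene in the shallow 30–40% of the depth range, which is also where
  the real instrument operates.
* **Scale.** Tests and the demo pipeline run reduced grids (16×16 to 48×48
  A-scans, 512–4096 spectral pixels) chosen so the whole suite completes in
  well under a minute while every estimator still has the sample sizes its
  accuracy analysis needs; the full 500×500×8192 geometry is supported by
  the same code paths.

What passing these tests shows — and what it does not: the pipeline
recovers known ground truth under a forward model with idealized speckle,
no multiple scattering, no confocal gating (the focus is assumed at the
surface, as the processing chain assumes too) and exactly the roll-off
model it compensates. Real tissue adds multiple scattering, focus effects
and fixation-dependent optical properties, which is why measured
attenuation coefficients in the literature span a wide range.

# Surface detection and region statistics

The surface detector smooths each A-scan with a 5-pixel forward running
mean (suppressing single speckle grains without delaying an onset), takes
noise statistics from the deepest 10% of samples, and marks the first
sustained crossing of `noise_mean + 4·noise_sd`. Columns whose peak lies
within 10 dB of the noise floor are flagged invalid, so pure-noise volumes
yield an all-invalid map; a degenerate zero-variance "noise" region
disables that gate, which keeps idealized step inputs exact. Detected maps
are median-filtered laterally (5 pixels).

Region statistics mirror the comparisons used for white matter, grey
matter and plaques: seeded uniform voxel subsampling from
surface-referenced slabs (`extract_region()`), intensity-versus-attenuation
scatter summaries with centroid separations
(`pair_intensity_attenuation()`), Welch two-sample t-tests (pooled-variance
optional) with Bonferroni correction over all pairs (`compare_groups()`),
and a clearing time-course that normalizes region amplitudes to the
pre-clearing measurement and fits a linear trend (`clearing_timecourse()`).
Intensities are compared on the dB scale in the pipeline, matching display
practice; the scale is a flag. Under the null, the family-wise error of
the Bonferroni procedure stays below its nominal level in 1000-replicate
seeded checks.

# Degenerate inputs and numerical conventions

* Depth slabs are half-open `[start, end)` in pixels after rounding the
  start down and the end up; index 0 is the zero-delay line.
* The last pixel of a local-attenuation profile has an empty tail and is
  invalid rather than extrapolated; a zero tail under nonzero intensity
  yields `Inf`, flagged invalid. Tail sums are accumulated from the bottom
  of the A-scan upward so profiles spanning many decades do not lose the
  tail to floating-point cancellation.
* Global fits return `valid = FALSE` (never an error mid-volume) for
  windows shorter than 8 samples, all-zero windows, or non-finite refined
  estimates; the log-linear seed is the fallback when refinement fails.
* All randomness flows from explicit seeds; identical configurations
  reproduce bit-identical raw volumes and checksum-identical pipeline
  outputs.
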