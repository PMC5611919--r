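# specoct

Analysis tools for spectral-domain **visible-light optical coherence
microscopy (OCM)** of brain tissue: spectral-domain reconstruction,
constant-axial-resolution Gaussian-window spectroscopic imaging,
depth-resolved attenuation mapping, and the region statistics used to
separate white matter (WM), grey matter (GM) and amyloid-beta plaques.
A seeded synthetic interferogram generator with full ground truth stands in
for the instrument, so every processing stage is testable on a desk.

## Who this is for

Researchers processing spectrometer-based OCT/OCM data in the visible range
(or prototyping such processing), and anyone who needs a verifiable,
deterministic forward model of a broadband spectral-domain system — source
envelope, k-space sampling, dispersion mismatch, sensitivity roll-off,
speckle, shot/excess noise and camera quantization — with layered,
stained-tissue-like phantoms.

## The models at the core

**Reconstruction.** A scatterer at optical depth $z$ produces a fringe
$\cos(2kz)$ across wavenumber $k = 2\pi/\lambda$. Per A-line the package
removes the reference background, resamples the spectrum onto a uniform
$k$ grid (cubic spline), applies a polynomial dispersion-correction phase
$\exp\!\big(i\sum_{j\ge2} a_j u^j\big)$ in normalized detuning $u$, and
Fourier transforms. Dispersion coefficients are estimated by minimizing the
Shannon entropy of the reconstructed intensity.

**Constant-resolution window design.** Gaussian sub-bands centred at
$\lambda_i$ share one axial resolution
$\Delta z = (2\ln 2/\pi)\,\lambda_i^2/\Delta\lambda_i$ when

$$\Delta\lambda_1 =
  \frac{\Delta\lambda_t}{1 + \lambda_1^{-2}\sum_{i=2}^{N}\lambda_i^2},
\qquad
\Delta\lambda_{i+1} = \frac{\lambda_{i+1}^2}{\lambda_i^2}\,\Delta\lambda_i,$$

which also makes the bandwidths sum exactly to the total FWHM
$\Delta\lambda_t$. Sub-band tomograms are energy-equalized, roll-off
compensated, and composed into RGB or two independent channels.

**Attenuation.** Globally per A-scan, $I(z) = I_0 e^{-\mu_t z}$ is fitted
below the detected surface; locally per pixel,
$\mu_t[i] = \tfrac{1}{2\Delta}\ln\big(1 + I[i]/\sum_{j>i} I[j]\big)$.
Both conventions are implemented exactly as written, with an explicit
`roundtrip` flag to compare them consistently.

**Statistics.** Seeded region sampling, intensity-vs-attenuation cluster
summaries, Welch/pooled two-sample t-tests with Bonferroni correction, and
optical-clearing time-courses normalized to the pre-clearing measurement.

## Worked example

Design the broadband three-window set, then image a speckled grey-matter
phantom ($\mu = 0.35\ \mathrm{mm^{-1}}$) and recover its attenuation:

```r
library(specoct)

design_windows(156, c(520, 560, 600))
#> Gaussian window set: 3 window(s), total FWHM 156 nm, dz = 2.67 um
#>  center_nm  fwhm_nm axial_resolution_um
#>        520 44.68475            2.670256
#>        560 51.82373            2.670256
#>        600 59.49153            2.670256

inst <- instrument_spec(n_spectral_pixels = 2048, reference_level = 2)
ph <- phantom_spec(lateral_shape = c(24, 24), lateral_pitch = 2,
                   layers = list(phantom_layer(25, 0.35, 0.001)),
                   speckle = TRUE, axial_jitter = TRUE)
truth <- build_phantom(ph, axial_extent = 250, axial_step = 1)
vol <- simulate_volume(truth, inst, seed = 42, noise = FALSE)

tom <- reconstruct(vol)
surf <- detect_surface(tom)
fit <- fit_region_attenuation(tom, surf, fit_depth = 0.18)
fit$mu
#> [1] 0.3811653
```

The three rounded bandwidths (45/52/59 nm) and the 2.7 µm common
resolution match the published design table; the region-averaged fit
recovers the $0.35\ \mathrm{mm^{-1}}$ ground truth within its documented
10% accuracy (here $0.381$, i.e. +8.9%). Sub-band spectral profiles of the
same (wavelength-neutral) phantom are flat across windows after energy
equalization:

```r
sb <- apply_windows(vol, design_windows(156, c(520, 560, 600)),
                    compensate_rolloff = 24)
spectral_profiles(sb, surf, region_spec("GM", c(1, 24), c(1, 24), c(10, 100)))
#>   center_nm fwhm_nm mean_intensity mean_attenuation
#> 1       520  44.685          0.990            2.169
#> 2       560  51.824          1.000            2.155
#> 3       600  59.492          0.986            2.131
```

(The local attenuation means carry the truncation bias inherent to
per-pixel estimation at shallow imaging depths — see the vignette — which
is why calibrated values come from the global fit.)

A whole analysis (simulate → reconstruct → spectroscopy → attenuation →
statistics) runs from one YAML/JSON configuration:

```r
run_pipeline("config.yaml")          # or: inst/cli/specoct run --config config.yaml
```

writing raw volumes (u16 + JSON sidecar), float TIFF maps, an RGB en-face
PNG, CSV tables and a checksummed run manifest; identical configurations
reproduce identical checksums.

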