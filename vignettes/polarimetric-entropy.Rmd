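---
title: "Quantifying melanin-driven polarization scrambling with Jones-matrix entropy"
author: "psoctEntropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying melanin-driven polarization scrambling with Jones-matrix entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psoctEntropy)
```

## The measurement problem

Melanin is a hallmark of healthy retinal pigment epithelium (RPE): its
granules scramble the polarization of backscattered light, and the amount of
scrambling tracks the local pigment load. Polarization-sensitive OCT
(PS-OCT) measures, for every voxel of a raster volume, the full complex 2x2
Jones matrix relating incident to backscattered polarization. Because
melanin's scrambling depends on the incident polarization state, a
Stokes-vector summary such as the degree of polarization uniformity cannot
characterise it unambiguously; the Jones matrix can. This package quantifies
the *spatial randomness* of the measured Jones matrices — their entropy —
and turns it into maps and regional statistics of relative melanin content,
for cultured RPE sheets on transwell inserts and for retinal volumes with
atrophy or a transplanted RPE graft.

## The entropy model

For each voxel, the Jones matrices of a small neighbourhood are vectorized
lexicographically, $k = (J_{11}, J_{12}, J_{21}, J_{22})^T$, and accumulated
into the local coherency (density) matrix

$$\rho \;=\; \frac{\sum_i k_i k_i^\dagger}{\sum_i \lVert k_i\rVert^2},$$

a 4x4 Hermitian, positive semi-definite, unit-trace matrix (the
Cloude–Pottier construction familiar from radar polarimetry). Its von
Neumann entropy with logarithm base 4,

$$H \;=\; -\sum_{i=1}^{4} \hat\lambda_i \,\log_4 \hat\lambda_i,$$

over the normalized eigenvalues $\hat\lambda_i$, is dimensionless and spans
$[0, 1]$: 0 when every matrix in the window is the same transformation up to
a complex factor (rank-1 $\rho$, uniform polarization), 1 when the window is
completely random (maximally mixed $\rho = I/4$). $H$ is invariant under any
fixed unitary change of the vectorization basis, which is why the simple
lexicographic basis is used rather than the Pauli basis: the two are
contractually equivalent for every quantity this package reports.

### Noise-bias correction

Additive circular Gaussian detection noise of per-element variance
$\sigma^2$ inflates entropy: in expectation it adds an isotropic term
$f \cdot I/4$ to $\rho$, with $f = 4\sigma^2 / \bar P$ the noise fraction of
the mean per-sample power $\bar P$ (noise included). `noiseBiasCorrect()`
subtracts that expectation, clips any negative eigenvalues to zero, and
renormalizes the trace — an expectation-subtraction with PSD re-projection.
It is unbiased to first order for additive i.i.d. circular Gaussian noise,
reduces exactly to the identity at zero noise, and forces the maximally
mixed state (with a `signalFree` flag) when the estimated noise power
reaches the total power. Windows whose mean intensity sits less than
`snrFloorDb` (default 5 dB) above the noise floor $4\sigma^2$ are masked
invalid outright: noise-dominated voxels have maximal entropy by
construction and would masquerade as melanin.

### Averaging kernel

`entropyVolume()` uses a rectangular kernel of halfwidths
`(depth, lateral, frame)`, default `c(1, 3, 0)`: a 3 x 7 x 1 window of 21
voxels. Rank-4 statistics need at least 4 samples; the default is chosen to
stay within the roughly 12.6-µm-thick RPE band axially (3 voxels at the
4.2 µm default pitch) while gathering enough lateral samples for a stable
spectrum. Edge voxels use the truncated window as long as it still holds 4
samples, so the usable field of view is not shrunk; windows below 4 samples
carry the `NA` sentinel. Eigenvalues in $(-10^{-10}, 0)$ returned by the
Hermitian solver are clipped to zero, and the final entropy is clamped to
$[0, 1]$ after allowing $10^{-9}$ of floating-point overshoot.

## The phantom generator

No PS-OCT instrument data ship with the package; every downstream stage is
exercised on seeded synthetic volumes from `buildPhantom()`. A phantom voxel
is composed as

$$J \;=\; B(z)\, S_{\text{local}} \times \text{reflectivity} \times a,$$

where $B(z)$ is the deterministic retarder accumulated along the A-scan
(per-layer birefringence), $S_{\text{local}}$ the local scattering matrix,
and $a$ a fully developed speckle factor — one circular complex Gaussian
draw per voxel *shared across the four matrix elements*. Element-independent
speckle would itself depolarize and confound the melanin signal; a shared
factor cancels exactly in $\rho$, which the scale-invariance tests verify.

Melanin is modelled as per-voxel i.i.d. random elliptical
retarder–diattenuator products: the retardance axis is uniform on the
Poincaré sphere, the retardance magnitude uniform on
$[0, \text{melaninToScrambling}(c)]$, and a bounded diattenuation scales
with the same dispersion. `melaninToScrambling()` is the simplest monotone
link from concentration $c \in [0,1]$ to dispersion: linear, 0 at $c = 0$
(melanin-free tissue must not scramble) and saturating at $\pi$ for
$c = 1$ (uniform retardance, uniform axis — completely random polarization).
Only monotonicity and the endpoints are contractual; the linear midpoint is
a package choice. Non-melanin tissue instead varies smoothly: a spatially
correlated retardance field (amplitude 0.1 rad, correlation length 8
voxels, always at least 5) so that windows of melanin-free tissue stay
essentially rank-1. The transwell membrane scrambles at maximal dispersion
regardless of melanin — its depolarization is structural (porous
microstructure), which is exactly why the in vitro projection rule must
exclude it.

Two standard scenes are provided. `invitroPhantomSpec()` places a cell layer
(melanin-free control or pigmented RPE) above a bright, intrinsically
depolarizing membrane. `invivoPhantomSpec()` stacks inner retina, a thin RPE
band (3 voxels ≈ 12.6 µm), and a melanin-rich depolarizing choroid, with a
parametric atrophic disc (melanin 0) and an optional concentric graft disc —
the intact/atrophic/graft topology of a transplanted macula with known
ground truth. The default raster mirrors the clinical acquisition: 256
B-scans of 1024 A-scans over 6 x 6 mm; the axial pitch defaults to
4.2 µm/voxel so that a 3-voxel measurement band spans 12.6 µm. The axial
pitch is an inference from the printed strip geometry, recorded here as an
assumption rather than an instrument fact.

What the phantoms do *not* emulate: wave propagation, multiple scattering,
the swept-source hardware (k-clock, depth-encoded dual-input multiplexing),
axial point-spread blurring, motion artefacts, and the anatomical
variability of real maculae. Passing phantom tests therefore demonstrates
that the estimator chain is correct under its stated statistical model, not
that clinical values (for example a mean intact-RPE entropy near 0.4) will
be reproduced on instrument data.

## Detection noise

`applyNoise()` adds i.i.d. circular complex Gaussian noise per element,
scaled so that mean per-element signal power over noise power equals the
requested SNR in dB, and records the exact variance in the volume metadata —
the known noise covariance consumed by the bias correction. The
noise-correction acceptance checks run at 10 dB on 64-sample pure-
polarization windows over 100 Monte-Carlo draws.

## Boundary curves

The analysis excludes depolarizing structures that are *not* RPE melanin by
geometry, not by thresholding entropy:

* **In vitro** — `detectMembraneTop()` finds, per A-scan, the strongest
  contiguous band above an adaptive (Otsu) threshold and takes its
  shallowest depth. Two robustness choices matter. First, fully developed
  speckle is exponentially distributed, so the threshold is computed on a
  laterally running-mean-smoothed intensity (window 9 A-scans) rather than
  the raw A-scan, where a single bright voxel dominates the histogram.
  Second, the band edge is extended upward while voxels stay above half the
  threshold (hysteresis), so a speckle dip at the band top cannot push the
  curve deeper. The detected curve is finally smoothed by a lateral running
  median (window 15). On phantoms the curve is required to sit within 1
  depth pixel of truth at 99% of A-scans (2 pixels at 10 dB).
* **In vivo** — clinical delineation is manual; curves enter through the
  CSV interface (`readDelineation()`, 0-based `frame,lateral,depth,label`
  rows, lossless round trip) with labels `rpe`, `atrophic`, `graft`. The
  file format accepts one curve set; reconciling multiple readers is left
  to the user. `graftAxialCentre()` re-centres graft curves at the integer
  midpoint of the detected band, a half-integer midpoint rounding towards
  the shallower depth (a deterministic, documented tie-break).

## En face projection rules

`enfaceMaxAbove()` implements the in vitro rule — the maximum valid entropy
strictly above the membrane top, so the membrane never contributes.
`enfaceBand()` implements the in vivo rule — the maximum valid entropy
within ±1 depth pixel (default) of the delineated curve, matching the
3-pixel measurement band and tolerant of ±1-pixel delineation error; depths
below the band never contribute, which is the mechanism that excludes
choroidal melanin. Sentinel positions stay `NA` ("no data"), never 0:
atrophy is *low* entropy, not missing data, and the two must not be
conflated. The poisoning tests set every excluded voxel to entropy 1 and
require bit-identical maps.

## Quantification

ROI statistics use the population standard deviation (divide by $n$): an
ROI is an exhaustive pixel set, not a sample. Strips default to 100 x 3
pixels — 586 x 12.6 µm on the clinical raster via `roiExtentUm()` — centred
at the delineated depth, pooling all 300 pixels into one mean/SD (the
per-row alternative is not emitted; median and skewness are, so the
symmetry assumption behind reporting a mean can be checked). The
photograph-to-map registration is an explicit affine transform (identity
for phantoms) standing in for manual registration.
`pigmentationEntropyRelation()` reports the Pearson correlation between ROI
grey means and entropy means and flags zero-variance degeneracy instead of
failing.

## Problem sizes and determinism

All simulations are seeded through one integer per phantom; identical specs
are bit-reproducible, and a private RNG stream restores the caller's
`.Random.seed`. The shipped checks use grids between 8 x 96 x 64 (parameter
recovery over 10 seeds x 5 melanin levels) and 64 x 128 x 128 (projection
poisoning), sizes at which the full pipeline runs in seconds per volume;
the clinical-scale default grid is supported but not exercised in tests.

## Known limitations

* The forward model for melanin scrambling is phenomenological; the mapping
  from concentration to dispersion is calibrated only at its endpoints.
* The noise-bias correction subtracts the first-order expectation of the
  noise term; it is an approximation of the exact estimator and leaves a
  small positive residual bias at very low SNR (visible in the Monte-Carlo
  checks as corrected entropy above zero at 10 dB).
* The membrane detector assumes a single dominant bright band per A-scan;
  stacked reflectors of comparable strength would need the manual pathway.
* Entropy saturates: windows mixing several strong scramblers cannot be
  distinguished beyond $H \approx 1$, so the concentration scale compresses
  at the top end.
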