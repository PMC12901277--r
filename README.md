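# radialpft

Direct polar-coordinate reconstruction of 2D radially acquired MRI
k-space, for researchers studying non-Cartesian reconstruction and
undersampling behavior. Radial data arrive natively as $F(\rho, \varphi)$
— samples along spokes through the k-space center — and the polar Fourier
transform (PFT) turns them into an image without gridding, k-space
interpolation or deapodization:

$$
f(r,\theta) \;=\; \mathrm{IFFT}_\theta\!\left[\, i^{\,n}\,
H_n\{\,\mathrm{FFT}_\varphi\!\left(F(\rho,\varphi)\right)\,\}\,\right],
$$

an azimuthal FFT into angular harmonics $F_n(\rho)$, an order-$n$ Hankel
transform $f_n(r) = 2\pi\int F_n(\rho)\,J_n(2\pi\rho r)\,\rho\,d\rho$ per
harmonic, $i^n$ phasing, and an inverse azimuthal FFT. The Bessel kernels
$J_n(2\pi\rho_k r_j)$ — the computational bottleneck — come from a
compiled recursive evaluator (series/asymptotic seeds for $J_0, J_1$,
upward recurrence for $x > n$, normalized Miller recurrence otherwise)
cached once per protocol.

The package provides, as S4 classes and functions:

* the acquisition model (`scanProtocol()`, `radialKSpace()`,
  `buildTrajectory()`) and the center-out reorganization that feeds the
  transform (`reorganizeCenterOut()`);
* the PFT chain (`pftReconstruct()`, with `azimuthalFFT()`,
  `hankelTransform()`, `assemblePolar()` exposed individually) plus
  nearest-neighbor polar-to-Cartesian display (`polarToCartesian()`,
  `cropSquare()`);
* a standard Kaiser–Bessel gridding comparator (`gridReconstruct()`,
  `densityWeights()`);
* analytic phantoms — point sources and disks sampled exactly on the
  trajectory — with noise, repetition series and gradient-delay
  corruption (`pointSourceKSpace()`, `diskPhantomKSpace()`, `addNoise()`,
  `repeatAcquisition()`, `applyGradientDelay()`);
* repeated-measurement SNR/CNR estimators and point-spread-function
  metrics (`snrMap()`, `cnr()`, `aliasingOnsetRadius()`,
  `artifactOnsetRadius()`, `sourceAliasingOnset()`, `nyquistSpokes()`,
  `acquisitionTime()`);
* an HDF5 k-space container (`writeKSpace()`/`readKSpace()`) and a small
  CLI (`inst/scripts/radialpft.R`) with `simulate`, `recon`, `psf`, `snr`
  and `bessel-check` subcommands.

## A worked example

Reconstruct a point source 30 mm off-center from a 4×-undersampled
63-spoke acquisition (0.9 mm pixels, base 256) and measure its ghost:

```r
library(radialpft)

p  <- scanProtocol(fovMm = 230.4, baseResolution = 256, nSpokes = 63)
p
#> ScanProtocol: bipolar, 63 spokes, base 256 (pixel 0.9 mm, FOV 230.4 mm)
#>   oversampling 2, k_max 0.5556 /mm, delta_k 0.00217 /mm, TR 4.3 ms, 1 coil(s)

ks  <- pointSourceKSpace(data.frame(r0 = 30, theta0 = -pi/2), p)
pol <- pftReconstruct(ks)                      # image in polar coordinates
pol
#> PolarImage: 256 radii (0..229.5 mm) x 504 angles x 1 coil(s), pad factor 4

ghostAmplitude(pol, -pi/2)                     # opposite-side aliasing ghost
#> [1] 0.05898461   (5.9% of the PSF peak: beyond the alias-free radius)

img <- cropSquare(polarToCartesian(pol), 230.4)  # square display image

nyquistSpokes(256)                             # spokes for full-FOV Nyquist
#> [1] 402
acquisitionTime(p)                             # seconds per slice at TR 4.30 ms
#> [1] 0.2709
```

The ghost at 5.9% of peak says this source sits outside the artifact-free
central region: sweeping the source outward, `sourceAliasingOnset(p)`
locates the 5% crossing at ≈ 21.8 mm, while the gridding comparator's
artifact pattern (`artifactOnsetRadius()` against a fully sampled
reference) starts at ≈ 34.6 mm — the space-variant PFT confines aliasing
to roughly half the gridding radius, trading peripheral azimuthal
resolution for a clean center.

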