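---
title: "Reconstructing radial MRI in polar coordinates: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing radial MRI in polar coordinates: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radialpft)
```

## The reconstruction problem

A 2D radial MRI acquisition samples k-space along spokes through the origin:
the data arrive natively in polar coordinates $F(\rho, \varphi)$, with
$\rho \in [0, k_{max}]$ the spatial frequency and $\varphi$ the spoke angle.
The conventional route to an image is *gridding*: density compensation,
convolution of the samples onto a Cartesian grid with a Kaiser–Bessel
kernel, inverse FFT, and deapodization. The polar Fourier transform (PFT)
instead evaluates the 2D inverse Fourier transform directly in polar
coordinates:

$$
f(r, \theta) \;=\; \mathrm{IFFT}_\theta\!\left[\, i^{\,n}\,
H_n\{\,\mathrm{FFT}_\varphi(F(\rho, \varphi))\,\}\,\right],
$$

where $\mathrm{FFT}_\varphi$ decomposes the k-space azimuth into angular
harmonics $F_n(\rho)$, $H_n$ is the order-$n$ Hankel transform
$f_n(r) = 2\pi\int_0^\infty F_n(\rho)\,J_n(2\pi\rho r)\,\rho\,d\rho$ linking
each harmonic's radial k-space profile to its radial image profile, and the
phased harmonics $i^n f_n(r)$ are recombined by an inverse FFT over the
image azimuth $\theta$. No k-space interpolation, convolution kernel or
deapodization appears; the radial weighting $\rho\,d\rho$ inside $H_n$ is
the only density compensation. The identity behind the factorization is the
Jacobi–Anger expansion
$e^{\,i z\cos\alpha} = \sum_n i^{\,n} J_n(z)\, e^{\,i n\alpha}$.

The package implements this chain (`reorganizeCenterOut()`,
`azimuthalFFT()`, `hankelTransform()`, `assemblePolar()`, composed by
`pftReconstruct()`), a standard gridding comparator (`gridReconstruct()`),
analytic phantom generators, and the SNR/CNR and point-spread-function
metrics needed to characterize both reconstructions under angular
undersampling.

## Data model and conventions

* **Units are physical.** Lengths in mm, spatial frequencies in 1/mm,
  angles in radians. Protocols with different FOV or oversampling share
  every code path.
* **Center-out reorganization.** Each spoke acquired from $-k_{max}$ to
  $+k_{max}$ is split at $k = 0$; the nonnegative half keeps the spoke
  angle $\varphi$, the negated half (reversed, so radius increases) moves to
  $\varphi + \pi$. An acquisition of $N_s$ spokes therefore yields
  $M = 2N_s$ half-spokes uniformly covering $[0, 2\pi)$ — for an even
  spoke count over $[0, \pi)$ (*monopolar*) as well as for an odd count
  over $[0, 2\pi)$ (*bipolar*). With an odd readout the shared $k = 0$
  sample is duplicated into both halves; it carries quadrature weight zero
  (the $\rho$ factor), so the duplication introduces no weighting bias.
  With an even readout the innermost samples sit at $\pm\Delta k/2$ and
  that half-pixel distance is kept exactly.
* **Transform conventions.** The forward angular transform uses
  $e^{-in\varphi}$ with $1/M$ scaling, the inverse $e^{+in\theta}$
  unscaled, and $i^n$ the 4-periodic table $(1, i, -1, -i)$. These choices
  are not individually identifiable from the factorized form, so the test
  suite pins the *set* jointly against a direct conjugate-phase quadrature
  oracle $\sum_{m,k} F\, e^{+2\pi i \rho_k r \cos(\varphi_m-\theta)}
  w_k \,\Delta\varphi$, which the chain must match to $10^{-6}$ relative
  error on instances where the Jacobi–Anger truncation is negligible
  ($2\pi\rho_{max} r_{max} \le M/4$). Overall scale is fixed only up to the
  constant implied by this oracle, since the continuous normalization of
  $H_n$ is conventional.
* **Quadrature.** $H_n$ is discretized with trapezoid weights
  $w_k = \rho_k\,\Delta\rho$, the end members halved. A disk spectrum must
  reproduce the jinc closed form $P\,J_1(2\pi P r)/r$ within 1% of peak on
  a 128-sample grid; an arbitrary row must match a 10×-oversampled
  quadrature within 0.5%.
* **Coil axis.** Carried unchanged through every stage; stages are
  independent per coil. Magnitude sum-of-squares combination is available
  but off by default.
* **Angular zero-padding.** Orders are zero-padded by `padFactor`
  (default 4) before the inverse FFT, interpolating the final image to
  $4M$ uniform angles. The default radial grid matches the pixel size,
  $r_j = j\,\Delta x$, out to the oversampled circular FOV; cropping to a
  square FOV happens only at display, after nearest-neighbor
  polar-to-Cartesian substitution (ties to the lower index; symmetric pixel
  centering $(i - (n-1)/2)\,\Delta x$).

## The Bessel kernel

The Hankel transforms need $J_n(2\pi\rho_k r_j)$ for every order, k-space
radius and image radius — the computational bottleneck. The evaluator
(C++, `besselJn()`) is two-stage: $J_0$ and $J_1$ from their ascending
series below $x = 12$ and the Hankel asymptotic expansion above; higher
orders by the three-term recurrence, run *upward* from $J_0, J_1$ while
$x > n$ (the stable direction) and otherwise *downward* (Miller's
algorithm) from a start order $\approx n + 2\lceil\sqrt{40n}\rceil$,
normalized with $J_0(x) + 2\sum_k J_{2k}(x) = 1$. The series/asymptotic
split for the seeds, rather than a fixed rational approximation, keeps the
seed error near machine precision; measured against base R's `besselJ`
over orders 0–255 and $x \in [0, 450]$ (step 0.05) the maximum absolute
error is $\sim 2\times10^{-12}$, far inside the $1.41\times10^{-6}$ budget
the application requires. Tables are built once per protocol/grid
fingerprint and served from a cache (`buildKernelTable()`,
`kernelBuildCount()`); negative orders are resolved at use through
$J_{-n} = (-1)^n J_n$, halving the table.

## The gridding comparator

`gridReconstruct()` standardizes on a Kaiser–Bessel kernel of width 4 grid
cells, grid oversampling 2 (with $\beta$ from the usual
width/oversampling prescription), ramp density compensation
($w \propto |k|$, a $k=0$ sample treated as lying at $\Delta k/8$, which
makes its ramp weight equal the central disk's exact area share), inverse
FFT and deapodization by the kernel transform, followed by a central crop.
A `voronoi` mode computes annular-sector areas directly; for uniform
radial trajectories the two coincide except in bookkeeping. Comparative
statements in this package therefore read as "PFT versus *a standard*
gridding", not versus any vendor implementation. Two known characteristics
of this comparator are verified rather than hidden: its PSF is
shift-invariant to well below 2% of peak, and a homogeneous disk
reconstructs with a broad central intensity dip of roughly 10% (the PFT
image of the same disk is uniform within 5% away from the edge ring — the
same uniformity contrast seen in scanner comparisons).

## Synthetic phantoms as study conditions

All experiments run on analytic k-space: point sources
($\sum_s a_s e^{-2\pi i \mathbf{k}\cdot\mathbf{x}_s}$) and disks
($a R\, J_1(2\pi|k|R)/|k|$, with the $|k|\to 0$ limit $\pi R^2$), sampled
*exactly* on the radial trajectory. Because the sampling operator is exact,
reconstruction error is attributable to the reconstructor alone. The
generators add what the study conditions require — complex Gaussian noise
of per-component deviation $\sigma$ (seeded, caller's RNG untouched),
repetition series with seeds derived from a base seed, and gradient-delay
corruption as a band-limited shift of $\delta$ samples along each spoke's
own readout direction (default $\delta = 0.5$; the magnitude is a free
simulation parameter, as no measured value is available). What they do
*not* emulate: sequence physics (bSSFP banding, relaxation, off-resonance),
coil sensitivity profiles (all channels are unit-sensitivity copies), or
vendor trajectory corrections. Passing tests therefore demonstrate
properties of the *reconstruction operators* under ideal sampling, not
end-to-end scanner fidelity.

The reference geometry mirrors a clinical protocol: 0.9 mm pixels, base
resolution 256, FOV 230.4 mm, readout oversampling 2, spoke counts
$\{31, 63, 127, 255/256\}$, TR 4.30 ms, 30 repetitions for SNR work.
Simulation-heavy properties run on a geometry-preserving scaled version
(base 64, FOV 57.6 mm, same pixel size) with a 20 mm water disk and
$\sigma = 3$ — chosen once to put central SNR in the 20–60 range typical
of phantom scans; PSF measurements use the full base-256 geometry.

## SNR, CNR and the PSF metrics

`snrMap()` implements the repeated-measurement estimator
$\mathrm{SNR} = \mu/\sigma$ with the *population* (divide-by-$N$) standard
deviation, exactly as the estimator is defined — not $N-1$. Pixels with
$\sigma = 0$ are flagged undefined and excluded from region averages.
Magnitude images are used throughout (scanner-realistic, hence Rician);
the Monte-Carlo check accounts for both the Rician moments and the
finite-$N$ bias of $\mu/\hat\sigma$. `cnr()` divides the region-mean
difference of the temporal-mean image by the mean temporal $\sigma$ over a
noise region; overlapping regions are permitted (identical regions give 0).

Characterizing *where* undersampling artifacts appear required
operational definitions the source material leaves open, and two of the
obvious candidates fail on inspection:

* a fixed 5%-of-peak threshold immediately outside the PSF main lobe
  triggers on the *intrinsic* sidelobe rings (18% and 6% of peak) of even
  a perfectly sampled PSF;
* the same threshold never triggers on gridding streaks of a unit point
  source, whose amplitude scales like $\sim 1/N_s$ of the peak
  (about 3.6% at $N_s = 63$).

The package therefore fixes three measures:

1. `aliasingOnsetRadius()` — the literal rule (smallest radius at which
   off-main-lobe intensity exceeds `threshold` × peak, main lobe = the
   contiguous $\ge 50\%$ region), with an optional fully-sampled
   *reference* PSF whose above-threshold footprint is excluded so the
   measure responds to undersampling rather than to sidelobe structure.
2. `artifactOnsetRadius()` — the artifact-free radius of a shift-invariant
   PSF: where the deviation from the fully sampled reference first exceeds
   5% of the deviation's own maximum. The transition is sharp (an order of
   magnitude over two pixels), making the radius insensitive to the
   fraction; at $N_s = 63$, base 256, it lands at 34.6 mm, within 4% of
   the classical azimuthal replication distance
   $N_s/(\pi k_{max}) = 36.1$ mm.
3. `ghostAmplitude()` / `sourceAliasingOnset()` — for the space-variant
   polar transform, the peak-normalized ghost on the half-plane opposite a
   point source, and the smallest source radius at which it exceeds 5% of
   peak. The ghost is measured in the native polar domain: the
   reconstruction's output is polar, and measuring after nearest-neighbor
   Cartesian resampling biases the peak (and hence the ratio) by the
   display stage. At $N_s = 63$ the onset is ≈ 21.8 mm, about 0.6× the
   gridding artifact-free radius.

Protocol arithmetic rounds out the metrics: the azimuthal Nyquist count
$N_s = N_{base}\,\pi/2$ (`nyquistSpokes()`, 402 for base 256) and
acquisition time $N_s \cdot TR$ (`acquisitionTime()`).

## Numerical and degenerate-input choices

* Non-uniform readout steps, duplicate azimuths after the center-out
  mapping, non-uniform azimuth spacing, orders outside the kernel table,
  `padFactor < 1`, crops beyond the image extent, empty polar grids and
  empty regions all raise errors rather than degrade silently.
* The duplicated $k=0$ sample is kept verbatim in both halves (no
  averaging across readout polarities): its weight is zero, so only the
  well-defined samples inform the image.
* Nearest-neighbor ties resolve to the lower index; radii beyond the polar
  support take a fill value.
* Determinism: every stochastic operation takes an explicit seed;
  repetition $i$ of a series uses `seed + i`. Identical inputs produce
  bit-identical kernel tables and images.

## Problem sizes

Accuracy-critical checks run at the full reference geometry (base 256,
orders to 255 for the Bessel sweep, 63-spoke PSF studies). Statistical
properties (SNR scaling across $N_s \in \{31, 63, 127, 255\}$ with 30
repetitions per condition, gradient-delay orderings, disk uniformity) run
at the scaled base-64 geometry, which preserves pixel size, oversampling
and the undersampling ratios while keeping each condition to a few seconds
of compute.

## Known limitations

* Uniform angle sets only; Golden-Angle and other non-uniform schemes are
  out of scope (the azimuthal FFT requires uniform sampling).
* No gradient-delay *correction* — the corruption model exists precisely
  to study the uncorrected transform's sensitivity; bipolar spoke
  alternation is the only mitigation exercised.
* Scanner-measured quantities (absolute SNR advantages, in vivo CNR,
  reconstruction wall-clock) depend on hardware and vendor pipelines and
  are deliberately not reproduced; the gridding comparator is a standard
  implementation, not a vendor clone.
* The polar image's azimuthal pixel size grows with radius; angular
  zero-padding interpolates display density but cannot add resolution
  beyond $k_{max}$.
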