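# S4 classes for the radial acquisition model and the reconstruction chain.
# Physical units are carried everywhere: lengths in mm, spatial frequencies
# in 1/mm, angles in radians, times in ms.

#' Scan protocol for a 2D radial acquisition
#'
#' Describes the geometry and timing of a radial scan: field of view, base
#' (image) matrix size, radial oversampling, spoke count and angular scheme,
#' repetition time and coil count.  The derived quantities pixel size,
#' \eqn{k_{max} = 1/(2\,\Delta x)} and radial step
#' \eqn{\Delta k = 1/(\mathrm{os}\cdot\mathrm{FOV})} are available through
#' [pixelSize()], [kMax()] and [deltaK()].
#'
#' Two angular schemes are supported.  A \emph{monopolar} acquisition uses an
#' even number of spokes uniformly spanning \eqn{[0, \pi)}, all read with the
#' same gradient polarity.  A \emph{bipolar} acquisition uses an odd number of
#' spokes evenly distributed over \eqn{[0, 2\pi)}, which alternates the
#' effective readout direction between angular neighbours.
#'
#' @slot fovMm field of view (mm)
#' @slot baseResolution image matrix size per side (even, >= 8)
#' @slot radialOversampling readout oversampling factor (1 or 2)
#' @slot nSpokes number of acquired spokes
#' @slot scheme `"monopolar"` or `"bipolar"`
#' @slot trMs repetition time (ms)
#' @slot nCoils number of receive channels
#' @seealso [scanProtocol()]
#' @export
setClass("ScanProtocol", representation(
  fovMm = "numeric",
  baseResolution = "integer",
  radialOversampling = "integer",
  nSpokes = "integer",
  scheme = "character",
  trMs = "numeric",
  nCoils = "integer"
))

setValidity("ScanProtocol", function(object) {
  msg <- character()
  if (length(object@fovMm) != 1 || !is.finite(object@fovMm) || object@fovMm <= 0)
    msg <- c(msg, "fovMm must be a single positive number")
  b <- object@baseResolution
  if (length(b) != 1 || b < 8 || b %% 2 != 0)
    msg <- c(msg, "baseResolution must be even and >= 8")
  if (!object@radialOversampling %in% c(1L, 2L))
    msg <- c(msg, "radialOversampling must be 1 or 2")
  if (object@nSpokes < 1)
    msg <- c(msg, "nSpokes must be >= 1")
  if (!object@scheme %in% c("monopolar", "bipolar"))
    msg <- c(msg, "scheme must be 'monopolar' or 'bipolar'")
  if (object@scheme == "monopolar" && object@nSpokes %% 2 != 0)
    msg <- c(msg, "monopolar scheme requires an even number of spokes (angles span [0, pi))")
  if (object@scheme == "bipolar" && object@nSpokes %% 2 != 1)
    msg <- c(msg, "bipolar scheme requires an odd number of spokes (angles span [0, 2*pi))")
  if (object@trMs <= 0) msg <- c(msg, "trMs must be positive")
  if (object@nCoils < 1) msg <- c(msg, "nCoils must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Radial k-space data
#'
#' Complex samples indexed `[coil, spoke, readout]` together with the spoke
#' angles and the signed radial positions of the readout samples (uniform
#' step `deltaK`, spanning \eqn{-k_{max}} to \eqn{+k_{max}}).
#'
#' @slot samples complex array, `nCoils x nSpokes x nReadout`
#' @slot anglesRad one angle per spoke, strictly increasing, in `[0, 2*pi)`
#' @slot readoutK signed radial sample positions (1/mm)
#' @slot protocol the [ScanProtocol-class] that produced the data
#' @seealso [radialKSpace()], [reorganizeCenterOut()]
#' @export
setClass("RadialKSpace", representation(
  samples = "array",
  anglesRad = "numeric",
  readoutK = "numeric",
  protocol = "ScanProtocol"
))

setValidity("RadialKSpace", function(object) {
  msg <- character()
  d <- dim(object@samples)
  p <- object@protocol
  if (length(d) != 3) return("samples must be a 3D array [coil, spoke, readout]")
  if (!is.complex(object@samples)) msg <- c(msg, "samples must be complex")
  if (d[1] != p@nCoils) msg <- c(msg, "coil dimension does not match protocol")
  if (d[2] != p@nSpokes) msg <- c(msg, "spoke dimension does not match protocol")
  nEven <- p@baseResolution * p@radialOversampling
  if (!d[3] %in% c(nEven, nEven + 1L))
    msg <- c(msg, sprintf("readout length must be %d (even) or %d (odd, includes k = 0)",
                          nEven, nEven + 1L))
  if (length(object@anglesRad) != d[2])
    msg <- c(msg, "need one angle per spoke")
  if (is.unsorted(object@anglesRad, strictly = TRUE))
    msg <- c(msg, "angles must be strictly increasing")
  if (any(object@anglesRad < 0 | object@anglesRad >= 2 * pi))
    msg <- c(msg, "angles must lie in [0, 2*pi)")
  if (length(object@readoutK) != d[3])
    msg <- c(msg, "readoutK length must match the readout dimension")
  if (max(abs(object@readoutK)) > kMaxOf(p) + deltaKOf(p) / 2 + 1e-9)
    msg <- c(msg, "|readoutK| exceeds k_max + deltaK/2")
  if (length(msg)) msg else TRUE
})

#' Center-out k-space
#'
#' Radial k-space reorganized for the polar transform chain: each spoke is
#' split at \eqn{k = 0} into two half-spokes sitting at azimuths exactly
#' \eqn{\pi} apart, giving `M = 2 * nSpokes` azimuths uniformly covering
#' \eqn{[0, 2\pi)} with nonnegative radii.  For an odd readout the shared
#' \eqn{k = 0} sample is duplicated into both halves; for an even readout the
#' innermost samples sit at \eqn{\pm\Delta k/2}.
#'
#' @slot F complex array `nCoils x M x K` indexed `[coil, azimuth, radial]`
#' @slot phiM azimuth angles (radians, ascending, uniform spacing `2*pi/M`)
#' @slot rhoK nonnegative radii (1/mm, uniform step `deltaK`)
#' @slot protocol originating [ScanProtocol-class]
#' @seealso [reorganizeCenterOut()], [azimuthalFFT()]
#' @export
setClass("CenterOutKSpace", representation(
  F = "array",
  phiM = "numeric",
  rhoK = "numeric",
  protocol = "ScanProtocol"
))

setValidity("CenterOutKSpace", function(object) {
  msg <- character()
  d <- dim(object@F)
  if (length(d) != 3) return("F must be a 3D array [coil, azimuth, radial]")
  if (d[2] != 2L * object@protocol@nSpokes)
    msg <- c(msg, "azimuth count must be 2 * nSpokes")
  if (length(object@phiM) != d[2]) msg <- c(msg, "phiM length must equal azimuth count")
  if (length(object@rhoK) != d[3]) msg <- c(msg, "rhoK length must equal radial count")
  if (any(object@rhoK < 0)) msg <- c(msg, "rhoK must be nonnegative")
  if (is.unsorted(object@rhoK)) msg <- c(msg, "rhoK must be nondecreasing")
  if (length(msg)) msg else TRUE
})

#' Cached Bessel kernel table for the Hankel transform
#'
#' Holds \eqn{J_n(2\pi \rho_k r_j)} for all orders `0..nMax` on the product of
#' a k-space radius grid and an image radius grid, order-major so each order's
#' `rho x r` block is consumed as one matrix product.  Negative orders are
#' resolved at use via \eqn{J_{-n} = (-1)^n J_n}.  Tables are immutable after
#' construction and cached per protocol/grid fingerprint (see
#' [buildKernelTable()]).
#'
#' @slot values numeric array `K x J x (nMax + 1)`
#' @slot rhoGrid k-space radii (1/mm)
#' @slot rGrid image radii (mm)
#' @slot nMax largest stored order
#' @slot cacheKey fingerprint of the generating grids
#' @export
setClass("BesselTable", representation(
  values = "array",
  rhoGrid = "numeric",
  rGrid = "numeric",
  nMax = "integer",
  cacheKey = "character"
))

setValidity("BesselTable", function(object) {
  d <- dim(object@values)
  msg <- character()
  if (length(d) != 3) return("values must be a 3D array [rho, r, order]")
  if (d[1] != length(object@rhoGrid)) msg <- c(msg, "rho dimension mismatch")
  if (d[2] != length(object@rGrid)) msg <- c(msg, "r dimension mismatch")
  if (d[3] != object@nMax + 1L) msg <- c(msg, "order dimension mismatch")
  if (max(abs(object@values)) > 1 + 1e-12) msg <- c(msg, "|J_n| must be <= 1")
  if (length(msg)) msg else TRUE
})

#' Azimuthal order spectra
#'
#' Output of the azimuthal FFT: one complex radial row per angular harmonic
#' (order), with orders centered on `-M/2 .. M/2 - 1`.
#'
#' @slot Fn complex array `nCoils x M x K` indexed `[coil, order, radial]`
#' @slot orders integer vector of harmonic numbers
#' @slot rhoGrid k-space radii (1/mm)
#' @slot protocol originating [ScanProtocol-class]
#' @export
setClass("OrderSpectra", representation(
  Fn = "array",
  orders = "integer",
  rhoGrid = "numeric",
  protocol = "ScanProtocol"
))

#' Radial harmonic profiles
#'
#' Hankel-transformed order spectra: one complex image-radius row per order,
#' before the \eqn{i^n} phasing and inverse azimuthal FFT.
#'
#' @slot fn complex array `nCoils x M x J` indexed `[coil, order, radius]`
#' @slot orders integer vector of harmonic numbers
#' @slot rGrid image radii (mm)
#' @slot protocol originating [ScanProtocol-class]
#' @export
setClass("RadialProfiles", representation(
  fn = "array",
  orders = "integer",
  rGrid = "numeric",
  protocol = "ScanProtocol"
))

#' Image on a polar grid
#'
#' Reconstructed image \eqn{f(r, \theta)} on a uniform polar grid starting at
#' \eqn{r = 0}, with `padFactor * M` uniform angles over \eqn{[0, 2\pi)}.
#'
#' @slot f complex array `J x Mpad x nCoils` indexed `[radius, angle, coil]`
#' @slot rGrid image radii (mm), uniform, starting at 0
#' @slot thetaGrid angles (radians), uniform over `[0, 2*pi)`
#' @slot padFactor angular zero-padding factor used during assembly
#' @slot protocol originating [ScanProtocol-class]
#' @seealso [pftReconstruct()], [polarToCartesian()]
#' @export
setClass("PolarImage", representation(
  f = "array",
  rGrid = "numeric",
  thetaGrid = "numeric",
  padFactor = "integer",
  protocol = "ScanProtocol"
))

setValidity("PolarImage", function(object) {
  msg <- character()
  d <- dim(object@f)
  if (length(d) != 3) return("f must be a 3D array [radius, angle, coil]")
  if (d[1] != length(object@rGrid)) msg <- c(msg, "rGrid length mismatch")
  if (d[2] != length(object@thetaGrid)) msg <- c(msg, "thetaGrid length mismatch")
  if (abs(object@rGrid[1]) > 1e-12) msg <- c(msg, "rGrid must start at 0")
  if (object@padFactor < 1L) msg <- c(msg, "padFactor must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Square Cartesian image
#'
#' A square image matrix with physical pixel size and an explicit (possibly
#' fractional) center index, so that images produced by the FFT-based
#' gridding path (center at `n/2 + 1`) and by symmetric polar resampling
#' (center at `(n + 1)/2`) can be analysed by the same region/radius tools.
#'
#' @slot pixels complex or numeric array, `n x n` or `n x n x nCoils`;
#'   first index is x, second is y
#' @slot pixelMm pixel size (mm)
#' @slot centerIndex 1-based (x, y) index of the image center
#' @export
setClass("CartesianImage", representation(
  pixels = "array",
  pixelMm = "numeric",
  centerIndex = "numeric"
))

setValidity("CartesianImage", function(object) {
  d <- dim(object@pixels)
  msg <- character()
  if (!length(d) %in% c(2L, 3L)) return("pixels must be an n x n (x coil) array")
  if (d[1] != d[2]) msg <- c(msg, "pixels must be square")
  if (object@pixelMm <= 0) msg <- c(msg, "pixelMm must be positive")
  if (length(object@centerIndex) != 2) msg <- c(msg, "centerIndex must have length 2")
  if (length(msg)) msg else TRUE
})

#' Gridding reconstruction settings
#'
#' Kaiser-Bessel gridding parameters: kernel width in grid cells, kernel
#' shape `beta` (default from the standard width/oversampling prescription),
#' Cartesian grid oversampling, and the density-compensation mode.
#'
#' @slot kernelWidth kernel support in grid cells (>= 2)
#' @slot kernelBeta Kaiser-Bessel shape parameter
#' @slot gridOversampling Cartesian grid oversampling factor (>= 1)
#' @slot dcMode `"ramp"` or `"voronoi"` density compensation
#' @seealso [griddingConfig()], [gridReconstruct()]
#' @export
setClass("GriddingConfig", representation(
  kernelWidth = "numeric",
  kernelBeta = "numeric",
  gridOversampling = "numeric",
  dcMode = "character"
))

setValidity("GriddingConfig", function(object) {
  msg <- character()
  if (object@kernelWidth < 2) msg <- c(msg, "kernelWidth must be >= 2")
  if (object@gridOversampling < 1) msg <- c(msg, "gridOversampling must be >= 1")
  if (!object@dcMode %in% c("ramp", "voronoi"))
    msg <- c(msg, "dcMode must be 'ramp' or 'voronoi'")
  if (length(msg)) msg else TRUE
})

#' Polar-to-Cartesian resampling settings
#'
#' @slot outMatrix output side length (pixels, >= 2)
#' @slot outPixelMm output pixel size (mm)
#' @slot fillValue value assigned beyond the polar support
#' @seealso [polarToCartesian()]
#' @export
setClass("ResampleSpec", representation(
  outMatrix = "integer",
  outPixelMm = "numeric",
  fillValue = "complex"
))

setValidity("ResampleSpec", function(object) {
  msg <- character()
  if (object@outMatrix < 2L) msg <- c(msg, "outMatrix must be >= 2")
  if (object@outPixelMm <= 0) msg <- c(msg, "outPixelMm must be positive")
  if (length(msg)) msg else TRUE
})

#' Pixel-wise SNR map from repeated acquisitions
#'
#' Temporal mean, population standard deviation and their ratio per pixel
#' over a series of co-registered magnitude images.  Pixels with zero
#' temporal deviation are flagged undefined (`NA` in the `snr` slot) and
#' excluded from region averages.
#'
#' @slot snr SNR matrix (`NA` where undefined)
#' @slot mu temporal mean matrix
#' @slot sigma temporal standard deviation matrix (divide-by-N)
#' @slot nRep number of repetitions
#' @slot pixelMm pixel size (mm)
#' @slot centerIndex 1-based (x, y) index of the image center
#' @seealso [snrMap()], [roiMeanSnr()]
#' @export
setClass("SnrMap", representation(
  snr = "matrix",
  mu = "matrix",
  sigma = "matrix",
  nRep = "integer",
  pixelMm = "numeric",
  centerIndex = "numeric"
))

#' Region of interest
#'
#' Disk, annulus or box region specified in mm relative to the image center.
#'
#' @slot shape `"disk"`, `"annulus"` or `"box"`
#' @slot params named list of geometry parameters (mm)
#' @seealso [roiDisk()], [roiAnnulus()], [roiBox()]
#' @export
setClass("Roi", representation(shape = "character", params = "list"))
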