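# Analytic phantom k-space: point sources and disks sampled exactly on the
# radial trajectory, plus noise, repetition and gradient-delay corruption.
# Phantoms are defined analytically in k-space (no rasterized ground truth),
# so the sampling operator is exact and reconstruction error is attributable
# to the reconstructor alone.

kVectors <- function(protocol, anglesRad, readoutK) {
  list(kx = outer(anglesRad, readoutK, function(a, k) k * cos(a)),
       ky = outer(anglesRad, readoutK, function(a, k) k * sin(a)))
}

#' Analytic radial k-space of point sources
#'
#' Each sample at k-vector \eqn{\mathbf{k} = |k|(\cos\varphi, \sin\varphi)}
#' receives \eqn{\sum_s a_s e^{-i 2\pi \mathbf{k}\cdot\mathbf{x}_s}}.  All
#' coils carry identical (unit-sensitivity) copies.
#'
#' @param sources data frame with columns `x`, `y` (mm) and `amplitude`
#'   (complex allowed); alternatively columns `r0` and `theta0` giving polar
#'   positions
#' @param protocol a [ScanProtocol-class]
#' @param oddReadout sample `k = 0` exactly (odd readout length)?
#' @return a [RadialKSpace-class]
#' @examples
#' p <- scanProtocol(57.6, 64, nSpokes = 63)
#' ks <- pointSourceKSpace(data.frame(x = 0, y = 0, amplitude = 1), p)
#' all(samples(ks) == 1 + 0i)  # zero phase for a source at the origin
#' @export
pointSourceKSpace <- function(sources, protocol, oddReadout = FALSE) {
  validObject(protocol)
  sources <- as.data.frame(sources)
  if (!all(c("x", "y") %in% names(sources)) &&
      all(c("r0", "theta0") %in% names(sources))) {
    sources$x <- sources$r0 * cos(sources$theta0)
    sources$y <- sources$r0 * sin(sources$theta0)
  }
  if (!all(c("x", "y") %in% names(sources)))
    stop("sources need columns x, y (mm) or r0, theta0")
  if (is.null(sources$amplitude)) sources$amplitude <- 1
  ang <- buildTrajectory(protocol)
  k <- readoutK(protocol, oddReadout)
  kv <- kVectors(protocol, ang, k)
  acc <- matrix(complex(real = 0), length(ang), length(k))
  for (s in seq_len(nrow(sources))) {
    acc <- acc + as.complex(sources$amplitude[s]) *
      exp(-2i * pi * (kv$kx * sources$x[s] + kv$ky * sources$y[s]))
  }
  sam <- array(complex(real = 0), c(protocol@nCoils, length(ang), length(k)))
  for (c in seq_len(protocol@nCoils)) sam[c, , ] <- acc
  radialKSpace(sam, protocol, anglesRad = ang, readoutK = k)
}

#' Analytic radial k-space of a disk phantom
#'
#' A uniform disk of radius \eqn{R} centered at \eqn{\mathbf{c}} contributes
#' \eqn{a\, R\, J_1(2\pi |k| R)/|k| \cdot e^{-i2\pi\mathbf{k}\cdot\mathbf{c}}}
#' per sample, with the \eqn{|k| \to 0} limit \eqn{a \pi R^2}.  Disks are
#' summed, making the generator linear in the amplitudes.
#'
#' @param disks data frame with columns `x`, `y` (mm), `radius` (mm) and
#'   `amplitude`
#' @param protocol a [ScanProtocol-class]
#' @param oddReadout sample `k = 0` exactly?
#' @return a [RadialKSpace-class]
#' @export
diskPhantomKSpace <- function(disks, protocol, oddReadout = FALSE) {
  validObject(protocol)
  disks <- as.data.frame(disks)
  if (is.null(disks$amplitude)) disks$amplitude <- 1
  if (any(disks$radius <= 0)) stop("disk radii must be positive")
  ang <- buildTrajectory(protocol)
  k <- readoutK(protocol, oddReadout)
  kv <- kVectors(protocol, ang, k)
  kAbs <- matrix(abs(k), length(ang), length(k), byrow = TRUE)
  acc <- matrix(complex(real = 0), length(ang), length(k))
  for (s in seq_len(nrow(disks))) {
    R <- disks$radius[s]
    env <- matrix(pi * R^2, length(ang), length(k))
    nz <- kAbs > 1e-12
    env[nz] <- R * besselJ(2 * pi * kAbs[nz] * R, 1) / kAbs[nz]
    acc <- acc + as.complex(disks$amplitude[s]) * env *
      exp(-2i * pi * (kv$kx * disks$x[s] + kv$ky * disks$y[s]))
  }
  sam <- array(complex(real = 0), c(protocol@nCoils, length(ang), length(k)))
  for (c in seq_len(protocol@nCoils)) sam[c, , ] <- acc
  radialKSpace(sam, protocol, anglesRad = ang, readoutK = k)
}

withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Add complex Gaussian noise to k-space
#'
#' Adds independent Gaussian noise of standard deviation `sigma` to the real
#' and imaginary component of every sample.  Deterministic for a given seed;
#' the caller's RNG state is left untouched.
#'
#' @param ks a [RadialKSpace-class]
#' @param sigma per-component noise standard deviation (>= 0)
#' @param seed integer seed
#' @return the noisy [RadialKSpace-class]
#' @export
addNoise <- function(ks, sigma, seed = 1L) {
  stopifnot(is(ks, "RadialKSpace"), sigma >= 0)
  if (sigma == 0) return(ks)
  n <- length(ks@samples)
  noise <- withSeed(seed, complex(real = rnorm(n, sd = sigma),
                                  imaginary = rnorm(n, sd = sigma)))
  ks@samples <- ks@samples + array(noise, dim(ks@samples))
  ks
}

#' Apply a gradient-delay shift along each spoke
#'
#' Resamples every spoke at \eqn{k + \delta\,\Delta k} along its own
#' acquisition direction using a band-limited (FFT phase-ramp) shift.  Under
#' a monopolar trajectory all spokes share gradient polarity, so the shifts
#' point into the same half-plane and add coherently; under a bipolar layout
#' the \eqn{[0, 2\pi)} angle coverage alternates the effective readout
#' direction, and the shifts largely cancel.
#'
#' @param ks a [RadialKSpace-class]
#' @param deltaSamples shift in (fractional) sample units; must satisfy
#'   `|deltaSamples| < nReadout / 4`
#' @return the corrupted [RadialKSpace-class]
#' @export
applyGradientDelay <- function(ks, deltaSamples) {
  stopifnot(is(ks, "RadialKSpace"))
  n <- dim(ks@samples)[3]
  if (abs(deltaSamples) >= n / 4) stop("|deltaSamples| must be < readout length / 4")
  if (deltaSamples == 0) return(ks)
  f <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2):1))   # FFT bin frequencies
  ramp <- exp(2i * pi * f * deltaSamples / n)
  if (n %% 2 == 0) ramp[n / 2 + 1] <- cos(pi * deltaSamples)  # real Nyquist bin
  d <- dim(ks@samples)
  for (c in seq_len(d[1])) for (j in seq_len(d[2])) {
    s <- ks@samples[c, j, ]
    ks@samples[c, j, ] <- fft(fft(s) * ramp, inverse = TRUE) / n
  }
  ks
}

#' Repeated noisy acquisitions, reconstructed
#'
#' Generates `nRep` independently seeded noisy copies of a clean acquisition
#' (seeds `seed + 1 .. seed + nRep`), reconstructs each with `recon`, and
#' stacks the magnitude images.
#'
#' @param ks clean [RadialKSpace-class]
#' @param sigma per-component noise standard deviation
#' @param nRep number of repetitions (>= 2)
#' @param seed base seed; repetition `i` uses `seed + i`
#' @param recon function mapping a [RadialKSpace-class] to a
#'   [CartesianImage-class] (e.g. [gridReconstruct()] or a wrapper around
#'   [pftReconstruct()] + [polarToCartesian()])
#' @return numeric 3D array `n x n x nRep` of magnitudes, with attributes
#'   `pixelMm` and `centerIndex` from the first reconstruction
#' @export
repeatAcquisition <- function(ks, sigma, nRep, seed = 1L, recon = gridReconstruct) {
  stopifnot(is(ks, "RadialKSpace"), nRep >= 2)
  out <- NULL
  for (i in seq_len(nRep)) {
    img <- recon(addNoise(ks, sigma, seed = seed + i))
    stopifnot(is(img, "CartesianImage"))
    m <- Mod(img@pixels)
    if (length(dim(m)) == 3) m <- m[, , 1]
    if (is.null(out)) {
      out <- array(0, c(dim(m), nRep))
      attr(out, "pixelMm") <- img@pixelMm
      attr(out, "centerIndex") <- img@centerIndex
    }
    out[, , i] <- m
  }
  out
}
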