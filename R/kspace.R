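# Radial k-space container and the center-out reorganization feeding the
# polar transform chain.

#' Construct a radial k-space container
#'
#' @param samples complex array `nCoils x nSpokes x nReadout` (a matrix is
#'   accepted for a single coil)
#' @param protocol a [ScanProtocol-class]
#' @param anglesRad spoke angles; defaults to [buildTrajectory()] of the
#'   protocol
#' @param readoutK signed radial sample positions; defaults to [readoutK()]
#'   with the parity implied by `dim(samples)`
#' @return a validated [RadialKSpace-class]
#' @export
radialKSpace <- function(samples, protocol, anglesRad = buildTrajectory(protocol),
                         readoutK = NULL) {
  if (is.matrix(samples)) {
    samples <- array(samples, c(1L, nrow(samples), ncol(samples)))
  }
  storage.mode(samples) <- "complex"
  if (is.null(readoutK)) {
    odd <- dim(samples)[3] %% 2 == 1
    readoutK <- readoutK(protocol, oddReadout = odd)
  }
  new("RadialKSpace", samples = samples, anglesRad = as.numeric(anglesRad),
      readoutK = as.numeric(readoutK), protocol = protocol)
}

#' @describeIn radialKSpace the complex sample array
#' @param x a [RadialKSpace-class]
#' @export
setMethod("samples", "RadialKSpace", function(x) x@samples)

#' @describeIn radialKSpace the originating protocol
#' @export
setMethod("protocol", "RadialKSpace", function(x) x@protocol)

setMethod("show", "RadialKSpace", function(object) {
  d <- dim(object@samples)
  cat(sprintf("RadialKSpace: %d coil(s) x %d spoke(s) x %d readout sample(s) (%s readout)\n",
              d[1], d[2], d[3], if (d[3] %% 2 == 1) "odd" else "even"))
  show(object@protocol)
})

#' Reorganize radial k-space into center-out half-spokes
#'
#' Splits every spoke at \eqn{k = 0} into two half-spokes: the nonnegative-k
#' samples stay at the spoke angle \eqn{\varphi} (ordered away from the
#' center) and the negative-k samples, reversed so the radius increases, move
#' to \eqn{\varphi + \pi \bmod 2\pi}.  For an odd readout the shared
#' \eqn{k = 0} sample is duplicated into both halves; for an even readout the
#' innermost samples keep their physical distance \eqn{\pm\Delta k/2} from
#' the center.  Output azimuths are sorted ascending and are required to be
#' uniform with spacing \eqn{2\pi/M}, `M = 2 * nSpokes`, as the azimuthal FFT
#' demands.
#'
#' @param ks a [RadialKSpace-class]
#' @return a [CenterOutKSpace-class] with `F` indexed `[coil, azimuth, radial]`
#' @export
reorganizeCenterOut <- function(ks) {
  stopifnot(is(ks, "RadialKSpace"))
  validObject(ks)
  k <- ks@readoutK
  dk <- diff(k)
  if (any(abs(dk - dk[1]) > 1e-9 * abs(dk[1])))
    stop("readoutK step is not uniform")
  n <- length(k)
  odd <- n %% 2 == 1
  if (odd) {
    iPos <- which(k >= -1e-12)           # includes the k = 0 sample
    iNeg <- rev(which(k <= 1e-12))       # duplicated k = 0, reversed order
  } else {
    iPos <- which(k > 0)
    iNeg <- rev(which(k < 0))
  }
  if (length(iPos) != length(iNeg))
    stop("readout samples are not symmetric about k = 0")
  rho <- k[iPos]

  ns <- ks@protocol@nSpokes
  M <- 2L * ns
  aziRaw <- c(ks@anglesRad, (ks@anglesRad + pi) %% (2 * pi))
  ord <- order(aziRaw)
  phi <- aziRaw[ord]
  if (any(diff(phi) < 1e-9))
    stop("duplicate azimuths after center-out mapping (angle collision mod 2*pi)")
  spacing <- 2 * pi / M
  if (any(abs(diff(phi) - spacing) > 1e-9))
    stop("azimuths are not uniform with spacing 2*pi/M; the azimuthal FFT requires uniform angular sampling")

  nc <- dim(ks@samples)[1]
  F <- array(complex(real = 0), c(nc, M, length(rho)))
  for (c in seq_len(nc)) {
    sp <- ks@samples[c, , , drop = FALSE]
    dim(sp) <- dim(ks@samples)[2:3]
    half <- rbind(sp[, iPos, drop = FALSE], sp[, iNeg, drop = FALSE])
    F[c, , ] <- half[ord, , drop = FALSE]
  }
  new("CenterOutKSpace", F = F, phiM = phi, rhoK = rho, protocol = ks@protocol)
}

#' @describeIn reorganizeCenterOut the originating protocol
#' @param x a [CenterOutKSpace-class]
#' @export
setMethod("protocol", "CenterOutKSpace", function(x) x@protocol)

setMethod("show", "CenterOutKSpace", function(object) {
  d <- dim(object@F)
  cat(sprintf("CenterOutKSpace: %d coil(s) x %d azimuth(s) x %d radii (rho in [%.4g, %.4g] /mm)\n",
              d[1], d[2], d[3], min(object@rhoK), max(object@rhoK)))
})
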