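# Scan protocol constructor, derived quantities and the spoke trajectory.

# internal plain-function forms used inside validity methods
pixelSizeOf <- function(p) p@fovMm / p@baseResolution
kMaxOf <- function(p) 1 / (2 * pixelSizeOf(p))
deltaKOf <- function(p) 1 / (p@radialOversampling * p@fovMm)

#' Create a radial scan protocol
#'
#' @param fovMm field of view (mm)
#' @param baseResolution image matrix size per side (even, >= 8)
#' @param nSpokes number of spokes; must be even for `"monopolar"` and odd
#'   for `"bipolar"`
#' @param scheme angular scheme; by default inferred from the spoke parity
#'   (even -> monopolar over `[0, pi)`, odd -> bipolar over `[0, 2*pi)`)
#' @param radialOversampling readout oversampling factor, 1 or 2 (default 2,
#'   the usual choice to keep the circular FOV alias-free)
#' @param trMs repetition time (ms)
#' @param nCoils number of receive channels
#' @return a validated [ScanProtocol-class]
#' @examples
#' p <- scanProtocol(fovMm = 230.4, baseResolution = 256, nSpokes = 63)
#' pixelSize(p)  # 0.9 mm
#' kMax(p)       # 1/(2 * 0.9) mm^-1
#' @export
scanProtocol <- function(fovMm, baseResolution, nSpokes,
                         scheme = c("auto", "monopolar", "bipolar"),
                         radialOversampling = 2L, trMs = 4.30, nCoils = 1L) {
  scheme <- match.arg(scheme)
  if (scheme == "auto")
    scheme <- if (nSpokes %% 2 == 0) "monopolar" else "bipolar"
  new("ScanProtocol",
      fovMm = as.numeric(fovMm),
      baseResolution = as.integer(baseResolution),
      radialOversampling = as.integer(radialOversampling),
      nSpokes = as.integer(nSpokes),
      scheme = scheme,
      trMs = as.numeric(trMs),
      nCoils = as.integer(nCoils))
}

#' @describeIn scanProtocol pixel size `fovMm / baseResolution` (mm)
#' @param x a [ScanProtocol-class] (or an object carrying one)
#' @export
setMethod("pixelSize", "ScanProtocol", function(x) pixelSizeOf(x))

#' @describeIn scanProtocol maximum sampled spatial frequency `1/(2 * pixel)` (1/mm)
#' @export
setMethod("kMax", "ScanProtocol", function(x) kMaxOf(x))

#' @describeIn scanProtocol radial sample spacing `1/(oversampling * fov)` (1/mm)
#' @export
setMethod("deltaK", "ScanProtocol", function(x) deltaKOf(x))

#' @describeIn scanProtocol number of spokes
#' @export
setMethod("nSpokes", "ScanProtocol", function(x) x@nSpokes)

#' @describeIn scanProtocol number of receive channels
#' @export
setMethod("nCoils", "ScanProtocol", function(x) x@nCoils)

setMethod("show", "ScanProtocol", function(object) {
  cat(sprintf("ScanProtocol: %s, %d spokes, base %d (pixel %.3g mm, FOV %.4g mm)\n",
              object@scheme, object@nSpokes, object@baseResolution,
              pixelSizeOf(object), object@fovMm))
  cat(sprintf("  oversampling %d, k_max %.4g /mm, delta_k %.4g /mm, TR %.3g ms, %d coil(s)\n",
              object@radialOversampling, kMaxOf(object), deltaKOf(object),
              object@trMs, object@nCoils))
})

#' Spoke angles of a radial trajectory
#'
#' Uniform spoke angles for the protocol's scheme: `j * pi / nSpokes` for a
#' monopolar acquisition (even spoke count over half the circle, all spokes
#' sharing gradient polarity) and `j * 2 * pi / nSpokes` for a bipolar one
#' (odd spoke count over the full circle, which alternates the effective
#' readout direction between angular neighbours).
#'
#' @param protocol a [ScanProtocol-class]
#' @return sorted ascending angles in radians, one per spoke
#' @examples
#' buildTrajectory(scanProtocol(57.6, 64, nSpokes = 2))  # 0, pi/2
#' @export
buildTrajectory <- function(protocol) {
  validObject(protocol)
  n <- protocol@nSpokes
  if (protocol@scheme == "monopolar") (0:(n - 1)) * pi / n
  else (0:(n - 1)) * 2 * pi / n
}

#' Signed readout sample positions
#'
#' Radial k-space positions along one spoke, uniform step [deltaK()], covering
#' \eqn{-k_{max}} to \eqn{+k_{max}}.  The even-length readout (the default,
#' `baseResolution * radialOversampling` samples) straddles the center with
#' innermost samples at \eqn{\pm\Delta k / 2}; the odd readout adds one sample
#' so that \eqn{k = 0} is measured exactly.
#'
#' @param protocol a [ScanProtocol-class]
#' @param oddReadout include the exact `k = 0` sample (odd readout length)?
#' @return numeric vector of signed k positions (1/mm)
#' @export
readoutK <- function(protocol, oddReadout = FALSE) {
  dk <- deltaKOf(protocol)
  n <- protocol@baseResolution * protocol@radialOversampling
  if (oddReadout) ((0:n) - n / 2) * dk
  else ((0:(n - 1)) - n / 2 + 0.5) * dk
}
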