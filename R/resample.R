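# Polar-to-Cartesian conversion by nearest-neighbor substitution and
# square-FOV cropping.

#' Resampling settings
#'
#' @param outMatrix output side length in pixels (>= 2)
#' @param outPixelMm output pixel size (mm)
#' @param fillValue value used beyond the polar support (default 0)
#' @return a [ResampleSpec-class]
#' @export
resampleSpec <- function(outMatrix, outPixelMm, fillValue = 0) {
  new("ResampleSpec", outMatrix = as.integer(outMatrix),
      outPixelMm = as.numeric(outPixelMm), fillValue = as.complex(fillValue))
}

#' Nearest-neighbor polar-to-Cartesian conversion
#'
#' Each Cartesian pixel center \eqn{(x, y)} (symmetric centering,
#' \eqn{x_i = (i - (n-1)/2)\,\Delta x}) maps to
#' \eqn{(r, \theta) = (\sqrt{x^2+y^2}, \mathrm{atan2}(y, x) \bmod 2\pi)} and
#' takes the value of the nearest polar node - nearest \eqn{r_j}, nearest
#' \eqn{\theta_t}, ties resolved to the lower index.  Radii beyond the polar
#' support receive `fillValue`.  Nearest-neighbor substitution avoids
#' interpolation-related smoothing: output values are a subset of input
#' values (plus the fill).
#'
#' @param pim a [PolarImage-class]
#' @param spec a [ResampleSpec-class]; by default a square matrix covering
#'   the polar support at the protocol's pixel size
#' @return a [CartesianImage-class] (first index x, second y, coil planes
#'   preserved)
#' @export
polarToCartesian <- function(pim, spec = NULL) {
  stopifnot(is(pim, "PolarImage"))
  if (length(pim@rGrid) == 0 || length(pim@thetaGrid) == 0)
    stop("empty polar grid")
  if (is.null(spec)) {
    px <- pixelSizeOf(pim@protocol)
    n <- 2L * length(pim@rGrid)
    spec <- resampleSpec(n, px)
  }
  n <- spec@outMatrix
  px <- spec@outPixelMm
  ctr <- (n + 1) / 2
  coord <- ((1:n) - ctr) * px
  x <- matrix(coord, n, n)
  y <- matrix(coord, n, n, byrow = TRUE)
  r <- sqrt(x^2 + y^2)
  th <- atan2(y, x) %% (2 * pi)

  dr <- if (length(pim@rGrid) > 1) pim@rGrid[2] - pim@rGrid[1] else 1
  Mpad <- length(pim@thetaGrid)
  dth <- 2 * pi / Mpad
  jr <- ceiling(r / dr - 0.5)                 # 0-based, ties to lower index
  jr[jr < 0] <- 0
  J <- length(pim@rGrid)
  jt <- ceiling(th / dth - 0.5) %% Mpad
  outside <- r > max(pim@rGrid) + 1e-12       # beyond the polar support
  jr[outside | jr > J - 1] <- J - 1           # placeholder, overwritten below

  nc <- dim(pim@f)[3]
  out <- array(spec@fillValue, c(n, n, nc))
  lin <- jr + 1L + jt * length(pim@rGrid)
  for (c in seq_len(nc)) {
    plane <- pim@f[, , c]
    vals <- plane[lin]
    vals[outside] <- spec@fillValue
    out[, , c] <- vals
  }
  new("CartesianImage", pixels = out, pixelMm = px, centerIndex = c(ctr, ctr))
}

#' Centered square crop of a Cartesian image
#'
#' Crops to `round(fovMm / pixelMm)` pixels per side about the image center,
#' preserving pixel size and center metadata.  Cropping to the image's own
#' extent is the identity; a crop of a crop equals the single smaller crop.
#'
#' @param img a [CartesianImage-class]
#' @param fovMm requested field of view (mm); must not exceed the image extent
#' @return the cropped [CartesianImage-class]
#' @export
cropSquare <- function(img, fovMm) {
  stopifnot(is(img, "CartesianImage"))
  n <- dim(img@pixels)[1]
  nOut <- as.integer(round(fovMm / img@pixelMm))
  if (nOut > n) stop("requested FOV exceeds the image extent")
  if (nOut == n) return(img)
  startX <- as.integer(round(img@centerIndex[1] - (nOut + 1) / 2)) + 1L
  startY <- as.integer(round(img@centerIndex[2] - (nOut + 1) / 2)) + 1L
  startX <- max(1L, min(startX, n - nOut + 1L))
  startY <- max(1L, min(startY, n - nOut + 1L))
  px <- img@pixels
  if (length(dim(px)) == 2) dim(px) <- c(dim(px), 1L)
  out <- px[startX:(startX + nOut - 1L), startY:(startY + nOut - 1L), , drop = FALSE]
  new("CartesianImage", pixels = out, pixelMm = img@pixelMm,
      centerIndex = c(img@centerIndex[1] - startX + 1,
                      img@centerIndex[2] - startY + 1))
}
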