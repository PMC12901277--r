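# Pixel-wise SNR/CNR estimators, PSF aliasing-onset measurement, and
# protocol arithmetic (azimuthal Nyquist spoke count, acquisition time).

#' Pixel-wise SNR map from an image series
#'
#' For each pixel, the temporal mean \eqn{\mu = \sum_i x_i / N}, the
#' population standard deviation
#' \eqn{\sigma = \sqrt{\sum_i (x_i - \mu)^2 / N}} (divide-by-N, not N-1),
#' and their ratio \eqn{\mathrm{SNR} = \mu/\sigma}.  Pixels with
#' \eqn{\sigma = 0} are flagged undefined (`NA`) and excluded from region
#' averages.
#'
#' @param series numeric 3D array `n x m x N` of co-registered magnitude
#'   images (as produced by [repeatAcquisition()]), `N >= 2`
#' @param pixelMm,centerIndex image geometry; default taken from the series
#'   attributes
#' @return an [SnrMap-class]
#' @export
snrMap <- function(series, pixelMm = attr(series, "pixelMm"),
                   centerIndex = attr(series, "centerIndex")) {
  d <- dim(series)
  if (length(d) != 3 || d[3] < 2)
    stop("series must be a 3D array with at least 2 repetitions")
  N <- d[3]
  mu <- rowMeans(series, dims = 2)
  sigma <- sqrt(rowMeans(series^2, dims = 2) - mu^2)
  sigma[sigma < 0] <- 0
  snr <- mu / sigma
  snr[sigma == 0] <- NA_real_
  if (is.null(pixelMm)) pixelMm <- 1
  if (is.null(centerIndex)) centerIndex <- (d[1:2] + 1) / 2
  new("SnrMap", snr = snr, mu = mu, sigma = sigma, nRep = as.integer(N),
      pixelMm = as.numeric(pixelMm), centerIndex = as.numeric(centerIndex))
}

setMethod("show", "SnrMap", function(object) {
  cat(sprintf("SnrMap: %d x %d pixels over %d repetitions (median SNR %.3g)\n",
              nrow(object@snr), ncol(object@snr), object@nRep,
              stats::median(object@snr, na.rm = TRUE)))
})

#' Regions of interest
#'
#' Constructors for disk, annulus and box regions in mm relative to the
#' image center.
#'
#' @param centerMm (x, y) offset of the region center from the image center
#' @param radiusMm disk radius
#' @return a [Roi-class]
#' @export
roiDisk <- function(radiusMm, centerMm = c(0, 0)) {
  new("Roi", shape = "disk", params = list(center = centerMm, radius = radiusMm))
}

#' @rdname roiDisk
#' @param innerMm,outerMm annulus radii (about the image center)
#' @export
roiAnnulus <- function(innerMm, outerMm, centerMm = c(0, 0)) {
  new("Roi", shape = "annulus",
      params = list(center = centerMm, inner = innerMm, outer = outerMm))
}

#' @rdname roiDisk
#' @param widthMm,heightMm box extents
#' @export
roiBox <- function(widthMm, heightMm, centerMm = c(0, 0)) {
  new("Roi", shape = "box",
      params = list(center = centerMm, width = widthMm, height = heightMm))
}

#' Rasterize a region onto an image grid
#'
#' @param roi a [Roi-class]
#' @param dims image dimensions (n x m)
#' @param pixelMm pixel size (mm)
#' @param centerIndex 1-based (x, y) center index
#' @return logical matrix of pixel membership
#' @export
rasterizeRoi <- function(roi, dims, pixelMm, centerIndex) {
  x <- ((1:dims[1]) - centerIndex[1]) * pixelMm
  y <- ((1:dims[2]) - centerIndex[2]) * pixelMm
  X <- matrix(x, dims[1], dims[2])
  Y <- matrix(y, dims[1], dims[2], byrow = TRUE)
  p <- roi@params
  mask <- switch(roi@shape,
    disk = (X - p$center[1])^2 + (Y - p$center[2])^2 <= p$radius^2,
    annulus = {
      r2 <- (X - p$center[1])^2 + (Y - p$center[2])^2
      r2 >= p$inner^2 & r2 <= p$outer^2
    },
    box = abs(X - p$center[1]) <= p$width / 2 & abs(Y - p$center[2]) <= p$height / 2,
    stop("unknown roi shape"))
  if (!any(mask)) stop("roi has empty pixel support on this grid")
  mask
}

#' Region means of images and SNR maps
#'
#' `roiMean()` averages a plain image matrix over a region; `roiMeanSnr()`
#' averages the defined (non-`NA`) pixels of an [SnrMap-class].
#'
#' @param img numeric matrix (or [CartesianImage-class], first plane's
#'   magnitude)
#' @param roi a [Roi-class]
#' @param pixelMm,centerIndex image geometry (taken from the object when it
#'   carries them)
#' @return scalar mean
#' @export
roiMean <- function(img, roi, pixelMm = NULL, centerIndex = NULL) {
  if (is(img, "CartesianImage")) {
    pixelMm <- img@pixelMm
    centerIndex <- img@centerIndex
    m <- Mod(img@pixels)
    if (length(dim(m)) == 3) m <- m[, , 1]
    img <- m
  }
  mask <- rasterizeRoi(roi, dim(img), pixelMm, centerIndex)
  mean(img[mask])
}

#' @rdname roiMean
#' @param map an [SnrMap-class]
#' @export
roiMeanSnr <- function(map, roi) {
  stopifnot(is(map, "SnrMap"))
  mask <- rasterizeRoi(roi, dim(map@snr), map@pixelMm, map@centerIndex)
  v <- map@snr[mask]
  v <- v[!is.na(v)]
  if (length(v) == 0) stop("all pixels in the region are undefined")
  mean(v)
}

#' Contrast-to-noise ratio between two regions
#'
#' \eqn{\mathrm{CNR} = (S_A - S_B)/\sigma}: the difference of the two region
#' means of the temporal-mean image, divided by the mean temporal standard
#' deviation over a noise region.
#'
#' @param series numeric 3D array of repeated magnitude images (as for
#'   [snrMap()])
#' @param roiA,roiB signal regions (disjoint)
#' @param noiseRoi region over which the temporal sigma is averaged
#' @param pixelMm,centerIndex image geometry; default from series attributes
#' @return scalar CNR
#' @export
cnr <- function(series, roiA, roiB, noiseRoi,
                pixelMm = attr(series, "pixelMm"),
                centerIndex = attr(series, "centerIndex")) {
  map <- snrMap(series, pixelMm, centerIndex)
  mask <- rasterizeRoi(noiseRoi, dim(map@sigma), map@pixelMm, map@centerIndex)
  sig <- mean(map@sigma[mask])
  if (sig <= 0) stop("zero noise estimate in the noise region")
  a <- rasterizeRoi(roiA, dim(map@mu), map@pixelMm, map@centerIndex)
  b <- rasterizeRoi(roiB, dim(map@mu), map@pixelMm, map@centerIndex)
  (mean(map@mu[a]) - mean(map@mu[b])) / sig
}

# contiguous region above `frac * peak` containing the peak, grown by
# iterated 4-neighbour dilation (the PSF main lobe)
mainLobeMask <- function(mag, peakIdx, frac = 0.5) {
  above <- mag >= frac * max(mag)
  mask <- matrix(FALSE, nrow(mag), ncol(mag))
  mask[peakIdx[1], peakIdx[2]] <- TRUE
  repeat {
    grown <- mask
    grown[-1, ] <- grown[-1, ] | mask[-nrow(mask), ]
    grown[-nrow(mask), ] <- grown[-nrow(mask), ] | mask[-1, ]
    grown[, -1] <- grown[, -1] | mask[, -ncol(mask)]
    grown[, -ncol(mask)] <- grown[, -ncol(mask)] | mask[, -1]
    grown <- grown & above
    if (all(grown == mask)) break
    mask <- grown
  }
  mask
}

#' Aliasing-onset radius of a point-source PSF
#'
#' Recenters on the PSF peak and returns the smallest radius (mm, about the
#' peak) at which any pixel outside the main lobe exceeds
#' `threshold * peak`.  The main lobe is the contiguous region above half
#' the peak containing the peak.  Because even an ideally sampled PSF
#' carries ring sidelobes above a few percent of its peak immediately
#' outside the main lobe, aliasing is judged against a fully sampled
#' reference PSF of the same reconstructor when one is supplied: pixels
#' where the reference itself exceeds the threshold are excluded, so the
#' measurement responds to undersampling artifacts rather than to the
#' intrinsic sidelobe structure.  Returns `Inf` when no pixel qualifies
#' within the frame.
#'
#' @param psf a [CartesianImage-class] (or magnitude matrix) of a single
#'   point source
#' @param threshold artifact threshold as a fraction of the peak (default 0.05)
#' @param reference optional fully sampled PSF of the same reconstructor
#'   (same grid); its pixels above `threshold * reference peak`, recentered
#'   on its own peak, are excluded from the artifact search
#' @param pixelMm pixel size when `psf` is a plain matrix
#' @return onset radius in mm, or `Inf`
#' @export
aliasingOnsetRadius <- function(psf, threshold = 0.05, reference = NULL,
                                pixelMm = NULL) {
  asMag <- function(x) {
    if (is(x, "CartesianImage")) {
      m <- Mod(x@pixels)
      if (length(dim(m)) == 3) m <- m[, , 1]
      m
    } else as.matrix(Mod(x))
  }
  if (is(psf, "CartesianImage")) pixelMm <- psf@pixelMm
  if (is.null(pixelMm)) stop("pixelMm required for a plain matrix")
  mag <- asMag(psf)
  pk <- which(mag == max(mag), arr.ind = TRUE)[1, ]
  if (max(mag) <= 0) stop("no identifiable peak")
  lobe <- mainLobeMask(mag, pk)
  excl <- lobe
  if (!is.null(reference)) {
    rmag <- asMag(reference)
    rpk <- which(rmag == max(rmag), arr.ind = TRUE)[1, ]
    rmask <- rmag > threshold * max(rmag)
    # align the reference peak with the psf peak, then exclude its footprint
    shift <- pk - rpk
    shifted <- matrix(FALSE, nrow(mag), ncol(mag))
    src <- which(rmask, arr.ind = TRUE)
    dst <- sweep(src, 2, shift, `+`)
    ok <- dst[, 1] >= 1 & dst[, 1] <= nrow(mag) & dst[, 2] >= 1 & dst[, 2] <= ncol(mag)
    shifted[dst[ok, , drop = FALSE]] <- TRUE
    excl <- excl | shifted
  }
  hot <- mag > threshold * max(mag) & !excl
  if (!any(hot)) return(Inf)
  idx <- which(hot, arr.ind = TRUE)
  d <- sqrt((idx[, 1] - pk[1])^2 + (idx[, 2] - pk[2])^2) * pixelMm
  min(d)
}

#' Azimuthal Nyquist spoke count
#'
#' The spoke count needed for full-FOV resolution at the maximum sampled
#' frequency: \eqn{N_{spokes} = N_{base}\,\pi/2}, rounded to the nearest
#' integer (about 400 for base 256).
#'
#' @param baseResolution image matrix size (>= 2)
#' @return integer spoke count
#' @export
nyquistSpokes <- function(baseResolution) {
  stopifnot(baseResolution >= 2)
  as.integer(round(baseResolution * pi / 2))
}

#' Acquisition time per slice
#'
#' `nSpokes * TR`, in seconds.
#'
#' @param protocol a [ScanProtocol-class]
#' @return seconds per slice
#' @export
acquisitionTime <- function(protocol) {
  stopifnot(protocol@trMs > 0)
  protocol@nSpokes * protocol@trMs / 1000
}

#' Radial SNR profile
#'
#' Means of the defined SNR pixels over concentric annuli, with the
#' least-squares slope of SNR versus radius.
#'
#' @param map an [SnrMap-class]
#' @param widthMm annulus width (mm)
#' @param maxRadiusMm outermost radius (default: largest inscribed circle)
#' @return list with `profile` (data frame of `radiusMm`, `meanSnr`, `nPix`)
#'   and `slope` (SNR per mm)
#' @export
radialSnrProfile <- function(map, widthMm = 2, maxRadiusMm = NULL) {
  stopifnot(is(map, "SnrMap"))
  d <- dim(map@snr)
  x <- ((1:d[1]) - map@centerIndex[1]) * map@pixelMm
  y <- ((1:d[2]) - map@centerIndex[2]) * map@pixelMm
  R <- sqrt(outer(x^2, y^2, `+`))
  if (is.null(maxRadiusMm))
    maxRadiusMm <- min(abs(range(x)), abs(range(y)))
  edges <- seq(0, maxRadiusMm, by = widthMm)
  rows <- lapply(seq_len(length(edges) - 1), function(i) {
    sel <- R >= edges[i] & R < edges[i + 1] & !is.na(map@snr)
    if (!any(sel)) return(NULL)
    data.frame(radiusMm = (edges[i] + edges[i + 1]) / 2,
               meanSnr = mean(map@snr[sel]), nPix = sum(sel))
  })
  profile <- do.call(rbind, rows)
  slope <- if (nrow(profile) >= 2)
    unname(coef(lm(meanSnr ~ radiusMm, data = profile))[2]) else NA_real_
  list(profile = profile, slope = slope)
}

#' Azimuthal FWHM of a polar-domain PSF
#'
#' Extracts the angular magnitude profile at the image radius nearest `r0Mm`
#' and returns its full width at half maximum as an arc length (mm),
#' interpolating the half-maximum crossings linearly.
#'
#' @param pim a [PolarImage-class] of a single point source at radius `r0Mm`
#' @param r0Mm source radius (mm)
#' @return azimuthal FWHM arc length (mm)
#' @export
psfAzimuthalFwhm <- function(pim, r0Mm) {
  stopifnot(is(pim, "PolarImage"))
  j <- which.min(abs(pim@rGrid - r0Mm))
  prof <- Mod(pim@f[j, , 1])
  Mpad <- length(prof)
  pk <- which.max(prof)
  prof <- prof[((seq_len(Mpad) - 1 + pk - 1 - Mpad %/% 2) %% Mpad) + 1]  # peak centered
  half <- prof[Mpad %/% 2 + 1] / 2
  i0 <- Mpad %/% 2 + 1
  right <- i0
  while (right < Mpad && prof[right + 1] >= half) right <- right + 1
  left <- i0
  while (left > 1 && prof[left - 1] >= half) left <- left - 1
  fr <- if (right < Mpad) (prof[right] - half) / (prof[right] - prof[right + 1]) else 0
  fl <- if (left > 1) (prof[left] - half) / (prof[left] - prof[left - 1]) else 0
  widthBins <- (right - left) + fr + fl
  widthBins * (2 * pi / Mpad) * r0Mm
}

#' Onset radius of the undersampling artifact pattern
#'
#' Measures where the artifact pattern of an undersampled PSF begins: the
#' smallest distance from the PSF peak at which the peak-normalized
#' deviation from a fully sampled reference PSF of the same reconstructor
#' exceeds `frac` times the deviation's own maximum.  Referencing the
#' artifact pattern to its own maximum makes the measure respond to where
#' artifacts begin rather than to their absolute amplitude (for a unit point
#' source the radial streak amplitude scales like `1/nSpokes` of the peak
#' and can sit below any fixed fraction of the peak); the transition is
#' sharp, so the radius is insensitive to `frac`.
#'
#' @param psf undersampled PSF ([CartesianImage-class] or magnitude matrix)
#' @param reference fully sampled PSF of the same reconstructor on the same
#'   grid
#' @param frac onset threshold as a fraction of the strongest artifact
#'   (default 0.05)
#' @param pixelMm pixel size when plain matrices are given
#' @return onset radius in mm (Inf if the deviation is identically zero)
#' @export
artifactOnsetRadius <- function(psf, reference, frac = 0.05, pixelMm = NULL) {
  asMag <- function(x) {
    if (is(x, "CartesianImage")) {
      m <- Mod(x@pixels)
      if (length(dim(m)) == 3) m <- m[, , 1]
      m
    } else as.matrix(Mod(x))
  }
  if (is(psf, "CartesianImage")) pixelMm <- psf@pixelMm
  if (is.null(pixelMm)) stop("pixelMm required for plain matrices")
  m <- asMag(psf); r <- asMag(reference)
  if (any(dim(m) != dim(r))) stop("psf and reference grids differ")
  art <- abs(m / max(m) - r / max(r))
  if (max(art) == 0) return(Inf)
  pk <- which(m == max(m), arr.ind = TRUE)[1, ]
  hot <- art > frac * max(art)
  idx <- which(hot, arr.ind = TRUE)
  d <- sqrt((idx[, 1] - pk[1])^2 + (idx[, 2] - pk[2])^2) * pixelMm
  min(d)
}

#' Ghost amplitude of a polar-domain point-source PSF
#'
#' The peak-normalized maximum of \eqn{|f(r, \theta)|} over the half-plane
#' opposite the source (angles within \eqn{\pi/2} of
#' \eqn{\theta_0 + \pi}), where undersampling ghosts of the polar transform
#' appear symmetrically opposite the source.  Measured in the native polar
#' domain so the display-stage Cartesian resampling cannot bias the ratio.
#'
#' @param pim a [PolarImage-class] of a single point source
#' @param sourceThetaRad angular position of the source
#' @return ghost amplitude as a fraction of the PSF peak
#' @export
ghostAmplitude <- function(pim, sourceThetaRad) {
  stopifnot(is(pim, "PolarImage"))
  f <- Mod(pim@f[, , 1])
  th <- pim@thetaGrid
  opp <- abs(((th - (sourceThetaRad + pi)) %% (2 * pi) + pi) %% (2 * pi) - pi) <= pi / 2
  max(f[, opp]) / max(f)
}

#' Smallest source radius at which the polar transform shows aliasing
#'
#' Sweeps a point source outward along \eqn{\theta_0 = -\pi/2},
#' reconstructing with the polar transform chain at each radius, until the
#' opposite-half-plane ghost ([ghostAmplitude()]) exceeds
#' `threshold` of the PSF peak; the first crossing is then refined by
#' bisection.  Returns `Inf` when no radius in the sweep shows a ghost
#' (e.g. at or above the azimuthal Nyquist spoke count).
#'
#' @param protocol a [ScanProtocol-class]
#' @param threshold ghost threshold as a fraction of the PSF peak
#'   (default 0.05)
#' @param radiiMm increasing sweep radii (mm)
#' @param padFactor angular zero-padding factor for the reconstruction
#' @param refineMm bisection tolerance (mm)
#' @return onset source radius in mm, or `Inf`
#' @export
sourceAliasingOnset <- function(protocol, threshold = 0.05,
                                radiiMm = seq(10, 40, by = 1), padFactor = 4L,
                                refineMm = 0.1) {
  ghostAt <- function(r0) {
    ks <- pointSourceKSpace(data.frame(r0 = r0, theta0 = -pi / 2), protocol)
    ghostAmplitude(pftReconstruct(ks, padFactor = padFactor), -pi / 2)
  }
  lo <- NA_real_; hi <- NA_real_
  for (r0 in radiiMm) {
    if (ghostAt(r0) > threshold) { hi <- r0; break } else lo <- r0
  }
  if (is.na(hi)) return(Inf)
  if (is.na(lo)) return(hi)
  while (hi - lo > refineMm) {
    mid <- (lo + hi) / 2
    if (ghostAt(mid) > threshold) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
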