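# Standard gridding reconstruction: density compensation, Kaiser-Bessel
# convolution onto an oversampled Cartesian grid, inverse FFT, deapodization
# and central crop.  Serves as the shift-invariant comparator for the polar
# transform chain.

#' Gridding configuration
#'
#' @param kernelWidth Kaiser-Bessel kernel support in grid cells (default 4)
#' @param gridOversampling Cartesian grid oversampling factor (default 2)
#' @param kernelBeta shape parameter; the default follows the standard
#'   width/oversampling prescription
#'   \eqn{\beta = \pi\sqrt{(W/\alpha)^2(\alpha - 1/2)^2 - 0.8}}
#' @param dcMode density-compensation mode, `"ramp"` (default) or `"voronoi"`
#' @return a [GriddingConfig-class]
#' @export
griddingConfig <- function(kernelWidth = 4, gridOversampling = 2,
                           kernelBeta = NULL, dcMode = c("ramp", "voronoi")) {
  dcMode <- match.arg(dcMode)
  if (is.null(kernelBeta)) {
    a <- gridOversampling
    kernelBeta <- pi * sqrt((kernelWidth / a)^2 * (a - 0.5)^2 - 0.8)
  }
  new("GriddingConfig", kernelWidth = as.numeric(kernelWidth),
      kernelBeta = as.numeric(kernelBeta),
      gridOversampling = as.numeric(gridOversampling), dcMode = dcMode)
}

#' Density-compensation weights for a uniform radial trajectory
#'
#' Ramp mode assigns \eqn{w \propto |k|} (the annular sector the sample
#' represents), with a center sample at \eqn{k = 0} treated as lying at
#' \eqn{\Delta k/8} - the value for which the ramp weight equals the exact
#' area of the central disk divided among the half-spokes.  Voronoi mode
#' computes each sample's annular-sector area
#' \eqn{\pi(k_{out}^2 - k_{in}^2)/M} directly.  Weights are normalized so
#' their total over all spokes is 1.
#'
#' @param ks a [RadialKSpace-class]
#' @param mode `"ramp"` or `"voronoi"`
#' @return numeric matrix `nSpokes x nReadout` of per-sample weights
#' @export
densityWeights <- function(ks, mode = c("ramp", "voronoi")) {
  mode <- match.arg(mode)
  stopifnot(is(ks, "RadialKSpace"))
  if (ks@protocol@nSpokes < 1) stop("no spokes")
  k <- ks@readoutK
  dk <- deltaKOf(ks@protocol)
  M <- 2 * ks@protocol@nSpokes          # half-spokes covering [0, 2*pi)
  if (mode == "ramp") {
    a <- abs(k)
    a[a < dk / 16] <- dk / 8            # k = 0 convention
    w <- a * dk * 2 * pi / M
  } else {
    inner <- pmax(abs(k) - dk / 2, 0)
    outer <- abs(k) + dk / 2
    w <- pi * (outer^2 - inner^2) / M
  }
  w <- matrix(w, nrow = ks@protocol@nSpokes, ncol = length(k), byrow = TRUE)
  w / sum(w)
}

# Kaiser-Bessel interpolation kernel on |u| <= W/2 (grid cells)
kbKernel <- function(u, width, beta) {
  t <- 1 - (2 * u / width)^2
  out <- numeric(length(u))
  ok <- t > 0
  out[ok] <- besselI(beta * sqrt(t[ok]), 0) / besselI(beta, 0)
  out
}

# Fourier transform of the KB kernel at image position p (pixels of a
# G-point grid); used for deapodization
kbDeapod <- function(p, width, beta, G) {
  z2 <- (pi * width * p / G)^2 - beta^2
  out <- numeric(length(p))
  pos <- z2 > 0
  out[pos] <- sin(sqrt(z2[pos])) / sqrt(z2[pos])
  out[!pos] <- sinh(sqrt(-z2[!pos])) / sqrt(-z2[!pos])
  out
}

fftshift2 <- function(m) {
  d <- dim(m)
  m[c((d[1] %/% 2 + 1):d[1], 1:(d[1] %/% 2)),
    c((d[2] %/% 2 + 1):d[2], 1:(d[2] %/% 2))]
}

#' Gridding reconstruction of radial k-space
#'
#' Density-compensated samples are convolved onto an oversampled Cartesian
#' grid with a Kaiser-Bessel kernel, inverse-2D-FFTed, deapodized by the
#' kernel's transform, and centrally cropped to `baseResolution` pixels.
#'
#' @param ks a [RadialKSpace-class]
#' @param cfg a [GriddingConfig-class]
#' @param combine `"none"` keeps per-coil complex planes; `"sos"` replaces
#'   them with one magnitude sum-of-squares plane
#' @return a [CartesianImage-class] (`baseResolution` per side, center at
#'   `n/2 + 1`)
#' @export
gridReconstruct <- function(ks, cfg = griddingConfig(),
                            combine = c("none", "sos")) {
  combine <- match.arg(combine)
  stopifnot(is(ks, "RadialKSpace"), is(cfg, "GriddingConfig"))
  validObject(ks); validObject(cfg)
  p <- ks@protocol
  N <- p@baseResolution
  G <- as.integer(round(cfg@gridOversampling * N))
  dkg <- 1 / (G * pixelSizeOf(p))
  W <- cfg@kernelWidth
  beta <- cfg@kernelBeta

  w <- densityWeights(ks, cfg@dcMode)
  ang <- ks@anglesRad
  kx <- outer(ang, ks@readoutK, function(a, k) k * cos(a))
  ky <- outer(ang, ks@readoutK, function(a, k) k * sin(a))
  gx <- as.vector(kx) / dkg + G / 2 + 1
  gy <- as.vector(ky) / dkg + G / 2 + 1
  wv <- as.vector(w)

  x0 <- ceiling(gx - W / 2); y0 <- ceiling(gy - W / 2)
  nOff <- floor(W) + 1
  nc <- dim(ks@samples)[1]
  planes <- array(complex(real = 0), c(N, N, nc))
  pix <- ((1:G) - (G / 2 + 1))
  deap <- kbDeapod(pix, W, beta, G)
  keep <- (G / 2 + 1 - N / 2):(G / 2 + N / 2)

  for (c in seq_len(nc)) {
    s <- ks@samples[c, , , drop = FALSE]
    dim(s) <- dim(ks@samples)[2:3]
    sv <- as.vector(s) * wv
    accRe <- matrix(0, G, G)
    accIm <- matrix(0, G, G)
    for (ax in 0:(nOff - 1)) {
      ix <- x0 + ax
      wx <- kbKernel(ix - gx, W, beta)
      for (ay in 0:(nOff - 1)) {
        iy <- y0 + ay
        wy <- kbKernel(iy - gy, W, beta)
        ww <- wx * wy
        ok <- ix >= 1 & ix <= G & iy >= 1 & iy <= G & ww > 0
        if (!any(ok)) next
        lin <- ix[ok] + (iy[ok] - 1) * G
        contrib <- sv[ok] * ww[ok]
        re <- rowsum(Re(contrib), lin)
        im <- rowsum(Im(contrib), lin)
        at <- as.integer(rownames(re))
        accRe[at] <- accRe[at] + re[, 1]
        accIm[at] <- accIm[at] + im[, 1]
      }
    }
    grid <- accRe + 1i * accIm
    img <- fftshift2(fft(fftshift2(grid), inverse = TRUE)) / G^2
    img <- img / outer(deap, deap)
    planes[, , c] <- img[keep, keep]
  }
  if (combine == "sos" && nc > 1) {
    sos <- sqrt(apply(abs(planes)^2, c(1, 2), sum))
    planes <- array(as.complex(sos), c(dim(sos), 1L))
  }
  new("CartesianImage", pixels = planes, pixelMm = pixelSizeOf(p),
      centerIndex = c(N / 2 + 1, N / 2 + 1))
}

#' @describeIn gridReconstruct pixel array of a Cartesian image
#' @param x a [CartesianImage-class]
#' @export
setMethod("pixels", "CartesianImage", function(x) x@pixels)

setMethod("show", "CartesianImage", function(object) {
  d <- dim(object@pixels)
  nc <- if (length(d) == 3) d[3] else 1L
  cat(sprintf("CartesianImage: %d x %d pixel(s) x %d plane(s), %.3g mm pixels, center (%.1f, %.1f)\n",
              d[1], d[2], nc, object@pixelMm,
              object@centerIndex[1], object@centerIndex[2]))
})
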