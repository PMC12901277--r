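# SNR/CNR estimators, onset measures and protocol arithmetic

test_that("the SNR map uses the population deviation and flags sigma = 0", {
  ser <- array(0, c(2, 2, 2))
  ser[1, 1, ] <- c(1, 3)      # mu = 2, sigma = 1 (divide-by-N), SNR = 2
  ser[2, 1, ] <- c(4, 4)      # constant -> undefined
  ser[1, 2, ] <- c(0, 2)
  ser[2, 2, ] <- c(5, 7)
  map <- snrMap(ser, pixelMm = 1, centerIndex = c(1.5, 1.5))
  expect_equal(map@mu[1, 1], 2)
  expect_equal(map@sigma[1, 1], 1)
  expect_equal(map@snr[1, 1], 2)
  expect_true(is.na(map@snr[2, 1]))
  expect_equal(map@nRep, 2L)
  expect_error(snrMap(ser[, , 1, drop = FALSE]), "at least 2")
})

test_that("magnitude-series SNR matches the Rician Monte-Carlo prediction", {
  # |mu + complex noise| with mu/sigma = 10, N = 30, 4096 pixels: the mean
  # estimated SNR sits within 5% of 10 (Rician mean/std plus the finite-N
  # inverse-sigma bias)
  set.seed(42)
  mu <- 10; sig <- 1; N <- 30; npix <- 64 * 64
  ser <- array(Mod(complex(real = mu + rnorm(npix * N, sd = sig),
                           imaginary = rnorm(npix * N, sd = sig))),
               c(64, 64, N))
  map <- snrMap(ser, pixelMm = 1, centerIndex = c(32.5, 32.5))
  expect_equal(mean(map@snr), 10, tolerance = 0.05)
})

test_that("region means and rasterization behave geometrically", {
  m <- matrix(3, 32, 32)
  expect_equal(roiMean(m, roiDisk(5), pixelMm = 1, centerIndex = c(16.5, 16.5)), 3)
  m[1:16, ] <- 1                       # half c1, half c2 with equal counts
  expect_equal(roiMean(m, roiBox(32, 32), pixelMm = 1, centerIndex = c(16.5, 16.5)), 2)
  # disk pixel count matches area within a boundary ring
  mask <- rasterizeRoi(roiDisk(8), c(64, 64), 1, c(32.5, 32.5))
  area <- pi * 64
  ring <- 2 * pi * 8
  expect_lt(abs(sum(mask) - area), ring)
  expect_error(rasterizeRoi(roiDisk(0.1), c(4, 4), 10, c(2.5, 2.5)), "empty")
})

test_that("CNR follows its definition and recovers a known contrast", {
  # direct arithmetic: S_A = 5, S_B = 3, sigma = 1 -> 2; A = B -> 0
  ser <- array(rep(c(5, 3, 0), each = 4), c(2, 2, 3))
  ser <- aperm(array(c(5, 5, 5, 3, 3, 3, 0, 1, 2), c(3, 3, 1)), c(3, 2, 1))
  # build explicitly: 3 x 1 image over 3 reps
  ser <- array(0, c(3, 1, 3))
  ser[1, 1, ] <- 5                     # region A, noiseless
  ser[2, 1, ] <- 3                     # region B, noiseless
  ser[3, 1, ] <- c(0, 1, 2)            # noise pixel, sigma = sqrt(2/3)
  roiA <- roiBox(0.9, 0.9, centerMm = c(-1, 0))
  roiB <- roiBox(0.9, 0.9, centerMm = c(0, 0))
  roiN <- roiBox(0.9, 0.9, centerMm = c(1, 0))
  got <- cnr(ser, roiA, roiB, roiN, pixelMm = 1, centerIndex = c(2, 1))
  expect_equal(got, (5 - 3) / sqrt(2 / 3))
  expect_equal(cnr(ser, roiA, roiA, roiN, pixelMm = 1, centerIndex = c(2, 1)), 0)
  expect_error(cnr(ser, roiA, roiB, roiB, pixelMm = 1,
                   centerIndex = c(2, 1)), "zero noise")

  # two known disks with injected image-domain noise, N = 30: recovered CNR
  # within 10% of the Rician-corrected analytic value
  truth <- matrix(0, 64, 64)
  xv <- (1:64) - 32.5
  X <- matrix(xv, 64, 64); Y <- t(X)
  truth[(X + 10)^2 + Y^2 <= 64] <- 5
  truth[(X - 10)^2 + Y^2 <= 64] <- 3
  set.seed(9)
  ser <- array(0, c(64, 64, 30))
  for (i in 1:30)
    ser[, , i] <- Mod(truth + complex(real = rnorm(4096), imaginary = rnorm(4096)))
  got <- cnr(ser, roiDisk(6, centerMm = c(-10, 0)), roiDisk(6, centerMm = c(10, 0)),
             roiDisk(6, centerMm = c(0, 20)), pixelMm = 1, centerIndex = c(32.5, 32.5))
  # analytic: difference of Rician means over the Rayleigh deviation
  # (exponentially scaled Bessel terms already absorb the e^{-a^2/4} factor)
  ricianMean <- function(a) sqrt(pi / 2) *
    ((1 + a^2 / 2) * besselI(a^2 / 4, 0, expon.scaled = TRUE) +
       (a^2 / 2) * besselI(a^2 / 4, 1, expon.scaled = TRUE))
  analytic <- (ricianMean(5) - ricianMean(3)) / sqrt(2 - pi / 2)
  expect_equal(got, analytic, tolerance = 0.10)
})

test_that("protocol arithmetic reproduces the printed spoke and timing numbers", {
  expect_equal(nyquistSpokes(256), 402L)
  expect_equal(nyquistSpokes(2), 3L)
  # monotone nondecreasing over bases 2..512
  expect_true(all(diff(vapply(2:512, nyquistSpokes, 1L)) >= 0))

  expect_equal(acquisitionTime(scanProtocol(230.4, 256, nSpokes = 255)),
               255 * 4.30 / 1000)
  expect_equal(round(acquisitionTime(scanProtocol(230.4, 256, nSpokes = 255)), 1), 1.1)
  expect_equal(round(acquisitionTime(scanProtocol(230.4, 256, nSpokes = 127)), 2), 0.55)
  expect_equal(acquisitionTime(scanProtocol(230.4, 256, nSpokes = 1, scheme = "bipolar",
                                            trMs = 4.30)), 0.0043)
})

test_that("radial SNR profiles report annular means and slopes", {
  # radially constant map -> slope 0; map = r -> slope 1 per mm
  n <- 64
  ctr <- c(32.5, 32.5)
  R <- sqrt(outer(((1:n) - ctr[1])^2, ((1:n) - ctr[2])^2, `+`)) * 1
  mk <- function(snr) new("SnrMap", snr = snr, mu = snr, sigma = snr * 0 + 1,
                          nRep = 5L, pixelMm = 1, centerIndex = ctr)
  pc <- radialSnrProfile(mk(matrix(7, n, n)), widthMm = 2)
  expect_equal(pc$slope, 0, tolerance = 1e-10)
  expect_true(all(abs(pc$profile$meanSnr - 7) < 1e-12))
  pr <- radialSnrProfile(mk(R), widthMm = 2)
  expect_equal(pr$slope, 1, tolerance = 0.02)
})

test_that("onset measures recognise synthetic artifact geometries", {
  # synthetic PSF: delta peak + artifact ring at 20 pixels, 8% of peak
  # (nearest lattice point with 19.5 < R < 20.5 lies at R = 19.65)
  n <- 101
  m <- matrix(0, n, n)
  m[51, 51] <- 1
  R <- sqrt(outer(((1:n) - 51)^2, ((1:n) - 51)^2, `+`))
  m[abs(R - 20) < 0.5] <- 0.08
  on1 <- aliasingOnsetRadius(m, threshold = 0.05, pixelMm = 1)
  expect_gt(on1, 19.4); expect_lt(on1, 20.2)
  # below threshold -> sentinel
  m2 <- m; m2[abs(R - 20) < 0.5] <- 0.04
  expect_identical(aliasingOnsetRadius(m2, threshold = 0.05, pixelMm = 1), Inf)
  # reference exclusion removes shared sidelobe structure
  ref <- matrix(0, n, n); ref[51, 51] <- 1
  ref[abs(R - 3) < 0.5] <- 0.10        # intrinsic sidelobe ring in both
  m3 <- m; m3[abs(R - 3) < 0.5] <- 0.10
  onNear <- aliasingOnsetRadius(m3, threshold = 0.05, pixelMm = 1)
  expect_gt(onNear, 2.4); expect_lt(onNear, 3.2)   # hits the sidelobe ring
  onRef <- aliasingOnsetRadius(m3, threshold = 0.05, reference = ref, pixelMm = 1)
  expect_gt(onRef, 19.4); expect_lt(onRef, 20.2)
  # artifact-pattern onset against the reference
  onArt <- artifactOnsetRadius(m3, ref, pixelMm = 1)
  expect_gt(onArt, 19.4); expect_lt(onArt, 20.2)
  expect_error(aliasingOnsetRadius(m * 0, pixelMm = 1), "peak")
})

test_that("the polar ghost measure and FWHM respond to source geometry", {
  p <- smallProtocol(nSpokes = 15)     # heavily undersampled at base 64
  mkPsf <- function(r0) pftReconstruct(
    pointSourceKSpace(data.frame(r0 = r0, theta0 = -pi / 2), p))
  # ghost grows with source radius under undersampling
  gNear <- ghostAmplitude(mkPsf(4), -pi / 2)
  gFar <- ghostAmplitude(mkPsf(18), -pi / 2)
  expect_gt(gFar, gNear)
  # fully sampled: no ghost above threshold anywhere in the sweep
  pFull <- smallProtocol(nSpokes = 101)
  expect_identical(sourceAliasingOnset(pFull, radiiMm = c(8, 12, 16, 20)), Inf)
  # azimuthal FWHM non-decreasing in source radius
  fw <- vapply(c(6, 12, 20), function(r0) psfAzimuthalFwhm(mkPsf(r0), r0), 0)
  expect_true(all(diff(fw) > 0))
})
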