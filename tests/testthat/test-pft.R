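# the polar transform chain against independent oracles

test_that("azimuthal FFT isolates harmonics and matches a direct DFT", {
  p <- tinyProtocol(nSpokes = 4)
  ks <- pointSourceKSpace(data.frame(x = 0, y = 0), p)
  co <- reorganizeCenterOut(ks)
  M <- dim(co@F)[2]
  K <- dim(co@F)[3]

  # constant over phi -> only order 0, value c
  co@F[1, , ] <- 3.2 + 0i
  sp <- azimuthalFFT(co)
  expect_equal(sp@Fn[1, which(sp@orders == 0), ], rep(3.2 + 0i, K))
  expect_lt(max(abs(sp@Fn[1, sp@orders != 0, ])), 1e-12)

  # single harmonic e^{i phi} -> only order 1
  co@F[1, , ] <- matrix(exp(1i * co@phiM), M, K)
  sp <- azimuthalFFT(co)
  expect_equal(sp@Fn[1, which(sp@orders == 1), ], rep(1 + 0i, K), tolerance = 1e-12)
  expect_lt(max(abs(sp@Fn[1, sp@orders != 1, ])), 1e-12)

  # random input vs direct O(M^2) DFT oracle
  set.seed(21)
  co@F[1, , ] <- complex(real = rnorm(M * K), imaginary = rnorm(M * K))
  sp <- azimuthalFFT(co)
  oracle <- t(vapply(sp@orders, function(n)
    colSums(co@F[1, , ] * exp(-1i * n * co@phiM)) / M, complex(K)))
  expect_lt(max(abs(sp@Fn[1, , ] - oracle)), 1e-12)
})

test_that("the order-n Hankel transform reproduces closed forms and fine quadrature", {
  # zero row -> zero profile
  rho <- seq(0, 0.5, length.out = 128)
  r <- seq(0, 24, length.out = 49)
  tab <- buildKernelTable(NULL, rho, r, nMax = 6)
  expect_equal(hankelTransform(rep(0 + 0i, 128), tab, 0), rep(0 + 0i, 49))

  # disk <-> jinc pair: F_0 = 1 for rho <= P gives P J_1(2 pi P r)/r
  P <- 0.3
  row <- as.complex(as.numeric(rho <= P))
  got <- hankelTransform(row, tab, 0)
  closed <- ifelse(r < 1e-9, pi * P^2, P * besselJ(2 * pi * P * r, 1) / r)
  expect_lt(max(abs(got - closed)), 0.01 * max(abs(closed)))

  # arbitrary row vs 10x-oversampled trapezoid quadrature oracle
  set.seed(2)
  rowFun <- function(x) exp(-18 * x) * cos(9 * x)
  row <- as.complex(rowFun(rho))
  got <- hankelTransform(row, tab, 3)
  rhoF <- seq(0, max(rho), length.out = 10 * length(rho))
  wF <- rhoF * (rhoF[2] - rhoF[1]); wF[1] <- wF[1] / 2; wF[length(wF)] <- wF[length(wF)] / 2
  oracle <- vapply(r, function(rj)
    2 * pi * sum(wF * rowFun(rhoF) * besselJ(2 * pi * rhoF * rj, 3)), 0)
  expect_lt(max(abs(got - oracle)), 0.005 * max(abs(oracle)))

  expect_error(hankelTransform(row, tab, 9), "outside")
})

test_that("polar assembly applies i^n phasing and matches a direct inverse DFT", {
  p <- tinyProtocol(nSpokes = 4)
  M <- 8L
  orders <- as.integer(-4:3)
  J <- 5L
  rGrid <- 0:4

  mk <- function(fnMat) new("RadialProfiles",
                            fn = array(fnMat, c(1, M, J)),
                            orders = orders, rGrid = rGrid, protocol = p)

  # only n = 0: theta-uniform image equal to the profile
  fn <- matrix(0 + 0i, M, J)
  fn[which(orders == 0), ] <- 2:6
  pol <- assemblePolar(mk(fn), padFactor = 2L)
  expect_equal(dim(pol@f), c(J, 16L, 1L))
  for (t in 1:16) expect_equal(pol@f[, t, 1], as.complex(2:6))

  # only n = 2: i^2 = -1 sign flip of that harmonic
  fn <- matrix(0 + 0i, M, J)
  fn[which(orders == 2), ] <- 1
  pol <- assemblePolar(mk(fn), padFactor = 1L)
  expect_equal(pol@f[1, , 1], -exp(2i * (0:7) * 2 * pi / 8), tolerance = 1e-12)

  # random profiles vs direct sum, pad 1
  set.seed(4)
  fn <- matrix(complex(real = rnorm(M * J), imaginary = rnorm(M * J)), M, J)
  pol <- assemblePolar(mk(fn), padFactor = 1L)
  ip <- c(1 + 0i, 1i, -1 + 0i, -1i)[(orders %% 4) + 1]
  theta <- (0:7) * 2 * pi / 8
  oracle <- vapply(seq_len(J), function(j)
    vapply(theta, function(th) sum(ip * fn[, j] * exp(1i * orders * th)),
           complex(1)), complex(8))
  expect_lt(max(abs(pol@f[, , 1] - t(oracle))), 1e-12)

  expect_error(assemblePolar(mk(fn), padFactor = 0L), "padFactor")
})

test_that("the full chain equals the direct conjugate-phase quadrature oracle", {
  # 32 spokes -> M = 64; r grid restricted so 2 pi rho_max r_max <= M/4
  p <- scanProtocol(16, 16, nSpokes = 32, radialOversampling = 1L)
  src <- data.frame(x = c(1.2, -2.0), y = c(0.5, 1.4), amplitude = c(1, 0.6))
  ks <- pointSourceKSpace(src, p)
  co <- reorganizeCenterOut(ks)
  rGrid <- (0:5) * pixelSize(p)
  expect_lte(2 * pi * max(co@rhoK) * max(rGrid), dim(co@F)[2] / 4)

  pol <- pftReconstruct(ks, padFactor = 1L, rGrid = rGrid)
  w <- hankelWeights(co@rhoK)
  M <- dim(co@F)[2]
  oracle <- matrix(0 + 0i, length(rGrid), M)
  for (jj in seq_along(rGrid)) for (tt in seq_len(M)) {
    th <- (tt - 1) * 2 * pi / M
    s <- 0 + 0i
    for (m in seq_len(M))
      s <- s + sum(co@F[1, m, ] * w *
                     exp(2i * pi * co@rhoK * rGrid[jj] * cos(co@phiM[m] - th)))
    oracle[jj, tt] <- s * 2 * pi / M
  }
  expect_lt(max(abs(pol@f[, , 1] - oracle)) / max(abs(oracle)), 1e-6)
})

test_that("the chain is linear and rotation-equivariant", {
  p <- tinyProtocol(nSpokes = 8)
  ksA <- pointSourceKSpace(data.frame(x = 1.1, y = -0.7), p)
  ksB <- diskPhantomKSpace(data.frame(x = 0.5, y = 0.2, radius = 2), p)
  ksSum <- ksA
  ksSum@samples <- 2 * ksA@samples - 0.7i * ksB@samples
  fA <- polarArray(pftReconstruct(ksA, padFactor = 2L))
  fB <- polarArray(pftReconstruct(ksB, padFactor = 2L))
  fS <- polarArray(pftReconstruct(ksSum, padFactor = 2L))
  expect_lt(max(abs(fS - (2 * fA - 0.7i * fB))), 1e-10 * max(abs(fS)))

  # rotating the trajectory by q * 2 pi / M shifts theta by q * padFactor bins
  q <- 3L; pad <- 2L
  M <- 2L * nSpokes(p)
  ks2 <- radialKSpace(ksA@samples, p,
                      anglesRad = (buildTrajectory(p) + q * 2 * pi / M) %% (2 * pi),
                      readoutK = ksA@readoutK)
  f1 <- polarArray(pftReconstruct(ksA, padFactor = pad))[, , 1]
  f2 <- polarArray(pftReconstruct(ks2, padFactor = pad))[, , 1]
  shift <- q * pad
  f1s <- f1[, ((seq_len(ncol(f1)) - 1 - shift) %% ncol(f1)) + 1]
  expect_lt(max(abs(f2 - f1s)) / max(abs(f1)), 1e-9)
})

test_that("a centered point source peaks at r = 0 with a pixel-wide main lobe", {
  p <- smallProtocol(nSpokes = 101)   # at the azimuthal Nyquist for base 64
  ks <- pointSourceKSpace(data.frame(x = 0, y = 0), p)
  pol <- pftReconstruct(ks)
  mag <- Mod(pol@f[, , 1])
  expect_equal(which.max(mag[, 1]), 1)          # maximal at r = 0
  radial <- mag[, 1] / max(mag)
  # half-maximum falls between the first and second radial sample:
  # main-lobe half-width about one pixel
  expect_gt(radial[1], 0.5)
  expect_lt(radial[3], 0.5)
})

test_that("multi-coil data reconstruct per coil with optional SoS combine", {
  p <- scanProtocol(16, 16, nSpokes = 8, radialOversampling = 1L, nCoils = 2L)
  ks <- pointSourceKSpace(data.frame(x = 1, y = 0), p)
  ks@samples[2, , ] <- 0.5 * ks@samples[2, , ]
  pol <- pftReconstruct(ks, padFactor = 1L)
  expect_equal(dim(pol@f)[3], 2L)
  expect_equal(pol@f[, , 2], 0.5 * pol@f[, , 1], tolerance = 1e-12)
  sos <- pftReconstruct(ks, padFactor = 1L, combine = "sos")
  expect_equal(dim(sos@f)[3], 1L)
  expect_equal(Re(sos@f[, , 1]),
               sqrt(abs(pol@f[, , 1])^2 + abs(pol@f[, , 2])^2), tolerance = 1e-12)
})
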