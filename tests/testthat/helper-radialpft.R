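# shared fixtures: scaled-down protocols and a pft -> cartesian convenience
smallProtocol <- function(nSpokes = 63, base = 64, fov = 57.6, os = 2L)
  scanProtocol(fovMm = fov, baseResolution = base, nSpokes = nSpokes,
               radialOversampling = os)

tinyProtocol <- function(nSpokes = 8, base = 16, fov = 16)
  scanProtocol(fovMm = fov, baseResolution = base, nSpokes = nSpokes,
               radialOversampling = 1L)

pftCart <- function(ks, padFactor = 4L) {
  cropSquare(polarToCartesian(pftReconstruct(ks, padFactor = padFactor)),
             ks@protocol@fovMm)
}

centeredDisk <- data.frame(x = 0, y = 0, radius = 20, amplitude = 1)
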