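# HDF5 k-space container and simple image export.

#' Read and write the HDF5 k-space container
#'
#' The container stores `/kspace_real` and `/kspace_imag` (coil x spoke x
#' readout), `/angles_rad`, `/readout_k`, and the protocol fields as root
#' attributes (`fov_mm`, `base_resolution`, `radial_oversampling`,
#' `n_spokes`, `scheme`, `tr_ms`, `n_coils`).
#'
#' @param ks a [RadialKSpace-class]
#' @param path file path (`.h5`)
#' @return `writeKSpace()` returns `path` invisibly; `readKSpace()` a
#'   [RadialKSpace-class]
#' @export
writeKSpace <- function(ks, path) {
  stopifnot(is(ks, "RadialKSpace"))
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("the rhdf5 package is required for HDF5 container i/o")
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(Re(ks@samples), path, "kspace_real")
  rhdf5::h5write(Im(ks@samples), path, "kspace_imag")
  rhdf5::h5write(ks@anglesRad, path, "angles_rad")
  rhdf5::h5write(ks@readoutK, path, "readout_k")
  p <- ks@protocol
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid))
  rhdf5::h5writeAttribute(p@fovMm, fid, "fov_mm")
  rhdf5::h5writeAttribute(p@baseResolution, fid, "base_resolution")
  rhdf5::h5writeAttribute(p@radialOversampling, fid, "radial_oversampling")
  rhdf5::h5writeAttribute(p@nSpokes, fid, "n_spokes")
  rhdf5::h5writeAttribute(p@scheme, fid, "scheme")
  rhdf5::h5writeAttribute(p@trMs, fid, "tr_ms")
  rhdf5::h5writeAttribute(p@nCoils, fid, "n_coils")
  invisible(path)
}

#' @rdname writeKSpace
#' @export
readKSpace <- function(path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("the rhdf5 package is required for HDF5 container i/o")
  re <- rhdf5::h5read(path, "kspace_real")
  im <- rhdf5::h5read(path, "kspace_imag")
  ang <- as.numeric(rhdf5::h5read(path, "angles_rad"))
  rk <- as.numeric(rhdf5::h5read(path, "readout_k"))
  at <- rhdf5::h5readAttributes(path, "/")
  p <- scanProtocol(fovMm = as.numeric(at$fov_mm),
                    baseResolution = as.integer(at$base_resolution),
                    nSpokes = as.integer(at$n_spokes),
                    scheme = as.character(at$scheme),
                    radialOversampling = as.integer(at$radial_oversampling),
                    trMs = as.numeric(at$tr_ms),
                    nCoils = as.integer(at$n_coils))
  radialKSpace(array(complex(real = re, imaginary = im), dim(re)), p,
               anglesRad = ang, readoutK = rk)
}

#' Write a magnitude PNG preview of an image
#'
#' Magnitude, windowed to `[0, quantile]`, written with the `png` package.
#'
#' @param img a [CartesianImage-class] or numeric matrix
#' @param path output path
#' @param windowQuantile upper display window quantile (default 0.999)
#' @return `path`, invisibly
#' @export
writeImagePNG <- function(img, path, windowQuantile = 0.999) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the png package is required for PNG export")
  m <- if (is(img, "CartesianImage")) {
    x <- Mod(img@pixels)
    if (length(dim(x)) == 3) x[, , 1] else x
  } else as.matrix(Mod(img))
  hi <- stats::quantile(m, windowQuantile)
  if (hi <= 0) hi <- 1
  m <- pmin(m / hi, 1)
  # image x right, y up -> raster rows top-down
  png::writePNG(t(m)[rev(seq_len(ncol(m))), ], path)
  invisible(path)
}
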