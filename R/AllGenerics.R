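# Generics for accessors shared across the container classes.

#' @rdname scanProtocol
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname scanProtocol
#' @export
setGeneric("kMax", function(x) standardGeneric("kMax"))

#' @rdname scanProtocol
#' @export
setGeneric("deltaK", function(x) standardGeneric("deltaK"))

#' @rdname scanProtocol
#' @export
setGeneric("nSpokes", function(x) standardGeneric("nSpokes"))

#' @rdname scanProtocol
#' @export
setGeneric("nCoils", function(x) standardGeneric("nCoils"))

#' @rdname scanProtocol
#' @export
setGeneric("protocol", function(x) standardGeneric("protocol"))

#' Extract the data payload of a container
#'
#' `samples()` returns the complex sample array of a [RadialKSpace-class],
#' `pixels()` the pixel array of a [CartesianImage-class], and
#' `polarArray()` the `[radius, angle, coil]` array of a [PolarImage-class].
#'
#' @param x the container object
#' @return the underlying array
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname samples
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname samples
#' @export
setGeneric("polarArray", function(x) standardGeneric("polarArray"))
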