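# R surface of the recursive Bessel evaluator and the per-protocol Hankel
# kernel cache.

#' Integer-order Bessel functions of the first kind, recursive evaluation
#'
#' Evaluates \eqn{J_n(x)} with the two-stage scheme used for the Hankel
#' kernel: orders 0 and 1 from series/asymptotic approximations, higher
#' orders by three-term recurrence - upward from \eqn{J_0, J_1} while the
#' argument dominates the order (`x > n`, the stable direction), otherwise
#' downward (Miller) recurrence from a starting order of about
#' \eqn{n + 2\lceil\sqrt{40 n}\rceil}, normalized with the even-order sum
#' identity \eqn{J_0(x) + 2\sum_{k\ge1} J_{2k}(x) = 1}.
#'
#' Negative orders are rejected; resolve them at call sites through
#' \eqn{J_{-n}(x) = (-1)^n J_n(x)}.
#'
#' @param n nonnegative integer order (scalar)
#' @param x nonnegative finite argument(s)
#' @return `J_n(x)`, vectorized over `x`
#' @examples
#' besselJn(0, 0)        # 1
#' besselJn(5, 2)        # matches besselJ(2, 5)
#' @export
besselJn <- function(n, x) {
  if (length(n) != 1 || n < 0 || n != round(n))
    stop("n must be a single nonnegative integer")
  if (any(!is.finite(x)) || any(x < 0))
    stop("x must be finite and nonnegative")
  .besselJnCpp(as.integer(n), as.numeric(x))
}

# per-session kernel cache; keys are grid fingerprints, values BesselTable
.kernelCache <- new.env(parent = emptyenv())
assign(".buildCount", 0L, envir = .kernelCache)

kernelCacheKey <- function(nMax, rhoGrid, rGrid) {
  paste(nMax,
        length(rhoGrid), format(sum(rhoGrid) + sum(rhoGrid^2), digits = 17),
        format(range(rhoGrid), digits = 17)[2],
        length(rGrid), format(sum(rGrid) + sum(rGrid^2), digits = 17),
        format(range(rGrid), digits = 17)[2],
        sep = "|")
}

#' Build (or fetch) the cached Hankel kernel table
#'
#' Computes \eqn{J_n(2\pi \rho_k r_j)} for all orders `0..nMax` over the given
#' grids.  The table is the computational bottleneck of the polar transform,
#' so it is built once per protocol/grid combination and served from an
#' in-session cache afterwards; [kernelBuildCount()] exposes how many tables
#' have actually been computed, making cache hits observable.  Rebuilding
#' with identical inputs returns bit-identical values.
#'
#' @param protocol a [ScanProtocol-class]; used to validate that the grids
#'   match the protocol geometry (may be `NULL` to skip the check)
#' @param rhoGrid nonnegative k-space radii (1/mm)
#' @param rGrid nonnegative image radii (mm)
#' @param nMax largest order to tabulate (>= 0)
#' @param cache serve repeated requests from the in-session cache?
#' @return a [BesselTable-class]
#' @export
buildKernelTable <- function(protocol, rhoGrid, rGrid, nMax, cache = TRUE) {
  if (any(!is.finite(rhoGrid)) || any(rhoGrid < 0) ||
      any(!is.finite(rGrid)) || any(rGrid < 0))
    stop("grids must be finite and nonnegative")
  if (nMax < 0) stop("nMax must be >= 0")
  if (!is.null(protocol)) {
    validObject(protocol)
    if (nMax < protocol@nSpokes)
      stop("nMax smaller than the protocol's order range (nSpokes)")
    if (max(rhoGrid) > kMaxOf(protocol) + deltaKOf(protocol))
      stop("rhoGrid extends beyond the protocol's k_max")
  }
  key <- kernelCacheKey(nMax, rhoGrid, rGrid)
  if (cache && !is.null(tab <- .kernelCache[[key]])) return(tab)
  vals <- .besselTableCpp(as.integer(nMax), as.numeric(rhoGrid), as.numeric(rGrid))
  tab <- new("BesselTable", values = vals, rhoGrid = as.numeric(rhoGrid),
             rGrid = as.numeric(rGrid), nMax = as.integer(nMax), cacheKey = key)
  if (cache) {
    .kernelCache[[key]] <- tab
    assign(".buildCount", get(".buildCount", envir = .kernelCache) + 1L,
           envir = .kernelCache)
  }
  tab
}

#' @describeIn buildKernelTable number of kernel tables computed (cache
#'   misses) in this session
#' @export
kernelBuildCount <- function() get(".buildCount", envir = .kernelCache)

#' @describeIn buildKernelTable drop all cached kernel tables
#' @export
clearKernelCache <- function() {
  rm(list = setdiff(ls(.kernelCache, all.names = TRUE), ".buildCount"),
     envir = .kernelCache)
  invisible(NULL)
}

#' Extract one order's kernel matrix
#'
#' Returns the `rho x r` matrix \eqn{J_n(2\pi \rho_k r_j)} for a (possibly
#' negative) order, applying \eqn{J_{-n} = (-1)^n J_n}.
#'
#' @param table a [BesselTable-class]
#' @param n integer order with `|n| <= nMax`
#' @return numeric matrix `length(rhoGrid) x length(rGrid)`
#' @export
kernelOrder <- function(table, n) {
  stopifnot(is(table, "BesselTable"))
  a <- abs(as.integer(n))
  if (a > table@nMax) stop("order outside table range")
  m <- table@values[, , a + 1L]
  if (n < 0 && a %% 2 == 1) -m else m
}

setMethod("show", "BesselTable", function(object) {
  d <- dim(object@values)
  cat(sprintf("BesselTable: orders 0..%d on %d rho x %d r grid (max argument %.4g)\n",
              object@nMax, d[1], d[2],
              2 * pi * max(object@rhoGrid) * max(object@rGrid)))
})
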