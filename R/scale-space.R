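# Sampled 1D Gaussian-derivative kernel of a given order at sigma (voxel
# units). Derivatives use the probabilists' Hermite recurrence
#   d^n/dx^n G(x; s) = (-1)^n s^-n He_n(x/s) G(x; s).
# Order 0 kernels are normalized to unit sum; orders >= 1 get their mean
# removed so that constants are annihilated exactly on the discrete grid.
gaussianKernel1d <- function(sigma, order = 0L, truncation = 4) {
  stopifnot(sigma > 0, order >= 0L)
  r <- max(1L, as.integer(ceiling(truncation * sigma)))
  x <- seq.int(-r, r)
  u <- x / sigma
  g <- exp(-u^2 / 2)
  g <- g / sum(g)
  if (order == 0L) return(g)
  he0 <- rep(1, length(u))
  he1 <- u
  if (order == 1L) {
    he <- he1
  } else {
    for (n in seq_len(order - 1L)) {
      he2 <- u * he1 - n * he0
      he0 <- he1
      he1 <- he2
    }
    he <- he1
  }
  k <- (-1)^order * he * g / sigma^order
  k - mean(k)
}

# Separable convolution of a 3D array with per-axis 1D kernels (reflected
# boundaries, shape-preserving).
convolveSeparable <- function(arr, kx, ky, kz) {
  d <- dim(arr)
  out <- .convAxis(as.double(arr), d, kx, 0L)
  out <- .convAxis(out, d, ky, 1L)
  out <- .convAxis(out, d, kz, 2L)
  array(out, d)
}

#' Gaussian smoothing of a volume
#'
#' Convolves a volume with a normalized Gaussian kernel of standard deviation
#' \code{probe@sigma}, given in physical units and converted per axis to voxel
#' units through the volume spacing. The convolution is separable, boundaries
#' are handled by symmetric reflection, and the kernel is truncated at
#' \code{probe@truncation} sigma per axis.
#'
#' @param vol a [Volume-class].
#' @param probe a [GaussianProbe-class] (or a single positive sigma, in which
#'   case a default probe is built).
#' @return a smoothed [Volume-class] of the same shape and geometry.
#' @examples
#' v <- Volume(array(0, c(17, 17, 17)))
#' v@data[9, 9, 9] <- 1
#' s <- gaussianSmooth(v, GaussianProbe(2))
#' s@data[9, 9, 9]            # ~ (2 * pi * 4)^(-3/2)
#' @export
setGeneric("gaussianSmooth",
           function(vol, probe) standardGeneric("gaussianSmooth"))

#' @rdname gaussianSmooth
#' @export
setMethod("gaussianSmooth", signature("Volume", "GaussianProbe"),
  function(vol, probe) {
    gaussianDerivative(vol, probe, c(0L, 0L, 0L))
  })

#' @rdname gaussianSmooth
#' @export
setMethod("gaussianSmooth", signature("Volume", "numeric"),
  function(vol, probe) gaussianSmooth(vol, GaussianProbe(probe)))

#' Gamma-normalized Gaussian spatial derivative of a volume
#'
#' Convolves a volume with the order-\code{(m, n, p)} Gaussian derivative
#' kernel at scale \code{probe@sigma} and multiplies the result by the
#' scale-normalization factor \eqn{\sigma^{(m+n+p)\gamma}}, which makes
#' derivative responses comparable across scales: without it, responses decay
#' with increasing sigma and scale selection is biased toward fine scales.
#' Orders \code{c(0, 0, 0)} reduce exactly to [gaussianSmooth()].
#'
#' @param vol a [Volume-class].
#' @param probe a [GaussianProbe-class]; sigma in physical units, converted
#'   per axis to voxel units via the volume spacing.
#' @param orders integer(3) derivative multi-index (m, n, p) along (x, y, z).
#' @return a [Volume-class] holding the normalized derivative response.
#' @export
setGeneric("gaussianDerivative",
           function(vol, probe, orders) standardGeneric("gaussianDerivative"))

#' @rdname gaussianDerivative
#' @export
setMethod("gaussianDerivative",
  signature("Volume", "GaussianProbe", "numeric"),
  function(vol, probe, orders) {
    if (length(orders) != 3L || any(orders < 0) || any(orders != round(orders)))
      stop("'orders' must be three non-negative integers (m, n, p)")
    orders <- as.integer(orders)
    sigVox <- probe@sigma / vol@spacing
    kx <- gaussianKernel1d(sigVox[1], orders[1], probe@truncation)
    ky <- gaussianKernel1d(sigVox[2], orders[2], probe@truncation)
    kz <- gaussianKernel1d(sigVox[3], orders[3], probe@truncation)
    # physical-unit derivatives: divide by spacing^order per axis
    out <- convolveSeparable(vol@data, kx, ky, kz) /
      prod(vol@spacing^orders)
    norm <- probe@sigma^(sum(orders) * probe@gamma)
    new("Volume", data = out * norm, spacing = vol@spacing,
        origin = vol@origin)
  })
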