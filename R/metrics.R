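#' Mean squared error between two volumes
#'
#' \eqn{MSE = \frac{1}{N}\sum_i (x_i - y_i)^2} over all N voxels. The
#' volumes must have identical shapes.
#'
#' @param x,y [Volume-class] objects or 3D arrays of the same shape.
#' @return a single non-negative number (intensity^2 units).
#' @export
setGeneric("mse", function(x, y) standardGeneric("mse"))

#' @rdname mse
#' @export
setMethod("mse", signature("Volume", "Volume"),
          function(x, y) mse(x@data, y@data))

#' @rdname mse
#' @export
setMethod("mse", signature("array", "array"), function(x, y) {
  if (!identical(dim(x), dim(y)))
    stop("volumes must have identical shapes: ",
         paste(dim(x), collapse = "x"), " vs ", paste(dim(y), collapse = "x"))
  mean((x - y)^2)
})

#' Peak signal-to-noise ratio
#'
#' \eqn{PSNR = 10 \log_{10}(L^2 / MSE)} in decibels, where L is the dynamic
#' range of allowable intensities. Lower MSE means higher PSNR means better
#' agreement with the reference. A perfect match (MSE = 0) is reported as
#' \code{Inf} rather than raising a numeric error.
#'
#' @param mseValue mean squared error, >= 0.
#' @param L dynamic range (default 1: filter outputs live in [0, 1]).
#' @return PSNR in dB; \code{Inf} when \code{mseValue} is 0.
#' @examples
#' psnr(0.00203)   # 26.93 dB
#' psnr(0.00214)   # 26.70 dB
#' @export
psnr <- function(mseValue, L = 1) {
  if (L <= 0) stop("dynamic range 'L' must be positive")
  if (mseValue < 0) stop("'mseValue' must be >= 0")
  if (mseValue == 0) return(Inf)
  10 * log10(L^2 / mseValue)
}

#' Objective quality report for a processed volume
#'
#' Computes MSE and PSNR of \code{y} against the reference \code{x} and
#' wraps them in a [QualityReport-class], printable as a one-line log entry
#' and convertible to a machine-readable key/value list via
#' \code{as.list()}.
#'
#' @param x reference ("ideal") [Volume-class] or array.
#' @param y processed ("degraded") [Volume-class] or array.
#' @param L dynamic range for PSNR (default 1).
#' @return a [QualityReport-class].
#' @export
qualityReport <- function(x, y, L = 1) {
  if (is(x, "Volume")) x <- x@data
  if (is(y, "Volume")) y <- y@data
  m <- mse(x, y)
  new("QualityReport", mse = m, psnr = psnr(m, L), L = L,
      n = as.integer(length(x)))
}

#' @describeIn qualityReport machine-readable key/value form.
#' @export
as.list.QualityReport <- function(x, ...) {
  list(mse = x@mse, psnr = x@psnr, L = x@L, n = x@n)
}
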