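#' Construct a Volume
#'
#' @param data a 3D numeric array (a plain vector or matrix is rejected).
#' @param spacing per-axis physical voxel size; recycled from length 1.
#' @param origin physical coordinate of voxel (1, 1, 1).
#' @return a [Volume-class] object.
#' @examples
#' v <- Volume(array(rnorm(8^3), c(8, 8, 8)), spacing = 0.018)
#' dim(v)
#' @export
Volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (is.null(dim(data)) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array")
  if (length(data) == 0L) stop("'data' must be non-empty")
  if (any(!is.finite(data)))
    stop("volume intensities must be finite (no NA/NaN/Inf)")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(origin) == 1L) origin <- rep(origin, 3L)
  storage.mode(data) <- "double"
  new("Volume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a GaussianProbe
#'
#' @param sigma probe standard deviation in physical length units.
#' @param gamma normalization exponent (default 1: plain sigma^2 scaling of
#'   second derivatives). 0.75, 1.25 and 1.5 are common alternatives for
#'   ridge detection.
#' @param truncation kernel half-width in units of sigma (default 4).
#' @return a [GaussianProbe-class] object.
#' @export
GaussianProbe <- function(sigma, gamma = 1, truncation = 4) {
  if (length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("'sigma' must be a single positive number")
  new("GaussianProbe", sigma = as.numeric(sigma), gamma = as.numeric(gamma),
      truncation = as.numeric(truncation))
}

#' Construct an ObjectnessParams
#'
#' @param a,b plate/line and blob sensitivities; the conventional tubular
#'   setting is 0.5 for both.
#' @param c noise-suppression scale. Leave \code{NA} (default) for automatic
#'   selection; supplying a value switches to manual mode.
#' @param polarity \code{"bright"} or \code{"dark"} objects.
#' @param measure \code{"frangi"} or \code{"sato"}.
#' @param alpha1,alpha2 Sato sensitivities, \code{alpha1 < alpha2}.
#' @param autoC derive c from the image; defaults to \code{is.na(c)}.
#' @param autoCDivisor divisor of the maximum Laplacian (default 10).
#' @return an [ObjectnessParams-class] object.
#' @export
ObjectnessParams <- function(a = 0.5, b = 0.5, c = NA_real_,
                             polarity = c("bright", "dark"),
                             measure = c("frangi", "sato"),
                             alpha1 = 0.5, alpha2 = 2,
                             autoC = is.na(c), autoCDivisor = 10) {
  polarity <- match.arg(polarity)
  measure <- match.arg(measure)
  new("ObjectnessParams", a = as.numeric(a), b = as.numeric(b),
      c = as.numeric(c), polarity = polarity, measure = measure,
      alpha1 = as.numeric(alpha1), alpha2 = as.numeric(alpha2),
      autoC = isTRUE(autoC), autoCDivisor = as.numeric(autoCDivisor))
}

#' Construct a ScaleSpec
#'
#' @param sigmaMin,sigmaMax scale bounds in physical length units.
#' @param nSteps number of scales.
#' @param stepFunction \code{"logarithmic"} (geometric in sigma, emphasizing
#'   finer scales) or \code{"linear"}.
#' @param gamma normalization exponent shared by all probes.
#' @return a [ScaleSpec-class] object.
#' @examples
#' makeScales(ScaleSpec(1, 30, 20, "logarithmic"))
#' @export
ScaleSpec <- function(sigmaMin = 1, sigmaMax = 30, nSteps = 20L,
                      stepFunction = c("logarithmic", "linear"), gamma = 1) {
  stepFunction <- match.arg(stepFunction)
  if (sigmaMin > sigmaMax)
    stop("'sigmaMin' must not exceed 'sigmaMax'")
  if (nSteps < 1)
    stop("'nSteps' must be >= 1")
  new("ScaleSpec", sigmaMin = as.numeric(sigmaMin),
      sigmaMax = as.numeric(sigmaMax), nSteps = as.integer(nSteps),
      stepFunction = stepFunction, gamma = as.numeric(gamma))
}

# ---- accessors -------------------------------------------------------------

#' Accessors for Volume and ResponseVolume objects
#'
#' \code{voxelData} returns the raw 3D array; \code{spacing} and
#' \code{origin} return the physical geometry; \code{dim} the grid shape.
#' On a [ResponseVolume-class], \code{responseVolume} and \code{bestScaleVolume}
#' extract the two result grids and \code{noiseCutoff} the c parameter used.
#'
#' @param object,x a [Volume-class] or [ResponseVolume-class].
#' @return the requested component.
#' @name volume-accessors
#' @aliases voxelData spacing origin
NULL

#' @rdname volume-accessors
#' @export
setGeneric("voxelData", function(object) standardGeneric("voxelData"))
#' @rdname volume-accessors
#' @export
setMethod("voxelData", "Volume", function(object) object@data)
#' @rdname volume-accessors
#' @export
setGeneric("spacing", function(object) standardGeneric("spacing"))
#' @rdname volume-accessors
#' @export
setMethod("spacing", "Volume", function(object) object@spacing)
#' @rdname volume-accessors
#' @export
setGeneric("origin", function(object) standardGeneric("origin"))
#' @rdname volume-accessors
#' @export
setMethod("origin", "Volume", function(object) object@origin)
#' @rdname volume-accessors
#' @export
setMethod("dim", "Volume", function(x) dim(x@data))

#' @rdname volume-accessors
#' @export
setGeneric("responseVolume", function(object) standardGeneric("responseVolume"))
#' @rdname volume-accessors
#' @export
setMethod("responseVolume", "ResponseVolume", function(object) object@response)
#' @rdname volume-accessors
#' @export
setGeneric("bestScaleVolume",
           function(object) standardGeneric("bestScaleVolume"))
#' @rdname volume-accessors
#' @export
setMethod("bestScaleVolume", "ResponseVolume",
          function(object) object@bestScale)
#' @rdname volume-accessors
#' @export
setGeneric("noiseCutoff", function(object) standardGeneric("noiseCutoff"))
#' @rdname volume-accessors
#' @export
setMethod("noiseCutoff", "ResponseVolume", function(object) object@cValue)

# ---- show methods ----------------------------------------------------------

setMethod("show", "Volume", function(object) {
  d <- dim(object@data)
  cat(sprintf("Volume: %d x %d x %d voxels, spacing (%s), origin (%s)\n",
              d[1], d[2], d[3],
              paste(signif(object@spacing, 4), collapse = ", "),
              paste(signif(object@origin, 4), collapse = ", ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "GaussianProbe", function(object) {
  cat(sprintf("GaussianProbe: sigma = %g (t = %g), gamma = %g, truncation = %g sigma\n",
              object@sigma, object@sigma^2, object@gamma, object@truncation))
})

setMethod("show", "HessianField", function(object) {
  d <- dim(object@ixx)
  cat(sprintf("HessianField at sigma = %g: %d x %d x %d voxels, 6 components\n",
              object@sigma, d[1], d[2], d[3]))
})

setMethod("show", "ObjectnessParams", function(object) {
  cat(sprintf("ObjectnessParams: measure = %s, polarity = %s, a = %g, b = %g\n",
              object@measure, object@polarity, object@a, object@b))
  if (object@autoC) {
    cat(sprintf("  c: automatic (max Laplacian / %g)\n", object@autoCDivisor))
  } else {
    cat(sprintf("  c: manual = %g\n", object@c))
  }
})

setMethod("show", "ScaleSpec", function(object) {
  cat(sprintf("ScaleSpec: %d %s scales in [%g, %g], gamma = %g\n",
              object@nSteps, object@stepFunction, object@sigmaMin,
              object@sigmaMax, object@gamma))
})

setMethod("show", "ResponseVolume", function(object) {
  d <- dim(object@response@data)
  cat(sprintf("ResponseVolume: %d x %d x %d voxels, %d scales in [%g, %g]\n",
              d[1], d[2], d[3], length(object@scales), min(object@scales),
              max(object@scales)))
  cat(sprintf("  c = %g (%s), response range [%.4g, %.4g]\n",
              object@cValue, object@cMode, min(object@response@data),
              max(object@response@data)))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %s grid, %d tube(s), %d distractor(s), noise sd = %g\n",
              paste(object@shape, collapse = " x "), length(object@tubes),
              length(object@distractors),
              if (is.null(object@noise$sd)) 0 else object@noise$sd))
})

setMethod("show", "QualityReport", function(object) {
  cat(format(object), "\n")
})

#' @describeIn qualityReport one-line log format of a report.
#' @param x a QualityReport.
#' @param ... ignored.
#' @export
format.QualityReport <- function(x, ...) {
  sprintf("QualityReport: MSE = %.6g, PSNR = %s dB (L = %g, n = %d)",
          x@mse, if (is.infinite(x@psnr)) "Inf (perfect match)"
                 else sprintf("%.4f", x@psnr), x@L, x@n)
}
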