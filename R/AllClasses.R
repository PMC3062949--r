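#' @useDynLib tubularity, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Volume: a 3D scalar intensity grid with physical voxel geometry
#'
#' The central data container of the package. Holds a 3D numeric array of
#' intensities together with the per-axis physical voxel spacing and the
#' physical coordinate of the first voxel. Array indices follow R's
#' column-major, 1-based convention \code{[x, y, z]}; the physical position
#' of voxel \code{(i, j, k)} is \code{origin + (c(i, j, k) - 1) * spacing}.
#'
#' @slot data 3D numeric array of intensities (arbitrary units).
#' @slot spacing numeric(3), physical size of a voxel per axis; all > 0.
#' @slot origin numeric(3), physical coordinate of voxel (1, 1, 1).
#'
#' @seealso [Volume()] for the user-facing constructor.
#' @exportClass Volume
setClass("Volume",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  prototype(data = array(0, c(1, 1, 1)), spacing = c(1, 1, 1),
            origin = c(0, 0, 0)))

setValidity("Volume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  if (any(dim(object@data) < 1L))
    msg <- c(msg, "all three dimensions must be >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three finite positive numbers")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be three finite numbers")
  if (length(msg)) msg else TRUE
})

#' GaussianProbe: a Gaussian observation kernel in scale space
#'
#' Describes one Gaussian probe: its standard deviation \eqn{\sigma} in
#' physical length units (the scale variance is \eqn{t = \sigma^2}), the
#' normalization exponent \eqn{\gamma} applied as \eqn{\sigma^{o\gamma}} to an
#' order-\eqn{o} derivative so responses are comparable across scales, and the
#' kernel truncation radius in units of \eqn{\sigma}.
#'
#' @slot sigma positive number, probe standard deviation (physical units).
#' @slot gamma non-negative normalization exponent (dimensionless).
#' @slot truncation kernel half-width in units of sigma; >= 3.
#'
#' @exportClass GaussianProbe
setClass("GaussianProbe",
  representation(sigma = "numeric", gamma = "numeric", truncation = "numeric"),
  prototype(sigma = 1, gamma = 1, truncation = 4))

setValidity("GaussianProbe", function(object) {
  msg <- character()
  if (length(object@sigma) != 1L || !is.finite(object@sigma) ||
      object@sigma <= 0)
    msg <- c(msg, "sigma must be a single positive number")
  if (length(object@gamma) != 1L || !is.finite(object@gamma) ||
      object@gamma < 0)
    msg <- c(msg, "gamma must be a single non-negative number")
  if (length(object@truncation) != 1L || !is.finite(object@truncation) ||
      object@truncation < 3)
    msg <- c(msg, "truncation must be >= 3 (in units of sigma)")
  if (length(msg)) msg else TRUE
})

#' HessianField: the six unique second-derivative components at one scale
#'
#' Per-voxel symmetric Hessian of a volume observed at scale \code{sigma},
#' built from gamma-normalized Gaussian second derivatives. Only the six
#' unique components are stored; the mixed components are shared across the
#' symmetric positions.
#'
#' @slot ixx,iyy,izz,ixy,ixz,iyz 3D arrays, the unique Hessian components
#'   (intensity / length^2, scaled by sigma^(2*gamma)).
#' @slot sigma the probe scale that produced the field (physical units).
#' @slot spacing voxel spacing inherited from the source volume.
#'
#' @exportClass HessianField
setClass("HessianField",
  representation(ixx = "array", iyy = "array", izz = "array",
                 ixy = "array", ixz = "array", iyz = "array",
                 sigma = "numeric", spacing = "numeric"))

setValidity("HessianField", function(object) {
  d <- dim(object@ixx)
  comps <- list(object@iyy, object@izz, object@ixy, object@ixz, object@iyz)
  if (!all(vapply(comps, function(x) identical(dim(x), d), logical(1))))
    return("all six components must share the same dimensions")
  if (length(object@sigma) != 1L || object@sigma <= 0)
    return("sigma must be a single positive number")
  TRUE
})

#' ObjectnessParams: sensitivity parameters of the objectness measures
#'
#' Collects the tuning parameters of the Frangi vesselness and Sato line
#' measures. For tubular objects the plate/line and blob sensitivities are
#' conventionally fixed at \code{a = 0.5, b = 0.5}; the noise-suppression
#' scale \code{c} is either supplied manually or derived automatically from
#' the image Laplacian (see [autoC()]).
#'
#' @slot a plate-vs-line sensitivity (dimensionless, > 0).
#' @slot b blob sensitivity (dimensionless, > 0).
#' @slot c noise-suppression scale in Hessian-component units; \code{NA}
#'   when \code{autoC} is on and the value has not been derived yet.
#' @slot polarity \code{"bright"} (bright tubes on dark background) or
#'   \code{"dark"}.
#' @slot measure \code{"frangi"} or \code{"sato"}.
#' @slot alpha1,alpha2 Sato sensitivities, \code{alpha1 < alpha2}.
#' @slot autoC logical: derive \code{c} from the image automatically.
#' @slot autoCDivisor positive divisor applied to the maximum Laplacian
#'   (default 10, i.e. one tenth).
#'
#' @exportClass ObjectnessParams
setClass("ObjectnessParams",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 polarity = "character", measure = "character",
                 alpha1 = "numeric", alpha2 = "numeric",
                 autoC = "logical", autoCDivisor = "numeric"),
  prototype(a = 0.5, b = 0.5, c = NA_real_, polarity = "bright",
            measure = "frangi", alpha1 = 0.5, alpha2 = 2,
            autoC = TRUE, autoCDivisor = 10))

setValidity("ObjectnessParams", function(object) {
  msg <- character()
  if (object@a <= 0 || object@b <= 0)
    msg <- c(msg, "a and b must be positive")
  if (!is.na(object@c) && object@c <= 0)
    msg <- c(msg, "c must be positive when supplied")
  if (!object@autoC && is.na(object@c))
    msg <- c(msg, "manual mode requires an explicit c > 0")
  if (object@autoC && !is.na(object@c))
    msg <- c(msg, "automatic mode forbids an explicit c")
  if (!object@polarity %in% c("bright", "dark"))
    msg <- c(msg, "polarity must be 'bright' or 'dark'")
  if (!object@measure %in% c("frangi", "sato"))
    msg <- c(msg, "measure must be 'frangi' or 'sato'")
  if (!(object@alpha1 > 0 && object@alpha2 > 0 &&
        object@alpha1 < object@alpha2))
    msg <- c(msg, "need 0 < alpha1 < alpha2")
  if (object@autoCDivisor <= 0)
    msg <- c(msg, "autoCDivisor must be positive")
  if (length(msg)) msg else TRUE
})

#' ScaleSpec: the list of Gaussian probe scales for a multiscale sweep
#'
#' Bounds and stepping rule for the scale sweep. Logarithmic stepping is a
#' geometric progression in sigma, which places more probes at finer scales;
#' linear stepping is arithmetic.
#'
#' @slot sigmaMin,sigmaMax scale bounds (physical length), min <= max.
#' @slot nSteps number of scales (>= 1).
#' @slot stepFunction \code{"logarithmic"} or \code{"linear"}.
#' @slot gamma normalization exponent shared by all probes.
#'
#' @exportClass ScaleSpec
setClass("ScaleSpec",
  representation(sigmaMin = "numeric", sigmaMax = "numeric",
                 nSteps = "integer", stepFunction = "character",
                 gamma = "numeric"),
  prototype(sigmaMin = 1, sigmaMax = 30, nSteps = 20L,
            stepFunction = "logarithmic", gamma = 1))

setValidity("ScaleSpec", function(object) {
  msg <- character()
  if (object@sigmaMin <= 0 || object@sigmaMax <= 0 ||
      object@sigmaMin > object@sigmaMax)
    msg <- c(msg, "need 0 < sigmaMin <= sigmaMax")
  if (object@nSteps < 1L)
    msg <- c(msg, "nSteps must be >= 1")
  if (!object@stepFunction %in% c("logarithmic", "linear"))
    msg <- c(msg, "stepFunction must be 'logarithmic' or 'linear'")
  if (object@gamma < 0)
    msg <- c(msg, "gamma must be non-negative")
  if (length(msg)) msg else TRUE
})

#' ResponseVolume: the per-voxel best tubularity response and its scale
#'
#' Result of a multiscale sweep: for every voxel, the maximum objectness
#' score over the scale list and the first scale achieving it.
#'
#' @slot response [Volume] of scores in [0, 1].
#' @slot bestScale [Volume] of the sigma achieving the per-voxel maximum.
#' @slot scales the sigma list that was swept.
#' @slot cValue the noise-suppression parameter used (derived or manual).
#' @slot cMode \code{"automatic"} or \code{"manual"}.
#'
#' @exportClass ResponseVolume
setClass("ResponseVolume",
  representation(response = "Volume", bestScale = "Volume",
                 scales = "numeric", cValue = "numeric", cMode = "character"))

setValidity("ResponseVolume", function(object) {
  if (!identical(dim(object@response@data), dim(object@bestScale@data)))
    return("response and bestScale must share dimensions")
  TRUE
})

#' PhantomSpec: declarative description of a synthetic test volume
#'
#' A phantom is composed additively from tubes (Gaussian or bar cross-section
#' profiles along a polyline centerline), non-tubular distractors (blobs,
#' plates), a polynomial background, and per-voxel Gaussian noise. The same
#' spec and seed always produce bit-identical output. Specs round-trip
#' through plain-text YAML via [readPhantomSpec()] / [writePhantomSpec()].
#'
#' @slot shape integer(3) grid dimensions.
#' @slot spacing numeric(3) voxel spacing.
#' @slot tubes list of tube descriptions (see [makeTube()]).
#' @slot distractors list of blob/plate descriptions.
#' @slot background polynomial coefficients per axis (see
#'   [makePolynomialBackground()]).
#' @slot noise list with elements \code{mean}, \code{sd}, \code{seed}.
#'
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(shape = "integer", spacing = "numeric", tubes = "list",
                 distractors = "list", background = "list", noise = "list"),
  prototype(shape = c(64L, 64L, 64L), spacing = c(1, 1, 1), tubes = list(),
            distractors = list(), background = list(),
            noise = list(mean = 0, sd = 0, seed = 1L)))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(object@shape < 1L))
    msg <- c(msg, "shape must be three positive integers")
  if (!is.null(object@noise$sd) && object@noise$sd < 0)
    msg <- c(msg, "noise sd must be >= 0")
  for (tb in object@tubes) {
    if (!is.null(tb$amplitude) && tb$amplitude < 0)
      msg <- c(msg, "tube amplitudes must be >= 0")
    if (identical(tb$profile, "gaussian") && !is.null(tb$sigma) &&
        tb$sigma <= 0)
      msg <- c(msg, "gaussian tube sigma must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' QualityReport: MSE and PSNR of a processed volume against a reference
#'
#' @slot mse mean squared error (intensity^2 units).
#' @slot psnr peak signal-to-noise ratio in dB; \code{Inf} for a perfect
#'   match (mse = 0).
#' @slot L dynamic range used for PSNR.
#' @slot n number of voxels compared.
#'
#' @exportClass QualityReport
setClass("QualityReport",
  representation(mse = "numeric", psnr = "numeric", L = "numeric",
                 n = "integer"))

setValidity("QualityReport", function(object) {
  if (object@mse < 0) return("mse must be >= 0")
  if (object@L <= 0) return("dynamic range L must be > 0")
  TRUE
})
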