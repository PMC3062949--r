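#' Hessian of a volume at one scale
#'
#' Computes the six unique components of the per-voxel symmetric Hessian
#' using gamma-normalized Gaussian second derivatives at \code{probe@sigma}.
#' Each mixed component is computed once and shared across its symmetric
#' positions.
#'
#' @param vol a [Volume-class].
#' @param probe a [GaussianProbe-class].
#' @return a [HessianField-class].
#' @export
setGeneric("hessianAtScale",
           function(vol, probe) standardGeneric("hessianAtScale"))

#' @rdname hessianAtScale
#' @export
setMethod("hessianAtScale", signature("Volume", "GaussianProbe"),
  function(vol, probe) {
    d2 <- function(orders) gaussianDerivative(vol, probe, orders)@data
    new("HessianField",
        ixx = d2(c(2, 0, 0)), iyy = d2(c(0, 2, 0)), izz = d2(c(0, 0, 2)),
        ixy = d2(c(1, 1, 0)), ixz = d2(c(1, 0, 1)), iyz = d2(c(0, 1, 1)),
        sigma = probe@sigma, spacing = vol@spacing)
  })

#' Per-voxel eigen-decomposition of a symmetric 3x3 field
#'
#' Diagonalizes the symmetric 3x3 Hessian at every voxel (cyclic Jacobi
#' rotations in compiled code, accurate to machine precision) and returns
#' eigenvalues ordered by ascending magnitude
#' \eqn{|\lambda_1| \le |\lambda_2| \le |\lambda_3|}; ties in magnitude are
#' broken by ascending signed value so outputs are deterministic.
#'
#' @param field a [HessianField-class], or a symmetric 3x3 \code{matrix} for
#'   a single decomposition.
#' @param vectors logical: also return the orthonormal eigenvector frames.
#' @return for a field: a list with 3D arrays \code{l1}, \code{l2}, \code{l3}
#'   (and matrices \code{e1}, \code{e2}, \code{e3} of per-voxel unit vectors,
#'   voxels in rows, when \code{vectors = TRUE}). For a matrix: a list with
#'   scalar \code{l1}, \code{l2}, \code{l3} (and 3-vectors \code{e1}..\code{e3}).
#' @examples
#' eigenSym3(diag(c(-3, 1, -0.5)))$l1   # -0.5: smallest magnitude first
#' @export
setGeneric("eigenSym3",
           function(field, vectors = FALSE) standardGeneric("eigenSym3"))

#' @rdname eigenSym3
#' @export
setMethod("eigenSym3", "HessianField", function(field, vectors = FALSE) {
  d <- dim(field@ixx)
  r <- .eigenSym3Field(as.double(field@ixx), as.double(field@iyy),
                       as.double(field@izz), as.double(field@ixy),
                       as.double(field@ixz), as.double(field@iyz),
                       isTRUE(vectors))
  r$l1 <- array(r$l1, d); r$l2 <- array(r$l2, d); r$l3 <- array(r$l3, d)
  r
})

#' @rdname eigenSym3
#' @export
setMethod("eigenSym3", "matrix", function(field, vectors = FALSE) {
  if (!identical(dim(field), c(3L, 3L)) ||
      max(abs(field - t(field))) > 1e-12 * (1 + max(abs(field))))
    stop("'field' must be a symmetric 3x3 matrix")
  r <- .eigenSym3Field(field[1, 1], field[2, 2], field[3, 3],
                       field[1, 2], field[1, 3], field[2, 3],
                       isTRUE(vectors))
  if (isTRUE(vectors)) {
    r$e1 <- as.numeric(r$e1); r$e2 <- as.numeric(r$e2)
    r$e3 <- as.numeric(r$e3)
  }
  r
})

#' Scale-normalized Laplacian field of a volume
#'
#' The Laplacian at scale sigma is the trace of the Hessian,
#' \eqn{I_{xx} + I_{yy} + I_{zz}}, equal to the sum of the Hessian
#' eigenvalues and invariant under rotation of the tensor basis. It is
#' computed with the same gamma-normalized derivatives as
#' [hessianAtScale()], so its values live in the same units as the
#' eigenvalue-based measures.
#'
#' @param vol a [Volume-class].
#' @param probe a [GaussianProbe-class].
#' @return a [Volume-class] holding the Laplacian response.
#' @export
setGeneric("laplacianField",
           function(vol, probe) standardGeneric("laplacianField"))

#' @rdname laplacianField
#' @export
setMethod("laplacianField", signature("Volume", "GaussianProbe"),
  function(vol, probe) {
    lap <- gaussianDerivative(vol, probe, c(2, 0, 0))@data +
           gaussianDerivative(vol, probe, c(0, 2, 0))@data +
           gaussianDerivative(vol, probe, c(0, 0, 2))@data
    new("Volume", data = lap, spacing = vol@spacing, origin = vol@origin)
  })

#' Automatic selection of the noise-suppression parameter c
#'
#' Derives the background noise-suppression parameter of the Frangi
#' vesselness measure from the image itself: compute the per-voxel Laplacian
#' (the sum of the Hessian eigenvalues), find its maximum value, and take one
#' \code{divisor}-th of it (one tenth by default). Because the only input is
#' the image being processed, the choice adapts automatically to voxel size
#' and noise level with no operator interaction.
#'
#' By default the Laplacian is evaluated at every scale in \code{scales} with
#' the same gamma normalization as the main sweep and the maximum is taken
#' globally, so that c shares units with the Frobenius norm S it is compared
#' against. \code{mode = "first-scale"} restricts the search to the smallest
#' scale.
#'
#' @param vol a [Volume-class]; must not be constant.
#' @param scales a [ScaleSpec-class], or a numeric vector of sigmas (gamma
#'   taken from \code{gamma}).
#' @param divisor positive number; default 10.
#' @param mode \code{"global"} (max over all scales) or \code{"first-scale"}.
#' @param gamma normalization exponent used when \code{scales} is numeric.
#' @return the derived c (single positive number).
#' @export
setGeneric("autoC",
  function(vol, scales, divisor = 10, mode = c("global", "first-scale"),
           gamma = 1) standardGeneric("autoC"))

#' @rdname autoC
#' @export
setMethod("autoC", signature("Volume", "ScaleSpec"),
  function(vol, scales, divisor = 10, mode = c("global", "first-scale"),
           gamma = 1) {
    autoC(vol, makeScales(scales), divisor, mode, gamma = scales@gamma)
  })

#' @rdname autoC
#' @export
setMethod("autoC", signature("Volume", "numeric"),
  function(vol, scales, divisor = 10, mode = c("global", "first-scale"),
           gamma = 1) {
    mode <- match.arg(mode)
    if (divisor <= 0) stop("'divisor' must be positive")
    rng <- range(vol@data)
    if (rng[1] == rng[2])
      stop("degenerate input: constant volume has no Laplacian structure, ",
           "cannot derive c")
    if (mode == "first-scale") scales <- min(scales)
    lapMax <- -Inf
    for (s in scales) {
      probe <- GaussianProbe(s, gamma = gamma)
      lapMax <- max(lapMax, max(laplacianField(vol, probe)@data))
    }
    if (!is.finite(lapMax) || lapMax <= 0)
      stop("degenerate input: maximum Laplacian is not positive, ",
           "cannot derive c")
    lapMax / divisor
  })
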