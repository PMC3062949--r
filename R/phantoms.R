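# Physical voxel-center coordinate grids for a given shape/spacing/origin.
coordGrids <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  cx <- origin[1] + (seq_len(shape[1]) - 1) * spacing[1]
  cy <- origin[2] + (seq_len(shape[2]) - 1) * spacing[2]
  cz <- origin[3] + (seq_len(shape[3]) - 1) * spacing[3]
  list(x = array(cx, shape),
       y = array(rep(cy, each = shape[1]), shape),
       z = array(rep(cz, each = shape[1] * shape[2]), shape))
}

# Per-voxel distance to a polyline (matrix of vertices, one per row, in
# physical coordinates). Straight two-point centerlines are the common case.
distanceToPolyline <- function(grids, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3, byrow = TRUE)
  if (nrow(pts) < 2L) stop("a centerline needs at least two vertices")
  d2min <- NULL
  for (i in seq_len(nrow(pts) - 1L)) {
    p <- pts[i, ]; q <- pts[i + 1L, ]
    u <- q - p
    len2 <- sum(u^2)
    if (len2 == 0) next
    t <- ((grids$x - p[1]) * u[1] + (grids$y - p[2]) * u[2] +
          (grids$z - p[3]) * u[3]) / len2
    t <- pmin(pmax(t, 0), 1)
    d2 <- (grids$x - p[1] - t * u[1])^2 + (grids$y - p[2] - t * u[2])^2 +
          (grids$z - p[3] - t * u[3])^2
    d2min <- if (is.null(d2min)) d2 else pmin(d2min, d2)
  }
  sqrt(d2min)
}

#' Rasterize one tube into a volume
#'
#' Renders a tube along a polyline centerline. With a \code{"gaussian"}
#' profile the intensity is \eqn{A e^{-r^2/2\sigma_{obj}^2}} with \eqn{r} the
#' distance to the centerline; with a \code{"bar"} profile it is \eqn{A} for
#' \eqn{r \le} \code{halfWidth} and 0 outside (a two-valued cross-section of
#' total width \code{2 * halfWidth}, the profile seen in imagers with very
#' narrow point-spread functions). Centerline vertices outside the grid are
#' allowed (the tube is clipped) with a warning.
#'
#' @param shape integer(3) grid dimensions.
#' @param centerline matrix of polyline vertices (rows, physical x/y/z), or a
#'   numeric vector of length 6 \code{c(p, q)} for a straight tube.
#' @param profile \code{"gaussian"} or \code{"bar"}.
#' @param sigma Gaussian cross-section width \eqn{\sigma_{obj}} (physical).
#' @param halfWidth bar profile half-width (physical).
#' @param amplitude peak intensity A (>= 0).
#' @param spacing,origin voxel geometry.
#' @return a [Volume-class].
#' @examples
#' tube <- makeTube(c(32, 32, 32), rbind(c(16, 16, 0), c(16, 16, 31)),
#'                  sigma = 3, amplitude = 1)
#' max(voxelData(tube))   # 1 on the axis
#' @export
makeTube <- function(shape, centerline, profile = c("gaussian", "bar"),
                     sigma = 3, halfWidth = 5, amplitude = 1,
                     spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  profile <- match.arg(profile)
  if (amplitude < 0) stop("'amplitude' must be >= 0")
  if (profile == "gaussian" && sigma <= 0) stop("'sigma' must be > 0")
  if (profile == "bar" && halfWidth <= 0) stop("'halfWidth' must be > 0")
  if (is.null(dim(centerline)))
    centerline <- matrix(centerline, ncol = 3, byrow = TRUE)
  g <- coordGrids(shape, spacing, origin)
  lo <- c(min(g$x), min(g$y), min(g$z)); hi <- c(max(g$x), max(g$y), max(g$z))
  if (any(t(centerline) < lo - spacing) || any(t(centerline) > hi + spacing))
    warning("centerline extends outside the grid; tube clipped")
  r <- distanceToPolyline(g, centerline)
  dat <- if (profile == "gaussian") {
    amplitude * exp(-r^2 / (2 * sigma^2))
  } else {
    amplitude * (r <= halfWidth)
  }
  Volume(array(dat, shape), spacing = spacing, origin = origin)
}

#' Non-tubular distractor objects
#'
#' \code{makeBlob} renders an isotropic Gaussian blob
#' \eqn{A e^{-|x-p|^2/2s^2}}; \code{makePlate} renders a plate (slab) with a
#' Gaussian profile across its normal direction. Both are used as
#' non-tubular distractors in phantoms.
#'
#' @param shape integer(3) grid dimensions.
#' @param position blob center / a point on the plate (physical coords).
#' @param size Gaussian width of the object (physical).
#' @param normal plate normal direction (need not be unit length).
#' @param amplitude peak intensity.
#' @param spacing,origin voxel geometry.
#' @return a [Volume-class].
#' @export
makeBlob <- function(shape, position, size = 3, amplitude = 1,
                     spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (size <= 0) stop("'size' must be > 0")
  g <- coordGrids(shape, spacing, origin)
  r2 <- (g$x - position[1])^2 + (g$y - position[2])^2 + (g$z - position[3])^2
  Volume(array(amplitude * exp(-r2 / (2 * size^2)), shape),
         spacing = spacing, origin = origin)
}

#' @rdname makeBlob
#' @export
makePlate <- function(shape, position, normal = c(0, 0, 1), size = 2,
                      amplitude = 1, spacing = c(1, 1, 1),
                      origin = c(0, 0, 0)) {
  if (size <= 0) stop("'size' must be > 0")
  n <- normal / sqrt(sum(normal^2))
  g <- coordGrids(shape, spacing, origin)
  d <- (g$x - position[1]) * n[1] + (g$y - position[2]) * n[2] +
       (g$z - position[3]) * n[3]
  Volume(array(amplitude * exp(-d^2 / (2 * size^2)), shape),
         spacing = spacing, origin = origin)
}

#' Polynomial intensity background
#'
#' Evaluates an additive per-axis polynomial background in normalized
#' coordinates: each axis coordinate is mapped to [0, 1] and the background
#' is \eqn{P_x(u) + P_y(v) + P_z(w)} with coefficient vectors in increasing
#' power order. Degrees up to 3 are supported. Models slowly varying
#' illumination/shading such as seen in tiled confocal acquisitions.
#'
#' @param shape integer(3) grid dimensions.
#' @param coefficients named list with any of \code{x}, \code{y}, \code{z},
#'   each a numeric vector (constant, linear, quadratic, cubic).
#' @param spacing,origin voxel geometry.
#' @return a [Volume-class].
#' @examples
#' bg <- makePolynomialBackground(c(16, 16, 16), list(x = c(0, 100)))
#' range(voxelData(bg))   # 0 .. 100 ramp along x
#' @export
makePolynomialBackground <- function(shape, coefficients,
                                     spacing = c(1, 1, 1),
                                     origin = c(0, 0, 0)) {
  polyEval <- function(coef, n) {
    if (is.null(coef)) return(rep(0, n))
    if (length(coef) > 4L) stop("polynomial degree <= 3 supported")
    u <- if (n == 1L) 0 else (seq_len(n) - 1) / (n - 1)
    out <- rep(0, n)
    for (k in seq_along(coef)) out <- out + coef[k] * u^(k - 1)
    out
  }
  px <- polyEval(coefficients$x, shape[1])
  py <- polyEval(coefficients$y, shape[2])
  pz <- polyEval(coefficients$z, shape[3])
  dat <- array(px, shape) + array(rep(py, each = shape[1]), shape) +
    array(rep(pz, each = shape[1] * shape[2]), shape)
  Volume(dat, spacing = spacing, origin = origin)
}

#' Add white Gaussian noise to a volume
#'
#' Adds independent per-voxel Gaussian noise drawn with R's Mersenne-Twister
#' generator. The caller's RNG state is saved and restored, so phantom
#' generation never perturbs outside randomness; the same seed always yields
#' a bit-identical noise field. \code{sd = 0} returns the input unchanged.
#'
#' @param vol a [Volume-class].
#' @param mean,sd noise moments; \code{sd >= 0}.
#' @param seed integer seed; \code{NULL} uses (and advances) the current
#'   RNG state.
#' @return a [Volume-class].
#' @export
addGaussianNoise <- function(vol, mean = 0, sd, seed = NULL) {
  if (sd < 0) stop("'sd' must be >= 0")
  if (sd == 0 && mean == 0) return(vol)
  noise <- withRNG(seed, stats::rnorm(length(vol@data), mean = mean, sd = sd))
  new("Volume", data = vol@data + array(noise, dim(vol@data)),
      spacing = vol@spacing, origin = vol@origin)
}

# Evaluate expr under a seeded RNG, restoring the caller's state afterwards.
withRNG <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Render a declarative PhantomSpec into volumes with ground truth
#'
#' Composes tubes, distractors and background additively, then adds noise.
#' Generation order never changes the result for a given seed because the
#' noise draw is isolated from the deterministic components.
#'
#' @param spec a [PhantomSpec-class].
#' @return a list with elements \code{degraded} (the noisy composite),
#'   \code{ideal} (noise-free composite), \code{tubes} (tubes only),
#'   \code{mask} (logical array, within 2 sigma / one half-width of a
#'   centerline), and \code{centerlines} (list of vertex matrices).
#' @export
generatePhantom <- function(spec) {
  if (!is(spec, "PhantomSpec")) stop("'spec' must be a PhantomSpec")
  validObject(spec)
  shape <- spec@shape
  sp <- spec@spacing
  acc <- Volume(array(0, shape), spacing = sp)
  tubesOnly <- array(0, shape)
  mask <- array(FALSE, shape)
  g <- coordGrids(shape, sp)
  centerlines <- list()
  for (tb in spec@tubes) {
    profile <- if (is.null(tb$profile)) "gaussian" else tb$profile
    v <- makeTube(shape, tb$centerline, profile = profile,
                  sigma = if (is.null(tb$sigma)) 3 else tb$sigma,
                  halfWidth = if (is.null(tb$halfWidth)) 5 else tb$halfWidth,
                  amplitude = if (is.null(tb$amplitude)) 1 else tb$amplitude,
                  spacing = sp)
    tubesOnly <- tubesOnly + v@data
    cl <- tb$centerline
    if (is.null(dim(cl))) cl <- matrix(cl, ncol = 3, byrow = TRUE)
    centerlines[[length(centerlines) + 1L]] <- cl
    r <- distanceToPolyline(g, cl)
    rad <- if (profile == "gaussian") 2 * tb$sigma else tb$halfWidth
    mask <- mask | (r <= rad)
  }
  acc@data <- acc@data + tubesOnly
  for (ds in spec@distractors) {
    kind <- if (is.null(ds$kind)) "blob" else ds$kind
    v <- if (kind == "blob") {
      makeBlob(shape, ds$position, size = ds$size,
               amplitude = ds$amplitude, spacing = sp)
    } else {
      makePlate(shape, ds$position,
                normal = if (is.null(ds$normal)) c(0, 0, 1) else ds$normal,
                size = ds$size, amplitude = ds$amplitude, spacing = sp)
    }
    acc@data <- acc@data + v@data
  }
  if (length(spec@background))
    acc@data <- acc@data +
      makePolynomialBackground(shape, spec@background, spacing = sp)@data
  ideal <- acc
  sd <- if (is.null(spec@noise$sd)) 0 else spec@noise$sd
  mn <- if (is.null(spec@noise$mean)) 0 else spec@noise$mean
  degraded <- addGaussianNoise(ideal, mean = mn, sd = sd,
                               seed = spec@noise$seed)
  list(degraded = degraded, ideal = ideal,
       tubes = Volume(tubesOnly, spacing = sp), mask = mask,
       centerlines = centerlines)
}

# Linear voxel indices of the voxels nearest to a set of physical points.
centerlineIndices <- function(shape, pts, spacing = c(1, 1, 1),
                              origin = c(0, 0, 0), step = 0.5) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3, byrow = TRUE)
  dense <- NULL
  for (i in seq_len(nrow(pts) - 1L)) {
    p <- pts[i, ]; q <- pts[i + 1L, ]
    n <- max(2L, ceiling(sqrt(sum((q - p)^2)) / step))
    t <- seq(0, 1, length.out = n)
    dense <- rbind(dense, cbind(p[1] + t * (q[1] - p[1]),
                                p[2] + t * (q[2] - p[2]),
                                p[3] + t * (q[3] - p[3])))
  }
  idx <- round(sweep(sweep(dense, 2, origin), 2, spacing, "/")) + 1
  keep <- idx[, 1] >= 1 & idx[, 1] <= shape[1] &
          idx[, 2] >= 1 & idx[, 2] <= shape[2] &
          idx[, 3] >= 1 & idx[, 3] <= shape[3]
  idx <- idx[keep, , drop = FALSE]
  unique((idx[, 3] - 1) * shape[1] * shape[2] + (idx[, 2] - 1) * shape[1] +
         idx[, 1])
}

#' Three-tube evaluation phantom (clean reference plus noisy copy)
#'
#' Builds the reference scene used for objective quality evaluation: three
#' parallel straight tubes with Gaussian cross-sections of distinct widths,
#' aligned with the z axis, then a copy degraded by white Gaussian noise.
#' Both volumes are rescaled by the tube amplitude so the clean image has
#' dynamic range 1.0, which makes MSE/PSNR values comparable across runs.
#' Default widths \code{sigmas = c(2, 4, 8)} span a two-octave range of tube
#' radii; the default \code{amplitude = 1000} with \code{noiseSd = 100}
#' gives a 10:1 peak-signal-to-noise-sd ratio before filtering.
#'
#' @param seed integer seed for the noise field.
#' @param shape grid dimensions (default 96^3).
#' @param sigmas Gaussian cross-section widths of the three tubes.
#' @param amplitude common peak intensity before normalization. The default
#'   14000 against \code{noiseSd = 100} reproduces the ~19:1 ratio of
#'   maximum image Laplacian to noise SD at which the automatic
#'   noise-suppression selection is reported to operate (16-bit micro-CT-like
#'   contrast); see the methods vignette.
#' @param noiseSd noise standard deviation on the pre-normalization scale.
#' @return list with [Volume-class] elements \code{ideal} and
#'   \code{degraded}, plus \code{mask} (logical array), \code{centerlineIdx}
#'   (linear voxel indices on the tube axes) and \code{noiseSdNormalized}.
#' @export
makeThreeTubePhantom <- function(seed = 1L, shape = c(96L, 96L, 96L),
                                 sigmas = c(2, 4, 8), amplitude = 14000,
                                 noiseSd = 100) {
  shape <- as.integer(shape)
  xs <- round(shape[1] * c(0.22, 0.5, 0.78))
  y0 <- round(shape[2] * 0.5)
  zend <- shape[3] - 1
  spec <- new("PhantomSpec", shape = shape, spacing = c(1, 1, 1),
              tubes = lapply(seq_along(sigmas), function(i) {
                list(centerline = rbind(c(xs[i], y0, 0), c(xs[i], y0, zend)),
                     profile = "gaussian", sigma = sigmas[i],
                     amplitude = amplitude)
              }),
              noise = list(mean = 0, sd = noiseSd, seed = as.integer(seed)))
  ph <- generatePhantom(spec)
  ideal <- ph$ideal; degraded <- ph$degraded
  ideal@data <- ideal@data / amplitude
  degraded@data <- degraded@data / amplitude
  cl <- unlist(lapply(ph$centerlines, function(p)
    centerlineIndices(shape, p)))
  list(ideal = ideal, degraded = degraded, mask = ph$mask,
       centerlineIdx = cl, noiseSdNormalized = noiseSd / amplitude)
}

#' Curved-tube phantom with non-tubular distractors
#'
#' Three curved tubes (sinusoidal centerlines) of distinct widths placed
#' amid Gaussian blob distractors, degraded by white Gaussian noise. The
#' scene exercises tube tracking in the presence of non-tubular objects.
#'
#' @param seed noise seed.
#' @param shape grid dimensions.
#' @param sigmas tube cross-section widths.
#' @param amplitude tube/distractor peak intensity.
#' @param noiseSd noise standard deviation (same intensity scale as
#'   \code{amplitude}; e.g. 25 or 50 against the default 1000).
#' @return list with \code{degraded}, \code{ideal}, \code{mask},
#'   \code{centerlineIdx}.
#' @export
makeCurvedTubePhantom <- function(seed = 1L, shape = c(64L, 64L, 64L),
                                  sigmas = c(1.5, 2.5, 4), amplitude = 1000,
                                  noiseSd = 25) {
  shape <- as.integer(shape)
  zend <- shape[3] - 1
  zs <- seq(0, zend, length.out = 33)
  curve <- function(x0, y0, ax, ay, phase) {
    cbind(x0 + ax * sin(2 * pi * zs / zend + phase),
          y0 + ay * cos(2 * pi * zs / zend + phase), zs)
  }
  n1 <- shape[1]
  cls <- list(curve(0.28 * n1, 0.30 * n1, 0.08 * n1, 0.05 * n1, 0),
              curve(0.55 * n1, 0.60 * n1, 0.06 * n1, 0.08 * n1, 1.3),
              curve(0.78 * n1, 0.35 * n1, 0.05 * n1, 0.06 * n1, 2.4))
  blobs <- list(
    list(kind = "blob", position = c(0.15, 0.75, 0.25) * n1, size = 3,
         amplitude = amplitude),
    list(kind = "blob", position = c(0.45, 0.20, 0.70) * n1, size = 5,
         amplitude = amplitude),
    list(kind = "blob", position = c(0.80, 0.80, 0.50) * n1, size = 4,
         amplitude = amplitude))
  spec <- new("PhantomSpec", shape = shape, spacing = c(1, 1, 1),
              tubes = lapply(seq_along(sigmas), function(i)
                list(centerline = cls[[i]], profile = "gaussian",
                     sigma = sigmas[i], amplitude = amplitude)),
              distractors = blobs,
              noise = list(mean = 0, sd = noiseSd, seed = as.integer(seed)))
  ph <- generatePhantom(spec)
  cl <- unlist(lapply(ph$centerlines, function(p)
    centerlineIndices(shape, p)))
  list(degraded = ph$degraded, ideal = ph$ideal, mask = ph$mask,
       centerlineIdx = cl)
}

#' Parallel tubes over a polynomial (optionally noisy) background
#'
#' Three straight tubes of distinct widths and mutual distances, aligned
#' with the z axis, superimposed on a smoothly varying polynomial intensity
#' background, with optional white Gaussian noise. Emulates fluorescence
#' scenes affected by shading/tiling backgrounds.
#'
#' @param seed noise seed.
#' @param shape grid dimensions.
#' @param sigmas tube widths.
#' @param amplitude tube peak intensity.
#' @param noiseSd noise standard deviation (0 for a noise-free background).
#' @param background per-axis polynomial coefficient list; the default is a
#'   ramp plus quadratic bowl spanning about 40% of the tube amplitude.
#' @return list with \code{degraded}, \code{ideal}, \code{tubes} (tubes
#'   only, no background), \code{mask}, \code{centerlineIdx}.
#' @export
makeParallelTubePhantom <- function(seed = 1L, shape = c(64L, 64L, 64L),
                                    sigmas = c(1.5, 2.5, 4),
                                    amplitude = 1000, noiseSd = 0,
                                    background = list(x = c(0, 400),
                                                      y = c(100, -200, 300))) {
  shape <- as.integer(shape)
  zend <- shape[3] - 1
  n1 <- shape[1]
  xs <- round(n1 * c(0.2, 0.46, 0.8))
  ys <- round(shape[2] * c(0.35, 0.65, 0.45))
  spec <- new("PhantomSpec", shape = shape, spacing = c(1, 1, 1),
              tubes = lapply(seq_along(sigmas), function(i)
                list(centerline = rbind(c(xs[i], ys[i], 0),
                                        c(xs[i], ys[i], zend)),
                     profile = "gaussian", sigma = sigmas[i],
                     amplitude = amplitude)),
              background = background,
              noise = list(mean = 0, sd = noiseSd, seed = as.integer(seed)))
  ph <- generatePhantom(spec)
  cl <- unlist(lapply(ph$centerlines, function(p)
    centerlineIndices(shape, p)))
  list(degraded = ph$degraded, ideal = ph$ideal, tubes = ph$tubes,
       mask = ph$mask, centerlineIdx = cl)
}

#' Read and write PhantomSpec objects as plain-text YAML
#'
#' Serializes the declarative phantom description so command-line runs are
#' fully scripted and reproducible.
#'
#' @param spec a [PhantomSpec-class].
#' @param path file path.
#' @return \code{readPhantomSpec} returns a [PhantomSpec-class];
#'   \code{writePhantomSpec} returns \code{path} invisibly.
#' @export
writePhantomSpec <- function(spec, path) {
  if (!is(spec, "PhantomSpec")) stop("'spec' must be a PhantomSpec")
  tubes <- lapply(spec@tubes, function(tb) {
    tb$centerline <- as.numeric(t(tb$centerline))
    tb
  })
  yaml::write_yaml(list(shape = as.integer(spec@shape),
                        spacing = as.numeric(spec@spacing),
                        tubes = tubes, distractors = spec@distractors,
                        background = spec@background, noise = spec@noise),
                   path)
  invisible(path)
}

#' @rdname writePhantomSpec
#' @export
readPhantomSpec <- function(path) {
  y <- yaml::read_yaml(path)
  tubes <- lapply(y$tubes, function(tb) {
    tb$centerline <- matrix(as.numeric(tb$centerline), ncol = 3, byrow = TRUE)
    tb
  })
  new("PhantomSpec", shape = as.integer(y$shape),
      spacing = as.numeric(y$spacing), tubes = tubes,
      distractors = if (is.null(y$distractors)) list() else y$distractors,
      background = if (is.null(y$background)) list() else y$background,
      noise = y$noise)
}
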