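#' Build the ordered list of probe scales
#'
#' Linear stepping returns an arithmetic progression between the bounds;
#' logarithmic stepping returns a geometric progression
#' \eqn{\sigma_i = \sigma_{min} (\sigma_{max}/\sigma_{min})^{i/(n-1)}},
#' which places strictly more probes below the arithmetic midpoint and so
#' emphasizes finer scales. A single step returns \code{sigmaMin}.
#'
#' @param spec a [ScaleSpec-class].
#' @return numeric vector of strictly increasing sigmas; first equals
#'   \code{sigmaMin} and last \code{sigmaMax} when \code{nSteps >= 2}.
#' @examples
#' makeScales(ScaleSpec(1, 30, 20, "logarithmic"))
#' @export
makeScales <- function(spec) {
  if (!is(spec, "ScaleSpec")) stop("'spec' must be a ScaleSpec")
  n <- spec@nSteps
  if (n == 1L) return(spec@sigmaMin)
  if (spec@stepFunction == "linear") {
    seq(spec@sigmaMin, spec@sigmaMax, length.out = n)
  } else {
    spec@sigmaMin * (spec@sigmaMax / spec@sigmaMin)^((seq_len(n) - 1) / (n - 1))
  }
}

#' Multiscale tubularity response of a volume
#'
#' Sweeps the scale list, computing at each scale the gamma-normalized
#' Hessian, its magnitude-ordered eigenvalues and the configured objectness
#' measure, and keeps the per-voxel running maximum together with the first
#' scale achieving it. Because the strongest normalized response occurs when
#' the probe size matches the local object width, the per-voxel best scale
#' estimates the local tube radius. Only one per-scale Hessian field is
#' resident at a time, so memory stays proportional to a handful of volumes.
#'
#' In automatic mode (\code{params@autoC}), the noise-suppression parameter c
#' is derived once with [autoC()] before the sweep (one extra Laplacian pass
#' over the scale list) and recorded in the result.
#'
#' @param vol a [Volume-class]; must be non-constant in automatic mode.
#' @param spec a [ScaleSpec-class].
#' @param params an [ObjectnessParams-class].
#' @param log optional function called with progress strings (stage names);
#'   used by the pipeline driver to record the stage sequence.
#' @return a [ResponseVolume-class].
#' @export
setGeneric("multiscaleObjectness",
  function(vol, spec, params, log = NULL)
    standardGeneric("multiscaleObjectness"))

#' @rdname multiscaleObjectness
#' @export
setMethod("multiscaleObjectness",
  signature("Volume", "ScaleSpec", "ObjectnessParams"),
  function(vol, spec, params, log = NULL) {
    logf <- if (is.null(log)) function(...) invisible(NULL) else log
    scales <- makeScales(spec)

    if (params@autoC) {
      logf("laplacian_sweep")
      cval <- autoC(vol, scales, divisor = params@autoCDivisor,
                    gamma = spec@gamma)
      logf(sprintf("auto_c c=%.10g", cval))
      params <- ObjectnessParams(a = params@a, b = params@b, c = cval,
                                 polarity = params@polarity,
                                 measure = params@measure,
                                 alpha1 = params@alpha1,
                                 alpha2 = params@alpha2,
                                 autoCDivisor = params@autoCDivisor)
      cMode <- "automatic"
    } else {
      cval <- params@c
      cMode <- "manual"
    }

    d <- dim(vol@data)
    best <- array(-Inf, d)
    bestScale <- array(scales[1], d)
    for (s in scales) {
      logf(sprintf("hessian_scale sigma=%.10g", s))
      probe <- GaussianProbe(s, gamma = spec@gamma)
      hf <- hessianAtScale(vol, probe)
      eig <- eigenSym3(hf)
      score <- objectnessScore(eig$l1, eig$l2, eig$l3, params)
      better <- score > best
      best[better] <- score[better]
      bestScale[better] <- s
      rm(hf, eig, score, better)
    }
    best[!is.finite(best)] <- 0

    new("ResponseVolume",
        response = new("Volume", data = best, spacing = vol@spacing,
                       origin = vol@origin),
        bestScale = new("Volume", data = bestScale, spacing = vol@spacing,
                        origin = vol@origin),
        scales = scales, cValue = cval, cMode = cMode)
  })
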