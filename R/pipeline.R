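#' Assemble a run configuration for the pipeline driver
#'
#' Mirrors the command-line interface one-to-one. The input is either a
#' volume file path, a [Volume-class], or a [PhantomSpec-class] (rendered at
#' run time). Noise suppression is \code{"automatic"} (c derived from the
#' image Laplacian) or \code{"manual"} (explicit \code{cValue} required, and
#' forbidden in automatic mode).
#'
#' @param input file path, [Volume-class] or [PhantomSpec-class].
#' @param outputDir directory for result volumes and MIPs; \code{NULL}
#'   disables file output.
#' @param polarity \code{"bright"} or \code{"dark"} objects.
#' @param measure \code{"frangi"} (tubular, with noise suppression) or
#'   \code{"sato"}.
#' @param sigmaMin,sigmaMax,nSteps,stepFunction scale sweep configuration.
#' @param gamma derivative normalization exponent.
#' @param noiseMode \code{"automatic"} or \code{"manual"}.
#' @param cValue manual noise-suppression parameter (manual mode only).
#' @param autoCDivisor divisor of the maximum Laplacian (default 10).
#' @param reference optional reference volume (path or [Volume-class]) for a
#'   [QualityReport-class] of the response.
#' @param seed seed recorded with the run (used by phantom inputs).
#' @param verbose print stage progress to stderr.
#' @return a \code{runConfig} list.
#' @export
runConfig <- function(input, outputDir = NULL,
                      polarity = c("bright", "dark"),
                      measure = c("frangi", "sato"),
                      sigmaMin = 1, sigmaMax = 30, nSteps = 20L,
                      stepFunction = c("logarithmic", "linear"), gamma = 1,
                      noiseMode = c("automatic", "manual"), cValue = NA_real_,
                      autoCDivisor = 10, reference = NULL, seed = 1L,
                      verbose = FALSE) {
  noiseMode <- match.arg(noiseMode)
  if (noiseMode == "manual" && (is.na(cValue) || cValue <= 0))
    stop("manual noise-suppression mode requires an explicit c > 0")
  if (noiseMode == "automatic" && !is.na(cValue))
    stop("automatic noise-suppression mode forbids an explicit c")
  structure(list(input = input, outputDir = outputDir,
                 polarity = match.arg(polarity), measure = match.arg(measure),
                 sigmaMin = sigmaMin, sigmaMax = sigmaMax,
                 nSteps = as.integer(nSteps),
                 stepFunction = match.arg(stepFunction), gamma = gamma,
                 noiseMode = noiseMode, cValue = cValue,
                 autoCDivisor = autoCDivisor, reference = reference,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "runConfig")
}

#' Run the full tubularity-enhancement pipeline
#'
#' Loads or generates the input volume, derives the noise-suppression
#' parameter when in automatic mode, sweeps the configured scales with
#' [multiscaleObjectness()], optionally scores the response against a
#' reference, and writes the response volume, best-scale volume and MIPs to
#' the output directory. The run log records every parameter, the seed, the
#' derived c and the ordered stage sequence; any stage failure aborts with a
#' stage-named error and removes partial outputs.
#'
#' @param config a [runConfig()] list.
#' @return a list with \code{response} (a [ResponseVolume-class]),
#'   \code{report} (a [QualityReport-class] or \code{NULL}), \code{log}
#'   (character vector), \code{stages} (stage names in execution order) and
#'   \code{files} (paths written).
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "runConfig")) stop("'config' must come from runConfig()")
  stages <- character()
  logLines <- character()
  files <- character()
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    logLines <<- c(logLines, line)
    if (config$verbose) message(line)
    invisible(NULL)
  }
  stage <- function(name, expr) {
    stages <<- c(stages, name)
    tryCatch(expr, error = function(e) {
      for (f in files) unlink(f)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  for (p in c("polarity", "measure", "sigmaMin", "sigmaMax", "nSteps",
              "stepFunction", "gamma", "noiseMode", "cValue", "autoCDivisor",
              "seed"))
    note("param %s=%s", p, format(config[[p]]))

  vol <- stage("load_input", {
    inp <- config$input
    if (is(inp, "Volume")) inp
    else if (is(inp, "PhantomSpec")) {
      if (is.null(inp@noise$seed)) inp@noise$seed <- config$seed
      generatePhantom(inp)$degraded
    } else if (is.character(inp)) readVolume(inp)
    else stop("input must be a path, Volume or PhantomSpec")
  })
  note("input %s voxels", paste(dim(vol@data), collapse = "x"))

  spec <- ScaleSpec(config$sigmaMin, config$sigmaMax, config$nSteps,
                    config$stepFunction, gamma = config$gamma)
  params <- if (config$noiseMode == "automatic") {
    ObjectnessParams(polarity = config$polarity, measure = config$measure,
                     autoCDivisor = config$autoCDivisor)
  } else {
    ObjectnessParams(polarity = config$polarity, measure = config$measure,
                     c = config$cValue, autoCDivisor = config$autoCDivisor)
  }

  resp <- stage("multiscale_sweep",
                multiscaleObjectness(vol, spec, params,
                                     log = function(s) {
                                       stages <<- c(stages, s)
                                       note("%s", s)
                                     }))
  note("derived c=%.10g (%s)", resp@cValue, resp@cMode)

  report <- NULL
  if (!is.null(config$reference)) {
    report <- stage("quality_report", {
      ref <- if (is(config$reference, "Volume")) config$reference
             else readVolume(config$reference)
      qualityReport(ref, resp@response)
    })
    note("%s", format(report))
  }

  if (!is.null(config$outputDir)) {
    stage("write_outputs", {
      dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
      out <- function(name) file.path(config$outputDir, name)
      files <<- c(files, out("response.nrrd"))
      writeVolume(resp@response, out("response.nrrd"))
      files <<- c(files, out("best_scale.nrrd"))
      writeVolume(resp@bestScale, out("best_scale.nrrd"))
      for (ax in c("x", "y", "z")) {
        f <- out(sprintf("mip_%s.tif", ax))
        files <<- c(files, f)
        m <- mipProject(resp@response, ax)
        tiff::writeTIFF(t(pmin(pmax(m, 0), 1)), f, bits.per.sample = 32L,
                        compression = "none")
      }
      files <<- c(files, out("run.log"))
      writeLines(logLines, out("run.log"))
    })
  }

  list(response = resp, report = report, log = logLines, stages = stages,
       files = files)
}

#' Manual-mode sweep of the noise-suppression parameter
#'
#' Evaluates the multiscale tubularity response for a whole grid of c values
#' in one pass: the Hessian eigenvalues at each scale are computed once and
#' shared across the grid, so the sweep costs about as much as a single run
#' (the classic manual trial-and-error search recomputed everything per
#' trial). When a reference volume is supplied, each c gets a
#' [QualityReport-class] against it.
#'
#' @param vol a [Volume-class] to filter.
#' @param spec a [ScaleSpec-class].
#' @param cValues positive numeric vector of noise-suppression parameters.
#' @param params an [ObjectnessParams-class] template (polarity, a, b used;
#'   its c/autoC settings are ignored).
#' @param reference optional reference [Volume-class] for MSE/PSNR.
#' @param keepResponses logical: also return the per-c response arrays.
#' @return a data.frame with columns \code{c}, and when a reference is
#'   given \code{mse} and \code{psnr}; with \code{keepResponses}, the
#'   responses are attached as attribute \code{"responses"} (a list).
#' @export
sweepNoiseSuppression <- function(vol, spec, cValues, params = ObjectnessParams(c = 1),
                                  reference = NULL, keepResponses = FALSE) {
  if (any(cValues <= 0)) stop("all c values must be positive")
  scales <- makeScales(spec)
  d <- dim(vol@data)
  nc <- length(cValues)
  best <- lapply(seq_len(nc), function(i) array(0, d))
  for (s in scales) {
    probe <- GaussianProbe(s, gamma = spec@gamma)
    hf <- hessianAtScale(vol, probe)
    eig <- eigenSym3(hf)
    rm(hf)
    for (i in seq_len(nc)) {
      p <- ObjectnessParams(a = params@a, b = params@b, c = cValues[i],
                            polarity = params@polarity,
                            measure = params@measure,
                            alpha1 = params@alpha1, alpha2 = params@alpha2)
      score <- objectnessScore(eig$l1, eig$l2, eig$l3, p)
      best[[i]] <- pmax(best[[i]], score)
    }
    rm(eig)
  }
  out <- data.frame(c = cValues)
  if (!is.null(reference)) {
    refDat <- if (is(reference, "Volume")) reference@data else reference
    out$mse <- vapply(best, function(b) mse(b, refDat), numeric(1))
    out$psnr <- vapply(out$mse, psnr, numeric(1))
  }
  if (keepResponses) attr(out, "responses") <- best
  out
}
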