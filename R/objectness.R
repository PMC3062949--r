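# Shared polarity handling: dark-on-bright structures are scored by negating
# the eigenvalue signs, so each measure is written once for the bright case.
flipIfDark <- function(l1, l2, l3, polarity) {
  if (identical(polarity, "dark")) list(l1 = -l1, l2 = -l2, l3 = -l3)
  else list(l1 = l1, l2 = l2, l3 = l3)
}

#' Frangi vesselness measure
#'
#' Scores how tube-like the local intensity curvature is from the
#' magnitude-ordered Hessian eigenvalues
#' \eqn{|\lambda_1| \le |\lambda_2| \le |\lambda_3|}:
#' \deqn{\nu = \left(1 - e^{-R_a^2/2a^2}\right) e^{-R_b^2/2b^2}
#'             \left(1 - e^{-S^2/2c^2}\right)}
#' with \eqn{R_a = |\lambda_2|/|\lambda_3|} separating plates from lines,
#' \eqn{R_b = |\lambda_1|/\sqrt{|\lambda_2\lambda_3|}} penalizing blobs, and
#' \eqn{S = \sqrt{\lambda_1^2+\lambda_2^2+\lambda_3^2}} (the Frobenius norm)
#' suppressing low-energy background against the noise scale \code{c}. For
#' bright tubes the score is 0 whenever \eqn{\lambda_2 > 0} or
#' \eqn{\lambda_3 > 0}; dark polarity negates the eigenvalues first. Voxels
#' with \eqn{\lambda_3 = 0} carry no second-order structure and score 0.
#' Scores always lie in [0, 1]. \eqn{R_a} and \eqn{R_b} are invariant under
#' intensity scaling, so only \code{c} depends on the acquisition.
#'
#' @param l1,l2,l3 eigenvalue arrays (or scalars), magnitude-ordered as
#'   produced by [eigenSym3()].
#' @param params an [ObjectnessParams-class]; \code{params@c} must be set
#'   (manual value or the result of [autoC()]).
#' @return array of vesselness scores in [0, 1], same shape as the input.
#' @examples
#' p <- ObjectnessParams(c = 100)
#' frangiVesselness(0, -100, -100, p)   # ~ (1 - exp(-2)) * (1 - exp(-1))
#' frangiVesselness(0.1, 2, -5, p)      # 0: lambda2 > 0
#' @export
frangiVesselness <- function(l1, l2, l3, params) {
  if (!is(params, "ObjectnessParams")) stop("'params' must be ObjectnessParams")
  cval <- params@c
  if (is.na(cval) || cval <= 0)
    stop("noise-suppression parameter c must be a positive number; ",
         "run autoC() first in automatic mode")
  e <- flipIfDark(l1, l2, l3, params@polarity)
  l1 <- e$l1; l2 <- e$l2; l3 <- e$l3

  absL2 <- abs(l2); absL3 <- abs(l3)
  ok <- l2 <= 0 & l3 <= 0 & absL3 > 0
  # guarded ratios: values only used where ok is TRUE
  ra2 <- ifelse(absL3 > 0, (absL2 / pmax(absL3, .Machine$double.xmin))^2, 0)
  rb2 <- ifelse(absL2 * absL3 > 0,
                l1^2 / pmax(absL2 * absL3, .Machine$double.xmin), 0)
  s2 <- l1^2 + l2^2 + l3^2
  v <- (1 - exp(-ra2 / (2 * params@a^2))) *
       exp(-rb2 / (2 * params@b^2)) *
       (1 - exp(-s2 / (2 * cval^2)))
  out <- ifelse(ok, v, 0)
  if (is.array(l1)) array(out, dim(l1)) else out
}

#' Sato line measure
#'
#' Line-likeness score built from two of the three Hessian eigenvalues.
#' With \eqn{\lambda_c = \min(-\lambda_2, -\lambda_3)} (positive inside a
#' bright tube):
#' \deqn{f = \exp\left(-\lambda_1^2 / 2(\alpha_1\lambda_c)^2\right)}
#' for \eqn{\lambda_1 \le 0}, with \eqn{\alpha_2} replacing \eqn{\alpha_1}
#' for \eqn{\lambda_1 > 0}, and 0 when \eqn{\lambda_c = 0}. The two
#' sensitivities \eqn{\alpha_1 < \alpha_2} weight the axial curvature
#' asymmetrically around zero. Unlike the Frangi measure there is no
#' background noise-suppression term.
#'
#' @param l1,l2,l3 magnitude-ordered eigenvalue arrays or scalars.
#' @param params an [ObjectnessParams-class]; uses \code{alpha1 < alpha2}
#'   and the polarity.
#' @return array of scores in [0, 1].
#' @examples
#' satoMeasure(-1, -2, -2, ObjectnessParams(c = 1))   # exp(-1/2)
#' @export
satoMeasure <- function(l1, l2, l3, params) {
  if (!is(params, "ObjectnessParams")) stop("'params' must be ObjectnessParams")
  e <- flipIfDark(l1, l2, l3, params@polarity)
  l1 <- e$l1; l2 <- e$l2; l3 <- e$l3
  lc <- pmin(-l2, -l3)
  alpha <- ifelse(l1 <= 0, params@alpha1, params@alpha2)
  denom <- 2 * (alpha * lc)^2
  out <- ifelse(lc != 0, exp(-l1^2 / pmax(denom, .Machine$double.xmin)), 0)
  if (is.array(l1)) array(out, dim(l1)) else out
}

# Dispatch on the configured measure; l1..l3 magnitude-ordered.
objectnessScore <- function(l1, l2, l3, params) {
  switch(params@measure,
         frangi = frangiVesselness(l1, l2, l3, params),
         sato = satoMeasure(l1, l2, l3, params),
         stop("unknown measure: ", params@measure))
}
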