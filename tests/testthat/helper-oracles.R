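# Independent oracles used across the suite. Everything here is deliberately
# naive (plain R loops, dense sums) and shares no code with the package
# internals beyond exported constructors.

# Symmetric reflection of an out-of-range 1-based index into [1, n]
# (a b c d -> d c b a | a b c d | d c b a), reimplemented independently.
reflectIdx <- function(i, n) {
  if (n == 1L) return(1L)
  period <- 2L * n
  i <- ((i - 1L) %% period) + 1L
  if (i > n) i <- period + 1L - i
  i
}

# Dense (non-separable) 3D convolution of `arr` with the outer product of
# three 1D kernels, evaluated at a single voxel. Oracle for the separable
# compiled path.
denseConvAt <- function(arr, kx, ky, kz, at) {
  d <- dim(arr)
  rx <- (length(kx) - 1L) / 2L
  ry <- (length(ky) - 1L) / 2L
  rz <- (length(kz) - 1L) / 2L
  acc <- 0
  for (a in seq_along(kx)) {
    ia <- reflectIdx(at[1] - (a - rx - 1L), d[1])
    for (b in seq_along(ky)) {
      ib <- reflectIdx(at[2] - (b - ry - 1L), d[2])
      for (cc in seq_along(kz)) {
        ic <- reflectIdx(at[3] - (cc - rz - 1L), d[3])
        acc <- acc + kx[a] * ky[b] * kz[cc] * arr[ia, ib, ic]
      }
    }
  }
  acc
}

# Analytic order-n Gaussian derivative at x for standard deviation s.
analyticGaussDeriv <- function(x, s, order = 0L) {
  u <- x / s
  g <- exp(-u^2 / 2) / (s * sqrt(2 * pi))
  he <- switch(order + 1L, rep(1, length(u)), u, u^2 - 1, u^3 - 3 * u)
  (-1)^order * he * g / s^order
}

# A smooth random field: white noise lightly smoothed so that relative
# tolerances are meaningful away from zero crossings.
smoothRandomVolume <- function(shape, seed, presmooth = 1.5) {
  set.seed(seed)
  v <- Volume(array(rnorm(prod(shape)), shape))
  gaussianSmooth(v, GaussianProbe(presmooth))
}

# Count of strict local maxima of a numeric vector.
countLocalMaxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(0L)
  sum(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n])
}

# Centerline voxel index matrix for a straight z-aligned tube at physical
# (x0, y0) in a cube of side n (spacing 1, origin 0), trimmed at both ends.
zTubeCenterline <- function(n, x0, y0, trim = 4L) {
  k <- (trim + 1L):(n - trim)
  cbind(rep(x0 + 1L, length(k)), rep(y0 + 1L, length(k)), k)
}
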