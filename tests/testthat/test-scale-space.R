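test_that("smoothing preserves constants and derivatives annihilate them", {
  v <- Volume(array(7, c(12, 10, 9)))
  for (s in c(0.8, 2, 5)) {
    expect_lt(max(abs(voxelData(gaussianSmooth(v, GaussianProbe(s))) - 7)),
              1e-10)
  }
  for (orders in list(c(1, 0, 0), c(0, 2, 0), c(1, 1, 0), c(0, 0, 2))) {
    out <- gaussianDerivative(v, GaussianProbe(2), orders)
    expect_lt(max(abs(voxelData(out))), 1e-10)
  }
})

test_that("an impulse smooths to the analytically sampled 3D Gaussian", {
  n <- 33L
  v <- Volume(array(0, c(n, n, n)))
  v@data[17, 17, 17] <- 1
  s <- gaussianSmooth(v, GaussianProbe(2))
  centre <- (2 * pi * 4)^(-3 / 2)
  expect_equal(voxelData(s)[17, 17, 17], centre, tolerance = 2e-4)
  # off-centre samples match the separable analytic profile
  for (off in list(c(3, 0, 0), c(2, 2, 1))) {
    expected <- prod(analyticGaussDeriv(off, 2, 0L) * sqrt(2 * pi) * 2) *
      centre
    got <- voxelData(s)[17 + off[1], 17 + off[2], 17 + off[3]]
    expect_equal(got, expected, tolerance = 5e-4)
  }
})

test_that("separable compiled convolution matches a dense naive oracle", {
  set.seed(42)
  arr <- array(rnorm(11 * 9 * 8), c(11, 9, 8))
  v <- Volume(arr)
  probe <- GaussianProbe(1.5)
  kx <- tubularity:::gaussianKernel1d(1.5, 0L, 4)
  ky <- tubularity:::gaussianKernel1d(1.5, 2L, 4)
  kz <- tubularity:::gaussianKernel1d(1.5, 1L, 4)
  got <- voxelData(gaussianDerivative(v, probe, c(0, 2, 1))) / 1.5^3
  for (at in list(c(6, 5, 4), c(1, 1, 1), c(11, 9, 8), c(2, 7, 3))) {
    expect_equal(got[at[1], at[2], at[3]],
                 denseConvAt(arr, kx, ky, kz, at), tolerance = 1e-12)
  }
})

test_that("ridge second-derivative response matches the closed form", {
  # profile A exp(-x^2 / 2 sigma_obj^2) extended along y and z
  sobj <- 5; A <- 2; n <- 81L
  x <- seq_len(n) - 41
  prof <- A * exp(-x^2 / (2 * sobj^2))
  v <- Volume(array(rep(prof, times = 15 * 15), c(n, 15, 15)))
  for (sp in c(2, 4, 6)) {
    for (gam in c(0.75, 1)) {
      r <- gaussianDerivative(v, GaussianProbe(sp, gamma = gam), c(2, 0, 0))
      t0 <- sobj^2; t <- sp^2
      expected <- -sp^(2 * gam) * A * sqrt(t0 / (t0 + t)) / (t0 + t)
      expect_equal(voxelData(r)[41, 8, 8], expected, tolerance = 5e-3)
    }
  }
})

test_that("normalized response peaks when the probe matches the object size", {
  # maximizing t^gamma (t0 + t)^(-3/2) for gamma = 3/4 gives t = t0
  sobj <- 5; n <- 81L
  x <- seq_len(n) - 41
  v <- Volume(array(rep(exp(-x^2 / (2 * sobj^2)), times = 9 * 9), c(n, 9, 9)))
  probes <- seq(1, 15, by = 0.5)
  resp <- vapply(probes, function(sp) {
    abs(voxelData(gaussianDerivative(v, GaussianProbe(sp, gamma = 0.75),
                                     c(2, 0, 0)))[41, 5, 5])
  }, numeric(1))
  expect_equal(probes[which.max(resp)], sobj)
})

test_that("heavy smoothing erases fine structure but keeps coarse structure", {
  n <- 160L
  x <- seq_len(n)
  fine <- exp(-(x - 40)^2 / (2 * 2^2))       # size-2 structure
  mid <- exp(-(x - 110)^2 / (2 * 10^2))      # size-10 structure
  coarse <- x / n                             # size ~ n ramp
  v <- Volume(array(rep(fine + mid + coarse, times = 24 * 24), c(n, 24, 24)))
  s <- gaussianSmooth(v, GaussianProbe(40))
  contrast <- function(a, centre)
    a[centre, 12, 12] - (a[centre - 8, 12, 12] + a[centre + 8, 12, 12]) / 2
  c0 <- contrast(voxelData(v), 40L)
  c1 <- contrast(voxelData(s), 40L)
  expect_lt(abs(c1 / c0), 0.01)
  # the coarse ramp survives essentially unchanged in the interior
  expect_gt(voxelData(s)[120, 12, 12] - voxelData(s)[60, 12, 12], 0.25)
})

test_that("smoothing obeys the Gaussian semigroup law", {
  v <- smoothRandomVolume(c(24, 24, 24), seed = 7)
  p1 <- GaussianProbe(2, truncation = 8)
  p2 <- GaussianProbe(3, truncation = 8)
  p12 <- GaussianProbe(sqrt(2^2 + 3^2), truncation = 8)
  twice <- gaussianSmooth(gaussianSmooth(v, p1), p2)
  once <- gaussianSmooth(v, p12)
  i <- 7:18
  a <- voxelData(twice)[i, i, i]; b <- voxelData(once)[i, i, i]
  expect_lt(max(abs(a - b) / (abs(b) + 1e-3)), 1e-6)
})

test_that("derivative and smoothing operators commute", {
  v <- smoothRandomVolume(c(22, 22, 22), seed = 11)
  pd <- GaussianProbe(1.8)
  ps <- GaussianProbe(2.5)
  a <- gaussianDerivative(gaussianSmooth(v, ps), pd, c(0, 2, 0))
  b <- gaussianSmooth(gaussianDerivative(v, pd, c(0, 2, 0)), ps)
  i <- 6:17
  expect_lt(max(abs(voxelData(a)[i, i, i] - voxelData(b)[i, i, i])), 1e-8)
})

test_that("smoothing and derivatives are linear operators", {
  set.seed(3)
  d <- c(14, 12, 10)
  v1 <- Volume(array(rnorm(prod(d)), d))
  v2 <- Volume(array(rnorm(prod(d)), d))
  comb <- Volume(2.5 * voxelData(v1) - 1.3 * voxelData(v2))
  for (orders in list(c(0, 0, 0), c(2, 0, 0), c(1, 0, 1))) {
    probe <- GaussianProbe(1.7)
    lhs <- voxelData(gaussianDerivative(comb, probe, orders))
    rhs <- 2.5 * voxelData(gaussianDerivative(v1, probe, orders)) -
      1.3 * voxelData(gaussianDerivative(v2, probe, orders))
    expect_lt(max(abs(lhs - rhs)), 1e-10)
  }
})

test_that("smoothing creates no new extrema in 1D profiles", {
  for (seed in 1:5) {
    set.seed(seed)
    v <- Volume(array(rnorm(200), c(200, 1, 1)))
    counts <- vapply(c(1, 2, 4, 8), function(s) {
      countLocalMaxima(as.vector(voxelData(gaussianSmooth(v, GaussianProbe(s)))))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("invalid scale-space parameters are rejected", {
  v <- Volume(array(1, c(4, 4, 4)))
  expect_error(GaussianProbe(-1), "positive")
  expect_error(GaussianProbe(0), "positive")
  expect_error(gaussianDerivative(v, GaussianProbe(1), c(-1, 0, 0)),
               "non-negative")
  expect_error(Volume(array(numeric(0), c(0, 1, 1))), "non-empty|>= 1")
  expect_error(Volume(array(c(1, NA), c(2, 1, 1))), "finite")
})
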