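test_that("gaussian tubes have the stated radial profile", {
  n <- 32L
  tube <- makeTube(c(n, n, n), rbind(c(16, 16, 0), c(16, 16, n - 1)),
                   sigma = 4, amplitude = 3)
  dat <- voxelData(tube)
  expect_equal(max(dat), 3)                      # on-axis voxels reach A
  expect_true(all(abs(dat[17, 17, ] - 3) < 1e-12))
  expect_equal(dat[17 + 4, 17, 10], 3 * exp(-1 / 2), tolerance = 1e-12)
  expect_equal(dat[17, 17 - 4, 10], 3 * exp(-1 / 2), tolerance = 1e-12)
})

test_that("bar tubes are exactly two-valued with total width 2 sigma = 10", {
  n <- 32L
  tube <- makeTube(c(n, n, n), rbind(c(16, 16, 0), c(16, 16, n - 1)),
                   profile = "bar", halfWidth = 5, amplitude = 2)
  vals <- sort(unique(as.vector(voxelData(tube))))
  expect_identical(vals, c(0, 2))
  prof <- voxelData(tube)[, 17, 16]
  expect_identical(sum(prof > 0), 11L)           # 2 * 5 + 1 voxels across
})

test_that("out-of-grid centerlines warn and are clipped", {
  expect_warning(makeTube(c(16L, 16L, 16L), rbind(c(8, 8, -10), c(8, 8, 40)),
                          sigma = 2), "clipped")
})

test_that("polynomial backgrounds evaluate per axis in [0,1] coordinates", {
  bg <- makePolynomialBackground(c(8L, 8L, 8L), list(x = 4.5))
  expect_true(all(voxelData(bg) == 4.5))
  ramp <- makePolynomialBackground(c(16L, 8L, 8L), list(x = c(0, 100)))
  expect_equal(voxelData(ramp)[16, 4, 4] - voxelData(ramp)[1, 4, 4], 100)
  quad <- makePolynomialBackground(c(9L, 9L, 9L),
                                   list(x = c(1, 0, 2), z = c(0, -1)))
  u <- (0:8) / 8
  expect_equal(voxelData(quad)[, 5, 3], 1 + 2 * u^2 - u[3], tolerance = 1e-12)
  expect_error(makePolynomialBackground(c(8L, 8L, 8L),
                                        list(x = rep(1, 5))), "degree")
})

test_that("a tube over a ramp yields a monotone baseline with a bump", {
  ph <- makeParallelTubePhantom(seed = 1, shape = c(48L, 48L, 48L),
                                sigmas = c(2, 2, 2), noiseSd = 0,
                                background = list(x = c(0, 400)))
  profile <- voxelData(ph$degraded)[, 18, 24]    # crosses the first tube
  baseline <- voxelData(ph$degraded)[, 40, 24]   # off-tube line
  expect_true(all(diff(baseline) >= -1e-9))      # monotone ramp
  bump <- profile - baseline
  expect_gt(max(bump), 900)                      # tube bump rides on top
  expect_lt(max(abs(bump[c(1:4, 45:48)])), 60)   # and decays off-axis
})

test_that("gaussian noise has the requested moments and is reproducible", {
  z <- Volume(array(0, c(100L, 100L, 100L)))
  a <- addGaussianNoise(z, 0, 100, seed = 11)
  expect_lt(abs(mean(voxelData(a))), 0.5)
  expect_lt(abs(sd(voxelData(a)) - 100), 0.5)
  b <- addGaussianNoise(z, 0, 100, seed = 11)
  expect_identical(voxelData(a), voxelData(b))
  d <- addGaussianNoise(z, 0, 100, seed = 12)
  expect_lt(abs(cor(as.vector(voxelData(a)), as.vector(voxelData(d)))), 0.01)
  expect_identical(addGaussianNoise(z, 0, 0), z)  # sd = 0 is the identity
})

test_that("noise draws do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- rnorm(1)
  set.seed(123)
  invisible(addGaussianNoise(Volume(array(0, c(4, 4, 4))), 0, 1, seed = 99))
  expect_identical(rnorm(1), before)
})

test_that("three-tube phantom separates cleanly into ideal plus noise", {
  # widths scaled to the 48^3 grid so neighbouring tubes do not overlap
  ph <- makeThreeTubePhantom(seed = 2, shape = c(48L, 48L, 48L),
                             sigmas = c(1.5, 2.5, 4))
  resid <- voxelData(ph$degraded) - voxelData(ph$ideal)
  expect_lt(abs(sd(resid) - ph$noiseSdNormalized) / ph$noiseSdNormalized,
            0.01)
  expect_lt(abs(mean(resid)), 5 * ph$noiseSdNormalized / sqrt(48^3))
  expect_identical(mse(ph$ideal, ph$ideal), 0)
  expect_equal(max(voxelData(ph$ideal)), 1, tolerance = 0.01)  # range ~ 1
  # ground truth: centerline voxels lie inside the mask and score intensity A
  expect_true(all(ph$mask[ph$centerlineIdx]))
  expect_true(all(voxelData(ph$ideal)[ph$centerlineIdx] > 0.99))
})

test_that("phantom composition is additive and order-independent", {
  shape <- c(24L, 24L, 24L)
  spec <- new("PhantomSpec", shape = shape, spacing = c(1, 1, 1),
              tubes = list(list(centerline = rbind(c(12, 12, 0), c(12, 12, 23)),
                                profile = "gaussian", sigma = 2,
                                amplitude = 10)),
              distractors = list(list(kind = "blob", position = c(6, 18, 12),
                                      size = 2, amplitude = 7)),
              background = list(x = c(1, 2)),
              noise = list(mean = 0, sd = 3, seed = 5L))
  ph <- generatePhantom(spec)
  manual <- voxelData(makeTube(shape, rbind(c(12, 12, 0), c(12, 12, 23)),
                               sigma = 2, amplitude = 10)) +
    voxelData(makeBlob(shape, c(6, 18, 12), size = 2, amplitude = 7)) +
    voxelData(makePolynomialBackground(shape, list(x = c(1, 2))))
  expect_equal(voxelData(ph$ideal), manual, tolerance = 1e-14)
  noise <- voxelData(addGaussianNoise(Volume(array(0, shape)), 0, 3,
                                      seed = 5L))
  expect_equal(voxelData(ph$degraded), manual + noise, tolerance = 1e-14)
  # regenerating from the same spec is bit-identical
  ph2 <- generatePhantom(spec)
  expect_identical(voxelData(ph$degraded), voxelData(ph2$degraded))
})

test_that("phantom specs round-trip through plain-text YAML", {
  spec <- new("PhantomSpec", shape = c(20L, 20L, 20L), spacing = c(1, 1, 2),
              tubes = list(list(centerline = rbind(c(10, 10, 0), c(10, 10, 38)),
                                profile = "gaussian", sigma = 2.5,
                                amplitude = 100)),
              background = list(y = c(0, 10)),
              noise = list(mean = 0, sd = 25, seed = 9L))
  path <- withr::local_tempfile(fileext = ".yaml")
  writePhantomSpec(spec, path)
  spec2 <- readPhantomSpec(path)
  expect_identical(voxelData(generatePhantom(spec)$degraded),
                   voxelData(generatePhantom(spec2)$degraded))
})
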