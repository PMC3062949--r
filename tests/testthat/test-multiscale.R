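test_that("scale lists follow the arithmetic and geometric stepping rules", {
  sc <- makeScales(ScaleSpec(1, 30, 20, "logarithmic"))
  expect_length(sc, 20)
  expect_equal(sc[1], 1)
  expect_equal(sc[20], 30)
  ratios <- sc[-1] / sc[-20]
  expect_equal(ratios, rep(30^(1 / 19), 19), tolerance = 1e-12)
  # geometric spacing emphasizes finer scales
  expect_gt(sum(sc < 15.5), sum(sc > 15.5))

  lin <- makeScales(ScaleSpec(2, 10, 5, "linear"))
  expect_equal(lin, c(2, 4, 6, 8, 10))
  expect_equal(makeScales(ScaleSpec(5, 5, 1, "linear")), 5)
  expect_error(ScaleSpec(10, 1, 5), "sigmaMax")
  expect_error(ScaleSpec(1, 10, 0), "nSteps")
})

test_that("a single-scale sweep reproduces the per-scale measure", {
  ph <- makeCurvedTubePhantom(seed = 5, shape = c(24L, 24L, 24L), noiseSd = 25)
  spec <- ScaleSpec(2, 2, 1)
  params <- ObjectnessParams(c = 50)
  r <- multiscaleObjectness(ph$degraded, spec, params)
  eig <- eigenSym3(hessianAtScale(ph$degraded, GaussianProbe(2)))
  direct <- frangiVesselness(eig$l1, eig$l2, eig$l3, params)
  expect_equal(voxelData(responseVolume(r)), direct, tolerance = 1e-14)
  expect_true(all(voxelData(bestScaleVolume(r)) == 2))
})

test_that("adding a scale never decreases any voxel's response", {
  ph <- makeCurvedTubePhantom(seed = 6, shape = c(24L, 24L, 24L), noiseSd = 25)
  params <- ObjectnessParams(c = 50)
  r3 <- multiscaleObjectness(ph$degraded, ScaleSpec(1, 4, 3), params)
  r4 <- multiscaleObjectness(ph$degraded, ScaleSpec(1, 4, 3), params)
  # same list plus one interior scale, evaluated through the numeric interface
  sc <- makeScales(ScaleSpec(1, 4, 3))
  perScale <- function(scales) {
    best <- array(0, dim(ph$degraded))
    for (s in scales) {
      eig <- eigenSym3(hessianAtScale(ph$degraded, GaussianProbe(s)))
      best <- pmax(best, frangiVesselness(eig$l1, eig$l2, eig$l3, params))
    }
    best
  }
  expect_true(all(perScale(c(sc, 3)) - perScale(sc) >= 0))
  expect_equal(perScale(sc), voxelData(responseVolume(r3)), tolerance = 1e-14)
  expect_equal(voxelData(responseVolume(r3)), voxelData(responseVolume(r4)))
})

test_that("responses commute with axis permutation of the scene", {
  n <- 28L
  tube <- makeTube(c(n, n, n), rbind(c(14, 12, 2), c(14, 12, n - 3)),
                   sigma = 2.5, amplitude = 100)
  perm <- Volume(aperm(voxelData(tube), c(3, 1, 2)))   # z -> x
  spec <- ScaleSpec(1.5, 4, 4)
  params <- ObjectnessParams(c = 10)
  r1 <- voxelData(responseVolume(multiscaleObjectness(tube, spec, params)))
  r2 <- voxelData(responseVolume(multiscaleObjectness(perm, spec, params)))
  expect_lt(max(abs(aperm(r1, c(3, 1, 2)) - r2)), 1e-12)
})

test_that("in-plane 45-degree rotation changes centerline response by < 5%", {
  n <- 48L
  axisTube <- makeTube(c(n, n, n), rbind(c(24, 24, 0), c(24, 24, n - 1)),
                       sigma = 2.5, amplitude = 100)
  diagTube <- makeTube(c(n, n, n), rbind(c(8, 8, 0), c(39, 39, n - 1)) ,
                       sigma = 2.5, amplitude = 100)
  # the diagonal tube runs at 45 degrees in the x-y plane over z
  spec <- ScaleSpec(1.5, 5, 6)
  params <- ObjectnessParams(c = 12)
  rA <- voxelData(responseVolume(multiscaleObjectness(axisTube, spec, params)))
  rD <- voxelData(responseVolume(multiscaleObjectness(diagTube, spec, params)))
  clA <- zTubeCenterline(n, 24, 24, trim = 10L)
  mA <- mean(rA[clA])
  # sample the diagonal centerline at integer voxels
  t <- seq(0.25, 0.75, length.out = 20)
  clD <- cbind(round(8 + t * 31) + 1, round(8 + t * 31) + 1,
               round(t * (n - 1)) + 1)
  mD <- mean(rD[clD])
  expect_lt(abs(mA - mD) / mA, 0.05)
})

test_that("best scale tracks the tube width on the centerline", {
  n <- 48L
  tube <- makeTube(c(n, n, n), rbind(c(24, 24, 0), c(24, 24, n - 1)),
                   sigma = 3, amplitude = 100)
  spec <- ScaleSpec(1, 10, 12, "logarithmic")
  sc <- makeScales(spec)
  # c at half the maximum Frobenius norm keeps the energy factor informative
  # on a noise-free phantom (on the centerline the shape ratios are flat in
  # scale, so scale discrimination comes through S)
  smax <- 0
  for (s in sc) {
    eig <- eigenSym3(hessianAtScale(tube, GaussianProbe(s)))
    smax <- max(smax, sqrt(max(eig$l1^2 + eig$l2^2 + eig$l3^2)))
  }
  r <- multiscaleObjectness(tube, spec, ObjectnessParams(c = smax / 2))
  cl <- zTubeCenterline(n, 24, 24)
  bs <- voxelData(bestScaleVolume(r))[cl]
  step <- sc[2] / sc[1]
  expect_true(all(bs / 3 <= step & 3 / bs <= step))
})

test_that("automatic mode derives c before sweeping and records it", {
  ph <- makeCurvedTubePhantom(seed = 7, shape = c(24L, 24L, 24L), noiseSd = 25)
  spec <- ScaleSpec(1, 4, 4)
  r <- multiscaleObjectness(ph$degraded, spec, ObjectnessParams())
  expect_equal(noiseCutoff(r), autoC(ph$degraded, makeScales(spec)))
  expect_identical(r@cMode, "automatic")
  # constant input aborts before the sweep
  expect_error(multiscaleObjectness(Volume(array(1, c(8, 8, 8))), spec,
                                    ObjectnessParams()), "degenerate")
})
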