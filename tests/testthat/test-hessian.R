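test_that("Hessian of a constant volume is zero in all six components", {
  hf <- hessianAtScale(Volume(array(3, c(10, 10, 10))), GaussianProbe(2))
  for (comp in c("ixx", "iyy", "izz", "ixy", "ixz", "iyz"))
    expect_lt(max(abs(slot(hf, comp))), 1e-10)
})

test_that("mixed Hessian components are computed once and shared", {
  v <- smoothRandomVolume(c(12, 12, 12), seed = 5)
  hf <- hessianAtScale(v, GaussianProbe(1.5))
  # the stored ixy is exactly the (1,1,0) derivative: one grid serves both
  # symmetric positions of the matrix
  expect_identical(hf@ixy,
                   voxelData(gaussianDerivative(v, GaussianProbe(1.5),
                                                c(1, 1, 0))))
})

test_that("tube Hessian: axis eigenvector and transverse negative curvature", {
  n <- 40L
  tube <- makeTube(c(n, n, n), rbind(c(20, 20, 0), c(20, 20, n - 1)),
                   sigma = 3, amplitude = 100)
  eig <- eigenSym3(hessianAtScale(tube, GaussianProbe(3)), vectors = TRUE)
  cl <- zTubeCenterline(n, 20, 20)
  lin <- (cl[, 3] - 1) * n * n + (cl[, 2] - 1) * n + cl[, 1]
  expect_true(all(abs(eig$e1[lin, 3]) > 0.99))   # e1 along the z axis
  expect_true(all(eig$l2[cl] < 0))
  expect_true(all(eig$l3[cl] < 0))
  # near-degenerate transverse pair for an axially symmetric tube
  expect_lt(max(abs(eig$l2[cl] - eig$l3[cl]) / abs(eig$l3[cl])), 1e-6)
})

test_that("eigenvalues are magnitude-ordered with signed tie-breaks", {
  e <- eigenSym3(diag(c(-3, 1, -0.5)))
  expect_equal(c(e$l1, e$l2, e$l3), c(-0.5, 1, -3))
  e <- eigenSym3(diag(c(1, 1, 1)))
  expect_equal(c(e$l1, e$l2, e$l3), c(1, 1, 1))
  # |.|-ties broken by ascending signed value
  e <- eigenSym3(diag(c(2, -2, 1)))
  expect_equal(c(e$l1, e$l2, e$l3), c(1, -2, 2))
})

test_that("compiled eigen-solver matches dense eigen() on random matrices", {
  set.seed(99)
  worstVal <- 0; worstRes <- 0
  for (i in 1:1000) {
    m <- matrix(rnorm(9), 3); m <- (m + t(m)) / 2
    e <- eigenSym3(m, vectors = TRUE)
    got <- sort(c(e$l1, e$l2, e$l3))
    ref <- sort(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
    worstVal <- max(worstVal, max(abs(got - ref)))
    for (k in 1:3) {
      lam <- c(e$l1, e$l2, e$l3)[k]
      vec <- list(e$e1, e$e2, e$e3)[[k]]
      worstRes <- max(worstRes, sqrt(sum((m %*% vec - lam * vec)^2)))
    }
  }
  expect_lt(worstVal, 1e-10)
  expect_lt(worstRes, 1e-8)
})

test_that("non-finite Hessian input raises an error naming the voxel", {
  v <- smoothRandomVolume(c(6, 6, 6), seed = 2)
  hf <- hessianAtScale(v, GaussianProbe(1))
  hf@ixx[2, 3, 4] <- NaN
  expect_error(eigenSym3(hf), "voxel")
})

test_that("Laplacian equals the Hessian trace and the eigenvalue sum", {
  v <- smoothRandomVolume(c(16, 16, 16), seed = 13)
  probe <- GaussianProbe(2)
  lap <- voxelData(laplacianField(v, probe))
  hf <- hessianAtScale(v, probe)
  expect_lt(max(abs(lap - (hf@ixx + hf@iyy + hf@izz))), 1e-12)
  eig <- eigenSym3(hf)
  expect_lt(max(abs(lap - (eig$l1 + eig$l2 + eig$l3))), 1e-8)
  expect_lt(max(abs(voxelData(laplacianField(Volume(array(5, c(8, 8, 8))),
                                             probe)))), 1e-10)
})

test_that("autoC is the maximum Laplacian over scales divided by the divisor", {
  ph <- makeCurvedTubePhantom(seed = 3, shape = c(32L, 32L, 32L), noiseSd = 25)
  scales <- c(1, 2, 4)
  lapMax <- max(vapply(scales, function(s)
    max(voxelData(laplacianField(ph$degraded, GaussianProbe(s)))), numeric(1)))
  expect_equal(autoC(ph$degraded, scales), lapMax / 10)
  expect_equal(autoC(ph$degraded, scales, divisor = 4), lapMax / 4)
  # first-scale mode uses only the smallest scale
  lap1 <- max(voxelData(laplacianField(ph$degraded, GaussianProbe(1))))
  expect_equal(autoC(ph$degraded, scales, mode = "first-scale"), lap1 / 10)
})

test_that("autoC is intensity-equivariant and translation-invariant", {
  ph <- makeCurvedTubePhantom(seed = 4, shape = c(32L, 32L, 32L), noiseSd = 25)
  scales <- c(1, 2, 4)
  c1 <- autoC(ph$degraded, scales)
  scaled <- Volume(voxelData(ph$degraded) * 3.7)
  expect_equal(autoC(scaled, scales), 3.7 * c1, tolerance = 1e-12)
  # integer shift of an interior structure leaves the max untouched
  n <- 40L
  blob <- makeBlob(c(n, n, n), c(16, 18, 20), size = 2.5, amplitude = 50)
  shifted <- makeBlob(c(n, n, n), c(19, 21, 23), size = 2.5, amplitude = 50)
  expect_equal(autoC(blob, scales), autoC(shifted, scales), tolerance = 1e-12)
})

test_that("autoC refuses degenerate volumes instead of returning c = 0", {
  expect_error(autoC(Volume(array(5, c(8, 8, 8))), c(1, 2)), "degenerate")
  expect_error(autoC(Volume(array(0, c(8, 8, 8))), c(1, 2)), "degenerate")
})
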