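test_that("attenuation scaling follows the power law and composes", {
  m <- constantMaps(4, IT = 0.25, phi = 0.3, r = 0.5)
  out <- scaleAttenuation(m, 2)
  expect_equal(transmittance(out)[1, 1], 0.0625, tolerance = 1e-12)
  expect_equal(direction(out), direction(m))
  expect_equal(retardation(out), retardation(m))
  # gamma 1 is the identity; gamma 2 then 0.5 composes to the identity
  expect_equal(transmittance(scaleAttenuation(m, 1)), transmittance(m))
  back <- scaleAttenuation(scaleAttenuation(m, 2), 0.5)
  expect_equal(transmittance(back), transmittance(m), tolerance = 1e-12)
  expect_error(scaleAttenuation(m, -1), "positive")
})

test_that("thickness scaling transforms retardation through the sine", {
  m <- constantMaps(4, IT = 0.5, phi = 0.3, r = sin(pi / 4))
  out <- scaleThickness(m, 2)
  expect_equal(retardation(out)[1, 1], 1, tolerance = 1e-12)
  expect_equal(transmittance(out)[1, 1], 0.25, tolerance = 1e-12)
  # past the principal branch the magnitude is taken: r = 1 doubles to 0
  m2 <- constantMaps(2, IT = 0.5, phi = 0.1, r = 1)
  expect_equal(retardation(scaleThickness(m2, 2))[1, 1], 0,
               tolerance = 1e-12)
  expect_equal(retardation(scaleThickness(m, 1)), retardation(m))
  expect_error(scaleThickness(m, 0), "positive")
})

test_that("resampling uses the transmittance-weighted complex average", {
  # two pixels with orthogonal directions cancel destructively
  m <- PLIMaps(matrix(1, 1, 2), matrix(c(0, pi / 2), 1, 2),
               matrix(1, 1, 2))
  W <- matrix(c(0.5, 0.5), 1, 2)
  out <- resampleMaps(m, W, outDim = c(1, 1))
  expect_equal(retardation(out)[1, 1], 0, tolerance = 1e-12)
  expect_equal(transmittance(out)[1, 1], 1)
  # equal directions are a fixed point
  m2 <- PLIMaps(matrix(1, 1, 2), matrix(0, 1, 2), matrix(1, 1, 2))
  out2 <- resampleMaps(m2, W, outDim = c(1, 1))
  expect_equal(retardation(out2)[1, 1], 1, tolerance = 1e-12)
  expect_equal(direction(out2)[1, 1], 0, tolerance = 1e-12)
  # a delta stencil copies its source pixel
  m3 <- randomMaps(3, seed = 2)
  W3 <- matrix(0, 9, 9); W3[cbind(1:9, 1:9)] <- 1
  out3 <- resampleMaps(m3, W3)
  expect_equal(transmittance(out3), transmittance(m3))
  expect_lt(max(angDiff(direction(out3), direction(m3))), 1e-9)
  # r never exceeds the maximum input retardation
  set.seed(3)
  W4 <- matrix(runif(18), 2, 9); W4 <- W4 / rowSums(W4)
  out4 <- resampleMaps(m3, W4, outDim = c(1, 2))
  expect_lte(max(retardation(out4)), max(retardation(m3)) + 1e-12)
})

test_that("direction correction agrees with the closed form for rotations", {
  expect_equal(correctDirection(matrix(pi / 6, 1, 1),
                                rotationMatrix(pi / 4))[1, 1],
               pi / 6 + pi / 4, tolerance = 1e-12)
  set.seed(4)
  for (i in 1:1000) {
    th <- runif(1, -pi, pi)
    phi <- matrix(runif(1, 0, pi), 1, 1)
    viaJac <- correctDirection(phi, rotationMatrix(th))
    closed <- wrapDirection(phi + th)
    expect_lt(angDiff(viaJac, closed)[1, 1], 1e-9)
  }
  # horizontal flip: 30 deg -> 150 deg (brute-force vector push)
  expect_equal(correctDirection(matrix(pi / 6, 1, 1), diag(c(-1, 1)))[1, 1],
               150 * pi / 180, tolerance = 1e-12)
  expect_equal(correctDirection(matrix(0.7, 1, 1), diag(2))[1, 1], 0.7)
  expect_error(correctDirection(matrix(0, 1, 1), matrix(0, 2, 2)),
               "singular")
})

test_that("affine augmentation rotates grid and directions together", {
  M <- matrix(runif(81), 9, 9)
  pm <- PLIMaps(M, matrix(0, 9, 9), matrix(0.8, 9, 9))
  rot <- affineAugment(pm, rotationMatrix(pi / 2))
  expect_true(all(abs(direction(rot) - pi / 2) < 1e-9))
  # 90 degrees about the center is an exact grid permutation:
  # output[r, c] = input[n + 1 - c, r]
  n <- 9
  expected <- matrix(0, n, n)
  for (r in 1:n) for (c in 1:n) expected[r, c] <- M[n + 1 - c, r]
  expect_equal(transmittance(rot), expected, tolerance = 1e-9)
  # identity transform is exact
  idm <- affineAugment(pm, diag(2))
  expect_equal(transmittance(idm), M, tolerance = 1e-12)
  expect_error(affineAugment(pm, matrix(0, 2, 2)), "degenerate")
})

test_that("rotation equivariance holds for the channel encoding", {
  # rotating the maps then encoding equals encoding then rotating the
  # channel grid with the phi-doubling phase shift
  maps <- randomMaps(9, seed = 8)
  th <- pi / 2
  rot <- affineAugment(maps, rotationMatrix(th))
  encRot <- channelEncode(rot)
  enc <- channelEncode(maps)
  n <- 9
  rotGrid <- function(M) {
    out <- matrix(0, n, n)
    for (r in 1:n) for (c in 1:n) out[r, c] <- M[n + 1 - c, r]
    out
  }
  z <- (enc[, , 2] + 1i * enc[, , 3]) * exp(2i * th)
  expect_equal(encRot[, , 1], rotGrid(enc[, , 1]), tolerance = 1e-9)
  expect_equal(encRot[, , 2], rotGrid(Re(z)), tolerance = 1e-9)
  expect_equal(encRot[, , 3], rotGrid(Im(z)), tolerance = 1e-9)
})

test_that("flips mirror the grid and reflect directions", {
  maps <- randomMaps(8, seed = 6)
  fx <- flipAugment(maps, "x")
  expect_equal(transmittance(fx), transmittance(maps)[, 8:1])
  expect_lt(max(angDiff(direction(fx), pi - direction(maps)[, 8:1])), 1e-9)
  fy <- flipAugment(maps, "y")
  expect_equal(transmittance(fy), transmittance(maps)[8:1, ])
  # flipping twice is the identity
  expect_equal(transmittance(flipAugment(fx, "x")), transmittance(maps))
  expect_lt(max(angDiff(direction(flipAugment(fx, "x")), direction(maps))),
            1e-9)
})

test_that("gaussian blur has exact constant fixed points and sigma-0 identity", {
  m <- constantMaps(12, IT = 0.7, phi = 0.9, r = 0.6)
  out <- gaussianBlurMaps(m, 1.5)
  expect_equal(transmittance(out), transmittance(m), tolerance = 1e-12)
  expect_equal(retardation(out), retardation(m), tolerance = 1e-12)
  expect_lt(max(angDiff(direction(out), direction(m))), 1e-9)
  m2 <- randomMaps(12, seed = 3)
  expect_identical(gaussianBlurMaps(m2, 0), m2)
  # blurring reduces spatial variance of transmittance
  b <- gaussianBlurMaps(m2, 2)
  expect_lt(var(as.vector(transmittance(b))),
            var(as.vector(transmittance(m2))))
  expect_error(gaussianBlurMaps(m2, -1), "non-negative")
})

test_that("augmentations preserve parameter-map invariants", {
  set.seed(10)
  for (i in 1:15) {
    maps <- randomMaps(20, seed = 100 + i)
    out <- randomPolicyApply(maps, augmentationPolicy(cropPx = 12L))
    expect_true(all(retardation(out) >= 0 & retardation(out) <= 1))
    expect_true(all(direction(out) >= 0 & direction(out) < pi))
    expect_true(all(transmittance(out) >= 0))
    expect_identical(dim(retardation(out)), c(12L, 12L))
  }
})

test_that("degenerate policy reduces to a center crop and seeds reproduce", {
  maps <- randomMaps(20, seed = 12)
  pol <- augmentationPolicy(gammaALog2Range = c(0, 0),
                            gammaTLog2Range = c(0, 0),
                            scaleRange = c(1, 1), rotationRange = c(0, 0),
                            shearRange = c(0, 0), flipProb = 0,
                            blurProb = 0, cropPx = 12L)
  out <- randomPolicyApply(maps, pol)
  ref <- centerCrop(maps, 12L)
  expect_equal(transmittance(out), transmittance(ref), tolerance = 1e-12)
  expect_lt(max(angDiff(direction(out), direction(ref))), 1e-9)
  # fixed seed gives bit-identical draws
  p2 <- augmentationPolicy(cropPx = 12L)
  a <- randomPolicyApply(maps, p2, seed = 99)
  b <- randomPolicyApply(maps, p2, seed = 99)
  expect_identical(transmittance(a), transmittance(b))
  expect_identical(direction(a), direction(b))
})

test_that("policies validate their ranges and serialize to YAML", {
  expect_error(augmentationPolicy(flipProb = 2), "probabilities")
  expect_error(augmentationPolicy(scaleRange = c(2, 1)), "well-ordered")
  pol <- augmentationPolicy(blurSigmaRange = c(0.5, 1.5), cropPx = 64L)
  path <- tempfile(fileext = ".yaml")
  writePolicy(pol, path)
  expect_equal(readPolicy(path), pol)
})
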