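test_that("encoder output dimension scales with the width fraction", {
  enc8 <- buildEncoder(encoderConfig(widthFraction = 1 / 8), seed = 1)
  expect_equal(enc8$featureDim, 256L)
  x <- array(rnorm(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  f <- PLItexture:::.encoderFwd(enc8, x)$features
  expect_identical(dim(f), c(2L, 256L))
  # quarter width: 4 * round(512 / 4) = 512
  enc4 <- buildEncoder(encoderConfig(widthFraction = 1 / 4), seed = 1)
  expect_equal(enc4$featureDim, 512L)
  expect_error(buildEncoder(encoderConfig(widthFraction = -1)), "positive")
})

test_that("full-width encoder produces 2048 features", {
  enc <- buildEncoder(encoderConfig(widthFraction = 1), seed = 1)
  expect_equal(enc$featureDim, 2048L)
  x <- array(rnorm(32 * 32 * 3), c(32, 32, 3, 1))
  expect_identical(dim(PLItexture:::.encoderFwd(enc, x)$features),
                   c(1L, 2048L))
})

naiveInfoNCE <- function(z, tau) {
  # brute-force double-loop reference
  u <- z / sqrt(rowSums(z^2))
  n2 <- nrow(u); N <- n2 / 2
  S <- matrix(0, n2, n2)
  for (i in 1:n2) for (k in 1:n2) S[i, k] <- sum(u[i, ] * u[k, ]) / tau
  tot <- 0
  for (i in 1:N) {
    j <- i + N
    for (pr in list(c(i, j), c(j, i))) {
      den <- 0
      for (k in setdiff(1:n2, pr[1])) den <- den + exp(S[pr[1], k])
      tot <- tot - log(exp(S[pr[1], pr[2]]) / den)
    }
  }
  tot / n2
}

test_that("InfoNCE matches the brute-force double loop", {
  set.seed(21)
  for (N in c(2, 5, 17, 32)) {
    z <- matrix(rnorm(2 * N * 8), 2 * N)
    expect_lt(abs(infoNCELoss(z, 0.5)$loss - naiveInfoNCE(z, 0.5)), 1e-6)
    expect_lt(abs(infoNCELoss(z, 0.07)$loss - naiveInfoNCE(z, 0.07)), 1e-6)
  }
  expect_error(infoNCELoss(matrix(0, 2, 3)), "zero-norm")
})

test_that("InfoNCE has the analytic degenerate values", {
  # a single pair has no negatives: loss is exactly zero
  z <- matrix(rnorm(2 * 6), 2)
  expect_equal(infoNCELoss(z, 0.5)$loss, 0)
  # two identical pairs with orthogonal negatives: closed form
  z2 <- rbind(c(1, 0), c(0, 1), c(1, 0), c(0, 1))
  expect_equal(infoNCELoss(z2, 0.5)$loss, log(1 + 2 * exp(-2)),
               tolerance = 1e-12)
})

test_that("InfoNCE is invariant to common rotation and batch permutation", {
  set.seed(22)
  N <- 8
  z <- matrix(rnorm(2 * N * 6), 2 * N)
  base <- infoNCELoss(z, 0.5)$loss
  # random orthogonal rotation of all projections
  Q <- qr.Q(qr(matrix(rnorm(36), 6)))
  expect_equal(infoNCELoss(z %*% Q, 0.5)$loss, base, tolerance = 1e-9)
  # permuting pair order (keeping partners aligned)
  perm <- sample(N)
  zp <- z[c(perm, perm + N), ]
  expect_equal(infoNCELoss(zp, 0.5)$loss, base, tolerance = 1e-9)
})

test_that("InfoNCE gradient matches finite differences", {
  set.seed(23)
  z <- matrix(rnorm(8 * 4), 8)
  g <- infoNCELoss(z, 0.5, grad = TRUE)$dz
  eps <- 1e-6
  for (idx in sample(length(z), 6)) {
    zp <- z; zp[idx] <- zp[idx] + eps
    zm <- z; zm[idx] <- zm[idx] - eps
    num <- (infoNCELoss(zp, 0.5)$loss - infoNCELoss(zm, 0.5)$loss) / (2 * eps)
    expect_equal(g[idx], num, tolerance = 1e-4)
  }
})

test_that("encoder layer gradients agree with finite differences", {
  set.seed(24)
  # a tiny convolution + batch norm stack checked end to end
  x <- array(rnorm(6 * 6 * 2 * 3), c(6, 6, 2, 3))
  lay <- PLItexture:::.convLayer(2L, 3L, 3L, 1L, 1L)
  bn <- PLItexture:::.bnLayer(3L)
  lossOf <- function(W) {
    l2 <- lay; l2$W <- W
    y <- PLItexture:::.convFwd(l2, x)
    b <- PLItexture:::.bnFwd(bn, y, TRUE)
    sum(pmax(b$y, 0)^2) / 2
  }
  y <- PLItexture:::.convFwd(lay, x)
  b <- PLItexture:::.bnFwd(bn, y, TRUE)
  r <- pmax(b$y, 0)
  dy <- r * (b$y > 0)
  dim(dy) <- dim(y)
  bb <- PLItexture:::.cpp_bn_backward(y, dy, bn$gamma, b$mean, b$var, bn$eps)
  cb <- PLItexture:::.convBwd(lay, x, bb$dx)
  eps <- 1e-5
  for (idx in sample(length(lay$W), 5)) {
    Wp <- lay$W; Wp[idx] <- Wp[idx] + eps
    Wm <- lay$W; Wm[idx] <- Wm[idx] - eps
    num <- (lossOf(Wp) - lossOf(Wm)) / (2 * eps)
    expect_equal(cb$dW[idx], num, tolerance = 1e-3)
  }
})

test_that("feature-map inference produces the documented grid geometry", {
  enc <- buildEncoder(encoderConfig(widthFraction = 1 / 16), seed = 2)
  maps <- randomMaps(96, seed = 31)
  fm <- inferFeatureMap(enc, maps, tilePx = 32L, stridePx = 16L)
  # floor((96 - 32) / 16) + 1 = 5
  expect_identical(dim(featureArray(fm))[1:2], c(5L, 5L))
  expect_equal(dim(featureArray(fm))[3], enc$featureDim)
  # tile-sized section gives a single cell
  fm1 <- inferFeatureMap(enc, randomMaps(32, seed = 32), tilePx = 32L)
  expect_identical(dim(featureArray(fm1))[1:2], c(1L, 1L))
  expect_error(inferFeatureMap(enc, randomMaps(16, seed = 33),
                               tilePx = 32L), "tile")
  # identical sections give identical feature maps (deterministic, no aug)
  fm2 <- inferFeatureMap(enc, maps, tilePx = 32L, stridePx = 16L)
  expect_identical(featureArray(fm), featureArray(fm2))
  # background tiles are flagged by the modal mask rule
  msk <- matrix(0L, 96, 96); msk[1:40, 1:96] <- 1L
  fm3 <- inferFeatureMap(enc, maps, tilePx = 32L, stridePx = 16L, mask = msk)
  expect_true(fm3@foreground[1, 1])
  expect_false(fm3@foreground[5, 1])
})

test_that("short contrastive training reduces the loss on a phantom", {
  ph <- testPhantom(seed = 41)
  pol <- augmentationPolicy(cropPx = 16L, blurSigmaRange = c(0, 1))
  cfg <- encoderConfig(batchPairs = 16L, standardizationBatches = 4L)
  mod <- trainContrastive(ph, cfg, mode = "cl3d", radiusUm = 40,
                          patchPx = 24L, policy = pol, steps = 30L,
                          seed = 5)
  expect_equal(nrow(mod$log), 30L)
  expect_true(all(is.finite(mod$log$loss)))
  first <- mean(mod$log$loss[1:8])
  last <- mean(tail(mod$log$loss, 8))
  expect_lt(last, first)
  # reproducible under the same seed
  mod2 <- trainContrastive(ph, cfg, mode = "cl3d", radiusUm = 40,
                           patchPx = 24L, policy = pol, steps = 3L,
                           seed = 5)
  expect_equal(mod2$log$loss, mod$log$loss[1:3], tolerance = 1e-12)
})

test_that("identical views without augmentation sit near the loss floor", {
  ph <- testPhantom(seed = 42)
  polId <- augmentationPolicy(gammaALog2Range = c(0, 0),
                              gammaTLog2Range = c(0, 0),
                              scaleRange = c(1, 1), rotationRange = c(0, 0),
                              shearRange = c(0, 0), flipProb = 0,
                              blurProb = 0, cropPx = 16L)
  cfg <- encoderConfig(batchPairs = 16L, standardizationBatches = 2L)
  same <- trainContrastive(ph, cfg, mode = "same", patchPx = 24L,
                           policy = polId, steps = 8L, seed = 6)
  hard <- trainContrastive(ph, cfg, mode = "cl3d", radiusUm = 40,
                           patchPx = 24L, policy = augmentationPolicy(
                             cropPx = 16L), steps = 8L, seed = 6)
  # identical positives make the objective easier from the start
  expect_lt(mean(same$log$loss), mean(hard$log$loss))
})

test_that("welford standardization matches two-pass statistics", {
  set.seed(43)
  st <- list(count = 0, mean = numeric(3), m2 = numeric(3), frozen = FALSE)
  xs <- lapply(1:5, function(i) array(rnorm(8 * 8 * 3 * 4, mean = i),
                                      c(8, 8, 3, 4)))
  for (x in xs) st <- PLItexture:::.welfordMerge(st, x)
  allm <- do.call(rbind, lapply(xs, function(x)
    matrix(aperm(x, c(1, 2, 4, 3)), 8 * 8 * 4, 3)))
  expect_equal(st$mean, colMeans(allm), tolerance = 1e-9)
  expect_equal(sqrt(st$m2 / st$count),
               apply(allm, 2, function(v) sqrt(mean((v - mean(v))^2))),
               tolerance = 1e-9)
})
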