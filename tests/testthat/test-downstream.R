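test_that("PCA reduction reports valid explained-variance structure", {
  set.seed(61)
  X <- matrix(rnorm(500 * 6), 500)
  out <- pcaReduce(X, 6, seed = 2)
  expect_equal(sum(out$explainedVariance), 1, tolerance = 1e-9)
  expect_true(all(diff(out$explainedVariance) <= 1e-12))
  # isotropic data spreads variance nearly equally
  expect_lt(max(out$explainedVariance) / min(out$explainedVariance), 1.6)
  # rank-1 data concentrates in the first component
  v <- rnorm(6)
  X1 <- outer(rnorm(200), v)
  out1 <- pcaReduce(X1, 2, seed = 2)
  expect_equal(out1$explainedVariance[1], 1, tolerance = 1e-9)
  expect_error(pcaReduce(X, 7), "dimension")
})

test_that("feature-map smoothing is a proper renormalized Gaussian", {
  arr <- array(rnorm(9 * 9 * 2), c(9, 9, 2))
  fm <- PLIFeatureMap(arr, 16L, 8L)
  expect_identical(featureArray(smoothFeatureMap(fm, 0)), arr)
  # constant channels are exact fixed points
  arr2 <- array(3.5, c(9, 9, 1))
  fmc <- PLIFeatureMap(arr2, 16L, 8L)
  expect_equal(featureArray(smoothFeatureMap(fmc, 2)), arr2,
               tolerance = 1e-12)
  # an impulse spreads into the sampled, renormalized Gaussian kernel
  imp <- array(0, c(11, 11, 1)); imp[6, 6, 1] <- 1
  fmi <- PLIFeatureMap(imp, 16L, 8L)
  sm <- featureArray(smoothFeatureMap(fmi, 1))[, , 1]
  # independent oracle: the impulse response is the outer product of the
  # documented 1D stencil (4-sigma truncation, renormalized at borders)
  wAt6 <- vapply(1:11, function(i) {
    j <- max(1, i - 4):min(11, i + 4)
    w <- exp(-((j - i)^2) / 2)
    if (6 %in% j) w[j == 6] / sum(w) else 0
  }, numeric(1))
  expect_equal(sm, outer(wAt6, wAt6), tolerance = 1e-9)
  expect_error(smoothFeatureMap(fmi, -1), "non-negative")
})

test_that("two-step clustering recovers well-separated mixtures", {
  set.seed(62)
  n <- 900
  centers <- rbind(c(0, 0, 0), c(8, 0, 0), c(0, 8, 8))
  lab <- sample(1:3, n, replace = TRUE)
  X <- centers[lab, ] + matrix(rnorm(n * 3, sd = 0.5), n)
  res <- twoStepCluster(X, k = 24L, subset = 600L, Ks = 2:6, seed = 3)
  cut3 <- cutLabels(res, 3L)
  # adjusted Rand index against the ground truth must be near-perfect
  ari <- function(a, b) {
    tab <- table(a, b)
    sij <- sum(choose(tab, 2)); si <- sum(choose(rowSums(tab), 2))
    sj <- sum(choose(colSums(tab), 2)); sn <- choose(length(a), 2)
    exp_ <- si * sj / sn
    (sij - exp_) / ((si + sj) / 2 - exp_)
  }
  expect_gt(ari(cut3, lab), 0.95)
  # silhouette curve bounded in [-1, 1] and maximal at the true K
  sil <- res@silhouette
  expect_true(all(abs(sil$score) <= 1, na.rm = TRUE))
  expect_equal(sil$K[which.max(sil$score)], 3L)
  # K = 1 cut collapses everything; fixed seeds reproduce centroids
  expect_true(all(cutLabels(res, 1L) == 1L))
  res2 <- twoStepCluster(X, k = 24L, subset = 600L, Ks = 2:6, seed = 3)
  expect_identical(res@centroids, res2@centroids)
  expect_error(twoStepCluster(X, k = 1000L, subset = 600L), "subset")
})

test_that("cross-section IoU follows set arithmetic", {
  a <- matrix(1L, 4, 6)
  expect_equal(as.numeric(crossSectionIoU(list(a, a))), 1)
  b <- matrix(2L, 4, 6)
  expect_equal(as.numeric(crossSectionIoU(list(a, b))), 0)
  # two half-overlapping strips: each cluster overlaps half its union
  s1 <- matrix(1L, 4, 6); s1[, 4:6] <- 2L
  s2 <- matrix(1L, 4, 6); s2[, 2:4] <- 2L
  # cluster 1: A = cols 1-3, B = cols 1 and 5-6 -> intersect 1, union 5
  # cluster 2: A = cols 4-6, B = cols 2-4 -> intersect 1 col, union 5
  got <- as.numeric(crossSectionIoU(list(s1, s2)))
  expect_equal(got, mean(c(4 / 20, 4 / 20)), tolerance = 1e-12)
  # symmetry in the pair order
  expect_equal(as.numeric(crossSectionIoU(list(s2, s1))), got)
  # foreground restriction
  fg <- matrix(TRUE, 4, 6); fg[, 5:6] <- FALSE
  expect_true(as.numeric(crossSectionIoU(list(s1, s2), list(fg, fg))) >= 0)
  expect_error(crossSectionIoU(list(a)), "two sections")
})

test_that("linear probe saturates on separable classes and nulls on noise", {
  set.seed(63)
  n <- 120
  y <- rep(1:2, each = n / 2)
  X <- cbind(ifelse(y == 1, -3, 3) + rnorm(n, sd = 0.3), rnorm(n))
  pr <- linearProbe(X, y, X, y, nPerClass = 2L, repeats = 10L, seed = 4)
  expect_equal(pr$meanF1, 1, tolerance = 1e-9)
  expect_true(all(pr$seF1 >= 0))
  # shuffled labels give chance-level macro F1 (about 1/C)
  ysh <- sample(y)
  prs <- linearProbe(X, ysh, X, sample(y), nPerClass = 20L, repeats = 15L,
                     seed = 5)
  expect_lt(abs(prs$meanF1 - 0.5), 0.2)
  expect_error(linearProbe(X, rep(1, n), X, rep(1, n), 2L), "two classes")
  expect_error(linearProbe(X, y, X, y, nPerClass = 1000L), "fewer")
})

test_that("probe standard error shrinks as repeats accumulate", {
  set.seed(64)
  n <- 200
  y <- rep(1:2, each = n / 2)
  X <- cbind(ifelse(y == 1, -1, 1) + rnorm(n, sd = 1.5), rnorm(n))
  few <- linearProbe(X, y, X, y, nPerClass = 5L, repeats = 8L, seed = 6)
  many <- linearProbe(X, y, X, y, nPerClass = 5L, repeats = 64L, seed = 6)
  expect_lt(many$seF1, few$seF1)
})

test_that("ridge morphology regression matches the linear-limit cases", {
  set.seed(65)
  n <- 400; d <- 5
  X <- matrix(rnorm(n * d), n)
  w <- rnorm(d)
  y <- as.vector(X %*% w) + 2
  # noiseless linear target, vanishing penalty: R^2 -> 1
  r2 <- morphologyRegression(X, y, l2 = 1e-8, nTrain = 200L, nTest = 200L,
                             seed = 7)
  expect_gt(r2[["target"]], 0.999)
  # independent target: R^2 near zero (may be slightly negative)
  r2n <- morphologyRegression(X, rnorm(n), l2 = 10, nTrain = 200L,
                              nTest = 200L, seed = 7)
  expect_lt(abs(r2n[["target"]]), 0.15)
  # training-data R^2 is non-increasing in the penalty
  trainR2 <- vapply(c(1e-6, 1, 1e2, 1e4), function(l2) {
    mu <- colMeans(X); Z <- sweep(X, 2, mu)
    A <- crossprod(Z) + l2 * diag(d)
    wfit <- solve(A, crossprod(Z, y - mean(y)))
    pred <- as.vector(Z %*% wfit) + mean(y)
    1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  }, numeric(1))
  expect_true(all(diff(trainR2) <= 1e-9))
  expect_error(morphologyRegression(X, rep(1, n)), "zero-variance")
})

test_that("RBF retrieval has the closed-form affinity profile", {
  X <- rbind(c(0, 0), c(3.5 * sqrt(2), 0), c(1, 1))
  aff <- rbfRetrieval(X, queryIdx = 1L, sigma = 3.5)
  expect_equal(aff[1], 1)
  expect_equal(aff[2], exp(-1), tolerance = 1e-12)
  expect_true(all(aff > 0 & aff <= 1))
  expect_error(rbfRetrieval(X, integer(0)), "query")
  expect_error(rbfRetrieval(X, 1L, fg = c(FALSE, TRUE, TRUE)), "foreground")
})

test_that("retrieval ranks same-region texture above other regions", {
  # phantom retrieval protocol: per-section feature maps, z-scored,
  # PCA-reduced, smoothed on the grid, then RBF affinity to a handful of
  # queries in the rare crossing-fiber region
  ph <- makePhantom(phantomSpec(height = 160L, width = 160L,
                                nSections = 3L, driftAmpPx = 1.5,
                                jitterRotDeg = 2, jitterTransPx = 1,
                                shotNoiseSd = 0), seed = 66)
  S <- 3L; tile <- 24L; stride <- 12L
  fms <- lapply(seq_len(S), function(z)
    classicFeatureMap(sections(ph)[[z]], "combined", tilePx = tile,
                      stridePx = stride, mask = masks(ph)[[z]], section = z))
  gd <- dim(featureArray(fms[[1]]))[1:2]
  X <- do.call(rbind, lapply(fms, function(fm)
    matrix(featureArray(fm), prod(gd))))
  modalLab <- function(z) {
    rows <- seq(1L, 160L - tile + 1L, stride)
    cols <- seq(1L, 160L - tile + 1L, stride)
    out <- matrix(0L, length(rows), length(cols))
    for (i in seq_along(rows)) for (j in seq_along(cols)) {
      v <- regionLabels(ph)[[z]][rows[i]:(rows[i] + tile - 1L),
                                 cols[j]:(cols[j] + tile - 1L)]
      out[i, j] <- which.max(tabulate(v + 1L)) - 1L
    }
    out
  }
  labs <- unlist(lapply(seq_len(S), function(z) as.vector(modalLab(z))))
  Z <- scale(X); Z[!is.finite(Z)] <- 0
  red <- pcaReduce(Z, 20, seed = 8)
  smX <- do.call(rbind, lapply(seq_len(S), function(z) {
    fm <- PLIFeatureMap(array(
      red$scores[((z - 1) * prod(gd) + 1):(z * prod(gd)), ], c(gd, 20)),
      tile, stride)
    matrix(featureArray(smoothFeatureMap(fm, 1)), prod(gd))
  }))
  target <- 4L
  idx <- which(labs == target)
  qs <- idx[1:6]
  aff <- rbfRetrieval(smX, qs, sigma = 3.5)
  pos <- aff[setdiff(idx, qs)]
  neg <- aff[labs != target & labs > 0]
  auc <- mean(outer(pos, neg, ">")) + 0.5 * mean(outer(pos, neg, "=="))
  expect_gt(auc, 0.9)
})
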