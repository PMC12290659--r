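#' Downstream evaluation of texture features
#'
#' PCA component maps, feature-map smoothing, two-step clustering with
#' silhouette curves and cross-section IoU, linear probing with minimal
#' labels, ridge regression of cortical morphology, and RBF-kernel
#' retrieval.
#'
#' @name downstream
NULL

#' PCA reduction fitted on a random voxel subset
#'
#' Principal components are estimated on a seeded random subset of feature
#' vectors and applied to all rows. Explained-variance ratios (relative to
#' the total variance of the subset) are returned in non-increasing order.
#'
#' @param X numeric matrix (n x d) of feature vectors.
#' @param nComponents number of components to keep (<= d).
#' @param subset maximum subset size used to fit the components.
#' @param seed RNG seed for the subset draw.
#' @return list with \code{scores} (n x nComponents), \code{rotation},
#'   \code{center} and \code{explainedVariance} (ratios, length
#'   nComponents).
#' @export
pcaReduce <- function(X, nComponents, subset = 1e6, seed = 1L) {
  d <- ncol(X)
  if (nComponents > d) stop("nComponents exceeds feature dimension")
  set.seed(seed)
  idx <- if (nrow(X) > subset) sample.int(nrow(X), subset) else seq_len(nrow(X))
  fit <- prcomp(X[idx, , drop = FALSE], center = TRUE, scale. = FALSE)
  ev <- fit$sdev^2
  ratio <- ev / sum(ev)
  scores <- sweep(X, 2, fit$center) %*% fit$rotation[, seq_len(nComponents),
                                                     drop = FALSE]
  list(scores = scores, rotation = fit$rotation[, seq_len(nComponents),
                                                drop = FALSE],
       center = fit$center, explainedVariance = ratio[seq_len(nComponents)])
}

#' In-plane Gaussian smoothing of a feature map
#'
#' Channel-wise separable Gaussian smoothing of the tile grid (stencils
#' renormalized at the grid border, so constant channels are fixed
#' points); sigma is measured in grid cells and sigma = 0 is the identity.
#'
#' @param fm a \linkS4class{PLIFeatureMap}.
#' @param sigma Gaussian standard deviation in grid cells.
#' @return smoothed \linkS4class{PLIFeatureMap}.
#' @export
smoothFeatureMap <- function(fm, sigma) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (sigma == 0) return(fm)
  f <- fm@features
  d <- dim(f)
  Kr <- .gaussWeights1d(d[1], sigma); Kc <- .gaussWeights1d(d[2], sigma)
  for (ch in seq_len(d[3]))
    f[, , ch] <- Kr %*% f[, , ch] %*% t(Kc)
  PLIFeatureMap(f, tilePx = fm@tilePx, stridePx = fm@stridePx,
                section = fm@section, foreground = fm@foreground,
                schema = fm@schema, pixelSize = fm@pixelSize)
}

#' Two-step clustering: k-means then Ward agglomeration of centroids
#'
#' k-means with \code{k} clusters is fitted on a seeded random subset; all
#' points are assigned to their nearest centroid; the centroids are then
#' agglomerated with Ward linkage on Euclidean distances, giving a
#' dendrogram that can be cut at any K <= k. Mean silhouette widths for
#' the requested cut sizes are computed on a capped subsample of the
#' k-means subset (silhouette cost is quadratic in the sample).
#'
#' @param X numeric matrix (n x d).
#' @param k number of k-means clusters (default 128).
#' @param subset k-means subset size (default 100000).
#' @param Ks cut sizes for the silhouette curve.
#' @param silhouetteMax cap on the silhouette subsample size.
#' @param seed RNG seed.
#' @return a \linkS4class{PLIClusterResult}.
#' @export
twoStepCluster <- function(X, k = 128L, subset = 100000L, Ks = 2:20,
                           silhouetteMax = 2000L, seed = 1L) {
  n <- nrow(X)
  if (k > min(subset, n)) stop("k exceeds the available subset")
  set.seed(seed)
  idx <- if (n > subset) sample.int(n, subset) else seq_len(n)
  km <- kmeans(X[idx, , drop = FALSE], centers = k, iter.max = 100L,
               nstart = 1L)
  assignments <- .nearestCentroid(X, km$centers)
  hc <- hclust(dist(km$centers), method = "ward.D2")
  Ks <- Ks[Ks >= 2L & Ks <= k]
  sidx <- if (length(idx) > silhouetteMax)
    idx[sample.int(length(idx), silhouetteMax)] else idx
  dmat <- dist(X[sidx, , drop = FALSE])
  sil <- vapply(Ks, function(K) {
    lab <- cutree(hc, K)[assignments[sidx]]
    if (length(unique(lab)) < 2L) return(NA_real_)
    mean(cluster::silhouette(lab, dmat)[, 3])
  }, numeric(1))
  new("PLIClusterResult", centroids = km$centers,
      assignments = as.integer(assignments), linkage = hc,
      silhouette = data.frame(K = Ks, score = sil),
      subsetIdx = as.integer(idx))
}

.nearestCentroid <- function(X, centers, block = 20000L) {
  n <- nrow(X)
  out <- integer(n)
  cn <- rowSums(centers^2)
  i <- 1L
  while (i <= n) {
    j <- min(i + block - 1L, n)
    D <- -2 * X[i:j, , drop = FALSE] %*% t(centers)
    D <- sweep(D, 2, cn, "+")
    out[i:j] <- max.col(-D, ties.method = "first")
    i <- j + 1L
  }
  out
}

#' Cluster labels at a dendrogram cut of K clusters
#' @param result a \linkS4class{PLIClusterResult}.
#' @param K number of clusters (<= number of centroids).
#' @return integer labels in 1..K for every assigned point.
#' @export
cutLabels <- function(result, K) {
  if (K < 1L || K > nrow(result@centroids)) stop("invalid cut size")
  if (K == 1L) return(rep(1L, length(result@assignments)))
  as.integer(cutree(result@linkage, K)[result@assignments])
}

#' Mean IoU of cluster assignments between neighboring sections
#'
#' For each adjacent section pair and each cluster present on foreground
#' pixels of either section, the intersection-over-union of the cluster's
#' pixel sets is computed at identical grid coordinates; cluster IoUs are
#' averaged per pair, then over pairs.
#'
#' @param labels list of integer label matrices (one per section, equal
#'   shapes) or a 3D array (sections first).
#' @param fg optional list of logical foreground matrices (default: all).
#' @return mean IoU in [0, 1]; per-pair means as attribute
#'   \code{"perPair"}.
#' @export
crossSectionIoU <- function(labels, fg = NULL) {
  if (is.array(labels) && length(dim(labels)) == 3L)
    labels <- lapply(seq_len(dim(labels)[1]), function(s) labels[s, , ])
  S <- length(labels)
  if (S < 2L) stop("need at least two sections")
  if (is.null(fg))
    fg <- lapply(labels, function(m) matrix(TRUE, nrow(m), ncol(m)))
  per <- numeric(S - 1L)
  for (s in seq_len(S - 1L)) {
    keep <- fg[[s]] & fg[[s + 1L]]
    if (!any(keep)) stop("no foreground overlap between sections")
    a <- labels[[s]][keep]; b <- labels[[s + 1L]][keep]
    cl <- sort(unique(c(a, b)))
    ious <- vapply(cl, function(cc) {
      ia <- a == cc; ib <- b == cc
      sum(ia & ib) / sum(ia | ib)
    }, numeric(1))
    per[s] <- mean(ious)
  }
  structure(mean(per), perPair = per)
}

.fitOvR <- function(X, y, classes, lambda = 1e-2) {
  # one-versus-rest ridge-regularized logistic regression (IRLS)
  d <- ncol(X)
  W <- matrix(0, length(classes), d + 1L)
  Xa <- cbind(1, X)
  for (ci in seq_along(classes)) {
    t <- as.numeric(y == classes[ci])
    w <- numeric(d + 1L)
    for (it in seq_len(25L)) {
      eta <- as.vector(Xa %*% w)
      p <- 1 / (1 + exp(-eta))
      g <- crossprod(Xa, p - t) + lambda * c(0, w[-1])
      r <- pmax(p * (1 - p), 1e-6)
      Hm <- crossprod(Xa * r, Xa) + lambda * diag(c(1e-8, rep(1, d)))
      step <- tryCatch(solve(Hm, g), error = function(e) NULL)
      if (is.null(step)) break
      w <- w - step
      if (max(abs(step)) < 1e-6) break
    }
    W[ci, ] <- w
  }
  W
}

.predictOvR <- function(W, X) {
  scores <- cbind(1, X) %*% t(W)
  max.col(scores, ties.method = "first")
}

#' Macro-averaged F1 score
#' @param pred,truth vectors of class labels.
#' @param classes label set to average over (default: union).
#' @return macro F1 in [0, 1].
#' @export
macroF1 <- function(pred, truth, classes = sort(unique(c(pred, truth)))) {
  f1 <- vapply(classes, function(cc) {
    tp <- sum(pred == cc & truth == cc)
    fp <- sum(pred == cc & truth != cc)
    fn <- sum(pred != cc & truth == cc)
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}

#' Linear evaluation of features with minimal labels
#'
#' For each entry of \code{nPerClass}, a one-versus-rest logistic
#' regression classifier is refitted \code{repeats} times on random
#' class-balanced training subsets and evaluated on the held-out set;
#' macro F1 mean and standard error over the refits are reported. The
#' caller supplies a train/test split (in the reference protocol the
#' split is by section identity).
#'
#' @param trainX,trainY training features and labels.
#' @param testX,testY held-out features and labels.
#' @param nPerClass vector of labeled-samples-per-class budgets.
#' @param repeats independent refits per budget (default 50).
#' @param seed RNG seed.
#' @return data.frame (class \code{"PLIProbeResult"}) with columns
#'   \code{n}, \code{meanF1}, \code{seF1}.
#' @export
linearProbe <- function(trainX, trainY, testX, testY,
                        nPerClass = c(30L), repeats = 50L, seed = 1L) {
  classes <- sort(unique(trainY))
  if (length(classes) < 2L) stop("need at least two classes")
  set.seed(seed)
  rows <- lapply(nPerClass, function(n) {
    if (any(table(factor(trainY, classes)) < n))
      stop("a class has fewer examples than requested per-class budget")
    f1s <- vapply(seq_len(repeats), function(r) {
      sel <- unlist(lapply(classes, function(cc)
        sample(which(trainY == cc), n)))
      W <- .fitOvR(trainX[sel, , drop = FALSE], trainY[sel], classes)
      pred <- classes[.predictOvR(W, testX)]
      macroF1(pred, testY, classes)
    }, numeric(1))
    data.frame(n = n, meanF1 = mean(f1s), seF1 = sd(f1s) / sqrt(repeats))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("PLIProbeResult", class(out))
  out
}

#' Ridge regression of morphological measures from features
#'
#' Features are z-score standardized on the training rows, a linear model
#' with L2 penalty \code{l2} is fitted by the closed-form normal
#' equations on \code{nTrain} seeded rows, and the coefficient of
#' determination R-squared is computed on \code{nTest} disjoint seeded
#' rows, per target.
#'
#' @param X feature matrix (n x d).
#' @param targets numeric vector or matrix/data.frame of target columns;
#'   rows with NA targets are dropped.
#' @param l2 ridge penalty (default 1e4).
#' @param nTrain,nTest train and test subset sizes (capped at the data).
#' @param seed RNG seed.
#' @return named numeric vector of test R-squared per target.
#' @export
morphologyRegression <- function(X, targets, l2 = 1e4, nTrain = 10000L,
                                 nTest = 10000L, seed = 1L) {
  if (is.null(dim(targets))) targets <- cbind(target = targets)
  targets <- as.matrix(targets)
  keep <- stats::complete.cases(targets)
  X <- X[keep, , drop = FALSE]; targets <- targets[keep, , drop = FALSE]
  n <- nrow(X)
  if (n < 4L) stop("not enough complete rows")
  set.seed(seed)
  idx <- sample.int(n)
  nTrain <- min(nTrain, floor(n / 2)); nTest <- min(nTest, n - nTrain)
  tr <- idx[seq_len(nTrain)]
  te <- idx[(nTrain + 1):(nTrain + nTest)]
  mu <- colMeans(X[tr, , drop = FALSE])
  sg <- apply(X[tr, , drop = FALSE], 2, sd)
  sg[sg < 1e-12] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sg, "/")
  out <- numeric(ncol(targets))
  names(out) <- colnames(targets)
  for (j in seq_len(ncol(targets))) {
    y <- targets[, j]
    if (sd(y[tr]) < 1e-12) stop("zero-variance target")
    ym <- mean(y[tr])
    A <- crossprod(Z[tr, , drop = FALSE]) + l2 * diag(ncol(Z))
    b <- crossprod(Z[tr, , drop = FALSE], y[tr] - ym)
    w <- solve(A, b)
    pred <- as.vector(Z[te, , drop = FALSE] %*% w) + ym
    ss_res <- sum((y[te] - pred)^2)
    ss_tot <- sum((y[te] - mean(y[te]))^2)
    out[j] <- 1 - ss_res / ss_tot
  }
  out
}

#' RBF-kernel retrieval of similar texture
#'
#' The query representation is the mean feature vector of the query rows;
#' each row's affinity is \eqn{\exp(-\|h - q\|^2 / (2\sigma^2))}. In the
#' reference protocol the features are PCA-reduced to 20 components and
#' smoothed with sigma = 2 grid cells before retrieval, and the kernel
#' width is 3.5.
#'
#' @param X feature matrix (n x d).
#' @param queryIdx row indices of the query examples.
#' @param sigma RBF kernel width (default 3.5).
#' @param fg optional logical vector; queries must be foreground.
#' @return numeric affinity vector in (0, 1], length n.
#' @export
rbfRetrieval <- function(X, queryIdx, sigma = 3.5, fg = NULL) {
  if (!length(queryIdx)) stop("need at least one query")
  if (!is.null(fg) && !all(fg[queryIdx])) stop("queries must lie on foreground")
  q <- colMeans(X[queryIdx, , drop = FALSE])
  d2 <- rowSums(sweep(X, 2, q)^2)
  exp(-d2 / (2 * sigma^2))
}
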