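#' SimCLR-style contrastive training and sliding-window inference
#'
#' Training pairs are sampled on the fly from a section stack by spatial
#' context sampling, augmented, channel-encoded, standardized by running
#' statistics, passed through the residual encoder and projection head,
#' and optimized with the InfoNCE objective using Adam.
#'
#' @name contrastive
NULL

.welfordMerge <- function(state, x) {
  # x: (H, W, C, N); merge per-channel pixel statistics
  d <- dim(x)
  nB <- d[1] * d[2] * d[4]
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), nB, d[3])
  mB <- colMeans(xm)
  m2B <- colSums(sweep(xm, 2, mB)^2)
  if (state$count == 0) {
    state$mean <- mB; state$m2 <- m2B; state$count <- nB
  } else {
    delta <- mB - state$mean
    tot <- state$count + nB
    state$mean <- state$mean + delta * nB / tot
    state$m2 <- state$m2 + m2B + delta^2 * state$count * nB / tot
    state$count <- tot
  }
  state
}

.standardize <- function(x, norm) {
  if (norm$count == 0) return(x)
  sdv <- sqrt(norm$m2 / norm$count)
  sdv[sdv < 1e-8] <- 1
  d <- dim(x)
  for (c in seq_len(d[3]))
    x[, , c, ] <- (x[, , c, ] - norm$mean[c]) / sdv[c]
  x
}

.batchFromPairs <- function(stack, pairs, patchPx, policy, augment = TRUE) {
  n <- nrow(pairs)
  crop <- if (augment) policy$cropPx else patchPx
  x <- array(0, c(crop, crop, 3L, 2L * n))
  for (i in seq_len(n)) {
    pr <- extractPair(stack,
                      list(section = pairs$aSection[i], row = pairs$aRow[i],
                           col = pairs$aCol[i]),
                      list(section = pairs$pSection[i], row = pairs$pRow[i],
                           col = pairs$pCol[i]), patchPx = patchPx)
    a <- pr$anchor; p <- pr$positive
    if (augment) {
      a <- randomPolicyApply(a, policy)
      p <- randomPolicyApply(p, policy)
    }
    x[, , , i] <- channelEncode(a)
    x[, , , n + i] <- channelEncode(p)
  }
  x
}

#' Train the contrastive encoder on a section stack
#'
#' Runs SimCLR-style optimization: per step, \code{cfg$batchPairs} fresh
#' positive pairs are sampled by context sampling, both members augmented
#' and channel-encoded, inputs standardized by running mean/sd accumulated
#' over the first \code{cfg$standardizationBatches} batches (then frozen),
#' and encoder plus projection head updated by Adam on the InfoNCE loss.
#' Training aborts with an error if the loss becomes non-finite.
#'
#' @param stack a \linkS4class{PLIStack} (at least 2 sections for
#'   cross-section sampling modes).
#' @param cfg an \code{\link{encoderConfig}}.
#' @param mode,radiusUm context sampling mode and radius (micrometers).
#' @param patchPx anchor patch size in pixels before augmentation.
#' @param policy an \code{\link{augmentationPolicy}}; its \code{cropPx} is
#'   the network input size.
#' @param steps number of optimization steps.
#' @param trainSections,valSections section indices for training pairs and
#'   for the fixed held-out validation pair set (NULL disables validation).
#' @param valPairs,valInterval validation set size and evaluation interval.
#' @param seed RNG seed controlling weight init, sampling and augmentation.
#' @param model optionally continue training an existing
#'   \code{\link{buildEncoder}} model.
#' @param verbose print per-step losses.
#' @return a \code{"PLIEncoder"} with elements \code{log} (data.frame of
#'   step and training loss) and \code{valLog}.
#' @export
trainContrastive <- function(stack, cfg = encoderConfig(), mode = "cl3d",
                             radiusUm = 118, patchPx = 192L,
                             policy = augmentationPolicy(),
                             steps = 100L,
                             trainSections = seq_along(stack@sections),
                             valSections = NULL, valPairs = 32L,
                             valInterval = 25L, seed = 1L, model = NULL,
                             verbose = FALSE) {
  set.seed(seed)
  if (is.null(model)) model <- buildEncoder(cfg)
  cfg <- model$cfg
  opt <- list(lr = cfg$learningRate, wd = cfg$weightDecay,
              b1 = 0.9, b2 = 0.999, eps = 1e-8, t = 0)
  state <- .optimizerInit(model)
  valX <- NULL
  if (!is.null(valSections)) {
    vp <- samplePairs(stack, valPairs, mode = mode, radiusUm = radiusUm,
                      patchPx = patchPx, sections = valSections)
    valX <- .batchFromPairs(stack, vp, patchPx, policy)
  }
  log <- data.frame(step = integer(0), loss = numeric(0))
  valLog <- data.frame(step = integer(0), loss = numeric(0))
  batches <- 0L
  for (step in seq_len(steps)) {
    pairs <- samplePairs(stack, cfg$batchPairs, mode = mode,
                         radiusUm = radiusUm, patchPx = patchPx,
                         sections = trainSections)
    x <- .batchFromPairs(stack, pairs, patchPx, policy)
    if (!model$norm$frozen) {
      model$norm <- .welfordMerge(model$norm, x)
      batches <- batches + 1L
      if (batches >= cfg$standardizationBatches) model$norm$frozen <- TRUE
    }
    x <- .standardize(x, model$norm)
    fw <- .encoderFwd(model, x, training = TRUE, keepCache = TRUE)
    model <- .updateRunningStats(model, fw$cache)
    hd <- .headFwd(model$head, fw$features)
    ls <- infoNCELoss(hd$z, tau = cfg$temperature, grad = TRUE)
    if (!is.finite(ls$loss))
      stop(sprintf("training diverged at step %d (non-finite loss)", step))
    hb <- .headBwd(model$head, hd$cache, ls$dz)
    grads <- .encoderBwd(model, fw$cache, hb$dfeat)
    grads$head <- hb$grads
    opt$t <- opt$t + 1
    up <- .applyUpdates(model, grads, state, opt)
    model <- up$model; state <- up$state
    log <- rbind(log, data.frame(step = step, loss = ls$loss))
    if (verbose) message(sprintf("step %4d  loss %.4f", step, ls$loss))
    if (!is.null(valX) && (step %% valInterval == 0L || step == steps)) {
      vz <- .standardize(valX, model$norm)
      vf <- .encoderFwd(model, vz, training = FALSE)
      vh <- .headFwd(model$head, vf$features)
      vl <- infoNCELoss(vh$z, tau = cfg$temperature)$loss
      valLog <- rbind(valLog, data.frame(step = step, loss = vl))
    }
  }
  model$log <- log
  model$valLog <- valLog
  model
}

#' Encode a list of patches into feature vectors
#'
#' Applies channel encoding, the frozen input standardization and the
#' encoder (batch-norm in inference mode, no augmentation).
#'
#' @param model a \code{"PLIEncoder"}.
#' @param patches list of \linkS4class{PLIMaps}, all of one size.
#' @param batchSize forward-pass batch size.
#' @return numeric matrix (length(patches) x featureDim).
#' @export
encodePatches <- function(model, patches, batchSize = 64L) {
  n <- length(patches)
  out <- matrix(0, n, model$featureDim)
  i <- 1L
  while (i <= n) {
    j <- min(i + batchSize - 1L, n)
    d <- dim(transmittance(patches[[i]]))
    x <- array(0, c(d[1], d[2], 3L, j - i + 1L))
    for (k in i:j) x[, , , k - i + 1L] <- channelEncode(patches[[k]])
    x <- .standardize(x, model$norm)
    fw <- .encoderFwd(model, x, training = FALSE)
    out[i:j, ] <- fw$features
    i <- j + 1L
  }
  out
}

#' Sliding-window feature-map inference for one section
#'
#' Divides the parameter maps into tiles of \code{tilePx} pixels with
#' stride \code{stridePx} (default 50 percent overlap), extracts one
#' feature vector per tile with the trained encoder (no augmentation), and
#' assembles the grid into a \linkS4class{PLIFeatureMap}. If a mask is
#' given, each tile is flagged foreground when its modal mask value is
#' tissue.
#'
#' @param model a \code{"PLIEncoder"}.
#' @param maps a \linkS4class{PLIMaps} section (at least tile-sized).
#' @param tilePx,stridePx tile geometry in pixels.
#' @param mask optional integer mask matrix (0 = background).
#' @param section section index stored in the result.
#' @param batchSize forward-pass batch size.
#' @return a \linkS4class{PLIFeatureMap}.
#' @export
inferFeatureMap <- function(model, maps, tilePx = 128L,
                            stridePx = tilePx %/% 2L, mask = NULL,
                            section = 1L, batchSize = 64L) {
  d <- dim(transmittance(maps))
  if (d[1] < tilePx || d[2] < tilePx) stop("section smaller than one tile")
  rows <- seq(1L, d[1] - tilePx + 1L, by = stridePx)
  cols <- seq(1L, d[2] - tilePx + 1L, by = stridePx)
  grid <- expand.grid(rI = seq_along(rows), cI = seq_along(cols))
  patches <- vector("list", nrow(grid))
  fg <- matrix(TRUE, length(rows), length(cols))
  for (g in seq_len(nrow(grid))) {
    r <- rows[grid$rI[g]]; c <- cols[grid$cI[g]]
    ri <- r:(r + tilePx - 1L); ci <- c:(c + tilePx - 1L)
    patches[[g]] <- PLIMaps(maps@transmittance[ri, ci],
                            maps@direction[ri, ci],
                            maps@retardation[ri, ci],
                            pixelSize = maps@pixelSize, I0 = maps@I0)
    if (!is.null(mask)) {
      tb <- tabulate(mask[ri, ci] + 1L)
      fg[grid$rI[g], grid$cI[g]] <- (which.max(tb) - 1L) > 0L
    }
  }
  feats <- encodePatches(model, patches, batchSize = batchSize)
  arr <- array(0, c(length(rows), length(cols), model$featureDim))
  for (g in seq_len(nrow(grid)))
    arr[grid$rI[g], grid$cI[g], ] <- feats[g, ]
  PLIFeatureMap(arr, tilePx = tilePx, stridePx = stridePx,
                section = section, foreground = fg,
                pixelSize = pixelSize(maps))
}
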