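# Layer primitives over the C++ kernels. Activations are (H, W, C, N)
# arrays; conv weights (Cout x Cin*KH*KW), linear weights (out x in).

.convLayer <- function(cin, cout, k, stride = 1L, pad = 0L) {
  fanin <- cin * k * k
  list(type = "conv",
       W = matrix(rnorm(cout * fanin, 0, sqrt(2 / fanin)), cout, fanin),
       b = numeric(cout), k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad))
}

.bnLayer <- function(c) {
  list(type = "bn", gamma = rep(1, c), beta = numeric(c),
       rmean = numeric(c), rvar = rep(1, c), eps = 1e-5, momentum = 0.1)
}

.linearLayer <- function(cin, cout) {
  list(type = "linear",
       W = matrix(rnorm(cout * cin, 0, sqrt(2 / cin)), cout, cin),
       b = numeric(cout))
}

.convFwd <- function(layer, x) {
  .cpp_conv_forward(x, layer$W, layer$b, layer$k, layer$k,
                    layer$stride, layer$pad)
}

.convBwd <- function(layer, x, dy) {
  .cpp_conv_backward(x, layer$W, dy, layer$k, layer$k,
                     layer$stride, layer$pad)
}

.bnFwd <- function(layer, x, training) {
  out <- .cpp_bn_forward(x, layer$gamma, layer$beta, layer$eps, training,
                         layer$rmean, layer$rvar)
  out
}

.reluFwd <- function(x) .cpp_relu_forward(x)

.reluBwd <- function(y, dy) .cpp_relu_backward(y, dy)

.gapFwd <- function(x) {
  d <- dim(x)
  m <- colMeans(matrix(x, d[1] * d[2], d[3] * d[4]))
  matrix(m, d[4], d[3], byrow = TRUE)   # N x C
}

.gapBwd <- function(dy, xdim) {
  # dy: N x C -> broadcast back over the spatial plane
  plane <- xdim[1] * xdim[2]
  per <- t(dy) / plane                  # C x N
  dx <- rep(as.vector(per), each = plane)
  dim(dx) <- xdim
  dx
}

#' Encoder and training configuration
#'
#' Defaults mirror the reference training recipe: a 50-layer bottleneck
#' residual encoder with all channel widths scaled by 1/8 (giving
#' 256-dimensional pooled features), a 2-layer projection head with hidden
#' size 90 and output size 32, InfoNCE temperature 0.5, 512 positive pairs
#' per step, Adam with learning rate 1e-3 and weight decay 1e-6, and input
#' standardization by running statistics accumulated over the first 1024
#' batches and then frozen.
#'
#' @param widthFraction channel width multiplier of the residual encoder.
#' @param inputChannels input channels (3: transmittance and the two
#'   direction/retardation channels).
#' @param projectionHidden,projectionOut projection head sizes.
#' @param temperature InfoNCE temperature.
#' @param batchPairs positive pairs per training step (the desk-scale
#'   configuration uses 64).
#' @param learningRate,weightDecay Adam optimizer settings.
#' @param standardizationBatches batches over which input running
#'   statistics are accumulated before freezing.
#' @return list of class \code{"EncoderConfig"}.
#' @export
encoderConfig <- function(widthFraction = 1 / 8, inputChannels = 3L,
                          projectionHidden = 90L, projectionOut = 32L,
                          temperature = 0.5, batchPairs = 512L,
                          learningRate = 1e-3, weightDecay = 1e-6,
                          standardizationBatches = 1024L) {
  if (temperature <= 0) stop("temperature must be positive")
  if (widthFraction <= 0) stop("widthFraction must be positive")
  if (batchPairs < 1) stop("batchPairs must be positive")
  structure(list(widthFraction = widthFraction,
                 inputChannels = as.integer(inputChannels),
                 projectionHidden = as.integer(projectionHidden),
                 projectionOut = as.integer(projectionOut),
                 temperature = temperature,
                 batchPairs = as.integer(batchPairs),
                 learningRate = learningRate, weightDecay = weightDecay,
                 standardizationBatches = as.integer(standardizationBatches)),
            class = "EncoderConfig")
}

.bottleneckBlock <- function(cin, width, stride) {
  down <- NULL
  if (stride != 1L || cin != 4L * width)
    down <- list(conv = .convLayer(cin, 4L * width, 1L, stride, 0L),
                 bn = .bnLayer(4L * width))
  list(conv1 = .convLayer(cin, width, 1L, 1L, 0L), bn1 = .bnLayer(width),
       conv2 = .convLayer(width, width, 3L, stride, 1L), bn2 = .bnLayer(width),
       conv3 = .convLayer(width, 4L * width, 1L, 1L, 0L),
       bn3 = .bnLayer(4L * width), down = down)
}

#' Build the width-reduced 50-layer residual encoder
#'
#' Standard bottleneck residual topology (stem 7x7/2 convolution, 3x3/2
#' max pooling, stages of 3/4/6/3 bottleneck blocks with expansion 4,
#' global average pooling; the final fully connected layer is removed)
#' with every channel width multiplied by \code{widthFraction}. At the
#' default fraction 1/8 the pooled output has 256 dimensions; at fraction
#' 1 it has 2048.
#'
#' @param cfg an \code{\link{encoderConfig}}.
#' @param seed optional seed for weight initialization.
#' @return list of class \code{"PLIEncoder"} with the encoder, the
#'   projection head, the configuration and (initially unset)
#'   input-standardization statistics.
#' @export
buildEncoder <- function(cfg = encoderConfig(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  wf <- cfg$widthFraction
  widths <- pmax(1L, as.integer(round(c(64, 128, 256, 512) * wf)))
  stem <- pmax(1L, as.integer(round(64 * wf)))
  if (any(widths < 1L)) stop("widthFraction produces empty blocks")
  counts <- c(3L, 4L, 6L, 3L)
  stages <- vector("list", 4L)
  cin <- stem
  for (s in seq_len(4L)) {
    blocks <- vector("list", counts[s])
    for (bI in seq_len(counts[s])) {
      stride <- if (bI == 1L && s > 1L) 2L else 1L
      blocks[[bI]] <- .bottleneckBlock(cin, widths[s], stride)
      cin <- 4L * widths[s]
    }
    stages[[s]] <- blocks
  }
  featureDim <- 4L * widths[4L]
  head <- list(fc1 = .linearLayer(featureDim, cfg$projectionHidden),
               fc2 = .linearLayer(cfg$projectionHidden, cfg$projectionOut))
  net <- list(stemConv = .convLayer(cfg$inputChannels, stem, 7L, 2L, 3L),
              stemBn = .bnLayer(stem), stages = stages)
  structure(list(net = net, head = head, cfg = cfg,
                 featureDim = featureDim,
                 norm = list(count = 0, mean = numeric(cfg$inputChannels),
                             m2 = numeric(cfg$inputChannels),
                             frozen = FALSE)),
            class = "PLIEncoder")
}

#' @export
print.PLIEncoder <- function(x, ...) {
  cat(sprintf(
    "PLIEncoder: residual bottleneck encoder, width fraction %.4g, D = %d\n",
    x$cfg$widthFraction, x$featureDim))
  cat(sprintf("  projection head %d -> %d -> %d, temperature %.2f\n",
              x$featureDim, x$cfg$projectionHidden, x$cfg$projectionOut,
              x$cfg$temperature))
  invisible(x)
}

.blockFwd <- function(block, x, training) {
  cache <- list(x = x)
  o1 <- .convFwd(block$conv1, x)
  b1 <- .bnFwd(block$bn1, o1, training)
  r1 <- .reluFwd(b1$y)
  o2 <- .convFwd(block$conv2, r1)
  b2 <- .bnFwd(block$bn2, o2, training)
  r2 <- .reluFwd(b2$y)
  o3 <- .convFwd(block$conv3, r2)
  b3 <- .bnFwd(block$bn3, o3, training)
  if (is.null(block$down)) {
    skip <- x
    cache$dcache <- NULL
  } else {
    sd <- .convFwd(block$down$conv, x)
    sb <- .bnFwd(block$down$bn, sd, training)
    skip <- sb$y
    cache$dcache <- list(sd = sd, sb = sb)
  }
  y <- .reluFwd(b3$y + skip)
  cache <- c(cache, list(o1 = o1, b1 = b1, r1 = r1, o2 = o2, b2 = b2,
                         r2 = r2, o3 = o3, b3 = b3, y = y))
  cache
}

.blockBwd <- function(block, cache, dy) {
  dsum <- .reluBwd(cache$y, dy)
  g <- list()
  bb3 <- .cpp_bn_backward(cache$o3, dsum, block$bn3$gamma,
                          cache$b3$mean, cache$b3$var, block$bn3$eps)
  g$bn3 <- list(dgamma = bb3$dgamma, dbeta = bb3$dbeta)
  cb3 <- .convBwd(block$conv3, cache$r2, bb3$dx)
  g$conv3 <- list(dW = cb3$dW, db = cb3$db)
  dr2 <- .reluBwd(cache$r2, cb3$dx)
  bb2 <- .cpp_bn_backward(cache$o2, dr2, block$bn2$gamma,
                          cache$b2$mean, cache$b2$var, block$bn2$eps)
  g$bn2 <- list(dgamma = bb2$dgamma, dbeta = bb2$dbeta)
  cb2 <- .convBwd(block$conv2, cache$r1, bb2$dx)
  g$conv2 <- list(dW = cb2$dW, db = cb2$db)
  dr1 <- .reluBwd(cache$r1, cb2$dx)
  bb1 <- .cpp_bn_backward(cache$o1, dr1, block$bn1$gamma,
                          cache$b1$mean, cache$b1$var, block$bn1$eps)
  g$bn1 <- list(dgamma = bb1$dgamma, dbeta = bb1$dbeta)
  cb1 <- .convBwd(block$conv1, cache$x, bb1$dx)
  g$conv1 <- list(dW = cb1$dW, db = cb1$db)
  dx <- cb1$dx
  if (is.null(block$down)) {
    dx <- dx + dsum
    g$down <- NULL
  } else {
    db <- .cpp_bn_backward(cache$dcache$sd, dsum, block$down$bn$gamma,
                           cache$dcache$sb$mean, cache$dcache$sb$var,
                           block$down$bn$eps)
    cd <- .convBwd(block$down$conv, cache$x, db$dx)
    g$down <- list(conv = list(dW = cd$dW, db = cd$db),
                   bn = list(dgamma = db$dgamma, dbeta = db$dbeta))
    dx <- dx + cd$dx
  }
  list(dx = dx, grads = g)
}

.encoderFwd <- function(model, x, training = FALSE, keepCache = FALSE) {
  net <- model$net
  cache <- list(x = x)
  o0 <- .convFwd(net$stemConv, x)
  b0 <- .bnFwd(net$stemBn, o0, training)
  r0 <- .reluFwd(b0$y)
  mp <- .cpp_maxpool_forward(r0, 3L, 2L, 1L)
  cache$o0 <- o0; cache$b0 <- b0; cache$r0 <- r0; cache$mp <- mp
  h <- mp$y
  scache <- vector("list", 4L)
  for (s in seq_len(4L)) {
    bc <- vector("list", length(net$stages[[s]]))
    for (bI in seq_along(net$stages[[s]])) {
      bc[[bI]] <- .blockFwd(net$stages[[s]][[bI]], h, training)
      h <- bc[[bI]]$y
    }
    scache[[s]] <- bc
  }
  cache$stages <- scache
  cache$hdim <- dim(h)
  feat <- .gapFwd(h)                    # N x D
  if (!keepCache) cache <- list(hdim = dim(h))
  list(features = feat, cache = cache)
}

.encoderBwd <- function(model, cache, dfeat) {
  net <- model$net
  dh <- .gapBwd(dfeat, cache$hdim)
  g <- list(stages = vector("list", 4L))
  for (s in rev(seq_len(4L))) {
    nb <- length(net$stages[[s]])
    gb <- vector("list", nb)
    for (bI in rev(seq_len(nb))) {
      out <- .blockBwd(net$stages[[s]][[bI]], cache$stages[[s]][[bI]], dh)
      dh <- out$dx
      gb[[bI]] <- out$grads
    }
    g$stages[[s]] <- gb
  }
  dr0 <- .cpp_maxpool_backward(dh, cache$mp$argmax, dim(cache$r0))
  dr0 <- .reluBwd(cache$r0, dr0)
  bb0 <- .cpp_bn_backward(cache$o0, dr0, net$stemBn$gamma,
                          cache$b0$mean, cache$b0$var, net$stemBn$eps)
  g$stemBn <- list(dgamma = bb0$dgamma, dbeta = bb0$dbeta)
  cb0 <- .convBwd(net$stemConv, cache$x, bb0$dx)
  g$stemConv <- list(dW = cb0$dW, db = cb0$db)
  g
}

.headFwd <- function(head, feat) {
  a1 <- feat %*% t(head$fc1$W) + rep(head$fc1$b, each = nrow(feat))
  r1 <- pmax(a1, 0)
  z <- r1 %*% t(head$fc2$W) + rep(head$fc2$b, each = nrow(feat))
  list(z = z, cache = list(feat = feat, a1 = a1, r1 = r1))
}

.headBwd <- function(head, cache, dz) {
  g <- list(fc2 = list(dW = t(dz) %*% cache$r1, db = colSums(dz)))
  dr1 <- dz %*% head$fc2$W
  da1 <- dr1 * (cache$a1 > 0)
  g$fc1 <- list(dW = t(da1) %*% cache$feat, db = colSums(da1))
  dfeat <- da1 %*% head$fc1$W
  list(dfeat = dfeat, grads = g)
}

#' InfoNCE contrastive loss
#'
#' Temperature-scaled cosine-similarity InfoNCE over a batch of 2N
#' projections holding N positive pairs: rows \code{i} and \code{i + N}
#' are partners. Each direction of each pair contributes
#' \deqn{\ell_{i,j} = -\log \frac{\exp(S_c(z_i, z_j)/\tau)}
#'   {\sum_{k \ne i} \exp(S_c(z_i, z_k)/\tau)}}
#' and the total loss is the mean over all 2N directions. Projections are
#' unit-normalized before the cosine similarity.
#'
#' @param z numeric matrix (2N x d) of projections.
#' @param tau temperature (> 0).
#' @param grad if TRUE, also return the gradient with respect to z.
#' @return list with \code{loss} and optionally \code{dz}.
#' @export
infoNCELoss <- function(z, tau = 0.5, grad = FALSE) {
  n2 <- nrow(z)
  if (n2 %% 2L != 0L) stop("batch must hold 2N projections")
  N <- n2 %/% 2L
  nrm <- sqrt(rowSums(z^2))
  if (any(nrm == 0)) stop("zero-norm projection")
  u <- z / nrm
  S <- (u %*% t(u)) / tau
  diag(S) <- -Inf
  partner <- c((N + 1):n2, 1:N)
  m <- apply(S, 1, max)
  lse <- m + log(rowSums(exp(S - m)))
  loss <- mean(lse - S[cbind(seq_len(n2), partner)])
  if (!grad) return(list(loss = loss))
  P <- exp(S - lse)                     # row-softmax with masked diagonal
  G <- P / n2
  G[cbind(seq_len(n2), partner)] <- G[cbind(seq_len(n2), partner)] - 1 / n2
  # S symmetric contribution: dL/du_i = sum_k (G[i,k] + G[k,i]) u_k / tau
  du <- ((G + t(G)) %*% u) / tau
  # through row normalization
  proj <- rowSums(du * u)
  dz <- (du - u * proj) / nrm
  list(loss = loss, dz = dz)
}

# Adam over the nested parameter tree ----------------------------------

.adamInitLike <- function(p) {
  if (is.list(p)) return(lapply(p, .adamInitLike))
  array(0, dim = if (is.null(dim(p))) length(p) else dim(p))
}

.adamStep <- function(p, g, m, v, lr, wd, b1, b2, eps, t) {
  g <- g + wd * p
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g^2
  mh <- m / (1 - b1^t)
  vh <- v / (1 - b2^t)
  list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
}

.updateLayer <- function(layer, grads, state, opt) {
  if (is.null(layer$type)) return(list(layer = layer, state = state))
  if (layer$type %in% c("conv", "linear")) {
    sW <- .adamStep(layer$W, grads$dW, state$mW, state$vW, opt$lr, opt$wd,
                    opt$b1, opt$b2, opt$eps, opt$t)
    sb <- .adamStep(layer$b, grads$db, state$mb, state$vb, opt$lr, 0,
                    opt$b1, opt$b2, opt$eps, opt$t)
    layer$W <- sW$p; layer$b <- as.numeric(sb$p)
    state$mW <- sW$m; state$vW <- sW$v
    state$mb <- sb$m; state$vb <- sb$v
  } else if (layer$type == "bn") {
    sg <- .adamStep(layer$gamma, grads$dgamma, state$mg, state$vg, opt$lr, 0,
                    opt$b1, opt$b2, opt$eps, opt$t)
    sb <- .adamStep(layer$beta, grads$dbeta, state$mb, state$vb, opt$lr, 0,
                    opt$b1, opt$b2, opt$eps, opt$t)
    layer$gamma <- as.numeric(sg$p); layer$beta <- as.numeric(sb$p)
    state$mg <- sg$m; state$vg <- sg$v
    state$mb <- sb$m; state$vb <- sb$v
  }
  list(layer = layer, state = state)
}

.stateForLayer <- function(layer) {
  if (layer$type %in% c("conv", "linear"))
    list(mW = layer$W * 0, vW = layer$W * 0,
         mb = layer$b * 0, vb = layer$b * 0)
  else
    list(mg = layer$gamma * 0, vg = layer$gamma * 0,
         mb = layer$beta * 0, vb = layer$beta * 0)
}

.blockState <- function(block) {
  st <- list(conv1 = .stateForLayer(block$conv1),
             bn1 = .stateForLayer(block$bn1),
             conv2 = .stateForLayer(block$conv2),
             bn2 = .stateForLayer(block$bn2),
             conv3 = .stateForLayer(block$conv3),
             bn3 = .stateForLayer(block$bn3))
  if (!is.null(block$down))
    st$down <- list(conv = .stateForLayer(block$down$conv),
                    bn = .stateForLayer(block$down$bn))
  st
}

.optimizerInit <- function(model) {
  net <- model$net
  list(stemConv = .stateForLayer(net$stemConv),
       stemBn = .stateForLayer(net$stemBn),
       stages = lapply(net$stages, function(st) lapply(st, .blockState)),
       fc1 = .stateForLayer(model$head$fc1),
       fc2 = .stateForLayer(model$head$fc2))
}

.applyUpdates <- function(model, grads, state, opt) {
  net <- model$net
  u <- .updateLayer(net$stemConv, grads$stemConv, state$stemConv, opt)
  net$stemConv <- u$layer; state$stemConv <- u$state
  u <- .updateLayer(net$stemBn, grads$stemBn, state$stemBn, opt)
  net$stemBn <- u$layer; state$stemBn <- u$state
  for (s in seq_len(4L)) {
    for (bI in seq_along(net$stages[[s]])) {
      blk <- net$stages[[s]][[bI]]
      gb <- grads$stages[[s]][[bI]]
      sb <- state$stages[[s]][[bI]]
      for (nm in c("conv1", "bn1", "conv2", "bn2", "conv3", "bn3")) {
        u <- .updateLayer(blk[[nm]], gb[[nm]], sb[[nm]], opt)
        blk[[nm]] <- u$layer; sb[[nm]] <- u$state
      }
      if (!is.null(blk$down)) {
        u <- .updateLayer(blk$down$conv, gb$down$conv, sb$down$conv, opt)
        blk$down$conv <- u$layer; sb$down$conv <- u$state
        u <- .updateLayer(blk$down$bn, gb$down$bn, sb$down$bn, opt)
        blk$down$bn <- u$layer; sb$down$bn <- u$state
      }
      net$stages[[s]][[bI]] <- blk
      state$stages[[s]][[bI]] <- sb
    }
  }
  u <- .updateLayer(model$head$fc1, grads$head$fc1, state$fc1, opt)
  model$head$fc1 <- u$layer; state$fc1 <- u$state
  u <- .updateLayer(model$head$fc2, grads$head$fc2, state$fc2, opt)
  model$head$fc2 <- u$layer; state$fc2 <- u$state
  model$net <- net
  list(model = model, state = state)
}

# update batch-norm running statistics from the batch statistics in cache
.updateRunningStats <- function(model, cache) {
  upd <- function(bn, b) {
    mom <- bn$momentum
    bn$rmean <- (1 - mom) * bn$rmean + mom * b$mean
    bn$rvar <- (1 - mom) * bn$rvar + mom * b$var
    bn
  }
  model$net$stemBn <- upd(model$net$stemBn, cache$b0)
  for (s in seq_len(4L)) {
    for (bI in seq_along(model$net$stages[[s]])) {
      blk <- model$net$stages[[s]][[bI]]
      bc <- cache$stages[[s]][[bI]]
      blk$bn1 <- upd(blk$bn1, bc$b1)
      blk$bn2 <- upd(blk$bn2, bc$b2)
      blk$bn3 <- upd(blk$bn3, bc$b3)
      if (!is.null(blk$down)) blk$down$bn <- upd(blk$down$bn, bc$dcache$sb)
      model$net$stages[[s]][[bI]] <- blk
    }
  }
  model
}
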