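#' Classical texture features for 3D-PLI
#'
#' Baseline texture descriptors computed on the map triplet
#' (transmittance normalized by I0, retardation, and the circular Sobel
#' direction-gradient map): first-order histogram statistics, local binary
#' patterns, and grey-level co-occurrence matrices, plus their
#' concatenation. All maps are valued in [0, 1], so a shared quantization
#' range is used throughout.
#'
#' @name classicfeatures
NULL

.sobelKx <- function() matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
# columns = x; Kx detects horizontal (x) gradients, Ky = t(Kx)

#' Sum of absolute entries of the combined Sobel stencil
#'
#' The normalizer of the direction-gradient map: the elementwise sum
#' \eqn{\sum |K_x + K_y|} of the two 3x3 Sobel kernels, which bounds
#' \eqn{|G_x + G_y|} for any unit-magnitude complex field. Evaluates to 12.
#' @return numeric(1).
#' @export
sobelNormalizer <- function() {
  Kx <- .sobelKx()
  sum(abs(Kx + t(Kx)))
}

.conv3x3 <- function(M, K) {
  # 2D convolution (kernel flipped), replicate padding
  H <- nrow(M); W <- ncol(M)
  P <- M[c(1, 1:H, H), c(1, 1:W, W)]
  out <- matrix(0 + 0i * 0, H, W)
  if (!is.complex(M)) out <- matrix(0, H, W)
  for (i in 1:3) {
    for (j in 1:3) {
      # convolution: flip kernel indices
      out <- out + K[4 - i, 4 - j] * P[(1:H) + i - 1, (1:W) + j - 1]
    }
  }
  out
}

#' Circular Sobel direction-gradient map
#'
#' Direction angles are lifted to the unit circle as
#' \eqn{z = \cos 2\varphi + i \sin 2\varphi} (resolving the modulo-pi
#' wrap), Sobel-filtered in both axes, and aggregated as
#' \eqn{\hat\varphi = |G_x + G_y| / 12 \in [0, 1]}. Constant direction
#' fields map to zero; the normalizer 12 is the absolute sum of the
#' combined kernel (\code{\link{sobelNormalizer}}).
#'
#' @param phi direction matrix (radians mod pi).
#' @return matrix of direction-gradient magnitudes in [0, 1].
#' @export
sobelDirection <- function(phi) {
  z <- exp(2i * phi)
  Kx <- .sobelKx()
  G <- .conv3x3(z, Kx + t(Kx))
  pmin(Mod(G) / sobelNormalizer(), 1)
}

.featureMapsOf <- function(maps) {
  list(IT = pmin(pmax(transmittance(maps) / incidentIntensity(maps), 0), 1),
       ret = pmin(pmax(retardation(maps), 0), 1),
       dirGrad = sobelDirection(direction(maps)))
}

#' First-order histogram features (dimension 15)
#'
#' For each of the three maps, a normalized 128-bin histogram over [0, 1]
#' is computed and summarized by mean, variance, skewness, excess
#' kurtosis and Shannon entropy (nats), all evaluated on the binned
#' distribution. Constant tiles give zero variance and zero entropy; a
#' uniform histogram gives entropy log(128).
#'
#' @param maps a \linkS4class{PLIMaps} tile.
#' @param nbins histogram resolution (default 128).
#' @return named numeric vector of length 15.
#' @export
histogramFeatures <- function(maps, nbins = 128L) {
  ms <- .featureMapsOf(maps)
  out <- numeric(0)
  centers <- (seq_len(nbins) - 0.5) / nbins
  for (nm in names(ms)) {
    v <- as.vector(ms[[nm]])
    if (!length(v)) stop("empty tile")
    idx <- pmin(pmax(floor(v * nbins), 0), nbins - 1L) + 1L
    p <- tabulate(idx, nbins) / length(v)
    m <- sum(p * centers)
    vr <- sum(p * (centers - m)^2)
    if (vr > 1e-12) {
      sk <- sum(p * (centers - m)^3) / vr^1.5
      ku <- sum(p * (centers - m)^4) / vr^2 - 3
    } else {
      vr <- 0; sk <- 0; ku <- 0
    }
    ent <- -sum(ifelse(p > 0, p * log(p), 0))
    f <- c(m, vr, sk, ku, ent)
    names(f) <- paste("hist", nm,
                      c("mean", "variance", "skewness", "kurtosis", "entropy"),
                      sep = "_")
    out <- c(out, f)
  }
  out
}

.lbpCodes <- function(M, R, P = 8L) {
  # rotation-invariant uniform LBP: codes 0..P (bit count) for uniform
  # patterns (<= 2 circular transitions), P+1 otherwise
  H <- nrow(M); W <- ncol(M)
  ang <- 2 * pi * (0:(P - 1)) / P
  dy <- -R * sin(ang); dx <- R * cos(ang)
  rr <- (R + 1):(H - R); cc <- (R + 1):(W - R)
  ctr <- M[rr, cc]
  bits <- array(0L, c(length(rr), length(cc), P))
  for (p in seq_len(P)) {
    ys <- outer(rr + dy[p], rep(1, length(cc)))
    xs <- outer(rep(1, length(rr)), cc + dx[p])
    y0 <- floor(ys); x0 <- floor(xs)
    fy <- ys - y0; fx <- xs - x0
    g <- function(yi, xi) M[cbind(as.vector(pmin(pmax(yi, 1), H)),
                                  as.vector(pmin(pmax(xi, 1), W)))]
    v <- (1 - fy) * (1 - fx) * matrix(g(y0, x0), length(rr)) +
         (1 - fy) * fx       * matrix(g(y0, x0 + 1), length(rr)) +
         fy * (1 - fx)       * matrix(g(y0 + 1, x0), length(rr)) +
         fy * fx             * matrix(g(y0 + 1, x0 + 1), length(rr))
    bits[, , p] <- (v >= ctr - 1e-12) * 1L
  }
  trans <- matrix(0L, length(rr), length(cc))
  for (p in seq_len(P)) {
    q <- if (p == P) 1L else p + 1L
    trans <- trans + (bits[, , p] != bits[, , q])
  }
  ones <- apply(bits, c(1, 2), sum)
  codes <- ifelse(trans <= 2L, ones, P + 1L)
  codes
}

#' Rotation-invariant uniform local binary pattern features (dimension 90)
#'
#' Eight-point LBP codes at radii 1, 2 and 3 pixels (bilinear neighbor
#' interpolation, rotation-invariant uniform mapping: uniform patterns
#' keyed by their bit count, all non-uniform patterns pooled), summarized
#' as a normalized 10-bin histogram per radius and map.
#'
#' @param maps a \linkS4class{PLIMaps} tile (edge > 2 x max radius).
#' @param radii neighborhood radii in pixels.
#' @return named numeric vector of length 90.
#' @export
lbpFeatures <- function(maps, radii = c(1L, 2L, 3L)) {
  ms <- .featureMapsOf(maps)
  d <- dim(transmittance(maps))
  if (min(d) <= 2L * max(radii)) stop("tile too small for LBP radii")
  out <- numeric(0)
  for (nm in names(ms)) {
    for (R in radii) {
      codes <- .lbpCodes(ms[[nm]], R)
      p <- tabulate(as.vector(codes) + 1L, 10L) / length(codes)
      names(p) <- paste("lbp", nm, paste0("r", R), 0:9, sep = "_")
      out <- c(out, p)
    }
  }
  out
}

.glcm <- function(Q, d, levels = 32L) {
  # symmetric normalized co-occurrence over the four standard angles
  offs <- list(c(0, d), c(-d, d), c(-d, 0), c(-d, -d))
  H <- nrow(Q); W <- ncol(Q)
  lapply(offs, function(o) {
    r1 <- max(1, 1 - o[1]):min(H, H - o[1])
    c1 <- max(1, 1 - o[2]):min(W, W - o[2])
    i <- as.vector(Q[r1, c1])
    j <- as.vector(Q[r1 + o[1], c1 + o[2]])
    counts <- tabulate(i * levels + j + 1L, levels * levels)
    P <- matrix(counts, levels, levels, byrow = TRUE)
    P <- P + t(P)
    P / sum(P)
  })
}

.glcmProps <- function(P) {
  levels <- nrow(P)
  i <- matrix(0:(levels - 1), levels, levels)
  j <- t(i)
  contrast <- sum(P * (i - j)^2)
  pi_ <- rowSums(P); pj <- colSums(P)
  mi <- sum((0:(levels - 1)) * pi_); mj <- sum((0:(levels - 1)) * pj)
  si <- sqrt(sum((0:(levels - 1) - mi)^2 * pi_))
  sj <- sqrt(sum((0:(levels - 1) - mj)^2 * pj))
  correlation <- if (si < 1e-12 || sj < 1e-12) 0 else
    sum(P * (i - mi) * (j - mj)) / (si * sj)
  energy <- sum(P^2)
  homogeneity <- sum(P / (1 + (i - j)^2))
  c(contrast = contrast, correlation = correlation, energy = energy,
    homogeneity = homogeneity)
}

#' Grey-level co-occurrence features (dimension 36)
#'
#' Symmetric, normalized GLCMs over 32 equally spaced bins of [0, 1], for
#' pixel distances 1, 2 and 4 and the four standard angles (0, 45, 90,
#' 135 degrees). Contrast, correlation, energy and homogeneity are
#' averaged over the angles (rotation robustness), giving 4 properties x
#' 3 distances x 3 maps. Correlation of a zero-variance (single-level)
#' tile is defined as 0.
#'
#' @param maps a \linkS4class{PLIMaps} tile.
#' @param distances co-occurrence distances in pixels.
#' @param levels quantization levels over [0, 1].
#' @return named numeric vector of length 36.
#' @export
glcmFeatures <- function(maps, distances = c(1L, 2L, 4L), levels = 32L) {
  ms <- .featureMapsOf(maps)
  out <- numeric(0)
  for (nm in names(ms)) {
    Q <- pmin(pmax(floor(ms[[nm]] * levels), 0), levels - 1L)
    for (d in distances) {
      props <- sapply(.glcm(Q, d, levels), .glcmProps)
      f <- rowMeans(props)
      names(f) <- paste("glcm", nm, paste0("d", d), names(f), sep = "_")
      out <- c(out, f)
    }
  }
  out
}

#' Combined classical texture feature vector (dimension 141)
#'
#' Concatenation of histogram (15), LBP (90) and GLCM (36) features in
#' that fixed order.
#'
#' @param maps a \linkS4class{PLIMaps} tile.
#' @return named numeric vector of length 141.
#' @export
combinedFeatures <- function(maps) {
  c(histogramFeatures(maps), lbpFeatures(maps), glcmFeatures(maps))
}

#' Classical texture feature map for one section
#'
#' Same tiling interface as \code{\link{inferFeatureMap}} (tiles of
#' \code{tilePx} with stride \code{stridePx}), so classical baselines and
#' learned features live on compatible grids.
#'
#' @param maps a \linkS4class{PLIMaps} section.
#' @param extractor which feature family to compute.
#' @param tilePx,stridePx tile geometry.
#' @param mask optional mask for tile foreground flags.
#' @param section stored section index.
#' @return a \linkS4class{PLIFeatureMap} with schema metadata.
#' @export
classicFeatureMap <- function(maps,
                              extractor = c("combined", "histogram",
                                            "lbp", "glcm"),
                              tilePx = 128L, stridePx = tilePx %/% 2L,
                              mask = NULL, section = 1L) {
  extractor <- match.arg(extractor)
  fn <- switch(extractor, combined = combinedFeatures,
               histogram = histogramFeatures, lbp = lbpFeatures,
               glcm = glcmFeatures)
  d <- dim(transmittance(maps))
  if (d[1] < tilePx || d[2] < tilePx) stop("section smaller than one tile")
  rows <- seq(1L, d[1] - tilePx + 1L, by = stridePx)
  cols <- seq(1L, d[2] - tilePx + 1L, by = stridePx)
  first <- NULL
  arr <- NULL
  fg <- matrix(TRUE, length(rows), length(cols))
  for (ri in seq_along(rows)) {
    for (ci in seq_along(cols)) {
      rr <- rows[ri]:(rows[ri] + tilePx - 1L)
      cc <- cols[ci]:(cols[ci] + tilePx - 1L)
      tile <- PLIMaps(maps@transmittance[rr, cc], maps@direction[rr, cc],
                      maps@retardation[rr, cc], pixelSize = maps@pixelSize,
                      I0 = maps@I0)
      f <- fn(tile)
      if (is.null(arr)) {
        first <- names(f)
        arr <- array(0, c(length(rows), length(cols), length(f)))
      }
      arr[ri, ci, ] <- f
      if (!is.null(mask)) {
        tb <- tabulate(mask[rr, cc] + 1L)
        fg[ri, ci] <- (which.max(tb) - 1L) > 0L
      }
    }
  }
  PLIFeatureMap(arr, tilePx = tilePx, stridePx = stridePx,
                section = section, foreground = fg, schema = first,
                pixelSize = pixelSize(maps))
}
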