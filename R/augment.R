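#' 3D-PLI augmentation algebra
#'
#' Augmentations for 3D-PLI must transform transmittance, direction and
#' retardation jointly and physically consistently. Intensity-level
#' resampling of the raw sinusoidal profiles corresponds, on parameter
#' maps, to a weighted mean of transmittance together with a
#' transmittance-weighted complex average of \eqn{r e^{i 2\varphi}}:
#' \deqn{I_T' = \sum_i w_i I_{T,i}, \qquad
#'       r' e^{i 2\varphi'} = \frac{1}{I_T'} \sum_i w_i r_i I_{T,i}
#'       e^{i 2\varphi_i}.}
#' Geometric transforms additionally require pushing direction vectors
#' through the transform Jacobian before pixels are moved.
#'
#' @name augment
NULL

.complexField <- function(maps) {
  retardation(maps) * transmittance(maps) * exp(2i * direction(maps))
}

.mapsFromComplex <- function(IT, F, template) {
  r <- ifelse(IT > 0, Mod(F) / IT, 0)
  r <- pmin(pmax(r, 0), 1)
  phi <- wrapDirection(0.5 * Arg(F))
  phi[r == 0] <- 0
  .newMaps(IT, phi, r, pixelSize = pixelSize(template),
           I0 = incidentIntensity(template))
}

#' Rescale the attenuation coefficient
#'
#' Scaling the attenuation coefficient by \eqn{\gamma_a} under the
#' Bouguer-Lambert law maps transmittance to
#' \eqn{I_T' = I_0 (I_T/I_0)^{\gamma_a}}; direction and retardation are
#' untouched.
#'
#' @param maps a \linkS4class{PLIMaps}.
#' @param gammaA positive scale factor for the attenuation coefficient.
#' @return augmented \linkS4class{PLIMaps}.
#' @export
scaleAttenuation <- function(maps, gammaA) {
  if (gammaA <= 0) stop("gammaA must be positive")
  I0 <- incidentIntensity(maps)
  IT <- I0 * (pmax(transmittance(maps), 0) / I0)^gammaA
  .newMaps(IT, direction(maps), retardation(maps),
           pixelSize = pixelSize(maps), I0 = I0, undefined = maps@undefined)
}

#' Rescale the birefringent section thickness
#'
#' Scaling thickness by \eqn{\gamma_t} scales the phase retardation
#' \eqn{\delta} linearly, so \eqn{r' = |\sin(\gamma_t \arcsin r)|}
#' (magnitude, since only \eqn{|\sin\delta|} is observable and
#' \eqn{\gamma_t \arcsin r} may leave the principal branch), and
#' transmittance follows \eqn{I_T' = I_0 (I_T/I_0)^{\gamma_t}}.
#'
#' @param maps a \linkS4class{PLIMaps}.
#' @param gammaT positive thickness scale factor.
#' @return augmented \linkS4class{PLIMaps}.
#' @export
scaleThickness <- function(maps, gammaT) {
  if (gammaT <= 0) stop("gammaT must be positive")
  I0 <- incidentIntensity(maps)
  r <- abs(sin(gammaT * asin(pmin(pmax(retardation(maps), 0), 1))))
  IT <- I0 * (pmax(transmittance(maps), 0) / I0)^gammaT
  .newMaps(IT, direction(maps), r,
           pixelSize = pixelSize(maps), I0 = I0, undefined = maps@undefined)
}

#' Resample parameter maps through an arbitrary weight operator
#'
#' The workhorse behind all geometric transforms and filters. \code{weights}
#' is an (nTarget x nSource) matrix whose rows are non-negative stencils
#' summing to 1 (rows of zeros are allowed and produce background pixels);
#' source and target pixels are vectorized column-major. Transmittance is
#' averaged directly; retardation and direction through the
#' transmittance-weighted complex average. Target pixels with zero
#' resampled transmittance get r = 0, phi = 0.
#'
#' @param maps a \linkS4class{PLIMaps}.
#' @param weights (nTarget x nSource) stencil matrix.
#' @param outDim integer c(rows, cols) of the target grid; defaults to the
#'   input shape (then nTarget must equal prod(dim)).
#' @return resampled \linkS4class{PLIMaps}.
#' @export
resampleMaps <- function(maps, weights, outDim = dim(maps)) {
  if (any(weights < -1e-12)) stop("stencil weights must be non-negative")
  nsrc <- prod(dim(maps))
  if (ncol(weights) != nsrc) stop("weights must have one column per source pixel")
  if (nrow(weights) != prod(outDim)) stop("weights rows must match outDim")
  IT <- as.vector(weights %*% as.vector(transmittance(maps)))
  F <- as.vector(weights %*% as.vector(.complexField(maps)))
  .mapsFromComplex(matrix(IT, outDim[1], outDim[2]),
                   matrix(F, outDim[1], outDim[2]), maps)
}

#' Correct direction angles for an in-plane linear transform
#'
#' Direction unit vectors \eqn{d = (\cos\varphi, \sin\varphi)} are pushed
#' through the (constant) Jacobian \eqn{A} of the pixel transform,
#' \eqn{d' = A d}, and re-expressed as angles modulo \eqn{\pi}. For a pure
#' rotation this reduces to \eqn{\varphi' = \varphi + \theta}. The
#' correction is applied before pixels are moved.
#'
#' @param phi direction matrix (radians mod pi).
#' @param A 2x2 Jacobian of the coordinate transform (x = column,
#'   y = row axes).
#' @return corrected direction matrix in \code{[0, pi)}.
#' @export
correctDirection <- function(phi, A) {
  if (abs(det(A)) < 1e-12) stop("singular Jacobian")
  d1 <- cos(phi); d2 <- sin(phi)
  e1 <- A[1, 1] * d1 + A[1, 2] * d2
  e2 <- A[2, 1] * d1 + A[2, 2] * d2
  wrapDirection(atan2(e2, e1))
}

#' Affine transform of parameter maps
#'
#' Applies \eqn{f(p) = A (p - c) + t + c} about the image center \eqn{c},
#' resampling with bilinear stencils (zero padding outside the source) and
#' correcting directions through the Jacobian \eqn{A} first.
#'
#' @param maps a \linkS4class{PLIMaps}.
#' @param A 2x2 linear part (x = column, y = row coordinates).
#' @param tvec length-2 translation (pixels), default c(0, 0).
#' @return transformed \linkS4class{PLIMaps} on the same grid.
#' @export
affineAugment <- function(maps, A, tvec = c(0, 0)) {
  if (abs(det(A)) < 1e-12) stop("degenerate affine matrix")
  H <- nrow(transmittance(maps)); W <- ncol(transmittance(maps))
  ctr <- c((W + 1) / 2, (H + 1) / 2)
  # target grid -> source coordinates via the inverse transform
  gx <- rep(seq_len(W), each = H)
  gy <- rep(seq_len(H), times = W)
  Ainv <- solve(A)
  dx <- gx - ctr[1] - tvec[1]
  dy <- gy - ctr[2] - tvec[2]
  xs <- Ainv[1, 1] * dx + Ainv[1, 2] * dy + ctr[1]
  ys <- Ainv[2, 1] * dx + Ainv[2, 2] * dy + ctr[2]
  # the resample kernel corrects directions through the Jacobian A before
  # moving pixels (same rule as correctDirection)
  out <- .cpp_affine_resample(transmittance(maps), retardation(maps),
                              direction(maps), xs, ys, A)
  .newMaps(matrix(out$IT, H, W), matrix(out$phi, H, W),
           matrix(out$r, H, W), pixelSize = pixelSize(maps),
           I0 = incidentIntensity(maps))
}

#' Rotation matrix for a counter-clockwise in-plane rotation
#' @param theta angle in radians.
#' @return 2x2 rotation matrix.
#' @export
rotationMatrix <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

#' Flip parameter maps along one axis
#'
#' A flip is an exact grid permutation; no interpolation is involved. The
#' direction correction follows from the reflection Jacobian
#' (\code{diag(-1, 1)} or \code{diag(1, -1)}), both of which map
#' \eqn{\varphi \to (\pi - \varphi) \bmod \pi}.
#'
#' @param maps a \linkS4class{PLIMaps}.
#' @param axis "x" mirrors columns (left-right), "y" mirrors rows.
#' @return flipped \linkS4class{PLIMaps}.
#' @export
flipAugment <- function(maps, axis = c("x", "y")) {
  axis <- match.arg(axis)
  A <- if (axis == "x") diag(c(-1, 1)) else diag(c(1, -1))
  phi <- correctDirection(direction(maps), A)
  fl <- function(M) if (axis == "x") M[, rev(seq_len(ncol(M))), drop = FALSE]
                    else M[rev(seq_len(nrow(M))), , drop = FALSE]
  .newMaps(fl(transmittance(maps)), fl(phi), fl(retardation(maps)),
           pixelSize = pixelSize(maps), I0 = incidentIntensity(maps),
           undefined = fl(maps@undefined))
}

.gaussWeights1d <- function(n, sigma) {
  # n x n row-normalized Gaussian operator, truncated at 4 sigma
  if (sigma <= 0) return(diag(n))
  rad <- max(1L, ceiling(4 * sigma))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- max(1L, i - rad):min(n, i + rad)
    w <- exp(-((j - i)^2) / (2 * sigma^2))
    K[i, j] <- w / sum(w)
  }
  K
}

#' Gaussian blur of parameter maps
#'
#' Separable Gaussian filtering (stencils truncated at 4 sigma and
#' renormalized at image borders, so constant fields are exact fixed
#' points), applied to transmittance and to the transmittance-weighted
#' complex direction/retardation field.
#'
#' @param maps a \linkS4class{PLIMaps}.
#' @param sigma standard deviation in pixels; 0 is the identity.
#' @return blurred \linkS4class{PLIMaps}.
#' @export
gaussianBlurMaps <- function(maps, sigma) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (sigma == 0) return(maps)
  H <- nrow(transmittance(maps)); W <- ncol(transmittance(maps))
  Kr <- .gaussWeights1d(H, sigma); Kc <- .gaussWeights1d(W, sigma)
  blur <- function(M) Kr %*% M %*% t(Kc)
  F <- .complexField(maps)
  IT <- blur(transmittance(maps))
  Fo <- blur(Re(F)) + 1i * blur(Im(F))
  .mapsFromComplex(IT, Fo, maps)
}

#' Center crop of parameter maps
#' @param maps a \linkS4class{PLIMaps}.
#' @param size crop edge length in pixels.
#' @return cropped \linkS4class{PLIMaps}.
#' @export
centerCrop <- function(maps, size) {
  H <- nrow(transmittance(maps)); W <- ncol(transmittance(maps))
  if (size > H || size > W) stop("crop larger than input")
  r0 <- floor((H - size) / 2); c0 <- floor((W - size) / 2)
  ri <- (r0 + 1):(r0 + size); ci <- (c0 + 1):(c0 + size)
  .newMaps(transmittance(maps)[ri, ci], direction(maps)[ri, ci],
           retardation(maps)[ri, ci], pixelSize = pixelSize(maps),
           I0 = incidentIntensity(maps),
           undefined = maps@undefined[ri, ci, drop = FALSE])
}

#' Random augmentation policy
#'
#' Defaults follow the reference training recipe: per-axis scaling in
#' [0.9, 1.3], rotation in [-180, 180] degrees, per-axis shearing in
#' [-20, 20] degrees with linear interpolation, center cropping to 128
#' pixels, random flips, thickness and attenuation scale factors
#' \eqn{2^u} with \eqn{u \sim U[-1, 1]}, and Gaussian blur with
#' probability 0.5 and sigma in [0, 2] pixels.
#'
#' @param gammaALog2Range,gammaTLog2Range log2 ranges of the attenuation and
#'   thickness scale factors.
#' @param scaleRange per-axis geometric scale range.
#' @param rotationRange rotation range in degrees.
#' @param shearRange per-axis shear range in degrees.
#' @param flipProb flip probability per axis.
#' @param blurProb blur application probability.
#' @param blurSigmaRange sigma range in pixels.
#' @param cropPx center-crop edge length in pixels.
#' @return a validated policy object (list of class
#'   \code{"AugmentationPolicy"}).
#' @export
augmentationPolicy <- function(gammaALog2Range = c(-1, 1),
                               gammaTLog2Range = c(-1, 1),
                               scaleRange = c(0.9, 1.3),
                               rotationRange = c(-180, 180),
                               shearRange = c(-20, 20),
                               flipProb = 0.5,
                               blurProb = 0.5,
                               blurSigmaRange = c(0, 2),
                               cropPx = 128L) {
  chkRange <- function(r, nm) {
    if (length(r) != 2L || r[1] > r[2])
      stop(nm, " must be a well-ordered interval")
  }
  chkRange(gammaALog2Range, "gammaALog2Range")
  chkRange(gammaTLog2Range, "gammaTLog2Range")
  chkRange(scaleRange, "scaleRange")
  chkRange(rotationRange, "rotationRange")
  chkRange(shearRange, "shearRange")
  chkRange(blurSigmaRange, "blurSigmaRange")
  if (flipProb < 0 || flipProb > 1 || blurProb < 0 || blurProb > 1)
    stop("probabilities must lie in [0, 1]")
  if (scaleRange[1] <= 0) stop("scale must be positive")
  structure(list(gammaALog2Range = gammaALog2Range,
                 gammaTLog2Range = gammaTLog2Range,
                 scaleRange = scaleRange, rotationRange = rotationRange,
                 shearRange = shearRange, flipProb = flipProb,
                 blurProb = blurProb, blurSigmaRange = blurSigmaRange,
                 cropPx = as.integer(cropPx)),
            class = "AugmentationPolicy")
}

#' Read / write an augmentation policy as YAML
#' @param path file path.
#' @param policy an \code{\link{augmentationPolicy}}.
#' @export
writePolicy <- function(policy, path) {
  yaml::write_yaml(unclass(policy), path)
  invisible(path)
}

#' @rdname writePolicy
#' @export
readPolicy <- function(path) {
  do.call(augmentationPolicy, yaml::read_yaml(path))
}

#' Apply a random augmentation draw to a patch
#'
#' Augmentation order: random affine (scale, rotation, shear about the
#' patch center, bilinear resampling) then center crop (discarding the
#' zero-padded margin), random flips, thickness scaling, attenuation
#' scaling, and finally Gaussian blur with the configured probability.
#' All randomness is drawn from R's RNG; set a seed for reproducibility.
#'
#' @param maps a \linkS4class{PLIMaps} patch (must exceed the crop size).
#' @param policy an \code{\link{augmentationPolicy}}.
#' @param seed optional integer; if given the RNG is seeded locally.
#' @return augmented \linkS4class{PLIMaps} of size \code{cropPx}.
#' @export
randomPolicyApply <- function(maps, policy = augmentationPolicy(),
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  u <- function(r) runif(1, r[1], r[2])
  sx <- u(policy$scaleRange); sy <- u(policy$scaleRange)
  th <- u(policy$rotationRange) * pi / 180
  hx <- tan(u(policy$shearRange) * pi / 180)
  hy <- tan(u(policy$shearRange) * pi / 180)
  A <- rotationMatrix(th) %*% matrix(c(1, hy, hx, 1), 2, 2) %*% diag(c(sx, sy))
  out <- affineAugment(maps, A)
  out <- centerCrop(out, policy$cropPx)
  if (runif(1) < policy$flipProb) out <- flipAugment(out, "x")
  if (runif(1) < policy$flipProb) out <- flipAugment(out, "y")
  out <- scaleThickness(out, 2^u(policy$gammaTLog2Range))
  out <- scaleAttenuation(out, 2^u(policy$gammaALog2Range))
  if (runif(1) < policy$blurProb)
    out <- gaussianBlurMaps(out, u(policy$blurSigmaRange))
  out
}
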