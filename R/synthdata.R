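#' Synthetic multi-section 3D-PLI phantom
#'
#' The phantom emulates a serial-sectioned block of cortex: an annular
#' gray-matter ribbon around a white-matter core, both drifting smoothly
#' across sections, with four regionally distinct fiber configurations:
#' \itemize{
#'   \item GM, superficial half: radial fibers (direction along the local
#'     surface normal),
#'   \item GM, deep half: tangential fibers (direction along the ribbon),
#'   \item WM, one half: a parallel in-plane bundle (high retardation),
#'   \item WM, other half: two crossing fiber populations whose sinusoidal
#'     profiles mix at the intensity level, which lowers the retrieved
#'     retardation below either population alone.
#' }
#' Sections are rendered through the full signal chain: fiber parameters
#' to 9-angle intensity profiles (with optional additive Gaussian sensor
#' noise and per-section attenuation outliers), then harmonic parameter
#' retrieval. Each section receives a small random in-plane affine jitter;
#' the section-to-reference transform is stored so context sampling can be
#' performed in the undistorted reference frame. Tissue masks
#' (BG/GM/WM), region labels, and analytic morphology (cortical depth,
#' curvature, sectioning obliqueness) are emitted from the phantom
#' geometry.
#'
#' @name synthdata
NULL

#' Phantom specification
#'
#' @param height,width section size in pixels.
#' @param nSections number of serial sections.
#' @param pixelSize in-plane pixel size in micrometers.
#' @param sectionSpacing section-to-section distance in micrometers.
#' @param rCtxFrac,rWMFrac pial and GM/WM radius as a fraction of the
#'   smaller image edge.
#' @param driftAmpPx amplitude (pixels) of the slow cross-section drift of
#'   the phantom center.
#' @param radiusDriftFrac relative amplitude of the slow radius drift.
#' @param jitterRotDeg,jitterTransPx per-section affine jitter: rotation
#'   range (+- degrees) and translation range (+- pixels). 0 gives identity
#'   transforms.
#' @param tJitterSd relative per-pixel jitter of the birefringent
#'   thickness (texture).
#' @param phiJitterDeg per-pixel direction jitter (degrees, sd).
#' @param shotNoiseSd additive Gaussian noise sd on the raw 9-angle
#'   intensities, in units of I0.
#' @param outlierProb probability for a section to be an attenuation
#'   outlier; \code{outlierFactor} scales its attenuation coefficient.
#' @param outlierFactor attenuation scale of outlier sections.
#' @param birefringence,wavelength optical constants of the signal model
#'   (effective birefringence, wavelength in nm).
#' @param I0 incident intensity.
#' @return a list of class \code{"PhantomSpec"}.
#' @export
phantomSpec <- function(height = 256L, width = 256L, nSections = 8L,
                        pixelSize = 1.3, sectionSpacing = 60,
                        rCtxFrac = 0.45, rWMFrac = 0.24,
                        driftAmpPx = 3, radiusDriftFrac = 0.04,
                        jitterRotDeg = 3, jitterTransPx = 2,
                        tJitterSd = 0.15, phiJitterDeg = 8,
                        shotNoiseSd = 0.01,
                        outlierProb = 0.1, outlierFactor = 1.5,
                        birefringence = 1.5e-3, wavelength = 550,
                        I0 = 1) {
  spec <- list(height = as.integer(height), width = as.integer(width),
               nSections = as.integer(nSections), pixelSize = pixelSize,
               sectionSpacing = sectionSpacing, rCtxFrac = rCtxFrac,
               rWMFrac = rWMFrac, driftAmpPx = driftAmpPx,
               radiusDriftFrac = radiusDriftFrac,
               jitterRotDeg = jitterRotDeg, jitterTransPx = jitterTransPx,
               tJitterSd = tJitterSd, phiJitterDeg = phiJitterDeg,
               shotNoiseSd = shotNoiseSd, outlierProb = outlierProb,
               outlierFactor = outlierFactor, birefringence = birefringence,
               wavelength = wavelength, I0 = I0)
  if (spec$rWMFrac >= spec$rCtxFrac) stop("WM radius must be below pial radius")
  if (spec$nSections < 1L) stop("need at least one section")
  structure(spec, class = "PhantomSpec")
}

#' Read / write a phantom specification as YAML
#' @param spec a \code{\link{phantomSpec}}.
#' @param path file path.
#' @export
writePhantomSpec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname writePhantomSpec
#' @export
readPhantomSpec <- function(path) do.call(phantomSpec, yaml::read_yaml(path))

# region recipes: fiber parameters per configuration
# (thickness um, inclination rad, attenuation 1/um, direction rule)
.phantomRecipes <- function() {
  list(
    gm_radial     = list(t = 35, alpha = 0.35, mu = 0.009),
    gm_tangential = list(t = 45, alpha = 0.15, mu = 0.011),
    wm_parallel   = list(t = 55, alpha = 0.10, mu = 0.019, phi0 = 30 * pi / 180),
    wm_crossing   = list(t = 55, alpha = 0.10, mu = 0.017,
                         phi1 = 30 * pi / 180, phi2 = 100 * pi / 180)
  )
}

# slow, smooth cross-section drift of the phantom geometry
.phantomGeometry <- function(spec, z) {
  S <- max(spec$nSections, 2L)
  ctr <- c(spec$width, spec$height) / 2
  cx <- ctr[1] + spec$driftAmpPx * sin(pi * z / S)
  cy <- ctr[2] + spec$driftAmpPx * cos(pi * z / S)
  rmin <- min(spec$height, spec$width)
  rCtx <- spec$rCtxFrac * rmin * (1 + spec$radiusDriftFrac * sin(2 * pi * z / S))
  rWM  <- spec$rWMFrac  * rmin * (1 + spec$radiusDriftFrac * cos(2 * pi * z / S))
  list(cx = cx, cy = cy, rCtx = rCtx, rWM = rWM)
}

#' Generate a synthetic serial-section stack
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @param seed integer seed; the output is reproducible bit for bit.
#' @return a \linkS4class{PLIStack} with masks (0 = BG, 1 = GM, 2 = WM),
#'   region labels (1 = GM radial, 2 = GM tangential, 3 = WM parallel
#'   bundle, 4 = WM crossing, 0 = BG), per-section transforms, and
#'   morphology ground truth (\code{depth} in [0, 1] on GM, 0 = pial;
#'   \code{curvature} of the pial surface in 1/mm; \code{obliqueness} of
#'   the sectioning plane in degrees, on GM).
#' @export
makePhantom <- function(spec = phantomSpec(), seed = 1L) {
  set.seed(seed)
  H <- spec$height; W <- spec$width; S <- spec$nSections
  rec <- .phantomRecipes()
  lambda_um <- spec$wavelength / 1000
  deltaOf <- function(t, alpha)
    2 * pi * t * spec$birefringence * cos(alpha)^2 / lambda_um
  rho <- rhoAngles()
  ctr <- c(W + 1, H + 1) / 2

  # per-section jitter and outlier draws (fixed order for reproducibility)
  thetas <- runif(S, -spec$jitterRotDeg, spec$jitterRotDeg) * pi / 180
  transx <- runif(S, -spec$jitterTransPx, spec$jitterTransPx)
  transy <- runif(S, -spec$jitterTransPx, spec$jitterTransPx)
  outlier <- runif(S) < spec$outlierProb
  if (spec$jitterRotDeg == 0) thetas[] <- 0
  if (spec$jitterTransPx == 0) { transx[] <- 0; transy[] <- 0 }

  gx <- rep(seq_len(W), each = H)   # x = column
  gy <- rep(seq_len(H), times = W)  # y = row

  sectionsL <- vector("list", S); masksL <- vector("list", S)
  labelsL <- vector("list", S); transformsL <- vector("list", S)
  depthL <- vector("list", S); curvL <- vector("list", S)
  obliqL <- vector("list", S)

  for (z in seq_len(S)) {
    Rz <- rotationMatrix(thetas[z])
    tz <- c(transx[z], transy[z])
    transformsL[[z]] <- cbind(Rz, as.vector(ctr + tz - Rz %*% ctr))
    # reference coordinates of every section pixel
    qx <- Rz[1, 1] * (gx - ctr[1]) + Rz[1, 2] * (gy - ctr[2]) + ctr[1] + tz[1]
    qy <- Rz[2, 1] * (gx - ctr[1]) + Rz[2, 2] * (gy - ctr[2]) + ctr[2] + tz[2]

    geo <- .phantomGeometry(spec, z)
    dx <- qx - geo$cx; dy <- qy - geo$cy
    rad <- sqrt(dx^2 + dy^2)
    beta <- atan2(dy, dx)

    mask <- integer(H * W)
    mask[rad <= geo$rCtx] <- 1L
    mask[rad <= geo$rWM] <- 2L
    region <- integer(H * W)
    depthv <- rep(NA_real_, H * W)
    gm <- mask == 1L
    depthv[gm] <- (geo$rCtx - rad[gm]) / (geo$rCtx - geo$rWM)
    region[gm & depthv < 0.5] <- 1L                  # superficial: radial
    region[gm & depthv >= 0.5] <- 2L                 # deep: tangential
    region[mask == 2L & qx < geo$cx] <- 3L           # WM parallel bundle
    region[mask == 2L & qx >= geo$cx] <- 4L          # WM crossing

    # fiber parameters in the reference frame
    phi_ref <- numeric(H * W)
    tt <- numeric(H * W); alp <- numeric(H * W); mu <- numeric(H * W)
    phi_ref[region == 1L] <- beta[region == 1L]
    phi_ref[region == 2L] <- beta[region == 2L] + pi / 2
    phi_ref[region == 3L] <- rec$wm_parallel$phi0
    phi_ref[region == 4L] <- rec$wm_crossing$phi1
    for (i in seq_along(rec)) {
      sel <- region == i
      tt[sel] <- rec[[i]]$t
      alp[sel] <- rec[[i]]$alpha
      mu[sel] <- rec[[i]]$mu
    }
    if (outlier[z]) mu <- mu * spec$outlierFactor
    # per-pixel texture jitter
    if (spec$tJitterSd > 0)
      tt <- pmax(tt * (1 + rnorm(H * W, 0, spec$tJitterSd)), 0)
    if (spec$phiJitterDeg > 0)
      phi_ref <- phi_ref + rnorm(H * W, 0, spec$phiJitterDeg * pi / 180)

    # section-frame direction: undo the jitter rotation
    phi_sec <- phi_ref - thetas[z]

    IT <- spec$I0 * exp(-tt * mu)
    delta <- deltaOf(tt, alp)
    prof <- array(0, c(H, W, 9L))
    cross <- region == 4L
    phi2_sec <- phi_ref - rec$wm_crossing$phi1 + rec$wm_crossing$phi2 -
      thetas[z]
    deltaHalf <- deltaOf(tt / 2, alp)
    for (k in seq_len(9L)) {
      s <- sin(delta) * sin(2 * rho[k] - 2 * phi_sec)
      if (any(cross)) {
        s[cross] <- 0.5 * sin(deltaHalf[cross]) *
          (sin(2 * rho[k] - 2 * phi_sec[cross]) +
           sin(2 * rho[k] - 2 * phi2_sec[cross]))
      }
      prof[, , k] <- matrix(IT / 2 * (1 + s), H, W)
    }
    if (spec$shotNoiseSd > 0)
      prof <- pmax(prof + rnorm(length(prof), 0, spec$shotNoiseSd * spec$I0), 0)

    sectionsL[[z]] <- retrieveParameters(
      PLISeries(prof, pixelSize = spec$pixelSize), I0 = spec$I0)
    masksL[[z]] <- matrix(mask, H, W)
    labelsL[[z]] <- matrix(region, H, W)
    depthL[[z]] <- matrix(depthv, H, W)

    # pial curvature (1/mm) and sectioning obliqueness (deg) on GM
    geoP <- .phantomGeometry(spec, z + 1e-3)
    geoM <- .phantomGeometry(spec, z - 1e-3)
    dz_um <- 2e-3 * spec$sectionSpacing
    dcx <- (geoP$cx - geoM$cx) * spec$pixelSize / dz_um
    dcy <- (geoP$cy - geoM$cy) * spec$pixelSize / dz_um
    dR  <- (geoP$rCtx - geoM$rCtx) * spec$pixelSize / dz_um
    ux <- dx / pmax(rad, 1e-9); uy <- dy / pmax(rad, 1e-9)
    nz <- -(ux * dcx + uy * dcy + dR)
    obl <- atan(abs(nz)) * 180 / pi
    oblM <- rep(NA_real_, H * W); oblM[gm] <- obl[gm]
    obliqL[[z]] <- matrix(oblM, H, W)
    curv <- rep(NA_real_, H * W)
    curv[gm] <- 1000 / (geo$rCtx * spec$pixelSize)
    curvL[[z]] <- matrix(curv, H, W)
  }

  PLIStack(sections = sectionsL, masks = masksL, labels = labelsL,
           transforms = transformsL, sectionSpacing = spec$sectionSpacing,
           morphology = list(depth = depthL, curvature = curvL,
                             obliqueness = obliqL))
}

#' Regular-grid labeled patch dataset from a stack
#'
#' Tiles every section on a regular grid and assigns each patch the modal
#' (most frequent) value of the segmentation mask (or of the region label
#' map) within the patch footprint.
#'
#' @param stack a \linkS4class{PLIStack}.
#' @param patchPx patch edge length in pixels.
#' @param stridePx grid stride in pixels (default \code{patchPx}).
#' @param labelSource "mask" for BG/GM/WM classes, "region" for fiber
#'   configuration identity.
#' @param sections integer indices of sections to tile (default all).
#' @return data.frame with columns \code{section}, \code{row}, \code{col}
#'   (1-based top-left pixel of the patch) and \code{class}.
#' @export
labeledPatchDataset <- function(stack, patchPx, stridePx = patchPx,
                                labelSource = c("mask", "region"),
                                sections = seq_along(stack@sections)) {
  labelSource <- match.arg(labelSource)
  d <- dim(stack@sections[[1]]@transmittance)
  if (patchPx > d[1] || patchPx > d[2]) stop("patch does not fit in sections")
  rows <- seq(1L, d[1] - patchPx + 1L, by = stridePx)
  cols <- seq(1L, d[2] - patchPx + 1L, by = stridePx)
  if (!length(rows) || !length(cols)) stop("empty patch grid")
  out <- vector("list", length(sections))
  for (i in seq_along(sections)) {
    z <- sections[i]
    lab <- if (labelSource == "mask") stack@masks[[z]] else stack@labels[[z]]
    grid <- expand.grid(row = rows, col = cols)
    cls <- mapply(function(r, c) {
      v <- lab[r:(r + patchPx - 1L), c:(c + patchPx - 1L)]
      tb <- tabulate(v + 1L)
      which.max(tb) - 1L
    }, grid$row, grid$col)
    out[[i]] <- data.frame(section = z, row = grid$row, col = grid$col,
                           class = as.integer(cls))
  }
  do.call(rbind, out)
}

#' Extract one patch of parameter maps
#' @param stack a \linkS4class{PLIStack}.
#' @param section section index.
#' @param row,col 1-based top-left pixel.
#' @param size patch edge length in pixels.
#' @return a \linkS4class{PLIMaps} patch.
#' @export
extractPatch <- function(stack, section, row, col, size) {
  m <- stack@sections[[section]]
  d <- dim(m@transmittance)
  if (row < 1 || col < 1 || row + size - 1 > d[1] || col + size - 1 > d[2])
    stop("patch footprint out of bounds")
  ri <- row:(row + size - 1L); ci <- col:(col + size - 1L)
  .newMaps(m@transmittance[ri, ci], m@direction[ri, ci],
           m@retardation[ri, ci], pixelSize = m@pixelSize, I0 = m@I0,
           undefined = m@undefined[ri, ci, drop = FALSE])
}
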