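#' Spatial context sampling of positive pairs
#'
#' Positive pairs for contrastive learning are built from spatial
#' neighborhood in the undistorted 3D reference space of a section stack.
#' Four sampling modes are supported:
#' \itemize{
#'   \item \code{"same"}: the anchor is its own positive.
#'   \item \code{"cl2d"}: the positive lies on an in-plane circle of radius
#'     r (micrometers) around the anchor, in the same section.
#'   \item \code{"cl3d"}: the displacement is drawn uniformly on the
#'     surface of a 3D sphere of radius r; the z-coordinate is snapped to
#'     the nearest section other than the anchor's (ties broken at random).
#'   \item \code{"nn"}: the positive sits at the anchor's in-plane
#'     reference coordinates in a random adjacent section.
#' }
#' Anchors are restricted to tissue (GM or WM mask); positive locations are
#' not mask-checked (set \code{strict = TRUE} to enforce it).
#'
#' @name sampling
NULL

.applyAffine <- function(tr, xy) {
  c(tr[1, 1] * xy[1] + tr[1, 2] * xy[2] + tr[1, 3],
    tr[2, 1] * xy[1] + tr[2, 2] * xy[2] + tr[2, 3])
}

.invertAffine <- function(tr) {
  A <- tr[, 1:2]; b <- tr[, 3]
  Ai <- solve(A)
  cbind(Ai, -Ai %*% b)
}

# vectorized z-snap rule: nearest section index to the (fractional)
# z-coordinate, excluding the anchor's own section; ties broken at random;
# out-of-range candidates give NA (the caller redraws the displacement)
.snapSections <- function(zidx, anchorSection, S) {
  lo <- floor(zidx); hi <- lo + 1
  d_lo <- zidx - lo; d_hi <- hi - zidx
  loOk <- lo >= 1 & lo <= S & lo != anchorSection
  hiOk <- hi >= 1 & hi <= S & hi != anchorSection
  pickLo <- loOk & (!hiOk | d_lo < d_hi |
                      (d_lo == d_hi & runif(length(zidx)) < 0.5))
  out <- rep(NA_integer_, length(zidx))
  out[pickLo] <- as.integer(lo[pickLo])
  rest <- !pickLo & hiOk
  out[rest] <- as.integer(hi[rest])
  out
}

.patchFits <- function(d, yx, patchPx) {
  r0 <- yx[1] - floor(patchPx / 2)
  c0 <- yx[2] - floor(patchPx / 2)
  r0 >= 1 && c0 >= 1 && r0 + patchPx - 1 <= d[1] && c0 + patchPx - 1 <= d[2]
}

#' Sample a random tissue anchor location
#'
#' Uniformly random over all foreground pixels (GM or WM) whose centered
#' patch footprint lies inside the section.
#'
#' @param stack a \linkS4class{PLIStack}.
#' @param patchPx anchor patch edge length in pixels (default 192).
#' @param sections candidate section indices (default all).
#' @param index optional precomputed eligible-pixel index (internal use by
#'   the pair sampler to avoid rescanning masks per draw).
#' @return list with \code{section}, \code{row}, \code{col} (patch center,
#'   1-based pixels).
#' @export
sampleAnchor <- function(stack, patchPx = 192L,
                         sections = seq_along(stack@sections),
                         index = NULL) {
  if (is.null(index)) index <- .anchorIndex(stack, patchPx, sections)
  if (sum(index$counts) == 0)
    stop("no foreground tissue available for anchors")
  zi <- sample.int(length(index$sections), 1L, prob = index$counts)
  idx <- index$idx[[zi]]
  pick <- idx[sample.int(length(idx), 1L)]
  list(section = index$sections[zi],
       row = ((pick - 1L) %% index$subRows) + index$rlo,
       col = ((pick - 1L) %/% index$subRows) + index$clo)
}

# precomputed eligible anchor pixels per section (foreground pixels whose
# centered patch fits inside the section)
.anchorIndex <- function(stack, patchPx, sections) {
  d <- dim(stack@sections[[1]]@transmittance)
  half <- ceiling(patchPx / 2)
  rlo <- half + 1L; rhi <- d[1] - half
  clo <- half + 1L; chi <- d[2] - half
  if (rhi < rlo || chi < clo) stop("patch does not fit inside sections")
  idx <- lapply(sections, function(z)
    which(stack@masks[[z]][rlo:rhi, clo:chi] > 0L))
  list(sections = sections, idx = idx,
       counts = vapply(idx, length, numeric(1)),
       rlo = rlo, clo = clo, subRows = rhi - rlo + 1L)
}

#' Sample a positive location for an anchor
#'
#' The anchor is mapped to the reference frame through its section
#' transform; a displacement of radius \code{radiusUm} is drawn (circle for
#' cl2d, sphere surface for cl3d, with the out-of-plane component measured
#' in physical micrometers before snapping to the section grid); the
#' displaced reference point is mapped into the target section's pixel
#' frame through that section's inverse transform. Draws whose target
#' section or patch footprint falls outside the stack are redrawn up to
#' \code{maxRetries} times.
#'
#' @param stack a \linkS4class{PLIStack}.
#' @param anchor anchor location as returned by \code{\link{sampleAnchor}}.
#' @param mode one of "same", "cl2d", "cl3d", "nn".
#' @param radiusUm sampling radius in micrometers (ignored for same/nn).
#' @param patchPx patch size the location must accommodate.
#' @param strict also require the positive center to be on tissue.
#' @param maxRetries bounded redraw attempts before failing.
#' @return list with \code{section}, \code{row}, \code{col}.
#' @export
samplePositive <- function(stack, anchor, mode = c("cl3d", "cl2d", "nn", "same"),
                           radiusUm = 118, patchPx = 192L, strict = FALSE,
                           maxRetries = 100L) {
  mode <- match.arg(mode)
  if (radiusUm < 0) stop("radius must be non-negative")
  S <- length(stack@sections)
  d <- dim(stack@sections[[1]]@transmittance)
  px <- pixelSize(stack)
  if (mode == "same" || (mode == "cl2d" && radiusUm == 0))
    return(anchor)
  if (mode == "nn" || (mode == "cl3d" && radiusUm == 0)) {
    cand <- intersect(c(anchor$section - 1L, anchor$section + 1L), seq_len(S))
    if (!length(cand)) stop("no adjacent section available")
    for (i in seq_len(maxRetries)) {
      z <- cand[sample.int(length(cand), 1L)]
      qref <- .applyAffine(stack@transforms[[anchor$section]],
                           c(anchor$col, anchor$row))
      pxy <- .applyAffine(.invertAffine(stack@transforms[[z]]), qref)
      loc <- list(section = z, row = round(pxy[2]), col = round(pxy[1]))
      if (.patchFits(d, c(loc$row, loc$col), patchPx) &&
          (!strict || stack@masks[[z]][loc$row, loc$col] > 0L))
        return(loc)
    }
    stop("could not place a positive sample within retry budget")
  }
  qref <- .applyAffine(stack@transforms[[anchor$section]],
                       c(anchor$col, anchor$row))
  qref_um <- qref * px
  z_um <- (anchor$section - 1L) * stack@sectionSpacing
  for (i in seq_len(maxRetries)) {
    if (mode == "cl2d") {
      ang <- runif(1, 0, 2 * pi)
      dxy <- radiusUm * c(cos(ang), sin(ang))
      z <- anchor$section
    } else {
      # uniform on the sphere surface: z-coordinate uniform on [-r, r]
      dz <- runif(1, -radiusUm, radiusUm)
      rin <- sqrt(max(radiusUm^2 - dz^2, 0))
      ang <- runif(1, 0, 2 * pi)
      dxy <- rin * c(cos(ang), sin(ang))
      zidx <- (z_um + dz) / stack@sectionSpacing + 1
      z <- .snapSections(zidx, anchor$section, S)
      if (is.na(z)) next
    }
    target_um <- qref_um + dxy
    pxy <- .applyAffine(.invertAffine(stack@transforms[[z]]), target_um / px)
    loc <- list(section = z, row = round(pxy[2]), col = round(pxy[1]))
    if (loc$row < 1 || loc$col < 1 || loc$row > d[1] || loc$col > d[2]) next
    if (!.patchFits(d, c(loc$row, loc$col), patchPx)) next
    if (strict && stack@masks[[z]][loc$row, loc$col] == 0L) next
    return(loc)
  }
  stop("could not place a positive sample within retry budget")
}

#' Extract the anchor/positive patch pair
#'
#' Patches are axis-aligned crops from each section's original
#' (unwarped) parameter maps; no direction re-rotation is applied, so the
#' per-section frames contribute natural orientation variation between the
#' two views.
#'
#' @param stack a \linkS4class{PLIStack}.
#' @param anchor,positive locations (section/row/col patch centers).
#' @param patchPx patch edge length in pixels.
#' @return list of two \linkS4class{PLIMaps} patches.
#' @export
extractPair <- function(stack, anchor, positive, patchPx = 192L) {
  crop <- function(loc) {
    r0 <- loc$row - floor(patchPx / 2)
    c0 <- loc$col - floor(patchPx / 2)
    extractPatch(stack, loc$section, r0, c0, patchPx)
  }
  list(anchor = crop(anchor), positive = crop(positive))
}

#' Sample a stream of positive pairs
#'
#' @param stack a \linkS4class{PLIStack}.
#' @param n number of pairs.
#' @param mode,radiusUm,patchPx,strict see \code{\link{samplePositive}}.
#' @param sections candidate anchor sections.
#' @param seed optional RNG seed.
#' @return data.frame of pair records (one row per pair) with anchor and
#'   positive section/row/col, the mode and the radius; writable as CSV
#'   for audit.
#' @export
samplePairs <- function(stack, n, mode = "cl3d", radiusUm = 118,
                        patchPx = 192L, strict = FALSE,
                        sections = seq_along(stack@sections), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aidx <- .anchorIndex(stack, patchPx, sections)
  rec <- vector("list", n)
  for (i in seq_len(n)) {
    p <- NULL
    for (att in seq_len(50L)) {
      # anchors whose neighborhood cannot host a positive are resampled
      a <- sampleAnchor(stack, patchPx = patchPx, sections = sections,
                        index = aidx)
      p <- tryCatch(samplePositive(stack, a, mode = mode,
                                   radiusUm = radiusUm, patchPx = patchPx,
                                   strict = strict),
                    error = function(e) NULL)
      if (!is.null(p)) break
    }
    if (is.null(p))
      stop("could not build a positive pair for the given stack geometry")
    rec[[i]] <- data.frame(mode = mode, radiusUm = radiusUm,
                           aSection = a$section, aRow = a$row, aCol = a$col,
                           pSection = p$section, pRow = p$row, pCol = p$col)
  }
  do.call(rbind, rec)
}
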