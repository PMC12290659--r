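#' @import methods
#' @importFrom stats rnorm runif sd var prcomp kmeans hclust cutree dist
#'   quantile median coef
#' @useDynLib PLItexture, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.same_dim <- function(a, b) identical(dim(a), dim(b))

#' Per-section 3D-PLI parameter maps
#'
#' Container for the co-registered triplet of 3D-PLI parameter maps of one
#' tissue section: transmittance \eqn{I_T} (mean transmitted light intensity,
#' in units of the incident intensity \eqn{I_0}), in-plane fiber direction
#' \eqn{\varphi} (radians, defined modulo \eqn{\pi} and stored canonically in
#' \eqn{[0, \pi)}), and retardation \eqn{|\sin\delta|} (dimensionless, in
#' \eqn{[0, 1]}). The \code{undefined} slot flags pixels where direction and
#' retardation could not be retrieved (zero signal).
#'
#' @slot transmittance numeric matrix, values in \code{[0, I0]}.
#' @slot direction numeric matrix, radians in \code{[0, pi)}.
#' @slot retardation numeric matrix, values in \code{[0, 1]}.
#' @slot pixelSize numeric(1), in-plane pixel size in micrometers.
#' @slot I0 numeric(1), incident light intensity (default 1).
#' @slot undefined logical matrix flagging pixels with undefined
#'   direction/retardation.
#' @export
setClass("PLIMaps",
  representation(
    transmittance = "matrix",
    direction     = "matrix",
    retardation   = "matrix",
    pixelSize     = "numeric",
    I0            = "numeric",
    undefined     = "matrix"
  ),
  prototype(pixelSize = 1.3, I0 = 1)
)

setValidity("PLIMaps", function(object) {
  msg <- character()
  if (!.same_dim(object@transmittance, object@direction) ||
      !.same_dim(object@transmittance, object@retardation))
    msg <- c(msg, "transmittance, direction and retardation must share dimensions")
  if (length(object@undefined) &&
      !.same_dim(object@transmittance, object@undefined))
    msg <- c(msg, "undefined flag matrix must match map dimensions")
  eps <- 1e-8
  if (any(object@retardation < -eps | object@retardation > 1 + eps, na.rm = TRUE))
    msg <- c(msg, "retardation must lie in [0, 1]")
  if (any(object@direction < -eps | object@direction >= pi + eps, na.rm = TRUE))
    msg <- c(msg, "direction must be canonical in [0, pi)")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a positive scalar")
  if (length(object@I0) != 1L || object@I0 <= 0)
    msg <- c(msg, "I0 must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Construct a PLIMaps object
#'
#' @param transmittance,direction,retardation numeric matrices of equal
#'   dimension. Direction is wrapped into \code{[0, pi)}.
#' @param pixelSize pixel size in micrometers (default 1.3).
#' @param I0 incident intensity the transmittance is measured against.
#' @param undefined optional logical matrix flagging invalid pixels.
#' @return A \linkS4class{PLIMaps} object.
#' @export
PLIMaps <- function(transmittance, direction, retardation,
                    pixelSize = 1.3, I0 = 1, undefined = NULL) {
  direction <- wrapDirection(as.matrix(direction))
  if (is.null(undefined))
    undefined <- matrix(FALSE, nrow(direction), ncol(direction))
  new("PLIMaps",
      transmittance = as.matrix(transmittance),
      direction = direction,
      retardation = as.matrix(retardation),
      pixelSize = pixelSize, I0 = I0, undefined = undefined)
}

#' Raw 9-angle 3D-PLI intensity series
#'
#' Intensity images recorded at the nine equidistant polarizer rotation
#' angles \eqn{\rho_k = k \cdot 20^\circ}, \eqn{k = 0, \dots, 8}, covering
#' 180 degrees of rotation.
#'
#' @slot intensities numeric array of dimension (H, W, 9), non-negative.
#' @slot pixelSize numeric(1), pixel size in micrometers.
#' @export
setClass("PLISeries",
  representation(intensities = "array", pixelSize = "numeric"),
  prototype(pixelSize = 1.3)
)

setValidity("PLISeries", function(object) {
  d <- dim(object@intensities)
  if (length(d) != 3L || d[3] != 9L)
    return("intensities must be an (H, W, 9) array: nine equidistant angles over 180 degrees")
  if (any(object@intensities < 0, na.rm = TRUE))
    return("intensities must be non-negative")
  TRUE
})

#' @rdname PLISeries-class
#' @param intensities (H, W, 9) array of intensities.
#' @param pixelSize pixel size in micrometers.
#' @export
PLISeries <- function(intensities, pixelSize = 1.3) {
  new("PLISeries", intensities = intensities, pixelSize = pixelSize)
}

#' Polarizer rotation angles of the 9-angle acquisition (radians)
#' @return numeric vector of the nine rotation angles.
#' @export
rhoAngles <- function() (0:8) * (20 * pi / 180)

#' Serial-section stack of 3D-PLI parameter maps
#'
#' An ordered stack of per-section \linkS4class{PLIMaps} with tissue masks
#' (0 = background, 1 = gray matter, 2 = white matter), integer region
#' labels identifying distinct fiber configurations, per-section in-plane
#' affine transforms into a common undistorted reference space, and optional
#' analytic morphology maps (cortical depth, curvature, obliqueness).
#'
#' Transforms are 2x3 matrices \code{[A | t]} mapping section pixel
#' coordinates \code{(x, y)} (x = column, y = row, 1-based) to reference
#' pixel coordinates via \code{A \%*\% p + t}.
#'
#' @slot sections list of \linkS4class{PLIMaps}, one per section.
#' @slot masks list of integer matrices in \{0, 1, 2\}.
#' @slot labels list of integer matrices (region identity, 0 on background).
#' @slot transforms list of 2x3 affine matrices (section to reference).
#' @slot sectionSpacing numeric(1), section-to-section distance in micrometers.
#' @slot morphology list with optional elements \code{depth}, \code{curvature},
#'   \code{obliqueness}, each a list of per-section matrices (NA off cortex
#'   where undefined).
#' @export
setClass("PLIStack",
  representation(
    sections       = "list",
    masks          = "list",
    labels         = "list",
    transforms     = "list",
    sectionSpacing = "numeric",
    morphology     = "list"
  ),
  prototype(sectionSpacing = 60, morphology = list())
)

setValidity("PLIStack", function(object) {
  n <- length(object@sections)
  if (n == 0L) return("stack must contain at least one section")
  if (!all(vapply(object@sections, is, logical(1), "PLIMaps")))
    return("sections must all be PLIMaps")
  d <- dim(object@sections[[1]]@transmittance)
  ok <- vapply(object@sections, function(s)
    identical(dim(s@transmittance), d), logical(1))
  if (!all(ok)) return("all sections must share the same shape")
  if (length(object@masks) != n || length(object@labels) != n ||
      length(object@transforms) != n)
    return("masks, labels and transforms must have one entry per section")
  if (!all(vapply(object@masks, function(m) identical(dim(m), d), logical(1))))
    return("mask dimensions must match section dimensions")
  if (!all(vapply(object@transforms, function(tr)
    is.matrix(tr) && all(dim(tr) == c(2L, 3L)), logical(1))))
    return("transforms must be 2x3 affine matrices")
  dets <- vapply(object@transforms, function(tr)
    tr[1, 1] * tr[2, 2] - tr[1, 2] * tr[2, 1], numeric(1))
  if (any(abs(dets) < 1e-12)) return("transforms must be invertible")
  if (object@sectionSpacing <= 0) return("sectionSpacing must be positive")
  TRUE
})

#' @rdname PLIStack-class
#' @param sections list of \linkS4class{PLIMaps}.
#' @param masks,labels lists of integer matrices.
#' @param transforms list of 2x3 affines; defaults to identities.
#' @param sectionSpacing section spacing in micrometers (default 60).
#' @param morphology optional morphology list.
#' @export
PLIStack <- function(sections, masks, labels = NULL, transforms = NULL,
                     sectionSpacing = 60, morphology = list()) {
  n <- length(sections)
  if (is.null(labels))
    labels <- lapply(masks, function(m) m)
  if (is.null(transforms))
    transforms <- replicate(n, cbind(diag(2), c(0, 0)), simplify = FALSE)
  new("PLIStack", sections = sections, masks = masks, labels = labels,
      transforms = transforms, sectionSpacing = sectionSpacing,
      morphology = morphology)
}

#' Grid of texture feature vectors for one section
#'
#' Features extracted on a regular tile grid (tile size \code{tilePx},
#' stride \code{stridePx}; the reference protocol uses 128-pixel tiles with
#' 50 percent overlap). Cell \code{[i, j, ]} holds the feature vector of the
#' tile whose top-left corner is at pixel
#' \code{(row = (i-1)*stride + 1, col = (j-1)*stride + 1)}.
#'
#' @slot features numeric array (gridRows, gridCols, D).
#' @slot tilePx,stridePx integer tile geometry in pixels.
#' @slot section integer section index the map belongs to.
#' @slot foreground logical matrix (gridRows, gridCols): tile has modal
#'   foreground mask value.
#' @slot schema character vector naming the D feature dimensions (may be
#'   empty for learned features).
#' @slot pixelSize numeric(1) pixel size of the underlying section in
#'   micrometers.
#' @export
setClass("PLIFeatureMap",
  representation(
    features   = "array",
    tilePx     = "integer",
    stridePx   = "integer",
    section    = "integer",
    foreground = "matrix",
    schema     = "character",
    pixelSize  = "numeric"
  ),
  prototype(section = 1L, schema = character(), pixelSize = 1.3)
)

setValidity("PLIFeatureMap", function(object) {
  d <- dim(object@features)
  if (length(d) != 3L) return("features must be a 3D array (rows, cols, D)")
  if (length(object@foreground) &&
      !identical(dim(object@foreground), d[1:2]))
    return("foreground grid must match feature grid")
  if (length(object@schema) && length(object@schema) != d[3])
    return("schema length must equal feature dimension")
  if (object@stridePx <= 0L || object@tilePx <= 0L)
    return("tilePx and stridePx must be positive")
  TRUE
})

#' @rdname PLIFeatureMap-class
#' @param features (rows, cols, D) array.
#' @param tilePx,stridePx tile geometry in pixels.
#' @param section section index.
#' @param foreground logical matrix; defaults to all TRUE.
#' @param schema optional feature names.
#' @param pixelSize pixel size in micrometers.
#' @export
PLIFeatureMap <- function(features, tilePx, stridePx, section = 1L,
                          foreground = NULL, schema = character(),
                          pixelSize = 1.3) {
  d <- dim(features)
  if (is.null(foreground)) foreground <- matrix(TRUE, d[1], d[2])
  new("PLIFeatureMap", features = features, tilePx = as.integer(tilePx),
      stridePx = as.integer(stridePx), section = as.integer(section),
      foreground = foreground, schema = schema, pixelSize = pixelSize)
}

#' Two-step clustering result
#'
#' Result of k-means clustering on a subsample followed by Ward
#' agglomeration of the k-means centroids. Cuts of the dendrogram at K
#' clusters relabel all points through their centroid assignment.
#'
#' @slot centroids k x d matrix of k-means centroids.
#' @slot assignments integer vector: nearest centroid per input point.
#' @slot linkage the \code{hclust} merge tree over centroids.
#' @slot silhouette data.frame with columns \code{K} and \code{score}
#'   (mean silhouette width on the k-means subsample, NA for K = 1).
#' @slot subsetIdx integer vector: indices of the k-means subsample.
#' @export
setClass("PLIClusterResult",
  representation(
    centroids   = "matrix",
    assignments = "integer",
    linkage     = "ANY",
    silhouette  = "data.frame",
    subsetIdx   = "integer"
  )
)

setValidity("PLIClusterResult", function(object) {
  k <- nrow(object@centroids)
  if (length(object@assignments) &&
      (min(object@assignments) < 1L || max(object@assignments) > k))
    return("assignments must index centroids")
  if (!is.null(object@linkage) && !inherits(object@linkage, "hclust"))
    return("linkage must be an hclust object")
  if (!is.null(object@linkage) && is.unsorted(object@linkage$height))
    return("linkage heights must be non-decreasing")
  TRUE
})
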