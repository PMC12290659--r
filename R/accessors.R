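#' Wrap direction angles into the canonical range [0, pi)
#'
#' All in-plane fiber direction arithmetic in the package is modulo pi,
#' because 3D-PLI cannot distinguish a fiber from its reverse.
#'
#' @param phi angles in radians (any range).
#' @return angles wrapped into \code{[0, pi)}.
#' @export
wrapDirection <- function(phi) {
  out <- phi %% pi
  # guard against pi itself from floating point of the modulo
  out[out >= pi] <- 0
  out
}

# fast internal constructor for hot paths: inputs already canonical,
# skip validity (public PLIMaps() remains the checked entry point)
.pkgCache <- new.env(parent = emptyenv())

.newMaps <- function(IT, phi, r, pixelSize, I0, undefined = NULL) {
  if (is.null(.pkgCache$mapsProto))
    .pkgCache$mapsProto <- new("PLIMaps", transmittance = matrix(0, 1, 1),
                               direction = matrix(0, 1, 1),
                               retardation = matrix(0, 1, 1),
                               pixelSize = 1, I0 = 1,
                               undefined = matrix(FALSE, 1, 1))
  out <- .pkgCache$mapsProto
  slot(out, "transmittance", check = FALSE) <- IT
  slot(out, "direction", check = FALSE) <- phi
  slot(out, "retardation", check = FALSE) <- r
  slot(out, "pixelSize", check = FALSE) <- pixelSize
  slot(out, "I0", check = FALSE) <- I0
  if (is.null(undefined)) undefined <- matrix(FALSE, nrow(IT), ncol(IT))
  slot(out, "undefined", check = FALSE) <- undefined
  out
}

#' @rdname PLIMaps-class
#' @param object,x a PLItexture S4 object.
#' @export
setGeneric("transmittance", function(x) standardGeneric("transmittance"))
#' @rdname PLIMaps-class
#' @export
setGeneric("direction", function(x) standardGeneric("direction"))
#' @rdname PLIMaps-class
#' @export
setGeneric("retardation", function(x) standardGeneric("retardation"))
#' @rdname PLIMaps-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname PLIMaps-class
#' @export
setGeneric("incidentIntensity", function(x) standardGeneric("incidentIntensity"))
#' @rdname PLISeries-class
#' @param x a \linkS4class{PLISeries}.
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname PLIStack-class
#' @param x a \linkS4class{PLIStack}.
#' @export
setGeneric("sections", function(x) standardGeneric("sections"))
#' @rdname PLIStack-class
#' @export
setGeneric("masks", function(x) standardGeneric("masks"))
#' @rdname PLIStack-class
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))
#' @rdname PLIStack-class
#' @export
setGeneric("transforms", function(x) standardGeneric("transforms"))
#' @rdname PLIStack-class
#' @export
setGeneric("sectionSpacing", function(x) standardGeneric("sectionSpacing"))
#' @rdname PLIStack-class
#' @export
setGeneric("morphology", function(x) standardGeneric("morphology"))
#' @rdname PLIFeatureMap-class
#' @param x a \linkS4class{PLIFeatureMap}.
#' @export
setGeneric("featureArray", function(x) standardGeneric("featureArray"))
#' @rdname PLIFeatureMap-class
#' @export
setGeneric("tilePx", function(x) standardGeneric("tilePx"))
#' @rdname PLIFeatureMap-class
#' @export
setGeneric("stridePx", function(x) standardGeneric("stridePx"))
#' @rdname PLIFeatureMap-class
#' @export
setGeneric("foreground", function(x) standardGeneric("foreground"))
#' @rdname PLIFeatureMap-class
#' @export
setGeneric("featureSchema", function(x) standardGeneric("featureSchema"))

setMethod("transmittance", "PLIMaps", function(x) x@transmittance)
setMethod("direction", "PLIMaps", function(x) x@direction)
setMethod("retardation", "PLIMaps", function(x) x@retardation)
setMethod("pixelSize", "PLIMaps", function(x) x@pixelSize)
setMethod("incidentIntensity", "PLIMaps", function(x) x@I0)
setMethod("pixelSize", "PLISeries", function(x) x@pixelSize)
setMethod("intensities", "PLISeries", function(x) x@intensities)
setMethod("sections", "PLIStack", function(x) x@sections)
setMethod("masks", "PLIStack", function(x) x@masks)
setMethod("regionLabels", "PLIStack", function(x) x@labels)
setMethod("transforms", "PLIStack", function(x) x@transforms)
setMethod("sectionSpacing", "PLIStack", function(x) x@sectionSpacing)
setMethod("morphology", "PLIStack", function(x) x@morphology)
setMethod("pixelSize", "PLIStack", function(x) x@sections[[1]]@pixelSize)
setMethod("featureArray", "PLIFeatureMap", function(x) x@features)
setMethod("tilePx", "PLIFeatureMap", function(x) x@tilePx)
setMethod("stridePx", "PLIFeatureMap", function(x) x@stridePx)
setMethod("foreground", "PLIFeatureMap", function(x) x@foreground)
setMethod("featureSchema", "PLIFeatureMap", function(x) x@schema)
setMethod("pixelSize", "PLIFeatureMap", function(x) x@pixelSize)

#' Number of sections in a stack
#' @param x a \linkS4class{PLIStack}.
#' @export
setMethod("length", "PLIStack", function(x) length(x@sections))

setMethod("dim", "PLIMaps", function(x) dim(x@transmittance))

setMethod("show", "PLIMaps", function(object) {
  d <- dim(object@transmittance)
  cat(sprintf("PLIMaps: %d x %d pixels at %.3g um/px (I0 = %.3g)\n",
              d[1], d[2], object@pixelSize, object@I0))
  cat(sprintf("  transmittance [%.3g, %.3g], retardation [%.3g, %.3g]\n",
              min(object@transmittance), max(object@transmittance),
              min(object@retardation), max(object@retardation)))
  invisible(NULL)
})

setMethod("show", "PLISeries", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("PLISeries: %d x %d pixels, 9 rotation angles (0..160 deg)\n",
              d[1], d[2]))
  invisible(NULL)
})

setMethod("show", "PLIStack", function(object) {
  d <- dim(object@sections[[1]]@transmittance)
  cat(sprintf(
    "PLIStack: %d sections of %d x %d px, spacing %.3g um, pixel %.3g um\n",
    length(object@sections), d[1], d[2], object@sectionSpacing,
    object@sections[[1]]@pixelSize))
  if (length(object@morphology))
    cat("  morphology:", paste(names(object@morphology), collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "PLIFeatureMap", function(object) {
  d <- dim(object@features)
  cat(sprintf(
    "PLIFeatureMap: %d x %d tiles (tile %d px, stride %d px), D = %d\n",
    d[1], d[2], object@tilePx, object@stridePx, d[3]))
  invisible(NULL)
})

setMethod("show", "PLIClusterResult", function(object) {
  cat(sprintf("PLIClusterResult: %d centroids, %d assigned points\n",
              nrow(object@centroids), length(object@assignments)))
  invisible(NULL)
})
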