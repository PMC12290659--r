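#' File formats
#'
#' Parameter maps and raw angle series are stored as multi-page TIFF with
#' a JSON sidecar (same path plus ".json") holding pixel size, incident
#' intensity and per-page scaling, so that values are reconstructed on
#' read. Section stacks are directories of per-section TIFFs plus a single
#' "stack.json" with transforms and spacing. Feature maps are stored as a
#' single JSON document (grids are small relative to the image data).
#'
#' @name pli-io
NULL

.tiffBits <- 16L   # 16-bit pages: ~1.5e-5 quantization over [0, 1]

#' Write / read parameter maps as multi-page TIFF + JSON sidecar
#'
#' Pages are, in order, transmittance / I0, direction / pi and
#' retardation, each in [0, 1].
#'
#' @param maps a \linkS4class{PLIMaps}.
#' @param path TIFF file path; the sidecar is written at
#'   \code{paste0(path, ".json")}.
#' @return \code{path} (write) or a \linkS4class{PLIMaps} (read).
#' @export
writeParameterMaps <- function(maps, path) {
  I0 <- incidentIntensity(maps)
  # transmittance may exceed I0 on noisy data; record the page scale
  itScale <- max(1, max(transmittance(maps) / I0, na.rm = TRUE))
  pages <- list(pmax(transmittance(maps) / I0, 0) / itScale,
                direction(maps) / pi,
                pmin(pmax(retardation(maps), 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = .tiffBits)
  jsonlite::write_json(list(kind = "PLIMaps", pixel_size_um = pixelSize(maps),
                            I0 = I0, transmittance_scale = itScale,
                            pages = c("transmittance", "direction",
                                      "retardation")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeParameterMaps
#' @export
readParameterMaps <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  sc <- if (is.null(meta$transmittance_scale)) 1 else meta$transmittance_scale
  PLIMaps(pages[[1]] * meta$I0 * sc, pages[[2]] * pi, pages[[3]],
          pixelSize = meta$pixel_size_um, I0 = meta$I0)
}

#' Write / read a 9-angle raw series as multi-page TIFF + JSON sidecar
#' @param series a \linkS4class{PLISeries}.
#' @param path TIFF file path.
#' @export
writeRawSeries <- function(series, path) {
  x <- intensities(series)
  scale <- max(x, 1e-12)
  pages <- lapply(seq_len(9L), function(k) x[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = .tiffBits)
  jsonlite::write_json(list(kind = "PLISeries",
                            pixel_size_um = pixelSize(series),
                            intensity_scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRawSeries
#' @export
readRawSeries <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  x <- array(0, c(dim(pages[[1]]), 9L))
  for (k in seq_len(9L)) x[, , k] <- pages[[k]] * meta$intensity_scale
  PLISeries(x, pixelSize = meta$pixel_size_um)
}

#' Write / read a section stack as a directory of TIFFs + stack.json
#'
#' Each section is stored as \code{section_###.tif} (parameter-map pages)
#' plus \code{mask_###.tif} and \code{labels_###.tif}; transforms, section
#' spacing and pixel size go into \code{stack.json}. Morphology ground
#' truth is not serialized (phantom stacks can be regenerated from their
#' specification and seed).
#'
#' @param stack a \linkS4class{PLIStack}.
#' @param dir directory path (created if missing).
#' @export
writeSectionStack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  S <- length(stack@sections)
  for (z in seq_len(S)) {
    writeParameterMaps(stack@sections[[z]],
                       file.path(dir, sprintf("section_%03d.tif", z)))
    tiff::writeTIFF(stack@masks[[z]] / 255,
                    file.path(dir, sprintf("mask_%03d.tif", z)),
                    bits.per.sample = 8L)
    tiff::writeTIFF(stack@labels[[z]] / 255,
                    file.path(dir, sprintf("labels_%03d.tif", z)),
                    bits.per.sample = 8L)
  }
  jsonlite::write_json(
    list(kind = "PLIStack", n_sections = S,
         section_spacing_um = stack@sectionSpacing,
         pixel_size_um = pixelSize(stack),
         transforms = lapply(stack@transforms, function(m)
           as.vector(t(m)))),
    file.path(dir, "stack.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeSectionStack
#' @export
readSectionStack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "stack.json"),
                              simplifyVector = TRUE)
  S <- meta$n_sections
  secs <- vector("list", S); msks <- vector("list", S)
  labs <- vector("list", S)
  for (z in seq_len(S)) {
    secs[[z]] <- readParameterMaps(file.path(dir,
                                             sprintf("section_%03d.tif", z)))
    msks[[z]] <- matrix(as.integer(round(
      tiff::readTIFF(file.path(dir, sprintf("mask_%03d.tif", z))) * 255)),
      nrow = nrow(secs[[z]]@transmittance))
    labs[[z]] <- matrix(as.integer(round(
      tiff::readTIFF(file.path(dir, sprintf("labels_%03d.tif", z))) * 255)),
      nrow = nrow(secs[[z]]@transmittance))
  }
  tr_raw <- meta$transforms
  if (is.matrix(tr_raw))
    tr_raw <- lapply(seq_len(nrow(tr_raw)), function(i) tr_raw[i, ])
  trs <- lapply(tr_raw, function(v) matrix(unlist(v), 2, 3, byrow = TRUE))
  PLIStack(secs, msks, labs, trs,
           sectionSpacing = meta$section_spacing_um)
}

#' Write / read a feature map as JSON
#' @param fm a \linkS4class{PLIFeatureMap}.
#' @param path JSON file path.
#' @export
writeFeatureMap <- function(fm, path) {
  d <- dim(fm@features)
  jsonlite::write_json(
    list(kind = "PLIFeatureMap", dim = d, tile_px = fm@tilePx,
         stride_px = fm@stridePx, section = fm@section,
         pixel_size_um = fm@pixelSize, schema = fm@schema,
         foreground = as.vector(fm@foreground),
         features = as.vector(fm@features)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeFeatureMap
#' @export
readFeatureMap <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  PLIFeatureMap(array(m$features, m$dim), tilePx = m$tile_px,
                stridePx = m$stride_px, section = m$section,
                foreground = matrix(m$foreground, m$dim[1], m$dim[2]),
                schema = if (length(m$schema)) m$schema else character(),
                pixelSize = m$pixel_size_um)
}

#' Save / load a trained encoder
#'
#' The encoder's weights, configuration and input statistics are written
#' as one JSON document (text-only, portable).
#'
#' @param model a \code{"PLIEncoder"}.
#' @param path JSON file path.
#' @export
writeEncoder <- function(model, path) {
  ser <- function(x) {
    if (is.list(x)) return(lapply(x, ser))
    if (is.matrix(x)) return(list(`_mat` = dim(x), v = as.vector(x)))
    x
  }
  obj <- list(kind = "PLIEncoder", cfg = unclass(model$cfg),
              featureDim = model$featureDim,
              net = ser(model$net), head = ser(model$head),
              norm = model$norm)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname writeEncoder
#' @export
readEncoder <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  de <- function(x) {
    if (is.list(x)) {
      if (!is.null(x[["_mat"]])) {
        d <- unlist(x[["_mat"]])
        return(matrix(unlist(x[["v"]]), d[1], d[2]))
      }
      if (length(x) && is.null(names(x)) &&
          all(vapply(x, function(e) is.atomic(e) && length(e) == 1L,
                     logical(1))))
        return(unlist(x))
      return(lapply(x, de))
    }
    x
  }
  cfg <- do.call(encoderConfig, lapply(raw$cfg, unlist))
  model <- list(net = de(raw$net), head = de(raw$head), cfg = cfg,
                featureDim = unlist(raw$featureDim),
                norm = list(count = unlist(raw$norm$count),
                            mean = unlist(raw$norm$mean),
                            m2 = unlist(raw$norm$m2),
                            frozen = isTRUE(unlist(raw$norm$frozen))))
  class(model) <- "PLIEncoder"
  model
}
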