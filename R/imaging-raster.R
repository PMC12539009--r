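# Minimal single-band planar raster container and IO.
#
# A bandRaster is a matrix of reflectances (or digital numbers) plus an
# affine georeference: top-left corner (xmin, ymax), square pixels of side
# pixelSize in CRS units, rows running north to south. On disk it is a TIFF
# (values scaled into [0,1], validity mask as a second channel when needed),
# an ESRI world file (.tfw) for the georeference, and a JSON sidecar for the
# band name, CRS tag and value scaling.

#' Construct a band raster
#'
#' @param values numeric matrix; rows north-to-south, columns west-to-east.
#'   \code{NA} marks missing pixels.
#' @param xmin,ymax coordinates of the top-left corner of the raster in CRS
#'   units (metres for a planar CRS).
#' @param pixelSize pixel side length in CRS units (> 0).
#' @param band band label, e.g. "668" for the 668 nm red band.
#' @param crs CRS tag (e.g. "EPSG:32632"); compared verbatim between rasters
#'   and polygons, no reprojection.
#' @return An object of class \code{bandRaster}.
#' @export
bandRaster <- function(values, xmin = 0, ymax = nrow(values) * pixelSize,
                       pixelSize = 1, band = "value", crs = "local") {
  stopIfNot(pixelSize > 0, "pixelSize must be positive")
  values <- as.matrix(values)
  structure(list(values = values, xmin = xmin, ymax = ymax,
                 pixelSize = pixelSize, band = band, crs = crs),
            class = "bandRaster")
}

#' @export
print.bandRaster <- function(x, ...) {
  cat(sprintf("bandRaster '%s': %d x %d px, pixel %g, origin (%g, %g), crs %s\n",
              x$band, nrow(x$values), ncol(x$values), x$pixelSize,
              x$xmin, x$ymax, x$crs))
  invisible(x)
}

# Pixel-centre coordinate grids.
pixelCentres <- function(r) {
  xs <- r$xmin + (seq_len(ncol(r$values)) - 0.5) * r$pixelSize
  ys <- r$ymax - (seq_len(nrow(r$values)) - 0.5) * r$pixelSize
  list(x = xs, y = ys)
}

#' Write / read a band raster
#'
#' \code{writeBandRaster} writes \code{<path>.tif} (32-bit TIFF, values
#' rescaled into [0,1]; a validity-mask channel is added when the raster has
#' missing pixels), \code{<path>.tfw} (world file) and \code{<path>.json}
#' (band, CRS, value scaling). \code{readBandRaster} reverses this.
#'
#' @param r a \code{\link{bandRaster}}.
#' @param path file path without extension.
#' @return \code{writeBandRaster} returns \code{path} invisibly;
#'   \code{readBandRaster} returns a \code{bandRaster}.
#' @export
writeBandRaster <- function(r, path) {
  v <- r$values
  fin <- v[is.finite(v)]
  lo <- if (length(fin)) min(fin) else 0
  hi <- if (length(fin)) max(fin) else 1
  if (hi <= lo) hi <- lo + 1
  sc <- (v - lo) / (hi - lo)
  hasNA <- anyNA(v)
  arr <- if (hasNA) {
    sc[is.na(sc)] <- 0
    array(c(sc, 1 - is.na(v)), dim = c(dim(v), 2))
  } else sc
  suppressWarnings(tiff::writeTIFF(arr, paste0(path, ".tif"),
                                   bits.per.sample = 32L))
  # world file: pixel size x, rotations, negative pixel size y, centre of
  # the top-left pixel
  writeLines(format(c(r$pixelSize, 0, 0, -r$pixelSize,
                      r$xmin + r$pixelSize / 2, r$ymax - r$pixelSize / 2),
                    digits = 17),
             paste0(path, ".tfw"))
  jsonlite::write_json(list(band = r$band, crs = r$crs, value_min = lo,
                            value_max = hi, mask = hasNA),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeBandRaster
#' @export
readBandRaster <- function(path) {
  arr <- suppressWarnings(tiff::readTIFF(paste0(path, ".tif")))
  tfw <- as.numeric(readLines(paste0(path, ".tfw")))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (length(dim(arr)) == 3) {
    v <- arr[, , 1]
    v[arr[, , 2] < 0.5] <- NA
  } else v <- arr
  v <- v * (meta$value_max - meta$value_min) + meta$value_min
  bandRaster(v, xmin = tfw[5] - tfw[1] / 2, ymax = tfw[6] - tfw[4] / 2,
             pixelSize = tfw[1], band = meta$band, crs = meta$crs)
}

#' Read / write plot polygons as GeoJSON
#'
#' Plot boundaries are polygons with a \code{plot_id} feature property.
#' Only Polygon geometries (outer ring) are supported; an optional
#' top-level \code{crs} name member is preserved as the CRS tag.
#'
#' @param path GeoJSON file path.
#' @return A list of class \code{plotPolygons}: each element has
#'   \code{plot_id} and \code{coords} (two-column matrix of the outer
#'   ring); attribute \code{crs}.
#' @export
readPlotPolygons <- function(path) {
  g <- jsonlite::read_json(path)
  crs <- if (!is.null(g$crs$properties$name)) g$crs$properties$name else "local"
  polys <- lapply(g$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) as.numeric(unlist(p))))
    list(plot_id = as.character(f$properties$plot_id), coords = m)
  })
  structure(polys, class = "plotPolygons", crs = crs)
}

#' @rdname readPlotPolygons
#' @param polys a \code{plotPolygons} list (elements with \code{plot_id} and
#'   \code{coords}).
#' @param crs CRS tag to record.
#' @export
writePlotPolygons <- function(polys, path, crs = attr(polys, "crs") %||% "local") {
  feats <- lapply(polys, function(p) {
    ring <- lapply(seq_len(nrow(p$coords)), function(i) as.numeric(p$coords[i, ]))
    list(type = "Feature",
         properties = list(plot_id = p$plot_id),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  obj <- list(type = "FeatureCollection",
              crs = list(type = "name", properties = list(name = crs)),
              features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-plot band/index medians from a raster
#'
#' Zonal median per plot polygon: the median of all pixels whose centre
#' falls inside the polygon, missing pixels excluded. Plots with fewer than
#' \code{minCoveragePx} valid pixels are flagged excluded and carry no
#' value (this mirrors dropping field plots with missing or extremely poor
#' vegetation coverage).
#'
#' @param raster a \code{\link{bandRaster}} or a named list of them (one per
#'   band/index).
#' @param polygons a \code{\link{readPlotPolygons}} result (or compatible
#'   list).
#' @param minCoveragePx minimum number of valid pixels (default 50).
#' @return data.frame: \code{plot_id}, \code{band}, \code{value},
#'   \code{n_valid_px}, \code{excluded}.
#' @export
extractPlotMedians <- function(raster, polygons, minCoveragePx = 50) {
  rl <- if (inherits(raster, "bandRaster")) {
    setNames(list(raster), raster$band)
  } else raster
  pcrs <- attr(polygons, "crs") %||% "local"
  out <- list()
  for (bn in names(rl)) {
    r <- rl[[bn]]
    if (!identical(r$crs, pcrs) && r$crs != "local" && pcrs != "local")
      stop("CRS mismatch: raster '", r$crs, "' vs polygons '", pcrs,
           "'; reproject inputs first")
    pc <- pixelCentres(r)
    grid <- cbind(rep(pc$x, each = length(pc$y)), rep(pc$y, length(pc$x)))
    vals <- as.vector(r$values)  # column-major matches grid ordering
    for (p in polygons) {
      cm <- p$coords
      if (min(cm[, 1]) < r$xmin - 1e-9 ||
          max(cm[, 1]) > r$xmin + ncol(r$values) * r$pixelSize + 1e-9 ||
          max(cm[, 2]) > r$ymax + 1e-9 ||
          min(cm[, 2]) < r$ymax - nrow(r$values) * r$pixelSize - 1e-9)
        stop("extraction error: polygon for plot '", p$plot_id,
             "' lies outside the raster extent")
      inside <- mgcv::in.out(rbind(cm, cm[1, ]), grid)
      px <- vals[inside]
      nValid <- sum(!is.na(px))
      excl <- nValid < minCoveragePx
      out[[length(out) + 1L]] <- data.frame(
        plot_id = p$plot_id, band = bn,
        value = if (excl) NA_real_ else median(px, na.rm = TRUE),
        n_valid_px = nValid, excluded = excl)
    }
  }
  do.call(rbind, out)
}
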