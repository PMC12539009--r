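#' Solve band reflectances that reproduce target index values
#'
#' Inverse problem for the fixture generator: given target PSRI, NDVI (and
#' optionally NDRE) values, choose per-band reflectances so that applying
#' the index formulas recovers the targets exactly. Blue is fixed, red
#' follows from NDVI and the 842 nm near-IR, the near-IR level follows from
#' PSRI, and the red edge from NDRE. On the dual camera the PSRI near-IR
#' band (740 nm) is taken as a fixed fraction (0.95) of the 842 nm band.
#' All solved bands must land in (0, 1]; unattainable targets raise an
#' error naming the violated band.
#'
#' @param psriTarget,ndviTarget,ndreTarget target index values (vectors are
#'   recycled to a common length; NDRE defaults to NDVI * 0.7).
#' @param blue fixed 475 nm blue reflectance (default 0.08).
#' @param camera a \code{\link{cameraModel}}.
#' @return data.frame of band reflectances, one column per band key
#'   ("475", "560", "668", "717", "740", "842"; no "740" on the MX camera).
#' @export
renderBandMedians <- function(psriTarget, ndviTarget, ndreTarget = NULL,
                              blue = 0.08, camera = cameraModel("dual")) {
  n <- max(length(psriTarget), length(ndviTarget))
  psri <- rep_len(psriTarget, n); ndvi <- rep_len(ndviTarget, n)
  ndre <- if (is.null(ndreTarget)) ndvi * 0.7 else rep_len(ndreTarget, n)
  stopIfNot(all(blue > 0 & blue <= 1), "value error: blue band outside (0, 1]")
  stopIfNot(all(abs(ndvi) < 1) && all(abs(ndre) < 1),
            "value error: NDVI/NDRE targets must lie in (-1, 1)")
  fracNir <- if (camera$psriNir == "740") 0.95 else 1
  g <- (1 - ndvi) / (1 + ndvi)          # red = g * nir842
  denom <- g / blue - fracNir
  if (any(denom <= 0))
    stop("value error: near-IR band unattainable for these PSRI/NDVI targets",
         " (red/blue ratio too small)")
  nir842 <- psri / denom
  red <- g * nir842
  nirPsri <- fracNir * nir842
  rededge <- nir842 * (1 - ndre) / (1 + ndre)
  green <- pmin(1, (blue + red) / 2 + 0.02)
  chk <- function(x, nm) if (any(x <= 0 | x > 1))
    stop("value error: ", nm, " band outside (0, 1] for some target") else x
  out <- data.frame(`475` = rep_len(blue, n), `560` = chk(green, "560"),
                    `668` = chk(red, "668"), `717` = chk(rededge, "717"),
                    `842` = chk(nir842, "842"), check.names = FALSE)
  if (camera$psriNir == "740") out[["740"]] <- chk(nirPsri, "740")
  out[, intersect(c("475", "560", "668", "717", "740", "842"), names(out))]
}

#' Render plot-grid rasters and polygons for one band
#'
#' Fixture generator for the imaging module: lays the plots out on a
#' regular grid, fills each plot rectangle with its target value (plus
#' optional zero-mean within-plot noise), and returns the raster together
#' with matching plot polygons. Off-plot pixels (the gaps) are missing.
#'
#' @param plotValues named numeric vector, one target value per plot id.
#' @param plotWidth,plotLength plot footprint in metres (default 3 x 7).
#' @param gap gap between plots in metres (>= 0; overlapping layouts are a
#'   layout error).
#' @param pixelSize pixel side in metres (default 0.02, i.e. 2 x 2 cm).
#' @param noiseSd within-plot pixel noise SD (default 0).
#' @param seed RNG seed for the noise.
#' @param band band label for the raster.
#' @param nPlotCols plots per grid row (default: near-square layout).
#' @return list: \code{raster} (a \code{\link{bandRaster}}), \code{polygons}
#'   (a \code{plotPolygons} list).
#' @export
renderPlotRaster <- function(plotValues, plotWidth = 3, plotLength = 7,
                             gap = 0.5, pixelSize = 0.02, noiseSd = 0,
                             seed = 1, band = "value", nPlotCols = NULL) {
  stopIfNot(pixelSize > 0, "argument error: pixel size must be positive")
  if (gap < 0) stop("layout error: negative gap would make plots overlap")
  nP <- length(plotValues)
  stopIfNot(nP > 0 && !is.null(names(plotValues)), "plotValues must be named")
  if (is.null(nPlotCols)) nPlotCols <- ceiling(sqrt(nP))
  nRows <- ceiling(nP / nPlotCols)
  pw <- round(plotWidth / pixelSize); ph <- round(plotLength / pixelSize)
  gpx <- round(gap / pixelSize)
  W <- nPlotCols * pw + (nPlotCols + 1) * gpx
  H <- nRows * ph + (nRows + 1) * gpx
  vals <- matrix(NA_real_, H, W)
  polys <- vector("list", nP)
  withSeed(childSeed(seed, "raster"), {
    for (i in seq_len(nP)) {
      pr <- (i - 1) %/% nPlotCols; pc <- (i - 1) %% nPlotCols
      r0 <- gpx + pr * (ph + gpx); c0 <- gpx + pc * (pw + gpx)
      block <- matrix(plotValues[i], ph, pw)
      if (noiseSd > 0) block <- block + rnorm(ph * pw, 0, noiseSd)
      vals[(r0 + 1):(r0 + ph), (c0 + 1):(c0 + pw)] <- block
      # polygon in map coordinates (y up, origin at raster bottom-left)
      x0 <- c0 * pixelSize; x1 <- (c0 + pw) * pixelSize
      yTop <- (H - r0) * pixelSize; yBot <- (H - r0 - ph) * pixelSize
      polys[[i]] <- list(plot_id = names(plotValues)[i],
                         coords = cbind(c(x0, x1, x1, x0),
                                        c(yBot, yBot, yTop, yTop)))
    }
  })
  list(raster = bandRaster(vals, xmin = 0, ymax = H * pixelSize,
                           pixelSize = pixelSize, band = band, crs = "local"),
       polygons = structure(polys, class = "plotPolygons", crs = "local"))
}

#' Simulate a daily min/max temperature series
#'
#' Seasonal sinusoid for the daily mean (coldest in mid January) with
#' normal day-to-day deviations; the diurnal range is drawn around
#' \code{spread} degrees. Deterministic under a fixed seed.
#'
#' @param startDate,endDate series range (start < end, inclusive).
#' @param seed integer seed.
#' @param meanAnnual annual mean temperature in deg C (default 10.5).
#' @param amplitude seasonal half-amplitude in deg C (default 9).
#' @param dailySd day-to-day SD of the daily mean (default 2.5).
#' @param spread mean diurnal range tmax - tmin (default 9).
#' @param spreadSd SD of the diurnal range (default 2; the range is floored
#'   at 0 so tmin <= tmax always).
#' @return data.frame: \code{date}, \code{tmin}, \code{tmax}.
#' @export
simulateTemperatures <- function(startDate, endDate, seed = 1,
                                 meanAnnual = 10.5, amplitude = 9,
                                 dailySd = 2.5, spread = 9, spreadSd = 2) {
  startDate <- as.Date(startDate); endDate <- as.Date(endDate)
  if (startDate >= endDate) stop("argument error: startDate must precede endDate")
  dates <- seq(startDate, endDate, by = "day")
  withSeed(childSeed(seed, "temperatures"), {
    doy <- as.integer(format(dates, "%j"))
    mean_d <- meanAnnual - amplitude * cos(2 * pi * (doy - 15) / 365.25) +
      rnorm(length(dates), 0, dailySd)
    rng <- pmax(spread + rnorm(length(dates), 0, spreadSd), 0)
    data.frame(date = dates, tmin = mean_d - rng / 2, tmax = mean_d + rng / 2)
  })
}
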