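test_that("vegetation index formulas and camera band selection", {
  expect_equal(computeIndex(c("842" = 0.5, "668" = 0.1), "NDVI"), 2 / 3)
  expect_equal(computeIndex(c("842" = 0.5, "717" = 0.3), "NDRE"), 0.25)
  expect_equal(computeIndex(c("668" = 0.2, "475" = 0.1, "740" = 0.5), "PSRI"),
               1.5)
  # PSRI near-IR band is camera specific: 740 nm dual, 842 nm MX
  b <- c("668" = 0.2, "475" = 0.1, "740" = 0.5, "842" = 0.9)
  expect_equal(computeIndex(b, "PSRI", cameraModel("dual")), 2 - 0.5)
  expect_equal(computeIndex(b, "PSRI", cameraModel("mx")), 2 - 0.9)
  expect_error(computeIndex(c("668" = 0.2, "475" = 0, "740" = 0.5), "PSRI"),
               "division")
  expect_error(computeIndex(c("842" = 0.5), "NDVI"), "configuration")
})

test_that("NDVI/NDRE antisymmetry and PSRI monotonicity in red", {
  set.seed(41)
  for (i in 1:20) {
    a <- runif(1, 0.05, 1); b <- runif(1, 0.05, 1)
    expect_equal(computeIndex(c("842" = a, "668" = b), "NDVI"),
                 -computeIndex(c("842" = b, "668" = a), "NDVI"))
  }
  reds <- seq(0.05, 0.9, by = 0.05)
  psri <- vapply(reds, function(r)
    computeIndex(c("668" = r, "475" = 0.1, "740" = 0.4), "PSRI"), 1)
  expect_true(all(diff(psri) > 0))
})

test_that("empirical-line calibration inverts the affine sensor model", {
  cal <- empiricalLineCalibrate(c(10, 50), c(0.1, 0.5), 30)
  expect_equal(cal$reflectance, 0.3, tolerance = 1e-12)
  expect_equal(empiricalLineCalibrate(c(10, 50), c(0.1, 0.5), 50)$reflectance,
               0.5, tolerance = 1e-12)   # interpolation node
  # noisy panels: gain/offset equal the normal-equation solution
  set.seed(42)
  rho <- seq(0.05, 0.85, by = 0.1)
  dn <- 12 + 90 * rho + rnorm(9, 0, 0.5)
  cal <- empiricalLineCalibrate(dn, rho, dn)
  X <- cbind(1, rho)
  beta <- solve(t(X) %*% X, t(X) %*% dn)
  expect_equal(cal$offset, beta[1], tolerance = 1e-10)
  expect_equal(cal$gain, beta[2], tolerance = 1e-10)
  # idempotence with identity panels
  scene <- matrix(runif(12), 3)
  out <- empiricalLineCalibrate(c(0, 1), c(0, 1), scene)
  expect_equal(out$reflectance, scene, tolerance = 1e-12)
  expect_warning(empiricalLineCalibrate(c(0, 1), c(0, 1), 1.7), "clipped")
  expect_error(empiricalLineCalibrate(5, 0.3, 1), "calibration error")
  expect_error(empiricalLineCalibrate(c(5, 9), c(0.3, 0.3), 1),
               "calibration error")
})

test_that("plot medians match brute-force sort medians and flag poor coverage", {
  r <- bandRaster(matrix(c(1, 3, 2, 4), 2, 2), xmin = 0, ymax = 2,
                  pixelSize = 1)
  sq <- list(list(plot_id = "p1",
                  coords = cbind(c(0, 2, 2, 0), c(0, 0, 2, 2))))
  polys <- structure(sq, class = "plotPolygons", crs = "local")
  out <- extractPlotMedians(r, polys, minCoveragePx = 1)
  expect_equal(out$value, 2.5)            # even-count median
  expect_equal(out$n_valid_px, 4)
  r3 <- bandRaster(matrix(c(1, 2, 9), 1, 3), xmin = 0, ymax = 1, pixelSize = 1)
  p3 <- structure(list(list(plot_id = "p", coords = cbind(c(0, 3, 3, 0),
                                                          c(0, 0, 1, 1)))),
                  class = "plotPolygons", crs = "local")
  expect_equal(extractPlotMedians(r3, p3, minCoveragePx = 1)$value, 2)
  # all pixels missing -> excluded, no value
  rNA <- bandRaster(matrix(NA_real_, 2, 2), xmin = 0, ymax = 2, pixelSize = 1)
  outNA <- extractPlotMedians(rNA, polys, minCoveragePx = 1)
  expect_true(outNA$excluded)
  expect_true(is.na(outNA$value))
  # brute force on a random raster with an interior rectangle
  set.seed(43)
  m <- matrix(runif(400), 20, 20)
  rr <- bandRaster(m, xmin = 0, ymax = 20, pixelSize = 1)
  pr <- structure(list(list(plot_id = "q", coords = cbind(c(3, 11, 11, 3),
                                                          c(5, 5, 14, 14)))),
                  class = "plotPolygons", crs = "local")
  got <- extractPlotMedians(rr, pr, minCoveragePx = 1)$value
  inside <- c()
  for (i in 1:20) for (j in 1:20) {
    x <- j - 0.5; y <- 20 - i + 0.5
    if (x > 3 && x < 11 && y > 5 && y < 14) inside <- c(inside, m[i, j])
  }
  s <- sort(inside); n <- length(s)
  brute <- if (n %% 2) s[(n + 1) / 2] else mean(s[n / 2 + 0:1])
  expect_equal(got, brute)
  # polygon outside the raster names the plot
  pOut <- structure(list(list(plot_id = "far", coords = cbind(c(30, 31, 31, 30),
                                                              c(0, 0, 1, 1)))),
                    class = "plotPolygons", crs = "local")
  expect_error(extractPlotMedians(rr, pOut), "far")
  # CRS mismatch is an explicit error, no reprojection
  rCrs <- bandRaster(m, xmin = 0, ymax = 20, pixelSize = 1, crs = "EPSG:32632")
  pCrs <- structure(pr, crs = "EPSG:4326")
  expect_error(extractPlotMedians(rCrs, pCrs), "CRS mismatch")
})

test_that("band rasters and polygons survive a disk round trip", {
  set.seed(44)
  m <- matrix(runif(600, 0, 1.4), 20, 30)
  m[sample(600, 25)] <- NA
  r <- bandRaster(m, xmin = 100, ymax = 250, pixelSize = 0.5, band = "668",
                  crs = "EPSG:32632")
  path <- file.path(tempdir(), "band668")
  writeBandRaster(r, path)
  r2 <- readBandRaster(path)
  expect_equal(r2$values, m, tolerance = 1e-6)
  expect_identical(is.na(r2$values), is.na(m))
  expect_equal(r2$xmin, 100); expect_equal(r2$ymax, 250)
  expect_equal(r2$pixelSize, 0.5)
  expect_identical(r2$crs, "EPSG:32632")
  polys <- structure(list(list(plot_id = "p1",
                               coords = cbind(c(0, 1, 1, 0), c(0, 0, 2, 2)))),
                     class = "plotPolygons", crs = "EPSG:32632")
  gj <- file.path(tempdir(), "plots.geojson")
  writePlotPolygons(polys, gj)
  p2 <- readPlotPolygons(gj)
  expect_identical(p2[[1]]$plot_id, "p1")
  expect_equal(p2[[1]]$coords, polys[[1]]$coords)
  expect_identical(attr(p2, "crs"), "EPSG:32632")
})

test_that("index-SPAD correlations report groups, pooled, CI and errors", {
  x <- seq_len(30)
  expect_equal(indexSpadCorrelation(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(indexSpadCorrelation(x, -x)$r, -1, tolerance = 1e-12)
  expect_error(indexSpadCorrelation(x, rep(1, 30)), "zero variance")
  g <- rep(c("low", "high"), each = 15)
  out <- indexSpadCorrelation(x, 2 * x + rnorm(30), group = g)
  expect_setequal(out$group, c("low", "high", "pooled"))
  # Fisher-CI coverage on simulated bivariate normal rho = 0.6, n = 221
  set.seed(45)
  inBand <- 0
  for (i in 1:1000) {
    a <- rnorm(221); b <- 0.6 * a + sqrt(1 - 0.36) * rnorm(221)
    r <- cor(a, b)
    if (r >= 0.48 && r <= 0.70) inBand <- inBand + 1
  }
  expect_gte(inBand / 1000, 0.95)
})
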