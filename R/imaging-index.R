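#' Camera model for multispectral index computation
#'
#' Two camera systems are supported: the 10-band dual system, whose 740 nm
#' band serves as the near-IR band of PSRI (closest to the index's original
#' 750 nm definition), and the 5-band MX system, which lacks the 740 nm
#' band so PSRI falls back to the 842 nm near-IR band. NDVI and NDRE always
#' use the 842 nm band.
#'
#' @param id \code{"dual"} (10-band) or \code{"mx"} (5-band).
#' @return list with \code{id}, \code{psriNir} (band key), \code{bands}
#'   (available band keys, nm centre wavelengths as strings).
#' @export
cameraModel <- function(id = c("dual", "mx")) {
  id <- match.arg(id)
  if (id == "dual")
    list(id = "dual", psriNir = "740",
         bands = c("444", "475", "531", "560", "650", "668", "705", "717",
                   "740", "842"))
  else
    list(id = "mx", psriNir = "842",
         bands = c("475", "560", "668", "717", "842"))
}

indexBands <- function(index, camera) {
  switch(index,
         NDVI = c(nir = "842", red = "668"),
         NDRE = c(nir = "842", rededge = "717"),
         PSRI = c(red = "668", blue = "475", nir = camera$psriNir),
         stop("unknown index: ", index))
}

#' Compute a vegetation index from band reflectances
#'
#' Index formulas (band keys are centre wavelengths in nm):
#' \itemize{
#'   \item NDVI = (NIR842 - Red668) / (NIR842 + Red668)
#'   \item NDRE = (NIR842 - RedEdge717) / (NIR842 + RedEdge717)
#'   \item PSRI = Red668 / Blue475 - NIR, with NIR = 740 nm on the dual
#'     camera and 842 nm on the MX camera.
#' }
#' NDVI and NDRE lie in [-1, 1]; PSRI is unbounded and increases as
#' senescence progresses.
#'
#' @param bands named list/vector of band reflectances; names are nm centre
#'   wavelengths ("475", "560", "668", "717", "740", "842"). Values may be
#'   vectors (elementwise computation).
#' @param index one of "NDVI", "NDRE", "PSRI".
#' @param camera a \code{\link{cameraModel}} (default dual).
#' @return Index value(s).
#' @examples
#' computeIndex(c("842" = 0.5, "668" = 0.1), "NDVI")          # 0.666...
#' computeIndex(c("668" = 0.2, "475" = 0.1, "740" = 0.5), "PSRI")  # 1.5
#' @export
computeIndex <- function(bands, index = c("NDVI", "NDRE", "PSRI"),
                         camera = cameraModel("dual")) {
  index <- match.arg(index)
  bands <- as.list(bands)
  need <- indexBands(index, camera)
  miss <- setdiff(need, names(bands))
  if (length(miss))
    stop("configuration error: index ", index, " needs band(s) ",
         paste(miss, collapse = ", "), " nm")
  b <- lapply(need, function(k) as.numeric(bands[[k]]))
  names(b) <- names(need)
  if (index == "NDVI") (b$nir - b$red) / (b$nir + b$red)
  else if (index == "NDRE") (b$nir - b$rededge) / (b$nir + b$rededge)
  else {
    if (any(b$blue == 0, na.rm = TRUE))
      stop("division error: blue reflectance is zero in PSRI")
    b$red / b$blue - b$nir
  }
}

#' Empirical-line reflectance calibration
#'
#' Fits, per band, the affine sensor model DN = gain * reflectance + offset
#' by least squares over reference panels of known reflectance, inverts it,
#' and applies it to scene digital numbers. Needs at least two panels with
#' distinct reflectances. Calibrated reflectance is clipped to [0, 1.5];
#' overshoot beyond that raises a warning, not an error.
#'
#' @param panelDn digital numbers observed on the reference panels.
#' @param panelReflectance known panel reflectances (same length).
#' @param sceneDn digital numbers to calibrate (any shape).
#' @return list: \code{reflectance} (same shape as \code{sceneDn}),
#'   \code{gain}, \code{offset}, \code{residuals} (panel-fit residuals in
#'   DN), \code{clipped} (count of clipped scene values).
#' @export
empiricalLineCalibrate <- function(panelDn, panelReflectance, sceneDn) {
  if (length(panelDn) < 2 || length(unique(panelReflectance)) < 2)
    stop("calibration error: need >= 2 panels with distinct reflectances")
  fit <- lm(panelDn ~ panelReflectance)
  offset <- unname(coef(fit)[1]); gain <- unname(coef(fit)[2])
  if (gain == 0) stop("calibration error: zero gain")
  rho <- (sceneDn - offset) / gain
  over <- sum(rho > 1.5, na.rm = TRUE) + sum(rho < 0, na.rm = TRUE)
  if (over > 0) {
    warning(over, " calibrated value(s) outside [0, 1.5] were clipped")
    rho <- pmin(pmax(rho, 0), 1.5)
  }
  list(reflectance = rho, gain = gain, offset = offset,
       residuals = unname(resid(fit)), clipped = over)
}

#' Correlation between a vegetation index and SPAD chlorophyll readings
#'
#' Pearson correlation of plot/cultivar index values with hand-held SPAD
#' chlorophyll estimates, within each nitrogen level and pooled across
#' levels, with Fisher-z 95\% confidence intervals and p-values.
#'
#' @param index numeric vegetation-index values.
#' @param spad matching SPAD values.
#' @param group optional grouping factor (N levels).
#' @return data.frame: \code{group} (including "pooled"), \code{r},
#'   \code{p}, \code{lo}, \code{hi}, \code{n}.
#' @export
indexSpadCorrelation <- function(index, spad, group = NULL) {
  grp <- if (is.null(group)) factor(rep("pooled", length(index)))
         else factor(group)
  levs <- levels(grp)
  if (!is.null(group)) levs <- c(levs, "pooled")
  rows <- lapply(levs, function(g) {
    sel <- if (g == "pooled") rep(TRUE, length(index)) else grp == g
    a <- index[sel]; b <- spad[sel]
    ok <- complete.cases(a, b); a <- a[ok]; b <- b[ok]
    stopIfNot(length(a) >= 3, paste("need >= 3 paired observations in group", g))
    if (sd(a) == 0 || sd(b) == 0)
      stop("undefined correlation: zero variance in group ", g)
    ct <- suppressWarnings(cor.test(a, b))
    ci <- if (!is.null(ct$conf.int)) ct$conf.int else c(NA, NA)
    data.frame(group = g, r = unname(ct$estimate), p = ct$p.value,
               lo = ci[1], hi = ci[2], n = length(a))
  })
  do.call(rbind, rows)
}
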