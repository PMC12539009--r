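#' Simulate a complete split-plot stay-green trial
#'
#' Generates plot-level observations (band reflectances and vegetation
#' indices per imaging date) and yields for a split-plot nitrogen trial,
#' with ground truth from the causal specification. Cultivar-by-N PSRI
#' trajectories are logistic in thermal time; lower nitrogen brings
#' senescence onset forward and speeds it up, favourable causal alleles
#' delay onset (low-N-specific loci only at the lowest dose). Band
#' reflectances are constructed so the index formulas recover the simulated
#' index values exactly. Grain yield is linear in the negative area under
#' the PSRI curve with nitrogen-specific noise chosen to reproduce the
#' target PSRI-yield correlations (strongest at low N).
#'
#' @param design a \code{\link{trialDesign}}.
#' @param genotypes a \linkS4class{GenotypePanel} covering at least
#'   \code{design$nCultivars} cultivars (planted causal markers are read
#'   from their \code{QTN_} names).
#' @param causal the \code{\link{causalSpec}} used for the panel.
#' @param params a \code{\link{senescenceParams}}.
#' @param seed integer master seed.
#' @param yieldMeans mean grain yield (g/m^2) per N level, low to high.
#' @param yieldGeneticSd SD of the senescence-driven yield component.
#' @param targetYieldCor target magnitudes of the within-N PSRI-yield
#'   correlation, low to high (defaults 0.8, 0.7, 0.7).
#' @param camera a \code{\link{cameraModel}} for the PSRI near-IR band.
#' @return list of class \code{syntheticTrial}: \code{observations} (long
#'   data.frame: plot_id, cultivar, n_level, n_dose, block, date, gdd, band
#'   reflectance columns, psri/ndvi/ndre, psri_true), \code{yields}
#'   (plot-level grain/straw yields, harvest index, soil N, NUE),
#'   \code{temperatures}, \code{gdd}, \code{truth} (cultivar onset shifts,
#'   per-plot AUC, yield slopes), plus the design/params/causal echoes.
#' @export
simulateTrial <- function(design, genotypes, causal = defaultCausalSpec(),
                          params = senescenceParams(), seed = 1,
                          yieldMeans = c(400, 650, 800), yieldGeneticSd = 60,
                          targetYieldCor = c(0.8, 0.7, 0.7),
                          camera = cameraModel("dual")) {
  nC <- design$nCultivars
  if (nrow(doses(genotypes)) < nC)
    stop("configuration error: genotype panel has ", nrow(doses(genotypes)),
         " cultivars but the design needs ", nC)
  panel <- genotypes[seq_len(nC), ]
  cvIds <- cultivars(panel)
  nLev <- names(design$nLevels)
  nN <- length(nLev); nB <- design$nBlocks
  dates <- design$imagingDates; nT <- length(dates)

  temps <- NULL
  gdd <- design$imagingGdd
  if (is.null(gdd)) {
    yr <- format(dates[1], "%Y")
    temps <- simulateTemperatures(as.Date(paste0(yr, "-01-01")),
                                  dates[nT], seed = childSeed(seed, "weather"))
    gdd <- unname(gddAtDates(temps, dates))
  }

  loci <- if (is.null(causal)) data.frame() else causal$loci
  qd <- if (nrow(loci)) {
    nm <- sprintf("QTN_%s_%.1f", loci$chrom, loci$pos / 1e6)
    causalDoses(panel)[, nm, drop = FALSE]  # columns in causal-spec order
  } else matrix(0, nC, 0, dimnames = list(cvIds, NULL))

  withSeed(childSeed(seed, "trial"), {
    cvShift <- rnorm(nC, 0, params$cultivarSd)
    # onset matrix cultivar x N level
    onset <- matrix(0, nC, nN, dimnames = list(cvIds, nLev))
    for (i in seq_len(nN)) {
      sh <- cvShift
      for (l in seq_len(nrow(loci))) {
        if (loci$nSpec[l] == "all" || i == 1L)
          sh <- sh + loci$effect[l] * qd[, l]
      }
      onset[, i] <- params$onset[i] + sh
    }

    plots <- expand.grid(cultivar = cvIds, n_level = nLev,
                         block = paste0("B", seq_len(nB)),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    plots$plot_id <- sprintf("P%04d", seq_len(nrow(plots)))
    mpKey <- paste(plots$n_level, plots$block)
    mpEff <- setNames(rnorm(length(unique(mpKey)), 0, params$mainPlotSd),
                      unique(mpKey))
    spEff <- rnorm(nrow(plots), 0, params$subPlotSd)
    iN <- match(plots$n_level, nLev)
    iC <- match(plots$cultivar, cvIds)

    obs <- list()
    psriTrueMat <- matrix(0, nrow(plots), nT)
    for (ti in seq_len(nT)) {
      tr <- psriTrajectory(gdd[ti], onset[cbind(iC, iN)], params$rate[iN],
                           params$baseline, params$asymptote,
                           params$plateauStart, params$plateauLength)
      psriTrueMat[, ti] <- tr
      psri <- tr + mpEff[mpKey] + spEff +
        rnorm(nrow(plots), 0, params$noiseSd)
      s <- pmin(pmax((psri - params$baseline) /
                       (params$asymptote - params$baseline), 0), 1)
      blue <- 0.08
      nir842 <- 0.55 - 0.25 * s
      nirPsri <- if (camera$psriNir == "740") 0.95 * nir842 else nir842
      red <- blue * (psri + nirPsri)
      ndre <- 0.66 - 0.44 * s
      rededge <- nir842 * (1 - ndre) / (1 + ndre)
      green <- (blue + red) / 2 + 0.02
      bands <- data.frame(`475` = blue, `560` = green, `668` = red,
                          `717` = rededge, `842` = nir842,
                          check.names = FALSE)
      if (camera$psriNir == "740") bands[["740"]] <- nirPsri
      o <- data.frame(plot_id = plots$plot_id, cultivar = plots$cultivar,
                      n_level = plots$n_level,
                      n_dose = unname(design$nLevels[iN]),
                      block = plots$block, date = dates[ti], gdd = gdd[ti],
                      stringsAsFactors = FALSE)
      o <- cbind(o, bands)
      o$psri <- computeIndex(bands, "PSRI", camera)
      o$ndvi <- computeIndex(bands, "NDVI", camera)
      o$ndre <- computeIndex(bands, "NDRE", camera)
      o$psri_true <- tr
      obs[[ti]] <- o
    }
    observations <- do.call(rbind, obs)

    # yields: linear in negative AUC of the (plot-intercept) PSRI curve
    aucBase <- psriTrueMat + spEff
    auc <- vapply(seq_len(nrow(plots)), function(p) {
      sum(diff(gdd) * (head(aucBase[p, ], -1) + aucBase[p, -1]) / 2)
    }, numeric(1))
    grain <- numeric(nrow(plots))
    slopes <- numeric(nN); noiseSds <- numeric(nN)
    for (i in seq_len(nN)) {
      sel <- iN == i
      sdA <- sd(auc[sel])
      slopes[i] <- if (sdA > 0) yieldGeneticSd / sdA else 0
      r <- targetYieldCor[min(i, length(targetYieldCor))]
      noiseSds[i] <- yieldGeneticSd * sqrt(1 / r^2 - 1)
      grain[sel] <- yieldMeans[min(i, length(yieldMeans))] -
        slopes[i] * (auc[sel] - mean(auc[sel])) +
        rnorm(sum(sel), 0, noiseSds[i])
    }
    grain <- pmax(grain, 10)
    hi <- pmin(pmax(0.45 + rnorm(nrow(plots), 0, 0.03), 0.2), 0.65)
    straw <- grain * (1 / hi - 1)
    soilN <- unname(design$nLevels[iN]) / 10  # kg/ha -> g/m^2
    yields <- data.frame(plot_id = plots$plot_id, cultivar = plots$cultivar,
                         n_level = plots$n_level, block = plots$block,
                         grain_yield = grain, straw_yield = straw,
                         harvest_index = harvestIndex(grain, straw),
                         soil_n = soilN, nue = nue(grain, soilN),
                         stringsAsFactors = FALSE)

    structure(list(observations = observations, yields = yields,
                   temperatures = temps, gdd = gdd,
                   truth = list(cvShift = setNames(cvShift, cvIds),
                                causalDoses = qd,
                                onset = onset, auc = auc, slopes = slopes,
                                yieldNoiseSds = noiseSds,
                                targetYieldCor = targetYieldCor),
                   design = design, params = params, causal = causal,
                   seed = seed),
              class = "syntheticTrial")
  })
}

#' @export
print.syntheticTrial <- function(x, ...) {
  cat("syntheticTrial:", x$design$nCultivars, "cultivars x",
      length(x$design$nLevels), "N levels x", x$design$nBlocks, "blocks,",
      length(x$design$imagingDates), "imaging dates\n")
  cat("  GDD at dates:", paste(round(x$gdd), collapse = ", "), "\n")
  invisible(x)
}

#' Analytic per-locus PVE of the planted causal loci
#'
#' Computes, from the generator's own parameters and the realised
#' genotypes, the expected marginal effect and percentage of variance
#' explained of each planted causal locus on the scale the association
#' scan sees: pooled genotype effects of square-root-transformed PSRI over
#' the chosen imaging dates. The phenotypic variance combines the
#' noiseless between-cultivar variance, the cultivar onset-shift variance
#' propagated through the trajectory (delta method), and the residual
#' variance of an estimated genotype mean under the design. PVE uses the
#' same convention as the scan: \code{100 * 2 maf (1-maf) beta^2 / var}.
#'
#' @param trial a \code{syntheticTrial}.
#' @param dates indices of the imaging dates to pool (default 2:3, the
#'   central senescence phase).
#' @param nLevels N-level labels to pool over (default all; pass the lowest
#'   level only to get the low-N scan scale).
#' @return data.frame: marker, beta, maf, pve.
#' @export
plantedPve <- function(trial, dates = 2:3, nLevels = NULL) {
  design <- trial$design; params <- trial$params
  loci <- trial$causal$loci
  nLev <- names(design$nLevels)
  if (is.null(nLevels)) nLevels <- nLev
  iLev <- match(nLevels, nLev)
  gdd <- trial$gdd[dates]
  cvIds <- names(trial$truth$cvShift)
  nC <- length(cvIds)

  # noiseless pooled value per cultivar as a function of its causal doses
  pooledValue <- function(extraShift) {
    # extraShift: vector per cultivar of onset delay (GDD), incl. causal
    vals <- matrix(0, nC, 0)
    for (i in iLev) {
      on <- params$onset[i] + extraShift[, i]
      for (g in gdd) {
        tr <- psriTrajectory(g, on, params$rate[i], params$baseline,
                             params$asymptote, params$plateauStart,
                             params$plateauLength)
        vals <- cbind(vals, transformPsri(tr))
      }
    }
    rowMeans(vals)
  }
  causalShift <- function(doseMat) {
    sh <- matrix(0, nC, length(nLev))
    for (i in seq_along(nLev))
      for (l in seq_len(nrow(loci)))
        if (loci$nSpec[l] == "all" || i == 1L)
          sh[, i] <- sh[, i] + loci$effect[l] * doseMat[, l]
    sh
  }
  doseMat <- trial$truth$causalDoses
  stopIfNot(!is.null(doseMat) && ncol(doseMat) == nrow(loci),
            "trial carries no causal dose ground truth")
  v <- pooledValue(causalShift(doseMat))
  # cultivar-shift variance via delta method (shift acts at every N level)
  h <- 1
  vPlus <- pooledValue(causalShift(doseMat) + h)
  deriv <- mean((vPlus - v) / h)
  shiftVar <- deriv^2 * params$cultivarSd^2
  # residual variance of a pooled genotype-mean estimate (transformed scale)
  dTrans <- mean(1 / (2 * sqrt(10 +
    (params$baseline + params$asymptote) / 2)))
  nPlots <- length(iLev) * design$nBlocks
  estVar <- dTrans^2 * (params$subPlotSd^2 / nPlots +
                        params$noiseSd^2 / (nPlots * length(gdd)))
  totVar <- var(v) + shiftVar + estVar
  out <- lapply(seq_len(nrow(loci)), function(l) {
    d <- doseMat[, l]
    beta <- cov(v, d) / var(d)
    p <- mean(d) / 2; mafL <- min(p, 1 - p)
    data.frame(marker = colnames(doseMat)[l], beta = beta, maf = mafL,
               pve = min(100, 100 * 2 * mafL * (1 - mafL) * beta^2 / totVar))
  })
  do.call(rbind, out)
}
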