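#' Pipeline configuration
#'
#' Assembles (and validates) the settings for a full stay-green analysis
#' run: trial simulation (or file inputs), camera model, thermal-time
#' settings, model transform, association-scan settings and haplotype
#' settings, under one master seed. A YAML file with the same field names
#' can be loaded with \code{\link{readPipelineConfig}}.
#'
#' @param outDir output directory for the run's artifacts.
#' @param seed master seed; every stochastic stage derives its own child
#'   seed from it.
#' @param simulate list: \code{nCultivars}, \code{nMarkers},
#'   \code{nBlocks} (defaults 221 / 1500 / 2). Set to \code{NULL} to use
#'   file inputs instead, in which case \code{genotypes} (HapMap-style
#'   CSV) and \code{observations} (long CSV) paths are required.
#' @param genotypes,observations,yields optional input file paths used
#'   when \code{simulate} is NULL.
#' @param camera "dual" or "mx".
#' @param gdd list: \code{baseTemp}, \code{upperCap}.
#' @param transform "sqrt10" or "none".
#' @param effects "unshrunken" or "shrunken".
#' @param gwas list: \code{pcs}, \code{alpha}, \code{model} ("multilocus"
#'   or "single").
#' @param haplotypes list: \code{r2Min}, \code{minMembers}, \code{kMax}.
#' @return Validated config list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(outDir, seed = 1,
                           simulate = list(nCultivars = 221, nMarkers = 1500,
                                           nBlocks = 2),
                           genotypes = NULL, observations = NULL,
                           yields = NULL, camera = "dual",
                           gdd = list(baseTemp = 4.0, upperCap = 25.0),
                           transform = "sqrt10", effects = "unshrunken",
                           gwas = list(pcs = 3, alpha = 0.05,
                                       model = "multilocus"),
                           haplotypes = list(r2Min = 0.7, minMembers = 5,
                                             kMax = 6)) {
  cfg <- structure(list(outDir = outDir, seed = as.integer(seed),
                        simulate = simulate, genotypes = genotypes,
                        observations = observations, yields = yields,
                        camera = camera, gdd = gdd, transform = transform,
                        effects = effects, gwas = gwas,
                        haplotypes = haplotypes),
                   class = "pipelineConfig")
  validatePipelineConfig(cfg)
  cfg
}

#' @rdname pipelineConfig
#' @param path YAML config file.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipelineConfig, y)
}

#' @rdname pipelineConfig
#' @param cfg a config list.
#' @export
validatePipelineConfig <- function(cfg) {
  stopIfNot(!is.null(cfg$outDir), "validation error: outDir missing")
  stopIfNot(!is.null(cfg$seed), "validation error: seed missing")
  if (is.null(cfg$simulate)) {
    if (is.null(cfg$genotypes))
      stop("validation error: genotype path missing (no simulate section)")
    if (is.null(cfg$observations))
      stop("validation error: observations path missing (no simulate section)")
    for (p in c(cfg$genotypes, cfg$observations, cfg$yields))
      stopIfNot(file.exists(p), paste("validation error: input not found:", p))
  }
  stopIfNot(cfg$camera %in% c("dual", "mx"), "camera must be dual or mx")
  stopIfNot(cfg$transform %in% c("sqrt10", "none"), "unknown transform")
  stopIfNot(cfg$gwas$model %in% c("multilocus", "single"), "unknown GWAS model")
  invisible(TRUE)
}

# short deterministic config fingerprint for provenance headers
configHash <- function(cfg) {
  s <- paste(deparse(cfg[setdiff(names(cfg), "outDir")]), collapse = "")
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 131 + k) %% 4294967291
  sprintf("%08x", as.integer(h %% 2147483647))
}

writeStageCsv <- function(df, path, stage, seed, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stage: %s; seed: %d; config: %s", stage, seed, hash),
             con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a stage output CSV (skipping the provenance header)
#' @param path CSV written by the pipeline.
#' @return data.frame.
#' @export
readStageCsv <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
           check.names = FALSE)
}

#' Run the full stay-green pipeline
#'
#' Executes the stages simulate, extract (raster zonal-median
#' cross-check), gdd, fitmodel, gwas and haplotypes on one config, writing
#' each stage's table to \code{outDir} with a provenance header (stage,
#' master seed, config fingerprint) and returning the in-memory results.
#' The last imaging date (advanced senescence) is excluded from the
#' repeated-measures model and the scan; genotype effects are pooled over
#' the central senescence dates (second and third flights). The
#' association scan runs twice: across N levels and within the lowest N
#' dose; haplotypes are called at up to three focal loci (two across-N,
#' one low-N-specific), named, tested, stacked and traced over decades.
#'
#' @param config a \code{\link{pipelineConfig}} (or path to a YAML file).
#' @return Invisibly, a list with all stage results (trial, fit, scans,
#'   haplotype calls, stay-green set, carrier fraction, stacking, trends,
#'   yield correlations) plus \code{files} (paths written).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  validatePipelineConfig(config)
  seed <- config$seed
  hash <- configHash(config)
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outDir, f)
  files <- character(0)
  emit <- function(df, name, stage) {
    p <- out(name)
    writeStageCsv(df, p, stage, seed, hash)
    files <<- c(files, p)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  camera <- cameraModel(config$camera)

  ## simulate (or load) ------------------------------------------------
  trial <- stage("simulate", {
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      causal <- defaultCausalSpec()
      panel <- simulateGenotypes(sim$nCultivars, sim$nMarkers, causal,
                                 seed = seed)
      design <- trialDesign(nCultivars = sim$nCultivars,
                            nBlocks = sim$nBlocks %||% 2)
      tr <- simulateTrial(design, panel, causal, senescenceParams(),
                          seed = seed, camera = camera)
      tr$panel <- panel
      emit(tr$observations, "observations.csv", "simulate")
      emit(tr$yields, "yields.csv", "simulate")
      emit(tr$temperatures, "temperatures.csv", "simulate")
      writeHapMap(panel, out("genotypes.hmp.csv"))
      files <- c(files, out("genotypes.hmp.csv"))
      tr
    } else {
      obs <- readStageCsv(config$observations)
      panel <- readHapMap(config$genotypes)
      yl <- if (!is.null(config$yields)) readStageCsv(config$yields) else NULL
      list(observations = obs, yields = yl, panel = panel,
           temperatures = NULL, gdd = sort(unique(obs$gdd)))
    }
  })
  panel <- trial$panel
  obs <- trial$observations
  dates <- sort(unique(as.character(obs$date)))

  ## extract: raster round-trip check on a small plot subset ------------
  extractCheck <- stage("extract", {
    d2 <- obs[as.character(obs$date) == dates[min(2, length(dates))], ]
    sub <- head(d2, 12)
    vals <- setNames(sub$psri, sub$plot_id)
    rp <- renderPlotRaster(vals, pixelSize = 0.05, seed = seed,
                           band = "PSRI")
    med <- extractPlotMedians(rp$raster, rp$polygons, minCoveragePx = 50)
    med$target <- vals[med$plot_id]
    emit(med, "extract_check.csv", "extract")
    med
  })

  ## gdd ----------------------------------------------------------------
  gddTab <- stage("gdd", {
    if (!is.null(trial$temperatures)) {
      cfgG <- gddConfig(baseTemp = config$gdd$baseTemp,
                        upperCap = config$gdd$upperCap)
      g <- gddAtDates(trial$temperatures, as.Date(dates), cfgG)
      tab <- data.frame(date = names(g), gdd = unname(g))
      emit(tab, "gdd.csv", "gdd")
      tab
    } else data.frame(date = dates, gdd = trial$gdd)
  })

  ## fitmodel ------------------------------------------------------------
  modelDates <- head(dates, -1)           # advanced-senescence date excluded
  central <- modelDates[c(length(modelDates) - 1, length(modelDates))]
  fit <- stage("fitmodel", {
    mo <- obs[as.character(obs$date) %in% modelDates,
              c("cultivar", "n_level", "block", "date", "psri")]
    names(mo)[names(mo) == "psri"] <- "value"
    f <- fitSplitPlot(mo, transform = config$transform,
                      effects = config$effects, pooledDates = central)
    vcTab <- do.call(rbind, lapply(names(f$components), function(d) {
      vc <- f$components[[d]]
      data.frame(date = d, vC = vc@vC, vCxN = vc@vCxN, vR = vc@vR,
                 reliability = reliability(vc))
    }))
    emit(vcTab, "variance_components.csv", "fitmodel")
    effTab <- data.frame(cultivar = rownames(f$effects), f$effects,
                         pooled = f$pooledEffects, check.names = FALSE)
    emit(effTab, "genotype_effects.csv", "fitmodel")
    emit(f$anova, "anova.csv", "fitmodel")
    f
  })
  lowLevel <- names(trial$design$nLevels)[1] %||% unique(obs$n_level)[1]
  lowFit <- stage("fitmodel", {
    mo <- obs[as.character(obs$date) %in% modelDates &
                obs$n_level == lowLevel,
              c("cultivar", "n_level", "block", "date", "psri")]
    names(mo)[names(mo) == "psri"] <- "value"
    fitSplitPlot(mo, transform = config$transform, effects = config$effects,
                 pooledDates = central)
  })

  ## gwas ----------------------------------------------------------------
  scan <- stage("gwas", {
    filt <- filterMarkers(panel)
    imp <- imputeMissing(filt)
    pcs <- pcaMarkers(imp, k = config$gwas$pcs)$scores
    scanFun <- if (config$gwas$model == "multilocus") multilocusScan
               else singleMarkerScan
    acrossN <- scanFun(fit$pooledEffects, imp, covariates = pcs,
                       alpha = config$gwas$alpha)
    lowN <- scanFun(lowFit$pooledEffects, imp, covariates = pcs,
                    alpha = config$gwas$alpha)
    emit(acrossN, "assoc_across_n.csv", "gwas")
    emit(lowN, "assoc_low_n.csv", "gwas")
    emit(manhattanTable(acrossN, markerMap(imp), config$gwas$alpha),
         "manhattan_across_n.csv", "gwas")
    qtn <- data.frame(
      scan = c(rep("acrossN", length(attr(acrossN, "pseudoQtn"))),
               rep("lowN", length(attr(lowN, "pseudoQtn")))),
      marker = c(attr(acrossN, "pseudoQtn"), attr(lowN, "pseudoQtn")))
    if (nrow(qtn)) emit(qtn, "pseudo_qtn.csv", "gwas")
    list(acrossN = acrossN, lowN = lowN, panel = imp, pcs = pcs)
  })

  ## haplotypes ----------------------------------------------------------
  hap <- stage("haplotypes", {
    hcfg <- config$haplotypes
    topMarkers <- function(res, n) {
      q <- attr(res, "pseudoQtn")
      if (is.null(q) || !length(q)) {
        ord <- res[order(res$p), ]
        q <- ord$marker
      }
      head(q, n)
    }
    focalAcross <- topMarkers(scan$acrossN, 2)
    # third locus: the strongest low-N signal independent of (not in LD
    # with) either across-N focal marker
    D <- doses(scan$panel)
    indep <- function(mk) all(vapply(focalAcross, function(f)
      mk != f && ldR2(D[, mk], D[, f]) <= hcfg$r2Min, TRUE))
    focalLowPool <- Filter(indep, topMarkers(scan$lowN, 10))
    focalLow <- head(focalLowPool, 1)
    foci <- c(focalAcross, focalLow)
    effFor <- function(mk) if (mk %in% focalLow) lowFit$pooledEffects
                           else fit$pooledEffects
    calls <- lapply(foci, function(mk) {
      bl <- collectBlock(mk, scan$panel, r2Min = hcfg$r2Min)
      cl <- clusterHaplotypes(scan$panel, bl, focal = mk, kMax = hcfg$kMax,
                              minMembers = hcfg$minMembers, seed = seed)
      favourableClusters(nameHaplotypes(cl, scan$panel), effFor(mk))
    })
    names(calls) <- foci
    callTab <- do.call(rbind, lapply(foci, function(mk) {
      cl <- calls[[mk]]
      data.frame(focal = mk, cultivar = names(cl@assignments),
                 cluster = unname(cl@assignments),
                 code = cl@codes[cl@assignments],
                 favourable = cl@favourable[cl@assignments])
    }))
    emit(callTab, "haplotype_calls.csv", "haplotypes")
    sg <- stayGreenSet(fit$pooledEffects)
    majors <- calls[focalAcross]
    cf <- carrierFraction(sg$set, majors)
    stack <- if (length(calls) == 3)
      stackingClasses(calls, traits = lowFit$pooledEffects) else NULL
    if (!is.null(stack)) emit(stack$classes, "stacking.csv", "haplotypes")
    trend <- tryCatch(
      alleleFrequencyTrend(panel, focalLow, allele = "alt",
                           origin = "Germany"),
      error = function(e) NULL)
    if (!is.null(trend)) emit(trend$table, "allele_trend.csv", "haplotypes")
    list(calls = calls, stayGreen = sg, carrierFraction = cf,
         stacking = stack, trend = trend, foci = foci)
  })

  ## trait correlations ---------------------------------------------------
  yieldCor <- stage("correlations", {
    if (is.null(trial$yields)) return(NULL)
    yl <- trial$yields
    co <- do.call(rbind, lapply(unique(yl$n_level), function(nl) {
      gy <- tapply(yl$grain_yield[yl$n_level == nl],
                   yl$cultivar[yl$n_level == nl], mean)
      sel <- obs$n_level == nl & as.character(obs$date) %in% central
      ps <- tapply(obs$psri[sel], obs$cultivar[sel], mean)
      common <- intersect(names(gy), names(ps))
      data.frame(n_level = nl, r = cor(ps[common], gy[common]),
                 n = length(common))
    }))
    emit(co, "psri_yield_correlations.csv", "correlations")
    co
  })

  res <- list(config = config, trial = trial, extractCheck = extractCheck,
              gdd = gddTab, fit = fit, lowFit = lowFit, scan = scan,
              haplotypes = hap, yieldCorrelations = yieldCor,
              centralDates = central, files = files)
  invisible(res)
}
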