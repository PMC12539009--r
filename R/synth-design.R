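#' Trial design for a split-plot nitrogen experiment
#'
#' Describes the layout the generator emulates: nitrogen doses as main
#' plots, complete cultivar sets in each of the blocks inside every main
#' plot, and a series of imaging dates.
#'
#' @param nCultivars number of cultivars (default 221).
#' @param nLevels named vector of nitrogen doses in kg N/ha, low to high
#'   (default low 81, intermediate 110, high 220: the low level is the
#'   mineral soil nitrogen with no added fertiliser).
#' @param nBlocks blocks (replications) per main plot (default 2).
#' @param imagingDates strictly increasing calendar dates of the flights.
#' @param plotWidth,plotLength plot size in metres (default 3 x 7).
#' @param imagingGdd optional precomputed cumulative GDD per imaging date;
#'   if NULL the trial simulator derives them from simulated temperatures.
#' @return list of class \code{trialDesign}.
#' @export
trialDesign <- function(nCultivars = 221,
                        nLevels = c(low = 81, intermediate = 110, high = 220),
                        nBlocks = 2,
                        imagingDates = as.Date(c("2020-05-27", "2020-06-09",
                                                 "2020-06-24", "2020-07-07")),
                        plotWidth = 3, plotLength = 7, imagingGdd = NULL) {
  stopIfNot(nCultivars > 0 && nBlocks > 0, "argument error: counts must be positive")
  imagingDates <- as.Date(imagingDates)
  stopIfNot(all(diff(imagingDates) > 0),
            "imaging dates must be strictly increasing")
  stopIfNot(is.null(imagingGdd) || length(imagingGdd) == length(imagingDates),
            "imagingGdd must match imagingDates")
  structure(list(nCultivars = nCultivars, nLevels = nLevels,
                 nBlocks = nBlocks, imagingDates = imagingDates,
                 plotWidth = plotWidth, plotLength = plotLength,
                 imagingGdd = imagingGdd),
            class = "trialDesign")
}

#' Causal-locus specification for the genotype simulator
#'
#' Each causal locus plants an effect on the senescence-onset thermal time:
#' every copy of the favourable allele delays onset by \code{effect} GDD
#' (lowering PSRI). Loci flagged \code{"low-only"} act only at the lowest
#' nitrogen dose. Markers within \code{ldBlockWidth} of a causal position
#' are generated in LD with it.
#'
#' @param loci data.frame with columns \code{chrom}, \code{pos} (bp),
#'   \code{favAllele} (base), \code{effect} (GDD onset delay per favourable
#'   allele copy, finite), \code{nSpec} ("all" or "low-only"),
#'   \code{maf} (minor allele frequency, 0 < maf < 0.5), \code{favIsMinor}
#'   (is the favourable allele the minor one?).
#' @param ldBlockWidth LD block half-width in bp on either side of the
#'   causal marker (default 1.5 Mbp).
#' @param ldMarkersPerSide markers generated in LD on each side (default 4).
#' @return list of class \code{causalSpec}.
#' @export
causalSpec <- function(loci, ldBlockWidth = 1.5e6, ldMarkersPerSide = 4) {
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "favAllele", "effect", "nSpec", "maf", "favIsMinor")
  stopIfNot(all(need %in% names(loci)),
            paste("loci needs columns:", paste(need, collapse = ", ")))
  stopIfNot(all(is.finite(loci$effect)), "effect sizes must be finite")
  stopIfNot(all(loci$nSpec %in% c("all", "low-only")),
            "nSpec must be 'all' or 'low-only'")
  stopIfNot(all(loci$maf > 0 & loci$maf < 0.5), "need 0 < maf < 0.5 per locus")
  structure(list(loci = loci, ldBlockWidth = ldBlockWidth,
                 ldMarkersPerSide = ldMarkersPerSide),
            class = "causalSpec")
}

#' Default causal specification
#'
#' Three planted loci mirroring the qualitative finding the pipeline is
#' meant to recover: two favourable-major-allele loci acting across all
#' nitrogen levels and one favourable-minor-allele locus acting only under
#' low nitrogen. Effect sizes (GDD onset delay per favourable allele copy)
#' are generator defaults sized so the first locus explains roughly a
#' quarter of the phenotypic variance of pooled genotype effects under the
#' default senescence parameters.
#'
#' @return A \code{\link{causalSpec}}.
#' @export
defaultCausalSpec <- function() {
  causalSpec(data.frame(
    chrom = c("2D", "4B", "3A"),
    pos = c(23.4e6, 15.3e6, 83.7e6),
    favAllele = c("G", "C", "C"),
    effect = c(32, 18, 30),
    nSpec = c("all", "all", "low-only"),
    maf = c(0.20, 0.25, 0.10),
    favIsMinor = c(FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE))
}

#' Senescence-trajectory parameters
#'
#' The generator's PSRI trajectory is a four-parameter logistic in thermal
#' time with an optional mid-season plateau: starting from \code{baseline},
#' PSRI rises towards \code{asymptote} with inflection at the
#' nitrogen-dependent \code{onset} (GDD) and slope \code{rate} (per GDD).
#' Lower nitrogen brings onset forward and speeds the rise. The optional
#' plateau pauses the progression for \code{plateauLength} GDD starting
#' \code{plateauStart} GDD after onset, mimicking the observed mid-season
#' stagnation of senescence in stay-green cultivars (senescence need not be
#' sigmoid).
#'
#' @param onset named vector, GDD at the logistic inflection per N level
#'   (low to high). The defaults spread onsets widely enough that the
#'   faster low-N curve has overtaken the slower high-N curve well before
#'   typical imaging starts, keeping the low >= intermediate >= high PSRI
#'   ordering at every imaging date.
#' @param rate named vector, logistic slope per GDD per N level (>= 0).
#' @param baseline,asymptote PSRI floor and ceiling (asymptote >= baseline).
#' @param cultivarSd SD of the cultivar-specific onset shift in GDD.
#' @param noiseSd residual SD of plot-level PSRI per date.
#' @param mainPlotSd,subPlotSd SDs of the main-plot (N x block) and
#'   sub-plot (plot-level, shared across dates) random intercepts on PSRI.
#' @param plateauStart,plateauLength optional plateau (GDD after onset /
#'   GDD duration); NULL disables it.
#' @return list of class \code{senescenceParams}.
#' @export
senescenceParams <- function(onset = c(low = 930, intermediate = 1000, high = 1070),
                             rate = c(low = 0.013, intermediate = 0.0115,
                                      high = 0.010),
                             baseline = 0.05, asymptote = 1.6,
                             cultivarSd = 22, noiseSd = 0.05,
                             mainPlotSd = 0.01, subPlotSd = 0.02,
                             plateauStart = NULL, plateauLength = NULL) {
  stopIfNot(all(rate >= 0), "rate must be >= 0")
  stopIfNot(asymptote >= baseline, "asymptote must be >= baseline")
  structure(list(onset = onset, rate = rate, baseline = baseline,
                 asymptote = asymptote, cultivarSd = cultivarSd,
                 noiseSd = noiseSd, mainPlotSd = mainPlotSd,
                 subPlotSd = subPlotSd, plateauStart = plateauStart,
                 plateauLength = plateauLength),
            class = "senescenceParams")
}

# Noiseless PSRI trajectory at thermal time gdd for one cultivar x N level.
# The plateau pauses effective thermal time.
psriTrajectory <- function(gdd, onset, rate, baseline, asymptote,
                           plateauStart = NULL, plateauLength = NULL) {
  eff <- gdd
  if (!is.null(plateauStart) && !is.null(plateauLength)) {
    p0 <- onset + plateauStart
    eff <- gdd - pmin(pmax(gdd - p0, 0), plateauLength)
  }
  baseline + (asymptote - baseline) * plogis(rate * (eff - onset))
}
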