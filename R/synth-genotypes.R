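#' Simulate a structured diversity-panel SNP matrix with planted causal loci
#'
#' Generates an (essentially inbred) cultivar panel with population
#' structure, a marker map across the 21 bread-wheat chromosomes, planted
#' causal markers at the positions of the causal specification, and LD
#' blocks around them. Structure arises from origin-by-decade groups whose
#' allele frequencies are perturbed around a panel-wide base frequency.
#' Markers inside an LD block are copies of the causal column with
#' per-cultivar re-draws at a rate set so the expected squared correlation
#' with the causal marker decays linearly from 1 (at 0 bp) to 0.7 at the
#' block edge.
#'
#' Marker naming encodes the ground truth: causal markers are
#' \code{QTN_<chrom>_<Mbp>}, their LD companions \code{LD_<chrom>_<Mbp>_<k>},
#' background markers \code{SNP<No>}. Minor-allele-favourable causal loci
#' get a rising allele-frequency ramp over decades (emulating indirect
#' selection), so temporal trend analyses have signal.
#'
#' @param nCultivars,nMarkers panel dimensions (positive; \code{nMarkers}
#'   must cover the causal loci and their LD companions).
#' @param causal a \code{\link{causalSpec}} (or NULL for none).
#' @param structureGroups number of origin-by-decade groups (default 12:
#'   two origins by six decades).
#' @param seed integer master seed.
#' @param inbred if TRUE (default) doses are 0/2; otherwise heterozygotes
#'   occur at Hardy-Weinberg proportions.
#' @param missingRate fraction of calls set missing (default 0.01).
#' @param structureSd SD of the per-group logit allele-frequency
#'   perturbation (default 0.6).
#' @return A \linkS4class{GenotypePanel} with cultivar metadata columns
#'   \code{decade}, \code{origin}, \code{group}.
#' @export
simulateGenotypes <- function(nCultivars, nMarkers, causal = defaultCausalSpec(),
                              structureGroups = 12, seed = 1, inbred = TRUE,
                              missingRate = 0.01, structureSd = 0.6) {
  stopIfNot(nCultivars > 0 && nMarkers > 0 && structureGroups > 0,
            "argument error: counts must be positive")
  loci <- if (is.null(causal)) data.frame() else causal$loci
  perLocus <- if (is.null(causal)) 0 else 1 + 2 * causal$ldMarkersPerSide
  stopIfNot(nMarkers >= nrow(loci) * perLocus,
            "argument error: nMarkers too small for the causal spec")
  withSeed(childSeed(seed, "genotypes"), {
    chroms <- paste0(rep(1:7, each = 3), c("A", "B", "D"))
    nDec <- ceiling(structureGroups / 2)
    decades <- paste0(seq(2010 - 10 * (nDec - 1), 2010, by = 10), "s")
    origin <- sample(c("Germany", "other"), nCultivars, replace = TRUE,
                     prob = c(0.75, 0.25))
    decade <- sample(decades, nCultivars, replace = TRUE)
    group <- paste(origin, decade, sep = "_")
    grpIdx <- as.integer(factor(group))
    nGrp <- max(grpIdx)
    cvIds <- sprintf("cv%03d", seq_len(nCultivars))

    drawDoses <- function(pByCv) {
      if (inbred) 2 * rbinom(nCultivars, 1, pByCv)
      else rbinom(nCultivars, 2, pByCv)
    }

    nBg <- nMarkers - nrow(loci) * perLocus
    mk <- list(); mp <- list()
    if (nBg > 0) {
      p0 <- runif(nBg, 0.05, 0.95)
      for (m in seq_len(nBg)) {
        pg <- plogis(qlogis(p0[m]) + rnorm(nGrp, 0, structureSd))
        mk[[length(mk) + 1L]] <- drawDoses(pg[grpIdx])
        al <- sample(c("A", "C", "G", "T"), 2)
        mp[[length(mp) + 1L]] <- data.frame(
          marker = sprintf("SNP%05d", m), chrom = sample(chroms, 1),
          pos = round(runif(1, 1e5, 7e8)), ref = al[1], alt = al[2],
          stringsAsFactors = FALSE)
      }
    }

    decIdx <- match(decade, decades)
    for (li in seq_len(nrow(loci))) {
      lc <- loci[li, ]
      favFreq <- if (lc$favIsMinor) lc$maf else 1 - lc$maf
      pByCv <- rep(favFreq, nCultivars)
      if (lc$favIsMinor && nDec > 1) {
        # rising favourable-minor frequency over decades, mean ~ favFreq
        ramp <- 0.4 + 1.2 * (decIdx - 1) / (nDec - 1)
        pByCv <- pmin(favFreq * ramp, 0.95)
      }
      causalDose <- drawDoses(pByCv)
      refBase <- setdiff(c("A", "C", "G", "T"), lc$favAllele)[1]
      tag <- sprintf("%s_%.1f", lc$chrom, lc$pos / 1e6)
      mk[[length(mk) + 1L]] <- causalDose
      mp[[length(mp) + 1L]] <- data.frame(
        marker = paste0("QTN_", tag), chrom = lc$chrom, pos = round(lc$pos),
        ref = refBase, alt = lc$favAllele, stringsAsFactors = FALSE)
      half <- causal$ldBlockWidth
      nSide <- causal$ldMarkersPerSide
      if (nSide > 0) {
        offs <- c(-rev(seq_len(nSide)), seq_len(nSide)) / nSide * half
        for (k in seq_along(offs)) {
          r2t <- 1 - 0.3 * abs(offs[k]) / half  # in [0.7, 1]
          s <- sqrt(r2t)
          keep <- runif(nCultivars) < s
          fresh <- drawDoses(rep(favFreq, nCultivars))
          mk[[length(mk) + 1L]] <- ifelse(keep, causalDose, fresh)
          mp[[length(mp) + 1L]] <- data.frame(
            marker = sprintf("LD_%s_%d", tag, k), chrom = lc$chrom,
            pos = round(lc$pos + offs[k]), ref = refBase,
            alt = lc$favAllele, stringsAsFactors = FALSE)
        }
      }
    }

    map <- do.call(rbind, mp)
    mat <- do.call(cbind, mk)
    if (missingRate > 0) {
      drop <- runif(length(mat)) < missingRate
      mat[drop] <- NA
    }
    dimnames(mat) <- list(cvIds, map$marker)
    ord <- order(map$chrom, map$pos)
    GenotypePanel(mat[, ord, drop = FALSE], map[ord, ],
                  data.frame(cultivar = cvIds, decade = decade,
                             origin = origin, group = group,
                             stringsAsFactors = FALSE))
  })
}

#' Dose of the favourable allele at the causal markers
#'
#' Helper pairing a simulated panel with its causal specification: returns
#' the per-cultivar favourable-allele dose for each planted causal marker
#' (the simulator codes the favourable allele as the alternative allele, so
#' this is the stored dose; missing calls are mean-imputed).
#'
#' @param panel a \linkS4class{GenotypePanel} from
#'   \code{\link{simulateGenotypes}}.
#' @return matrix cultivars x causal markers.
#' @export
causalDoses <- function(panel) {
  qtn <- grep("^QTN_", markers(panel), value = TRUE)
  stopIfNot(length(qtn) > 0, "panel has no planted causal markers")
  d <- doses(panel)[, qtn, drop = FALSE]
  for (j in seq_len(ncol(d))) {
    mi <- is.na(d[, j])
    if (any(mi)) d[mi, j] <- mean(d[, j], na.rm = TRUE)
  }
  d
}
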