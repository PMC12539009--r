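#' Filter markers by minor allele frequency, missingness and polymorphism
#'
#' Discards monomorphic markers, markers with minor allele frequency below
#' \code{mafMin} and markers with more than \code{missingMax} missing
#' calls. Boundaries are kept: MAF exactly at the threshold and
#' missingness exactly at the cap are retained.
#'
#' @param geno a \linkS4class{GenotypePanel}.
#' @param mafMin minimum MAF retained (default 0.03).
#' @param missingMax maximum missing-call rate retained (default 0.05).
#' @return The filtered \code{GenotypePanel}; attribute \code{report} is a
#'   list with counts removed per rule (a marker failing several rules is
#'   counted once, by the first rule in the order monomorphic, MAF,
#'   missingness).
#' @export
filterMarkers <- function(geno, mafMin = 0.03, missingMax = 0.05) {
  stopIfNot(ncol(doses(geno)) > 0, "empty genotype matrix")
  mf <- maf(geno); mr <- missingRate(geno)
  mono <- apply(doses(geno), 2, function(x) length(unique(na.omit(x))) < 2)
  badMaf <- !mono & mf < mafMin
  badMiss <- !mono & !badMaf & mr > missingMax
  keep <- !(mono | badMaf | badMiss)
  if (!any(keep))
    stop("empty-panel error: all markers removed by filtering")
  out <- geno[, keep]
  attr(out, "report") <- list(input = length(keep), retained = sum(keep),
                              monomorphic = sum(mono), lowMaf = sum(badMaf),
                              highMissing = sum(badMiss))
  out
}

#' Mean-impute missing genotype calls
#'
#' Replaces missing doses by the per-marker mean of observed doses, which
#' preserves allele frequencies; the number of imputed calls is recorded.
#'
#' @param geno a \linkS4class{GenotypePanel}.
#' @return The completed panel with attribute \code{nImputed}.
#' @export
imputeMissing <- function(geno) {
  d <- doses(geno)
  nImp <- sum(is.na(d))
  if (nImp > 0) {
    cm <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- cm[idx[, 2]]
  }
  out <- new("GenotypePanel", doses = d, map = geno@map, info = geno@info)
  attr(out, "nImputed") <- nImp
  out
}

#' Principal components of the marker matrix
#'
#' PCA of the centred dose matrix (population-structure covariates for the
#' association scan). Variance-explained fractions are reported so the
#' structure captured by each component can be judged.
#'
#' @param geno a complete (imputed) \linkS4class{GenotypePanel}.
#' @param k number of components (default 3).
#' @param scale. scale markers to unit variance (default FALSE).
#' @return list: \code{scores} (cultivars x k), \code{varExplained}
#'   (fractions, nonincreasing), \code{sdev}.
#' @export
pcaMarkers <- function(geno, k = 3, scale. = FALSE) {
  d <- doses(geno)
  stopIfNot(!anyNA(d), "impute missing calls before PCA")
  stopIfNot(nrow(d) >= k + 1, "need at least k + 1 cultivars")
  pr <- prcomp(d, center = TRUE, scale. = scale.)
  rk <- sum(pr$sdev > max(pr$sdev) * 1e-8)
  if (k > rk) stop("rank error: k exceeds the rank of the dose matrix (", rk, ")")
  list(scores = pr$x[, seq_len(k), drop = FALSE],
       varExplained = (pr$sdev^2 / sum(pr$sdev^2))[seq_len(k)],
       sdev = pr$sdev)
}

# Align a covariate matrix to the scanned cultivar subset: by rownames
# when present, otherwise assuming row order matches the phenotype vector.
alignCovariates <- function(covariates, pheno, common) {
  if (is.null(covariates)) return(NULL)
  covariates <- as.matrix(covariates)
  if (is.null(rownames(covariates))) {
    stopIfNot(nrow(covariates) == length(pheno),
              "covariates without rownames must match the phenotype length")
    rownames(covariates) <- names(pheno)
  }
  covariates[common, , drop = FALSE]
}

# Core scan machinery: OLS of phenotype on each marker dose plus fixed
# covariates, via residualisation (Frisch-Waugh). Returns one row per
# marker. Collinear markers get NA p-values and a flag.
scanCore <- function(y, X, covariates = NULL) {
  n <- length(y)
  C <- cbind(rep(1, n), covariates)
  qrC <- qr(C)
  yR <- qr.resid(qrC, y)
  XR <- qr.resid(qrC, X)
  xss <- colSums(XR^2)
  dfRes <- n - qr(C)$rank - 1
  beta <- colSums(XR * yR) / xss
  rss <- sum(yR^2) - beta^2 * xss
  sigma2 <- rss / dfRes
  se <- sqrt(sigma2 / xss)
  tstat <- beta / se
  p <- 2 * pt(abs(tstat), dfRes, lower.tail = FALSE)
  collinear <- xss < max(xss, 1) * 1e-10
  beta[collinear] <- NA; se[collinear] <- NA; p[collinear] <- NA
  data.frame(marker = colnames(X), effect = beta, se = se, p = p,
             collinear = collinear, stringsAsFactors = FALSE)
}

#' Single-marker association scan
#'
#' Ordinary-least-squares association of genotype effects with each marker
#' dose, adjusting for fixed covariates (typically the first principal
#' components of the marker matrix). The marker effect is the dose
#' coefficient; its t-test gives the p-value. Bonferroni and
#' Benjamini-Hochberg control and the per-marker percentage of phenotypic
#' variance explained are attached.
#'
#' @param pheno named numeric vector of genotype effects (names = cultivar
#'   ids, transformed-PSRI scale).
#' @param geno a \linkS4class{GenotypePanel} (missing calls are
#'   mean-imputed internally).
#' @param covariates cultivar x q matrix of covariates (e.g.
#'   \code{pcaMarkers()$scores}); rownames must identify cultivars.
#' @param alpha significance level for the multiple-testing flags.
#' @return An association data.frame: marker, effect, se, p, pAdj (BH),
#'   bonferroniSignificant, fdrSignificant, pve, maf, collinear.
#' @export
singleMarkerScan <- function(pheno, geno, covariates = NULL, alpha = 0.05) {
  common <- intersect(names(pheno), cultivars(geno))
  stopIfNot(length(common) >= 10,
            "phenotype and genotype cultivar sets overlap in < 10 cultivars")
  geno <- imputeMissing(geno[common, ])
  y <- pheno[common]
  covariates <- alignCovariates(covariates, pheno, common)
  res <- scanCore(y, doses(geno), covariates)
  res$maf <- maf(geno)[res$marker]
  mt <- multipleTesting(res$p, alpha = alpha)
  res$pAdj <- mt$pAdj
  res$bonferroniSignificant <- mt$bonferroniSignificant
  res$fdrSignificant <- mt$fdrSignificant
  res$pve <- ifelse(is.na(res$effect), NA,
                    pve(res$effect, res$maf, var(y)))
  rownames(res) <- NULL
  res
}

#' Iterative multi-locus association scan
#'
#' A simplified iterative-conditioning scan in the spirit of multi-locus
#' GWAS models: starting from the covariate-adjusted single-marker scan,
#' the most significant marker passing the Bonferroni threshold that is
#' not in LD (r-squared above \code{r2Max}) with an already selected
#' pseudo-QTN is added to the covariate set, and the scan repeats. The
#' procedure stops when no further marker qualifies or after
#' \code{maxIter} rounds. Final p-values come from the last rescan, with
#' each selected pseudo-QTN tested leave-one-out (conditioning on the
#' other selected QTNs only).
#'
#' @inheritParams singleMarkerScan
#' @param alpha genome-wide level defining the Bonferroni entry threshold.
#' @param maxIter maximum number of conditioning rounds (default 10).
#' @param r2Max LD threshold excluding near-duplicates of selected QTNs.
#' @return As \code{\link{singleMarkerScan}}, plus attribute
#'   \code{pseudoQtn} (character vector of selected markers, in selection
#'   order) and column \code{isPseudoQtn}.
#' @export
multilocusScan <- function(pheno, geno, covariates = NULL, alpha = 0.05,
                           maxIter = 10, r2Max = 0.7) {
  common <- intersect(names(pheno), cultivars(geno))
  stopIfNot(length(common) >= 10,
            "phenotype and genotype cultivar sets overlap in < 10 cultivars")
  geno <- imputeMissing(geno[common, ])
  y <- pheno[common]
  D <- doses(geno)
  covariates <- alignCovariates(covariates, pheno, common)
  m <- ncol(D)
  bonf <- alpha / m
  selected <- character(0)
  for (it in seq_len(maxIter)) {
    covNow <- cbind(covariates, D[, selected, drop = FALSE])
    res <- scanCore(y, D, covNow)
    res <- res[!(res$marker %in% selected), ]
    cand <- res[!is.na(res$p) & res$p < bonf, ]
    if (!nrow(cand)) break
    cand <- cand[order(cand$p), ]
    pick <- NA_character_
    for (mk in cand$marker) {
      ok <- TRUE
      for (s in selected)
        if (ldR2(D[, mk], D[, s]) > r2Max) { ok <- FALSE; break }
      if (ok) { pick <- mk; break }
    }
    if (is.na(pick)) break
    selected <- c(selected, pick)
  }
  if (length(selected) == maxIter)
    warning("multilocus scan stopped at maxIter = ", maxIter)
  # final p-values: last rescan conditioning on all selected QTNs;
  # selected QTNs themselves tested leave-one-out
  covAll <- cbind(covariates, D[, selected, drop = FALSE])
  final <- scanCore(y, D, covAll)
  for (s in selected) {
    others <- setdiff(selected, s)
    covLoo <- cbind(covariates, D[, others, drop = FALSE])
    row <- scanCore(y, D[, s, drop = FALSE], covLoo)
    final[final$marker == s, c("effect", "se", "p", "collinear")] <-
      row[, c("effect", "se", "p", "collinear")]
  }
  final$maf <- maf(geno)[final$marker]
  mt <- multipleTesting(final$p, alpha = alpha)
  final$pAdj <- mt$pAdj
  final$bonferroniSignificant <- mt$bonferroniSignificant
  final$fdrSignificant <- mt$fdrSignificant
  final$pve <- ifelse(is.na(final$effect), NA,
                      pve(final$effect, final$maf, var(y)))
  final$isPseudoQtn <- final$marker %in% selected
  attr(final, "pseudoQtn") <- selected
  rownames(final) <- NULL
  final
}

#' Multiple-testing control
#'
#' Bonferroni threshold (alpha / m) and Benjamini-Hochberg step-up
#' adjusted p-values with a false-discovery-rate cut-off at \code{alpha}.
#'
#' @param p vector of p-values in (0, 1] (NA allowed, ignored for m).
#' @param alpha level (default 0.05).
#' @return list: \code{bonferroniThreshold}, \code{pAdj} (BH),
#'   \code{bonferroniSignificant}, \code{fdrSignificant}.
#' @export
multipleTesting <- function(p, alpha = 0.05) {
  stopIfNot(length(p) > 0, "argument error: empty p-value vector")
  m <- sum(!is.na(p))
  stopIfNot(m > 0, "argument error: no non-missing p-values")
  thr <- alpha / m
  pAdj <- p.adjust(p, method = "BH")
  list(bonferroniThreshold = thr,
       pAdj = pAdj,
       bonferroniSignificant = !is.na(p) & p < thr,
       fdrSignificant = !is.na(pAdj) & pAdj <= alpha)
}

#' Percentage of phenotypic variance explained by a marker
#'
#' \deqn{PVE = 100 \cdot 2 \, maf (1 - maf) \, \beta^2 / Var(y)} capped at
#' 100. This is the usual allele-frequency-weighted effect-size summary; on
#' a fully inbred panel (doses 0/2) the realised dose variance is twice
#' the binomial term, so the figure is conservative there.
#'
#' @param effect marker effect (dose coefficient).
#' @param maf minor allele frequency in [0, 0.5].
#' @param phenotypeVariance variance of the phenotype (> 0).
#' @return PVE in percent, in [0, 100].
#' @examples
#' pve(1, 0.5, 2)  # 25
#' @export
pve <- function(effect, maf, phenotypeVariance) {
  stopIfNot(all(phenotypeVariance > 0), "phenotype variance must be positive")
  stopIfNot(all(maf >= 0 & maf <= 0.5), "maf must lie in [0, 0.5]")
  pmin(100, 100 * 2 * maf * (1 - maf) * effect^2 / phenotypeVariance)
}

#' Manhattan-ready association table
#'
#' Orders association results by chromosome and position, attaches
#' -log10(p), a genome-wide cumulative position, and both significance
#' thresholds, ready for a Manhattan plot.
#'
#' @param results association data.frame (from a scan), needing columns
#'   \code{marker} and \code{p}.
#' @param map marker map with \code{marker}, \code{chrom}, \code{pos}.
#' @param alpha level for the thresholds (default 0.05).
#' @return data.frame sorted chromosome-major: marker, chrom, pos,
#'   cumPos (strictly increasing), p, negLog10P, bonferroniThreshold,
#'   fdrThreshold (largest raw p flagged by BH, NA when none).
#' @export
manhattanTable <- function(results, map, alpha = 0.05) {
  idx <- match(results$marker, map$marker)
  if (anyNA(idx))
    stop("mapping error: no map entry for ",
         paste(head(results$marker[is.na(idx)], 5), collapse = ", "))
  d <- data.frame(marker = results$marker, chrom = map$chrom[idx],
                  pos = map$pos[idx], p = results$p,
                  stringsAsFactors = FALSE)
  d <- d[order(d$chrom, d$pos), ]
  offsets <- c(0, cumsum(tapply(d$pos, factor(d$chrom, unique(d$chrom)), max) + 1))
  cp <- d$pos + offsets[match(d$chrom, unique(d$chrom))]
  # tiny strictly increasing jitter resolves tied positions
  d$cumPos <- cp + (seq_len(nrow(d)) - 1) * 1e-9
  d$negLog10P <- -log10(d$p)
  mt <- multipleTesting(results$p, alpha = alpha)
  d$bonferroniThreshold <- mt$bonferroniThreshold
  flagged <- results$p[mt$fdrSignificant]
  d$fdrThreshold <- if (length(flagged)) max(flagged) else NA_real_
  rownames(d) <- NULL
  d
}
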