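# Shared fixtures, built in code.

# Balanced split-plot observations drawn from the variance-component model
# y = mu + N + B + c_k + (cn)_ki + e, with c ~ N(0, vC), cn ~ N(0, vCxN),
# e ~ N(0, vR). Returns a long data.frame ready for fitSplitPlot.
makeBalancedObs <- function(nCultivars = 20, nLevels = 3, nBlocks = 2,
                            vC = 1, vCxN = 0.3, vR = 0.6, mu = 5,
                            date = "d1") {
  cv <- sprintf("c%02d", seq_len(nCultivars))
  nl <- paste0("N", seq_len(nLevels))
  blk <- paste0("B", seq_len(nBlocks))
  g <- expand.grid(cultivar = cv, n_level = nl, block = blk, date = date,
                   stringsAsFactors = FALSE)
  cEff <- rnorm(nCultivars, 0, sqrt(vC))
  cnEff <- matrix(rnorm(nCultivars * nLevels, 0, sqrt(vCxN)), nCultivars)
  nEff <- seq_len(nLevels) * 0.5
  bEff <- seq_len(nBlocks) * 0.2
  i <- match(g$cultivar, cv); j <- match(g$n_level, nl)
  g$value <- mu + nEff[j] + bEff[match(g$block, blk)] + cEff[i] +
    cnEff[cbind(i, j)] + rnorm(nrow(g), 0, sqrt(vR))
  g
}

# Tiny genotype panel with explicit doses (cultivars x markers).
makePanel <- function(doseMat, chrom = NULL, pos = NULL,
                      ref = "A", alt = "G", info = NULL) {
  m <- ncol(doseMat)
  if (is.null(colnames(doseMat)))
    colnames(doseMat) <- sprintf("M%02d", seq_len(m))
  if (is.null(rownames(doseMat)))
    rownames(doseMat) <- sprintf("cv%03d", seq_len(nrow(doseMat)))
  map <- data.frame(marker = colnames(doseMat),
                    chrom = if (is.null(chrom)) rep("1A", m) else chrom,
                    pos = if (is.null(pos)) seq_len(m) * 1e5 else pos,
                    ref = rep_len(ref, m), alt = rep_len(alt, m),
                    stringsAsFactors = FALSE)
  GenotypePanel(doseMat, map, info)
}

# Adjusted Rand index between two partitions (independent of any package
# clustering code; plain contingency-table formula).
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sumij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2)); bj <- sum(choose(colSums(tab), 2))
  expct <- ai * bj / choose(n, 2)
  mx <- (ai + bj) / 2
  if (mx == expct) return(1)
  (sumij - expct) / (mx - expct)
}
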