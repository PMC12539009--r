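#' Linkage disequilibrium as squared dose correlation
#'
#' Composite LD: the squared Pearson correlation of allele-dose vectors,
#' appropriate for unphased data from an essentially inbred panel.
#' Symmetric and invariant to allele relabelling (x to 2 - x).
#'
#' @param a,b dose vectors for two markers (pairwise-complete values used).
#' @param minN minimum number of cultivars observed at both markers.
#' @return r-squared in [0, 1].
#' @export
ldR2 <- function(a, b, minN = 10) {
  ok <- complete.cases(a, b)
  stopIfNot(sum(ok) >= minN,
            paste("need >=", minN, "cultivars observed at both markers"))
  a <- a[ok]; b <- b[ok]
  if (sd(a) == 0 || sd(b) == 0)
    stop("undefined-LD error: monomorphic marker")
  cor(a, b)^2
}

#' Collect the LD block around a focal marker
#'
#' Starting at the focal marker, extends along the chromosome over
#' physically adjacent markers in map order, in both directions, adding
#' each marker while its LD (r-squared) with the focal marker exceeds
#' \code{r2Min}; extension stops at the first failure per direction
#' (contiguous-run rule). A gap-tolerant variant
#' (\code{maxSkip} > 0) may step over that many consecutive failures.
#'
#' @param focal focal marker id.
#' @param geno a \linkS4class{GenotypePanel}.
#' @param r2Min LD inclusion threshold (default 0.7, exclusive).
#' @param maxSkip markers allowed to be skipped per direction (default 0).
#' @return list: \code{members} (marker ids in map order, focal included),
#'   \code{spanMbp} (min/max position in Mbp), \code{r2} (named r-squared
#'   with the focal marker).
#' @export
collectBlock <- function(focal, geno, r2Min = 0.7, maxSkip = 0) {
  map <- markerMap(geno)
  stopIfNot(focal %in% map$marker, paste("focal marker", focal, "not in map"))
  chr <- map$chrom[map$marker == focal]
  onChr <- map[map$chrom == chr, ]
  onChr <- onChr[order(onChr$pos), ]
  idx <- which(onChr$marker == focal)
  D <- doses(geno)
  fd <- D[, focal]
  if (length(unique(na.omit(fd))) < 2)
    stop("undefined-LD error: focal marker is monomorphic")
  r2s <- setNames(1, focal)
  pick <- idx
  for (dir in c(-1L, 1L)) {
    j <- idx + dir; skipped <- 0
    while (j >= 1 && j <= nrow(onChr)) {
      mk <- onChr$marker[j]
      r2 <- tryCatch(ldR2(fd, D[, mk]), error = function(e) 0)
      if (r2 > r2Min) {
        pick <- c(pick, j)
        r2s[mk] <- r2
        skipped <- 0
      } else {
        skipped <- skipped + 1
        if (skipped > maxSkip) break
      }
      j <- j + dir
    }
  }
  pick <- sort(unique(pick))
  members <- onChr$marker[pick]
  list(members = members,
       spanMbp = range(onChr$pos[pick]) / 1e6,
       r2 = r2s[members])
}

#' Cluster cultivars into haplotypes over an LD block
#'
#' K-means on the (imputed) dose sub-matrix of the block markers, with a
#' fixed-seed multi-start. k is chosen as the largest k not exceeding
#' \code{kMax} for which every cluster holds at least \code{minMembers}
#' cultivars (k scanned downward; k = 1 is the degenerate fallback), so no
#' emitted haplotype is smaller than the membership rule allows.
#'
#' @param geno a \linkS4class{GenotypePanel}.
#' @param block result of \code{\link{collectBlock}} (or a character vector
#'   of member marker ids; the first is taken as focal if \code{focal} is
#'   missing).
#' @param focal focal marker id (defaults to the block's first member).
#' @param kMax maximum clusters tried (default 6).
#' @param minMembers minimum cultivars per cluster (default 5).
#' @param seed RNG seed for the k-means multi-start.
#' @param nstart k-means restarts (default 25).
#' @return A \linkS4class{HaplotypeCall} (codes and favourable flags unset;
#'   see \code{\link{nameHaplotypes}} and \code{\link{favourableClusters}}).
#' @export
clusterHaplotypes <- function(geno, block, focal = NULL, kMax = 6,
                              minMembers = 5, seed = 1, nstart = 25) {
  if (is.character(block)) block <- list(members = block, spanMbp = c(NA, NA))
  members <- block$members
  if (is.null(focal)) focal <- members[1]
  stopIfNot(length(members) >= 1, "block must contain at least one marker")
  sub <- imputeMissing(geno[, members])
  X <- doses(sub)
  nC <- nrow(X)
  if (nC < minMembers)
    stop("infeasible-clustering error: fewer than ", minMembers, " cultivars")
  nDistinct <- nrow(unique(X))
  assign <- NULL; kUsed <- 1L
  kTop <- min(kMax, nDistinct, nC %/% minMembers)
  for (k in (if (kTop >= 2) seq(kTop, 2L, by = -1L) else integer(0))) {
    km <- withSeed(childSeed(seed, paste0("kmeans", k)),
                   kmeans(X, centers = k, nstart = nstart, iter.max = 50))
    if (min(table(km$cluster)) >= minMembers) {
      assign <- km$cluster; kUsed <- k; break
    }
  }
  if (is.null(assign)) assign <- rep(1L, nC)
  # relabel clusters by decreasing size (stable, deterministic)
  sizes <- table(assign)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relab <- integer(length(sizes)); relab[as.integer(names(sizes))[ord]] <-
    seq_along(ord)
  assign <- relab[assign]
  sizes <- as.integer(table(assign))
  fd <- doses(imputeMissing(geno[, focal, drop = FALSE]))[, 1]
  mapRow <- markerMap(geno)[focal, ]
  pAlt <- mean(fd) / 2
  majorIsAlt <- pAlt > 0.5
  new("HaplotypeCall", focal = focal, members = members,
      spanMbp = as.numeric(block$spanMbp),
      assignments = setNames(as.integer(assign), rownames(X)),
      codes = rep(NA_character_, kUsed),
      sizes = sizes,
      favourable = rep(NA, kUsed),
      majorAllele = if (majorIsAlt) mapRow$alt else mapRow$ref,
      minorAllele = if (majorIsAlt) mapRow$ref else mapRow$alt,
      flags = character(0))
}

#' Name haplotype clusters by their focal-marker allele
#'
#' Codes are built from the modal focal-marker allele of each cluster: 'M'
#' plus the base for the panel-wide major allele, 'm' plus the base for
#' the minor allele. When several clusters share the same first letter and
#' base, the largest keeps the bare code and later ones (in descending
#' size order) receive a variant suffix 'v' ('v2', 'v3' beyond two, with a
#' flag, since the code grammar foresees a single variant letter). A tie
#' in a cluster's modal allele is broken towards the major allele and
#' flagged.
#'
#' @param call a \linkS4class{HaplotypeCall}.
#' @param geno the \linkS4class{GenotypePanel} the call was made from.
#' @return The call with \code{codes} filled in.
#' @export
nameHaplotypes <- function(call, geno) {
  fd <- doses(imputeMissing(geno[names(call@assignments), call@focal,
                                 drop = FALSE]))[, 1]
  majorIsAlt <- mean(fd) / 2 > 0.5
  flags <- call@flags
  k <- length(call@sizes)
  first <- character(k); base <- character(k)
  for (cl in seq_len(k)) {
    dcl <- fd[call@assignments == cl]
    altShare <- mean(dcl) / 2
    if (abs(altShare - 0.5) < 1e-12) {
      isAlt <- majorIsAlt  # tie: towards the major allele
      flags <- c(flags, sprintf("cluster %d: modal-allele tie", cl))
    } else isAlt <- altShare > 0.5
    isMajor <- (isAlt == majorIsAlt)
    first[cl] <- if (isMajor) "M" else "m"
    base[cl] <- if (isMajor) call@majorAllele else call@minorAllele
  }
  codes <- character(k)
  combo <- paste0(first, base)
  for (u in unique(combo)) {
    idx <- which(combo == u)
    idx <- idx[order(-call@sizes[idx], idx)]
    suff <- c("", "v", paste0("v", seq_len(max(0, length(idx) - 2)) + 1))
    if (length(idx) > 2)
      flags <- c(flags, paste0("more than two '", u,
                               "' clusters: numbered variant suffixes used"))
    codes[idx] <- paste0(u, suff[seq_along(idx)])
  }
  call@codes <- codes
  call@flags <- unique(flags)
  validObject(call)
  call
}

#' Flag favourable haplotype clusters
#'
#' A cluster is favourable when its cultivars' mean genotype effect on
#' PSRI lies below the locus grand mean and the difference from the
#' remaining cultivars is significant (Welch t-test at \code{alpha}):
#' favourable variants delay senescence, i.e. lower PSRI.
#'
#' @param call a \linkS4class{HaplotypeCall}.
#' @param effects named numeric genotype effects (transformed-PSRI scale).
#' @param alpha significance level (default 0.05).
#' @return The call with \code{favourable} filled in.
#' @export
favourableClusters <- function(call, effects, alpha = 0.05) {
  common <- intersect(names(call@assignments), names(effects))
  asg <- call@assignments[common]; eff <- effects[common]
  grand <- mean(eff)
  fav <- logical(length(call@sizes))
  for (cl in seq_along(call@sizes)) {
    inCl <- eff[asg == cl]; outCl <- eff[asg != cl]
    if (length(inCl) < 2 || length(outCl) < 2) { fav[cl] <- FALSE; next }
    tt <- t.test(inCl, outCl)
    fav[cl] <- mean(inCl) < grand && tt$p.value < alpha
  }
  call@favourable <- fav
  call
}

#' Test trait differences between haplotype clusters
#'
#' Chooses the test the data support: variance homogeneity is assessed by
#' Levene's test (alpha = 0.05); with three or more groups, homogeneous
#' variances lead to ANOVA with Tukey HSD grouping letters, heterogeneous
#' variances to Kruskal-Wallis with Bonferroni-adjusted pairwise Wilcoxon
#' letters. With two groups a Student (homogeneous) or Welch
#' (heterogeneous) t-test is used. Constant groups force the
#' nonparametric branch.
#'
#' @param values trait values (e.g. genotype effects, yields).
#' @param groups factor of haplotype assignments/codes (>= 2 groups with
#'   >= 2 observations each).
#' @param alpha level used for the letters (default 0.05).
#' @return list: \code{test} (branch used), \code{statistic}, \code{p},
#'   \code{letters} (named grouping letters), \code{levene_p},
#'   \code{note}.
#' @export
haplotypeEffectTest <- function(values, groups, alpha = 0.05) {
  groups <- droplevels(factor(groups))
  ok <- complete.cases(values, groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  ng <- nlevels(groups)
  # internal hyphen-free level codes (labels like "F-F-U" would collide
  # with the "a-b" separator in TukeyHSD comparison names)
  origLv <- levels(groups)
  safeLv <- sprintf("g%02d", seq_len(ng))
  groups <- factor(safeLv[as.integer(groups)], levels = safeLv)
  stopIfNot(ng >= 2, "need at least two groups")
  stopIfNot(all(table(groups) >= 2), "every group needs >= 2 observations")
  gsd <- tapply(values, groups, sd)
  note <- ""
  if (any(gsd == 0) && !all(gsd == 0)) {
    equalVar <- FALSE
    levP <- NA_real_
    note <- "constant group present: nonparametric branch forced"
  } else if (all(gsd == 0)) {
    equalVar <- TRUE; levP <- 1
  } else {
    levP <- car::leveneTest(values ~ groups)[1, "Pr(>F)"]
    equalVar <- levP >= 0.05
  }
  lv <- levels(groups)
  if (ng == 2) {
    tt <- t.test(values ~ groups, var.equal = equalVar)
    sig <- tt$p.value < alpha
    letters_out <- if (sig) setNames(c("a", "b"), origLv)
                   else setNames(c("a", "a"), origLv)
    return(list(test = if (equalVar) "Student t" else "Welch t",
                statistic = unname(tt$statistic), p = tt$p.value,
                letters = letters_out, levene_p = levP, note = note))
  }
  if (equalVar) {
    fit <- aov(values ~ groups)
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
    stat <- summary(fit)[[1]][["F value"]][1]
    tk <- TukeyHSD(fit)$groups
    sigMat <- matrix(FALSE, ng, ng, dimnames = list(lv, lv))
    prs <- strsplit(rownames(tk), "-", fixed = TRUE)
    for (i in seq_along(prs))
      sigMat[prs[[i]][1], prs[[i]][2]] <-
        sigMat[prs[[i]][2], prs[[i]][1]] <- tk[i, "p adj"] < alpha
    test <- "ANOVA + Tukey HSD"
  } else {
    kw <- kruskal.test(values, groups)
    p <- kw$p.value; stat <- unname(kw$statistic)
    pw <- suppressWarnings(
      pairwise.wilcox.test(values, groups, p.adjust.method = "bonferroni",
                           exact = FALSE))
    sigMat <- matrix(FALSE, ng, ng, dimnames = list(lv, lv))
    pv <- pw$p.value
    for (i in rownames(pv)) for (j in colnames(pv))
      if (!is.na(pv[i, j]))
        sigMat[i, j] <- sigMat[j, i] <- pv[i, j] < alpha
    test <- "Kruskal-Wallis + pairwise Wilcoxon"
  }
  letters_out <- assignGroupLetters(lv, sigMat)
  names(letters_out) <- origLv
  list(test = test, statistic = stat, p = p, letters = letters_out,
       levene_p = levP, note = note)
}

#' Stacking classes over three focal loci
#'
#' Combines per-cultivar favourable/unfavourable status at three
#' configured loci (fixed order) into a stacking label such as "U-U-U",
#' "F-U-U", "F-F-U" or "F-F-F", and tests the trait across classes.
#' Cultivars uncalled at any locus are excluded and logged.
#'
#' @param calls list of three \linkS4class{HaplotypeCall}s (favourable
#'   flags set), in the configured locus order.
#' @param traits optional named trait values for the per-class test.
#' @return list: \code{classes} (data.frame cultivar, label, plus one
#'   logical column per locus), \code{counts} (table of labels),
#'   \code{test} (a \code{\link{haplotypeEffectTest}} report or NULL),
#'   \code{excluded} (cultivars dropped).
#' @export
stackingClasses <- function(calls, traits = NULL) {
  stopIfNot(length(calls) == 3, "exactly three loci must be configured")
  favBy <- lapply(calls, function(cl) {
    stopIfNot(!anyNA(cl@favourable),
              "favourable flags unset: run favourableClusters() first")
    setNames(cl@favourable[cl@assignments], names(cl@assignments))
  })
  all_cv <- unique(unlist(lapply(favBy, names)))
  called <- Reduce(intersect, lapply(favBy, names))
  excluded <- setdiff(all_cv, called)
  if (length(excluded))
    message(length(excluded), " cultivar(s) uncalled at >= 1 locus excluded")
  flagMat <- vapply(favBy, function(f) f[called], logical(length(called)))
  labels <- apply(flagMat, 1, function(f)
    paste(ifelse(f, "F", "U"), collapse = "-"))
  classes <- data.frame(cultivar = called,
                        locus1 = flagMat[, 1], locus2 = flagMat[, 2],
                        locus3 = flagMat[, 3], label = labels,
                        stringsAsFactors = FALSE)
  test <- NULL
  if (!is.null(traits)) {
    tv <- traits[called]
    keepLab <- names(table(labels))[table(labels) >= 2]
    sel <- labels %in% keepLab & !is.na(tv)
    if (length(unique(labels[sel])) >= 2)
      test <- haplotypeEffectTest(tv[sel], labels[sel])
  }
  list(classes = classes, counts = table(labels), test = test,
       excluded = excluded)
}

#' Fraction of a cultivar set carrying all configured favourable variants
#'
#' Percentage of the (stay-green) set whose members carry the favourable
#' haplotype variant at every one of the configured loci.
#'
#' @param set character vector of cultivar ids (nonempty).
#' @param calls list of \linkS4class{HaplotypeCall}s with favourable flags.
#' @return Percentage in [0, 100]; cultivars uncalled at a locus count as
#'   non-carriers.
#' @export
carrierFraction <- function(set, calls) {
  stopIfNot(length(set) > 0, "stay-green set is empty")
  carries <- rep(TRUE, length(set))
  for (cl in calls) {
    fav <- setNames(cl@favourable[cl@assignments], names(cl@assignments))
    carries <- carries & !is.na(fav[set]) & fav[set]
  }
  100 * mean(carries)
}

#' Allele-frequency trend over decades of cultivar release
#'
#' Frequency of an allele of interest per decade (within an optional
#' origin group), with counts, and a Mann-Kendall-type monotone-trend test
#' (Kendall correlation of frequency with decade order) when three or more
#' decades are present. Decades without cultivars are omitted with a note.
#'
#' @param geno a \linkS4class{GenotypePanel} whose \code{cultivarInfo} has
#'   a \code{decade} column (and optionally \code{origin}).
#' @param marker marker id.
#' @param allele base whose frequency is tracked ("alt" / "ref" also
#'   accepted).
#' @param origin optional origin-group filter (e.g. "Germany").
#' @return list: \code{table} (decade, n, frequency), \code{trend}
#'   (list(tau, p) or NULL for fewer than 3 decades).
#' @export
alleleFrequencyTrend <- function(geno, marker, allele = "alt", origin = NULL) {
  info <- cultivarInfo(geno)
  stopIfNot("decade" %in% names(info), "cultivar metadata needs a decade column")
  keep <- rep(TRUE, nrow(info))
  if (!is.null(origin)) {
    stopIfNot("origin" %in% names(info), "no origin column in metadata")
    keep <- info$origin == origin
  }
  d <- doses(geno)[keep, marker]
  dec <- as.character(info$decade[keep])
  mapRow <- markerMap(geno)[marker, ]
  if (allele %in% c(mapRow$ref, "ref")) d <- 2 - d
  else stopIfNot(allele %in% c(mapRow$alt, "alt"),
                 paste("allele must be", mapRow$ref, "or", mapRow$alt))
  ok <- !is.na(d)
  d <- d[ok]; dec <- dec[ok]
  decs <- sort(unique(dec))
  tab <- data.frame(decade = decs,
                    n = as.integer(table(factor(dec, decs))),
                    frequency = as.numeric(tapply(d, factor(dec, decs),
                                                  function(x) mean(x) / 2)))
  trend <- NULL
  if (nrow(tab) >= 3) {
    ct <- suppressWarnings(cor.test(seq_len(nrow(tab)), tab$frequency,
                                    method = "kendall"))
    trend <- list(tau = unname(ct$estimate), p = ct$p.value)
  }
  list(table = tab, trend = trend)
}
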