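#' Fit the split-plot model to plot-level index observations
#'
#' Fits the repeated-measures split-plot model for a trial with nitrogen
#' level as the main plot, blocks as replications, cultivars as sub-plots
#' and imaging date as the repeated factor:
#' \deqn{Y = \mu + N + B + nb + C + CN + cnb + T + TN + TC + TNC + \epsilon}
#' with main-plot error nb, sub-plot error cnb and residual error. Three
#' things are produced per imaging date: variance components (cultivar,
#' cultivar-by-N, residual), genotype effects, and a fixed-effect ANOVA
#' table in which N is tested against the main-plot stratum, cultivar and
#' cultivar-by-N against the sub-plot stratum, and time terms against the
#' residual with a Greenhouse-Geisser correction.
#'
#' Variance components for balanced data are the expected-mean-squares
#' (method-of-moments) solutions with cultivar and cultivar-by-N random;
#' negative solutions are truncated at zero and flagged. Unbalanced data
#' fall back to REML (\pkg{lme4}).
#'
#' Genotype effects per date are centred cultivar means of the transformed
#' response (\code{unshrunken}, the default) or those means shrunken by the
#' date's reliability (\code{shrunken}, the balanced-design best linear
#' unbiased prediction).
#'
#' @param obs long data.frame with columns \code{cultivar}, \code{n_level},
#'   \code{block}, \code{date}, and the response column \code{value}.
#' @param transform \code{"sqrt10"} (default; \code{sqrt(x + 10)}) or
#'   \code{"none"}.
#' @param effects \code{"unshrunken"} or \code{"shrunken"}.
#' @param pooledDates dates over which pooled genotype effects are averaged
#'   (default: all dates present).
#' @param repsPerBlock replicates per block (default 1); the reliability
#'   denominator uses r = blocks x repsPerBlock.
#' @return A list of class \code{splitPlotFit}: \code{components} (named
#'   list of \linkS4class{VarianceComponents} per date), \code{effects}
#'   (cultivar x date matrix), \code{pooledEffects} (named vector),
#'   \code{anova} (data.frame), \code{epsilon} (Greenhouse-Geisser),
#'   \code{method} ("EMS" or "REML"), \code{transform}, \code{effectMode}.
#' @export
fitSplitPlot <- function(obs, transform = c("sqrt10", "none"),
                         effects = c("unshrunken", "shrunken"),
                         pooledDates = NULL, repsPerBlock = 1) {
  transform <- match.arg(transform)
  effects <- match.arg(effects)
  need <- c("cultivar", "n_level", "block", "date", "value")
  stopIfNot(all(need %in% names(obs)),
            paste("obs needs columns:", paste(need, collapse = ", ")))
  obs <- obs[complete.cases(obs[need]), need]
  obs$y <- if (transform == "sqrt10") transformPsri(obs$value) else obs$value
  cv <- factor(obs$cultivar); nl <- factor(obs$n_level)
  blk <- factor(obs$block); tp <- factor(as.character(obs$date))
  n <- nlevels(nl); b <- nlevels(blk); tN <- nlevels(tp)
  if (n == 1 && b == 1)
    stop("inestimable components: design has neither replication nor N levels")
  counts <- table(cv, nl, blk, tp)
  balanced <- all(counts == counts[1]) && counts[1] >= 1

  dates <- levels(tp)
  comp <- vector("list", length(dates)); names(comp) <- dates
  effMat <- matrix(NA_real_, nlevels(cv), length(dates),
                   dimnames = list(levels(cv), dates))
  r <- b * repsPerBlock
  for (d in dates) {
    sel <- tp == d
    comp[[d]] <- if (balanced)
      emsComponents(obs$y[sel], cv[sel], nl[sel], blk[sel], r = r)
    else remlComponents(obs$y[sel], cv[sel], nl[sel], blk[sel], r = r)
    m <- tapply(obs$y[sel], cv[sel], mean)
    eff <- m - mean(m)
    if (effects == "shrunken") eff <- eff * reliability(comp[[d]])
    effMat[names(eff), d] <- eff
  }
  if (is.null(pooledDates)) pooledDates <- dates
  pooledDates <- as.character(pooledDates)
  stopIfNot(all(pooledDates %in% dates), "pooledDates must be observed dates")
  pooled <- rowMeans(effMat[, pooledDates, drop = FALSE])

  # Fixed-effect ANOVA with proper error strata via aov().
  mp <- interaction(nl, blk, drop = TRUE)
  adf <- data.frame(y = obs$y, nl = nl, blk = blk, cv = cv, tp = tp, mp = mp)
  eps <- NA_real_
  if (tN >= 2) {
    form <- if (n > 1) y ~ nl * cv * tp + blk + Error(mp / cv)
            else y ~ cv * tp + blk + Error(mp / cv)
    fit <- aov(form, data = adf)
    # Greenhouse-Geisser epsilon from the sub-plot x time covariance
    # (series centred within N x time cells).
    sp <- interaction(nl, blk, cv, drop = TRUE)
    cellMean <- ave(adf$y, nl, tp)
    resY <- adf$y - cellMean
    wide <- tapply(resY, list(sp, tp), mean)
    if (nrow(wide) > tN && !anyNA(wide))
      eps <- as.numeric(greenhouseGeisserEpsilon(wide))
  } else {
    form <- if (n > 1) y ~ nl * cv + blk + Error(mp)
            else y ~ cv + blk + Error(mp)
    fit <- aov(form, data = adf)
  }
  atab <- tidyAovStrata(fit, eps)

  structure(list(components = comp, effects = effMat, pooledEffects = pooled,
                 anova = atab, epsilon = eps,
                 method = if (balanced) "EMS" else "REML",
                 transform = transform, effectMode = effects,
                 design = list(n = n, blocks = b, r = r, dates = dates)),
            class = "splitPlotFit")
}

#' @export
print.splitPlotFit <- function(x, ...) {
  cat("Split-plot fit (", x$method, "): ", nrow(x$effects), " cultivars, ",
      x$design$n, " N levels, ", x$design$blocks, " blocks, ",
      length(x$design$dates), " dates\n", sep = "")
  for (d in names(x$components)) {
    vc <- x$components[[d]]
    cat(sprintf("  %s: V_C=%.4g V_CxN=%.4g V_R=%.4g reliability=%.3f\n",
                d, vc@vC, vc@vCxN, vc@vR, reliability(vc)))
  }
  if (is.finite(x$epsilon))
    cat(sprintf("  Greenhouse-Geisser epsilon = %.3f\n", x$epsilon))
  invisible(x)
}

# Expected-mean-squares (method-of-moments) variance components for one
# date of a balanced split-plot: cultivar and cultivar-by-N random
# (unrestricted convention), N and block fixed.
emsComponents <- function(y, cv, nl, blk, r) {
  c_ <- nlevels(droplevels(cv)); n <- nlevels(droplevels(nl))
  b <- nlevels(droplevels(blk))
  gm <- mean(y)
  cvM <- tapply(y, cv, mean); nlM <- tapply(y, nl, mean)
  blkM <- tapply(y, blk, mean)
  ssC <- n * b * sum((cvM - gm)^2)
  ssT <- sum((y - gm)^2)
  if (n > 1) {
    cnM <- tapply(y, list(cv, nl), mean)
    ssCN <- b * sum((sweep(sweep(cnM, 1, cvM), 2, nlM) + gm)^2)
    nbM <- tapply(y, list(nl, blk), mean)
    ssNB <- c_ * sum((sweep(sweep(nbM, 1, nlM), 2, blkM) + gm)^2)
    ssN <- c_ * b * sum((nlM - gm)^2)
    ssB <- c_ * n * sum((blkM - gm)^2)
    ssE <- ssT - ssN - ssB - ssNB - ssC - ssCN
    dfE <- n * (b - 1) * (c_ - 1)
    msE <- if (dfE > 0) ssE / dfE else 0
    msC <- ssC / (c_ - 1)
    msCN <- ssCN / ((c_ - 1) * (n - 1))
    vR <- msE
    vCN <- (msCN - msE) / b
    vC <- (msC - msCN) / (n * b)
  } else {
    if (b == 1) stop("inestimable components: single N level without blocks")
    ssB <- sum((blkM - gm)^2) * c_
    ssE <- ssT - ssC - ssB
    dfE <- (b - 1) * (c_ - 1)
    msE <- if (dfE > 0) ssE / dfE else 0
    vR <- msE
    vCN <- 0
    vC <- (ssC / (c_ - 1) - msE) / b
  }
  varianceComponents(vC, vCN, max(vR, 0), n = n, r = r)
}

# REML fallback for unbalanced data.
remlComponents <- function(y, cv, nl, blk, r) {
  df <- data.frame(y = y, cv = cv, nl = nl, blk = blk)
  n <- nlevels(droplevels(nl))
  form <- if (n > 1) y ~ nl + blk + (1 | cv) + (1 | cv:nl)
          else y ~ blk + (1 | cv)
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(form, data = df,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  get1 <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) v[1] else 0
  }
  varianceComponents(get1("cv"), get1("cv:nl"), get1("Residual"), n = n, r = r)
}

# Flatten summary(aov-with-Error) into one table; apply the
# Greenhouse-Geisser correction to time-stratum terms.
tidyAovStrata <- function(fit, eps) {
  sm <- summary(fit)
  out <- list()
  for (stratum in names(sm)) {
    tabs <- sm[[stratum]]
    tab <- if (is.list(tabs)) tabs[[1]] else tabs
    tab <- as.data.frame(tab)
    term <- trimws(rownames(tab))
    keep <- term != "Residuals"
    if (!any(keep)) next
    res <- tab[!keep, , drop = FALSE]
    dfden <- if (nrow(res)) res$Df[1] else NA
    d <- data.frame(term = term[keep], stratum = sub("^Error: ", "", stratum),
                    df = tab$Df[keep], ss = tab$`Sum Sq`[keep],
                    ms = tab$`Mean Sq`[keep],
                    F = if ("F value" %in% names(tab)) tab$`F value`[keep] else NA,
                    dfDen = dfden,
                    p = if ("Pr(>F)" %in% names(tab)) tab$`Pr(>F)`[keep] else NA)
    isTime <- grepl("tp", d$term) & sub("^Error: ", "", stratum) == "Within"
    d$pGG <- d$p
    if (!is.na(eps) && any(isTime) && !anyNA(d$F[isTime]))
      d$pGG[isTime] <- pf(d$F[isTime], eps * d$df[isTime],
                          eps * d$dfDen[isTime], lower.tail = FALSE)
    out[[length(out) + 1L]] <- d
  }
  do.call(rbind, out)
}
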