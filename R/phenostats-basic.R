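#' Square-root transform for PSRI
#'
#' PSRI takes small negative values early in the season; a constant of 10 is
#' added before the square root so the response handed to the linear model
#' is strictly positive: \code{sqrt(x + 10)}.
#'
#' @param x PSRI value(s), each > -10.
#' @return \code{sqrt(x + 10)}.
#' @examples
#' transformPsri(-1)  # 3
#' transformPsri(6)   # 4
#' @export
transformPsri <- function(x) {
  if (any(x <= -10, na.rm = TRUE))
    stop("transformPsri is defined only for x > -10")
  sqrt(x + 10)
}

#' Relative senescence rate
#'
#' Percent change in PSRI between two imaging dates:
#' \deqn{RSR = 100 (PSRI_{later} - PSRI_{earlier}) / PSRI_{earlier}.}
#' Positive values indicate progressing senescence. Computed on the raw
#' (untransformed) PSRI scale.
#'
#' @param earlier,later PSRI at the earlier and later date (vectorised).
#' @return Percent change; carries attribute \code{signInverted} marking
#'   entries with a negative earlier value (interpretation flips there).
#' @examples
#' relativeSenescenceRate(2, 3)  # 50
#' @export
relativeSenescenceRate <- function(earlier, later) {
  if (any(earlier == 0, na.rm = TRUE))
    stop("relative senescence rate undefined: PSRI at earlier date is zero")
  inv <- !is.na(earlier) & earlier < 0
  if (any(inv))
    warning("negative PSRI at earlier date: sign interpretation inverted for ",
            sum(inv), " value(s)")
  out <- 100 * (later - earlier) / earlier
  attr(out, "signInverted") <- inv
  out
}

#' Nitrogen use efficiency
#'
#' Grain yield per unit soil-available nitrogen (both per square metre), a
#' dimensionless ratio.
#'
#' @param grainYield grain yield in g/m^2 (>= 0).
#' @param soilAvailableN soil-available N in g N/m^2 (> 0).
#' @return NUE ratio(s).
#' @examples
#' nue(500, 10)  # 50
#' @export
nue <- function(grainYield, soilAvailableN) {
  if (any(soilAvailableN <= 0, na.rm = TRUE))
    stop("soil available nitrogen must be positive")
  grainYield / soilAvailableN
}

#' Harvest index
#'
#' Grain yield divided by total above-ground biomass (grain + straw).
#'
#' @param grainYield,strawYield yields in the same unit; their sum must be
#'   positive.
#' @return Fraction in [0, 1].
#' @examples
#' harvestIndex(4, 6)  # 0.4
#' @export
harvestIndex <- function(grainYield, strawYield) {
  if (any(grainYield + strawYield <= 0, na.rm = TRUE))
    stop("total above-ground biomass must be positive")
  grainYield / (grainYield + strawYield)
}

#' Greenhouse-Geisser epsilon
#'
#' Sphericity-correction factor for repeated-measures F tests, computed from
#' the covariance matrix of the repeated measurements. Under compound
#' symmetry epsilon is 1; it is bounded below by 1/(t - 1) for t time
#' points. Adjusted degrees of freedom are epsilon times the nominal ones.
#'
#' @param x either a t x t covariance matrix of the repeated measures, or an
#'   n x t data matrix (rows = subjects) from which the covariance is taken.
#' @return Epsilon in [1/(t-1), 1], with attribute \code{t}.
#' @export
greenhouseGeisserEpsilon <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) == ncol(x) && isSymmetric(unname(x), tol = 1e-8)) {
    S <- x
  } else {
    if (nrow(x) <= ncol(x))
      stop("rank error: need more subjects than time points to estimate the covariance")
    S <- stats::cov(x)
  }
  t <- ncol(S)
  if (t < 2) stop("need at least two time points")
  if (t == 2) {
    eps <- 1
  } else {
    md <- mean(diag(S)); m <- mean(S); ri <- rowMeans(S)
    num <- t^2 * (md - m)^2
    den <- (t - 1) * (sum(S^2) - 2 * t * sum(ri^2) + t^2 * m^2)
    if (den <= 0) stop("rank error: degenerate covariance matrix")
    eps <- num / den
  }
  eps <- min(max(eps, 1 / (t - 1)), 1)
  attr(eps, "t") <- t
  eps
}

#' Pairwise trait correlations by group
#'
#' Pearson correlations between all pairs of traits, within each group and
#' pooled, with p-values and Fisher-z 95\% confidence intervals. Because NUE
#' is yield divided by a within-group constant, NUE and grain yield share
#' identical correlations with every other trait inside a group.
#'
#' @param traits data.frame of numeric trait columns (rows = cultivars).
#' @param group optional factor splitting rows into groups (e.g. N levels).
#' @return data.frame with columns \code{group} ("pooled" included),
#'   \code{trait1}, \code{trait2}, \code{r}, \code{p}, \code{lo}, \code{hi},
#'   \code{n}.
#' @export
traitCorrelations <- function(traits, group = NULL) {
  traits <- as.data.frame(traits)
  num <- vapply(traits, is.numeric, logical(1))
  traits <- traits[num]
  grp <- if (is.null(group)) factor(rep("pooled", nrow(traits)))
         else factor(group)
  levs <- levels(grp)
  if (!is.null(group)) levs <- c(levs, "pooled")
  out <- list()
  combs <- utils::combn(names(traits), 2)
  for (g in levs) {
    rows <- if (g == "pooled") rep(TRUE, nrow(traits)) else grp == g
    for (cc in seq_len(ncol(combs))) {
      a <- traits[[combs[1, cc]]][rows]; b <- traits[[combs[2, cc]]][rows]
      ok <- complete.cases(a, b); a <- a[ok]; b <- b[ok]
      if (length(a) < 3) next
      if (sd(a) == 0 || sd(b) == 0) {
        warning("undefined correlation (constant trait) for pair ",
                combs[1, cc], "/", combs[2, cc], " in group ", g)
        next
      }
      ct <- suppressWarnings(cor.test(a, b))
      ci <- if (!is.null(ct$conf.int)) ct$conf.int else c(NA, NA)
      out[[length(out) + 1L]] <- data.frame(
        group = g, trait1 = combs[1, cc], trait2 = combs[2, cc],
        r = unname(ct$estimate), p = ct$p.value,
        lo = ci[1], hi = ci[2], n = length(a))
    }
  }
  do.call(rbind, out)
}

#' Select the stay-green cultivar set
#'
#' Stay-green cultivars are the best-performing 25\% of the panel by pooled
#' genotype effect on PSRI over the central senescence phase. Because low
#' PSRI indicates delayed senescence, the set is the \code{fraction} of
#' cultivars with the lowest pooled effects; the set size is
#' \code{ceiling(fraction * N)}. Ties at the boundary are broken by stable
#' cultivar-id order and flagged.
#'
#' @param effects named numeric vector of pooled genotype effects (names =
#'   cultivar ids).
#' @param fraction fraction of the panel to flag (default 0.25).
#' @return list with \code{set} (character vector of flagged cultivars),
#'   \code{size}, and \code{tie} (TRUE if the boundary was tied).
#' @export
stayGreenSet <- function(effects, fraction = 0.25) {
  stopIfNot(length(effects) >= 4, "need at least 4 cultivars")
  stopIfNot(!is.null(names(effects)), "effects must be named by cultivar")
  k <- ceiling(fraction * length(effects))
  ord <- order(effects, names(effects))
  set <- names(effects)[ord[seq_len(k)]]
  tie <- k < length(effects) && effects[ord[k]] == effects[ord[k + 1]]
  list(set = set, size = k, tie = tie)
}
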