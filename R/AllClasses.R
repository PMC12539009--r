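#' @import methods
#' @importFrom stats aov anova aggregate coef complete.cases cor cor.test
#'   kmeans kruskal.test lm median na.omit p.adjust pchisq pf plogis pnorm
#'   prcomp pt qnorm quantile resid rnorm runif rbinom sd setNames t.test
#'   TukeyHSD var wilcox.test residuals as.formula model.matrix pairwise.wilcox.test
#' @importFrom utils head read.csv write.csv
NULL

#' GenotypePanel: cultivar-by-marker allele doses with a marker map
#'
#' Container for a diversity-panel SNP matrix. Rows are cultivars, columns
#' are markers; entries are allele doses 0/1/2 (dose of the alternative,
#' i.e. non-reference, allele) with \code{NA} for missing calls. A marker
#' map (chromosome, 1-based physical position, reference/alternative bases)
#' and optional per-cultivar metadata (decade of release, origin group)
#' travel with the matrix.
#'
#' @slot doses numeric matrix, cultivars x markers, values in \{0,1,2,NA\}.
#' @slot map data.frame with columns \code{marker}, \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}; one row per marker, in column order of
#'   \code{doses}.
#' @slot info data.frame of per-cultivar metadata (may have zero columns),
#'   one row per cultivar in row order of \code{doses}.
#' @exportClass GenotypePanel
setClass("GenotypePanel",
  representation(doses = "matrix", map = "data.frame", info = "data.frame"))

setValidity("GenotypePanel", function(object) {
  msg <- character()
  d <- object@doses
  if (!is.numeric(d)) msg <- c(msg, "doses must be a numeric matrix")
  if (is.null(rownames(d)) || is.null(colnames(d)))
    msg <- c(msg, "doses must have cultivar rownames and marker colnames")
  bad <- d[!is.na(d)]
  if (length(bad) && (min(bad) < 0 || max(bad) > 2))
    msg <- c(msg, "doses must lie in [0, 2] (0/1/2 calls; fractional only after imputation) or be NA")
  if (nrow(object@map) != ncol(d))
    msg <- c(msg, "map must have one row per marker")
  else {
    need <- c("marker", "chrom", "pos", "ref", "alt")
    if (!all(need %in% names(object@map)))
      msg <- c(msg, paste("map needs columns:", paste(need, collapse = ", ")))
    else {
      if (!identical(as.character(object@map$marker), colnames(d)))
        msg <- c(msg, "map$marker must match colnames(doses) in order")
      if (any(object@map$pos < 1, na.rm = TRUE))
        msg <- c(msg, "positions must be 1-based and positive")
    }
  }
  if (nrow(object@info) != nrow(d))
    msg <- c(msg, "info must have one row per cultivar")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypePanel
#'
#' @param doses cultivar x marker dose matrix (0/1/2/NA) with dimnames.
#' @param map marker map data.frame (\code{marker}, \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}); reordered to match \code{colnames(doses)}.
#' @param info optional per-cultivar metadata data.frame with rownames or a
#'   \code{cultivar} column.
#' @return A \linkS4class{GenotypePanel}.
#' @export
GenotypePanel <- function(doses, map, info = NULL) {
  doses <- as.matrix(doses)
  storage.mode(doses) <- "double"
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  map$marker <- as.character(map$marker)
  idx <- match(colnames(doses), map$marker)
  if (anyNA(idx) || anyDuplicated(colnames(doses)))
    stop("map must carry exactly one row per marker in doses")
  map <- map[idx, , drop = FALSE]
  rownames(map) <- map$marker
  if (is.null(info)) {
    info <- data.frame(row.names = rownames(doses))
  } else {
    info <- as.data.frame(info, stringsAsFactors = FALSE)
    if ("cultivar" %in% names(info)) rownames(info) <- info$cultivar
    info <- info[rownames(doses), , drop = FALSE]
    rownames(info) <- rownames(doses)
  }
  new("GenotypePanel", doses = doses, map = map, info = info)
}

#' @rdname GenotypePanel
#' @param x,object a \code{GenotypePanel}.
#' @export
setGeneric("doses", function(x) standardGeneric("doses"))
#' @rdname GenotypePanel
#' @export
setMethod("doses", "GenotypePanel", function(x) x@doses)

#' @rdname GenotypePanel
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))
#' @rdname GenotypePanel
#' @export
setMethod("markerMap", "GenotypePanel", function(x) x@map)

#' @rdname GenotypePanel
#' @export
setGeneric("cultivarInfo", function(x) standardGeneric("cultivarInfo"))
#' @rdname GenotypePanel
#' @export
setMethod("cultivarInfo", "GenotypePanel", function(x) x@info)

#' @rdname GenotypePanel
#' @export
setGeneric("cultivars", function(x) standardGeneric("cultivars"))
#' @rdname GenotypePanel
#' @export
setMethod("cultivars", "GenotypePanel", function(x) rownames(x@doses))

#' @rdname GenotypePanel
#' @export
setGeneric("markers", function(x) standardGeneric("markers"))
#' @rdname GenotypePanel
#' @export
setMethod("markers", "GenotypePanel", function(x) colnames(x@doses))

#' Per-marker minor allele frequency
#'
#' Allele frequency of the rarer allele, computed from observed doses
#' (missing calls ignored). Always in [0, 0.5].
#' @param x a \linkS4class{GenotypePanel}.
#' @return Named numeric vector, one entry per marker.
#' @export
setGeneric("maf", function(x) standardGeneric("maf"))
#' @rdname maf
#' @export
setMethod("maf", "GenotypePanel", function(x) {
  p <- colMeans(x@doses, na.rm = TRUE) / 2
  pmin(p, 1 - p)
})

#' Per-marker missing-call rate
#' @param x a \linkS4class{GenotypePanel}.
#' @return Named numeric vector in [0, 1].
#' @export
setGeneric("missingRate", function(x) standardGeneric("missingRate"))
#' @rdname missingRate
#' @export
setMethod("missingRate", "GenotypePanel", function(x) colMeans(is.na(x@doses)))

#' @rdname GenotypePanel
#' @param i,j cultivar / marker indices.
#' @param drop ignored; subsetting always returns a \code{GenotypePanel}.
#' @param ... ignored.
#' @export
setMethod("[", "GenotypePanel", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@doses))
  if (missing(j)) j <- seq_len(ncol(x@doses))
  new("GenotypePanel",
      doses = x@doses[i, j, drop = FALSE],
      map = x@map[j, , drop = FALSE],
      info = x@info[i, , drop = FALSE])
})

setMethod("show", "GenotypePanel", function(object) {
  d <- object@doses
  cat("GenotypePanel:", nrow(d), "cultivars x", ncol(d), "markers\n")
  cat("  chromosomes:", paste(unique(object@map$chrom), collapse = ", "), "\n")
  mr <- mean(is.na(d))
  cat(sprintf("  missing calls: %.2f%%; median MAF: %.3f\n",
              100 * mr, median(maf(object))))
  if (ncol(object@info))
    cat("  cultivar metadata:", paste(names(object@info), collapse = ", "), "\n")
})

#' VarianceComponents: split-plot variance decomposition for genotype means
#'
#' Holds the cultivar (\code{vC}), cultivar-by-nitrogen interaction
#' (\code{vCxN}) and residual (\code{vR}) variance components of the
#' split-plot model, together with the design constants needed for the
#' reliability of genotype means: \code{n}, the number of nitrogen levels,
#' and \code{r}, the number of replications (blocks x replicates per block).
#'
#' @slot vC,vCxN,vR non-negative variances.
#' @slot n,r design counts.
#' @slot truncated character vector naming components whose method-of-moments
#'   solution was negative and was truncated to zero.
#' @exportClass VarianceComponents
setClass("VarianceComponents",
  representation(vC = "numeric", vCxN = "numeric", vR = "numeric",
                 n = "numeric", r = "numeric", truncated = "character"))

setValidity("VarianceComponents", function(object) {
  msg <- character()
  if (any(c(object@vC, object@vCxN, object@vR) < 0))
    msg <- c(msg, "variance components must be >= 0")
  if (object@n < 1 || object@r < 1) msg <- c(msg, "need n >= 1 and r >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a VarianceComponents object
#'
#' Negative inputs for the variance components are truncated to zero and
#' recorded in the \code{truncated} slot (standard practice for
#' method-of-moments solutions).
#'
#' @param vC,vCxN,vR cultivar, cultivar-by-N and residual variances.
#' @param n number of nitrogen levels.
#' @param r number of replications (blocks x replicates per block).
#' @return A \linkS4class{VarianceComponents}.
#' @export
varianceComponents <- function(vC, vCxN, vR, n, r) {
  comp <- c(vC = vC, vCxN = vCxN, vR = vR)
  trunc <- names(comp)[comp < 0]
  comp <- pmax(comp, 0)
  new("VarianceComponents", vC = unname(comp["vC"]), vCxN = unname(comp["vCxN"]),
      vR = unname(comp["vR"]), n = as.numeric(n), r = as.numeric(r),
      truncated = trunc)
}

setMethod("show", "VarianceComponents", function(object) {
  cat(sprintf("VarianceComponents: V_C = %.4g, V_CxN = %.4g, V_R = %.4g (n = %g, r = %g)\n",
              object@vC, object@vCxN, object@vR, object@n, object@r))
  if (length(object@truncated))
    cat("  truncated at zero:", paste(object@truncated, collapse = ", "), "\n")
  cat(sprintf("  reliability of genotype means: %.4f\n", reliability(object)))
})

#' Reliability of genotype means
#'
#' Ratio of the cultivar variance to the variance of a genotype mean under
#' the trial design: \deqn{V_C / (V_C + V_{CxN}/n + V_R/(r n))} where n is
#' the number of nitrogen levels and r the number of replications. High
#' reliability means cultivar means mostly reflect genetic differences.
#'
#' @param x a \linkS4class{VarianceComponents}.
#' @return Reliability in [0, 1].
#' @export
setGeneric("reliability", function(x) standardGeneric("reliability"))

#' @rdname reliability
#' @export
setMethod("reliability", "VarianceComponents", function(x) {
  denom <- x@vC + x@vCxN / x@n + x@vR / (x@r * x@n)
  if (denom <= 0)
    stop("undefined reliability: all variance components are zero")
  x@vC / denom
})

#' HaplotypeCall: clustered haplotypes around a focal marker
#'
#' Result of LD-block collection and k-means clustering around a focal GWAS
#' marker. Cultivars are assigned to clusters; clusters are (optionally)
#' named by the focal-marker allele they carry (M/m + base + variant suffix)
#' and flagged favourable where their mean genotype effect on PSRI is
#' significantly below the locus mean.
#'
#' @slot focal focal marker id.
#' @slot members member marker ids (the LD block, including the focal marker).
#' @slot spanMbp numeric length-2, min and max physical position of the block
#'   in Mbp.
#' @slot assignments named integer vector, cluster index per cultivar.
#' @slot codes per-cluster haplotype codes (\code{NA} until named).
#' @slot sizes per-cluster member counts.
#' @slot favourable per-cluster logical (\code{NA} until tested).
#' @slot majorAllele,minorAllele focal-marker bases.
#' @slot flags character notes (ties, grammar overflow, ...).
#' @exportClass HaplotypeCall
setClass("HaplotypeCall",
  representation(focal = "character", members = "character",
                 spanMbp = "numeric", assignments = "integer",
                 codes = "character", sizes = "integer",
                 favourable = "logical", majorAllele = "character",
                 minorAllele = "character", flags = "character"))

setValidity("HaplotypeCall", function(object) {
  msg <- character()
  k <- length(object@sizes)
  if (length(object@codes) != k || length(object@favourable) != k)
    msg <- c(msg, "codes, sizes and favourable must have one entry per cluster")
  if (!all(object@assignments %in% seq_len(k)))
    msg <- c(msg, "assignments must index the clusters")
  if (any(duplicated(object@codes[!is.na(object@codes)])))
    msg <- c(msg, "cluster codes must be unique within a focal locus")
  if (length(msg)) msg else TRUE
})

setMethod("show", "HaplotypeCall", function(object) {
  cat("HaplotypeCall at", object@focal, "-", length(object@members),
      "member markers, span", sprintf("%.2f-%.2f Mbp\n",
                                      object@spanMbp[1], object@spanMbp[2]))
  lab <- ifelse(is.na(object@codes), paste0("cluster", seq_along(object@sizes)),
                object@codes)
  fav <- ifelse(is.na(object@favourable), "",
                ifelse(object@favourable, " [favourable]", ""))
  for (i in seq_along(object@sizes))
    cat(sprintf("  %s: %d cultivars%s\n", lab[i], object@sizes[i], fav[i]))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})

#' @rdname HaplotypeCall
#' @param x a \code{HaplotypeCall}.
#' @return \code{clusterAssignments} returns the named integer vector of
#'   per-cultivar cluster indices; \code{haplotypeCodes} the per-cluster codes.
#' @export
setGeneric("clusterAssignments", function(x) standardGeneric("clusterAssignments"))
#' @rdname HaplotypeCall
#' @export
setMethod("clusterAssignments", "HaplotypeCall", function(x) x@assignments)

#' @rdname HaplotypeCall
#' @export
setGeneric("haplotypeCodes", function(x) standardGeneric("haplotypeCodes"))
#' @rdname HaplotypeCall
#' @export
setMethod("haplotypeCodes", "HaplotypeCall", function(x) x@codes)
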