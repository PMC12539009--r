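#' Read / write genotypes as HapMap-style CSV
#'
#' The HapMap-style layout has one row per marker with columns \code{rs},
#' \code{chrom}, \code{pos}, \code{alleles} ("ref/alt"), followed by one
#' column per cultivar holding the alt-allele dose (0/1/2, empty or NA for
#' missing).
#'
#' @param path CSV file path.
#' @return \code{readHapMap} returns a \linkS4class{GenotypePanel};
#'   \code{writeHapMap} returns \code{path} invisibly.
#' @export
readHapMap <- function(path) {
  x <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("rs", "chrom", "pos", "alleles")
  stopIfNot(all(need %in% names(x)),
            paste("HapMap CSV needs columns:", paste(need, collapse = ", ")))
  al <- strsplit(as.character(x$alleles), "/", fixed = TRUE)
  map <- data.frame(marker = as.character(x$rs), chrom = as.character(x$chrom),
                    pos = as.numeric(x$pos),
                    ref = vapply(al, `[`, "", 1), alt = vapply(al, `[`, "", 2),
                    stringsAsFactors = FALSE)
  cvCols <- setdiff(names(x), need)
  m <- t(as.matrix(x[cvCols]))
  storage.mode(m) <- "double"
  dimnames(m) <- list(cvCols, map$marker)
  GenotypePanel(m, map)
}

#' @rdname readHapMap
#' @param geno a \linkS4class{GenotypePanel}.
#' @export
writeHapMap <- function(geno, path) {
  map <- markerMap(geno)
  out <- data.frame(rs = map$marker, chrom = map$chrom, pos = map$pos,
                    alleles = paste(map$ref, map$alt, sep = "/"),
                    stringsAsFactors = FALSE, check.names = FALSE)
  out <- cbind(out, as.data.frame(t(doses(geno)), check.names = FALSE))
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Minimal GT-field reader: converts diploid genotype strings to alt-allele
#' doses (0/1/2; missing to NA). Requires the \pkg{vcfR} package.
#'
#' @param path VCF file path (uncompressed or bgzipped).
#' @return A \linkS4class{GenotypePanel} (cultivars = VCF samples).
#' @export
readVcfGenotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("readVcfGenotypes requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  doseOf <- function(g) {
    ifelse(is.na(g) | g %in% c(".", "./.", ".|."), NA_real_,
           vapply(strsplit(gsub("\\|", "/", g), "/"), function(a)
             sum(a != "0" & a != "."), numeric(1)))
  }
  m <- apply(gt, 2, doseOf)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, "_", fix$POS), fix$ID)
  map <- data.frame(marker = ids, chrom = fix$CHROM, pos = as.numeric(fix$POS),
                    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  m <- t(m)
  dimnames(m) <- list(colnames(gt), ids)
  GenotypePanel(m, map)
}
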