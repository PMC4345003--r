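#' @import methods
NULL

#' GenotypeData: individuals x SNPs genotype matrix with locus metadata
#'
#' Container for a biallelic genotype matrix coded as counts of the minor
#' allele (0 = major homozygote, 1 = heterozygote, 2 = minor homozygote,
#' \code{NA} = missing), together with per-SNP metadata.  Rows are
#' individuals (row names are the sample identifiers), columns are SNPs and
#' are named by SNP identifier.  SNP positions are 1-based base-pair
#' coordinates, the MAP/VCF convention.
#'
#' @slot genotypes numeric matrix, individuals x SNPs, values in
#'   \{0, 1, 2, NA\}.
#' @slot snpInfo data.frame with one row per SNP and columns \code{snpId},
#'   \code{chrom}, \code{pos}, \code{majorAllele}, \code{minorAllele}.
#'
#' @aliases GenotypeData-class
#' @export
setClass("GenotypeData",
  representation(genotypes = "matrix", snpInfo = "data.frame"))

setValidity("GenotypeData", function(object) {
  g <- object@genotypes
  si <- object@snpInfo
  msg <- character(0)
  need <- c("snpId", "chrom", "pos", "majorAllele", "minorAllele")
  if (!all(need %in% names(si)))
    return(paste("snpInfo must have columns:", paste(need, collapse = ", ")))
  if (ncol(g) != nrow(si))
    msg <- c(msg, "ncol(genotypes) must equal nrow(snpInfo)")
  if (anyDuplicated(si$snpId))
    msg <- c(msg, "duplicate SNP ids in snpInfo")
  if (any(si$pos < 1, na.rm = TRUE))
    msg <- c(msg, "SNP positions must be >= 1 (1-based coordinates)")
  if (is.null(rownames(g)) || anyDuplicated(rownames(g)))
    msg <- c(msg, "genotype matrix needs unique row names (sample ids)")
  if (!identical(colnames(g), as.character(si$snpId)))
    msg <- c(msg, "colnames(genotypes) must match snpInfo$snpId")
  vals <- g[!is.na(g)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    msg <- c(msg, "genotype values must be 0, 1, 2 or NA")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a GenotypeData object
#'
#' @param genotypes numeric matrix of minor-allele counts (individuals x
#'   SNPs) with sample ids as row names.
#' @param snpInfo data.frame with columns \code{snpId}, \code{chrom},
#'   \code{pos}, \code{majorAllele}, \code{minorAllele}.
#' @return A \linkS4class{GenotypeData} object.
#' @examples
#' g <- matrix(c(0, 1, 2, 0), 2, 2,
#'             dimnames = list(c("i1", "i2"), c("s1", "s2")))
#' si <- data.frame(snpId = c("s1", "s2"), chrom = "1", pos = c(100, 200),
#'                  majorAllele = "A", minorAllele = "G")
#' GenotypeData(g, si)
#' @export
GenotypeData <- function(genotypes, snpInfo) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "double"
  snpInfo <- as.data.frame(snpInfo, stringsAsFactors = FALSE)
  snpInfo$snpId <- as.character(snpInfo$snpId)
  snpInfo$chrom <- as.character(snpInfo$chrom)
  rownames(snpInfo) <- NULL
  if (is.null(colnames(genotypes)))
    colnames(genotypes) <- snpInfo$snpId
  new("GenotypeData", genotypes = genotypes, snpInfo = snpInfo)
}

#' ExpressionData: individuals x probes expression matrix with probe
#' annotations
#'
#' Continuous (pre-adjusted) expression values, one row per individual, one
#' column per probe.  Probe annotations use BED conventions: \code{start}
#' and \code{end} are 0-based half-open coordinates and \code{midpoint} is
#' \code{floor((start + end) / 2)}, the anchor for cis/trans window
#' classification.  \code{probeInfo} may have zero rows when annotations
#' are unavailable.
#'
#' @slot values numeric matrix, individuals x probes.
#' @slot probeInfo data.frame with columns \code{probeId}, \code{chrom},
#'   \code{start}, \code{end}, \code{midpoint} (possibly zero rows).
#'
#' @aliases ExpressionData-class
#' @export
setClass("ExpressionData",
  representation(values = "matrix", probeInfo = "data.frame"))

setValidity("ExpressionData", function(object) {
  v <- object@values
  pi <- object@probeInfo
  msg <- character(0)
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    msg <- c(msg, "expression matrix needs unique row names (sample ids)")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    msg <- c(msg, "expression matrix needs unique column names (probe ids)")
  if (nrow(pi) > 0) {
    need <- c("probeId", "chrom", "start", "end", "midpoint")
    if (!all(need %in% names(pi)))
      return(paste("probeInfo must have columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(pi$probeId))
      msg <- c(msg, "duplicate probe ids in probeInfo")
    bad <- !is.na(pi$start) & !is.na(pi$end) & pi$start >= pi$end
    if (any(bad))
      msg <- c(msg, "probe intervals must satisfy start < end")
    if (!all(pi$probeId %in% colnames(v)))
      msg <- c(msg, "probeInfo contains probes absent from the matrix")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct an ExpressionData object
#'
#' @param values numeric matrix of expression values (individuals x probes)
#'   with sample ids as row names and probe ids as column names.
#' @param probeInfo optional data.frame with columns \code{probeId},
#'   \code{chrom}, \code{start}, \code{end} (BED, 0-based half-open);
#'   \code{midpoint} is computed as \code{floor((start + end) / 2)} if
#'   absent.
#' @return An \linkS4class{ExpressionData} object.
#' @export
ExpressionData <- function(values, probeInfo = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(probeInfo)) {
    probeInfo <- data.frame(probeId = character(0), chrom = character(0),
                            start = numeric(0), end = numeric(0),
                            midpoint = numeric(0))
  } else {
    probeInfo <- as.data.frame(probeInfo, stringsAsFactors = FALSE)
    probeInfo$probeId <- as.character(probeInfo$probeId)
    probeInfo$chrom <- as.character(probeInfo$chrom)
    if (is.null(probeInfo$midpoint))
      probeInfo$midpoint <- floor((probeInfo$start + probeInfo$end) / 2)
    rownames(probeInfo) <- NULL
  }
  new("ExpressionData", values = values, probeInfo = probeInfo)
}

# ---- accessors ----

#' @describeIn GenotypeData genotype matrix accessor
#' @param object,x a GenotypeData or ExpressionData object
#' @export
setGeneric("genotypes", function(object) standardGeneric("genotypes"))

#' @rdname GenotypeData
#' @export
setMethod("genotypes", "GenotypeData", function(object) object@genotypes)

#' @describeIn GenotypeData SNP metadata accessor
#' @export
setGeneric("snpInfo", function(object) standardGeneric("snpInfo"))

#' @rdname GenotypeData
#' @export
setMethod("snpInfo", "GenotypeData", function(object) object@snpInfo)

#' @describeIn ExpressionData expression matrix accessor
#' @param object,x an ExpressionData object
#' @export
setGeneric("exprValues", function(object) standardGeneric("exprValues"))

#' @rdname ExpressionData
#' @export
setMethod("exprValues", "ExpressionData", function(object) object@values)

#' @describeIn ExpressionData probe annotation accessor
#' @export
setGeneric("probeInfo", function(object) standardGeneric("probeInfo"))

#' @rdname ExpressionData
#' @export
setMethod("probeInfo", "ExpressionData", function(object) object@probeInfo)

#' @describeIn GenotypeData sample identifiers
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' @rdname GenotypeData
#' @export
setMethod("sampleIds", "GenotypeData", function(object) rownames(object@genotypes))

#' @rdname ExpressionData
#' @export
setMethod("sampleIds", "ExpressionData", function(object) rownames(object@values))

# ---- subsetting ----

#' @rdname GenotypeData
#' @param i sample index (ids, logical or integer)
#' @param j SNP / probe index
#' @param ... ignored
#' @param drop ignored; objects are never dropped to vectors
#' @export
setMethod("[", "GenotypeData", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@genotypes))
  if (missing(j)) j <- seq_len(ncol(x@genotypes))
  g <- x@genotypes[i, j, drop = FALSE]
  si <- x@snpInfo[match(colnames(g), x@snpInfo$snpId), , drop = FALSE]
  rownames(si) <- NULL
  new("GenotypeData", genotypes = g, snpInfo = si)
})

#' @rdname ExpressionData
#' @param i sample index
#' @param j probe index
#' @param ... ignored
#' @param drop ignored
#' @export
setMethod("[", "ExpressionData", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@values))
  if (missing(j)) j <- seq_len(ncol(x@values))
  v <- x@values[i, j, drop = FALSE]
  pi <- x@probeInfo[x@probeInfo$probeId %in% colnames(v), , drop = FALSE]
  rownames(pi) <- NULL
  new("ExpressionData", values = v, probeInfo = pi)
})

# ---- show ----

setMethod("show", "GenotypeData", function(object) {
  g <- object@genotypes
  nm <- sum(is.na(g))
  cat("GenotypeData:", nrow(g), "individuals x", ncol(g), "SNPs\n")
  cat("  chromosomes:",
      paste(unique(object@snpInfo$chrom), collapse = ", "), "\n")
  cat(sprintf("  missing genotypes: %d (%.2f%%)\n", nm,
              100 * nm / max(1, length(g))))
})

setMethod("show", "ExpressionData", function(object) {
  v <- object@values
  cat("ExpressionData:", nrow(v), "individuals x", ncol(v), "probes\n")
  cat("  annotated probes:", nrow(object@probeInfo), "\n")
})
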