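#' Minor allele frequency of one SNP
#'
#' Count of the coded (minor) allele over twice the number of non-missing
#' individuals, folded to at most 0.5.
#'
#' @param genotypeColumn numeric vector of 0/1/2/NA genotypes.
#' @return the MAF, or \code{NA} if every genotype is missing.
#' @examples
#' computeMaf(c(0, 0, 1, 2))      # 3/8
#' computeMaf(c(0, 1, NA, 2))     # 3/6, missing excluded
#' @export
computeMaf <- function(genotypeColumn) {
  ok <- !is.na(genotypeColumn)
  if (!any(ok)) return(NA_real_)
  f <- sum(genotypeColumn[ok]) / (2 * sum(ok))
  min(f, 1 - f)
}

#' Hardy-Weinberg equilibrium chi-squared test
#'
#' Pearson chi-squared of the observed genotype counts against the
#' expectations n*q^2, 2npq, n*p^2 implied by the observed allele
#' frequency, on 1 degree of freedom, without continuity correction.  A
#' monomorphic SNP carries no evidence of violation and is assigned
#' chi-squared 0, p = 1.
#'
#' @param genotypeColumn numeric vector of 0/1/2/NA genotypes.
#' @return list with \code{chi2} and \code{p}.
#' @export
hweTest <- function(genotypeColumn) {
  g <- genotypeColumn[!is.na(genotypeColumn)]
  if (length(g) == 0) stop("no non-missing genotypes")
  obs <- tabulate(g + 1, nbins = 3)
  n <- sum(obs)
  p <- (2 * obs[3] + obs[2]) / (2 * n)   # coded-allele frequency
  if (p == 0 || p == 1) return(list(chi2 = 0, p = 1))
  q <- 1 - p
  expd <- n * c(q^2, 2 * p * q, p^2)
  chi2 <- sum((obs - expd)^2 / expd)
  list(chi2 = chi2,
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' SNP quality control
#'
#' Retains autosomal SNPs with MAF strictly greater than \code{cfg$mafMin},
#' missingness at most \code{cfg$missMax}, and Hardy-Weinberg p at least
#' \code{cfg$hweAlpha}.  The fate of every SNP is recorded.
#'
#' @param gd a \linkS4class{GenotypeData}.
#' @param cfg a \code{\link{pipelineConfig}} (or any list with
#'   \code{mafMin}, \code{missMax}, \code{hweAlpha}).
#' @return list with \code{genotypes} (the filtered
#'   \linkS4class{GenotypeData}) and \code{records}, a data.frame with one
#'   row per input SNP: \code{snpId}, \code{maf}, \code{missingness},
#'   \code{hweChi2}, \code{hweP}, \code{autosomal}, \code{pass}.
#' @export
filterSnps <- function(gd, cfg = pipelineConfig()) {
  g <- genotypes(gd)
  si <- snpInfo(gd)
  m <- ncol(g)
  maf <- apply(g, 2, computeMaf)
  miss <- colMeans(is.na(g))
  hw <- apply(g, 2, function(col) {
    if (all(is.na(col))) return(c(NA_real_, NA_real_))
    h <- hweTest(col)
    c(h$chi2, h$p)
  })
  auto <- isAutosome(si$chrom)
  pass <- !is.na(maf) & maf > cfg$mafMin & miss <= cfg$missMax &
    !is.na(hw[2, ]) & hw[2, ] >= cfg$hweAlpha & auto
  rec <- data.frame(snpId = si$snpId, maf = maf, missingness = miss,
                    hweChi2 = hw[1, ], hweP = hw[2, ], autosomal = auto,
                    pass = pass, row.names = NULL,
                    stringsAsFactors = FALSE)
  list(genotypes = gd[, which(pass)], records = rec)
}

#' Flag probes whose genomic interval contains a catalogued SNP
#'
#' A probe is blacklisted when any SNP position from the supplied variant
#' catalogue lies inside the probe's BED interval: a 1-based SNP position p
#' is inside [start, end) iff \code{start <= p - 1 < end}.  Probes without
#' coordinates are flagged unmappable and excluded.  With no catalogue,
#' nothing is blacklisted and a warning is raised.
#'
#' @param probeInfo probe annotation data.frame (\code{probeId},
#'   \code{chrom}, \code{start}, \code{end}).
#' @param snpCatalogue data.frame with columns \code{chrom} and \code{pos}
#'   (1-based), e.g. the \code{snpInfo} of a reference panel -- it need not
#'   be restricted to genotyped SNPs.  May be NULL.
#' @return data.frame: \code{probeId}, \code{blacklistHit},
#'   \code{unmappable}, \code{keep}.
#' @export
removeBlacklistedProbes <- function(probeInfo, snpCatalogue = NULL) {
  unmappable <- is.na(probeInfo$chrom) | is.na(probeInfo$start) |
    is.na(probeInfo$end)
  hit <- rep(FALSE, nrow(probeInfo))
  if (is.null(snpCatalogue) || nrow(snpCatalogue) == 0) {
    warning("no SNP catalogue provided; no probes blacklisted")
  } else {
    for (i in which(!unmappable)) {
      same <- normChrom(snpCatalogue$chrom) == normChrom(probeInfo$chrom[i])
      p0 <- snpCatalogue$pos[same] - 1   # SNP in 0-based coordinates
      hit[i] <- any(probeInfo$start[i] <= p0 & p0 < probeInfo$end[i])
    }
  }
  data.frame(probeId = probeInfo$probeId, blacklistHit = hit,
             unmappable = unmappable, keep = !hit & !unmappable,
             stringsAsFactors = FALSE)
}

#' Select the most variable transcripts by interquartile range
#'
#' The IQR of each probe's non-missing values (type-7 linear-interpolation
#' quartiles) ranks the probes; the top
#' \code{ceiling(topFraction * nProbes)} are selected, with ties at the
#' cutoff broken by probe id lexical order.
#'
#' @param ed an \linkS4class{ExpressionData}.
#' @param topFraction fraction of probes to keep.
#' @return data.frame: \code{probeId}, \code{iqr}, \code{selected},
#'   ordered as the input probes.
#' @export
selectVariableTranscripts <- function(ed, topFraction = 0.05) {
  v <- exprValues(ed)
  if (ncol(v) < 1) stop("no probes")
  iqr <- apply(v, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(NA_real_)
    unname(diff(stats::quantile(x, c(0.25, 0.75), type = 7)))
  })
  k <- ceiling(topFraction * ncol(v))
  ord <- order(-iqr, colnames(v))
  sel <- rep(FALSE, ncol(v))
  sel[ord[seq_len(min(k, ncol(v)))]] <- TRUE
  sel[is.na(iqr)] <- FALSE
  data.frame(probeId = colnames(v), iqr = iqr, selected = sel,
             row.names = NULL, stringsAsFactors = FALSE)
}
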