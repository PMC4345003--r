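#' Rank-transform a vector of expression values
#'
#' Non-missing values are mapped to ranks 1..m (m the non-missing count),
#' ties receiving the average of the tied rank span; missing values stay
#' missing.  The maximum rank therefore equals the number of individuals
#' with a measurement.
#'
#' @param values numeric vector.
#' @return numeric vector of ranks with NAs preserved.
#' @examples
#' rankTransform(c(3.2, 1.1, 5.0))  # 2 1 3
#' rankTransform(c(4, 4, 9))        # 1.5 1.5 3
#' @export
rankTransform <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2) stop("need at least 2 non-missing values to rank")
  out <- rep(NA_real_, length(values))
  out[ok] <- rank(values[ok], ties.method = "average")
  names(out) <- names(values)
  out
}

#' Classify a SNP as cis or trans for a probe
#'
#' cis iff the SNP lies on the probe's chromosome and within \code{window}
#' bp (inclusive) of the probe midpoint; otherwise trans (further away or
#' on a different chromosome).
#'
#' @param snpChrom,snpPos SNP chromosome and 1-based position (vectors
#'   recycle).
#' @param probeChrom,probeMidpoint probe chromosome and midpoint.
#' @param window window size in bp.
#' @return character vector, \code{"cis"} or \code{"trans"}.
#' @export
classifyCisTrans <- function(snpChrom, snpPos, probeChrom, probeMidpoint,
                             window = 1e6) {
  stopifnot(window > 0)
  cis <- normChrom(snpChrom) == normChrom(probeChrom) &
    abs(snpPos - probeMidpoint) <= window
  ifelse(cis, "cis", "trans")
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: q_(i) = min over j >= i of m p_(j) / j, with
#' monotonicity enforced.
#'
#' @param pValues numeric vector of p-values in [0, 1].
#' @return q-values in the input order.
#' @export
bhFdr <- function(pValues) {
  if (length(pValues) == 0) return(numeric(0))
  if (any(is.na(pValues)) || any(pValues < 0 | pValues > 1))
    stop("p-values must lie in [0, 1] with no NAs")
  stats::p.adjust(pValues, method = "BH")
}

#' Marginal eQTL scan with rank-transform regression
#'
#' For every selected probe and every SNP, ordinary least squares of the
#' probe's expression ranks on the additive genotype code plus covariates
#' (covariates enter on their raw scale; only the response is ranked).
#' Each test is complete-case for that (SNP, probe) pair.  Tests with fewer
#' than \code{ncov + 3} usable individuals are skipped and counted in the
#' \code{"skipped"} attribute.  Every test is labelled cis or trans and BH
#' q-values are computed separately within each class.
#'
#' @param gd a \linkS4class{GenotypeData} (post-QC).
#' @param ed an \linkS4class{ExpressionData} with probe annotations.
#' @param covariates numeric matrix (individuals x covariates, rows aligned
#'   to the cohort) or NULL.
#' @param window cis window in bp.
#' @param selectedProbes probe ids to scan; defaults to all annotated
#'   probes.
#' @return data.frame of marginal hits: \code{probeId}, \code{snpId},
#'   \code{nUsed}, \code{beta}, \code{se}, \code{t}, \code{p}, \code{q},
#'   \code{eqtlClass}.
#' @export
marginalScan <- function(gd, ed, covariates = NULL, window = 1e6,
                         selectedProbes = NULL) {
  g <- genotypes(gd)
  si <- snpInfo(gd)
  pinfo <- probeInfo(ed)
  if (nrow(pinfo) == 0) stop("expression data has no probe annotations")
  v <- exprValues(ed)
  stopifnot(identical(rownames(g), rownames(v)))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == nrow(g))
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
  }
  probes <- if (is.null(selectedProbes)) pinfo$probeId else
    intersect(selectedProbes, pinfo$probeId)
  ncov <- if (is.null(covariates)) 0 else ncol(covariates)
  rows <- vector("list", length(probes) * ncol(g))
  skipped <- 0L
  r <- 0L
  for (pb in probes) {
    pi <- pinfo[pinfo$probeId == pb, ]
    y <- rankTransform(v[, pb])
    cls <- classifyCisTrans(si$chrom, si$pos, pi$chrom, pi$midpoint, window)
    for (j in seq_len(ncol(g))) {
      gj <- g[, j]
      cc <- !is.na(y) & !is.na(gj)
      if (ncov > 0) cc <- cc & stats::complete.cases(covariates)
      n <- sum(cc)
      if (n < ncov + 3) { skipped <- skipped + 1L; next }
      X <- cbind(`(Intercept)` = 1,
                 if (ncov > 0) covariates[cc, , drop = FALSE],
                 genotype = gj[cc])
      fit <- fitOls(y[cc], X)
      tt <- olsTerm(fit, "genotype")
      if (is.na(tt$p)) { skipped <- skipped + 1L; next }
      r <- r + 1L
      rows[[r]] <- data.frame(probeId = pb, snpId = si$snpId[j],
                              nUsed = n, beta = tt$beta, se = tt$se,
                              t = tt$t, p = tt$p, eqtlClass = cls[j],
                              stringsAsFactors = FALSE)
    }
  }
  hits <- if (r > 0) do.call(rbind, rows[seq_len(r)]) else
    data.frame(probeId = character(0), snpId = character(0),
               nUsed = integer(0), beta = numeric(0), se = numeric(0),
               t = numeric(0), p = numeric(0), eqtlClass = character(0),
               stringsAsFactors = FALSE)
  hits$q <- NA_real_
  for (cl in c("cis", "trans")) {
    idx <- hits$eqtlClass == cl
    if (any(idx)) hits$q[idx] <- bhFdr(hits$p[idx])
  }
  hits <- hits[, c("probeId", "snpId", "nUsed", "beta", "se", "t", "p",
                   "q", "eqtlClass")]
  attr(hits, "skipped") <- skipped
  hits
}

#' Gate marginal eQTLs at an FDR threshold
#'
#' Retains hits with q strictly below the threshold (a hit with q exactly
#' at the threshold is removed).
#'
#' @param hits data.frame from \code{\link{marginalScan}}.
#' @param fdrThreshold the (liberal) FDR gate, default 0.5.
#' @return the gated subset, same columns.
#' @export
gateEqtls <- function(hits, fdrThreshold = 0.5) {
  out <- hits[!is.na(hits$q) & hits$q < fdrThreshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}
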