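# Tracy-Widom (beta = 1) upper-tail quantiles, the standard tabulated
# values used for testing genotype eigenvalues.
.twQuantiles <- data.frame(
  alpha = c(0.05, 0.01, 0.001),
  quantile = c(0.9793, 2.0234, 3.2724))

#' Genotype principal components analysis
#'
#' Each SNP column is mean-centred and scaled by sqrt(p(1-p)), with p the
#' observed allele frequency of the coded allele; missing entries are set
#' to 0 after centring (mean imputation on the standardized scale, used for
#' the PCA only).  The individual-by-individual covariance
#' X X' / nSNPs is eigendecomposed; scores are the unit-norm eigenvectors
#' with a deterministic sign convention (the largest-magnitude entry of
#' each component is positive).  Zero-variance columns are dropped with a
#' warning.
#'
#' @param gd a \linkS4class{GenotypeData}.
#' @return list of class \code{"GenotypePca"}: \code{eigenvalues}
#'   (descending), \code{scores} (individuals x components, unit columns),
#'   \code{nSnpsUsed}.
#' @export
genotypePca <- function(gd) {
  G <- genotypes(gd)
  if (nrow(G) < 2 || ncol(G) < 2)
    stop("need at least 2 individuals and 2 SNPs")
  pj <- colMeans(G, na.rm = TRUE) / 2
  v <- pj * (1 - pj)
  obsVar <- apply(G, 2, stats::var, na.rm = TRUE)
  keep <- !is.na(pj) & v > 0 & !is.na(obsVar) & obsVar > 0
  if (!all(keep))
    warning(sum(!keep), " zero-variance SNP column(s) dropped from PCA")
  if (sum(keep) < 2) stop("fewer than 2 usable SNP columns")
  X <- scale(G[, keep, drop = FALSE], center = 2 * pj[keep],
             scale = sqrt(v[keep]))
  X[is.na(X)] <- 0
  C <- tcrossprod(X) / ncol(X)
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  vecs <- e$vectors
  for (k in seq_len(ncol(vecs))) {
    j <- which.max(abs(vecs[, k]))
    if (vecs[j, k] < 0) vecs[, k] <- -vecs[, k]
  }
  rownames(vecs) <- rownames(G)
  colnames(vecs) <- paste0("PC", seq_len(ncol(vecs)))
  structure(list(eigenvalues = vals, scores = vecs, nSnpsUsed = sum(keep)),
            class = "GenotypePca")
}

#' @export
print.GenotypePca <- function(x, ...) {
  cat("GenotypePca:", nrow(x$scores), "individuals,", x$nSnpsUsed,
      "SNPs used\n")
  cat("  top eigenvalues:",
      paste(signif(utils::head(x$eigenvalues, 5), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Tracy-Widom significance of principal components
#'
#' Sequential test down the eigenvalue spectrum.  For the leading remaining
#' eigenvalue, the effective marker count is estimated from the eigenvalue
#' moments, n' = ((m+1) S1^2) / ((m-1) S2 - S1^2) with S1, S2 the sum and
#' sum of squares of the m remaining eigenvalues; the normalized eigenvalue
#' l = m lambda / S1 is centred and scaled by
#' mu = (sqrt(n'-1) + sqrt(m))^2 / n' and
#' sigma = ((sqrt(n'-1) + sqrt(m)) / n') (1/sqrt(n'-1) + 1/sqrt(m))^(1/3),
#' and the statistic compared against the tabulated Tracy-Widom (beta = 1)
#' quantile.  Testing stops at the first non-significant component.
#'
#' @param eigenvalues eigenvalues from \code{\link{genotypePca}}
#'   (descending).
#' @param alpha significance level; one of the tabulated 0.05, 0.01, 0.001.
#' @return list: \code{twStats} (one per tested component),
#'   \code{significant} (logical), \code{nSignificant}.
#' @export
tracyWidomTest <- function(eigenvalues, alpha = 0.05) {
  row <- which(abs(.twQuantiles$alpha - alpha) < 1e-12)
  if (length(row) != 1)
    stop("alpha must be one of the tabulated levels: ",
         paste(.twQuantiles$alpha, collapse = ", "))
  qthr <- .twQuantiles$quantile[row]
  ev <- eigenvalues[eigenvalues > 0]
  if (length(ev))
    ev <- ev[ev > max(ev) * 1e-9]   # discard numerically null dimensions
  stats <- numeric(0)
  sig <- logical(0)
  L <- length(ev)
  for (i in seq_len(L)) {
    rem <- ev[i:L]
    m <- length(rem)
    if (m < 3) break
    s1 <- sum(rem)
    s2 <- sum(rem^2)
    denom <- (m - 1) * s2 - s1^2
    if (denom <= 0) break            # spectrum flatter than Marchenko-Pastur
    neff <- (m + 1) * s1^2 / denom
    if (neff <= 1) break
    l <- m * rem[1] / s1
    sq1 <- sqrt(neff - 1)
    sq2 <- sqrt(m)
    mu <- (sq1 + sq2)^2 / neff
    sgm <- (sq1 + sq2) / neff * (1 / sq1 + 1 / sq2)^(1 / 3)
    x <- (l - mu) / sgm
    stats <- c(stats, x)
    sig <- c(sig, x > qthr)
    if (!x > qthr) break
  }
  list(twStats = stats, significant = sig, nSignificant = sum(sig))
}

#' Iterative PCA outlier removal
#'
#' Individuals whose score on any of the top \code{nComponents} components
#' exceeds \code{sdThreshold} standard deviations of that component are
#' removed, the PCA recomputed, for up to \code{nIterations} rounds (the
#' usual smartpca-style defaults: 6 SD, 5 iterations, 10 components).
#'
#' @param gd a \linkS4class{GenotypeData}.
#' @param sdThreshold outlier threshold in component standard deviations.
#' @param nIterations maximum removal rounds.
#' @param nComponents number of leading components examined.
#' @return character vector of outlier sample ids (possibly empty), with
#'   attribute \code{"iteration"} giving the round each was flagged in.
#' @export
detectOutliers <- function(gd, sdThreshold = 6, nIterations = 5,
                           nComponents = 10) {
  remaining <- sampleIds(gd)
  out <- character(0)
  iter <- integer(0)
  for (it in seq_len(nIterations)) {
    if (length(remaining) < 3)
      stop("all (or nearly all) individuals removed as outliers")
    p <- suppressWarnings(genotypePca(gd[remaining, ]))
    k <- min(nComponents, ncol(p$scores))
    flagged <- rep(FALSE, length(remaining))
    for (c in seq_len(k)) {
      s <- p$scores[, c]
      sdc <- stats::sd(s)
      if (sdc > 0) flagged <- flagged | abs(s) > sdThreshold * sdc
    }
    if (!any(flagged)) break
    out <- c(out, remaining[flagged])
    iter <- c(iter, rep(it, sum(flagged)))
    remaining <- remaining[!flagged]
  }
  if (length(out) == length(sampleIds(gd)))
    stop("all individuals removed as outliers")
  attr(out, "iteration") <- iter
  out
}
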