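# Shared fixture builders and independent oracles.

# GenotypeData from a bare matrix, default metadata.
makeGd <- function(g, chrom = NULL, pos = NULL) {
  g <- as.matrix(g)
  if (is.null(rownames(g))) rownames(g) <- sprintf("i%03d", seq_len(nrow(g)))
  if (is.null(colnames(g))) colnames(g) <- sprintf("s%03d", seq_len(ncol(g)))
  if (is.null(chrom)) chrom <- rep("1", ncol(g))
  if (is.null(pos)) pos <- seq_len(ncol(g)) * 1000
  GenotypeData(g, data.frame(snpId = colnames(g), chrom = chrom, pos = pos,
                             majorAllele = "A", minorAllele = "G",
                             stringsAsFactors = FALSE))
}

# brute-force Hardy-Weinberg chi-squared from genotype counts
hweOracle <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  p <- (2 * n2 + n1) / (2 * n)
  if (p == 0 || p == 1) return(list(chi2 = 0, p = 1))
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  chi2 <- sum((c(n0, n1, n2) - e)^2 / e)
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}

# brute-force Benjamini-Hochberg step-up
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# genotype pair with unambiguous phase: haplotypes are drawn explicitly and
# individuals that would be double-heterozygous are rejected, so the sample
# haplotype counts are known exactly
phaseKnownPair <- function(n, fA, flipFrac, seed) {
  set.seed(seed)
  h <- matrix(NA_real_, 0, 4)
  while (nrow(h) < n) {
    h1a <- rbinom(3 * n, 1, fA)
    h2a <- rbinom(3 * n, 1, fA)
    h1b <- ifelse(runif(3 * n) < flipFrac, 1 - h1a, h1a)
    h2b <- ifelse(runif(3 * n) < flipFrac, 1 - h2a, h2a)
    cand <- cbind(h1a, h2a, h1b, h2b)
    gA <- h1a + h2a
    gB <- h1b + h2b
    cand <- cand[!(gA == 1 & gB == 1), , drop = FALSE]
    h <- rbind(h, cand)
  }
  h <- h[seq_len(n), , drop = FALSE]
  hapTab <- table(factor(c(h[, 1], h[, 2]), 0:1),
                  factor(c(h[, 3], h[, 4]), 0:1)) / (2 * n)
  pA <- sum(hapTab[2, ]); pB <- sum(hapTab[, 2])
  D <- hapTab[2, 2] - pA * pB
  r2 <- if (pA %in% c(0, 1) || pB %in% c(0, 1)) NA else
    D^2 / (pA * (1 - pA) * pB * (1 - pB))
  list(gA = h[, 1] + h[, 2], gB = h[, 3] + h[, 4], r2 = unname(r2))
}
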