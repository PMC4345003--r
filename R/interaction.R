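#' Linkage-disequilibrium r-squared between two SNPs
#'
#' Default estimator: maximum-likelihood haplotype frequencies from the
#' 3x3 genotype table by EM (only the double-heterozygote cell has
#' ambiguous phase), iterated to a tolerance of 1e-10 or at most 1000
#' iterations, then r^2 = D^2 / (pA qA pB qB).  A monomorphic margin makes
#' r^2 undefined; it is returned as 0 with a warning.  The
#' \code{"composite"} method is the squared Pearson correlation of the
#' genotype codes, available for sensitivity analysis.
#'
#' @param genoA,genoB numeric 0/1/2/NA genotype vectors over the same
#'   individuals; at least 20 complete pairs are required (the EM is
#'   unstable below that).
#' @param method \code{"em"} or \code{"composite"}.
#' @param tol EM convergence tolerance on haplotype frequencies.
#' @param maxIter EM iteration cap.
#' @return r^2 in [0, 1].
#' @export
ldR2 <- function(genoA, genoB, method = c("em", "composite"),
                 tol = 1e-10, maxIter = 1000) {
  method <- match.arg(method)
  cc <- !is.na(genoA) & !is.na(genoB)
  if (sum(cc) < 20)
    stop("need at least 20 complete genotype pairs for LD estimation")
  a <- genoA[cc]
  b <- genoB[cc]
  if (method == "composite") {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning("monomorphic SNP; r2 undefined, returning 0")
      return(0)
    }
    return(stats::cor(a, b)^2)
  }
  n <- matrix(0, 3, 3)
  for (i in 0:2) for (j in 0:2) n[i + 1, j + 1] <- sum(a == i & b == j)
  N <- sum(n)
  # unambiguous haplotype counts; index 1 = major allele, 2 = minor
  h <- matrix(0, 2, 2)   # h[alleleA, alleleB]
  contrib <- function(i, j) {
    # two haplotypes of an (i, j) genotype, phase-determined unless i=j=1
    aA <- c(rep(2, i), rep(1, 2 - i))
    aB <- c(rep(2, j), rep(1, 2 - j))
    list(c(aA[1], aB[1]), c(aA[2], aB[2]))
  }
  for (i in 0:2) for (j in 0:2) {
    if (i == 1 && j == 1) next
    cnt <- n[i + 1, j + 1]
    if (cnt == 0) next
    for (hp in contrib(i, j)) h[hp[1], hp[2]] <- h[hp[1], hp[2]] + cnt
  }
  nDH <- n[2, 2]
  # initialize at linkage equilibrium from observed allele frequencies
  fA <- (2 * sum(n[3, ]) + sum(n[2, ])) / (2 * N)
  fB <- (2 * sum(n[, 3]) + sum(n[, 2])) / (2 * N)
  if (fA %in% c(0, 1) || fB %in% c(0, 1)) {
    warning("monomorphic SNP; r2 undefined, returning 0")
    return(0)
  }
  p <- c(p11 = (1 - fA) * (1 - fB), p12 = (1 - fA) * fB,
         p21 = fA * (1 - fB), p22 = fA * fB)
  for (it in seq_len(maxIter)) {
    # E: split double heterozygotes between the two phasings
    denom <- p["p22"] * p["p11"] + p["p21"] * p["p12"]
    pc <- if (denom > 0) (p["p22"] * p["p11"]) / denom else 0.5
    num <- c(h[1, 1] + nDH * pc, h[1, 2] + nDH * (1 - pc),
             h[2, 1] + nDH * (1 - pc), h[2, 2] + nDH * pc)
    pNew <- num / (2 * N)
    names(pNew) <- names(p)
    if (max(abs(pNew - p)) < tol) { p <- pNew; break }
    p <- pNew
  }
  pA <- p["p21"] + p["p22"]
  pB <- p["p12"] + p["p22"]
  denom <- pA * (1 - pA) * pB * (1 - pB)
  if (denom <= 0) {
    warning("degenerate haplotype frequencies; r2 undefined, returning 0")
    return(0)
  }
  D <- p["p22"] - pA * pB
  unname(min(1, D^2 / denom))
}

#' Enumerate cis-trans interaction candidates
#'
#' For each probe with at least one gated cis-eQTL and one gated
#' trans-eQTL, all cis x trans SNP combinations are formed (a SNP gated in
#' both classes for the same probe is never paired with itself).
#' Intra-chromosomal pairs are kept only when their LD satisfies
#' r^2 < \code{ldR2Max}; inter-chromosomal pairs are exempt from the LD
#' filter.
#'
#' @param gatedHits gated marginal hits (see \code{\link{gateEqtls}}).
#' @param gd the \linkS4class{GenotypeData} the hits came from (for LD and
#'   positions).
#' @param ldR2Max LD exclusion bound.
#' @param ldMethod estimator passed to \code{\link{ldR2}}.
#' @return data.frame of candidates: \code{probeId}, \code{snpA} (cis),
#'   \code{snpB} (trans), \code{sameChromosome}, \code{distance} (bp, NA
#'   for inter-chromosomal), \code{r2} (NA when exempt).  The number of
#'   LD-excluded pairs is in the \code{"ldExcluded"} attribute.
#' @export
enumeratePairsCisTrans <- function(gatedHits, gd, ldR2Max = 0.01,
                                   ldMethod = "em") {
  si <- snpInfo(gd)
  g <- genotypes(gd)
  cache <- new.env(parent = emptyenv())
  r2of <- function(s1, s2) {
    key <- paste(sort(c(s1, s2)), collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- ldR2(g[, s1], g[, s2], method = ldMethod)
    cache[[key]] <- val
    val
  }
  out <- list()
  excluded <- 0L
  for (pb in unique(gatedHits$probeId)) {
    hp <- gatedHits[gatedHits$probeId == pb, ]
    cis <- hp$snpId[hp$eqtlClass == "cis"]
    trans <- hp$snpId[hp$eqtlClass == "trans"]
    if (length(cis) == 0 || length(trans) == 0) next
    for (sa in cis) for (sb in trans) {
      if (sa == sb) next
      ia <- match(sa, si$snpId); ib <- match(sb, si$snpId)
      same <- normChrom(si$chrom[ia]) == normChrom(si$chrom[ib])
      dist <- if (same) abs(si$pos[ia] - si$pos[ib]) else NA_real_
      r2 <- if (same) r2of(sa, sb) else NA_real_
      if (same && r2 >= ldR2Max) { excluded <- excluded + 1L; next }
      out[[length(out) + 1L]] <- data.frame(
        probeId = pb, snpA = sa, snpB = sb, sameChromosome = same,
        distance = dist, r2 = r2, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(probeId = character(0), snpA = character(0),
               snpB = character(0), sameChromosome = logical(0),
               distance = numeric(0), r2 = numeric(0),
               stringsAsFactors = FALSE)
  attr(res, "ldExcluded") <- excluded
  res
}

#' Enumerate cis-cis interaction candidates
#'
#' All unordered pairs of gated cis-eQTLs for the same probe satisfying:
#' same chromosome, separation at most \code{maxDistance} and at least
#' \code{minDistance} (both inclusive), and LD r^2 < \code{ldR2Max}.
#'
#' @param gatedHits gated marginal hits from the 10 Mb cis definition.
#' @param gd the \linkS4class{GenotypeData} the hits came from.
#' @param maxDistance maximum pair separation in bp.
#' @param minDistance minimum pair separation in bp.
#' @param ldR2Max LD exclusion bound.
#' @param ldMethod estimator passed to \code{\link{ldR2}}.
#' @return data.frame of candidates with the same columns as
#'   \code{\link{enumeratePairsCisTrans}}.
#' @export
enumeratePairsCisCis <- function(gatedHits, gd, maxDistance = 1e7,
                                 minDistance = 1e5, ldR2Max = 0.01,
                                 ldMethod = "em") {
  si <- snpInfo(gd)
  g <- genotypes(gd)
  out <- list()
  excluded <- 0L
  for (pb in unique(gatedHits$probeId)) {
    hp <- gatedHits[gatedHits$probeId == pb, ]
    cis <- unique(hp$snpId[hp$eqtlClass == "cis"])
    if (length(cis) < 2) next
    cis <- sort(cis)
    for (u in seq_len(length(cis) - 1)) for (w in (u + 1):length(cis)) {
      sa <- cis[u]; sb <- cis[w]
      ia <- match(sa, si$snpId); ib <- match(sb, si$snpId)
      if (normChrom(si$chrom[ia]) != normChrom(si$chrom[ib])) next
      dist <- abs(si$pos[ia] - si$pos[ib])
      if (dist > maxDistance || dist < minDistance) next
      r2 <- ldR2(g[, sa], g[, sb], method = ldMethod)
      if (r2 >= ldR2Max) { excluded <- excluded + 1L; next }
      out[[length(out) + 1L]] <- data.frame(
        probeId = pb, snpA = sa, snpB = sb, sameChromosome = TRUE,
        distance = dist, r2 = r2, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(probeId = character(0), snpA = character(0),
               snpB = character(0), sameChromosome = logical(0),
               distance = numeric(0), r2 = numeric(0),
               stringsAsFactors = FALSE)
  attr(res, "ldExcluded") <- excluded
  res
}

#' Two-locus genotype cell-count filter
#'
#' Counts complete-case individuals in each of the nine (gA, gB) genotype
#' combinations; the pair passes when every cell holds at least
#' \code{minCell} individuals.
#'
#' @param genoA,genoB genotype vectors.
#' @param minCell minimum per-cell count.
#' @return list with \code{minCellObserved} and \code{pass}.
#' @export
cellCountFilter <- function(genoA, genoB, minCell = 10) {
  cc <- !is.na(genoA) & !is.na(genoB)
  tab <- table(factor(genoA[cc], levels = 0:2),
               factor(genoB[cc], levels = 0:2))
  m <- min(tab)
  list(minCellObserved = as.integer(m), pass = m >= minCell)
}

#' Product-coded two-locus interaction test
#'
#' Ordinary least squares of the expression ranks on gA + gB + gA*gB plus
#' covariates, complete-case.  The interaction is coded as the product of
#' the additive genotype codes (possible values 0, 1, 2, 4, spanning the
#' nine genotype combinations); the reported effect size is the product
#' coefficient and its two-sided t-test p-value measures interaction
#' significance.
#'
#' @param genoA,genoB genotype vectors.
#' @param exprRanks rank-transformed expression (NAs allowed).
#' @param covariates numeric matrix aligned to individuals, or NULL.
#' @return list: \code{beta3}, \code{se}, \code{t}, \code{p}, \code{nUsed},
#'   \code{skipped} (TRUE with a \code{reason} when the design is
#'   rank-deficient or too small).
#' @export
interactionTest <- function(genoA, genoB, exprRanks, covariates = NULL) {
  cc <- !is.na(genoA) & !is.na(genoB) & !is.na(exprRanks)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    cc <- cc & stats::complete.cases(covariates)
  }
  ncov <- if (is.null(covariates)) 0 else ncol(covariates)
  n <- sum(cc)
  if (n < ncov + 5)
    return(list(skipped = TRUE, reason = "too few complete cases",
                nUsed = n))
  X <- cbind(`(Intercept)` = 1,
             if (ncov > 0) covariates[cc, , drop = FALSE],
             gA = genoA[cc], gB = genoB[cc],
             gAxgB = genoA[cc] * genoB[cc])
  fit <- fitOls(exprRanks[cc], X)
  if (fit$rank < ncol(X))
    return(list(skipped = TRUE, reason = "rank-deficient design",
                nUsed = n))
  tt <- olsTerm(fit, "gAxgB")
  list(skipped = FALSE, beta3 = tt$beta, se = tt$se, t = tt$t, p = tt$p,
       nUsed = n)
}

#' Bonferroni significance threshold
#'
#' alpha divided by the number of interaction tests actually fitted in the
#' run.
#'
#' @param nTests number of tests (>= 1).
#' @param alpha familywise error rate.
#' @return the per-test threshold.
#' @examples
#' bonferroniThreshold(10349)  # 4.83e-06
#' @export
bonferroniThreshold <- function(nTests, alpha = 0.05) {
  if (nTests < 1) stop("nTests must be >= 1")
  alpha / nTests
}

#' Pairwise interaction scan
#'
#' Drives the interaction stage for one tissue/strategy run: enumerates
#' candidates according to the configured strategy, applies the nine-cell
#' count filter, fits the product-coded rank-regression interaction model
#' for every surviving pair, and computes the Bonferroni threshold over the
#' tests actually fitted (skipped rank-deficient fits are excluded from the
#' denominator and logged).
#'
#' @param gd post-QC \linkS4class{GenotypeData}.
#' @param ed \linkS4class{ExpressionData} (ranks are computed per probe).
#' @param gatedHits gated marginal hits.
#' @param covariates covariate matrix or NULL.
#' @param config a \code{\link{pipelineConfig}}.
#' @return list: \code{hits} (one row per fitted test: candidate columns
#'   plus \code{minCell}, \code{nUsed}, \code{beta3}, \code{se}, \code{t},
#'   \code{p}, \code{bonferroniThreshold}, \code{significant}),
#'   \code{candidates} (all enumerated pairs with their filter fates),
#'   \code{nTests}, \code{threshold}, \code{nSkipped}.
#' @export
interactionScan <- function(gd, ed, gatedHits, covariates = NULL,
                            config = pipelineConfig()) {
  cand <- if (config$strategy == "cis_trans")
    enumeratePairsCisTrans(gatedHits, gd, config$ldR2Max, config$ldMethod)
  else
    enumeratePairsCisCis(gatedHits, gd, config$cisWindow,
                         config$pairMinDistance, config$ldR2Max,
                         config$ldMethod)
  g <- genotypes(gd)
  v <- exprValues(ed)
  ranksOf <- new.env(parent = emptyenv())
  rows <- list()
  fate <- character(nrow(cand))
  minCells <- integer(nrow(cand))
  nSkipped <- 0L
  for (i in seq_len(nrow(cand))) {
    gA <- g[, cand$snpA[i]]
    gB <- g[, cand$snpB[i]]
    cf <- cellCountFilter(gA, gB, config$minCellCount)
    minCells[i] <- cf$minCellObserved
    if (!cf$pass) { fate[i] <- "cell_count"; next }
    pb <- cand$probeId[i]
    if (is.null(ranksOf[[pb]])) ranksOf[[pb]] <- rankTransform(v[, pb])
    it <- interactionTest(gA, gB, ranksOf[[pb]], covariates)
    if (isTRUE(it$skipped)) {
      fate[i] <- it$reason
      nSkipped <- nSkipped + 1L
      next
    }
    fate[i] <- "tested"
    rows[[length(rows) + 1L]] <- cbind(
      cand[i, , drop = FALSE],
      data.frame(minCell = cf$minCellObserved, nUsed = it$nUsed,
                 beta3 = it$beta3, se = it$se, t = it$t, p = it$p,
                 stringsAsFactors = FALSE))
  }
  cand$minCell <- minCells
  cand$fate <- fate
  hits <- if (length(rows)) do.call(rbind, rows) else NULL
  nTests <- length(rows)
  threshold <- if (nTests > 0) bonferroniThreshold(nTests, config$alpha)
               else NA_real_
  if (!is.null(hits)) {
    hits$bonferroniThreshold <- threshold
    hits$significant <- hits$p < threshold
    rownames(hits) <- NULL
  }
  list(hits = hits, candidates = cand, nTests = nTests,
       threshold = threshold, nSkipped = nSkipped)
}
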