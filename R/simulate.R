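#' Simulation configuration
#'
#' Conditions for the synthetic cohort generator.  Defaults mirror the
#' sample size the discovery analyses are designed around (500 individuals)
#' and the post-QC allele-frequency spectrum (MAF in (0.2, 0.5]).
#'
#' @param nIndividuals number of individuals.
#' @param nSnps number of SNPs, split evenly across chromosomes.
#' @param nChromosomes number of chromosomes.
#' @param chromLength chromosome length in bp; SNPs are evenly spaced.
#' @param mafRange minor-allele-frequency interval, a subset of (0, 0.5].
#' @param ldBlockSize number of consecutive SNPs per LD block.
#' @param ldRho copying probability of the first-order haplotype process
#'   within a block, in [0, 1); equals the adjacent-SNP allelic correlation
#'   when block allele frequencies are equal.
#' @param missingRate per-genotype missingness probability.
#' @param nProbes number of expression probes.
#' @param noise one of \code{"gaussian"}, \code{"lognormal"}, \code{"t3"}.
#' @param noiseScale multiplier applied to the noise draw.
#' @param nSubpops number of subpopulations (1 = unstructured).
#' @param fst Wright's fixation index for the Balding-Nichols subpopulation
#'   allele-frequency draw (used when \code{nSubpops > 1}).
#' @param seed integer seed; all generator output is reproducible from it.
#' @return A list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(nIndividuals = 500, nSnps = 100,
                             nChromosomes = 1, chromLength = 1e8,
                             mafRange = c(0.2, 0.5), ldBlockSize = 5,
                             ldRho = 0, missingRate = 0, nProbes = 10,
                             noise = c("gaussian", "lognormal", "t3"),
                             noiseScale = 1, nSubpops = 1, fst = 0,
                             seed = 1L) {
  noise <- match.arg(noise)
  if (mafRange[1] <= 0 || mafRange[2] > 0.5 || mafRange[1] > mafRange[2])
    stop("mafRange must be an interval within (0, 0.5]")
  if (ldRho < 0 || ldRho >= 1) stop("ldRho must lie in [0, 1)")
  if (missingRate < 0 || missingRate >= 1) stop("missingRate must lie in [0, 1)")
  if (nSubpops > 1 && (fst <= 0 || fst >= 1))
    stop("fst must lie in (0, 1) when nSubpops > 1")
  structure(list(nIndividuals = nIndividuals, nSnps = nSnps,
                 nChromosomes = nChromosomes, chromLength = chromLength,
                 mafRange = mafRange, ldBlockSize = ldBlockSize,
                 ldRho = ldRho, missingRate = missingRate,
                 nProbes = nProbes, noise = noise, noiseScale = noiseScale,
                 nSubpops = nSubpops, fst = fst, seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Simulate a genotype cohort
#'
#' Haplotypes are generated by a first-order copying process: within an LD
#' block each successive allele copies the previous one with probability
#' \code{ldRho} and is otherwise drawn fresh at the SNP's allele frequency;
#' a genotype is the sum of two independent haplotypes.  With
#' \code{nSubpops > 1} each subpopulation receives its own allele frequency
#' from the Balding-Nichols construction
#' Beta(p(1-F)/F, (1-p)(1-F)/F); degenerate draws (a subpopulation
#' frequency outside (0.005, 0.995)) are resampled, with an error after 100
#' attempts.  Missingness is applied uniformly at \code{missingRate}.
#' Columns are then oriented so the coded allele is the observed minor
#' allele.
#'
#' @param cfg a \code{\link{simulationConfig}}.
#' @return A \linkS4class{GenotypeData}; the subpopulation assignment is
#'   kept in the \code{"subpop"} attribute.
#' @export
simulateGenotypes <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  n <- cfg$nIndividuals
  m <- cfg$nSnps
  perChrom <- diff(round(seq(0, m, length.out = cfg$nChromosomes + 1)))
  chrom <- rep(as.character(seq_len(cfg$nChromosomes)), perChrom)
  pos <- unlist(lapply(perChrom, function(k)
    round(seq_len(k) * cfg$chromLength / (k + 1))), use.names = FALSE)
  pos <- pmax(pos, 1)
  maf <- stats::runif(m, cfg$mafRange[1], cfg$mafRange[2])

  subpop <- rep_len(seq_len(cfg$nSubpops), n)
  if (cfg$nSubpops > 1) subpop <- sample(subpop)
  freq <- matrix(rep(maf, each = cfg$nSubpops), cfg$nSubpops, m)
  if (cfg$nSubpops > 1) {
    shapeF <- (1 - cfg$fst) / cfg$fst
    for (j in seq_len(m)) {
      for (try in seq_len(100)) {
        fj <- stats::rbeta(cfg$nSubpops, maf[j] * shapeF,
                           (1 - maf[j]) * shapeF)
        if (all(fj > 0.005 & fj < 0.995)) break
        if (try == 100)
          stop("could not draw feasible subpopulation frequencies for SNP ", j)
      }
      freq[, j] <- fj
    }
  }

  blockStart <- ((seq_len(m) - 1) %% cfg$ldBlockSize == 0) |
    c(TRUE, chrom[-1] != chrom[-m])
  drawHaplotype <- function() {
    H <- matrix(0L, n, m)
    for (j in seq_len(m)) {
      fresh <- stats::runif(n) < freq[subpop, j]
      if (blockStart[j] || cfg$ldRho == 0) {
        H[, j] <- fresh
      } else {
        copy <- stats::runif(n) < cfg$ldRho
        H[, j] <- ifelse(copy, H[, j - 1], fresh)
      }
    }
    H
  }
  G <- drawHaplotype() + drawHaplotype()
  storage.mode(G) <- "double"
  if (cfg$missingRate > 0)
    G[stats::runif(n * m) < cfg$missingRate] <- NA_real_

  bases <- c("A", "C", "G", "T")
  allelePairs <- vapply(seq_len(m), function(j) sample(bases, 2),
                        character(2))
  dimnames(G) <- list(sprintf("ind%04d", seq_len(n)),
                      sprintf("snp%04d", seq_len(m)))
  si <- data.frame(snpId = colnames(G), chrom = chrom, pos = pos,
                   majorAllele = allelePairs[1, ],
                   minorAllele = allelePairs[2, ],
                   stringsAsFactors = FALSE)
  gd <- orientToMinor(GenotypeData(G, si))
  attr(gd, "subpop") <- subpop
  gd
}

#' Planted two-locus effects on expression
#'
#' One row per planted probe: expression is
#' \code{beta1 * gA + beta2 * gB + beta3 * gA * gB + noise}, with the
#' interaction coded as the product of the additive genotype codes.
#'
#' @param probeId target probe identifier.
#' @param snpA,snpB identifiers of the two causal SNPs (must differ).
#' @param beta1,beta2 main-effect sizes, expression units per allele.
#' @param beta3 interaction-effect size, expression units per product unit.
#' @return A one-row data.frame; rows may be \code{rbind}-ed.
#' @export
plantedEffect <- function(probeId, snpA, snpB, beta1 = 0, beta2 = 0,
                          beta3 = 0) {
  if (snpA == snpB) stop("snpA and snpB must differ")
  data.frame(probeId = probeId, snpA = snpA, snpB = snpB,
             beta1 = beta1, beta2 = beta2, beta3 = beta3,
             stringsAsFactors = FALSE)
}

#' Simulate expression with planted genetic effects
#'
#' Probes named in \code{effects} receive the planted two-locus signal on
#' the raw expression scale; all other probes are pure noise.  Individuals
#' missing either causal genotype of a planted probe receive a noise-only
#' value and are recorded in the \code{"missingCovariateCases"} attribute
#' (complete-case handling is the scan's job, not the generator's).
#'
#' @param gd a \linkS4class{GenotypeData}.
#' @param effects data.frame of \code{\link{plantedEffect}} rows (or NULL).
#' @param nProbes total number of probes.
#' @param noise noise family: \code{"gaussian"}, \code{"lognormal"}
#'   (log-sd 1) or \code{"t3"} (Student t, 3 df).
#' @param noiseScale noise multiplier.
#' @param probeInfo optional probe annotations; probe ids default to
#'   \code{probe01, probe02, ...} when absent.
#' @param seed integer seed.
#' @return An \linkS4class{ExpressionData}.
#' @export
simulateExpression <- function(gd, effects = NULL, nProbes = 10,
                               noise = c("gaussian", "lognormal", "t3"),
                               noiseScale = 1, probeInfo = NULL, seed = 1L) {
  noise <- match.arg(noise)
  set.seed(seed)
  n <- nrow(genotypes(gd))
  probeIds <- if (!is.null(probeInfo)) as.character(probeInfo$probeId)
              else sprintf("probe%02d", seq_len(nProbes))
  nProbes <- length(probeIds)
  rnoise <- switch(noise,
    gaussian = function(k) stats::rnorm(k) * noiseScale,
    lognormal = function(k) stats::rlnorm(k, 0, 1) * noiseScale,
    t3 = function(k) stats::rt(k, df = 3) * noiseScale)
  E <- matrix(rnoise(n * nProbes), n, nProbes,
              dimnames = list(sampleIds(gd), probeIds))
  missCases <- data.frame(probeId = character(0), individual = character(0),
                          stringsAsFactors = FALSE)
  if (!is.null(effects) && nrow(effects)) {
    g <- genotypes(gd)
    for (k in seq_len(nrow(effects))) {
      ef <- effects[k, ]
      if (!all(c(ef$snpA, ef$snpB) %in% colnames(g)))
        stop("unknown SNP id in planted effect: ",
             paste(setdiff(c(ef$snpA, ef$snpB), colnames(g)), collapse = ", "))
      if (!ef$probeId %in% probeIds)
        stop("unknown probe id in planted effect: ", ef$probeId)
      gA <- g[, ef$snpA]
      gB <- g[, ef$snpB]
      signal <- ef$beta1 * gA + ef$beta2 * gB + ef$beta3 * gA * gB
      miss <- is.na(signal)
      signal[miss] <- 0
      E[, ef$probeId] <- E[, ef$probeId] + signal
      if (any(miss))
        missCases <- rbind(missCases,
          data.frame(probeId = ef$probeId,
                     individual = sampleIds(gd)[miss],
                     stringsAsFactors = FALSE))
    }
  }
  ed <- ExpressionData(E, probeInfo)
  attr(ed, "missingCovariateCases") <- missCases
  ed
}

#' Interaction effect size for a target variance share
#'
#' Solves for the product-term coefficient beta3 such that the interaction
#' accounts for a given share of the phenotypic variance (the population
#' analogue of the difference in adjusted R^2 between the full and
#' main-effects models), assuming Hardy-Weinberg genotype frequencies and
#' independence of the two loci.  Closed form: with \code{v} the residual
#' variance of the product term after projection on the two main effects,
#' the equation \code{beta3^2 v = share * var(y)} is quadratic in beta3 and
#' the positive root is returned.
#'
#' @param mafA,mafB minor allele frequencies of the two loci.
#' @param beta1,beta2 main-effect sizes on the raw expression scale.
#' @param sigma noise standard deviation (raw scale).
#' @param share target interaction variance share, in (0, 1).
#' @return beta3 (positive).
#' @export
interactionEffectForShare <- function(mafA, mafB, beta1 = 0.5, beta2 = 0.5,
                                      sigma = 1, share = 0.05) {
  stopifnot(share > 0, share < 1)
  momg <- function(f) {
    mu <- 2 * f
    v <- 2 * f * (1 - f)
    c(mu = mu, v = v, m2 = v + mu^2)
  }
  a <- momg(mafA); b <- momg(mafB)
  varW <- a["m2"] * b["m2"] - (a["mu"] * b["mu"])^2
  covA <- a["v"] * b["mu"]   # cov(gA, gA*gB)
  covB <- b["v"] * a["mu"]
  vres <- varW - b["mu"]^2 * a["v"] - a["mu"]^2 * b["v"]
  # beta3^2 * vres = share * (b1^2 vA + b2^2 vB + beta3^2 varW
  #                           + 2 b1 beta3 covA + 2 b2 beta3 covB + sigma^2)
  qa <- unname(vres - share * varW)
  qb <- unname(-share * 2 * (beta1 * covA + beta2 * covB))
  qc <- unname(-share * (beta1^2 * a["v"] + beta2^2 * b["v"] + sigma^2))
  if (qa <= 0) stop("target share infeasible for these allele frequencies")
  unname((-qb + sqrt(qb^2 - 4 * qa * qc)) / (2 * qa))
}

#' Calibrate the interaction effect to a rank-scale variance share
#'
#' The discovery models are fitted on expression ranks, and ranking
#' attenuates a raw-scale interaction: a product term planted at a given
#' raw variance share explains roughly half that share after the rank
#' transform.  This calibrator finds, by bisection on a large simulated
#' reference population, the beta3 whose incremental R-squared on the
#' ranked response (full versus main-effects model) equals
#' \code{targetShare}.  The closed-form raw-scale solution of
#' \code{\link{interactionEffectForShare}} seeds the bracket.
#'
#' @param mafA,mafB minor allele frequencies of the two loci.
#' @param beta1,beta2 raw-scale main-effect sizes.
#' @param noise noise family (\code{"gaussian"}, \code{"lognormal"},
#'   \code{"t3"}).
#' @param noiseScale noise multiplier.
#' @param targetShare target rank-scale interaction variance share.
#' @param nCalib reference population size for the bisection.
#' @param seed integer seed for the reference draw.
#' @return beta3 (positive).
#' @export
calibrateInteractionShare <- function(mafA, mafB, beta1 = 0.5, beta2 = 0.5,
                                      noise = "gaussian", noiseScale = 1,
                                      targetShare = 0.05, nCalib = 20000,
                                      seed = 1L) {
  set.seed(seed)
  gA <- stats::rbinom(nCalib, 2, mafA)
  gB <- stats::rbinom(nCalib, 2, mafB)
  eps <- switch(noise,
    gaussian = stats::rnorm(nCalib) * noiseScale,
    lognormal = stats::rlnorm(nCalib, 0, 1) * noiseScale,
    t3 = stats::rt(nCalib, df = 3) * noiseScale)
  qx0 <- qr(cbind(1, gA, gB))
  qx1 <- qr(cbind(1, gA, gB, gA * gB))
  shareAt <- function(b3) {
    r <- rank(beta1 * gA + beta2 * gB + b3 * gA * gB + eps)
    rss0 <- sum(qr.resid(qx0, r)^2)
    rss1 <- sum(qr.resid(qx1, r)^2)
    (rss0 - rss1) / sum((r - mean(r))^2)
  }
  lo <- 0
  hi <- interactionEffectForShare(mafA, mafB, beta1, beta2, noiseScale,
                                  targetShare)
  # the rank-scale share saturates as beta3 grows (ranks are bounded), so
  # an unreachable target must fail rather than expand forever
  expansions <- 0
  while (shareAt(hi) < targetShare) {
    hi <- hi * 2
    expansions <- expansions + 1
    if (expansions > 20)
      stop("target rank-scale share ", targetShare,
           " exceeds the attainable maximum (about ",
           signif(shareAt(hi), 2), ") for these conditions")
  }
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    if (shareAt(mid) < targetShare) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulate Hi-C pairs and regulatory tracks around a cohort
#'
#' Causal (epistatic) SNP pairs receive a Hi-C fragment pair -- each
#' fragment start within \code{window} bp of its SNP -- with probability
#' \code{enrichmentFold * backgroundRate}; background SNP pairs receive one
#' with probability \code{backgroundRate}; additional fragment pairs are
#' placed uniformly on the genome.  Promoter and enhancer tracks are built
#' the same way at the single-SNP level: a causal SNP is covered by an
#' interval with probability \code{enrichmentFold * backgroundRate}, any
#' other SNP with probability \code{backgroundRate}.
#'
#' @param snpInfo SNP metadata data.frame (\code{snpId}, \code{chrom},
#'   \code{pos}).
#' @param causalPairs data.frame with columns \code{snpA}, \code{snpB}
#'   (may have zero rows).
#' @param backgroundPairs data.frame with columns \code{snpA}, \code{snpB}.
#' @param enrichmentFold fold enrichment of causal pairs/SNPs (>= 1).
#' @param backgroundRate baseline mapping probability;
#'   \code{enrichmentFold * backgroundRate} must not exceed 1.
#' @param window bp tolerance between a SNP and a fragment start.
#' @param nRandomFragments uniformly placed decoy fragment pairs.
#' @param chromLength genome coordinate upper bound for decoys.
#' @param seed integer seed.
#' @return list with elements \code{hic} (data.frame: chromA, startA,
#'   chromB, startB), \code{promoters} and \code{enhancers} (GRanges).
#' @export
simulateAnnotations <- function(snpInfo, causalPairs, backgroundPairs,
                                enrichmentFold = 1, backgroundRate = 0.1,
                                window = 5000, nRandomFragments = 20,
                                chromLength = 1e8, seed = 1L) {
  if (enrichmentFold < 1) stop("enrichmentFold must be >= 1")
  if (enrichmentFold * backgroundRate > 1)
    stop("enrichmentFold * backgroundRate exceeds 1")
  set.seed(seed)
  lookup <- function(id) {
    i <- match(id, snpInfo$snpId)
    if (any(is.na(i))) stop("unknown SNP id: ", id[is.na(i)][1])
    snpInfo[i, , drop = FALSE]
  }
  fragNear <- function(pairs, rate) {
    if (is.null(pairs) || nrow(pairs) == 0) return(NULL)
    hit <- stats::runif(nrow(pairs)) < rate
    if (!any(hit)) return(NULL)
    A <- lookup(pairs$snpA[hit]); B <- lookup(pairs$snpB[hit])
    data.frame(chromA = A$chrom,
               startA = pmax(1, A$pos + sample(-window:window, sum(hit),
                                               replace = TRUE)),
               chromB = B$chrom,
               startB = pmax(1, B$pos + sample(-window:window, sum(hit),
                                               replace = TRUE)),
               stringsAsFactors = FALSE)
  }
  chroms <- unique(snpInfo$chrom)
  decoys <- data.frame(
    chromA = sample(chroms, nRandomFragments, replace = TRUE),
    startA = sample.int(chromLength, nRandomFragments, replace = TRUE),
    chromB = sample(chroms, nRandomFragments, replace = TRUE),
    startB = sample.int(chromLength, nRandomFragments, replace = TRUE),
    stringsAsFactors = FALSE)
  hic <- rbind(fragNear(causalPairs, enrichmentFold * backgroundRate),
               fragNear(backgroundPairs, backgroundRate),
               decoys)
  rownames(hic) <- NULL

  causalSnps <- unique(c(causalPairs$snpA, causalPairs$snpB))
  track <- function() {
    rate <- ifelse(snpInfo$snpId %in% causalSnps,
                   enrichmentFold * backgroundRate, backgroundRate)
    hit <- stats::runif(nrow(snpInfo)) < rate
    if (!any(hit)) return(GenomicRanges::GRanges())
    s <- snpInfo[hit, , drop = FALSE]
    GenomicRanges::GRanges(s$chrom,
                           IRanges::IRanges(pmax(1, s$pos - 500),
                                            s$pos + 500))
  }
  list(hic = hic, promoters = track(), enhancers = track())
}

#' Simulate a complete epistasis study
#'
#' One seeded call produces a cohort with a planted cis-trans interacting
#' pair, sized for end-to-end pipeline runs: 500 individuals, two
#' chromosomes (a 4 Mb gene-dense region carrying the target probe and a
#' second chromosome supplying trans SNPs), and an interaction effect
#' calibrated by \code{\link{calibrateInteractionShare}} so that the
#' product term accounts for the requested share of the rank-scale
#' phenotypic variance.  The planted SNPs are assigned common minor alleles
#' (MAF about 0.45-0.5) so that the nine-cell sample-size constraint is
#' attainable at this cohort size.
#'
#' @param seed integer seed.
#' @param nIndividuals cohort size.
#' @param share target interaction variance share.
#' @param beta1,beta2 raw-scale main-effect sizes.
#' @param noise noise family for expression.
#' @param noiseScale noise multiplier.
#' @param nullInteraction if TRUE the pair is planted with beta3 = 0
#'   (main effects only).
#' @return list with \code{genotypes}, \code{expression}, \code{truth}
#'   (probeId, snpA, snpB, beta3) and the \code{config} used.
#' @export
simulateEpistasisStudy <- function(seed = 1L, nIndividuals = 500,
                                   share = 0.05, beta1 = 0.5, beta2 = 0.5,
                                   noise = "gaussian", noiseScale = 1,
                                   nullInteraction = FALSE) {
  cfg <- simulationConfig(nIndividuals = nIndividuals, nSnps = 40,
                          nChromosomes = 2, chromLength = 4e6,
                          mafRange = c(0.4, 0.5), ldBlockSize = 5,
                          ldRho = 0.2, missingRate = 0.01,
                          nProbes = 10, noise = noise,
                          noiseScale = noiseScale, seed = seed)
  gd <- simulateGenotypes(cfg)
  si <- snpInfo(gd)

  # probe in the middle of chromosome 1; nearest chrom-1 SNP is the cis
  # partner, a chromosome-2 SNP the trans partner
  mid <- cfg$chromLength / 2
  probes <- data.frame(
    probeId = sprintf("probe%02d", 1:10),
    chrom = rep(c("1", "2"), each = 5),
    start = rep(round(seq(0.3, 0.7, length.out = 5) * cfg$chromLength),
                times = 2),
    end = rep(round(seq(0.3, 0.7, length.out = 5) * cfg$chromLength),
              times = 2) + 60,
    stringsAsFactors = FALSE)
  probes$start[1] <- mid - 30; probes$end[1] <- mid + 30

  onChr1 <- which(si$chrom == "1")
  snpA <- si$snpId[onChr1[which.min(abs(si$pos[onChr1] - mid))]]
  onChr2 <- which(si$chrom == "2")
  snpB <- si$snpId[onChr2[ceiling(length(onChr2) / 2)]]

  # make the causal pair common so every two-locus cell is populated
  g <- genotypes(gd)
  set.seed(seed + 7L)
  for (s in c(snpA, snpB)) {
    f <- stats::runif(1, 0.45, 0.5)
    keepNa <- is.na(g[, s])
    g[, s] <- stats::rbinom(nrow(g), 2, f)
    g[keepNa, s] <- NA
  }
  gd <- orientToMinor(GenotypeData(g, si))

  beta3 <- if (nullInteraction) 0 else
    calibrateInteractionShare(mean(g[, snpA], na.rm = TRUE) / 2,
                              mean(g[, snpB], na.rm = TRUE) / 2,
                              beta1, beta2, noise, noiseScale, share,
                              seed = seed + 13L)
  eff <- plantedEffect("probe01", snpA, snpB, beta1, beta2, beta3)
  ed <- simulateExpression(gd, eff, noise = noise, noiseScale = noiseScale,
                           probeInfo = probes, seed = seed + 1L)
  list(genotypes = gd, expression = ed,
       truth = list(probeId = "probe01", snpA = snpA, snpB = snpB,
                    beta3 = beta3),
       config = cfg)
}
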