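test_that("LD r2 handles perfect, absent and degenerate disequilibrium", {
  set.seed(1)
  g <- rbinom(200, 2, 0.4)
  expect_equal(ldR2(g, g), 1, tolerance = 1e-9)

  hits <- vapply(1:100, function(s) {
    set.seed(s)
    ldR2(rbinom(500, 2, 0.3), rbinom(500, 2, 0.3)) < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.98)

  expect_warning(r0 <- ldR2(rep(0, 30), rbinom(30, 2, 0.5)), "monomorphic")
  expect_equal(r0, 0)
  expect_error(ldR2(rbinom(10, 2, 0.5), rbinom(10, 2, 0.5)), "at least 20")
  expect_equal(ldR2(g, 2 - g, method = "composite"), 1, tolerance = 1e-12)
})

test_that("EM r2 is symmetric and equals haplotype counting when phase is unambiguous", {
  for (s in 1:20) {
    pk <- phaseKnownPair(120, runif(1, 0.3, 0.6), runif(1, 0.05, 0.5), s)
    if (is.na(pk$r2)) next
    em <- ldR2(pk$gA, pk$gB)
    expect_equal(em, pk$r2, tolerance = 1e-8)
    expect_equal(em, ldR2(pk$gB, pk$gA), tolerance = 1e-12)
  }
  set.seed(99)
  a <- rbinom(300, 2, 0.35); b <- rbinom(300, 2, 0.45)
  expect_equal(ldR2(a, b), ldR2(b, a), tolerance = 1e-12)
})

test_that("cis-trans enumeration forms the cis x trans product with LD exemptions", {
  set.seed(3)
  n <- 1000   # large n keeps sampling r2 of independent SNPs below 0.01
  g <- matrix(rbinom(n * 6, 2, 0.4), n, 6)
  g[, 6] <- g[, 5]   # snp f duplicates snp e: r2 = 1
  colnames(g) <- letters[1:6]
  gd <- makeGd(g, chrom = c("1", "1", "2", "2", "1", "1"),
               pos = c(1e6, 2e6, 1e6, 2e6, 8e6, 9e6))
  gated <- data.frame(probeId = "pr",
                      snpId = c("a", "b", "c", "d", "e", "f"),
                      eqtlClass = c("cis", "cis", "trans", "trans", "trans",
                                    "trans"),
                      stringsAsFactors = FALSE)
  cand <- enumeratePairsCisTrans(gated, gd)
  # 2 cis x 4 trans = 8; intra-chromosomal (a,e) (a,f) (b,e) (b,f) need LD:
  # independent simulated SNPs pass, so all 8 survive
  expect_equal(nrow(cand), 8)
  expect_true(all(is.na(cand$r2[!cand$sameChromosome])))
  expect_true(all(!is.na(cand$r2[cand$sameChromosome])))

  # put a cis SNP in perfect LD with a trans SNP on the same chromosome
  g2 <- g; g2[, 5] <- g2[, 1]
  gd2 <- makeGd(g2, chrom = c("1", "1", "2", "2", "1", "1"),
                pos = c(1e6, 2e6, 1e6, 2e6, 8e6, 9e6))
  cand2 <- enumeratePairsCisTrans(gated, gd2)
  expect_false(any(cand2$snpA == "a" & cand2$snpB == "e"))
  expect_equal(attr(cand2, "ldExcluded"), 1L)

  # a SNP gated in both classes is never paired with itself
  gatedSelf <- rbind(gated,
                     data.frame(probeId = "pr", snpId = "a",
                                eqtlClass = "trans"))
  candSelf <- enumeratePairsCisTrans(gatedSelf, gd)
  expect_false(any(candSelf$snpA == candSelf$snpB))
})

test_that("cis-cis enumeration applies both distance bounds inclusively", {
  set.seed(4)
  n <- 1000
  g <- matrix(rbinom(n * 5, 2, 0.4), n, 5)
  colnames(g) <- letters[1:5]
  gd <- makeGd(g, chrom = "1",
               pos = c(1e6, 1e6 + 5e4, 1e6 + 1e5, 1e6 + 4e6, 1e6 + 1.2e7))
  gated <- data.frame(probeId = "pr", snpId = letters[1:5],
                      eqtlClass = "cis", stringsAsFactors = FALSE)
  cand <- enumeratePairsCisCis(gated, gd)
  key <- paste(cand$snpA, cand$snpB)
  expect_false("a b" %in% key)            # 50 kb apart: too close
  expect_true("a c" %in% key)             # exactly 100 kb: retained
  expect_false("a e" %in% key)            # 11 Mb or more: too far
  expect_true("d e" %in% key)             # 8 Mb apart

  # four mutually eligible cis SNPs give C(4,2) = 6 unordered pairs
  set.seed(14)
  g4 <- matrix(rbinom(n * 4, 2, 0.4), n, 4)
  colnames(g4) <- letters[1:4]
  gd4 <- makeGd(g4, chrom = "1", pos = c(1e6, 1.2e6, 1.4e6, 1.6e6))
  gated4 <- data.frame(probeId = "pr", snpId = letters[1:4],
                       eqtlClass = "cis", stringsAsFactors = FALSE)
  expect_equal(nrow(enumeratePairsCisCis(gated4, gd4)), 6)
})

test_that("the nine-cell filter counts complete cases and LD depletes the double-minor cell", {
  gA <- rep(0:2, each = 30)
  gB <- rep(rep(0:2, times = 3), each = 10)
  expect_true(cellCountFilter(gA, gB, 10)$pass)
  gB2 <- gB; gB2[1] <- NA
  cf <- cellCountFilter(gA, gB2, 10)
  expect_equal(cf$minCellObserved, 9L)
  expect_false(cf$pass)

  fails <- vapply(1:20, function(s) {
    gd <- simulateGenotypes(simulationConfig(nIndividuals = 500, nSnps = 2,
                                             mafRange = c(0.28, 0.32),
                                             ldRho = 0.9, ldBlockSize = 2,
                                             seed = s))
    g <- genotypes(gd)
    !cellCountFilter(g[, 1], g[, 2], 10)$pass
  }, logical(1))
  expect_gte(mean(fails), 0.5)
})

test_that("the interaction model uses product coding and recovers coefficients exactly", {
  set.seed(5)
  n <- 300
  gA <- rbinom(n, 2, 0.5)
  gB <- rbinom(n, 2, 0.5)
  y <- 1 + 2 * gA + 3 * gB + 0.7 * gA * gB
  it <- interactionTest(gA, gB, y)
  expect_equal(it$beta3, 0.7, tolerance = 1e-8)
  expect_equal(max(abs(range(gA * gB))), 4)   # coding spans 0..4
  expect_true(all(unique(gA * gB) %in% c(0, 1, 2, 4)))

  yMain <- 1 + 2 * gA + 3 * gB
  expect_lt(abs(interactionTest(gA, gB, yMain)$beta3), 1e-8)

  # aliased design is skipped, not mis-tested
  sk <- interactionTest(gA, gA, y)
  expect_true(sk$skipped)
})

test_that("the interaction p-value is invariant under monotone transforms of expression", {
  set.seed(6)
  n <- 400
  gA <- rbinom(n, 2, 0.45)
  gB <- rbinom(n, 2, 0.45)
  y <- 0.4 * gA + 0.4 * gB + 0.5 * gA * gB + rnorm(n)
  r1 <- interactionTest(gA, gB, rankTransform(y))
  r2 <- interactionTest(gA, gB, rankTransform(exp(y)))
  r3 <- interactionTest(gA, gB, rankTransform(y^3 + 5 * y))
  expect_identical(r1$p, r2$p)
  expect_identical(r1$p, r3$p)
})

test_that("interaction type-I error stays near nominal with skewed noise", {
  ps <- vapply(1:500, function(s) {
    set.seed(s)
    n <- 500
    gA <- rbinom(n, 2, 0.45)
    gB <- rbinom(n, 2, 0.45)
    y <- 0.5 * gA + 0.5 * gB + rlnorm(n, 0, 1)
    interactionTest(gA, gB, rankTransform(y))$p
  }, numeric(1))
  rate <- mean(ps < 0.05)
  expect_gt(rate, 0.05 - 1.96 * sqrt(0.05 * 0.95 / 500))
  expect_lt(rate, 0.05 + 1.96 * sqrt(0.05 * 0.95 / 500))
})

test_that("Bonferroni thresholds divide alpha by the fitted test count", {
  expect_equal(bonferroniThreshold(1, 0.05), 0.05)
  expect_error(bonferroniThreshold(0), ">= 1")
  expect_equal(signif(bonferroniThreshold(10349, 0.05), 3), 4.83e-6)
  expect_equal(signif(bonferroniThreshold(14226, 0.05), 3), 3.51e-6)
})

test_that("the surviving pair set does not depend on filter order", {
  st <- simulateEpistasisStudy(seed = 9)
  gd <- st$genotypes
  g <- genotypes(gd)
  si <- snpInfo(gd)
  cfg <- pipelineConfig("cis_cis")
  gated <- data.frame(probeId = "pr",
                      snpId = si$snpId[si$chrom == "1"],
                      eqtlClass = "cis", stringsAsFactors = FALSE)

  # independent predicate computation over all unordered pairs
  ids <- sort(gated$snpId)
  pairs <- t(combn(ids, 2))
  pred <- apply(pairs, 1, function(pr) {
    ia <- match(pr[1], si$snpId); ib <- match(pr[2], si$snpId)
    d <- abs(si$pos[ia] - si$pos[ib])
    okDist <- d >= cfg$pairMinDistance && d <= cfg$cisWindow
    okLd <- ldR2(g[, pr[1]], g[, pr[2]]) < cfg$ldR2Max
    okCell <- cellCountFilter(g[, pr[1]], g[, pr[2]], cfg$minCellCount)$pass
    c(okDist, okLd, okCell)
  })
  # intersection is order-free by construction; the pipeline's staged
  # filtering must reach the same surviving set
  keep <- pred[1, ] & pred[2, ] & pred[3, ]
  cand <- enumeratePairsCisCis(gated, gd, cfg$cisWindow,
                               cfg$pairMinDistance, cfg$ldR2Max)
  surv <- vapply(seq_len(nrow(cand)), function(i)
    cellCountFilter(g[, cand$snpA[i]], g[, cand$snpB[i]],
                    cfg$minCellCount)$pass, logical(1))
  got <- sort(paste(cand$snpA[surv], cand$snpB[surv]))
  want <- sort(paste(pairs[keep, 1], pairs[keep, 2]))
  expect_identical(got, want)
})

test_that("interactionScan fits every surviving pair and flags against Bonferroni", {
  st <- simulateEpistasisStudy(seed = 2)
  res <- runPipeline(st$genotypes, st$expression,
                     pipelineConfig("cis_trans", seed = 2))
  sc <- res$interactions
  expect_equal(sc$nTests, nrow(sc$hits))
  expect_equal(sc$threshold, 0.05 / sc$nTests)
  expect_identical(sc$hits$significant, sc$hits$p < sc$threshold)
  expect_true(all(sc$hits$minCell >= 10))
  expect_true(all(sc$candidates$fate %in%
                    c("tested", "cell_count", "too few complete cases",
                      "rank-deficient design")))
})
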