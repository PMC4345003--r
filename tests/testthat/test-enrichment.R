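test_that("pair-to-Hi-C mapping is inclusive at 5 kb and requires one SNP per locus", {
  hic <- data.frame(chromA = "6", startA = 100000,
                    chromB = "6", startB = 900000,
                    stringsAsFactors = FALSE)
  s1 <- list(chrom = "6", pos = 105000)   # exactly +5 kb of locus A
  s2 <- list(chrom = "6", pos = 895000)   # exactly -5 kb of locus B
  expect_true(mapPairToHic(s1, s2, hic))
  expect_false(mapPairToHic(list(chrom = "6", pos = 105001), s2, hic))

  # both SNPs near the same locus is not a mapping
  bothA <- list(chrom = "6", pos = 99000)
  expect_false(mapPairToHic(s1, bothA, hic))

  expect_false(mapPairToHic(s1, s2, hic[0, ]))

  # symmetric in the SNPs and in the Hi-C loci
  expect_true(mapPairToHic(s2, s1, hic))
  swapped <- data.frame(chromA = "6", startA = 900000,
                        chromB = "6", startB = 100000,
                        stringsAsFactors = FALSE)
  expect_true(mapPairToHic(s1, s2, swapped))
})

test_that("SNP-to-interval mapping honours the BED half-open convention", {
  d <- withr::local_tempdir()
  bp <- file.path(d, "t.bed")
  writeLines("chr6\t100\t200\tprom", bp)
  track <- readIntervals(bp)
  expect_true(mapSnpToIntervals("6", 150, track))
  expect_true(mapSnpToIntervals("6", 200, track))    # 0-based 199, inside
  expect_false(mapSnpToIntervals("6", 100, track))   # 0-based 99, outside
  expect_false(mapSnpToIntervals("6", 201, track))
  expect_false(mapSnpToIntervals("7", 150, track))
  expect_false(mapSnpToIntervals("6", 150, GenomicRanges::GRanges()))
})

test_that("2x2 enrichment reproduces its closed form and degenerate cases", {
  r <- enrichment2x2(10, 10, 10, 10)
  expect_equal(r$oddsRatio, 1)
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)

  # zero cell: Haldane-Anscombe for the odds ratio only
  rz <- enrichment2x2(5, 0, 10, 20)
  expect_equal(rz$oddsRatio, (5.5 * 20.5) / (0.5 * 10.5))
  expect_equal(rz$chi2, 35 * (5 * 20 - 0)^2 / (5 * 30 * 15 * 20))

  # integer-typed counts from nrow()/sum() must not overflow on large tables
  big <- enrichment2x2(118L, 203L, 13450L, 112423L)
  ref <- suppressWarnings(chisq.test(matrix(c(118, 13450, 203, 112423), 2),
                                     correct = FALSE))
  expect_equal(big$chi2, unname(ref$statistic), tolerance = 1e-10)

  expect_error(enrichment2x2(0, 0, 5, 5), "row totals")
  expect_error(enrichment2x2(-1, 2, 3, 4), "nonnegative")
  # zero column margin carries no information
  r0 <- enrichment2x2(0, 10, 0, 20)
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p, 1)
})

test_that("2x2 chi-squared and p agree with chisq.test over an exhaustive grid", {
  for (a in 0:7) for (b in 0:7) for (c in 0:7) for (d in 0:7) {
    if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) next
    got <- enrichment2x2(a, b, c, d)
    ref <- suppressWarnings(
      chisq.test(matrix(c(a, c, b, d), 2), correct = FALSE))
    expect_equal(got$chi2, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("the sweep Bonferroni-corrects across the comparison family with set semantics", {
  d <- withr::local_tempdir()
  bp <- file.path(d, "t.bed")
  writeLines(c("1\t1000\t2000\tprom"), bp)
  track <- readIntervals(bp)

  epi <- data.frame(snpId = c("a", "a", "b"), chrom = "1",
                    pos = c(1500, 1500, 5000), stringsAsFactors = FALSE)
  bg <- data.frame(snpId = letters[3:12], chrom = "1",
                   pos = c(1600, rep(9000, 9)), stringsAsFactors = FALSE)
  sw <- enrichmentSweep(epi, bg, list(prom = track))
  # SNP "a" counted once: a = 1 of 2 epistatic; background 1 of 10
  expect_equal(sw$a, 1); expect_equal(sw$b, 1)
  expect_equal(sw$c, 1); expect_equal(sw$d, 9)
  expect_equal(sw$correctedAlpha, 0.05)

  sw21 <- enrichmentSweep(epi, bg, list(prom = track), nComparisons = 21)
  expect_equal(signif(sw21$correctedAlpha, 2), 2.4e-3)

  # identical mapping rates: no enrichment
  epi2 <- data.frame(chrom = "1", pos = c(rep(1500, 5), rep(9000, 5)))
  bg2 <- data.frame(chrom = "1", pos = c(rep(1500, 10), rep(9000, 10)))
  sw2 <- enrichmentSweep(epi2, bg2, list(prom = track))
  expect_equal(sw2$oddsRatio, 1)
  expect_false(sw2$significant)
})

test_that("hicEnrichment builds the significant-vs-tested table symmetrically", {
  gd <- makeGd(matrix(rbinom(40 * 4, 2, 0.4), 40, 4),
               chrom = c("1", "1", "2", "2"),
               pos = c(1e6, 2e6, 1e6, 2e6))
  si <- snpInfo(gd)
  hits <- data.frame(snpA = si$snpId[c(1, 1, 2)],
                     snpB = si$snpId[c(3, 4, 4)],
                     significant = c(TRUE, FALSE, FALSE),
                     stringsAsFactors = FALSE)
  hic <- data.frame(chromA = "1", startA = 1e6 + 2000,
                    chromB = "2", startB = 1e6 - 2000,
                    stringsAsFactors = FALSE)
  res <- hicEnrichment(hits, gd, hic)
  expect_equal(attr(res, "mapped"), c(TRUE, FALSE, FALSE))
  expect_equal(res$a, 1)   # significant & mapped
  expect_equal(res$d, 2)   # tested non-significant, unmapped
})

test_that("annotation fixtures reproduce the dialled enrichment fold", {
  gd <- simulateGenotypes(simulationConfig(nIndividuals = 30, nSnps = 200,
                                           nChromosomes = 4, seed = 4))
  si <- snpInfo(gd)
  set.seed(9)
  allp <- t(combn(si$snpId, 2))
  idx <- sample(nrow(allp), 1100)
  causal <- data.frame(snpA = allp[idx[1:100], 1],
                       snpB = allp[idx[1:100], 2],
                       stringsAsFactors = FALSE)
  bg <- data.frame(snpA = allp[idx[101:1100], 1],
                   snpB = allp[idx[101:1100], 2],
                   stringsAsFactors = FALSE)
  loc <- function(id) {
    i <- match(id, si$snpId)
    list(chrom = si$chrom[i], pos = si$pos[i])
  }
  orOf <- function(fold, s) {
    ann <- simulateAnnotations(si, causal, bg, enrichmentFold = fold,
                               backgroundRate = 0.15, seed = s)
    mp <- function(p) sum(vapply(seq_len(nrow(p)), function(i)
      mapPairToHic(loc(p$snpA[i]), loc(p$snpB[i]), ann$hic), logical(1)))
    a <- mp(causal); c_ <- mp(bg)
    enrichment2x2(a, nrow(causal) - a, c_, nrow(bg) - c_)$oddsRatio
  }
  null <- vapply(1:40, function(s) orOf(1, s), numeric(1))
  expect_lt(abs(mean(log(null))), 0.2)   # mean log-OR compatible with OR 1

  strong <- vapply(1:8, function(s) orOf(5, s), numeric(1))
  expect_gt(min(strong), 2)

  # no causal pairs: every fragment is background or decoy
  ann0 <- simulateAnnotations(si, causal[0, ], bg, enrichmentFold = 3,
                              backgroundRate = 0.1, seed = 1,
                              nRandomFragments = 5)
  expect_lte(nrow(ann0$hic), nrow(bg) + 5)
  expect_error(simulateAnnotations(si, causal, bg, enrichmentFold = 20,
                                   backgroundRate = 0.1), "exceeds 1")
  expect_error(simulateAnnotations(si, causal, bg, enrichmentFold = 0.5),
               ">= 1")
})
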