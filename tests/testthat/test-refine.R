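test_that("redundant interactions collapse by LD and interaction sign", {
  set.seed(1)
  n <- 80
  c1 <- rbinom(n, 2, 0.4)
  t1 <- rbinom(n, 2, 0.4)
  p1 <- rbinom(n, 2, 0.4)
  p2 <- rbinom(n, 2, 0.4)
  g <- cbind(c1 = c1, c2 = c1, c3 = c1, t1 = t1, p1 = p1, p2 = p2)
  gd <- makeGd(g)

  # three cis SNPs in complete LD sharing one trans partner, same sign
  hits <- data.frame(probeId = "pr", snpA = c("c1", "c2", "c3"),
                     snpB = "t1", beta3 = c(2, 1.5, 1.8),
                     stringsAsFactors = FALSE)
  grp <- groupRedundant(hits, gd)
  expect_equal(length(unique(grp$groupId)), 1)

  # an opposite-sign member splits off
  hits2 <- hits
  hits2$beta3[2] <- -1
  grp2 <- groupRedundant(hits2, gd)
  expect_equal(length(unique(grp2$groupId)), 2)
  expect_equal(grp2$groupId[1], grp2$groupId[3])

  # fully independent pairs stay singletons
  hits3 <- data.frame(probeId = "pr", snpA = c("c1", "p1"),
                      snpB = c("t1", "p2"), beta3 = c(1, 1),
                      stringsAsFactors = FALSE)
  grp3 <- groupRedundant(hits3, gd)
  expect_equal(length(unique(grp3$groupId)), 2)

  # a partition: every hit gets exactly one group id
  for (g_ in list(grp, grp2, grp3))
    expect_true(all(!is.na(g_$groupId)) && nrow(g_) == nrow(g_))
})

test_that("stepwise AIC keeps a strong planted interaction and suppresses noise terms", {
  res <- vapply(1:15, function(s) {
    st <- simulateEpistasisStudy(seed = s, share = 0.05)
    g <- genotypes(st$genotypes)
    v <- exprValues(st$expression)
    mains <- g[, c(st$truth$snpA, st$truth$snpB, "snp0002", "snp0021")]
    colnames(mains) <- c("A", "B", "C", "D")
    kept <- stepwiseAic(rankTransform(v[, "probe01"]), mains,
                        list(iAB = c("A", "B"), iCD = c("C", "D")))
    c(planted = "iAB" %in% kept, spurious = "iCD" %in% kept,
      hierarchyOk = !("iAB" %in% kept) ||
        all(c("A", "B") %in% kept))
  }, logical(3))
  expect_gte(mean(res["planted", ]), 0.9)
  expect_lte(mean(res["spurious", ]), 0.35)
  expect_true(all(res["hierarchyOk", ]))
})

test_that("stepwise AIC rarely retains interactions under a pure-noise response", {
  none <- vapply(1:100, function(s) {
    set.seed(s)
    n <- 500
    mains <- cbind(mA = rbinom(n, 2, 0.45), mB = rbinom(n, 2, 0.45))
    y <- rank(rnorm(n))
    !("iAB" %in% stepwiseAic(y, mains, list(iAB = c("mA", "mB"))))
  }, logical(1))
  # the AIC retention probability of a 1-df noise term is P(chi2 > 2) = 0.157
  expect_gte(mean(none), 0.8)
})

test_that("stepwise AIC never ends above the full model and resolves aliased terms", {
  set.seed(7)
  n <- 300
  mains <- cbind(A = rbinom(n, 2, 0.45), B = rbinom(n, 2, 0.45))
  y <- rank(0.4 * mains[, "A"] + 0.8 * mains[, "A"] * mains[, "B"] + rnorm(n))
  ints <- list(i1 = c("A", "B"), i2 = c("A", "B"))   # identical products
  kept <- stepwiseAic(y, mains, ints)
  expect_equal(sum(c("i1", "i2") %in% kept), 1)
  expect_equal(attr(kept, "aliased"), "i2")
  trace <- attr(kept, "trace")
  expect_lte(attr(kept, "aic"), trace[1] + 1e-9)
  expect_true(all(diff(trace) < 0))
})

test_that("model comparison matches lm/logLik and flags saturated fits", {
  set.seed(8)
  n <- 250
  gA <- rbinom(n, 2, 0.45)
  gB <- rbinom(n, 2, 0.45)
  cov <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "pc1"))
  y <- rankTransform(0.5 * gA + 0.3 * gB + 0.6 * gA * gB + rnorm(n))
  cm <- compareModels(y, gA, gB, cov)
  fitM <- lm(y ~ cov + gA + gB)
  fitF <- lm(y ~ cov + gA + gB + I(gA * gB))
  expect_equal(cm$adjR2Main, summary(fitM)$adj.r.squared, tolerance = 1e-8)
  expect_equal(cm$adjR2Full, summary(fitF)$adj.r.squared, tolerance = 1e-8)
  expect_equal(cm$lrtStat, as.numeric(2 * (logLik(fitF) - logLik(fitM))),
               tolerance = 1e-8)
  expect_equal(cm$interactionVarianceShare, cm$adjR2Full - cm$adjR2Main)

  # aliased interaction (gB identically 0): identical nested models
  cm0 <- compareModels(y, gA, rep(0, n))
  expect_equal(cm0$lrtStat, 0, tolerance = 1e-10)
  expect_equal(cm0$lrtP, 1)

  # noiseless limit saturates the full model
  yExact <- 1 + gA + gB + 2 * gA * gB
  expect_warning(cmS <- compareModels(yExact, gA, gB), "saturated")
  expect_true(is.na(cmS$lrtStat))
  expect_equal(cmS$adjR2Full, 1)
})

test_that("a planted rank-scale share near 0.05 is recovered by model comparison", {
  shares <- vapply(1:10, function(s) {
    st <- simulateEpistasisStudy(seed = s, share = 0.05)
    g <- genotypes(st$genotypes)
    v <- exprValues(st$expression)
    compareModels(rankTransform(v[, "probe01"]),
                  g[, st$truth$snpA], g[, st$truth$snpB])$interactionVarianceShare
  }, numeric(1))
  expect_true(all(abs(shares - 0.05) < 0.02))
})

test_that("distance distribution tests behave at the null, the identity and a planted shift", {
  set.seed(9)
  tested <- runif(2000, 1e5, 1e7)

  idt <- distanceDistributionTest(tested, tested)
  expect_equal(idt$D, 0)
  expect_equal(idt$p, 1)

  short <- sort(tested)[1:200]
  sh <- distanceDistributionTest(short, tested)
  expect_lt(sh$p, 1e-4)

  ps <- vapply(1:20, function(s) {
    set.seed(100 + s)
    distanceDistributionTest(sample(tested, 150), tested)$p
  }, numeric(1))
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)

  expect_error(distanceDistributionTest(numeric(0), tested), "non-empty")
  df <- data.frame(distance = c(NA, 2e5, 3e5))
  expect_equal(length(suppressWarnings(
    distanceDistributionTest(df, tested))$D), 1)
})
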