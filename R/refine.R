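#' Collapse significant interactions into non-redundant groups
#'
#' Two significant interactions for the same probe are redundant when
#' their cis-SNPs are in LD (r^2 >= \code{groupR2Min}), their partner SNPs
#' are identical or in LD at the same bound, and their interaction
#' coefficients agree in sign.  The transitive closure of this relation
#' partitions the hits into groups.
#'
#' @param hits data.frame of significant interactions with columns
#'   \code{probeId}, \code{snpA}, \code{snpB}, \code{beta3}.
#' @param gd the \linkS4class{GenotypeData} the hits came from.
#' @param groupR2Min LD bound for declaring two SNPs redundant.
#' @param ldMethod estimator passed to \code{\link{ldR2}}.
#' @return the input data.frame with added columns \code{groupId} (e.g.
#'   \code{"probe01:1"}) and \code{groupSign} (\code{"positive"} /
#'   \code{"negative"}).
#' @export
groupRedundant <- function(hits, gd, groupR2Min = 0.5, ldMethod = "em") {
  if (nrow(hits) == 0) stop("no significant hits to group")
  g <- genotypes(gd)
  cache <- new.env(parent = emptyenv())
  r2of <- function(s1, s2) {
    if (s1 == s2) return(1)
    key <- paste(sort(c(s1, s2)), collapse = "|")
    if (is.null(cache[[key]]))
      cache[[key]] <- ldR2(g[, s1], g[, s2], method = ldMethod)
    cache[[key]]
  }
  hits$groupId <- NA_character_
  hits$groupSign <- ifelse(hits$beta3 >= 0, "positive", "negative")
  for (pb in unique(hits$probeId)) {
    idx <- which(hits$probeId == pb)
    k <- length(idx)
    parent <- seq_len(k)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (u in seq_len(k)) for (w in seq_len(k)) {
      if (u >= w) next
      hu <- hits[idx[u], ]; hw <- hits[idx[w], ]
      if (hu$groupSign != hw$groupSign) next
      cisLinked <- r2of(hu$snpA, hw$snpA) >= groupR2Min
      partnerLinked <- hu$snpB == hw$snpB ||
        r2of(hu$snpB, hw$snpB) >= groupR2Min
      if (cisLinked && partnerLinked) {
        ru <- find(u); rw <- find(w)
        if (ru != rw) parent[rw] <- ru
      }
    }
    roots <- vapply(seq_len(k), find, integer(1))
    gid <- match(roots, unique(roots))
    hits$groupId[idx] <- paste0(pb, ":", gid)
  }
  rownames(hits) <- NULL
  hits
}

#' Bidirectional stepwise model selection by AIC
#'
#' Starts from the full model holding all main-effect and interaction
#' terms (plus any covariates, which are never candidates for removal) and
#' repeatedly takes the single add or drop move that most decreases
#' AIC = n log(RSS/n) + 2k, stopping when no move improves it.  Under the
#' default hierarchy rule an interaction term may only be present alongside
#' both of its main effects; \code{hierarchy = FALSE} reproduces
#' unconstrained selection.  Aliased columns of the full design are dropped
#' up front and reported in the \code{"aliased"} attribute.  Rows are fixed
#' to the complete cases of the full design so every candidate model is
#' compared on the same data.
#'
#' @param exprRanks rank-transformed expression vector.
#' @param mains named numeric matrix of main-effect (genotype) columns.
#' @param interactions named list; each element is the character pair of
#'   main-effect names whose product forms the interaction term.
#' @param covariates numeric matrix or NULL; always kept in the model.
#' @param hierarchy enforce the marginality constraint (default TRUE).
#' @param maxSteps safety cap on the number of moves.
#' @return character vector of retained term names (attributes:
#'   \code{"aic"}, the final AIC; \code{"trace"}, AIC after each move;
#'   \code{"aliased"}, terms removed for aliasing).
#' @export
stepwiseAic <- function(exprRanks, mains, interactions = list(),
                        covariates = NULL, hierarchy = TRUE,
                        maxSteps = 50) {
  mains <- as.matrix(mains)
  if (is.null(colnames(mains))) stop("mains must have column names")
  intNames <- names(interactions)
  if (length(interactions) && is.null(intNames))
    stop("interactions must be a named list")
  for (nm in intNames) {
    pr <- interactions[[nm]]
    if (!all(pr %in% colnames(mains)))
      stop("interaction '", nm, "' references unknown main effects")
  }
  cc <- !is.na(exprRanks) & stats::complete.cases(mains)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    cc <- cc & stats::complete.cases(covariates)
  }
  y <- exprRanks[cc]
  n <- length(y)
  base <- cbind(`(Intercept)` = rep(1, n),
                if (!is.null(covariates)) covariates[cc, , drop = FALSE])
  cols <- cbind(mains[cc, , drop = FALSE],
                vapply(intNames, function(nm) {
                  pr <- interactions[[nm]]
                  mains[cc, pr[1]] * mains[cc, pr[2]]
                }, numeric(n)))
  colnames(cols) <- c(colnames(mains), intNames)
  allTerms <- colnames(cols)
  if (n <= ncol(base) + length(allTerms))
    stop("full model has at least as many columns as complete-case rows")

  # drop aliased columns of the full design first
  qx <- qr(cbind(base, cols))
  aliased <- character(0)
  if (qx$rank < ncol(base) + ncol(cols)) {
    keepIdx <- sort(qx$pivot[seq_len(qx$rank)])
    keepIdx <- keepIdx[keepIdx > ncol(base)] - ncol(base)
    aliased <- setdiff(allTerms, allTerms[keepIdx])
    allTerms <- allTerms[keepIdx]
  }
  isInt <- allTerms %in% intNames
  names(isInt) <- allTerms

  aicOf <- function(terms) {
    X <- cbind(base, cols[, terms, drop = FALSE])
    rss <- sum(qr.resid(qr(X), y)^2)
    n * log(rss / n) + 2 * ncol(X)
  }
  legal <- function(terms) {
    if (!hierarchy) return(TRUE)
    for (nm in terms[terms %in% intNames]) {
      if (!all(interactions[[nm]] %in% terms)) return(FALSE)
    }
    TRUE
  }
  current <- allTerms
  aic <- aicOf(current)
  trace <- aic
  for (step in seq_len(maxSteps)) {
    moves <- list()
    for (tm in current) {
      cand <- setdiff(current, tm)
      if (legal(cand)) moves[[paste0("-", tm)]] <- cand
    }
    for (tm in setdiff(allTerms, current)) {
      cand <- c(current, tm)
      if (legal(cand)) moves[[paste0("+", tm)]] <- cand
    }
    if (!length(moves)) break
    aics <- vapply(moves, aicOf, numeric(1))
    best <- which.min(aics)
    if (aics[best] >= aic - 1e-10) break
    current <- moves[[best]]
    aic <- aics[best]
    trace <- c(trace, aic)
  }
  out <- allTerms[allTerms %in% current]
  attr(out, "aic") <- aic
  attr(out, "trace") <- trace
  attr(out, "aliased") <- aliased
  out
}

#' Compare main-effects and interaction models for one pair
#'
#' Fits the two nested rank-regression models (gA + gB + covariates,
#' with and without the product term) on the shared complete cases and
#' reports adjusted R^2 for both, the Gaussian maximum-likelihood
#' likelihood-ratio statistic n log(RSS_main / RSS_full) with its 1-df
#' chi-squared p-value, and the interaction variance share
#' (adjusted R^2 full minus adjusted R^2 main; may be negative for null
#' pairs).
#'
#' @param exprRanks rank-transformed expression vector.
#' @param genoA,genoB genotype vectors.
#' @param covariates numeric matrix or NULL.
#' @return one-row data.frame: \code{nUsed}, \code{adjR2Main},
#'   \code{adjR2Full}, \code{lrtStat}, \code{lrtP},
#'   \code{interactionVarianceShare}.  A saturated full model
#'   (RSS = 0) leaves the LRT undefined (NA) with a warning.
#' @export
compareModels <- function(exprRanks, genoA, genoB, covariates = NULL) {
  cc <- !is.na(exprRanks) & !is.na(genoA) & !is.na(genoB)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    cc <- cc & stats::complete.cases(covariates)
  }
  y <- exprRanks[cc]
  n <- length(y)
  base <- cbind(`(Intercept)` = rep(1, n),
                if (!is.null(covariates)) covariates[cc, , drop = FALSE],
                gA = genoA[cc], gB = genoB[cc])
  fitM <- fitOls(y, base)
  fitF <- fitOls(y, cbind(base, gAxgB = genoA[cc] * genoB[cc]))
  tss <- sum((y - mean(y))^2)
  adj <- function(fit) 1 - (fit$rss / fit$df) / (tss / (n - 1))
  adjM <- adj(fitM)
  adjF <- adj(fitF)
  if (fitF$rss <= 1e-10 * max(tss, 1)) {
    warning("saturated full model; likelihood ratio undefined")
    lrt <- NA_real_
    lrtP <- NA_real_
  } else {
    lrt <- n * log(fitM$rss / fitF$rss)
    lrtP <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  }
  data.frame(nUsed = n, adjR2Main = adjM, adjR2Full = adjF,
             lrtStat = lrt, lrtP = lrtP,
             interactionVarianceShare = adjF - adjM)
}

#' Compare distance distributions of significant and tested pairs
#'
#' Two-sample Kolmogorov-Smirnov test (asymptotic p) of the
#' intra-chromosomal bp separations of the significant pairs against those
#' of all tested pairs.
#'
#' @param significant,tested numeric distance vectors, or data.frames with
#'   a \code{distance} column (NA separations -- inter-chromosomal pairs --
#'   are dropped).
#' @return list with \code{D} and \code{p}.
#' @export
distanceDistributionTest <- function(significant, tested) {
  dist <- function(x) {
    if (is.data.frame(x)) x <- x$distance
    x[!is.na(x)]
  }
  s <- dist(significant)
  t <- dist(tested)
  if (length(s) == 0 || length(t) == 0)
    stop("both distance sets must be non-empty")
  ks <- suppressWarnings(stats::ks.test(s, t, exact = FALSE))
  list(D = unname(ks$statistic), p = unname(ks$p.value))
}
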