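#' Run the full epistatic eQTL discovery pipeline
#'
#' Executes, for one cohort and one strategy, the stages in their fixed
#' order: SNP quality control; probe blacklist screening (when a variant
#' catalogue is supplied) and IQR-based transcript selection; genotype PCA
#' with iterative outlier removal and a re-check of the SNP filters on the
#' trimmed cohort; Tracy-Widom selection of PC covariates (or the
#' configured override); the rank-transform marginal scan with per-class
#' BH FDR gating; and the pairwise interaction scan with Bonferroni
#' correction.
#'
#' @param gd a \linkS4class{GenotypeData}.
#' @param ed an \linkS4class{ExpressionData} with probe annotations, rows
#'   aligned to \code{gd}.
#' @param config a \code{\link{pipelineConfig}}.
#' @param snpCatalogue optional variant catalogue (data.frame with
#'   \code{chrom}, \code{pos}) for probe blacklisting; NULL skips the
#'   screen.
#' @param removeOutliers run PCA outlier removal (default TRUE).
#' @return list: \code{snpQc} (per-SNP records), \code{probeSelection},
#'   \code{outliers}, \code{pca}, \code{nPcs}, \code{covariates},
#'   \code{marginal}, \code{gated}, \code{interactions} (the
#'   \code{\link{interactionScan}} result) and \code{log}, a named count
#'   vector tracing every filter stage.
#' @export
runPipeline <- function(gd, ed, config = pipelineConfig(),
                        snpCatalogue = NULL, removeOutliers = TRUE) {
  stopifnot(identical(sampleIds(gd), sampleIds(ed)))
  log <- c(individuals = nrow(genotypes(gd)), snpsIn = ncol(genotypes(gd)),
           probesIn = ncol(exprValues(ed)))

  qc <- filterSnps(gd, config)
  gdQ <- qc$genotypes
  log["snpsAfterQc"] <- ncol(genotypes(gdQ))

  pinfo <- probeInfo(ed)
  if (!is.null(snpCatalogue)) {
    bl <- removeBlacklistedProbes(pinfo, snpCatalogue)
    pinfo <- pinfo[bl$keep, , drop = FALSE]
  }
  sel <- selectVariableTranscripts(ed, config$iqrTopFraction)
  selected <- intersect(sel$probeId[sel$selected], pinfo$probeId)
  log["probesSelected"] <- length(selected)

  outliers <- character(0)
  if (removeOutliers)
    outliers <- suppressWarnings(detectOutliers(gdQ))
  log["outliers"] <- length(outliers)
  if (length(outliers)) {
    keep <- setdiff(sampleIds(gdQ), outliers)
    gdQ <- gdQ[keep, ]
    ed <- ed[keep, ]
    # allele frequencies move when individuals are dropped: re-check QC
    qc2 <- filterSnps(gdQ, config)
    gdQ <- qc2$genotypes
    log["snpsAfterReQc"] <- ncol(genotypes(gdQ))
  }

  pca <- suppressWarnings(genotypePca(gdQ))
  nPcs <- if (identical(config$nPcs, "auto"))
    tracyWidomTest(pca$eigenvalues, config$alpha)$nSignificant
  else as.integer(config$nPcs)
  nPcs <- min(nPcs, ncol(pca$scores))
  covariates <- if (nPcs > 0) pca$scores[, seq_len(nPcs), drop = FALSE]
                else NULL
  log["nPcCovariates"] <- nPcs

  marginal <- marginalScan(gdQ, ed, covariates, config$cisWindow,
                           selectedProbes = selected)
  gated <- gateEqtls(marginal, config$fdrThreshold)
  log["marginalTests"] <- nrow(marginal)
  log["gatedHits"] <- nrow(gated)

  interactions <- interactionScan(gdQ, ed, gated, covariates, config)
  log["pairCandidates"] <- nrow(interactions$candidates)
  log["interactionTests"] <- interactions$nTests
  log["significantInteractions"] <-
    if (is.null(interactions$hits)) 0L else sum(interactions$hits$significant)

  list(snpQc = qc$records, probeSelection = sel, outliers = outliers,
       pca = pca, nPcs = nPcs, covariates = covariates,
       marginal = marginal, gated = gated, interactions = interactions,
       genotypes = gdQ, expression = ed, config = config, log = log)
}
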