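#' Read a genotype matrix with SNP metadata
#'
#' Two dialects are supported.  \code{"tsv"}: a tab-separated file whose
#' first column holds individual ids and whose remaining columns (named by
#' SNP id in the header) hold minor-allele counts in \{0, 1, 2, NA\},
#' accompanied by a SNP metadata table (\code{snpInfoPath}) with columns
#' \code{snpId}, \code{chrom}, \code{pos}, \code{majorAllele},
#' \code{minorAllele}.  \code{"ped_map"}: PLINK-style text PED/MAP, where
#' each SNP occupies two allele columns ("0 0" = missing) and alleles are
#' recoded to counts of the minor allele.
#'
#' After loading, any SNP whose stated minor allele has an observed allele
#' frequency above 0.5 is flipped (counts become \code{2 - g}, alleles are
#' swapped) so that the coding is always against the major allele: 0 = AA,
#' 1 = Aa, 2 = aa with A the major allele.  Flipped SNP ids are recorded in
#' the \code{"flippedSnps"} attribute.
#'
#' @param path genotype TSV (dialect \code{"tsv"}) or PED file
#'   (\code{"ped_map"}).
#' @param dialect one of \code{"tsv"}, \code{"ped_map"}.
#' @param snpInfoPath SNP metadata TSV (required for \code{"tsv"}).
#' @param mapPath MAP file path; defaults to \code{path} with its extension
#'   replaced by \code{.map}.
#' @return A \linkS4class{GenotypeData} object with attribute
#'   \code{"flippedSnps"}.
#' @export
readGenotypes <- function(path, dialect = c("tsv", "ped_map"),
                          snpInfoPath = NULL, mapPath = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "tsv") {
    if (is.null(snpInfoPath)) stop("snpInfoPath is required for the tsv dialect")
    raw <- utils::read.delim(path, check.names = FALSE,
                             colClasses = "character")
    if (ncol(raw) < 2) stop("genotype TSV needs an id column and >= 1 SNP")
    ids <- raw[[1]]
    snpIds <- names(raw)[-1]
    if (anyDuplicated(snpIds))
      stop("duplicate SNP id in genotype header: ",
           snpIds[duplicated(snpIds)][1])
    g <- matrix(NA_real_, nrow(raw), length(snpIds),
                dimnames = list(ids, snpIds))
    for (j in seq_along(snpIds)) {
      col <- raw[[j + 1]]
      miss <- is.na(col) | col == "NA" | col == ""
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!miss & (is.na(num) | !(num %in% c(0, 1, 2))))
      if (length(bad))
        stop(sprintf("malformed genotype value '%s' at row %d, SNP '%s'",
                     col[bad[1]], bad[1], snpIds[j]))
      num[miss] <- NA_real_
      g[, j] <- num
    }
    si <- utils::read.delim(snpInfoPath, check.names = FALSE,
                            stringsAsFactors = FALSE)
    si <- si[match(snpIds, si$snpId), , drop = FALSE]
    if (any(is.na(si$snpId)))
      stop("snpInfo file is missing metadata for some SNPs in ", path)
  } else {
    if (is.null(mapPath)) mapPath <- sub("\\.[^.]*$", ".map", path)
    mp <- utils::read.table(mapPath, header = FALSE,
                            stringsAsFactors = FALSE)
    names(mp)[1:4] <- c("chrom", "snpId", "cm", "pos")
    if (anyDuplicated(mp$snpId))
      stop("duplicate SNP id in MAP file: ", mp$snpId[duplicated(mp$snpId)][1])
    pd <- utils::read.table(path, header = FALSE, colClasses = "character")
    if (ncol(pd) != 6 + 2 * nrow(mp))
      stop("PED file has ", ncol(pd), " columns; expected ",
           6 + 2 * nrow(mp), " for ", nrow(mp), " SNPs")
    ids <- pd[[2]]
    nsnp <- nrow(mp)
    g <- matrix(NA_real_, nrow(pd), nsnp, dimnames = list(ids, mp$snpId))
    major <- minor <- character(nsnp)
    for (j in seq_len(nsnp)) {
      a1 <- pd[[6 + 2 * j - 1]]
      a2 <- pd[[6 + 2 * j]]
      miss <- a1 == "0" | a2 == "0"
      alleles <- sort(unique(c(a1[!miss], a2[!miss])))
      if (length(alleles) > 2)
        stop("more than two alleles for SNP '", mp$snpId[j], "'")
      if (length(alleles) == 0) {
        major[j] <- minor[j] <- NA_character_
        next
      }
      counts <- table(factor(c(a1[!miss], a2[!miss]), levels = alleles))
      # minor = less frequent allele; deterministic tie-break by sort order
      ord <- order(counts, seq_along(counts))
      minor[j] <- alleles[ord[1]]
      major[j] <- alleles[if (length(alleles) == 2) ord[2] else ord[1]]
      if (length(alleles) == 1) minor[j] <- NA_character_
      gj <- (a1 == minor[j]) + (a2 == minor[j])
      gj[miss] <- NA
      g[, j] <- gj
    }
    g[, is.na(minor)] <- ifelse(is.na(g[, is.na(minor), drop = FALSE]), NA, 0)
    si <- data.frame(snpId = mp$snpId, chrom = as.character(mp$chrom),
                     pos = mp$pos, majorAllele = major, minorAllele = minor,
                     stringsAsFactors = FALSE)
  }
  gd <- GenotypeData(g, si)
  orientToMinor(gd)
}

# Flip any SNP whose coded allele has observed frequency > 0.5 so the
# value-2 homozygote is always the minor homozygote.
orientToMinor <- function(gd) {
  g <- genotypes(gd)
  si <- snpInfo(gd)
  freq <- colMeans(g, na.rm = TRUE) / 2
  flip <- which(!is.na(freq) & freq > 0.5)
  if (length(flip)) {
    g[, flip] <- 2 - g[, flip]
    tmp <- si$majorAllele[flip]
    si$majorAllele[flip] <- si$minorAllele[flip]
    si$minorAllele[flip] <- tmp
  }
  out <- GenotypeData(g, si)
  attr(out, "flippedSnps") <- si$snpId[flip]
  out
}

#' Write a genotype matrix
#'
#' Inverse of \code{\link{readGenotypes}} for both dialects.
#'
#' @param gd a \linkS4class{GenotypeData} object.
#' @param path output genotype TSV or PED file.
#' @param snpInfoPath output SNP metadata TSV (tsv dialect).
#' @param mapPath output MAP path (ped_map dialect); defaults to \code{path}
#'   with extension \code{.map}.
#' @param dialect one of \code{"tsv"}, \code{"ped_map"}.
#' @return \code{path}, invisibly.
#' @export
writeGenotypes <- function(gd, path, snpInfoPath = NULL, mapPath = NULL,
                           dialect = c("tsv", "ped_map")) {
  dialect <- match.arg(dialect)
  g <- genotypes(gd)
  si <- snpInfo(gd)
  if (dialect == "tsv") {
    if (is.null(snpInfoPath)) stop("snpInfoPath is required for the tsv dialect")
    df <- data.frame(individual = rownames(g), g, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(si, snpInfoPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    if (is.null(mapPath)) mapPath <- sub("\\.[^.]*$", ".map", path)
    utils::write.table(
      data.frame(si$chrom, si$snpId, 0, si$pos),
      mapPath, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
    n <- nrow(g)
    ped <- matrix("0", n, 6 + 2 * ncol(g))
    ped[, 1] <- ped[, 2] <- rownames(g)
    ped[, 3] <- ped[, 4] <- "0"; ped[, 5] <- "0"; ped[, 6] <- "-9"
    for (j in seq_len(ncol(g))) {
      gj <- g[, j]
      a1 <- ifelse(is.na(gj), "0", ifelse(gj >= 1, si$minorAllele[j],
                                          si$majorAllele[j]))
      a2 <- ifelse(is.na(gj), "0", ifelse(gj == 2, si$minorAllele[j],
                                          si$majorAllele[j]))
      ped[, 6 + 2 * j - 1] <- a1
      ped[, 6 + 2 * j] <- a2
    }
    utils::write.table(ped, path, sep = " ", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read an expression matrix aligned to a genotype cohort
#'
#' Tab-separated file: first column individual ids, remaining columns named
#' by probe id, values numeric or NA.  The returned matrix is restricted to
#' the individuals shared with \code{genotypes} and reordered to match the
#' genotype sample order; the number of dropped individuals is recorded in
#' the \code{"droppedIndividuals"} attribute.
#'
#' @param path expression TSV.
#' @param genotypes a \linkS4class{GenotypeData} object defining the cohort.
#' @param probeInfo optional probe annotation data.frame (see
#'   \code{\link{readProbeAnnotations}}).
#' @return An \linkS4class{ExpressionData} object.
#' @export
readExpression <- function(path, genotypes, probeInfo = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  ids <- raw[[1]]
  probeIds <- names(raw)[-1]
  v <- matrix(NA_real_, nrow(raw), length(probeIds),
              dimnames = list(ids, probeIds))
  for (j in seq_along(probeIds)) {
    col <- raw[[j + 1]]
    miss <- is.na(col) | col == "NA" | col == ""
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!miss & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric expression value '%s' at row %d, probe '%s'",
                   col[bad[1]], bad[1], probeIds[j]))
    v[, j] <- num
  }
  gids <- sampleIds(genotypes)
  shared <- gids[gids %in% ids]
  if (length(shared) == 0)
    stop("no individuals shared between expression and genotype data")
  dropped <- sum(!(ids %in% gids))
  v <- v[match(shared, ids), , drop = FALSE]
  ed <- ExpressionData(v, probeInfo)
  attr(ed, "droppedIndividuals") <- dropped
  ed
}

#' Write an expression matrix
#'
#' @param ed an \linkS4class{ExpressionData} object.
#' @param path output TSV.
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(ed, path) {
  v <- exprValues(ed)
  df <- data.frame(individual = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read probe annotations (BED-like)
#'
#' Tab-separated, no header: chrom, start, end, probeId, with BED 0-based
#' half-open coordinates.  The probe midpoint is
#' \code{floor((start + end) / 2)}.
#'
#' @param path annotation file.
#' @return data.frame with columns \code{probeId}, \code{chrom},
#'   \code{start}, \code{end}, \code{midpoint}.
#' @export
readProbeAnnotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0)
    return(data.frame(probeId = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      midpoint = numeric(0)))
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:4] <- c("chrom", "start", "end", "probeId")
  if (any(df$start >= df$end))
    stop("probe interval with start >= end in ", path)
  data.frame(probeId = as.character(df$probeId),
             chrom = as.character(df$chrom),
             start = df$start, end = df$end,
             midpoint = floor((df$start + df$end) / 2),
             stringsAsFactors = FALSE)
}

#' Write probe annotations (BED-like)
#'
#' @param probeInfo data.frame as returned by
#'   \code{\link{readProbeAnnotations}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeProbeAnnotations <- function(probeInfo, path) {
  utils::write.table(
    probeInfo[, c("chrom", "start", "end", "probeId")], path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3+ interval track
#'
#' Parsed with \code{rtracklayer}; BED 0-based half-open intervals become
#' the usual 1-based closed \code{GRanges}, so a SNP at 1-based position p
#' lies in BED interval [s, e) iff \code{start(gr) <= p & p <= end(gr)}.
#'
#' @param path BED file (an empty file yields an empty GRanges).
#' @return A \code{GRanges}; the BED name field, when present, is kept in
#'   metadata column \code{name}.
#' @export
readIntervals <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) return(GenomicRanges::GRanges())
  gr <- rtracklayer::import(path, format = "BED")
  if (any(GenomicRanges::width(gr) < 1))
    stop("interval with start >= end in ", path)
  gr
}

#' Write a GRanges interval track as BED
#'
#' @param gr a GRanges.
#' @param path output BED file.
#' @return \code{path}, invisibly.
#' @export
writeIntervals <- function(gr, path) {
  if (length(gr) == 0) {
    file.create(path)
    return(invisible(path))
  }
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a Hi-C fragment-pair table
#'
#' Tab-separated with header columns \code{chromA}, \code{startA},
#' \code{chromB}, \code{startB}: the chromosome and alignment start
#' position of the two loci of each contact pair.
#'
#' @param path pair table TSV.
#' @return data.frame with the four columns above.
#' @export
readHicPairs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chromA", "startA", "chromB", "startB")
  if (!all(need %in% names(df)))
    stop("Hi-C pair table must have columns: ", paste(need, collapse = ", "))
  df$chromA <- as.character(df$chromA)
  df$chromB <- as.character(df$chromB)
  df
}

#' Write a Hi-C fragment-pair table
#'
#' @param pairs data.frame with columns \code{chromA}, \code{startA},
#'   \code{chromB}, \code{startB}.
#' @param path output TSV.
#' @return \code{path}, invisibly.
#' @export
writeHicPairs <- function(pairs, path) {
  utils::write.table(pairs[, c("chromA", "startA", "chromB", "startB")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles every tunable threshold of the discovery pipeline.  Defaults are
#' the study settings: MAF > 0.2, missingness <= 20\%, HWE alpha 0.05, top
#' 5\% most-variable probes by IQR, marginal FDR gate 0.5, pair LD bound
#' r^2 < 0.01, at least 10 individuals in each of the nine two-locus
#' genotype cells, and a cis window of 1 Mb (cis-trans strategy) or 10 Mb
#' (cis-cis, with pairs additionally >= 100 kb apart).
#'
#' @param strategy \code{"cis_trans"} or \code{"cis_cis"}.
#' @param mafMin minimum minor allele frequency (strict >).
#' @param missMax maximum missingness fraction (inclusive).
#' @param hweAlpha Hardy-Weinberg chi-squared alpha; SNPs with p below it
#'   are removed.
#' @param iqrTopFraction fraction of probes kept by IQR ranking.
#' @param fdrThreshold marginal-eQTL gate (hits kept when q < threshold).
#' @param ldR2Max maximum LD r^2 between intra-chromosomal pair members.
#' @param minCellCount minimum count per two-locus genotype cell.
#' @param cisWindow bp window around the probe midpoint defining cis;
#'   defaults to 1e6 (cis_trans) or 1e7 (cis_cis).
#' @param pairMinDistance minimum bp separation of a cis-cis pair.
#' @param nPcs \code{"auto"} (Tracy-Widom significant count) or an integer
#'   override of the number of PC covariates.
#' @param alpha familywise error rate for Bonferroni correction.
#' @param ldMethod LD estimator for pair filtering, \code{"em"} (maximum
#'   likelihood haplotype frequencies) or \code{"composite"} (squared
#'   genotype correlation).
#' @param seed integer seed recorded with the run.
#' @return A list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(strategy = c("cis_trans", "cis_cis"),
                           mafMin = 0.2, missMax = 0.2, hweAlpha = 0.05,
                           iqrTopFraction = 0.05, fdrThreshold = 0.5,
                           ldR2Max = 0.01, minCellCount = 10,
                           cisWindow = NULL, pairMinDistance = 1e5,
                           nPcs = "auto", alpha = 0.05,
                           ldMethod = c("em", "composite"), seed = 1L) {
  strategy <- match.arg(strategy)
  ldMethod <- match.arg(ldMethod)
  if (is.null(cisWindow))
    cisWindow <- if (strategy == "cis_trans") 1e6 else 1e7
  fr <- c(mafMin = mafMin, missMax = missMax, hweAlpha = hweAlpha,
          iqrTopFraction = iqrTopFraction, fdrThreshold = fdrThreshold,
          ldR2Max = ldR2Max, alpha = alpha)
  if (any(fr < 0 | fr > 1))
    stop("fractions/probabilities must lie in [0, 1]: ",
         paste(names(fr)[fr < 0 | fr > 1], collapse = ", "))
  if (cisWindow <= pairMinDistance)
    stop("cisWindow must exceed pairMinDistance")
  if (!identical(nPcs, "auto") && (!is.numeric(nPcs) || nPcs < 0))
    stop("nPcs must be \"auto\" or a nonnegative integer")
  structure(list(strategy = strategy, mafMin = mafMin, missMax = missMax,
                 hweAlpha = hweAlpha, iqrTopFraction = iqrTopFraction,
                 fdrThreshold = fdrThreshold, ldR2Max = ldR2Max,
                 minCellCount = minCellCount, cisWindow = cisWindow,
                 pairMinDistance = pairMinDistance, nPcs = nPcs,
                 alpha = alpha, ldMethod = ldMethod,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' @export
print.PipelineConfig <- function(x, ...) {
  cat("PipelineConfig (", x$strategy, ")\n", sep = "")
  for (nm in setdiff(names(x), "strategy"))
    cat(sprintf("  %-16s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys may use the snake_case names (\code{maf_min}, \code{miss_max},
#' \code{hwe_alpha}, \code{iqr_top_fraction}, \code{fdr_threshold},
#' \code{ld_r2_max}, \code{min_cell_count}, \code{cis_window},
#' \code{pair_min_distance}, \code{n_pcs}, \code{ld_method}) or the
#' camelCase argument names of \code{\link{pipelineConfig}}.
#'
#' @param path YAML file.
#' @return A \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  map <- c(maf_min = "mafMin", miss_max = "missMax", hwe_alpha = "hweAlpha",
           iqr_top_fraction = "iqrTopFraction",
           fdr_threshold = "fdrThreshold", ld_r2_max = "ldR2Max",
           min_cell_count = "minCellCount", cis_window = "cisWindow",
           pair_min_distance = "pairMinDistance", n_pcs = "nPcs",
           ld_method = "ldMethod")
  nm <- names(y)
  hit <- nm %in% names(map)
  names(y)[hit] <- map[nm[hit]]
  unknown <- setdiff(names(y), names(formals(pipelineConfig)))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  do.call(pipelineConfig, y)
}
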