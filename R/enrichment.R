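#' Map a SNP pair onto Hi-C contact pairs
#'
#' TRUE iff some Hi-C pair has one SNP within \code{window} bp (inclusive)
#' of one locus' alignment start and the other SNP within \code{window} bp
#' of the other locus, in either orientation.  Both SNPs near the same
#' locus do not count: the SNPs must map one each.
#'
#' @param snp1,snp2 lists or one-row data.frames with \code{chrom} and
#'   \code{pos}.
#' @param hic Hi-C pair data.frame (\code{chromA}, \code{startA},
#'   \code{chromB}, \code{startB}).
#' @param window bp tolerance, default 5000.
#' @return logical flag.
#' @export
mapPairToHic <- function(snp1, snp2, hic, window = 5000) {
  stopifnot(window > 0)
  if (is.null(hic) || nrow(hic) == 0) return(FALSE)
  near <- function(snp, chrom, start)
    normChrom(snp$chrom) == normChrom(chrom) & abs(snp$pos - start) <= window
  n1A <- near(snp1, hic$chromA, hic$startA)
  n1B <- near(snp1, hic$chromB, hic$startB)
  n2A <- near(snp2, hic$chromA, hic$startA)
  n2B <- near(snp2, hic$chromB, hic$startB)
  any((n1A & n2B) | (n1B & n2A))
}

#' Map a SNP onto an interval track
#'
#' TRUE iff the SNP position falls inside any interval of the track.
#' Tracks are GRanges in the 1-based closed convention produced by
#' \code{\link{readIntervals}}, so a 1-based SNP position p lies in BED
#' interval [s, e) iff s < p <= e, i.e. s <= p - 1 < e.
#'
#' @param snpChrom,snpPos SNP chromosome and 1-based position.
#' @param track a GRanges.
#' @return logical flag.
#' @export
mapSnpToIntervals <- function(snpChrom, snpPos, track) {
  if (length(track) == 0) return(FALSE)
  same <- normChrom(as.character(GenomicRanges::seqnames(track))) ==
    normChrom(snpChrom)
  any(same & GenomicRanges::start(track) <= snpPos &
        snpPos <= GenomicRanges::end(track))
}

#' 2x2 enrichment table statistics
#'
#' Odds ratio and Pearson chi-squared test of independence (1 df, no
#' continuity correction) for the table
#' \tabular{lcc}{
#'   \tab mapped \tab unmapped \cr
#'   epistatic \tab a \tab b \cr
#'   background \tab c \tab d \cr
#' }
#' When any cell is zero the Haldane-Anscombe +0.5 correction is applied to
#' all four cells for the odds ratio only; the chi-squared statistic is
#' always computed from the raw counts.  A zero column margin carries no
#' information and yields chi-squared 0, p = 1.
#'
#' @param a,b,c,d the four cell counts.
#' @return one-row data.frame: \code{a}, \code{b}, \code{c}, \code{d},
#'   \code{oddsRatio}, \code{chi2}, \code{p}.
#' @examples
#' enrichment2x2(14, 20, 913, 8859)   # odds ratio 6.79
#' @export
enrichment2x2 <- function(a, b, c, d) {
  # double arithmetic: (ad - bc)^2 overflows 32-bit integers on real tables
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop("cell counts must be nonnegative")
  if (a + b < 1 || c + d < 1)
    stop("both row totals must be at least 1")
  oc <- if (any(cells == 0)) cells + 0.5 else cells
  or <- unname((oc["a"] * oc["d"]) / (oc["b"] * oc["c"]))
  n <- a + b + c + d
  m1 <- a + b; m2 <- c + d; k1 <- a + c; k2 <- b + d
  if (k1 == 0 || k2 == 0) {
    chi2 <- 0
    p <- 1
  } else {
    chi2 <- n * (a * d - b * c)^2 / (m1 * m2 * k1 * k2)
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  data.frame(a = a, b = b, c = c, d = d, oddsRatio = or, chi2 = chi2,
             p = p)
}

#' Enrichment sweep of SNP sets over annotation tracks
#'
#' For each track, counts how many epistatic and background SNPs map into
#' it (set semantics: a SNP appearing in several interactions counts once;
#' duplicates by \code{snpId}, or by position when ids are absent, are
#' removed) and computes the 2x2 enrichment.  Significance is assessed
#' against the Bonferroni-corrected level alpha / nComparisons.
#'
#' @param epistaticSnps,backgroundSnps data.frames with columns
#'   \code{chrom}, \code{pos} (and optionally \code{snpId}); the two sets
#'   should be disjoint.
#' @param tracks named list of GRanges.
#' @param alpha familywise error rate.
#' @param nComparisons Bonferroni denominator; defaults to the number of
#'   tracks, but should cover the full track x query-tissue family when
#'   the sweep is part of a larger analysis.
#' @return data.frame, one row per track: \code{track}, the 2x2 columns of
#'   \code{\link{enrichment2x2}}, \code{correctedAlpha},
#'   \code{significant}.
#' @export
enrichmentSweep <- function(epistaticSnps, backgroundSnps, tracks,
                            alpha = 0.05, nComparisons = length(tracks)) {
  dedup <- function(s) {
    key <- if (!is.null(s$snpId)) s$snpId else paste(s$chrom, s$pos)
    s[!duplicated(key), , drop = FALSE]
  }
  epi <- dedup(epistaticSnps)
  bg <- dedup(backgroundSnps)
  correctedAlpha <- alpha / nComparisons
  rows <- lapply(names(tracks), function(nm) {
    tr <- tracks[[nm]]
    mapped <- function(s) sum(vapply(seq_len(nrow(s)), function(i)
      mapSnpToIntervals(s$chrom[i], s$pos[i], tr), logical(1)))
    a <- mapped(epi)
    c_ <- mapped(bg)
    res <- enrichment2x2(a, nrow(epi) - a, c_, nrow(bg) - c_)
    cbind(data.frame(track = nm, stringsAsFactors = FALSE), res)
  })
  out <- do.call(rbind, rows)
  out$correctedAlpha <- correctedAlpha
  out$significant <- out$p < correctedAlpha
  out
}

#' Hi-C enrichment of significant versus tested interactions
#'
#' Builds the 2x2 table whose rows are the significant (epistatic) pairs
#' and the remaining tested (non-epistatic) pairs, and whose columns are
#' mapping / not mapping to at least one Hi-C contact pair.
#'
#' @param interactionHits the \code{hits} data.frame of
#'   \code{\link{interactionScan}} (needs \code{snpA}, \code{snpB},
#'   \code{significant}).
#' @param gd the \linkS4class{GenotypeData} (for SNP coordinates).
#' @param hic Hi-C pair data.frame.
#' @param window bp tolerance, default 5000.
#' @return one-row data.frame from \code{\link{enrichment2x2}} plus a
#'   \code{mapped} logical vector attribute aligned to the input rows.
#' @export
hicEnrichment <- function(interactionHits, gd, hic, window = 5000) {
  si <- snpInfo(gd)
  loc <- function(id) {
    i <- match(id, si$snpId)
    list(chrom = si$chrom[i], pos = si$pos[i])
  }
  mapped <- vapply(seq_len(nrow(interactionHits)), function(i)
    mapPairToHic(loc(interactionHits$snpA[i]),
                 loc(interactionHits$snpB[i]), hic, window), logical(1))
  sig <- interactionHits$significant
  res <- enrichment2x2(sum(mapped & sig), sum(!mapped & sig),
                       sum(mapped & !sig), sum(!mapped & !sig))
  attr(res, "mapped") <- mapped
  res
}
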