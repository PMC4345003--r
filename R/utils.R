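# Internal helpers shared across modules.

# Least squares on an explicit design matrix.  Returns coefficients (NA for
# aliased columns), standard errors, RSS and residual df -- enough for
# t-tests, adjusted R^2 and likelihood-ratio statistics without refitting.
fitOls <- function(y, X) {
  stopifnot(nrow(X) == length(y))
  qx <- qr(X)
  r <- qx$rank
  cf <- qr.coef(qx, y)
  res <- qr.resid(qx, y)
  rss <- sum(res^2)
  df <- length(y) - r
  se <- rep(NA_real_, ncol(X))
  if (df > 0 && r > 0) {
    piv <- qx$pivot[seq_len(r)]
    Rm <- qr.R(qx)[seq_len(r), seq_len(r), drop = FALSE]
    xtxinv <- chol2inv(Rm)
    se[piv] <- sqrt(pmax(diag(xtxinv), 0) * rss / df)
  }
  names(se) <- colnames(X)
  list(coef = cf, se = se, rss = rss, df = df, rank = r, residuals = res)
}

# Two-sided t-test for one coefficient of a fitOls() fit.
olsTerm <- function(fit, term) {
  b <- unname(fit$coef[term])
  s <- unname(fit$se[term])
  if (is.na(b) || is.na(s) || s == 0 || fit$df < 1)
    return(list(beta = b, se = s, t = NA_real_, p = NA_real_))
  tv <- b / s
  list(beta = b, se = s, t = tv,
       p = 2 * stats::pt(abs(tv), fit$df, lower.tail = FALSE))
}

# Chromosome labels are compared after stripping any "chr" prefix so that
# "chr6" and "6" refer to the same chromosome.
normChrom <- function(x) sub("^chr", "", as.character(x))

isAutosome <- function(chrom) normChrom(chrom) %in% as.character(1:22)

`%||%` <- function(a, b) if (is.null(a)) b else a
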