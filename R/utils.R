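# Internal numerical helpers shared across modules.

# log(sum(exp(x))) without overflow; ABFs at large z exceed double range.
logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Residualise the columns of M on the column space of C (C must include the
# intercept if one is wanted).  Uses a QR once per covariate matrix.
residualise <- function(M, C) {
  if (is.null(C) || ncol(C) == 0L) return(M)
  qrC <- qr(C)
  M - qr.fitted(qrC, M)
}

# Mass simple regressions of each column of Y on each column of X after both
# have been residualised on the same covariates.  Returns beta, se, t, p for
# the given (gene index, snp index) pairs, with t-distribution df adjusted for
# the projected-out covariates.  Workhorse of the cis and trans scans.
pairwiseAssoc <- function(Yr, Xr, geneIdx, snpIdx, dfResid) {
  stopifnot(length(geneIdx) == length(snpIdx))
  xx <- colSums(Xr^2)
  beta <- se <- tval <- numeric(length(geneIdx))
  yy <- colSums(Yr^2)
  for (k in seq_along(geneIdx)) {
    g <- geneIdx[k]; s <- snpIdx[k]
    b <- sum(Xr[, s] * Yr[, g]) / xx[s]
    rss <- yy[g] - b^2 * xx[s]
    rss <- max(rss, 0)
    sigma2 <- rss / dfResid
    beta[k] <- b
    se[k] <- sqrt(sigma2 / xx[s])
    tval[k] <- b / se[k]
  }
  p <- 2 * pt(-abs(tval), df = dfResid)
  data.frame(beta = beta, se = se, t = tval, p = pmin(pmax(p, .Machine$double.xmin), 1))
}

# Vectorised over all SNPs for one gene: much faster inner loop for scans.
assocOneGene <- function(yr, Xr, dfResid) {
  xx <- colSums(Xr^2)
  xy <- as.vector(crossprod(Xr, yr))
  beta <- xy / xx
  rss <- pmax(sum(yr^2) - beta^2 * xx, 0)
  se <- sqrt(rss / dfResid / xx)
  tval <- beta / se
  p <- 2 * pt(-abs(tval), df = dfResid)
  data.frame(beta = beta, se = se, t = tval,
             p = pmin(pmax(p, .Machine$double.xmin), 1))
}

# Split a length-n index vector into consecutive chunks of at most `size`.
chunkIndices <- function(n, size) {
  if (n == 0L) return(list())
  split(seq_len(n), ceiling(seq_len(n) / size))
}

# Derive a stage-specific 32-bit seed from a master seed, so that each
# pipeline stage has its own reproducible stream.
stageSeed <- function(seed, stage) {
  offs <- sum(utf8ToInt(stage)) * 1009L
  as.integer((as.numeric(seed) * 48271 + offs) %% 2147483647)
}
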