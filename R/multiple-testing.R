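#' @include preprocess.R
NULL

#' Benjamini-Hochberg step-up FDR control
#'
#' @param p numeric vector of p-values between 0 and 1; `NA`/`NaN` is an error.
#' @param alpha target FDR (default 0.05).
#' @return list with `q` (BH-adjusted p-values), `reject` (logical), and
#'   `threshold` (the largest rejected p-value, `NA` if none).
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.5), alpha = 0.05)$reject
#' @export
bhFdr <- function(p, alpha = 0.05) {
  if (any(!is.finite(p))) stop("p-values must be finite (no NA/NaN)")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  q <- p.adjust(p, method = "BH")
  reject <- q <= alpha
  list(q = q, reject = reject,
       threshold = if (any(reject)) max(p[reject]) else NA_real_)
}

#' Effective number of independent tests in a SNP window
#'
#' eigen-decomposition based estimate: SNPs are split into consecutive chunks
#' of at most `chunk`, and within each chunk the effective count is the
#' smallest number of top eigenvalues of the dosage correlation matrix that
#' explain at least `varExplained` of the total variance.  Chunk counts are
#' summed and capped at the number of SNPs.  Zero-variance SNPs are dropped
#' from the correlation matrix with a warning.
#'
#' @param dosage samples x SNPs dosage matrix for the window.
#' @param varExplained variance fraction (default 0.99).
#' @param chunk maximum chunk width (default 200).
#' @return integer effective test count (`0` for an empty window).
#' @export
effectiveTests <- function(dosage, varExplained = 0.99, chunk = 200L) {
  if (is.null(dim(dosage))) dosage <- matrix(dosage, ncol = 1)
  v <- apply(dosage, 2, var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance SNP(s) dropped from m_eff estimation")
    dosage <- dosage[, v > 0, drop = FALSE]
  }
  m <- ncol(dosage)
  if (m == 0L) return(0L)
  total <- 0L
  for (idx in chunkIndices(m, chunk)) {
    cm <- cor(dosage[, idx, drop = FALSE])
    ev <- eigen(cm, symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
    cum <- cumsum(ev) / sum(ev)
    total <- total + which(cum >= varExplained - 1e-12)[1]
  }
  min(as.integer(total), m)
}

#' Hierarchical (local x global) multiple-testing correction
#'
#' Implements the two-level correction used for per-condition cis scans: each
#' gene's minimum nominal p-value is locally adjusted by its effective
#' independent SNP count, `p_local = min(1, p_min * m_eff)`; genes are then
#' globally corrected across the transcriptome by Benjamini-Hochberg at
#' `fdr`.  The largest locally adjusted p-value passing the global step
#' (`p_star`) defines each gene's nominal significance threshold
#' `p_star / m_eff`, against which individual SNP p-values are compared.
#'
#' @param minP named numeric: minimum nominal p per gene.
#' @param mEff named numeric: effective SNP count per gene (same order).
#' @param fdr global FDR level (default 0.05).
#' @return data.frame with `gene_id`, `m_eff`, `p_local`, `q_global`,
#'   `is_egene`, `nominal_threshold` (NA when no gene is significant), plus
#'   attribute `p_star`.
#' @export
hierarchicalCorrection <- function(minP, mEff, fdr = 0.05) {
  stopifnot(length(minP) == length(mEff))
  pLocal <- pmin(1, minP * mEff)
  bh <- bhFdr(pLocal, alpha = fdr)
  pStar <- bh$threshold
  out <- data.frame(
    gene_id = if (!is.null(names(minP))) names(minP) else seq_along(minP),
    m_eff = as.numeric(mEff), p_local = pLocal, q_global = bh$q,
    is_egene = bh$reject,
    nominal_threshold = if (is.na(pStar)) NA_real_ else pStar / mEff,
    stringsAsFactors = FALSE)
  attr(out, "p_star") <- pStar
  out
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha family-wise error target.
#' @param nTests number of tests.
#' @return `alpha / nTests`.
#' @export
bonferroniThreshold <- function(alpha, nTests) alpha / nTests

#' Effective number of independent genome-wide tests
#'
#' The count implied by a family-wise `alpha` and the conventional
#' genome-wide significance level: `alpha / gwSig` (1e6 for 0.05 and 5e-8).
#' Used as the per-gene multiplier in the gene-level FDR correction of the
#' trans scan.
#'
#' @param alpha family-wise error target (default 0.05).
#' @param gwSig genome-wide significance level (default 5e-8).
#' @return the effective test count.
#' @export
effectiveGenomeWideTests <- function(alpha = 0.05, gwSig = 5e-8) alpha / gwSig
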