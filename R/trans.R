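#' @include reqtl.R
NULL

#' Cross-chromosome trans-eQTL scan
#'
#' Tests every gene against every SNP on a *different* chromosome, with the
#' same linear model and covariates as the cis scan.  To bound memory on
#' large scans only rows with `p < keepP` are returned, together with each
#' gene's minimum p-value row (always kept), which is sufficient for all
#' three correction schemes.
#'
#' @inheritParams cisScan
#' @param keepP retention threshold for reported rows (default 1e-5).
#' @return data.frame `gene_id`, `snp_id`, `beta`, `se`, `t`, `p`, `n`,
#'   `is_gene_min`; attribute `n_tests` carries the total number of tests
#'   performed (needed for the genome-wide FDR scheme).
#' @export
transScan <- function(study, panel, condition, keepP = 1e-5) {
  des <- conditionDesign(study, panel, condition)
  snps <- snpInfo(panel)
  genes <- geneInfo(study)
  n <- nrow(des$Y)
  dfResid <- n - ncol(des$C) - 1L
  Yr <- residualise(des$Y, des$C)
  Xr <- residualise(des$X, des$C)
  ok <- colSums(Xr^2) > 1e-12
  out <- list(); nTests <- 0
  for (i in seq_len(nrow(genes))) {
    w <- which(snps$chrom != genes$chrom[i] & ok)
    if (!length(w)) next
    st <- assocOneGene(Yr[, i], Xr[, w, drop = FALSE], dfResid)
    nTests <- nTests + length(w)
    keep <- st$p < keepP
    keep[which.min(st$p)] <- TRUE
    df <- data.frame(gene_id = genes$gene_id[i], snp_id = snps$snp_id[w][keep],
                     st[keep, , drop = FALSE], n = n, stringsAsFactors = FALSE)
    df$is_gene_min <- df$p == min(st$p)
    out[[length(out) + 1L]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_tests") <- nTests
  res
}

#' The three trans multiple-testing schemes
#'
#' Scheme 1 (genome-wide FDR): Benjamini-Hochberg over the nominal p-values
#' of *all* trans tests at `fdr` (the sub-threshold storage of [transScan()]
#' is handled by treating unstored rows as non-significant, which is exact
#' for any BH threshold below `keepP`).  Scheme 2 (gene-level FDR): each
#' gene's minimum p is multiplied by the effective genome-wide test count
#' (1e6, capped at 1) and BH is applied across genes.  Scheme 3 (gene-level
#' Bonferroni): a gene is significant when its minimum p is below
#' `5e-8 / nGenes`.
#'
#' @param results data.frame from [transScan()] (attribute `n_tests` set).
#' @param nGenes number of genes tested (denominator of scheme 3).
#' @param fdr FDR level for schemes 1 and 2 (default 0.05).
#' @param gwSig genome-wide significance level (default 5e-8).
#' @return `results` with logical columns `genomewide_fdr_sig`,
#'   `genelevel_fdr_sig`, `genelevel_bonf_sig` added (gene-level scheme
#'   flags are set on each gene's minimum-p row).
#' @export
transMultipleTesting <- function(results, nGenes, fdr = 0.05, gwSig = 5e-8) {
  nTests <- attr(results, "n_tests")
  if (is.null(nTests)) stop("results lack the n_tests attribute")
  # scheme 1: BH over all tests; unstored p-values are all >= keepP and can
  # only push the step-up threshold down, never up, so rank within the full
  # test count is exact for stored rows
  o <- order(results$p)
  pSorted <- results$p[o]
  passes <- pSorted <= fdr * seq_along(pSorted) / nTests
  thr1 <- if (any(passes)) pSorted[max(which(passes))] else -Inf
  results$genomewide_fdr_sig <- results$p <= thr1
  # scheme 2: per-gene min p times the effective genome-wide test count
  mins <- results[results$is_gene_min & !duplicated(results$gene_id), ]
  adj <- pmin(1, mins$p * effectiveGenomeWideTests(gwSig = gwSig))
  bh <- bhFdr(adj, alpha = fdr)
  sigGenes2 <- mins$gene_id[bh$reject]
  results$genelevel_fdr_sig <- results$is_gene_min & results$gene_id %in% sigGenes2
  # scheme 3: gene-level Bonferroni at 5e-8 / nGenes
  thr3 <- transBonferroniThreshold(nGenes, gwSig)
  sigGenes3 <- mins$gene_id[mins$p < thr3]
  results$genelevel_bonf_sig <- results$is_gene_min &
    results$gene_id %in% sigGenes3
  results
}

#' Link trans hits to cis eGenes (mediation trios)
#'
#' A trio (SNP, cis gene, trans gene) is formed whenever a significant
#' trans-eSNP is also a significant cis-eSNP of a local gene — either by
#' exact id, or through a proxy in LD (`r^2 >= proxyR2`) when `useProxy`.
#'
#' @param transHits data.frame of significant trans rows (`gene_id`,
#'   `snp_id`).
#' @param esnps named list of significant cis-eSNP ids per cis eGene (from
#'   [mapCisEqtls()]).
#' @param panel a [GenotypePanel-class] (only needed for proxy matching).
#' @param useProxy match through LD proxies (default FALSE: exact ids only).
#' @param proxyR2 LD threshold for proxies (default 0.8).
#' @return data.frame `snp_id`, `cis_gene`, `trans_gene`.
#' @export
linkTransToCis <- function(transHits, esnps, panel = NULL, useProxy = FALSE,
                           proxyR2 = 0.8) {
  out <- list()
  for (i in seq_len(nrow(transHits))) {
    s <- transHits$snp_id[i]
    for (g in names(esnps)) {
      hit <- s %in% esnps[[g]]
      if (!hit && useProxy && !is.null(panel)) {
        hit <- any(vapply(esnps[[g]], function(e)
          snpR2(panel, s, e) >= proxyR2, logical(1)))
      }
      if (hit)
        out[[length(out) + 1L]] <- data.frame(
          snp_id = s, cis_gene = g, trans_gene = transHits$gene_id[i],
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(snp_id = character(), cis_gene = character(),
                      trans_gene = character(), stringsAsFactors = FALSE))
  unique(do.call(rbind, out))
}

#' Gene-level Bonferroni threshold for the trans scan
#'
#' @param nGenes number of genes tested.
#' @param gwSig genome-wide significance level (default 5e-8).
#' @return `gwSig / nGenes` (3.8e-12 for 13,109 genes).
#' @export
transBonferroniThreshold <- function(nGenes, gwSig = 5e-8) gwSig / nGenes
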