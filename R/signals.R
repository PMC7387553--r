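#' @include cis-scan.R
NULL

# Re-scan one gene's cis window with extra conditioning SNPs appended to the
# covariates.  Candidates collinear with the conditioning set (residual
# variance ~ 0) are excluded, as are the conditioning SNPs themselves.
conditionalGeneScan <- function(study, panel, condition, geneId,
                                conditioningSnps = character(),
                                windowBp = 1e6) {
  des <- conditionDesign(study, panel, condition)
  genes <- geneInfo(study)
  gi <- match(geneId, genes$gene_id)
  if (is.na(gi)) stop("unknown gene: ", geneId)
  snps <- snpInfo(panel)
  w <- cisWindowSnps(snps, genes$chrom[gi], genes$tss[gi], windowBp)
  if (!length(w)) stop("gene has no cis SNPs: ", geneId)
  C <- des$C
  if (length(conditioningSnps)) {
    bad <- setdiff(conditioningSnps, snps$snp_id)
    if (length(bad)) stop("conditioning SNP(s) missing from panel: ",
                          paste(bad, collapse = ", "))
    C <- cbind(C, des$X[, conditioningSnps, drop = FALSE])
  }
  qrC <- qr(C)
  C <- C[, qrC$pivot[seq_len(qrC$rank)], drop = FALSE]  # drop collinear cols
  cand <- w[!(snps$snp_id[w] %in% conditioningSnps)]
  if (!length(cand)) return(NULL)
  n <- nrow(des$Y)
  dfResid <- n - ncol(C) - 1L
  yr <- residualise(des$Y[, gi, drop = FALSE], C)[, 1]
  Xr <- residualise(des$X[, cand, drop = FALSE], C)
  keep <- colSums(Xr^2) > 1e-8
  if (any(!keep))
    message(sum(!keep), " candidate SNP(s) collinear with conditioning set excluded")
  cand <- cand[keep]
  if (!length(cand)) return(NULL)
  st <- assocOneGene(yr, Xr[, keep, drop = FALSE], dfResid)
  data.frame(gene_id = geneId, snp_id = snps$snp_id[cand], st, n = n,
             stringsAsFactors = FALSE)
}

#' Forward stage of the conditional analysis
#'
#' Starting from an eGene's top SNP, iteratively re-scans the cis window with
#' all previously selected SNPs as covariates, adding the new top SNP while
#' any association stays below the gene's nominal threshold.
#'
#' @param study,panel,condition as in [cisScan()].
#' @param geneId the eGene.
#' @param topSnp the unconditional top SNP (seeds the list).
#' @param nominalThreshold the gene's nominal p threshold from
#'   [mapCisEqtls()].
#' @param windowBp cis window (default 1e6).
#' @param maxIter iteration cap (default 10; multi-signal genes are rare).
#' @return ordered character vector of independent signal SNPs.
#' @export
forwardStage <- function(study, panel, condition, geneId, topSnp,
                         nominalThreshold, windowBp = 1e6, maxIter = 10L) {
  selected <- topSnp
  for (it in seq_len(maxIter)) {
    sc <- conditionalGeneScan(study, panel, condition, geneId,
                              conditioningSnps = selected, windowBp = windowBp)
    if (is.null(sc) || min(sc$p) >= nominalThreshold) break
    top <- topSnpPerGene(sc, snpInfo(panel))
    selected <- c(selected, top$snp_id)
  }
  selected
}

#' Backward stage of the conditional analysis
#'
#' Each forward-selected signal is re-tested in a leave-one-out model that
#' adjusts for all other selected SNPs (plus the original covariates); it is
#' retained when the strongest association in that model still beats the
#' gene's nominal threshold.  The retained signals, with their statistics
#' from the leave-one-out model, form the final signal set.
#'
#' @inheritParams forwardStage
#' @param forwardSnps SNP list from [forwardStage()].
#' @return data.frame (`gene_id`, `condition`, `snp_id`, `beta`, `se`, `p`,
#'   `rank`) with one row per retained independent signal.
#' @export
backwardStage <- function(study, panel, condition, geneId, forwardSnps,
                          nominalThreshold, windowBp = 1e6) {
  keep <- list()
  for (i in seq_along(forwardSnps)) {
    others <- forwardSnps[-i]
    sc <- conditionalGeneScan(study, panel, condition, geneId,
                              conditioningSnps = others, windowBp = windowBp)
    if (is.null(sc)) next
    if (min(sc$p) < nominalThreshold) {
      row <- sc[sc$snp_id == forwardSnps[i], , drop = FALSE]
      if (nrow(row) == 0) next
      keep[[length(keep) + 1L]] <- data.frame(
        gene_id = geneId, condition = condition, snp_id = forwardSnps[i],
        beta = row$beta, se = row$se, p = row$p, rank = i,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(keep))
    return(data.frame(gene_id = character(), condition = character(),
                      snp_id = character(), beta = numeric(), se = numeric(),
                      p = numeric(), rank = integer(), stringsAsFactors = FALSE))
  do.call(rbind, keep)
}

#' Independent cis signals for one eGene (forward + backward)
#'
#' @inheritParams forwardStage
#' @return the [backwardStage()] data.frame.
#' @export
independentSignals <- function(study, panel, condition, geneId, topSnp,
                               nominalThreshold, windowBp = 1e6,
                               maxIter = 10L) {
  fw <- forwardStage(study, panel, condition, geneId, topSnp,
                     nominalThreshold, windowBp, maxIter)
  backwardStage(study, panel, condition, geneId, fw, nominalThreshold,
                windowBp)
}

#' Cross-condition conditioning of an eGene's signals
#'
#' Re-scans condition B's cis window for the gene while adjusting for
#' condition A's top eSNP.  If any SNP stays below B's nominal threshold the
#' two signals are classified `"independent"`; otherwise `"shared"` — which,
#' as for the underlying procedure, means shared *or* underpowered to detect
#' independence.
#'
#' @param study,panel as elsewhere.
#' @param geneId gene significant in both conditions.
#' @param topSnpA top eSNP in the conditioning condition A.
#' @param conditionB condition to re-scan.
#' @param nominalThresholdB B's per-gene nominal threshold.
#' @param windowBp cis window.
#' @return `"independent"` or `"shared"`.
#' @export
crossConditionConditioning <- function(study, panel, geneId, topSnpA,
                                       conditionB, nominalThresholdB,
                                       windowBp = 1e6) {
  if (!topSnpA %in% snpInfo(panel)$snp_id)
    stop("conditioning SNP missing from panel: ", topSnpA)
  sc <- conditionalGeneScan(study, panel, conditionB, geneId,
                            conditioningSnps = topSnpA, windowBp = windowBp)
  if (!is.null(sc) && min(sc$p) < nominalThresholdB) "independent" else "shared"
}
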