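#' @include multiple-testing.R
NULL

# Assemble the per-condition design: expression (samples x genes), dosages
# aligned to the condition's samples, covariate matrix with intercept.
conditionDesign <- function(study, panel, condition) {
  Y <- exprMatrix(study, condition)
  cd <- sampleSheet(study)
  cd <- cd[cd$condition == condition, , drop = FALSE]
  missing <- setdiff(cd$individual_id, individualIds(panel))
  if (length(missing))
    stop("individuals without genotypes: ", paste(head(missing, 5), collapse = ", "))
  X <- dosages(panel)[cd$individual_id, , drop = FALSE]
  rownames(X) <- cd$sample_id
  C <- cbind(`(Intercept)` = 1, covariateMatrix(study, condition))
  list(Y = Y, X = X, C = C, samples = cd)
}

# cis SNP column indices for one gene (inclusive 1 Mb window both sides).
cisWindowSnps <- function(snps, chrom, tss, windowBp) {
  which(snps$chrom == chrom & abs(snps$pos - tss) <= windowBp)
}

#' Per-condition cis-eQTL scan
#'
#' Ordinary least squares of each gene's (inverse-normal transformed)
#' expression on the dosage of every SNP within `windowBp` of its TSS
#' (inclusive on both sides), adjusting for the study covariates.  p-values
#' come from the two-sided t distribution with `n - k - 1` degrees of
#' freedom.  Genes without cis SNPs are skipped with a `message()`;
#' zero-variance SNPs are excluded from the window.
#'
#' @param study an [ExpressionStudy-class] (expression already INT-scaled).
#' @param panel a [GenotypePanel-class] covering the study individuals.
#' @param condition condition label to scan.
#' @param windowBp cis window half-width in bp (default 1e6).
#' @return data.frame of association statistics: `gene_id`, `snp_id`,
#'   `beta`, `se`, `t`, `p`, `n`.
#' @export
cisScan <- function(study, panel, condition, windowBp = 1e6) {
  des <- conditionDesign(study, panel, condition)
  snps <- snpInfo(panel)
  genes <- geneInfo(study)
  n <- nrow(des$Y)
  dfResid <- n - ncol(des$C) - 1L
  Yr <- residualise(des$Y, des$C)
  Xr <- residualise(des$X, des$C)
  ok <- colSums(Xr^2) > 1e-12
  out <- vector("list", nrow(genes))
  skipped <- 0L
  for (i in seq_len(nrow(genes))) {
    w <- cisWindowSnps(snps, genes$chrom[i], genes$tss[i], windowBp)
    w <- w[ok[w]]
    if (!length(w)) { skipped <- skipped + 1L; next }
    st <- assocOneGene(Yr[, i], Xr[, w, drop = FALSE], dfResid)
    out[[i]] <- data.frame(gene_id = genes$gene_id[i],
                           snp_id = snps$snp_id[w], st, n = n,
                           stringsAsFactors = FALSE)
  }
  if (skipped > 0) message(skipped, " gene(s) without cis SNPs skipped")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Deterministic top-SNP choice: smallest p, then largest |beta|, then
# smallest genomic position.
topSnpPerGene <- function(assoc, snps) {
  pos <- snps$pos[match(assoc$snp_id, snps$snp_id)]
  o <- order(assoc$gene_id, assoc$p, -abs(assoc$beta), pos)
  a <- assoc[o, , drop = FALSE]
  a[!duplicated(a$gene_id), , drop = FALSE]
}

#' Map significant eGenes and eSNPs in one condition
#'
#' Runs [cisScan()], estimates each gene's effective independent SNP count
#' with [effectiveTests()], applies the hierarchical correction
#' ([hierarchicalCorrection()]) across genes at `fdr`, and collects for each
#' significant eGene its top SNP and the full set of significant eSNPs
#' (nominal p at or below the gene's nominal threshold; the top SNP always
#' belongs to the set).
#'
#' @inheritParams cisScan
#' @param fdr global FDR across genes (default 0.05).
#' @param varExplained,chunk passed to [effectiveTests()].
#' @return list with `assoc` (the scan), `egenes` (one row per tested gene:
#'   `gene_id`, `condition`, `m_eff`, `top_snp`, `top_p`, `top_beta`,
#'   `p_local`, `q_global`, `is_egene`, `nominal_threshold`), and `esnps`
#'   (named list of significant SNP ids per eGene).
#' @export
mapCisEqtls <- function(study, panel, condition, windowBp = 1e6, fdr = 0.05,
                        varExplained = 0.99, chunk = 200L) {
  assoc <- cisScan(study, panel, condition, windowBp = windowBp)
  snps <- snpInfo(panel)
  genesTested <- unique(assoc$gene_id)
  d <- dosages(panel)
  cd <- sampleSheet(study)
  ids <- cd$individual_id[cd$condition == condition]
  mEff <- vapply(genesTested, function(g) {
    sn <- assoc$snp_id[assoc$gene_id == g]
    suppressWarnings(
      effectiveTests(d[ids, sn, drop = FALSE], varExplained, chunk))
  }, numeric(1))
  top <- topSnpPerGene(assoc, snps)
  top <- top[match(genesTested, top$gene_id), ]
  minP <- setNames(top$p, genesTested)
  hc <- hierarchicalCorrection(minP, mEff[genesTested], fdr = fdr)
  egenes <- data.frame(
    gene_id = genesTested, condition = condition, m_eff = hc$m_eff,
    top_snp = top$snp_id, top_p = top$p, top_beta = top$beta,
    p_local = hc$p_local, q_global = hc$q_global, is_egene = hc$is_egene,
    nominal_threshold = hc$nominal_threshold, stringsAsFactors = FALSE)
  esnps <- list()
  for (g in genesTested[egenes$is_egene]) {
    thr <- egenes$nominal_threshold[egenes$gene_id == g]
    rows <- assoc$gene_id == g & assoc$p <= thr
    esnps[[g]] <- assoc$snp_id[rows]
  }
  list(assoc = assoc, egenes = egenes, esnps = esnps,
       p_star = attr(hc, "p_star"))
}
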