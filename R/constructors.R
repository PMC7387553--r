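#' @include AllGenerics.R
NULL

defaultConditionTable <- function() {
  data.frame(
    condition = c("resting_myeloid", "lps_myeloid", "resting_t", "pha_t"),
    cell_type = c("myeloid", "myeloid", "t", "t"),
    treatment = c("resting", "stimulated", "resting", "stimulated"),
    stringsAsFactors = FALSE)
}

#' Build a simulation configuration
#'
#' Defaults emulate the paired cord-blood design the package targets: 135
#' genotyped individuals, four conditions (resting/LPS-stimulated myeloid
#' cells, resting/PHA-stimulated T cells) with post-QC sample sizes near
#' 116/125/126/127 and a complete-case core of ~95 individuals, SNPs with
#' MAF >= 10% in LD blocks, and planted cis-eQTLs, response eQTLs (including
#' sign flips), and cis-mediated trans trios.
#'
#' @param nIndividuals cohort size.
#' @param conditionTable data.frame of conditions (see [SimConfig-class]).
#' @param retention per-condition retention fractions (named or in
#'   `conditionTable` order).
#' @param coreFraction fraction retained in every condition.
#' @param nGenes,nSnps,nChromosomes,snpSpacingBp genome layout.
#' @param ldBlockSize,withinBlockR LD-block structure.
#' @param mafRange alternative-allele frequency range, within 0.10-0.50.
#' @param nCisEqtls,nReqtls,nSignflipReqtls,nTransTrios planted effect counts.
#' @param effectSizeSd,conditionEffectSd,individualReSd,noiseSd variance
#'   components (expression s.d. units).
#' @param nCovariates covariate count (sex + 3 genotype PCs + 10 latent
#'   factors).
#' @param seed master RNG seed.
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nIndividuals = 40, nGenes = 20, nSnps = 100, seed = 1)
#' @export
simConfig <- function(nIndividuals = 135L,
                      conditionTable = defaultConditionTable(),
                      retention = c(116, 125, 126, 127) / 135,
                      coreFraction = 95 / 135,
                      nGenes = 300L, nSnps = 1500L, nChromosomes = 4L,
                      snpSpacingBp = 10000L, ldBlockSize = 10L,
                      withinBlockR = 0.8, mafRange = c(0.10, 0.50),
                      nCisEqtls = 60L, nReqtls = 20L, nSignflipReqtls = 2L,
                      nTransTrios = 5L, effectSizeSd = 0.6,
                      conditionEffectSd = 0.5, individualReSd = 0.5,
                      noiseSd = 1, nCovariates = 14L, seed = 1L) {
  if (is.null(names(retention))) names(retention) <- conditionTable$condition
  new("SimConfig", nIndividuals = as.integer(nIndividuals),
      conditionTable = conditionTable, retention = retention,
      coreFraction = coreFraction, nGenes = as.integer(nGenes),
      nSnps = as.integer(nSnps), nChromosomes = as.integer(nChromosomes),
      snpSpacingBp = as.integer(snpSpacingBp),
      ldBlockSize = as.integer(ldBlockSize), withinBlockR = withinBlockR,
      mafRange = mafRange, nCisEqtls = as.integer(nCisEqtls),
      nReqtls = as.integer(nReqtls),
      nSignflipReqtls = as.integer(nSignflipReqtls),
      nTransTrios = as.integer(nTransTrios), effectSizeSd = effectSizeSd,
      conditionEffectSd = conditionEffectSd, individualReSd = individualReSd,
      noiseSd = noiseSd, nCovariates = as.integer(nCovariates),
      seed = as.integer(seed))
}

#' Construct a genotype panel
#'
#' @param dosage individuals x SNPs numeric matrix with dosages in 0-2
#'   (`NA` = missing call); needs row and column names.
#' @param snps data.frame with `snp_id`, `chrom`, `pos`, `ref`, `alt` and
#'   optionally `maf` (recomputed from the dosages when absent).
#' @param meta optional metadata list.
#' @return a validated [GenotypePanel-class].
#' @export
genotypePanel <- function(dosage, snps, meta = list()) {
  dosage <- as.matrix(dosage)
  if (is.null(colnames(dosage))) colnames(dosage) <- snps$snp_id
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("ind", seq_len(nrow(dosage)))
  if (is.null(snps$maf)) {
    f <- colMeans(dosage, na.rm = TRUE) / 2
    snps$maf <- pmin(f, 1 - f)
  }
  rownames(snps) <- NULL
  new("GenotypePanel", dosage = dosage, snps = snps, meta = meta)
}

#' Construct a truth table
#'
#' @param cis,trans,gwasLoci,causalGenes data.frames as documented in
#'   [TruthTable-class]; all default to empty.
#' @return a validated [TruthTable-class].
#' @export
truthTable <- function(cis = emptyCisTruth(), trans = emptyTransTruth(),
                       gwasLoci = emptyGwasLociTruth(),
                       causalGenes = emptyCausalGeneTruth()) {
  new("TruthTable", cis = cis, trans = trans, gwasLoci = gwasLoci,
      causalGenes = causalGenes)
}

emptyCisTruth <- function() data.frame(
  gene_id = character(), snp_id = character(), cell_type = character(),
  beta_resting = numeric(), beta_stimulated = numeric(),
  is_reqtl = logical(), is_signflip = logical(), stringsAsFactors = FALSE)

emptyTransTruth <- function() data.frame(
  snp_id = character(), cis_gene = character(), trans_gene = character(),
  cell_type = character(), a = numeric(), b = numeric(), c_prime = numeric(),
  stringsAsFactors = FALSE)

emptyGwasLociTruth <- function() data.frame(
  locus_id = character(), disease = character(), causal_snp = character(),
  eqtl_snp = character(), shared_with_eqtl = logical(), gamma = numeric(),
  stringsAsFactors = FALSE)

emptyCausalGeneTruth <- function() data.frame(
  gene_id = character(), disease = character(), effect = numeric(),
  stringsAsFactors = FALSE)

#' Construct a paired-condition expression study
#'
#' @param exprs genes x samples numeric matrix (rownames gene ids, colnames
#'   sample ids).
#' @param samples sample sheet data.frame with `sample_id`, `individual_id`,
#'   `condition` and covariate columns; one row per column of `exprs`.
#' @param genes gene annotation data.frame with `gene_id`, `chrom`, `tss`;
#'   one row per row of `exprs`.
#' @param conditionTable condition-to-cell-type/treatment map.
#' @param covariateNames character vector of covariate columns in `samples`.
#' @return a validated [ExpressionStudy-class].
#' @export
expressionStudy <- function(exprs, samples, genes,
                            conditionTable = defaultConditionTable(),
                            covariateNames = character()) {
  stopifnot(ncol(exprs) == nrow(samples), nrow(exprs) == nrow(genes))
  rownames(exprs) <- genes$gene_id
  colnames(exprs) <- samples$sample_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = exprs),
    rowData = S4Vectors::DataFrame(genes, row.names = genes$gene_id),
    colData = S4Vectors::DataFrame(samples, row.names = samples$sample_id))
  new("ExpressionStudy", se, conditionTable = conditionTable,
      covariateNames = covariateNames)
}
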