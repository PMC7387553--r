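#' @include stimqtl-package.R
NULL

#' Simulation configuration for the synthetic paired-condition study
#'
#' Holds every knob of the synthetic-data generator: cohort size, the four
#' experimental conditions (cell type x treatment) with per-condition
#' retention fractions emulating unequal post-QC sample sizes, genome layout,
#' LD-block structure, and the numbers and magnitudes of planted effects.
#'
#' @slot nIndividuals number of genotyped individuals.
#' @slot conditionTable data.frame with columns `condition`, `cell_type`,
#'   `treatment` (`"resting"` or `"stimulated"`).
#' @slot retention named numeric, fraction of individuals retained per
#'   condition (emulates post-QC attrition); names match `conditionTable$condition`.
#' @slot coreFraction fraction of individuals guaranteed present in all
#'   conditions (the complete-case core).
#' @slot nGenes,nSnps,nChromosomes,snpSpacingBp genome layout; SNPs are evenly
#'   spaced `snpSpacingBp` apart and split across chromosomes.
#' @slot ldBlockSize SNPs per LD block.
#' @slot withinBlockR target adjacent-SNP dosage correlation within a block,
#'   at least 0 and below 1.
#' @slot mafRange range the per-block alternative-allele frequency is drawn
#'   from; constrained to 0.10-0.50 (the analysis MAF floor).
#' @slot nCisEqtls,nReqtls,nSignflipReqtls,nTransTrios planted effect counts.
#' @slot effectSizeSd s.d. of planted genotype effect sizes (expression s.d.
#'   per alternative allele).
#' @slot conditionEffectSd s.d. of per-gene condition main effects.
#' @slot individualReSd random-intercept s.d. shared across paired samples.
#' @slot noiseSd residual s.d.
#' @slot nCovariates number of measured/latent covariates (sex + 3 genotype-PC
#'   proxies + 10 latent factors = 14).
#' @slot seed master RNG seed; each stage derives its own stream from it.
#' @export
setClass("SimConfig", representation(
  nIndividuals = "integer", conditionTable = "data.frame",
  retention = "numeric", coreFraction = "numeric",
  nGenes = "integer", nSnps = "integer", nChromosomes = "integer",
  snpSpacingBp = "integer", ldBlockSize = "integer", withinBlockR = "numeric",
  mafRange = "numeric", nCisEqtls = "integer", nReqtls = "integer",
  nSignflipReqtls = "integer", nTransTrios = "integer",
  effectSizeSd = "numeric", conditionEffectSd = "numeric",
  individualReSd = "numeric", noiseSd = "numeric",
  nCovariates = "integer", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  ct <- object@conditionTable
  if (!all(c("condition", "cell_type", "treatment") %in% names(ct)))
    msg <- c(msg, "conditionTable needs columns condition, cell_type, treatment")
  if (!all(ct$treatment %in% c("resting", "stimulated")))
    msg <- c(msg, "treatment must be 'resting' or 'stimulated'")
  if (!setequal(names(object@retention), ct$condition))
    msg <- c(msg, "retention must be named by condition")
  if (any(object@retention <= 0) || any(object@retention > 1))
    msg <- c(msg, "retention fractions must be in (0, 1]")
  if (length(object@mafRange) != 2 || object@mafRange[1] < 0.10 ||
      object@mafRange[2] > 0.50 || diff(object@mafRange) < 0)
    msg <- c(msg, "mafRange must lie within [0.10, 0.50]")
  if (object@withinBlockR < 0 || object@withinBlockR >= 1)
    msg <- c(msg, "withinBlockR must be in [0, 1)")
  counts <- c(object@nGenes, object@nSnps, object@nCisEqtls, object@nReqtls,
              object@nSignflipReqtls, object@nTransTrios)
  if (any(counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (object@nSignflipReqtls > object@nReqtls)
    msg <- c(msg, "nSignflipReqtls must not exceed nReqtls")
  if (object@nReqtls > object@nCisEqtls)
    msg <- c(msg, "nReqtls must not exceed nCisEqtls")
  if (length(msg)) msg else TRUE
})

#' Genotype dosage panel
#'
#' Individuals-by-SNPs dosage matrix (0-2 copies of the alternative allele,
#' possibly fractional for imputed data, `NA` for missing calls) plus a SNP
#' table with genomic coordinates, alleles and minor allele frequency.
#'
#' @slot dosage numeric matrix, individuals x SNPs; rownames are individual
#'   ids, colnames SNP ids.
#' @slot snps data.frame with columns `snp_id`, `chrom`, `pos` (1-based bp),
#'   `ref`, `alt`, `maf`.
#' @slot meta list of free-form metadata (e.g. generator parameters).
#' @export
setClass("GenotypePanel", representation(
  dosage = "matrix", snps = "data.frame", meta = "list"))

setValidity("GenotypePanel", function(object) {
  msg <- character()
  d <- object@dosage; s <- object@snps
  if (ncol(d) != nrow(s)) msg <- c(msg, "dosage columns must match snp table rows")
  need <- c("snp_id", "chrom", "pos", "ref", "alt", "maf")
  if (!all(need %in% names(s))) {
    msg <- c(msg, paste("snp table needs columns:", paste(need, collapse = ", ")))
  } else if (nrow(s) > 0) {
    if (anyDuplicated(s$snp_id)) msg <- c(msg, "SNP ids must be unique")
    if (any(s$pos <= 0)) msg <- c(msg, "positions must be positive")
    rng <- range(d, na.rm = TRUE)
    if (nrow(d) > 0 && (rng[1] < 0 || rng[2] > 2))
      msg <- c(msg, "dosages must lie in [0, 2]")
    if (nrow(d) > 0) {
      f <- colMeans(d, na.rm = TRUE) / 2
      maf <- pmin(f, 1 - f)
      if (any(abs(maf - s$maf) > 1e-9, na.rm = TRUE))
        msg <- c(msg, "stored MAF inconsistent with dosages")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic study
#'
#' Records every planted effect so downstream recovery can be scored:
#' cis eQTL pairs (with per-treatment betas; sign-flip response eQTLs have
#' opposite signs), cis-mediated trans trios (a, b, c' path coefficients),
#' GWAS loci that do or do not share their causal SNP with an eQTL, and genes
#' with a true causal effect on a disease liability.
#'
#' @slot cis data.frame: `gene_id`, `snp_id`, `cell_type`, `beta_resting`,
#'   `beta_stimulated`, `is_reqtl`, `is_signflip`.
#' @slot trans data.frame: `snp_id`, `cis_gene`, `trans_gene`, `cell_type`,
#'   `a`, `b`, `c_prime`.
#' @slot gwasLoci data.frame: `locus_id`, `disease`, `causal_snp`,
#'   `eqtl_snp`, `shared_with_eqtl`, `gamma` (liability effect per allele).
#' @slot causalGenes data.frame: `gene_id`, `disease`, `effect` (liability
#'   units per s.d. expression).
#' @export
setClass("TruthTable", representation(
  cis = "data.frame", trans = "data.frame",
  gwasLoci = "data.frame", causalGenes = "data.frame"))

setValidity("TruthTable", function(object) {
  msg <- character()
  cis <- object@cis
  if (nrow(cis)) {
    flips <- cis$is_signflip
    if (any(flips & cis$beta_resting * cis$beta_stimulated >= 0))
      msg <- c(msg, "sign-flip reQTLs must have beta_resting * beta_stimulated < 0")
    if (any(cis$is_signflip & !cis$is_reqtl))
      msg <- c(msg, "sign-flip pairs must be reQTLs")
  }
  if (length(msg)) msg else TRUE
})

#' Paired-condition expression study
#'
#' A thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding
#' all samples of all conditions in one genes-by-samples assay.  `colData`
#' carries the sample sheet (sample id, individual id, condition, covariates);
#' `rowData` carries the gene annotation (chromosome, TSS).  Per-condition
#' samples-by-genes matrices are extracted with [exprMatrix()].
#'
#' @slot conditionTable data.frame mapping `condition` to `cell_type` and
#'   `treatment`.
#' @slot covariateNames character: the colData columns used as model
#'   covariates in every association scan (the study's fixed covariate set).
#' @export
setClass("ExpressionStudy",
  contains = "SummarizedExperiment",
  representation(conditionTable = "data.frame", covariateNames = "character"))

setValidity("ExpressionStudy", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  need <- c("sample_id", "individual_id", "condition")
  if (!all(need %in% names(cd)))
    msg <- c(msg, paste("colData needs columns:", paste(need, collapse = ", ")))
  else {
    if (!all(cd$condition %in% object@conditionTable$condition))
      msg <- c(msg, "conditions in colData missing from conditionTable")
    key <- paste(cd$individual_id, cd$condition)
    if (anyDuplicated(key))
      msg <- c(msg, "each individual may contribute at most one sample per condition")
  }
  if (!all(object@covariateNames %in% names(cd)))
    msg <- c(msg, "covariateNames must be colData columns")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("chrom", "tss") %in% names(rd)))
    msg <- c(msg, "rowData needs columns chrom, tss")
  if (length(msg)) msg else TRUE
})
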