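#' @include constructors.R
NULL

#' @rdname GenotypePanel-class
#' @export
setMethod("dosages", "GenotypePanel", function(x) x@dosage)

#' @rdname GenotypePanel-class
#' @export
setMethod("snpInfo", "GenotypePanel", function(x) x@snps)

#' @rdname GenotypePanel-class
#' @export
setMethod("individualIds", "GenotypePanel", function(x) rownames(x@dosage))

#' @rdname GenotypePanel-class
#' @export
setMethod("show", "GenotypePanel", function(object) {
  cat("GenotypePanel:", nrow(object@dosage), "individuals x",
      ncol(object@dosage), "SNPs\n")
  if (nrow(object@snps)) {
    cat("  chromosomes:", paste(unique(object@snps$chrom), collapse = ", "), "\n")
    cat(sprintf("  MAF range: %.3f-%.3f\n", min(object@snps$maf), max(object@snps$maf)))
  }
})

# Subset a panel to a SNP id set (order preserved as given).
#' Subset a genotype panel by SNP ids
#' @param panel a [GenotypePanel-class]
#' @param snpIds character vector of SNP ids to keep, in order
#' @return a new `GenotypePanel`
#' @export
subsetSnps <- function(panel, snpIds) {
  idx <- match(snpIds, panel@snps$snp_id)
  if (anyNA(idx)) stop("unknown SNP id(s): ",
                       paste(snpIds[is.na(idx)], collapse = ", "))
  genotypePanel(panel@dosage[, idx, drop = FALSE],
                panel@snps[idx, , drop = FALSE], meta = panel@meta)
}

#' @rdname ExpressionStudy-class
#' @export
setMethod("conditionNames", "ExpressionStudy", function(x) x@conditionTable$condition)

#' @rdname ExpressionStudy-class
#' @export
setMethod("conditionTable", "ExpressionStudy", function(x) x@conditionTable)

#' @rdname ExpressionStudy-class
#' @export
setMethod("sampleSheet", "ExpressionStudy", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname ExpressionStudy-class
#' @export
setMethod("geneInfo", "ExpressionStudy", function(x)
  as.data.frame(SummarizedExperiment::rowData(x)))

#' @rdname ExpressionStudy-class
#' @export
setMethod("covariateNames", "ExpressionStudy", function(x) x@covariateNames)

#' @rdname ExpressionStudy-class
#' @param condition condition label (one of `conditionNames(x)`)
#' @export
setMethod("exprMatrix", "ExpressionStudy", function(x, condition) {
  keep <- SummarizedExperiment::colData(x)$condition == condition
  if (!any(keep)) stop("no samples for condition: ", condition)
  t(SummarizedExperiment::assay(x, "exprs")[, keep, drop = FALSE])
})

#' @rdname ExpressionStudy-class
#' @export
setMethod("covariateMatrix", "ExpressionStudy", function(x, condition) {
  cd <- sampleSheet(x)
  cd <- cd[cd$condition == condition, , drop = FALSE]
  m <- as.matrix(cd[, covariateNames(x), drop = FALSE])
  rownames(m) <- cd$sample_id
  storage.mode(m) <- "double"
  m
})

#' @rdname ExpressionStudy-class
#' @export
setMethod("show", "ExpressionStudy", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("ExpressionStudy:", nrow(object), "genes x", ncol(object), "samples\n")
  tab <- table(cd$condition)
  for (cn in names(tab)) cat("  ", cn, ": ", tab[[cn]], " samples\n", sep = "")
  cat("  covariates:", length(object@covariateNames), "\n")
})

#' @rdname TruthTable-class
#' @export
setMethod("cisTruth", "TruthTable", function(x) x@cis)

#' @rdname TruthTable-class
#' @export
setMethod("transTruth", "TruthTable", function(x) x@trans)

#' @rdname TruthTable-class
#' @export
setMethod("gwasLociTruth", "TruthTable", function(x) x@gwasLoci)

#' @rdname TruthTable-class
#' @export
setMethod("causalGeneTruth", "TruthTable", function(x) x@causalGenes)

#' @rdname TruthTable-class
#' @param object a `TruthTable`
#' @export
setMethod("show", "TruthTable", function(object) {
  cat("TruthTable:", nrow(object@cis), "cis pairs (",
      sum(object@cis$is_reqtl), "reQTLs,", sum(object@cis$is_signflip),
      "sign-flips ),", nrow(object@trans), "trans trios,",
      nrow(object@gwasLoci), "GWAS loci,", nrow(object@causalGenes),
      "causal genes\n")
})

#' @rdname SimConfig-class
#' @param object a `SimConfig`
#' @export
setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nIndividuals, "individuals,",
      nrow(object@conditionTable), "conditions,", object@nGenes, "genes,",
      object@nSnps, "SNPs (blocks of", object@ldBlockSize, ", target r =",
      object@withinBlockR, ")\n")
  cat("  planted:", object@nCisEqtls, "cis eQTLs (", object@nReqtls,
      "reQTLs,", object@nSignflipReqtls, "sign-flips ),",
      object@nTransTrios, "trans trios; seed", object@seed, "\n")
})
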