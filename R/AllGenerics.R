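#' @include AllClasses.R
NULL

#' @rdname GenotypePanel-class
#' @param object,x a `GenotypePanel`
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname GenotypePanel-class
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @rdname GenotypePanel-class
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' @rdname ExpressionStudy-class
#' @param x,object an `ExpressionStudy`
#' @export
setGeneric("conditionNames", function(x) standardGeneric("conditionNames"))

#' @rdname ExpressionStudy-class
#' @export
setGeneric("conditionTable", function(x) standardGeneric("conditionTable"))

#' @rdname ExpressionStudy-class
#' @export
setGeneric("sampleSheet", function(x) standardGeneric("sampleSheet"))

#' @rdname ExpressionStudy-class
#' @export
setGeneric("geneInfo", function(x) standardGeneric("geneInfo"))

#' @rdname ExpressionStudy-class
#' @export
setGeneric("covariateNames", function(x) standardGeneric("covariateNames"))

#' @rdname ExpressionStudy-class
#' @export
setGeneric("exprMatrix", function(x, condition) standardGeneric("exprMatrix"))

#' @rdname ExpressionStudy-class
#' @export
setGeneric("covariateMatrix", function(x, condition) standardGeneric("covariateMatrix"))

#' @rdname TruthTable-class
#' @param x a `TruthTable`
#' @export
setGeneric("cisTruth", function(x) standardGeneric("cisTruth"))

#' @rdname TruthTable-class
#' @export
setGeneric("transTruth", function(x) standardGeneric("transTruth"))

#' @rdname TruthTable-class
#' @export
setGeneric("gwasLociTruth", function(x) standardGeneric("gwasLociTruth"))

#' @rdname TruthTable-class
#' @export
setGeneric("causalGeneTruth", function(x) standardGeneric("causalGeneTruth"))
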