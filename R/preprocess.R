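#' @include methods.R
NULL

# Hardy-Weinberg chi-square (1 d.f., no continuity correction) from rounded
# genotype counts.
hwePvalue <- function(g) {
  g <- round(g[!is.na(g)])
  n <- length(g)
  if (n == 0) return(NA_real_)
  counts <- c(sum(g == 0), sum(g == 1), sum(g == 2))
  p <- (counts[2] + 2 * counts[3]) / (2 * n)
  expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  if (any(expd == 0)) return(1)
  x2 <- sum((counts - expd)^2 / expd)
  pchisq(x2, df = 1, lower.tail = FALSE)
}

#' Genotype quality control
#'
#' Removes SNPs with missing call rate above `maxMissing`, minor allele
#' frequency below `minMaf`, or Hardy-Weinberg equilibrium chi-square p-value
#' below `hwePMin` (computed on dosages rounded to hard calls).
#'
#' @param panel a [GenotypePanel-class].
#' @param maxMissing maximum tolerated missing call rate (default 0.01, i.e.
#'   SNPs missing in >1% of individuals are dropped).
#' @param minMaf MAF floor (default 0.01; MAF < 1% dropped).
#' @param hwePMin HWE p-value floor (default 1e-6).
#' @return the filtered [GenotypePanel-class]; a warning is raised if every
#'   SNP is removed.
#' @export
genotypeQc <- function(panel, maxMissing = 0.01, minMaf = 0.01,
                       hwePMin = 1e-6) {
  d <- dosages(panel); s <- snpInfo(panel)
  if (ncol(d) == 0L) return(panel)
  missRate <- colMeans(is.na(d))
  hwe <- apply(d, 2, hwePvalue)
  keep <- missRate <= maxMissing & s$maf >= minMaf & (is.na(hwe) | hwe >= hwePMin)
  if (!any(keep)) warning("genotype QC removed every SNP")
  genotypePanel(d[, keep, drop = FALSE], s[keep, , drop = FALSE],
                meta = panel@meta)
}

#' Analysis MAF filter
#'
#' Restricts the panel to SNPs with MAF at or above the analysis floor
#' (default 10%, inclusive), the threshold used for all association scans.
#'
#' @param panel a [GenotypePanel-class].
#' @param minMaf inclusive MAF floor.
#' @return the filtered panel.
#' @export
analysisMafFilter <- function(panel, minMaf = 0.10) {
  keep <- snpInfo(panel)$maf >= minMaf
  genotypePanel(dosages(panel)[, keep, drop = FALSE],
                snpInfo(panel)[keep, , drop = FALSE], meta = panel@meta)
}

#' Detectability filter for expression features
#'
#' A gene (probe) is kept if it is detected (detection p-value <= `pThresh`)
#' in at least `condFrac` of the samples of any single condition, or in at
#' least `allFrac` of all samples.  Missing detection p-values count as
#' undetected (reported via `message()`).
#'
#' @param detectionP samples x genes matrix of detection p-values between 0 and 1.
#' @param condition character vector, condition per sample (row).
#' @param condFrac per-condition detection fraction (default 2.5%).
#' @param allFrac overall detection fraction (default 5%).
#' @param pThresh detection p-value cutoff (default 0.01).
#' @return character vector (or column indices if unnamed) of kept genes.
#' @export
detectabilityFilter <- function(detectionP, condition, condFrac = 0.025,
                                allFrac = 0.05, pThresh = 0.01) {
  stopifnot(nrow(detectionP) == length(condition))
  nMiss <- sum(is.na(detectionP))
  if (nMiss > 0)
    message(nMiss, " missing detection p-value(s) treated as undetected")
  det <- !is.na(detectionP) & detectionP <= pThresh
  inAll <- colMeans(det) >= allFrac
  inCond <- rep(FALSE, ncol(detectionP))
  for (cond in unique(condition)) {
    rows <- condition == cond
    inCond <- inCond | colMeans(det[rows, , drop = FALSE]) >= condFrac
  }
  keep <- inCond | inAll
  if (!is.null(colnames(detectionP))) colnames(detectionP)[keep] else which(keep)
}

#' Select one probe per gene
#'
#' For genes measured by several probes, keeps the probe with the highest
#' mean intensity; exact ties are broken towards the lexicographically
#' smallest probe id so the choice is deterministic.
#'
#' @param mat samples x probes intensity matrix (colnames = probe ids).
#' @param probeGene named character: gene id per probe id.
#' @return character vector of kept probe ids (one per gene).
#' @export
selectProbePerGene <- function(mat, probeGene) {
  stopifnot(all(colnames(mat) %in% names(probeGene)))
  means <- colMeans(mat, na.rm = TRUE)
  df <- data.frame(probe = colnames(mat),
                   gene = probeGene[colnames(mat)],
                   mean = means, stringsAsFactors = FALSE)
  df <- df[order(df$gene, -df$mean, df$probe), ]
  df$probe[!duplicated(df$gene)]
}

#' Quantile normalisation followed by log2
#'
#' Forces every sample (row) to the cross-sample mean quantile distribution,
#' then log2-transforms.  Inputs must be positive intensities (assumed
#' background-corrected); a non-positive value after normalisation is an
#' error.
#'
#' @param mat samples x genes positive intensity matrix.
#' @return the normalised, log2-scale matrix.
#' @export
quantileNormaliseLog2 <- function(mat) {
  if (any(mat <= 0, na.rm = TRUE))
    stop("quantile normalisation expects positive intensities")
  qn <- t(limma::normalizeQuantiles(t(mat)))
  if (any(qn <= 0, na.rm = TRUE))
    stop("non-positive value after quantile normalisation")
  dimnames(qn) <- dimnames(mat)
  log2(qn)
}

#' Rank-based inverse normal transform (Blom offset)
#'
#' Maps a vector to normal quantiles `qnorm((rank - 3/8) / (n + 1/4))` with
#' average ranks for ties, so each transformed gene is standard-normal-like.
#'
#' @param x numeric vector, length >= 3, not constant.
#' @return the transformed vector.
#' @export
inverseNormalTransform <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 3) stop("inverse normal transform needs n >= 3")
  if (length(unique(x[ok])) == 1L) stop("cannot rank a constant vector")
  r <- rank(x[ok], ties.method = "average")
  out <- rep(NA_real_, length(x))
  out[ok] <- qnorm((r - 3 / 8) / (sum(ok) + 1 / 4))
  out
}

#' Apply the inverse normal transform per gene within each condition
#'
#' @param study an [ExpressionStudy-class].
#' @return the study with the `exprs` assay replaced by its per-condition,
#'   per-gene rank-based inverse normal transform.
#' @export
intTransformStudy <- function(study) {
  a <- SummarizedExperiment::assay(study, "exprs")
  cond <- sampleSheet(study)$condition
  for (cn in unique(cond)) {
    cols <- cond == cn
    a[, cols] <- t(apply(a[, cols, drop = FALSE], 1, inverseNormalTransform))
  }
  SummarizedExperiment::assay(study, "exprs") <- a
  study
}

#' Outlier sample filter on detectable-probe counts
#'
#' Removes samples whose number of detectable probes lies outside
#' median +/- 2 x IQR.
#'
#' @param counts named numeric vector of detectable-probe counts per sample.
#' @return names (or indices) of the kept samples.
#' @export
outlierSampleFilter <- function(counts) {
  med <- median(counts)
  iqr <- stats::IQR(counts)
  keep <- counts >= med - 2 * iqr & counts <= med + 2 * iqr
  if (!is.null(names(counts))) names(counts)[keep] else which(keep)
}

#' Probe missingness filter
#'
#' Drops probes with missing values in at least `maxMissingSamples` samples.
#'
#' @param mat samples x probes matrix.
#' @param maxMissingSamples threshold (default 5; missing in >= 5 samples
#'   drops the probe).
#' @return column names (or indices) of kept probes.
#' @export
probeMissingnessFilter <- function(mat, maxMissingSamples = 5) {
  nMiss <- colSums(is.na(mat))
  keep <- nMiss < maxMissingSamples
  if (!is.null(colnames(mat))) colnames(mat)[keep] else which(keep)
}

#' Latent technical factors as per-condition expression principal components
#'
#' Computes the top `nFactors` principal components of the (inverse-normal
#' transformed) expression of each condition and writes them into the sample
#' sheet as covariates `f1..fk`, replacing any existing columns of the same
#' name.  This plays the role usually taken by latent-factor models of
#' technical variation, deterministically.
#'
#' @param study an [ExpressionStudy-class] (INT-transformed for eQTL use).
#' @param nFactors number of components (default 10).
#' @return the study with factor covariates filled in and registered in
#'   `covariateNames`.
#' @export
addExpressionFactors <- function(study, nFactors = 10L) {
  cd <- SummarizedExperiment::colData(study)
  a <- SummarizedExperiment::assay(study, "exprs")
  fnames <- paste0("f", seq_len(nFactors))
  for (fn in fnames) cd[[fn]] <- NA_real_
  for (cond in unique(cd$condition)) {
    cols <- which(cd$condition == cond)
    x <- t(a[, cols, drop = FALSE])
    x <- sweep(x, 2, colMeans(x))
    pc <- svd(x, nu = nFactors, nv = 0)$u[, seq_len(nFactors), drop = FALSE]
    for (k in seq_len(nFactors)) cd[cols, fnames[k]] <- pc[, k]
  }
  SummarizedExperiment::colData(study) <- cd
  study@covariateNames <- union(study@covariateNames, fnames)
  validObject(study)
  study
}
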