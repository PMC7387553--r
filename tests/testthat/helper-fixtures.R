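# Shared fixtures and independent oracles used across test files.

# A small but complete synthetic study (panel + truth + study), cached per
# seed within one test run.
smallCfg <- function(seed = 1, ...) {
  simConfig(nIndividuals = 60L, nGenes = 30L, nSnps = 200L, nCisEqtls = 8L,
            nReqtls = 3L, nSignflipReqtls = 1L, nTransTrios = 2L,
            seed = seed, ...)
}

# Panel built directly from a dosage matrix (bypasses the generator).
toyPanel <- function(dosage, chrom = NULL, pos = NULL) {
  m <- ncol(dosage)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  ids <- sprintf("s%03d", seq_len(m))
  colnames(dosage) <- ids
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("ind", seq_len(nrow(dosage)))
  genotypePanel(dosage, data.frame(
    snp_id = ids, chrom = chrom, pos = pos, ref = rep("A", m),
    alt = rep("G", m), stringsAsFactors = FALSE))
}

# Brute-force BH step-up: largest k with p_(k) <= k*alpha/m rejects p_(1..k).
bruteForceBH <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- suppressWarnings(max(which(ps <= seq_len(m) * alpha / m)))
  reject <- rep(FALSE, m)
  if (is.finite(k)) reject[o[seq_len(k)]] <- TRUE
  reject
}

# Direct single-block eigendecomposition oracle for the effective test count.
effectiveTestsOracle <- function(dosage, varExplained = 0.99) {
  keep <- apply(dosage, 2, var) > 0
  ev <- eigen(cor(dosage[, keep, drop = FALSE]), symmetric = TRUE,
              only.values = TRUE)$values
  unname(which(cumsum(pmax(ev, 0)) / sum(pmax(ev, 0)) >=
                 varExplained - 1e-12)[1])
}
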