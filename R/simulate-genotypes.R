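#' @include constructors.R
NULL

# P(Z1 > tau, Z2 > tau) for standard bivariate normal with correlation rho,
# by one-dimensional quadrature (no external bivariate-normal dependency).
bivarUpperTail <- function(tau, rho) {
  if (abs(rho) < 1e-12) return(pnorm(tau, lower.tail = FALSE)^2)
  f <- function(z) dnorm(z) * pnorm((rho * z - tau) / sqrt(1 - rho^2))
  stats::integrate(f, lower = tau, upper = Inf, rel.tol = 1e-9)$value
}

# Correlation between the two threshold indicators I(Z > tau) induced by a
# latent correlation rho.
indicatorCor <- function(tau, rho) {
  p <- pnorm(tau, lower.tail = FALSE)
  (bivarUpperTail(tau, rho) - p^2) / (p * (1 - p))
}

# Latent (copula) correlation needed so that allele indicators at allele
# frequency p attain a target dosage correlation.  Thresholding attenuates
# correlation, so the latent value must exceed the target.  Root finding is
# cached on a rounded frequency grid (the attenuation varies slowly in p).
.latentRhoCache <- new.env(parent = emptyenv())

calibrateLatentRho <- function(p, targetR) {
  if (targetR <= 0) return(0)
  pKey <- round(p, 3)
  key <- paste(pKey, signif(targetR, 6))
  hit <- .latentRhoCache[[key]]
  if (!is.null(hit)) return(hit)
  tau <- qnorm(1 - pKey)
  f <- function(rho) indicatorCor(tau, rho) - targetR
  upper <- 0.9999
  rho <- if (f(upper) < 0) upper  # target not attainable; saturate
    else stats::uniroot(f, lower = targetR, upper = upper, tol = 1e-6)$root
  .latentRhoCache[[key]] <- rho
  rho
}

# One block of haplotype latent variables with AR(1) latent correlation.
arLatent <- function(n, m, rho) {
  Z <- matrix(rnorm(n * m), n, m)
  if (rho > 0 && m > 1) {
    s <- sqrt(1 - rho^2)
    for (j in 2:m) Z[, j] <- rho * Z[, j - 1] + s * Z[, j]
  }
  Z
}

# Draw dosages for one LD block: two latent haplotypes per individual,
# thresholded at the Hardy-Weinberg quantile of the alternative-allele
# frequency, then summed.
drawBlockDosage <- function(n, m, p, latentRho) {
  tau <- qnorm(1 - p)
  (arLatent(n, m, latentRho) > tau) + (arLatent(n, m, latentRho) > tau)
}

# Partition SNP indices into LD blocks that never span chromosomes.
blockLayout <- function(nSnps, nChromosomes, blockSize) {
  perChrom <- diff(round(seq(0, nSnps, length.out = nChromosomes + 1)))
  blocks <- list(); idx <- 0L
  for (ch in seq_len(nChromosomes)) {
    nc <- perChrom[ch]
    if (nc == 0L) next
    for (grp in chunkIndices(nc, blockSize)) {
      blocks[[length(blocks) + 1L]] <-
        list(chrom = as.character(ch), idx = idx + grp)
    }
    idx <- idx + nc
  }
  blocks
}

#' Simulate a genotype panel with block LD structure
#'
#' Genotypes are generated with a Gaussian copula per LD block: two latent
#' haplotype vectors per individual follow an AR(1) process whose latent
#' correlation is calibrated numerically so that the *dosage* correlation of
#' adjacent SNPs matches `withinBlockR(cfg)` despite threshold attenuation.
#' Each latent variable is thresholded at the Hardy-Weinberg quantile of the
#' block's alternative-allele frequency (drawn from `mafRange`) and the two
#' haplotypes summed to a 0/1/2 dosage.  Blocks whose realised sample MAF
#' falls below 0.08, or that come out monomorphic, are redrawn (monomorphic
#' redraws are reported via `message()`).
#'
#' @param cfg a [SimConfig-class].
#' @return a [GenotypePanel-class]; `meta(panel)$blocks` records the per-block
#'   allele frequency and latent correlation so that additional cohorts (e.g.
#'   a GWAS sample) can be drawn from the same population.
#' @examples
#' panel <- simulateGenotypes(simConfig(nIndividuals = 50, nSnps = 60, seed = 1))
#' @export
simulateGenotypes <- function(cfg) {
  set.seed(stageSeed(cfg@seed, "genotypes"))
  n <- cfg@nIndividuals
  if (cfg@nSnps == 0L) {
    return(genotypePanel(
      matrix(numeric(0), nrow = n, ncol = 0,
             dimnames = list(paste0("ind", seq_len(n)), NULL)),
      data.frame(snp_id = character(), chrom = character(), pos = integer(),
                 ref = character(), alt = character(), maf = numeric()),
      meta = list(blocks = list())))
  }
  blocks <- blockLayout(cfg@nSnps, cfg@nChromosomes, cfg@ldBlockSize)
  dosage <- matrix(0, n, cfg@nSnps)
  blockMeta <- vector("list", length(blocks))
  nMono <- 0L
  for (b in seq_along(blocks)) {
    blk <- blocks[[b]]
    m <- length(blk$idx)
    for (try in seq_len(200L)) {
      p <- runif(1, cfg@mafRange[1], cfg@mafRange[2])
      latentRho <- calibrateLatentRho(p, cfg@withinBlockR)
      d <- drawBlockDosage(n, m, p, latentRho)
      f <- colMeans(d) / 2
      mono <- any(f == 0 | f == 1)
      if (mono) nMono <- nMono + 1L
      if (!mono && (n < 25 || all(pmin(f, 1 - f) >= 0.08))) break
    }
    dosage[, blk$idx] <- d
    blockMeta[[b]] <- list(chrom = blk$chrom, idx = blk$idx, p = p,
                           latentRho = latentRho)
  }
  if (nMono > 0) message(nMono, " monomorphic block draw(s) were resampled")
  chrom <- character(cfg@nSnps); pos <- integer(cfg@nSnps)
  for (blk in blocks) chrom[blk$idx] <- blk$chrom
  # positions restart on each chromosome, evenly spaced
  for (ch in unique(chrom)) {
    onCh <- which(chrom == ch)
    pos[onCh] <- 50000L + (seq_along(onCh) - 1L) * cfg@snpSpacingBp
  }
  snps <- data.frame(
    snp_id = sprintf("rs%05d", seq_len(cfg@nSnps)),
    chrom = chrom, pos = pos,
    ref = "A", alt = "G", stringsAsFactors = FALSE)
  rownames(dosage) <- paste0("ind", seq_len(n))
  colnames(dosage) <- snps$snp_id
  genotypePanel(dosage, snps,
                meta = list(blocks = blockMeta,
                            snpSpacingBp = cfg@snpSpacingBp))
}
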