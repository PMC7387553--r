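#' @include simulate-expression.R
NULL

# Regenerate dosages for one stored block in a fresh cohort, reproducibly
# given (seed, block index).
regenBlock <- function(blockMeta, b, nGwas, seed) {
  set.seed(stageSeed(seed, paste0("gwasblock", b)))
  blk <- blockMeta[[b]]
  drawBlockDosage(nGwas, length(blk$idx), blk$p, blk$latentRho)
}

#' Simulate GWAS summary statistics from a liability model
#'
#' Draws an independent cohort of `nGwas` individuals from the same LD-block
#' population as `panel` (using the block parameters stored by
#' [simulateGenotypes()]), builds a disease liability from (i) the planted
#' GWAS-locus SNP effects and (ii) the planted causal genes, whose effect is
#' transmitted through the genetic component of their expression (their
#' planted cis-eQTL SNPs), and regresses the liability on every SNP to
#' produce marginal beta, SE and p per SNP.  Memory stays bounded by
#' generating blocks twice from per-block seeds: once to assemble the
#' liability, once to compute the per-SNP statistics.
#'
#' @param panel a [GenotypePanel-class] from [simulateGenotypes()].
#' @param truth a [TruthTable-class].
#' @param nGwas GWAS cohort size (>= 1000 recommended).
#' @param seed RNG seed for the GWAS cohort.
#' @param diseases diseases to emit (default: all named in the truth).
#' @return named list of data.frames, one per disease, with columns `snp_id`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, `beta`, `se`, `p`, `n`.
#' @export
simulateGwas <- function(panel, truth, nGwas = 20000L, seed = 1L,
                         diseases = NULL) {
  blocks <- panel@meta$blocks
  if (is.null(blocks))
    stop("panel lacks generator block metadata; use simulateGenotypes()")
  snps <- snpInfo(panel)
  loci <- gwasLociTruth(truth); cg <- causalGeneTruth(truth)
  cis <- cisTruth(truth)
  if (is.null(diseases)) {
    diseases <- unique(c(loci$disease, cg$disease))
    if (!length(diseases)) diseases <- "disease1"
  }
  badSnp <- setdiff(loci$causal_snp, snps$snp_id)
  if (length(badSnp)) stop("GWAS truth refers to unknown SNP(s): ",
                           paste(badSnp, collapse = ", "))
  out <- list()
  for (dis in diseases) {
    # SNPs with a direct liability effect, and per-allele effects inherited
    # through causal genes' cis-eQTLs
    direct <- loci[loci$disease == dis, , drop = FALSE]
    eff <- setNames(direct$gamma, direct$causal_snp)
    genes <- cg[cg$disease == dis, , drop = FALSE]
    if (nrow(genes)) {
      for (j in seq_len(nrow(genes))) {
        pairs <- cis[cis$gene_id == genes$gene_id[j], , drop = FALSE]
        for (k in seq_len(nrow(pairs))) {
          s <- pairs$snp_id[k]
          add <- genes$effect[j] * pairs$beta_resting[k]
          eff[s] <- if (s %in% names(eff)) eff[[s]] + add else add
        }
      }
    }
    effIdx <- match(names(eff), snps$snp_id)
    # pass 1: liability from the effect SNPs only
    set.seed(stageSeed(seed, paste0("gwasnoise_", dis)))
    y <- rnorm(nGwas)
    if (length(eff)) {
      for (b in seq_along(blocks)) {
        hit <- which(effIdx %in% blocks[[b]]$idx)
        if (!length(hit)) next
        d <- regenBlock(blocks, b, nGwas, seed)
        for (h in hit) {
          col <- match(effIdx[h], blocks[[b]]$idx)
          y <- y + eff[[h]] * d[, col]
        }
      }
    }
    # pass 2: marginal OLS of liability on every SNP
    beta <- se <- numeric(nrow(snps))
    for (b in seq_along(blocks)) {
      d <- regenBlock(blocks, b, nGwas, seed)
      dc <- sweep(d, 2, colMeans(d))
      xx <- colSums(dc^2)
      xy <- as.vector(crossprod(dc, y - mean(y)))
      bb <- xy / xx
      rss <- pmax(sum((y - mean(y))^2) - bb^2 * xx, 0)
      beta[blocks[[b]]$idx] <- bb
      se[blocks[[b]]$idx] <- sqrt(rss / (nGwas - 2) / xx)
    }
    tval <- beta / se
    out[[dis]] <- data.frame(
      snp_id = snps$snp_id, chrom = snps$chrom, pos = snps$pos,
      effect_allele = snps$alt, other_allele = snps$ref,
      beta = beta, se = se, p = 2 * pt(-abs(tval), df = nGwas - 2),
      n = nGwas, stringsAsFactors = FALSE)
  }
  out
}

#' Flip the reported allele orientation of GWAS rows
#'
#' Emulates an external study that reports the other allele as the effect
#' allele: swaps `effect_allele`/`other_allele` and negates `beta` for the
#' selected SNPs.  Harmonisation ([harmoniseInstruments()]) restores the
#' original orientation, so flipping is an involution up to harmonisation.
#'
#' @param gwas a GWAS summary data.frame.
#' @param snpIds SNPs to flip; default all.
#' @return the flipped data.frame.
#' @export
flipGwasAlleles <- function(gwas, snpIds = gwas$snp_id) {
  i <- gwas$snp_id %in% snpIds
  ea <- gwas$effect_allele[i]
  gwas$effect_allele[i] <- gwas$other_allele[i]
  gwas$other_allele[i] <- ea
  gwas$beta[i] <- -gwas$beta[i]
  gwas
}
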