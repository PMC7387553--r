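#' @include mediation.R
NULL

#' Wakefield log approximate Bayes factor
#'
#' For an estimate `beta` with standard error `se` and prior effect variance
#' `W`, with `z = beta/se`, `V = se^2` and shrinkage `r = W/(W+V)`:
#' `log ABF = 0.5*log(1 - r) + z^2*r/2`, the log Bayes factor for
#' association against the null.
#'
#' @param beta,se effect estimate and standard error (`se > 0`).
#' @param W prior variance of the true effect.
#' @return the log ABF (vectorised).
#' @export
logAbf <- function(beta, se, W) {
  if (any(se <= 0)) stop("standard errors must be positive")
  z <- beta / se
  r <- W / (W + se^2)
  0.5 * log(1 - r) + z^2 * r / 2
}

#' Colocalisation priors
#'
#' @param p1,p2 prior probability that a SNP is causal for trait 1 / trait 2
#'   only (default 1e-4).
#' @param p12 prior that a SNP is causal for both (default 1e-6, the
#'   conservative choice; must not exceed `min(p1, p2)`).
#' @param W1 prior effect variance for trait 1 (default 0.15^2, quantitative
#'   trait scale).
#' @param W2 prior effect variance for trait 2 (default 0.2^2, log-odds
#'   scale for a binary trait).
#' @return a validated list of priors.
#' @export
colocPriors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-6,
                        W1 = 0.15^2, W2 = 0.2^2) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1, p12 > 0, p12 < 1)
  if (p12 > min(p1, p2)) stop("p12 must not exceed min(p1, p2)")
  list(p1 = p1, p2 = p2, p12 = p12, W1 = W1, W2 = W2)
}

#' Posterior probabilities of the five colocalisation hypotheses
#'
#' Enumerates single-causal-variant configurations over the shared SNP set:
#' H0 no causal variant for either trait, H1/H2 a causal variant for the
#' eQTL/GWAS trait only, H3 distinct causal variants, H4 one shared causal
#' variant.  Per-SNP evidence enters through Wakefield log ABFs; sums over
#' configurations use log-sum-exp throughout.  The decision applies the
#' power filter first (`underpowered` when `PP3 + PP4 < 0.8`), then the
#' ratio rule (`colocalised` when `PP4 / PP3 >= 5`, else `distinct`).
#'
#' @param eqtl,gwas data.frames with `snp_id`, `beta`, `se` over an aligned,
#'   harmonised SNP set.
#' @param priors from [colocPriors()].
#' @return list with `pp` (named PP0..PP4, summing to 1), `decision`,
#'   `n_snps`.
#' @export
colocPosteriors <- function(eqtl, gwas, priors = colocPriors()) {
  shared <- intersect(eqtl$snp_id, gwas$snp_id)
  if (length(shared) == 0L) stop("no shared SNPs between the two traits")
  e <- eqtl[match(shared, eqtl$snp_id), ]
  g <- gwas[match(shared, gwas$snp_id), ]
  l1 <- logAbf(e$beta, e$se, priors$W1)
  l2 <- logAbf(g$beta, g$se, priors$W2)
  s1 <- logSumExp(l1); s2 <- logSumExp(l2); s12 <- logSumExp(l1 + l2)
  nS <- length(shared)
  lH <- c(
    H0 = 0,
    H1 = log(priors$p1) + s1,
    H2 = log(priors$p2) + s2,
    H3 = if (nS > 1) {
      # sum over i != j of exp(l1_i + l2_j)
      both <- s1 + s2
      log(priors$p1) + log(priors$p2) +
        both + log1p(-exp(s12 - both))
    } else -Inf,
    H4 = log(priors$p12) + s12)
  pp <- exp(lH - logSumExp(lH))
  pp <- pp / sum(pp)
  names(pp) <- paste0("PP", 0:4)
  decision <- if (pp[["PP3"]] + pp[["PP4"]] < 0.8) "underpowered"
    else if (pp[["PP3"]] == 0 || pp[["PP4"]] / pp[["PP3"]] >= 5) "colocalised"
    else "distinct"
  list(pp = pp, decision = decision, n_snps = nS)
}

#' Select loci for colocalisation testing
#'
#' A locus is formed around the top cis-eSNP of each eGene whose significant
#' eSNP set contains a SNP with GWAS p-value at or below `gwasP`.  The SNP
#' set is the intersection of the eQTL and GWAS summary sets within an
#' inclusive `window`-bp window centred on the top eSNP (+/- window/2); loci
#' with fewer than `minSnps` shared SNPs are skipped with status
#' `"skipped"`.
#'
#' @param egenes `egenes` data.frame from [mapCisEqtls()] (significant rows
#'   used).
#' @param esnps significant eSNP list from [mapCisEqtls()].
#' @param gwas GWAS summary data.frame (`snp_id`, `p`, ...).
#' @param snps SNP table of the panel (`snp_id`, `chrom`, `pos`).
#' @param gwasP GWAS significance threshold for locus selection (default
#'   1e-6).
#' @param window full window width in bp (default 400 kb).
#' @param minSnps minimum shared SNPs (default 25).
#' @return data.frame `gene_id`, `top_snp`, `n_snps`, `status`, with the
#'   per-locus shared SNP ids as a list column `snp_ids`.
#' @export
selectColocLoci <- function(egenes, esnps, gwas, snps, gwasP = 1e-6,
                            window = 400000, minSnps = 25L) {
  sig <- egenes[egenes$is_egene, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(sig))) {
    g <- sig$gene_id[i]
    es <- esnps[[g]]
    gp <- gwas$p[match(es, gwas$snp_id)]
    if (!any(!is.na(gp) & gp <= gwasP)) next
    top <- sig$top_snp[i]
    ti <- match(top, snps$snp_id)
    inWin <- snps$snp_id[snps$chrom == snps$chrom[ti] &
                         abs(snps$pos - snps$pos[ti]) <= window / 2]
    shared <- intersect(inWin, gwas$snp_id)
    status <- if (length(shared) < minSnps) "skipped" else "selected"
    out[[length(out) + 1L]] <- data.frame(
      gene_id = g, top_snp = top, n_snps = length(shared), status = status,
      snp_ids = I(list(shared)), stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(gene_id = character(), top_snp = character(),
                      n_snps = integer(), status = character(),
                      snp_ids = I(list()), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Sensitivity of the colocalisation decision to the p12 prior
#'
#' Recomputes the posteriors over a log-spaced grid of `p12` values
#' (default 1e-9 to 1e-5) and reports whether the decision is unchanged
#' across the grid.  PP4 is monotone non-decreasing in p12.
#'
#' @inheritParams colocPosteriors
#' @param grid p12 values (default 9 points, 1e-9..1e-5 log-spaced).
#' @return list with `table` (data.frame `p12`, `PP3`, `PP4`, `decision`)
#'   and `robust` (logical: decision identical across the grid).
#' @export
p12Sensitivity <- function(eqtl, gwas, priors = colocPriors(),
                           grid = 10^seq(-9, -5, length.out = 9)) {
  rows <- lapply(grid, function(p12) {
    pr <- colocPriors(p1 = priors$p1, p2 = priors$p2, p12 = p12,
                      W1 = priors$W1, W2 = priors$W2)
    res <- colocPosteriors(eqtl, gwas, pr)
    data.frame(p12 = p12, PP3 = res$pp[["PP3"]], PP4 = res$pp[["PP4"]],
               decision = res$decision, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  list(table = tab, robust = length(unique(tab$decision)) == 1L)
}

#' Harmonise GWAS summary rows to the eQTL allele orientation
#'
#' Flips the GWAS beta when its effect/other alleles are swapped relative to
#' the eQTL alt/ref; drops strand-ambiguous (A/T, C/G) SNPs and allele
#' mismatches.
#'
#' @param gwas GWAS summary data.frame with `snp_id`, `effect_allele`,
#'   `other_allele`, `beta`.
#' @param snps panel SNP table (`snp_id`, `ref`, `alt`).
#' @return the harmonised GWAS subset (effect allele = panel alt).
#' @export
harmoniseGwasToPanel <- function(gwas, snps) {
  m <- match(gwas$snp_id, snps$snp_id)
  keep <- !is.na(m)
  gwas <- gwas[keep, , drop = FALSE]; m <- m[keep]
  pal <- paste0(gwas$effect_allele, gwas$other_allele) %in%
    c("AT", "TA", "CG", "GC")
  sameOrient <- gwas$effect_allele == snps$alt[m] &
    gwas$other_allele == snps$ref[m]
  swapped <- gwas$effect_allele == snps$ref[m] &
    gwas$other_allele == snps$alt[m]
  gwas$beta[swapped] <- -gwas$beta[swapped]
  ea <- gwas$effect_allele[swapped]
  gwas$effect_allele[swapped] <- gwas$other_allele[swapped]
  gwas$other_allele[swapped] <- ea
  gwas[!pal & (sameOrient | swapped), , drop = FALSE]
}
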