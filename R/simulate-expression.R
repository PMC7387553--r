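#' @include simulate-genotypes.R
NULL

#' Deterministic gene annotation for a simulated study
#'
#' Places `nGenes(cfg)` genes on the simulated chromosomes with TSS drawn
#' uniformly over each chromosome's SNP span (so that every gene has cis SNPs
#' within 1 Mb).  Deterministic given the configuration seed.
#'
#' @param cfg a [SimConfig-class].
#' @return data.frame with `gene_id`, `chrom`, `tss`.
#' @export
geneAnnotation <- function(cfg) {
  set.seed(stageSeed(cfg@seed, "genes"))
  nPerChrom <- diff(round(seq(0, cfg@nSnps, length.out = cfg@nChromosomes + 1)))
  span <- 50000L + pmax(nPerChrom - 1L, 0L) * cfg@snpSpacingBp
  chrom <- as.character(rep(seq_len(cfg@nChromosomes), length.out = cfg@nGenes))
  tss <- integer(cfg@nGenes)
  for (ch in seq_len(cfg@nChromosomes)) {
    onCh <- which(chrom == as.character(ch))
    tss[onCh] <- sort(sample(seq(50000L, span[ch]), length(onCh), replace = TRUE))
  }
  data.frame(gene_id = sprintf("gene%04d", seq_len(cfg@nGenes)),
             chrom = chrom, tss = tss, stringsAsFactors = FALSE)
}

#' Plant ground-truth effects into a simulated study
#'
#' Chooses cis eQTL gene-SNP pairs (SNP within 1 Mb of the gene TSS), marks a
#' subset as response eQTLs (different effect in the stimulated condition of
#' the pair's cell type) including sign flips, builds cis-mediated trans trios
#' (exposure SNP -> cis mediator gene -> trans gene on another chromosome),
#' GWAS loci that share or do not share their causal SNP with an eQTL, and
#' genes with a causal effect on a disease liability.
#'
#' @param panel a [GenotypePanel-class] from [simulateGenotypes()].
#' @param cfg the [SimConfig-class] used to build the panel.
#' @param genes gene annotation, normally [geneAnnotation()] of `cfg`.
#' @param nSharedLoci,nDistinctLoci GWAS loci whose causal SNP is / is not an
#'   eQTL causal SNP.
#' @param nCausalGenes genes given a causal effect on the disease liability.
#' @param diseases disease labels to cycle GWAS loci over.
#' @return a [TruthTable-class].
#' @export
plantTruth <- function(panel, cfg, genes = geneAnnotation(cfg),
                       nSharedLoci = 4L, nDistinctLoci = 2L,
                       nCausalGenes = 2L, diseases = "disease1") {
  set.seed(stageSeed(cfg@seed, "truth"))
  snps <- snpInfo(panel)
  cis <- emptyCisTruth()
  if (cfg@nCisEqtls > 0L) {
    eligible <- which(vapply(seq_len(nrow(genes)), function(i) {
      any(snps$chrom == genes$chrom[i] & abs(snps$pos - genes$tss[i]) <= 1e6)
    }, logical(1)))
    pick <- sample(eligible, min(cfg@nCisEqtls, length(eligible)))
    snpPick <- vapply(pick, function(i) {
      cand <- which(snps$chrom == genes$chrom[i] &
                    abs(snps$pos - genes$tss[i]) <= 1e6)
      sample(cand, 1L)
    }, integer(1))
    k <- length(pick)
    betaRest <- rnorm(k, 0, cfg@effectSizeSd)
    betaStim <- betaRest
    isReqtl <- rep(FALSE, k); isFlip <- rep(FALSE, k)
    if (cfg@nReqtls > 0L) {
      re <- sample(k, min(cfg@nReqtls, k))
      isReqtl[re] <- TRUE
      betaStim[re] <- betaRest[re] + rnorm(length(re), 0, cfg@effectSizeSd)
      nf <- min(cfg@nSignflipReqtls, length(re))
      if (nf > 0L) {
        fl <- re[seq_len(nf)]
        isFlip[fl] <- TRUE
        betaStim[fl] <- -betaRest[fl]
      }
      # reQTLs whose perturbed beta landed on the same value are still reQTLs
      same <- isReqtl & betaStim == betaRest
      betaStim[same] <- betaRest[same] + cfg@effectSizeSd
    }
    cis <- data.frame(
      gene_id = genes$gene_id[pick], snp_id = snps$snp_id[snpPick],
      cell_type = sample(unique(cfg@conditionTable$cell_type), k, replace = TRUE),
      beta_resting = betaRest, beta_stimulated = betaStim,
      is_reqtl = isReqtl, is_signflip = isFlip, stringsAsFactors = FALSE)
  }
  trans <- emptyTransTruth()
  if (cfg@nTransTrios > 0L && nrow(cis) > 0L) {
    src <- which(!cis$is_reqtl)
    if (length(src) < cfg@nTransTrios) src <- seq_len(nrow(cis))
    src <- head(src, cfg@nTransTrios)
    used <- cis$gene_id
    transGene <- character(0)
    for (i in src) {
      geneCh <- genes$chrom[match(cis$gene_id[i], genes$gene_id)]
      snpCh <- snps$chrom[match(cis$snp_id[i], snps$snp_id)]
      cand <- genes$gene_id[genes$chrom != snpCh & genes$chrom != geneCh &
                            !(genes$gene_id %in% c(used, transGene))]
      if (!length(cand)) next
      transGene <- c(transGene, sample(cand, 1L))
    }
    src <- src[seq_along(transGene)]
    if (length(src)) {
      trans <- data.frame(
        snp_id = cis$snp_id[src], cis_gene = cis$gene_id[src],
        trans_gene = transGene, cell_type = cis$cell_type[src],
        a = cis$beta_resting[src],
        b = sample(c(-1, 1), length(src), replace = TRUE) *
          runif(length(src), 0.6, 1.0),
        c_prime = rnorm(length(src), 0, 0.15), stringsAsFactors = FALSE)
    }
  }
  gwasLoci <- emptyGwasLociTruth()
  nLoci <- nSharedLoci + nDistinctLoci
  if (nLoci > 0L && nrow(cis) > 0L) {
    take <- sample(nrow(cis), min(nLoci, nrow(cis)))
    shared <- seq_along(take) <= min(nSharedLoci, length(take))
    causal <- character(length(take))
    for (j in seq_along(take)) {
      eqtlSnp <- cis$snp_id[take[j]]
      if (shared[j]) {
        causal[j] <- eqtlSnp
      } else {
        i <- match(eqtlSnp, snps$snp_id)
        cand <- which(snps$chrom == snps$chrom[i] &
                      abs(snps$pos - snps$pos[i]) <= 2e5 &
                      snps$snp_id != eqtlSnp)
        causal[j] <- if (length(cand)) snps$snp_id[sample(cand, 1L)] else eqtlSnp
      }
    }
    gwasLoci <- data.frame(
      locus_id = sprintf("locus%02d", seq_along(take)),
      disease = rep(diseases, length.out = length(take)),
      causal_snp = causal, eqtl_snp = cis$snp_id[take],
      shared_with_eqtl = shared,
      gamma = sample(c(-1, 1), length(take), replace = TRUE) *
        runif(length(take), 0.08, 0.15), stringsAsFactors = FALSE)
  }
  causalGenes <- emptyCausalGeneTruth()
  if (nCausalGenes > 0L && nrow(cis) > 0L) {
    cg <- sample(cis$gene_id, min(nCausalGenes, nrow(cis)))
    causalGenes <- data.frame(
      gene_id = cg, disease = rep(diseases, length.out = length(cg)),
      effect = sample(c(-1, 1), length(cg), replace = TRUE) *
        runif(length(cg), 0.15, 0.3), stringsAsFactors = FALSE)
  }
  truthTable(cis = cis, trans = trans, gwasLoci = gwasLoci,
             causalGenes = causalGenes)
}

#' Simulate paired-condition expression with planted effects
#'
#' Expression for each gene is the sum of covariate effects (sex, three
#' genotype-PC proxies, ten latent factors with small loadings on all genes),
#' a per-gene condition main effect, the planted condition-specific genotype
#' effect, an individual random intercept shared across that individual's
#' paired samples, trans trio contributions (b times the realised mediator
#' expression plus the direct effect), and Gaussian noise.  Unequal
#' per-condition sample sizes are produced by retaining
#' `round(retention * nIndividuals)` individuals per condition, always
#' including a common core of `round(coreFraction * nIndividuals)`.
#'
#' @param panel [GenotypePanel-class] the truth refers to.
#' @param truth [TruthTable-class] of planted effects.
#' @param cfg the [SimConfig-class].
#' @param genes gene annotation (defaults to [geneAnnotation()]).
#' @return an [ExpressionStudy-class] whose sample sheet carries the 14
#'   covariates (`sex`, `gpc1`-`gpc3`, `f1`-`f10`) used by the scans.
#' @export
simulateExpression <- function(panel, truth, cfg, genes = geneAnnotation(cfg)) {
  set.seed(stageSeed(cfg@seed, "expression"))
  snps <- snpInfo(panel)
  cis <- cisTruth(truth); trans <- transTruth(truth)
  badSnp <- setdiff(c(cis$snp_id, trans$snp_id), snps$snp_id)
  if (length(badSnp)) stop("truth refers to unknown SNP(s): ",
                           paste(badSnp, collapse = ", "))
  badGene <- setdiff(c(cis$gene_id, trans$cis_gene, trans$trans_gene),
                     genes$gene_id)
  if (length(badGene)) stop("truth refers to unknown gene(s): ",
                            paste(badGene, collapse = ", "))
  n <- cfg@nIndividuals
  inds <- individualIds(panel)
  ct <- cfg@conditionTable
  nCore <- round(cfg@coreFraction * n)
  core <- sample(inds, nCore)
  retained <- lapply(ct$condition, function(cond) {
    target <- round(cfg@retention[[cond]] * n)
    extra <- setdiff(inds, core)
    c(core, sample(extra, max(0, min(target, n) - nCore)))
  })
  names(retained) <- ct$condition

  nGenes <- nrow(genes)
  # individual-level covariates
  sex <- rbinom(n, 1, 0.5)
  gpc <- matrix(rnorm(n * 3), n, 3)
  names(sex) <- rownames(gpc) <- inds
  # gene-level effect sizes
  bSex <- rnorm(nGenes, 0, 0.2)
  bGpc <- matrix(rnorm(nGenes * 3, 0, 0.2), nGenes, 3)
  loadF <- matrix(rnorm(nGenes * 10, 0, 0.2), nGenes, 10)
  condEff <- matrix(rnorm(nGenes * nrow(ct), 0, cfg@conditionEffectSd),
                    nGenes, nrow(ct), dimnames = list(NULL, ct$condition))
  u <- matrix(rnorm(n * nGenes, 0, cfg@individualReSd), n, nGenes,
              dimnames = list(inds, genes$gene_id))

  exprList <- list(); sheetList <- list()
  for (ci in seq_len(nrow(ct))) {
    cond <- ct$condition[ci]
    ids <- retained[[cond]]
    m <- length(ids)
    fac <- matrix(rnorm(m * 10), m, 10)
    E <- matrix(0, m, nGenes, dimnames = list(NULL, genes$gene_id))
    E <- E + outer(sex[ids], bSex) + gpc[ids, , drop = FALSE] %*% t(bGpc) +
      fac %*% t(loadF) +
      matrix(condEff[, cond], m, nGenes, byrow = TRUE) + u[ids, , drop = FALSE]
    # planted cis effects: active only in the pair's cell type, with the
    # treatment-specific beta
    if (nrow(cis)) {
      active <- cis[cis$cell_type == ct$cell_type[ci], , drop = FALSE]
      if (nrow(active)) {
        beta <- if (ct$treatment[ci] == "resting") active$beta_resting else
          active$beta_stimulated
        g <- dosages(panel)[ids, active$snp_id, drop = FALSE]
        for (j in seq_len(nrow(active)))
          E[, active$gene_id[j]] <- E[, active$gene_id[j]] + beta[j] * g[, j]
      }
    }
    if (cfg@noiseSd > 0)
      E <- E + matrix(rnorm(m * nGenes, 0, cfg@noiseSd), m, nGenes)
    # trans trios: outcome depends on the realised mediator expression
    if (nrow(trans)) {
      activeT <- trans[trans$cell_type == ct$cell_type[ci], , drop = FALSE]
      for (j in seq_len(nrow(activeT))) {
        g <- dosages(panel)[ids, activeT$snp_id[j]]
        E[, activeT$trans_gene[j]] <- E[, activeT$trans_gene[j]] +
          activeT$b[j] * E[, activeT$cis_gene[j]] + activeT$c_prime[j] * g
      }
    }
    sheet <- data.frame(
      sample_id = paste0(ids, "_", cond), individual_id = ids,
      condition = cond, sex = sex[ids], stringsAsFactors = FALSE)
    sheet[, paste0("gpc", 1:3)] <- gpc[ids, , drop = FALSE]
    sheet[, paste0("f", 1:10)] <- fac
    rownames(E) <- sheet$sample_id
    exprList[[cond]] <- E
    sheetList[[cond]] <- sheet
  }
  samples <- do.call(rbind, sheetList)
  rownames(samples) <- NULL
  exprs <- t(do.call(rbind, exprList))
  covNames <- c("sex", paste0("gpc", 1:3), paste0("f", 1:10))
  covNames <- head(covNames, cfg@nCovariates)
  expressionStudy(exprs, samples, genes, conditionTable = ct,
                  covariateNames = covNames)
}

#' One-call simulation of a complete synthetic study
#'
#' @param cfg a [SimConfig-class].
#' @param ... passed to [plantTruth()].
#' @return list with `panel`, `truth`, `genes`, `study`.
#' @export
simulateStudy <- function(cfg, ...) {
  panel <- simulateGenotypes(cfg)
  genes <- geneAnnotation(cfg)
  truth <- plantTruth(panel, cfg, genes = genes, ...)
  study <- simulateExpression(panel, truth, cfg, genes = genes)
  list(panel = panel, truth = truth, genes = genes, study = study)
}
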