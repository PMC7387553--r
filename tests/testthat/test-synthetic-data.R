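test_that("simulated dosages stay in range and respect the sample MAF floor", {
  cfg <- simConfig(nIndividuals = 2L, nSnps = 3L, nGenes = 5L,
                   nCisEqtls = 0L, nReqtls = 0L, nSignflipReqtls = 0L,
                   nTransTrios = 0L, seed = 1)
  p <- simulateGenotypes(cfg)
  expect_equal(dim(dosages(p)), c(2L, 3L))
  expect_true(all(dosages(p) %in% 0:2))

  cfg2 <- simConfig(nIndividuals = 200L, nSnps = 100L, seed = 2)
  p2 <- simulateGenotypes(cfg2)
  expect_true(all(dosages(p2) >= 0 & dosages(p2) <= 2))
  expect_true(all(snpInfo(p2)$maf >= 0.08))
})

test_that("degenerate configurations give empty panels, not errors", {
  cfg <- simConfig(nSnps = 0L, nGenes = 2L, nCisEqtls = 0L, nReqtls = 0L,
                   nSignflipReqtls = 0L, nTransTrios = 0L, seed = 1)
  p <- simulateGenotypes(cfg)
  expect_equal(ncol(dosages(p)), 0L)
  expect_equal(nrow(dosages(p)), cfg@nIndividuals)
})

test_that("adjacent within-block dosage correlation tracks the target", {
  # independence case: target r = 0
  cfg0 <- simConfig(nIndividuals = 1000L, nSnps = 40L, withinBlockR = 0,
                    seed = 3)
  d0 <- dosages(simulateGenotypes(cfg0))
  adjPairs <- function(cfg, d) {
    blocks <- stimqtl:::blockLayout(ncol(d), cfg@nChromosomes, cfg@ldBlockSize)
    unlist(lapply(blocks, function(b) {
      idx <- b$idx
      if (length(idx) < 2) return(NULL)
      vapply(seq_len(length(idx) - 1L),
             function(j) cor(d[, idx[j]], d[, idx[j + 1]]), numeric(1))
    }))
  }
  expect_lt(mean(abs(adjPairs(cfg0, d0))), 0.1)

  # calibrated case: target r = 0.8, averaged over 20 seeded replicates
  rs <- vapply(1:20, function(s) {
    cfg <- simConfig(nIndividuals = 2000L, nSnps = 30L, withinBlockR = 0.8,
                     seed = s)
    mean(adjPairs(cfg, dosages(simulateGenotypes(cfg))))
  }, numeric(1))
  expect_gt(mean(rs), 0.7)
  expect_lt(mean(rs), 0.9)
})

test_that("expression is null-calibrated when no effects are planted", {
  cfg <- simConfig(nIndividuals = 100L, nGenes = 50L, nSnps = 100L,
                   nCisEqtls = 0L, nReqtls = 0L, nSignflipReqtls = 0L,
                   nTransTrios = 0L, seed = 4)
  sim <- simulateStudy(cfg)
  Y <- exprMatrix(sim$study, "resting_t")
  cd <- sampleSheet(sim$study)
  ids <- cd$individual_id[cd$condition == "resting_t"]
  X <- dosages(sim$panel)[ids, ]
  set.seed(5)
  n <- nrow(Y)
  tstats <- replicate(1000, {
    y <- Y[, sample(ncol(Y), 1)]
    x <- X[, sample(ncol(X), 1)]
    f <- summary(lm(y ~ x))$coefficients
    f["x", "t value"]
  })
  # sampled gene-SNP pairs can repeat, so allow ties in the KS statistic
  ks <- suppressWarnings(stats::ks.test(pt(tstats, df = n - 2), "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("noiseless planted effects are recovered exactly", {
  cfg <- simConfig(nIndividuals = 50L, nGenes = 10L, nSnps = 60L,
                   nCisEqtls = 0L, nReqtls = 0L, nSignflipReqtls = 0L,
                   nTransTrios = 0L, noiseSd = 0, individualReSd = 0,
                   conditionEffectSd = 0, seed = 6)
  panel <- simulateGenotypes(cfg)
  genes <- geneAnnotation(cfg)
  snps <- snpInfo(panel)
  w <- which(snps$chrom == genes$chrom[1] &
             abs(snps$pos - genes$tss[1]) <= 1e6)[1]
  cis <- data.frame(gene_id = genes$gene_id[1], snp_id = snps$snp_id[w],
                    cell_type = "t", beta_resting = 1, beta_stimulated = 1,
                    is_reqtl = FALSE, is_signflip = FALSE)
  truth <- truthTable(cis = cis)
  study <- simulateExpression(panel, truth, cfg, genes = genes)
  y <- exprMatrix(study, "resting_t")[, genes$gene_id[1]]
  cd <- sampleSheet(study)
  rt <- cd[cd$condition == "resting_t", ]
  g <- dosages(panel)[rt$individual_id, snps$snp_id[w]]
  # covariate effects cancel within dosage groups only after adjusting, so
  # regress out the known covariates exactly
  C <- as.matrix(rt[, covariateNames(study)])
  yAdj <- residuals(lm(y ~ C))
  gAdj <- residuals(lm(g ~ C))
  beta <- coef(lm(yAdj ~ gAdj))[2]
  expect_equal(unname(beta), 1, tolerance = 1e-9)
  # and the noiseless dosage-group contrast without covariates at all
  cfg0 <- simConfig(nIndividuals = 50L, nGenes = 10L, nSnps = 60L,
                    nCisEqtls = 0L, nReqtls = 0L, nSignflipReqtls = 0L,
                    nTransTrios = 0L, noiseSd = 0, individualReSd = 0,
                    conditionEffectSd = 0, seed = 6)
  study0 <- simulateExpression(panel, truth, cfg0, genes = genes)
  y0 <- exprMatrix(study0, "resting_t")[, genes$gene_id[1]]
  fit <- lm(y0 ~ g + C)
  expect_equal(unname(coef(fit)["g"]), 1, tolerance = 1e-9)
})

test_that("sign-flip reQTLs yield opposite per-condition slopes", {
  hits <- vapply(1:100, function(s) {
    cfg <- simConfig(nIndividuals = 120L, nGenes = 5L, nSnps = 30L,
                     nCisEqtls = 0L, nReqtls = 0L, nSignflipReqtls = 0L,
                     nTransTrios = 0L, retention = rep(1, 4), seed = 1000 + s)
    panel <- simulateGenotypes(cfg)
    genes <- geneAnnotation(cfg)
    snps <- snpInfo(panel)
    w <- which(snps$chrom == genes$chrom[1] &
               abs(snps$pos - genes$tss[1]) <= 1e6)[1]
    if (is.na(w)) return(NA)
    cis <- data.frame(gene_id = genes$gene_id[1], snp_id = snps$snp_id[w],
                      cell_type = "t", beta_resting = 0.5,
                      beta_stimulated = -0.5, is_reqtl = TRUE,
                      is_signflip = TRUE)
    study <- simulateExpression(panel, truthTable(cis = cis), cfg,
                                genes = genes)
    slope <- function(cond) {
      y <- exprMatrix(study, cond)[, genes$gene_id[1]]
      cd <- sampleSheet(study); cd <- cd[cd$condition == cond, ]
      g <- dosages(panel)[cd$individual_id, snps$snp_id[w]]
      coef(lm(y ~ g))[2]
    }
    slope("resting_t") > 0 && slope("pha_t") < 0
  }, logical(1))
  expect_gte(mean(hits, na.rm = TRUE), 0.95)
})

test_that("sample counts follow the per-condition retention rule", {
  cfg <- smallCfg(seed = 7)
  sim <- simulateStudy(cfg)
  cd <- sampleSheet(sim$study)
  for (cond in conditionNames(sim$study)) {
    expect_equal(sum(cd$condition == cond),
                 round(cfg@retention[[cond]] * cfg@nIndividuals))
  }
  # the complete-case core is present in every condition
  tab <- table(cd$individual_id)
  expect_gte(sum(tab == 4), round(cfg@coreFraction * cfg@nIndividuals) - 1)
})

test_that("identical configuration and seed reproduce identical outputs", {
  a <- simulateStudy(smallCfg(seed = 11))
  b <- simulateStudy(smallCfg(seed = 11))
  expect_identical(dosages(a$panel), dosages(b$panel))
  expect_identical(cisTruth(a$truth), cisTruth(b$truth))
  expect_identical(SummarizedExperiment::assay(a$study),
                   SummarizedExperiment::assay(b$study))
  ga <- simulateGwas(a$panel, a$truth, nGwas = 500, seed = 3)
  gb <- simulateGwas(b$panel, b$truth, nGwas = 500, seed = 3)
  expect_identical(ga, gb)
})

test_that("null GWAS p-values show no genomic inflation", {
  lambdas <- vapply(1:10, function(s) {
    cfg <- simConfig(nIndividuals = 50L, nGenes = 5L, nSnps = 100L,
                     nCisEqtls = 0L, nReqtls = 0L, nSignflipReqtls = 0L,
                     nTransTrios = 0L, seed = 100 + s)
    panel <- simulateGenotypes(cfg)
    truth <- truthTable()  # nothing planted
    g <- simulateGwas(panel, truth, nGwas = 2000, seed = s,
                      diseases = "d")$d
    chisq <- qchisq(g$p, df = 1, lower.tail = FALSE)
    median(chisq) / qchisq(0.5, df = 1)
  }, numeric(1))
  expect_gt(mean(lambdas), 0.9)
  expect_lt(mean(lambdas), 1.1)
})

test_that("shared-causal GWAS loci put the association peak on the eQTL SNP", {
  hits <- vapply(1:10, function(s) {
    cfg <- simConfig(nIndividuals = 60L, nGenes = 10L, nSnps = 60L,
                     nCisEqtls = 4L, nReqtls = 0L, nSignflipReqtls = 0L,
                     nTransTrios = 0L, seed = 200 + s)
    panel <- simulateGenotypes(cfg)
    genes <- geneAnnotation(cfg)
    truth <- plantTruth(panel, cfg, genes = genes, nSharedLoci = 1L,
                        nDistinctLoci = 0L, nCausalGenes = 0L)
    loci <- gwasLociTruth(truth)
    g <- simulateGwas(panel, truth, nGwas = 20000, seed = s)[[loci$disease[1]]]
    snps <- snpInfo(panel)
    causal <- loci$causal_snp[1]
    ci <- match(causal, snps$snp_id)
    win <- snps$snp_id[snps$chrom == snps$chrom[ci] &
                       abs(snps$pos - snps$pos[ci]) <= 2e5]
    top <- g$snp_id[g$snp_id %in% win][which.min(g$p[g$snp_id %in% win])]
    # count as a hit if the top GWAS SNP is the causal SNP or a near-perfect proxy
    top == causal || cor(dosages(panel)[, top], dosages(panel)[, causal])^2 > 0.95
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("allele flipping is an involution under harmonisation", {
  cfg <- smallCfg(seed = 13)
  sim <- simulateStudy(cfg)
  g <- simulateGwas(sim$panel, sim$truth, nGwas = 500, seed = 1)[[1]]
  flipped <- flipGwasAlleles(g, snpIds = g$snp_id[1:50])
  expect_equal(flipped$beta[1:50], -g$beta[1:50])
  expect_equal(flipped$effect_allele[1:50], g$other_allele[1:50])
  restored <- harmoniseGwasToPanel(flipped, snpInfo(sim$panel))
  m <- match(g$snp_id, restored$snp_id)
  expect_equal(restored$beta[m], g$beta)
  expect_true(all(restored$effect_allele == snpInfo(sim$panel)$alt))
})
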