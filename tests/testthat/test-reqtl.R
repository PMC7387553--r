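# A paired two-condition fixture with a planted interaction effect.
reqtlFixture <- function(seed, betaRest, betaStim, n = 100L, noiseSd = 0.2) {
  cfg <- simConfig(nIndividuals = n, nGenes = 4L, nSnps = 30L,
                   nCisEqtls = 0L, nReqtls = 0L, nSignflipReqtls = 0L,
                   nTransTrios = 0L, retention = rep(1, 4), coreFraction = 1,
                   noiseSd = noiseSd, seed = seed)
  panel <- simulateGenotypes(cfg)
  genes <- geneAnnotation(cfg)
  snps <- snpInfo(panel)
  w <- which(snps$chrom == genes$chrom[1] &
             abs(snps$pos - genes$tss[1]) <= 1e6)[1]
  cis <- data.frame(gene_id = genes$gene_id[1], snp_id = snps$snp_id[w],
                    cell_type = "t", beta_resting = betaRest,
                    beta_stimulated = betaStim,
                    is_reqtl = betaRest != betaStim,
                    is_signflip = betaRest * betaStim < 0)
  study <- simulateExpression(panel, truthTable(cis = cis), cfg,
                              genes = genes)
  list(study = study, panel = panel, gene = genes$gene_id[1],
       snp = snps$snp_id[w])
}

test_that("interaction fit matches lme4 REML estimates", {
  skip_if_not_installed("lme4")
  fx <- reqtlFixture(seed = 1, betaRest = 0.3, betaStim = 0.9)
  des <- reqtlDesign(fx$study, fx$panel, "t", fx$gene, fx$snp)
  f <- fitInteractionLmm(des)
  df <- data.frame(y = des$y, x = des$x, c = des$cond, S = des$individual,
                   des$covs)
  cn <- colnames(des$covs)
  form <- stats::as.formula(paste(
    "y ~ x + c + x:c +", paste(cn, collapse = "+"), "+",
    paste(paste0(cn, ":c"), collapse = "+"), "+ (1|S)"))
  m <- lme4::lmer(form, data = df, REML = TRUE)
  sm <- summary(m)$coefficients
  expect_equal(f$beta, sm["x:c", "Estimate"], tolerance = 1e-6)
  expect_equal(f$se, sm["x:c", "Std. Error"], tolerance = 1e-6)
})

test_that("no-response and planted-response interactions are estimated correctly", {
  # equal betas: interaction near zero
  fx0 <- reqtlFixture(seed = 2, betaRest = 0.5, betaStim = 0.5)
  f0 <- fitInteractionLmm(reqtlDesign(fx0$study, fx0$panel, "t", fx0$gene,
                                      fx0$snp))
  expect_lt(abs(f0$beta), 0.1)
  # betaRest 0.2 -> betaStim 0.8: interaction ~ 0.6; sign flip ~ -1.0
  est <- vapply(1:20, function(s) {
    fx <- reqtlFixture(seed = 10 + s, betaRest = 0.2, betaStim = 0.8)
    fitInteractionLmm(reqtlDesign(fx$study, fx$panel, "t", fx$gene,
                                  fx$snp))$beta
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.6), 0.15)
  flip <- vapply(1:20, function(s) {
    fx <- reqtlFixture(seed = 40 + s, betaRest = 0.5, betaStim = -0.5)
    fitInteractionLmm(reqtlDesign(fx$study, fx$panel, "t", fx$gene,
                                  fx$snp))$beta
  }, numeric(1))
  expect_lt(abs(mean(flip) + 1.0), 0.15)
})

test_that("singular designs fail with the collinear column named", {
  fx <- reqtlFixture(seed = 3, betaRest = 0.3, betaStim = 0.3)
  des <- reqtlDesign(fx$study, fx$panel, "t", fx$gene, fx$snp)
  des$covs <- cbind(des$covs, dup = des$covs[, 1])
  expect_error(fitInteractionLmm(des), "collinear")
})

test_that("permutation p-values obey the (s+1)/(n+1) formula and its bounds", {
  fx <- reqtlFixture(seed = 4, betaRest = 0, betaStim = 1.5, noiseSd = 0.2)
  des <- reqtlDesign(fx$study, fx$panel, "t", fx$gene, fx$snp)
  pr <- suppressMessages(
    permuteConditionWithinIndividual(des, nPerm = 200L, seed = 5))
  expect_equal(pr$p_emp, (pr$s + 1) / (pr$n_perm + 1))
  expect_gte(pr$p_emp, 1 / (pr$n_perm + 1))
  # strong planted response: no permuted statistic beats the observed one
  expect_equal(pr$s, 0L)
  expect_equal(pr$p_emp, 1 / 201)
  # null gene: s can reach n, p_emp capped at 1
  fxN <- reqtlFixture(seed = 6, betaRest = 0, betaStim = 0)
  desN <- reqtlDesign(fxN$study, fxN$panel, "t", fxN$gene, fxN$snp)
  prN <- suppressMessages(
    permuteConditionWithinIndividual(desN, nPerm = 50L, seed = 7))
  expect_lte(prN$p_emp, 1)
  expect_lte(prN$s, prN$n_perm)
})

test_that("permutation is deterministic given the seed and supports early stopping", {
  fx <- reqtlFixture(seed = 8, betaRest = 0.2, betaStim = 0.2)
  des <- reqtlDesign(fx$study, fx$panel, "t", fx$gene, fx$snp)
  a <- suppressMessages(permuteConditionWithinIndividual(des, 100L, seed = 9))
  b <- suppressMessages(permuteConditionWithinIndividual(des, 100L, seed = 9))
  expect_identical(a$s, b$s)
  expect_identical(a$p_emp, b$p_emp)
  es <- suppressMessages(
    permuteConditionWithinIndividual(des, 1000L, seed = 9, earlyStop = 10L))
  expect_lte(es$n_perm, 1000L)
  expect_gte(es$s, 10L)
})

test_that("permutation p-values are uniform under the null", {
  # many null genes from one simulated study; moderate permutation depth
  cfg <- simConfig(nIndividuals = 60L, nGenes = 100L, nSnps = 60L,
                   nCisEqtls = 0L, nReqtls = 0L, nSignflipReqtls = 0L,
                   nTransTrios = 0L, retention = rep(1, 4), coreFraction = 1,
                   seed = 12)
  sim <- simulateStudy(cfg)
  st <- intTransformStudy(sim$study)
  genes <- geneInfo(st)
  snps <- snpInfo(sim$panel)
  set.seed(13)
  pvals <- vapply(seq_len(100), function(i) {
    w <- which(snps$chrom == genes$chrom[i] &
               abs(snps$pos - genes$tss[i]) <= 1e6)
    des <- reqtlDesign(st, sim$panel, "t", genes$gene_id[i],
                       snps$snp_id[sample(w, 1)])
    permuteConditionWithinIndividual(des, nPerm = 60L,
                                     seed = 1000 + i)$p_emp
  }, numeric(1))
  # permutation p-values are discrete, so ties are expected; the KS test is
  # only used as an approximate uniformity check
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("reQTL test selection follows the top-eSNP LD rule", {
  set.seed(14)
  d <- matrix(rbinom(200 * 3, 2, 0.4), 200, 3)
  d[, 2] <- d[, 1]                                  # r^2 = 1 with SNP 1
  d[, 3] <- rbinom(200, 2, 0.4)                     # independent
  panel <- toyPanel(d)
  mkEg <- function(genes, snp, p) data.frame(
    gene_id = genes, top_snp = snp, top_p = p,
    is_egene = rep(TRUE, length(genes)), stringsAsFactors = FALSE)
  # identical top SNP in both conditions: one test
  t1 <- selectReqtlTests(mkEg("g1", "s001", 1e-8), mkEg("g1", "s001", 1e-6),
                         panel)
  expect_equal(nrow(t1), 1L)
  # r^2 = 1 between different top SNPs: the more significant one only
  t2 <- selectReqtlTests(mkEg("g1", "s001", 1e-8), mkEg("g1", "s002", 1e-6),
                         panel)
  expect_equal(nrow(t2), 1L)
  expect_equal(t2$snp_id, "s001")
  # low LD: both tested
  t3 <- selectReqtlTests(mkEg("g1", "s001", 1e-8), mkEg("g1", "s003", 1e-6),
                         panel)
  expect_equal(nrow(t3), 2L)
  # eGene in one condition only: one test
  t4 <- selectReqtlTests(mkEg("g1", "s001", 1e-8),
                         mkEg(character(0), character(0), numeric(0)), panel)
  expect_equal(nrow(t4), 1L)
})

test_that("reqtlFdr matches bhFdr and recovers planted response eQTLs", {
  res <- data.frame(gene_id = paste0("g", 1:4), snp_id = paste0("s", 1:4),
                    p_emp = c(0.001, 0.02, 0.8, 1))
  out <- reqtlFdr(res, alpha = 0.05)
  expect_identical(out$significant, bhFdr(res$p_emp, 0.05)$reject)
  allNull <- data.frame(gene_id = "g", snp_id = "s", p_emp = 1)
  expect_length(attr(reqtlFdr(allNull), "regenes"), 0L)
  # planted interaction = 1.0 recovered with high power
  hits <- vapply(1:10, function(s) {
    fx <- reqtlFixture(seed = 100 + s, betaRest = 0, betaStim = 1,
                       noiseSd = 0.5)
    st <- intTransformStudy(fx$study)
    des <- reqtlDesign(st, fx$panel, "t", fx$gene, fx$snp)
    pr <- suppressMessages(
      permuteConditionWithinIndividual(des, nPerm = 200L, seed = s))
    pr$p_emp <= 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
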