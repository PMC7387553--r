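mkStats <- function(snp, ea, oa, beta, se = 0.05, p = 1e-8) {
  data.frame(snp_id = snp, effect_allele = ea, other_allele = oa,
             beta = beta, se = se, p = p, stringsAsFactors = FALSE)
}

test_that("harmonisation flips swapped alleles, drops palindromes, and is idempotent", {
  expo <- mkStats(c("s1", "s2", "s3", "s4"), c("G", "G", "A", "G"),
                  c("A", "A", "T", "T"), beta = c(0.5, 0.4, 0.3, 0.2))
  outc <- mkStats(c("s1", "s2", "s3", "s4"), c("A", "G", "A", "C"),
                  c("G", "A", "T", "A"), beta = c(-0.25, 0.2, 0.15, 0.1))
  h <- harmoniseInstruments(expo, outc)
  # s1 swapped: beta flipped back to +0.25; s2 aligned; s3 palindromic (A/T)
  # dropped; s4 allele mismatch dropped
  expect_setequal(h$snp_id, c("s1", "s2"))
  expect_equal(h$beta_outcome[h$snp_id == "s1"], 0.25)
  expect_equal(h$beta_outcome[h$snp_id == "s2"], 0.2)
  removed <- attr(h, "removed")
  expect_equal(removed$reason[removed$snp_id == "s3"], "strand_ambiguous")
  expect_equal(removed$reason[removed$snp_id == "s4"], "allele_mismatch")
  # idempotence: harmonising the harmonised set changes nothing
  asOutcome <- data.frame(snp_id = h$snp_id, effect_allele = h$effect_allele,
                          other_allele = h$other_allele,
                          beta = h$beta_outcome, se = h$se_outcome,
                          p = h$p_outcome, stringsAsFactors = FALSE)
  h2 <- harmoniseInstruments(expo, asOutcome)
  expect_equal(h2$beta_outcome, h$beta_outcome)
  expect_error(harmoniseInstruments(expo, mkStats("zz", "G", "A", 1)),
               "overlap")
})

test_that("LD pruning keeps the most significant of correlated instruments", {
  set.seed(1)
  n <- 300
  d <- matrix(rbinom(n * 5, 2, 0.4), n, 5)
  d[, 2] <- d[, 1]                       # duplicate of SNP 1
  d[, 4] <- d[, 3]                       # duplicate of SNP 3
  panel <- toyPanel(d)
  cand <- data.frame(snp_id = paste0("s", sprintf("%03d", 1:5)),
                     effect_allele = "G", other_allele = "A",
                     beta_exposure = 0.5, se_exposure = 0.05,
                     p_exposure = c(1e-8, 1e-6, 1e-7, 1e-9, 1e-5),
                     beta_outcome = 0.1, se_outcome = 0.05, p_outcome = 0.01,
                     stringsAsFactors = FALSE)
  pruned <- ldPruneInstruments(cand, panel)
  # brute-force greedy oracle: order by p, keep if r^2 < 0.1 with all kept
  o <- order(cand$p_exposure)
  keep <- character(0)
  for (i in o) {
    ok <- all(vapply(keep, function(k)
      cor(d[, match(k, cand$snp_id)], d[, i])^2 < 0.1, logical(1)))
    if (ok) keep <- c(keep, cand$snp_id[i])
  }
  expect_setequal(pruned$snp_id, keep)
  expect_equal(nrow(pruned), 3L)          # one per duplicate pair + SNP 5
  # perfectly correlated pair reduces to the more significant member
  two <- cand[1:2, ]
  expect_equal(ldPruneInstruments(two, panel, minIvs = 1L)$snp_id, "s001")
  # independent instruments all survive
  ind <- cand[c(1, 3, 5), ]
  expect_equal(nrow(ldPruneInstruments(ind, panel)), 3L)
})

test_that("MR estimators agree on consistent ratios and IVW matches hand WLS", {
  ivs <- data.frame(snp_id = paste0("s", 1:3), effect_allele = "G",
                    other_allele = "A",
                    beta_exposure = c(0.5, 0.4, 0.2),
                    se_exposure = c(0.03, 0.03, 0.03),
                    p_exposure = 1e-8,
                    beta_outcome = c(0.25, 0.20, 0.10),
                    se_outcome = c(0.05, 0.05, 0.05),
                    p_outcome = 1e-4, stringsAsFactors = FALSE)
  est <- mrEstimates(ivs, nBoot = 200L, seed = 1)
  # all ratios are exactly 0.5: every point estimate equals 0.5
  expect_equal(est$estimate, rep(0.5, 4), tolerance = 1e-9)
  # IVW as hand-computed weighted least squares through the origin
  w <- 1 / ivs$se_outcome^2
  handIvw <- sum(w * ivs$beta_exposure * ivs$beta_outcome) /
    sum(w * ivs$beta_exposure^2)
  expect_equal(est$estimate[est$method == "ivw"], handIvw)
  # ... and as the precision-weighted mean of ratio estimates
  ratio <- ivs$beta_outcome / ivs$beta_exposure
  wr <- (ivs$beta_exposure / ivs$se_outcome)^2
  expect_equal(est$estimate[est$method == "ivw"],
               sum(wr * ratio) / sum(wr), tolerance = 1e-10)
})

test_that("weighted median equals the plain median under equal weights", {
  x <- c(0.1, 0.5, 0.2, 0.9, 0.4)
  expect_equal(stimqtl:::weightedMedianEstimate(x, rep(1, 5)), median(x))
  x4 <- c(0.1, 0.2, 0.6, 0.8)
  expect_equal(stimqtl:::weightedMedianEstimate(x4, rep(1, 4)), median(x4))
})

test_that("IVW confidence intervals cover a planted causal effect", {
  theta <- 0.3
  covered <- vapply(1:50, function(s) {
    set.seed(s)
    J <- 8
    bx <- runif(J, 0.3, 0.8)
    sx <- rep(0.04, J); sy <- rep(0.03, J)
    bxh <- bx + rnorm(J, 0, sx)
    byh <- theta * bx + rnorm(J, 0, sy)
    ivs <- data.frame(snp_id = paste0("s", 1:J), effect_allele = "G",
                      other_allele = "A", beta_exposure = bxh,
                      se_exposure = sx, p_exposure = 1e-8,
                      beta_outcome = byh, se_outcome = sy, p_outcome = 1e-4,
                      stringsAsFactors = FALSE)
    est <- mrEstimates(ivs, nBoot = 100L, seed = s)
    ivw <- est[est$method == "ivw", ]
    ivw$estimate - 1.96 * ivw$se <= theta &&
      theta <= ivw$estimate + 1.96 * ivw$se
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("directional pleiotropy triggers the Egger intercept test", {
  # directional pleiotropy on half the IVs, carried by the weaker
  # instruments (the regime where the intercept is identifiable)
  flagged <- vapply(1:20, function(s) {
    set.seed(s)
    J <- 12
    bx <- c(runif(J / 2, 0.05, 0.15), runif(J / 2, 0.5, 1.0))
    pleio <- c(rep(0.1, J / 2), rep(0, J / 2))
    sx <- rep(0.03, J); sy <- rep(0.02, J)
    ivs <- data.frame(snp_id = paste0("s", 1:J), effect_allele = "G",
                      other_allele = "A",
                      beta_exposure = bx + rnorm(J, 0, sx),
                      se_exposure = sx, p_exposure = 1e-8,
                      beta_outcome = 0.1 * bx + pleio + rnorm(J, 0, sy),
                      se_outcome = sy, p_outcome = 1e-3,
                      stringsAsFactors = FALSE)
    est <- mrEstimates(ivs, nBoot = 100L, seed = s)
    attr(est, "egger_intercept_p") <= 0.05
  }, logical(1))
  expect_gte(mean(flagged), 0.7)
})

test_that("each method holds its type-I error under the null", {
  res <- vapply(1:500, function(s) {
    set.seed(s)
    J <- 10
    bx <- runif(J, 0.3, 0.8)
    sx <- rep(0.04, J); sy <- rep(0.04, J)
    ivs <- data.frame(snp_id = paste0("s", 1:J), effect_allele = "G",
                      other_allele = "A", beta_exposure = bx + rnorm(J, 0, sx),
                      se_exposure = sx, p_exposure = 1e-8,
                      beta_outcome = rnorm(J, 0, sy), se_outcome = sy,
                      p_outcome = 0.5, stringsAsFactors = FALSE)
    est <- mrEstimates(ivs, nBoot = 150L, seed = s)
    setNames(est$p <= 0.05, est$method)
  }, logical(4))
  rates <- rowMeans(res)
  # no method is anti-conservative
  expect_true(all(rates <= 0.10))
  # IVW and weighted median track the nominal level; the weighted mode and
  # the random-effects Egger test are conservative by construction, so only
  # their upper bound is asserted
  expect_gte(rates[["ivw"]], 0.02)
  expect_gte(rates[["weighted_median"]], 0.02)
})

test_that("zero-exposure-beta instruments are dropped with a warning", {
  ivs <- data.frame(snp_id = paste0("s", 1:4), effect_allele = "G",
                    other_allele = "A", beta_exposure = c(0.5, 0.4, 0.3, 0),
                    se_exposure = 0.03, p_exposure = 1e-8,
                    beta_outcome = c(0.27, 0.18, 0.16, 0.1), se_outcome = 0.05,
                    p_outcome = 1e-3, stringsAsFactors = FALSE)
  expect_warning(est <- mrEstimates(ivs, nBoot = 50L, seed = 1), "zero exposure")
  expect_equal(attr(est, "n_ivs"), 3L)
})

test_that("the consensus verdict follows the 3-of-4 and pleiotropy rules", {
  mk <- function(ps, intP) {
    est <- data.frame(method = c("ivw", "weighted_median", "weighted_mode",
                                 "egger"),
                      estimate = 0.1, se = 0.05, p = ps,
                      stringsAsFactors = FALSE)
    attr(est, "egger_intercept_p") <- intP
    est
  }
  expect_equal(mrVerdict(mk(c(0.01, 0.02, 0.03, 0.04), 0.5))$verdict,
               "causal_suggestive")
  expect_equal(mrVerdict(mk(c(0.01, 0.02, 0.3, 0.4), 0.5))$verdict,
               "not_significant")
  expect_equal(mrVerdict(mk(c(0.01, 0.02, 0.03, 0.2), 0.5))$verdict,
               "causal_suggestive")
  expect_equal(mrVerdict(mk(c(0.01, 0.01, 0.01, 0.01), 0.01))$verdict,
               "excluded_pleiotropy")
})
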