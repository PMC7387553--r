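#' @include trans.R
NULL

# Extract the (y, x, m, covariates) vectors for a mediation trio in one
# condition.
mediationDesign <- function(study, panel, condition, snpId, cisGene,
                            transGene) {
  cd <- sampleSheet(study)
  cd <- cd[cd$condition == condition, , drop = FALSE]
  a <- SummarizedExperiment::assay(study, "exprs")
  for (g in c(cisGene, transGene))
    if (!g %in% rownames(a)) stop("unknown gene: ", g)
  if (!snpId %in% snpInfo(panel)$snp_id) stop("unknown SNP: ", snpId)
  list(x = as.numeric(dosages(panel)[cd$individual_id, snpId]),
       m = as.numeric(a[cisGene, cd$sample_id]),
       y = as.numeric(a[transGene, cd$sample_id]),
       covs = {
         cm <- as.matrix(cd[, covariateNames(study), drop = FALSE])
         storage.mode(cm) <- "double"; cm
       },
       individual = cd$individual_id)
}

# Path coefficients from two OLS fits sharing the same covariates:
# a: mediator ~ x; (b, c'): outcome ~ x + mediator.
mediationPaths <- function(x, m, y, covs) {
  C <- cbind(1, covs)
  f1 <- lm.fit(cbind(C, x = x), m)
  qrX <- qr(cbind(C, x = x, m = m))
  if (qrX$rank < ncol(qrX$qr))
    stop("mediator collinear with exposure/covariates")
  f2 <- lm.fit(cbind(C, x = x, m = m), y)
  a <- f1$coefficients[["x"]]
  cPrime <- f2$coefficients[["x"]]
  b <- f2$coefficients[["m"]]
  list(a = a, b = b, c_prime = cPrime, indirect = a * b,
       total = a * b + cPrime,
       prop_mediated = if (abs(a * b + cPrime) > 0) a * b / (a * b + cPrime)
         else NA_real_)
}

#' Path estimates for a mediation trio
#'
#' Estimates the exposure-to-mediator effect `a` (OLS of the cis gene on the
#' SNP dosage plus covariates) and, from the multiple regression of the
#' trans gene on dosage and cis gene with the same covariates, the
#' mediator-to-outcome effect `b` and the direct effect `c'`.  The indirect
#' effect is `a*b`, the total effect `a*b + c'` (an algebraic identity under
#' the shared-covariate linear model), and the proportion mediated
#' `a*b / (a*b + c')` (reported raw and clipped to the range -1..2 for display
#' stability).
#'
#' @param study,panel as elsewhere.
#' @param condition condition the trio was observed in.
#' @param snpId,cisGene,transGene the trio (exposure, mediator, outcome).
#' @return data.frame with one row: `a`, `b`, `c_prime`, `indirect`,
#'   `total`, `prop_mediated`, `prop_mediated_clipped`.
#' @export
estimatePaths <- function(study, panel, condition, snpId, cisGene,
                          transGene) {
  des <- mediationDesign(study, panel, condition, snpId, cisGene, transGene)
  pth <- mediationPaths(des$x, des$m, des$y, des$covs)
  data.frame(snp_id = snpId, cis_gene = cisGene, trans_gene = transGene,
             condition = condition, a = pth$a, b = pth$b,
             c_prime = pth$c_prime, indirect = pth$indirect,
             total = pth$total, prop_mediated = pth$prop_mediated,
             prop_mediated_clipped = pmin(pmax(pth$prop_mediated, -1), 2),
             stringsAsFactors = FALSE)
}

#' Nonparametric bootstrap for the indirect effect
#'
#' Resamples individuals with replacement, recomputes `a*b` on each
#' resample, and reports the percentile confidence interval and the
#' two-sided p-value from the bootstrap distribution's sign crossing
#' (`2 * min(P(ab* <= 0), P(ab* >= 0))`, floored at `1/nBoot`).  Resamples
#' with a constant dosage are redrawn (warned about when they exceed 1%).
#' `bootstrapIndirect` is the vector-level engine; `bootstrapMediation`
#' extracts the trio from a study.
#'
#' @param x,m,y exposure dosage, mediator and outcome vectors.
#' @param covs optional covariate matrix.
#' @param nBoot bootstrap replicates (default 10000).
#' @param seed RNG seed.
#' @param level CI level (default 0.95).
#' @return list with `p`, `ci` (length 2), `ab` (observed), `boot`
#'   (replicate values).
#' @export
bootstrapIndirect <- function(x, m, y, covs = NULL, nBoot = 10000L,
                              seed = 1L, level = 0.95) {
  if (is.null(covs)) covs <- matrix(numeric(0), nrow = length(x), ncol = 0)
  obs <- mediationPaths(x, m, y, covs)
  n <- length(x)
  set.seed(seed)
  ab <- numeric(nBoot)
  redraws <- 0L
  for (b in seq_len(nBoot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (var(x[idx]) > 0) break
      redraws <- redraws + 1L
    }
    pth <- mediationPaths(x[idx], m[idx], y[idx], covs[idx, , drop = FALSE])
    ab[b] <- pth$indirect
  }
  if (redraws > 0.01 * nBoot)
    warning(redraws, " degenerate resamples (constant dosage) were redrawn")
  alpha <- 1 - level
  ci <- unname(quantile(ab, c(alpha / 2, 1 - alpha / 2)))
  p <- 2 * min(mean(ab <= 0), mean(ab >= 0))
  p <- min(1, max(p, 1 / nBoot))
  list(p = p, ci = ci, ab = obs$indirect, boot = ab)
}

#' @rdname bootstrapIndirect
#' @inheritParams estimatePaths
#' @export
bootstrapMediation <- function(study, panel, condition, snpId, cisGene,
                               transGene, nBoot = 10000L, seed = 1L,
                               level = 0.95) {
  des <- mediationDesign(study, panel, condition, snpId, cisGene, transGene)
  bootstrapIndirect(des$x, des$m, des$y, des$covs, nBoot = nBoot,
                    seed = seed, level = level)
}

#' Mediation testing for a set of trios with BH correction
#'
#' @param study,panel as elsewhere.
#' @param trios data.frame with `snp_id`, `cis_gene`, `trans_gene`,
#'   `condition`.
#' @param nBoot,seed bootstrap settings.
#' @param alpha FDR level (default 0.05).
#' @return data.frame with path estimates, bootstrap `p`, `q` and
#'   `significant` per trio (empty input returns an empty frame).
#' @export
mediationFdr <- function(study, panel, trios, nBoot = 10000L, seed = 1L,
                         alpha = 0.05) {
  if (nrow(trios) == 0L)
    return(data.frame())
  rows <- vector("list", nrow(trios))
  for (i in seq_len(nrow(trios))) {
    est <- estimatePaths(study, panel, trios$condition[i], trios$snp_id[i],
                         trios$cis_gene[i], trios$trans_gene[i])
    bt <- bootstrapMediation(study, panel, trios$condition[i],
                             trios$snp_id[i], trios$cis_gene[i],
                             trios$trans_gene[i], nBoot = nBoot,
                             seed = stageSeed(seed, paste0("boot", i)))
    est$p <- bt$p; est$ci_lower <- bt$ci[1]; est$ci_upper <- bt$ci[2]
    rows[[i]] <- est
  }
  out <- do.call(rbind, rows)
  bh <- bhFdr(out$p, alpha = alpha)
  out$q <- bh$q
  out$significant <- bh$reject
  out
}
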