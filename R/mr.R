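#' @include coloc.R
NULL

#' Harmonise exposure (eQTL) and outcome (GWAS) summary statistics
#'
#' Aligns the outcome effect allele to the exposure effect allele, flipping
#' the outcome beta when the allele pair is swapped; removes strand-ambiguous
#' (A/T, C/G) palindromic SNPs and rows whose allele pairs cannot be
#' reconciled (reason codes returned).  Idempotent: harmonising an already
#' harmonised set changes nothing.
#'
#' @param exposure data.frame with `snp_id`, `effect_allele`, `other_allele`,
#'   `beta`, `se`, `p`.
#' @param outcome data.frame with the same columns.
#' @return data.frame of instrument candidates: `snp_id`, `effect_allele`,
#'   `other_allele`, `beta_exposure`, `se_exposure`, `p_exposure`,
#'   `beta_outcome`, `se_outcome`, `p_outcome`; attribute `removed` lists
#'   dropped SNPs with reasons.
#' @export
harmoniseInstruments <- function(exposure, outcome) {
  shared <- intersect(exposure$snp_id, outcome$snp_id)
  if (!length(shared)) stop("no overlapping SNPs between exposure and outcome")
  e <- exposure[match(shared, exposure$snp_id), ]
  o <- outcome[match(shared, outcome$snp_id), ]
  pal <- paste0(e$effect_allele, e$other_allele) %in%
    c("AT", "TA", "CG", "GC")
  same <- o$effect_allele == e$effect_allele & o$other_allele == e$other_allele
  swap <- o$effect_allele == e$other_allele & o$other_allele == e$effect_allele
  beta_out <- ifelse(swap, -o$beta, o$beta)
  keep <- !pal & (same | swap)
  removed <- data.frame(
    snp_id = shared[!keep],
    reason = ifelse(pal[!keep], "strand_ambiguous", "allele_mismatch"),
    stringsAsFactors = FALSE)
  out <- data.frame(
    snp_id = shared, effect_allele = e$effect_allele,
    other_allele = e$other_allele,
    beta_exposure = e$beta, se_exposure = e$se, p_exposure = e$p,
    beta_outcome = beta_out, se_outcome = o$se, p_outcome = o$p,
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

#' Greedy LD pruning of instrument candidates
#'
#' Orders candidates by ascending exposure p-value and retains each SNP only
#' if its dosage `r^2` with every already-retained SNP stays below `r2`.
#' Gene-disease pairs ending with fewer than `minIvs` instruments should be
#' skipped by the caller (a `message()` notes this).
#'
#' @param candidates data.frame from [harmoniseInstruments()].
#' @param panel a [GenotypePanel-class] supplying LD.
#' @param r2 pruning threshold (default 0.1; `r^2 >= r2` is pruned).
#' @param minIvs minimum instruments to proceed (default 3).
#' @return the pruned data.frame (possibly with < `minIvs` rows; the caller
#'   decides whether to skip).
#' @export
ldPruneInstruments <- function(candidates, panel, r2 = 0.1, minIvs = 3L) {
  o <- order(candidates$p_exposure)
  cand <- candidates[o, , drop = FALSE]
  kept <- integer()
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (k in kept) {
      if (snpR2(panel, cand$snp_id[i], cand$snp_id[k]) >= r2) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  out <- cand[kept, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) < minIvs)
    message("only ", nrow(out), " instrument(s) survive LD pruning (< ",
            minIvs, ")")
  out
}

# Weighted median of x with weights w (Bowden et al. interpolation).
weightedMedianEstimate <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cs <- cumsum(w) - w / 2
  if (cs[1] >= 0.5) return(x[1])
  if (cs[length(cs)] <= 0.5) return(x[length(x)])
  i <- max(which(cs < 0.5))
  x[i] + (x[i + 1] - x[i]) * (0.5 - cs[i]) / (cs[i + 1] - cs[i])
}

# Weighted mode: maximiser of a weighted normal-kernel density of the ratio
# estimates, modified-Silverman bandwidth times phi.
weightedModeEstimate <- function(x, w, phi = 1) {
  w <- w / sum(w)
  s <- 0.9 * min(sd(x), mad(x)) / length(x)^(1 / 5)
  if (!is.finite(s) || s <= 0) s <- 0.9 * sd(x) / length(x)^(1 / 5)
  if (!is.finite(s) || s <= 0) return(median(x))
  h <- max(phi * s, .Machine$double.eps)
  grid <- seq(min(x) - 3 * h, max(x) + 3 * h, length.out = 512)
  dens <- as.vector(dnorm(outer(grid, x, "-") / h) %*% w)
  grid[which.max(dens)]
}

#' Two-sample Mendelian randomisation estimates (four methods)
#'
#' Computes, from a harmonised and pruned instrument set, the inverse
#' variance weighted (IVW) estimate (weighted regression of outcome on
#' exposure betas through the origin, weights `1/se_outcome^2`, with
#' multiplicative random-effects scaling of the SE floored at 1), the
#' weighted median of ratio estimates (parametric-bootstrap SE), the
#' weighted mode (weighted kernel density of ratios, modified-Silverman
#' bandwidth, bootstrap SE), and MR-Egger regression with intercept after
#' orienting all exposure betas positive (the intercept's p-value is the
#' pleiotropy test).  First-order ratio SEs `se_outcome/|beta_exposure|`
#' supply the median/mode weights.  Instruments with zero exposure beta have
#' no defined ratio and are dropped with a warning.
#'
#' @param ivs data.frame from [ldPruneInstruments()] (>= 3 rows).
#' @param nBoot bootstrap draws for the median/mode SEs (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @param phi weighted-mode bandwidth factor (default 1).
#' @return data.frame with one row per method (`ivw`, `weighted_median`,
#'   `weighted_mode`, `egger`): `estimate`, `se`, `p`, plus attributes
#'   `egger_intercept`, `egger_intercept_se`, `egger_intercept_p`, `n_ivs`.
#' @export
mrEstimates <- function(ivs, nBoot = 1000L, seed = 1L, phi = 1) {
  zero <- ivs$beta_exposure == 0
  if (any(zero)) {
    warning(sum(zero), " instrument(s) with zero exposure beta dropped")
    ivs <- ivs[!zero, , drop = FALSE]
  }
  J <- nrow(ivs)
  if (J < 3L) stop("need at least 3 instruments")
  bx <- ivs$beta_exposure; by <- ivs$beta_outcome
  sx <- ivs$se_exposure; sy <- ivs$se_outcome
  # IVW: weighted through-origin regression; equals the precision-weighted
  # mean of ratio estimates with weights bx^2/sy^2
  wIvw <- 1 / sy^2
  ivwEst <- sum(wIvw * bx * by) / sum(wIvw * bx^2)
  ivwSigma2 <- sum(wIvw * (by - ivwEst * bx)^2) / (J - 1)
  ivwSe <- sqrt(max(ivwSigma2, 1) / sum(wIvw * bx^2))
  ivwP <- 2 * pnorm(-abs(ivwEst / ivwSe))
  # ratio estimates and first-order SEs for median/mode
  ratio <- by / bx
  ratioSe <- sy / abs(bx)
  wRatio <- 1 / ratioSe^2
  medEst <- weightedMedianEstimate(ratio, wRatio)
  modeEst <- weightedModeEstimate(ratio, wRatio, phi = phi)
  set.seed(seed)
  medB <- modeB <- numeric(nBoot)
  for (b in seq_len(nBoot)) {
    bxB <- rnorm(J, bx, sx); byB <- rnorm(J, by, sy)
    rB <- byB / bxB
    wB <- (abs(bxB) / sy)^2
    medB[b] <- weightedMedianEstimate(rB, wB)
    modeB[b] <- weightedModeEstimate(rB, wB, phi = phi)
  }
  medSe <- sd(medB); modeSe <- sd(modeB)
  # Egger: orient exposure betas positive, weighted regression with intercept
  sgn <- sign(bx); sgn[sgn == 0] <- 1
  bxE <- bx * sgn; byE <- by * sgn
  fit <- lm(byE ~ bxE, weights = 1 / sy^2)
  sm <- summary(fit)
  scale <- max(1, sm$sigma)
  eggerEst <- coef(fit)[["bxE"]]
  eggerSe <- sm$coefficients["bxE", "Std. Error"] / sm$sigma * scale
  intEst <- coef(fit)[["(Intercept)"]]
  intSe <- sm$coefficients["(Intercept)", "Std. Error"] / sm$sigma * scale
  eggerP <- 2 * pt(-abs(eggerEst / eggerSe), df = J - 2)
  intP <- 2 * pt(-abs(intEst / intSe), df = J - 2)
  out <- data.frame(
    method = c("ivw", "weighted_median", "weighted_mode", "egger"),
    estimate = c(ivwEst, medEst, modeEst, eggerEst),
    se = c(ivwSe, medSe, modeSe, eggerSe),
    p = c(ivwP, 2 * pnorm(-abs(medEst / medSe)),
          2 * pnorm(-abs(modeEst / modeSe)), eggerP),
    stringsAsFactors = FALSE)
  attr(out, "egger_intercept") <- intEst
  attr(out, "egger_intercept_se") <- intSe
  attr(out, "egger_intercept_p") <- intP
  attr(out, "n_ivs") <- J
  out
}

#' Consensus verdict over the four MR methods
#'
#' `excluded_pleiotropy` when the Egger intercept p-value is at or below
#' `pleiotropyAlpha` (regardless of the method p-values);
#' `causal_suggestive` when at least three of the four methods reach
#' `alpha`; otherwise `not_significant`.  No multiple-testing correction is
#' applied across genes or diseases.
#'
#' @param estimates data.frame from [mrEstimates()].
#' @param alpha per-method significance level (default 0.05).
#' @param pleiotropyAlpha Egger-intercept exclusion level (default 0.05).
#' @return list with `verdict`, `n_methods_significant`, `pleiotropy_p`.
#' @export
mrVerdict <- function(estimates, alpha = 0.05, pleiotropyAlpha = 0.05) {
  intP <- attr(estimates, "egger_intercept_p")
  nSig <- sum(estimates$p <= alpha)
  verdict <- if (!is.null(intP) && intP <= pleiotropyAlpha) "excluded_pleiotropy"
    else if (nSig >= 3L) "causal_suggestive" else "not_significant"
  list(verdict = verdict, n_methods_significant = nSig, pleiotropy_p = intP)
}
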