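#' @include signals.R
NULL

# ---- random-intercept linear mixed model, profiled REML ----------------
# V = sigma_e^2 (I + lambda Z Z') with one random intercept per individual.
# Whitening V^{-1/2} is closed-form per group, so the profiled REML
# criterion reduces to a 1-d optimisation over log(lambda).

# Whiten columns of M (or a vector) given group index list and lambda.
# V_g^{-1/2} = I - ((1 - 1/sqrt(1 + k lambda))/k) J for a group of size k
# (for k = 1 this is multiplication by 1/sqrt(1 + lambda)), applied
# vectorised via per-group column sums.
whitenByGroup <- function(M, groupIdx, lambda) {
  vec <- is.null(dim(M))
  if (vec) M <- matrix(M, ncol = 1)
  gi <- integer(nrow(M))
  for (g in seq_along(groupIdx)) gi[groupIdx[[g]]] <- g
  k <- lengths(groupIdx)
  shrink <- (1 - 1 / sqrt(1 + k * lambda)) / k
  gs <- rowsum(M, gi, reorder = TRUE)
  out <- M - gs[gi, , drop = FALSE] * shrink[gi]
  if (vec) out[, 1] else out
}

remlDeviance <- function(logLambda, y, X, groupIdx, n, p) {
  lambda <- exp(logLambda)
  ys <- whitenByGroup(y, groupIdx, lambda)
  Xs <- whitenByGroup(X, groupIdx, lambda)
  fit <- .lm.fit(Xs, ys)
  rss <- sum(fit$residuals^2)
  k <- lengths(groupIdx)
  # |V_g| = 1 + k*lambda for a unit-diagonal compound-symmetry block
  logDetV <- sum(log1p(k * lambda))
  XtX <- crossprod(Xs)
  logDetXtX <- determinant(XtX, logarithm = TRUE)$modulus[1]
  (n - p) * log(rss / (n - p)) + logDetV + logDetXtX
}

# Fit y ~ X + (1 | group) by profiled REML.  Returns coefficients, their
# covariance, the variance ratio lambda and residual variance.
randomInterceptFit <- function(y, X, group) {
  n <- length(y); p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("singular fixed-effect design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  groupIdx <- split(seq_len(n), group)
  opt <- optimize(remlDeviance, interval = c(-12, 12), y = y, X = X,
                  groupIdx = groupIdx, n = n, p = p, tol = 1e-7)
  lambda <- exp(opt$minimum)
  if (opt$minimum <= -11.9) lambda <- 0  # boundary: no between-individual variance
  ys <- whitenByGroup(y, groupIdx, lambda)
  Xs <- whitenByGroup(X, groupIdx, lambda)
  fit <- lm.fit(Xs, ys)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (n - p)
  XtXinv <- chol2inv(chol(crossprod(Xs)))
  se <- sqrt(diag(XtXinv) * sigma2)
  names(se) <- colnames(X)
  list(coef = fit$coefficients, se = se, lambda = lambda, sigma2 = sigma2,
       groupIdx = groupIdx, df = n - p)
}

# ---- response-eQTL design ----------------------------------------------

#' Assemble the interaction design for one gene-SNP pair in a cell type
#'
#' Combines the resting and stimulated samples of `cellType`, returning the
#' response `y` (expression), dosage `x`, condition indicator `cond`
#' (resting = 0, stimulated = 1), the covariate matrix, and the individual
#' grouping for the random intercept.
#'
#' @param study an [ExpressionStudy-class] (INT within condition).
#' @param panel a [GenotypePanel-class].
#' @param cellType `"myeloid"` or `"t"` (a `cell_type` of the study).
#' @param geneId,snpId the pair to test.
#' @return list with `y`, `x`, `cond`, `covs`, `individual`.
#' @export
reqtlDesign <- function(study, panel, cellType, geneId, snpId) {
  ct <- conditionTable(study)
  conds <- ct$condition[ct$cell_type == cellType]
  if (length(conds) != 2L) stop("cell type must have exactly two conditions")
  cd <- sampleSheet(study)
  cd <- cd[cd$condition %in% conds, , drop = FALSE]
  a <- SummarizedExperiment::assay(study, "exprs")
  y <- a[geneId, cd$sample_id]
  x <- dosages(panel)[cd$individual_id, snpId]
  treat <- ct$treatment[match(cd$condition, ct$condition)]
  covs <- as.matrix(cd[, covariateNames(study), drop = FALSE])
  storage.mode(covs) <- "double"
  list(y = as.numeric(y), x = as.numeric(x),
       cond = as.numeric(treat == "stimulated"), covs = covs,
       individual = cd$individual_id)
}

# Full fixed-effect matrix of the interaction model for a given condition
# vector: intercept, x, c, x:c, covariates, covariate:c interactions.
interactionModelMatrix <- function(design, cond = design$cond) {
  X <- cbind(`(Intercept)` = 1, x = design$x, c = cond,
             `x:c` = design$x * cond, design$covs,
             design$covs * cond)
  colnames(X)[(5 + ncol(design$covs)):ncol(X)] <-
    paste0(colnames(design$covs), ":c")
  X
}

#' Fit the genotype-by-condition interaction mixed model
#'
#' Fits `y ~ x + c + x:c + covariates + covariates:c + (1 | individual)` by
#' profiled REML (the random-intercept covariance has a closed-form
#' whitening, so the fit reduces to one-dimensional optimisation; it agrees
#' with `lme4::lmer` REML estimates).  Returns the interaction (`x:c`)
#' coefficient, its standard error and Wald t statistic; the two-sided
#' p-value uses `n - p` degrees of freedom and is superseded by the
#' permutation p-value for inference.
#'
#' @param design list from [reqtlDesign()].
#' @return list with `beta`, `se`, `t`, `p`, `lambda` (variance ratio),
#'   `n`, and the full fitted object in `fit`.
#' @export
fitInteractionLmm <- function(design) {
  X <- interactionModelMatrix(design)
  fit <- randomInterceptFit(design$y, X, design$individual)
  b <- fit$coef[["x:c"]]; se <- fit$se[["x:c"]]
  tval <- b / se
  list(beta = b, se = se, t = tval,
       p = 2 * pt(-abs(tval), df = fit$df), lambda = fit$lambda,
       n = length(design$y), fit = fit)
}

#' Within-individual permutation null for the interaction test
#'
#' Each permutation independently swaps (or not) the condition labels of
#' every individual's paired samples; individuals observed in one condition
#' keep their label.  The model is refit per permutation with the
#' random-intercept variance ratio held at its observed-data REML estimate
#' (the grouping structure, and hence the whitening, is unchanged by the
#' permutation), and the permuted Wald |t| of the interaction term is
#' compared with the observed one.  The empirical p-value is
#' `(s + 1) / (nPerm + 1)` where `s` counts permuted statistics at least as
#' extreme.
#'
#' @param design list from [reqtlDesign()].
#' @param nPerm number of permutations (default 1000).
#' @param seed RNG seed.
#' @param earlyStop optional: stop permuting once `s` reaches this count
#'   (the p-value can no longer reach significance); `Inf` disables.
#' @return list with `p_emp`, `s`, `n_perm` (permutations actually run),
#'   `observed` (the observed fit as from [fitInteractionLmm()]).
#' @export
permuteConditionWithinIndividual <- function(design, nPerm = 1000L, seed = 1L,
                                             earlyStop = Inf) {
  obs <- fitInteractionLmm(design)
  lambda <- obs$lambda
  groupIdx <- split(seq_along(design$y), design$individual)
  paired <- Filter(function(idx) length(idx) == 2L &&
                     sum(design$cond[idx]) == 1L, groupIdx)
  if (!length(paired))
    stop("no individuals with both conditions; permutation null unavailable")
  nSingle <- length(groupIdx) - length(paired)
  if (nSingle > 0)
    message(nSingle, " individual(s) with a single condition keep their label")
  ys <- whitenByGroup(design$y, groupIdx, lambda)
  n <- length(design$y)
  nCov <- ncol(design$covs)
  p <- 4L + 2L * nCov
  # columns not involving the condition are permutation-invariant: whiten once
  staticW <- whitenByGroup(cbind(1, design$x, design$covs), groupIdx, lambda)
  # condition-dependent block (c, covs:c, x:c), rebuilt per permutation with
  # x:c LAST so its t-statistic falls out of the Cholesky factor directly
  dynRaw <- cbind(1, design$covs, design$x)
  pairedMat <- do.call(rbind, paired)  # two sample indices per paired individual
  yy <- sum(ys^2)
  # hoisted whitening constants (grouping never changes under permutation)
  gi <- integer(n)
  for (g in seq_along(groupIdx)) gi[groupIdx[[g]]] <- g
  shrinkRow <- ((1 - 1 / sqrt(1 + lengths(groupIdx) * lambda)) /
                  lengths(groupIdx))[gi]
  whitenFast <- function(M) M - rowsum(M, gi, reorder = TRUE)[gi, , drop = FALSE] * shrinkRow
  set.seed(seed)
  s <- 0L; done <- 0L
  for (b in seq_len(nPerm)) {
    cond <- design$cond
    flip <- runif(nrow(pairedMat)) < 0.5
    idxFlip <- as.vector(pairedMat[flip, , drop = FALSE])
    cond[idxFlip] <- 1 - cond[idxFlip]
    dynW <- whitenFast(dynRaw * cond)
    Xs <- cbind(staticW, dynW)
    XtX <- crossprod(Xs)
    Xty <- crossprod(Xs, ys)
    R <- chol(XtX)
    beta <- backsolve(R, forwardsolve(t(R), Xty))
    rss <- max(yy - sum(beta * Xty), 0)
    sigma2 <- rss / (n - p)
    # x:c is the last column: its inverse-XtX diagonal is 1/R[p,p]^2
    tPerm <- beta[p] * R[p, p] / sqrt(sigma2)
    if (abs(tPerm) >= abs(obs$t)) s <- s + 1L
    done <- b
    if (s >= earlyStop) break
  }
  list(p_emp = (s + 1) / (done + 1), s = s, n_perm = done, observed = obs)
}

# Squared dosage correlation between two SNPs.
snpR2 <- function(panel, snp1, snp2) {
  d <- dosages(panel)
  cor(d[, snp1], d[, snp2], use = "complete.obs")^2
}

#' Select the interaction tests for a cell type
#'
#' Per cell type, eGenes significant in one condition contribute their top
#' eSNP; eGenes significant in both conditions contribute both top eSNPs
#' when those are not in high LD (`r^2 < r2Thresh`), and only the more
#' significant one otherwise (identical SNPs are tested once).
#'
#' @param egenesRest,egenesStim `egenes` data.frames from [mapCisEqtls()] for
#'   the resting and stimulated condition of one cell type.
#' @param panel a [GenotypePanel-class] (for LD).
#' @param r2Thresh high-LD cutoff (default 0.8).
#' @return data.frame `gene_id`, `snp_id`, `source` (condition(s) the SNP
#'   came from).
#' @export
selectReqtlTests <- function(egenesRest, egenesStim, panel, r2Thresh = 0.8) {
  er <- egenesRest[egenesRest$is_egene, , drop = FALSE]
  es <- egenesStim[egenesStim$is_egene, , drop = FALSE]
  genes <- union(er$gene_id, es$gene_id)
  out <- list()
  for (g in genes) {
    inR <- g %in% er$gene_id; inS <- g %in% es$gene_id
    if (inR && inS) {
      sr <- er$top_snp[er$gene_id == g]; ss <- es$top_snp[es$gene_id == g]
      if (sr == ss || snpR2(panel, sr, ss) >= r2Thresh) {
        pr <- er$top_p[er$gene_id == g]; ps <- es$top_p[es$gene_id == g]
        pick <- if (pr <= ps) sr else ss
        out[[length(out) + 1L]] <- data.frame(gene_id = g, snp_id = pick,
                                              source = "both",
                                              stringsAsFactors = FALSE)
      } else {
        out[[length(out) + 1L]] <- data.frame(
          gene_id = g, snp_id = c(sr, ss), source = c("resting", "stimulated"),
          stringsAsFactors = FALSE)
      }
    } else if (inR) {
      out[[length(out) + 1L]] <- data.frame(gene_id = g,
                                            snp_id = er$top_snp[er$gene_id == g],
                                            source = "resting",
                                            stringsAsFactors = FALSE)
    } else {
      out[[length(out) + 1L]] <- data.frame(gene_id = g,
                                            snp_id = es$top_snp[es$gene_id == g],
                                            source = "stimulated",
                                            stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(), snp_id = character(),
                      source = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Run all interaction tests for a cell type
#'
#' @param study,panel as elsewhere.
#' @param cellType cell type label.
#' @param tests data.frame from [selectReqtlTests()].
#' @param nPerm,seed,earlyStop permutation settings.
#' @return data.frame with one row per test: `gene_id`, `snp_id`, `beta`,
#'   `se`, `t`, `s`, `n_perm`, `p_emp`.
#' @export
reqtlScan <- function(study, panel, cellType, tests, nPerm = 1000L,
                      seed = 1L, earlyStop = Inf) {
  rows <- vector("list", nrow(tests))
  for (i in seq_len(nrow(tests))) {
    des <- reqtlDesign(study, panel, cellType, tests$gene_id[i],
                       tests$snp_id[i])
    pr <- permuteConditionWithinIndividual(
      des, nPerm = nPerm, seed = stageSeed(seed, paste0("perm", i)),
      earlyStop = earlyStop)
    rows[[i]] <- data.frame(
      gene_id = tests$gene_id[i], snp_id = tests$snp_id[i],
      beta = pr$observed$beta, se = pr$observed$se, t = pr$observed$t,
      s = pr$s, n_perm = pr$n_perm, p_emp = pr$p_emp,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' FDR control for response-eQTL calls
#'
#' Benjamini-Hochberg on the permutation p-values of all interaction tests
#' in a cell type; response eGenes are genes with at least one significant
#' test.
#'
#' @param results data.frame from [reqtlScan()].
#' @param alpha FDR level (default 0.05).
#' @return `results` with columns `q` and `significant` added, plus
#'   attribute `regenes` (character vector of response eGenes).
#' @export
reqtlFdr <- function(results, alpha = 0.05) {
  if (nrow(results) == 0L) {
    attr(results, "regenes") <- character()
    return(results)
  }
  bh <- bhFdr(results$p_emp, alpha = alpha)
  results$q <- bh$q
  results$significant <- bh$reject
  attr(results, "regenes") <- unique(results$gene_id[results$significant])
  results
}
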