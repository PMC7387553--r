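#' @include mr.R
NULL

#' Storey pi0 estimate (smoother method)
#'
#' For each lambda in the grid, `pi0(lambda) = #{p > lambda} / (n (1 -
#' lambda))`; a natural cubic smoothing spline (3 d.f.) through these values
#' is evaluated at the largest lambda and clipped to the unit interval.  Deterministic.
#'
#' @param p p-values (n >= 10; fewer is an error, the estimate is unstable).
#' @param lambda evaluation grid (default 0.05 to 0.95 by 0.05).
#' @return list with `pi0`, `pi1 = 1 - pi0`, and the raw `pi0_lambda` grid.
#' @export
pi0Estimate <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  if (length(p) < 10) stop("pi0 estimation needs at least 10 p-values")
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be finite and in [0, 1]")
  n <- length(p)
  pi0l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- smooth.spline(lambda, pi0l, df = 3)
  pi0 <- predict(fit, x = max(lambda))$y
  pi0 <- min(max(pi0, 0), 1)
  list(pi0 = pi0, pi1 = 1 - pi0, pi0_lambda = setNames(pi0l, lambda))
}

#' Replication rate (pi1) of one dataset's significant pairs in another
#'
#' Looks up the discovery-significant gene-SNP pairs in the replication
#' dataset's p-values and estimates the proportion of true alternatives
#' among them as `pi1 = 1 - pi0`.  Unmatched pairs are counted and excluded.
#' Note (as recorded in the returned metadata) that this sharing measure
#' ignores the direction and magnitude of the effects.
#'
#' @param discoveryPairs data.frame with `gene_id`, `snp_id` of significant
#'   discovery associations.
#' @param replication data.frame with `gene_id`, `snp_id`, `p` from the
#'   replication dataset.
#' @return list with `pi1`, `pi0`, `n_pairs` (matched), `n_unmatched`, and
#'   `note`.
#' @export
replicationRate <- function(discoveryPairs, replication) {
  keyD <- paste(discoveryPairs$gene_id, discoveryPairs$snp_id)
  keyR <- paste(replication$gene_id, replication$snp_id)
  m <- match(keyD, keyR)
  matched <- !is.na(m)
  if (!any(matched)) stop("no discovery pair found in the replication set")
  p <- replication$p[m[matched]]
  est <- pi0Estimate(p)
  list(pi1 = est$pi1, pi0 = est$pi0, n_pairs = sum(matched),
       n_unmatched = sum(!matched),
       note = paste("pi1 quantifies p-value sharing only; it does not take",
                    "the direction or magnitude of effects into account"))
}
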