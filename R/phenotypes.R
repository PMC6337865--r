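#' Simulate heritable phenotypes
#'
#' Draws `n_causal` causal variants at random, samples additive effects from
#' a standard normal, builds true breeding values (TBV) from the diploid
#' genotypes and adds a residual whose variance is rescaled so that the
#' realised ratio Var(TBV)/Var(y) equals `target_h2` (the residual is
#' orthogonalised against TBV and variance-matched, so the realised
#' heritability is exact up to floating point rather than merely in
#' expectation). Phenotypes play the role of already covariate-adjusted
#' records.
#'
#' @param panel a [haplotype_panel()].
#' @param n_causal number of causal variants.
#' @param target_h2 narrow-sense heritability in `[0, 1]`.
#' @param seed optional integer seed.
#' @return A tibble with `individual_id`, `y_adj`, `true_breeding_value`,
#'   `target_h2`; causal variant indices and effects are kept in the
#'   `causal` attribute.
#' @export
simulate_phenotypes <- function(panel, n_causal = 100L, target_h2 = 0.3,
                                seed = NULL) {
  if (target_h2 < 0 || target_h2 > 1) {
    stop("target_h2 must lie in [0, 1]", call. = FALSE)
  }
  if (n_causal > n_variants(panel)) {
    stop("n_causal exceeds the number of variants", call. = FALSE)
  }
  n <- n_individuals(panel)
  with_seed_if(seed, {
    causal <- sort(sample.int(n_variants(panel), n_causal))
    effects <- rnorm(n_causal)
    if (target_h2 == 0) effects[] <- 0
    G <- genotype_matrix(panel)[, causal, drop = FALSE]
    tbv <- drop(G %*% effects)
    tbv <- tbv - mean(tbv)
    if (target_h2 == 1) {
      y <- tbv
    } else if (target_h2 == 0 || var(tbv) == 0) {
      y <- rnorm(n)
      tbv <- rep(0, n)
    } else {
      e <- rnorm(n)
      # strip the TBV component, then match the residual variance exactly
      e <- e - tbv * (sum(e * tbv) / sum(tbv^2))
      e <- e * sqrt(var(tbv) * (1 - target_h2) / target_h2 / var(e))
      y <- tbv + e
    }
    out <- tibble::tibble(
      individual_id = panel$individual_ids,
      y_adj = y, true_breeding_value = tbv, target_h2 = target_h2
    )
    attr(out, "causal") <- tibble::tibble(variant_idx = causal, effect = effects)
    out
  })
}
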