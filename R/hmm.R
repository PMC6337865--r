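#' Haplotype-copying HMM parameters
#'
#' @param error_rate per-site allele mismatch probability at typed sites
#'   (in `(0, 0.5)`).
#' @param switch_scale expected haplotype switches per Morgan; the default
#'   100 gives roughly one expected switch per Mb at the default map scale.
#' @param cm_per_mb map-scale constant (centimorgan per megabase) used to
#'   convert physical to map distance.
#' @return An `hmm_params` list.
#' @export
hmm_params <- function(error_rate = 1e-3, switch_scale = 100, cm_per_mb = 1) {
  stopifnot(error_rate > 0, error_rate < 0.5, switch_scale > 0, cm_per_mb > 0)
  structure(list(error_rate = error_rate, switch_scale = switch_scale,
                 cm_per_mb = cm_per_mb), class = "hmm_params")
}

# per-step switch probabilities 1 - exp(-lambda * d_Morgans) between
# adjacent variants; independent chromosomes switch with probability 1
switch_probs <- function(variants, params) {
  m <- nrow(variants)
  if (m < 2) return(numeric(0))
  d <- diff(variants$pos)
  same <- variants$chrom[-1] == variants$chrom[-m]
  morgans <- d * params$cm_per_mb / 1e6 / 100
  rho <- 1 - exp(-params$switch_scale * morgans)
  rho[!same] <- 1
  rho
}

#' Li-Stephens copying posteriors for one target haplotype
#'
#' Runs the scaled forward-backward pass of the haplotype-copying HMM:
#' hidden state = which reference haplotype is being copied; between
#' adjacent variants at map distance d the chain stays put with probability
#' `exp(-lambda d) + (1 - exp(-lambda d))/H` and moves to each other
#' haplotype with probability `(1 - exp(-lambda d))/H`; typed sites emit the
#' observed allele with probability `1 - error_rate` on match, `error_rate`
#' on mismatch; untyped sites are uninformative. The posterior allele dosage
#' at variant j is the posterior-weighted mean of the reference alleles.
#'
#' @param target_alleles integer vector over the reference variants with the
#'   observed allele (0/1) at typed positions and `NA` elsewhere.
#' @param ref a [haplotype_panel()] providing the reference haplotypes.
#' @param params an [hmm_params()].
#' @param keep_posteriors return the full variants x haplotypes posterior
#'   matrix (memory-heavy; intended for small instances).
#' @return List with `dosage` (length = reference variants), `loglik` and,
#'   optionally, `posteriors`.
#' @export
li_stephens_posteriors <- function(target_alleles, ref, params = hmm_params(),
                                   keep_posteriors = FALSE) {
  stopifnot(length(target_alleles) == n_variants(ref))
  if (nrow(ref$haplotypes) < 2) {
    stop("reference panel must hold at least 2 haplotypes", call. = FALSE)
  }
  obs <- ifelse(is.na(target_alleles), -1L, as.integer(target_alleles))
  rho <- switch_probs(ref$variants, params)
  ls_forward_backward_cpp(ref$haplotypes, obs, rho, params$error_rate,
                          keep_posteriors)
}

#' Minimac-style dosage R-squared quality statistic
#'
#' Measures how far the haplotype dosages at one variant are from their
#' shrunken expectation under the estimated allele frequency: with
#' \eqn{\hat p} the mean haplotype dosage, `rsq` is the population variance
#' of the dosages (dividing by the haplotype count) over
#' \eqn{\hat p (1-\hat p)}. Fully shrunk (constant) dosages give 0; hard 0/1
#' dosages give 1. The raw value can marginally exceed 1; clamping to
#' `[0, 1]` is applied only downstream for binning/reporting.
#'
#' @param hap_dosages numeric vector of per-haplotype dosages in `[0, 1]`
#'   (at one variant, across all target haplotypes), or a matrix with one
#'   column per variant.
#' @return The raw `rsq` value (or vector, for a matrix input).
#' @export
rsq_statistic <- function(hap_dosages) {
  if (is.matrix(hap_dosages)) {
    if (nrow(hap_dosages) < 2) stop("need >= 2 haplotype dosages", call. = FALSE)
    if (any(hap_dosages < 0 | hap_dosages > 1)) {
      stop("haplotype dosages must lie in [0, 1]", call. = FALSE)
    }
    p <- colMeans(hap_dosages)
    v <- colMeans(hap_dosages^2) - p^2
    out <- ifelse(p <= 0 | p >= 1, 0, v / (p * (1 - p)))
    return(pmax(out, 0))
  }
  if (length(hap_dosages) < 2) stop("need >= 2 haplotype dosages", call. = FALSE)
  if (any(hap_dosages < 0 | hap_dosages > 1)) {
    stop("haplotype dosages must lie in [0, 1]", call. = FALSE)
  }
  p <- mean(hap_dosages)
  if (p <= 0 || p >= 1) return(0)
  max(mean((hap_dosages - p)^2) / (p * (1 - p)), 0)
}
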