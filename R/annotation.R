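#' Assign annotation-class labels to variants
#'
#' A label simulator (not a functional predictor): every variant gets one of
#' the five classes `intergenic`, `intronic`, `updownstream5kb`, `missense`,
#' `utr`. Realised class counts match the requested proportions exactly
#' (largest-remainder rounding), and classes with a positive MAF bias are
#' preferentially drawn from rare variants (sampling weight
#' \eqn{e^{-bias \cdot maf}}), so that e.g. missense variants end up with a
#' larger share of MAF < 0.05 than intergenic variants.
#'
#' @param variants a variant tibble with a `maf` column (or a
#'   [haplotype_panel()], whose variant table is used and returned updated).
#' @param class_proportions named proportions over the five classes,
#'   summing to 1.
#' @param class_maf_bias named non-negative rare-preference weights.
#' @param seed optional integer seed.
#' @return The input with `annotation_class` filled in.
#' @export
assign_annotation_classes <- function(variants,
                                      class_proportions = c(
                                        intergenic = 0.63, intronic = 0.30,
                                        updownstream5kb = 0.064,
                                        missense = 0.003, utr = 0.003),
                                      class_maf_bias = c(
                                        intergenic = 0, intronic = 0,
                                        updownstream5kb = 3,
                                        missense = 20, utr = 10),
                                      seed = NULL) {
  if (inherits(variants, "haplotype_panel")) {
    panel <- variants
    panel$variants <- assign_annotation_classes(
      panel$variants, class_proportions, class_maf_bias, seed
    )
    return(panel)
  }
  classes <- c("intergenic", "intronic", "updownstream5kb", "missense", "utr")
  stopifnot(all(classes %in% names(class_proportions)))
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    stop("class_proportions must sum to 1", call. = FALSE)
  }
  n <- nrow(variants)
  # largest-remainder apportionment of exact class counts
  raw <- class_proportions[classes] * n
  cnt <- floor(raw)
  left <- n - sum(cnt)
  if (left > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(left)]
    cnt[extra] <- cnt[extra] + 1
  }

  with_seed_if(seed, {
    label <- rep(NA_character_, n)
    unassigned <- seq_len(n)
    # most rare-biased classes pick first so their weighting bites
    for (cl in names(sort(class_maf_bias[classes], decreasing = TRUE))) {
      k <- cnt[[cl]]
      if (k == 0 || !length(unassigned)) next
      w <- exp(-class_maf_bias[[cl]] * variants$maf[unassigned])
      take <- if (k >= length(unassigned)) {
        unassigned
      } else {
        unassigned[sample.int(length(unassigned), k, prob = w)]
      }
      label[take] <- cl
      unassigned <- setdiff(unassigned, take)
    }
    variants$annotation_class <- label
    variants
  })
}
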