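#' Filter a reference panel on minor allele count
#'
#' Restricts the panel to biallelic variants with MAC >= `min_mac` (the
#' conventional reference-panel cleanup before imputation; the default
#' removes variants with minor allele counts below 5 across the reference
#' animals). A removal log with per-reason counts is attached.
#'
#' @param panel a [haplotype_panel()].
#' @param min_mac minimum minor allele count to retain.
#' @param keep_positions optional tibble of `chrom`, `pos` (e.g. an array
#'   panel) exempt from the MAC filter — array positions must stay in the
#'   imputation scope even when rare in a reduced reference.
#' @return The filtered [haplotype_panel()] with a `removal_log` attribute
#'   (tibble of `reason`, `n`).
#' @export
filter_reference <- function(panel, min_mac = 5L, keep_positions = NULL) {
  v <- panel$variants
  biallelic <- nchar(v$ref_allele) == 1L & nchar(v$alt_allele) == 1L &
    v$ref_allele != v$alt_allele
  keep <- biallelic & v$mac >= min_mac
  if (!is.null(keep_positions)) {
    keep <- keep | variant_key(v) %in%
      variant_key(keep_positions)
  }
  log <- tibble::tibble(
    reason = c("multiallelic", "low_mac", "retained"),
    n = c(sum(!biallelic), sum(biallelic & v$mac < min_mac), sum(keep))
  )
  if (!any(keep)) warning("reference panel is empty after MAC filtering")
  out <- subset_panel(panel, variant_idx = which(keep))
  attr(out, "removal_log") <- log
  out
}

#' Impute a masked target panel against a reference panel
#'
#' Runs the Li-Stephens copying HMM ([li_stephens_posteriors()]) for each
#' target haplotype over the full reference variant scope. Per-individual
#' genotype dosages are the sum of the individual's two haplotype dosages;
#' most-likely genotypes are the dosage rounded half-to-even and clamped to
#' `{0, 1, 2}`; the per-variant quality statistic comes from
#' [rsq_statistic()] over all target haplotype dosages.
#'
#' @param targets a phased [haplotype_panel()] restricted to the array
#'   positions.
#' @param ref the reference [haplotype_panel()] (already MAC-filtered).
#' @param array the [ascertain_array_panel()] the targets were typed on.
#' @param params an [hmm_params()].
#' @return An `imputed_set`: list with `variants` (reference variant table
#'   plus `rsq`, `typed`), `hap_dosages` (haplotypes x variants),
#'   `geno_dosages`, `most_likely` (individuals x variants) and
#'   `individual_ids`.
#' @export
impute_panel <- function(targets, ref, array, params = hmm_params()) {
  ref_keys <- variant_key(ref$variants)
  arr_keys <- variant_key(array)
  typed_idx <- match(arr_keys, ref_keys)
  if (anyNA(typed_idx)) {
    stop("typed position absent from reference panel: ",
         paste(head(arr_keys[is.na(typed_idx)], 3), collapse = ", "),
         call. = FALSE)
  }
  tgt_keys <- variant_key(targets$variants)
  if (!identical(sort(tgt_keys), sort(arr_keys))) {
    stop("target panel is not restricted to the array positions", call. = FALSE)
  }
  tgt_order <- match(arr_keys, tgt_keys)

  M <- n_variants(ref)
  n_hap <- nrow(targets$haplotypes)
  hap_dos <- matrix(0, nrow = n_hap, ncol = M)
  obs <- rep(NA_integer_, M)
  for (h in seq_len(n_hap)) {
    obs[] <- NA_integer_
    obs[typed_idx] <- targets$haplotypes[h, tgt_order]
    hap_dos[h, ] <- li_stephens_posteriors(obs, ref, params)$dosage
  }
  hap_dos <- pmin(pmax(hap_dos, 0), 1)

  odd <- seq(1L, n_hap, by = 2L)
  geno <- hap_dos[odd, , drop = FALSE] + hap_dos[odd + 1L, , drop = FALSE]
  most <- round(pmin(pmax(geno, 0), 2))
  storage.mode(most) <- "integer"

  variants <- ref$variants
  variants$rsq <- rsq_statistic(hap_dos)
  variants$typed <- FALSE
  variants$typed[typed_idx] <- TRUE

  structure(
    list(variants = variants, hap_dosages = hap_dos, geno_dosages = geno,
         most_likely = most, individual_ids = targets$individual_ids),
    class = "imputed_set"
  )
}

#' @export
print.imputed_set <- function(x, ...) {
  cat("<imputed_set> ", length(x$individual_ids), " individuals x ",
      nrow(x$variants), " variants (", sum(x$variants$typed),
      " typed)\n", sep = "")
  invisible(x)
}

# harden an imputed_set to a phased panel of most-likely haplotype alleles
harden_to_panel <- function(imputed, template_variants, individual_ids,
                            breed_labels) {
  hap <- round(imputed$hap_dosages)
  storage.mode(hap) <- "integer"
  haplotype_panel(hap, template_variants, individual_ids, breed_labels)
}

#' Stepwise (chained) imputation through intermediate array densities
#'
#' Emulates imputation from a low-density array to sequence through
#' intermediate densities: LD positions are imputed up to the 50k scope,
#' hardened to most-likely haplotype alleles, imputed up to the HD scope,
#' hardened again, and finally imputed to the full sequence scope. The
#' final `typed` mask marks the HD positions (downstream accuracy
#' evaluation excludes typed positions).
#'
#' @param targets_ld phased target panel restricted to the LD positions.
#' @param ref the full-sequence reference [haplotype_panel()]
#'   (MAC-filtered); the 50k- and HD-scope references are derived from it.
#' @param arrays named list of [ascertain_array_panel()]s with elements
#'   `LD`, `50k`, `HD`, nested (`LD` within `50k` within `HD`).
#' @param params an [hmm_params()].
#' @param ref_50k,ref_hd optional explicit intermediate reference panels; by
#'   default the full-sequence reference masked to the 50k / HD positions
#'   (passing different intermediate references mirrors pipelines whose
#'   chip-density reference sets contain different animals).
#' @return An `imputed_set` over the full reference scope.
#' @export
stepwise_impute <- function(targets_ld, ref, arrays, params = hmm_params(),
                            ref_50k = NULL, ref_hd = NULL) {
  stopifnot(all(c("LD", "50k", "HD") %in% names(arrays)))
  key <- variant_key
  if (!all(key(arrays$LD) %in% key(arrays$`50k`)) ||
      !all(key(arrays$`50k`) %in% key(arrays$HD)) ||
      !all(key(arrays$HD) %in% variant_key(ref$variants))) {
    stop("array panels must be nested: LD within 50k within HD within the reference scope",
         call. = FALSE)
  }
  ref50 <- ref_50k %||% mask_to_panel(ref, arrays$`50k`)
  refhd <- ref_hd %||% mask_to_panel(ref, arrays$HD)

  s1 <- impute_panel(targets_ld, ref50, arrays$LD, params)
  t50 <- harden_to_panel(s1, ref50$variants, targets_ld$individual_ids,
                         targets_ld$breed_labels)
  s2 <- impute_panel(t50, refhd, arrays$`50k`, params)
  thd <- harden_to_panel(s2, refhd$variants, targets_ld$individual_ids,
                         targets_ld$breed_labels)
  impute_panel(thd, ref, arrays$HD, params)
}
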