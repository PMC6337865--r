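#' Balanced cross-validation fold plan
#'
#' Random balanced partition of individuals into `k` folds (sizes differ by
#' at most 1). In each fold's run the held-out individuals are imputation
#' targets while the remaining individuals stay in the reference.
#'
#' @param individual_ids character vector of ids.
#' @param k number of folds (default fivefold).
#' @param seed optional integer seed.
#' @return A `fold_plan` tibble with `individual_id` and `fold`.
#' @export
make_fold_plan <- function(individual_ids, k = 5L, seed = NULL) {
  n <- length(individual_ids)
  if (k < 2 || k > n) {
    stop("k must lie in [2, number of individuals]", call. = FALSE)
  }
  with_seed_if(seed, {
    sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
    fold <- rep(seq_len(k), sizes)[sample.int(n)]
    out <- tibble::tibble(individual_id = individual_ids, fold = fold)
    structure(out, k = as.integer(k), class = c("fold_plan", class(out)))
  })
}

#' Mask a panel down to array positions
#'
#' Restricts a phased panel to exactly the array positions (emulating a
#' sequenced animal genotyped only on the chip), preserving phase.
#'
#' @param panel a [haplotype_panel()].
#' @param array an [ascertain_array_panel()] (or any tibble of
#'   `chrom`, `pos`).
#' @return The restricted [haplotype_panel()].
#' @export
mask_to_panel <- function(panel, array) {
  keys <- variant_key(panel$variants)
  arr_keys <- variant_key(array)
  idx <- match(arr_keys, keys)
  if (anyNA(idx)) {
    stop("array position absent from panel: ",
         paste(head(arr_keys[is.na(idx)], 3), collapse = ", "), call. = FALSE)
  }
  subset_panel(panel, variant_idx = sort(idx))
}

#' Cross-validated imputation of a panel
#'
#' The masking/cross-validation design: for each fold, the held-out target
#' individuals are reduced to the array positions and imputed from a
#' reference made of all remaining individuals (MAC-filtered per fold);
#' results are pooled over folds on the variant scope shared by every
#' fold's filtered reference. The pooled per-variant quality statistic is
#' recomputed from the pooled haplotype dosages.
#'
#' @param panel the truth [haplotype_panel()] (full variant density).
#' @param array the [ascertain_array_panel()] defining the typed positions.
#' @param params an [hmm_params()].
#' @param target_ids individuals eligible as imputation targets (default:
#'   all); non-target individuals always stay in the reference.
#' @param k folds (default 5).
#' @param min_mac reference MAC filter applied per fold.
#' @param seed optional integer seed (drives the fold plan).
#' @param extra_reference optional [haplotype_panel()] of additional
#'   individuals that join every fold's reference (e.g. other breeds).
#' @param stepwise_arrays optional named list of nested arrays (`LD`,
#'   `50k`, `HD`): targets are then masked to the LD positions and imputed
#'   through the chained [stepwise_impute()] route instead of directly from
#'   `array`.
#' @return An `imputation_cv` object: pooled `imputed_set` fields plus the
#'   `fold_plan` and the truth genotypes of the targets.
#' @export
run_crossval <- function(panel, array, params = hmm_params(),
                         target_ids = panel$individual_ids, k = 5L,
                         min_mac = 5L, seed = NULL, extra_reference = NULL,
                         stepwise_arrays = NULL) {
  plan <- make_fold_plan(target_ids, k = k, seed = seed)
  keep_pos <- if (is.null(stepwise_arrays)) array else stepwise_arrays$HD
  fold_sets <- vector("list", k)
  for (f in seq_len(k)) {
    held <- plan$individual_id[plan$fold == f]
    ref_ids <- setdiff(panel$individual_ids, held)
    ref <- subset_panel(panel, individuals = ref_ids)
    if (!is.null(extra_reference)) {
      ref <- bind_panels(ref, extra_reference)
    }
    ref <- filter_reference(ref, min_mac = min_mac, keep_positions = keep_pos)
    if (is.null(stepwise_arrays)) {
      targets <- mask_to_panel(subset_panel(panel, individuals = held), array)
      fold_sets[[f]] <- impute_panel(targets, ref, array, params)
    } else {
      targets <- mask_to_panel(subset_panel(panel, individuals = held),
                               stepwise_arrays$LD)
      fold_sets[[f]] <- stepwise_impute(targets, ref, stepwise_arrays, params)
    }
  }
  pool_folds(fold_sets, panel, plan)
}

# row-bind two panels sharing the same variant scope
bind_panels <- function(a, b) {
  if (!identical(variant_key(a$variants), variant_key(b$variants))) {
    stop("panels do not share a variant scope", call. = FALSE)
  }
  haplotype_panel(rbind(a$haplotypes, b$haplotypes), a$variants,
                  c(a$individual_ids, b$individual_ids),
                  c(a$breed_labels, b$breed_labels))
}

# pool per-fold imputed sets on their shared variant scope
pool_folds <- function(fold_sets, truth, plan) {
  ids <- unlist(lapply(fold_sets, `[[`, "individual_ids"))
  if (anyDuplicated(ids)) {
    stop("individual imputed in more than one fold: ",
         ids[duplicated(ids)][1], call. = FALSE)
  }
  keys <- lapply(fold_sets, function(s) variant_key(s$variants))
  shared <- Reduce(intersect, keys)
  hap <- do.call(rbind, lapply(fold_sets, function(s) {
    s$hap_dosages[, match(shared, variant_key(s$variants)), drop = FALSE]
  }))
  geno <- do.call(rbind, lapply(fold_sets, function(s) {
    s$geno_dosages[, match(shared, variant_key(s$variants)), drop = FALSE]
  }))
  most <- do.call(rbind, lapply(fold_sets, function(s) {
    s$most_likely[, match(shared, variant_key(s$variants)), drop = FALSE]
  }))
  v1 <- fold_sets[[1]]$variants
  variants <- v1[match(shared, variant_key(v1)), ]
  variants$rsq <- rsq_statistic(hap)

  structure(
    list(variants = variants, hap_dosages = hap, geno_dosages = geno,
         most_likely = most, individual_ids = ids, fold_plan = plan,
         truth = truth),
    class = "imputation_cv"
  )
}

#' @export
print.imputation_cv <- function(x, ...) {
  cat("<imputation_cv> ", length(x$individual_ids), " target individuals x ",
      nrow(x$variants), " variants pooled over ",
      attr(x$fold_plan, "k"), " folds\n", sep = "")
  invisible(x)
}

#' Per-variant empirical imputation accuracy
#'
#' For every variant, pools the (imputed value, true genotype) pairs of the
#' held-out individuals across all folds and computes the Pearson
#' correlation — the empirical imputation accuracy. Typed (array) variants
#' and variants with zero variance on either side are flagged and excluded
#' from scoring, never silently dropped.
#'
#' @param imputed an `imputation_cv` from [run_crossval()], or a list of
#'   per-fold `imputed_set`s (then `truth` and `fold_plan` are required).
#' @param truth the truth [haplotype_panel()] (defaults to the one stored in
#'   the `imputation_cv`).
#' @param fold_plan the [make_fold_plan()] used (stored in `imputation_cv`).
#' @param use_dosage score genotype dosages (`TRUE`, the dosage-based
#'   accuracy) or most-likely genotypes (`FALSE`, the hard-call accuracy).
#' @return An `accuracy_table` tibble: `chrom`, `pos`, `empirical_r`, `rsq`,
#'   `maf` (reference MAF), `window_id` (1-Mb bin), `annotation_class`,
#'   `n_individuals`, `excluded_reason`.
#' @export
per_variant_accuracy <- function(imputed, truth = NULL, fold_plan = NULL,
                                 use_dosage = TRUE) {
  if (!inherits(imputed, "imputation_cv")) {
    stopifnot(is.list(imputed), !is.null(truth), !is.null(fold_plan))
    imputed <- pool_folds(imputed, truth, fold_plan)
  }
  truth <- truth %||% imputed$truth
  v <- imputed$variants
  key <- variant_key(v)
  tkey <- variant_key(truth$variants)
  tidx <- match(key, tkey)
  if (anyNA(tidx)) stop("truth panel does not cover all imputed variants",
                        call. = FALSE)
  G <- genotype_matrix(truth)[imputed$individual_ids, tidx, drop = FALSE]
  X <- if (use_dosage) imputed$geno_dosages else imputed$most_likely

  n <- nrow(G)
  vt <- matrixStats_colvar(G)
  vi <- matrixStats_colvar(X)
  r <- rep(NA_real_, ncol(G))
  ok <- !v$typed & vt > 0 & vi > 0
  if (any(ok)) {
    Gc <- sweep(G[, ok, drop = FALSE], 2, colMeans(G[, ok, drop = FALSE]))
    Xc <- sweep(X[, ok, drop = FALSE], 2, colMeans(X[, ok, drop = FALSE]))
    r[ok] <- colSums(Gc * Xc) / sqrt(colSums(Gc^2) * colSums(Xc^2))
  }
  excluded <- dplyr::case_when(
    v$typed ~ "typed",
    vt == 0 ~ "monomorphic_truth",
    vi == 0 ~ "monomorphic_imputed",
    TRUE ~ "none"
  )
  out <- tibble::tibble(
    chrom = v$chrom, pos = v$pos,
    empirical_r = r, rsq = v$rsq,
    maf = truth$variants$maf[tidx],
    window_id = paste0(v$chrom, ":", v$pos %/% 1e6),
    annotation_class = v$annotation_class,
    n_individuals = n,
    excluded_reason = excluded
  )
  structure(out, class = c("accuracy_table", class(out)))
}

# population column variance without an extra dependency
matrixStats_colvar <- function(m) {
  colMeans(m^2) - colMeans(m)^2
}

#' Quality-statistic threshold policies
#'
#' The standard filters on the imputation quality statistic: `thr0` retains
#' everything, `thr4` retains `rsq > 0.4`, `thr8` retains `rsq > 0.8`, and
#' `thr0-4` retains the complement `rsq <= 0.4` (inclusive), used for the
#' poorly imputed stratum in the genomic-prediction experiment.
#'
#' @param name one of `"thr0"`, `"thr4"`, `"thr8"`, `"thr0-4"`.
#' @return A `threshold_policy` list with `name` and `rule` (predicate on
#'   rsq).
#' @export
threshold_policy <- function(name = c("thr0", "thr4", "thr8", "thr0-4")) {
  name <- match.arg(name)
  rule <- switch(name,
    "thr0" = function(rsq) rep(TRUE, length(rsq)),
    "thr4" = function(rsq) rsq > 0.4,
    "thr8" = function(rsq) rsq > 0.8,
    "thr0-4" = function(rsq) rsq <= 0.4
  )
  structure(list(name = name, rule = rule), class = "threshold_policy")
}

#' Apply a quality-statistic threshold to an accuracy table
#'
#' @param acc an `accuracy_table` from [per_variant_accuracy()].
#' @param policy a [threshold_policy()] or a policy name.
#' @return List with `acc` (the retained scorable variants),
#'   `retained_count` and `discarded_count`
#'   (`retained + discarded` equals the scorable total).
#' @export
apply_threshold <- function(acc, policy) {
  if (is.character(policy)) policy <- threshold_policy(policy)
  scorable <- acc[acc$excluded_reason == "none", ]
  keep <- policy$rule(scorable$rsq)
  list(acc = scorable[keep, ],
       retained_count = sum(keep),
       discarded_count = sum(!keep))
}

#' MAF-band ladders for stratified accuracy summaries
#'
#' `"contiguous"` (default) is the clean ladder 0.01-0.02, ..., 0.08-0.10,
#' 0.10-0.50; `"printed"` reproduces the conventional published ladder,
#' which skips 0.04-0.05 and lists both 0.06-0.07 and 0.06-0.08.
#'
#' @param preset `"contiguous"` or `"printed"`.
#' @return A tibble of `lower`, `upper`, `band` labels.
#' @export
maf_bands_preset <- function(preset = c("contiguous", "printed")) {
  preset <- match.arg(preset)
  if (preset == "contiguous") {
    lower <- c(0.01, 0.02, 0.03, 0.04, 0.05, 0.06, 0.07, 0.08, 0.10)
    upper <- c(0.02, 0.03, 0.04, 0.05, 0.06, 0.07, 0.08, 0.10, 0.50)
  } else {
    lower <- c(0.01, 0.02, 0.03, 0.05, 0.06, 0.06, 0.08, 0.10)
    upper <- c(0.02, 0.03, 0.04, 0.06, 0.07, 0.08, 0.10, 0.50)
  }
  tibble::tibble(lower = lower, upper = upper,
                 band = sprintf("%.2f-%.2f", lower, upper))
}

#' Stratified accuracy summaries
#'
#' Mean empirical accuracy, variant count and mean quality statistic per
#' stratum. Available stratifiers: MAF bands (half-open `[lower, upper)`),
#' 100 quality-statistic bins of width 0.01 on the clamped statistic
#' (`[l, l+0.01)`, last bin closed at 1), non-overlapping 1-Mb windows
#' (half-open), annotation class, and chromosome. Only scorable variants
#' (`excluded_reason == "none"`) enter the means; exclusion counts are
#' attached as the `exclusions` attribute so the accounting reconciles.
#' Empty strata are reported with `n = 0` and no mean.
#'
#' @param acc an `accuracy_table`.
#' @param stratifier one of `"maf_bands"`, `"rsq_bins"`, `"windows_1mb"`,
#'   `"annotation_class"`, `"chromosome"`.
#' @param maf_bands band ladder tibble (see [maf_bands_preset()]).
#' @return An `accuracy_summary` tibble with `stratum`, `n`, `mean_r`,
#'   `mean_rsq` (plus stratifier-specific columns).
#' @export
stratified_summary <- function(acc,
                               stratifier = c("maf_bands", "rsq_bins",
                                              "windows_1mb",
                                              "annotation_class",
                                              "chromosome"),
                               maf_bands = maf_bands_preset()) {
  stratifier <- match.arg(stratifier)
  stopifnot(nrow(acc) > 0)
  sc <- acc[acc$excluded_reason == "none", ]
  excl <- dplyr::count(acc[acc$excluded_reason != "none", ],
                       .data$excluded_reason, name = "n")

  summarise_groups <- function(df, key) {
    df |>
      dplyr::group_by(stratum = .data[[key]]) |>
      dplyr::summarise(n = dplyr::n(),
                       mean_r = mean(.data$empirical_r),
                       mean_rsq = mean(.data$rsq), .groups = "drop")
  }

  out <- switch(stratifier,
    maf_bands = {
      band_of <- rep(NA_character_, nrow(sc))
      top <- max(maf_bands$upper)
      for (i in seq_len(nrow(maf_bands))) {
        hit <- sc$maf >= maf_bands$lower[i] &
          (sc$maf < maf_bands$upper[i] |
             (maf_bands$upper[i] == top & sc$maf == top))
        band_of[hit & is.na(band_of)] <- maf_bands$band[i]
      }
      # variants below the first band edge are kept in the accounting
      band_of[is.na(band_of)] <- "outside_bands"
      res <- summarise_groups(dplyr::mutate(sc, band = band_of), "band")
      full <- tibble::tibble(stratum = c(maf_bands$band,
                                         if ("outside_bands" %in% res$stratum)
                                           "outside_bands")) |>
        dplyr::left_join(res, by = "stratum") |>
        dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
      full
    },
    rsq_bins = {
      rc <- pmin(pmax(sc$rsq, 0), 1)
      bin <- pmin(floor(rc / 0.01), 99)
      res <- summarise_groups(
        dplyr::mutate(sc, bin = sprintf("%.2f-%.2f", bin * 0.01,
                                        bin * 0.01 + 0.01)), "bin")
      full <- tibble::tibble(
        stratum = sprintf("%.2f-%.2f", 0:99 * 0.01, 0:99 * 0.01 + 0.01),
        midpoint = 0:99 * 0.01 + 0.005
      ) |>
        dplyr::left_join(res, by = "stratum") |>
        dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
      full
    },
    windows_1mb = {
      res <- summarise_groups(sc, "window_id")
      res |>
        tidyr::separate_wider_delim("stratum", delim = ":",
                                    names = c("chrom", "window"),
                                    cols_remove = FALSE) |>
        dplyr::mutate(window_start = as.numeric(.data$window) * 1e6,
                      window_end = (as.numeric(.data$window) + 1) * 1e6) |>
        dplyr::select(-"window") |>
        dplyr::arrange(.data$chrom, .data$window_start)
    },
    annotation_class = summarise_groups(sc, "annotation_class"),
    chromosome = summarise_groups(sc, "chrom")
  )
  structure(out, stratifier = stratifier, exclusions = excl,
            total_variants = nrow(acc),
            class = c("accuracy_summary", class(out)))
}
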