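test_that("fold plans are balanced, deterministic, and validated", {
  ids <- paste0("mer", 1:117)
  plan <- make_fold_plan(ids, k = 5, seed = 1)
  expect_setequal(as.integer(table(plan$fold)), c(24L, 24L, 23L, 23L, 23L))
  expect_identical(plan, make_fold_plan(ids, k = 5, seed = 1))
  expect_false(identical(plan$fold, make_fold_plan(ids, k = 5, seed = 2)$fold))
  expect_error(make_fold_plan(ids, k = 120), "k must lie")
  expect_error(make_fold_plan(ids, k = 1), "k must lie")
})

test_that("masking restricts exactly to array positions and is idempotent", {
  s <- small_sim()
  arr <- s$arrays$`50k`
  m1 <- mask_to_panel(s$panel, arr)
  expect_equal(n_variants(m1), nrow(arr))
  expect_identical(variant_key(m1$variants),
                   paste(arr$chrom, arr$pos, sep = ":"))
  m2 <- mask_to_panel(m1, arr)
  expect_identical(m1$haplotypes, m2$haplotypes)

  all_arr <- tibble::tibble(chrom = s$panel$variants$chrom,
                            pos = s$panel$variants$pos)
  expect_identical(mask_to_panel(s$panel, all_arr)$haplotypes,
                   s$panel$haplotypes)
  expect_error(mask_to_panel(m1, tibble::tibble(chrom = "chr1", pos = 1L)),
               "absent from panel")
})

test_that("per-variant accuracy matches the direct Pearson formula and flags degenerate cases", {
  # 4 target individuals, 3 variants: perfect, noisy, constant-truth
  truth_hap <- rbind(
    c(0L, 0L, 1L), c(0L, 0L, 1L),   # ind1: g = 0, 0, 2
    c(1L, 1L, 1L), c(0L, 0L, 1L),   # ind2: g = 1, 1, 2
    c(1L, 1L, 1L), c(1L, 1L, 1L),   # ind3: g = 2, 2, 2
    c(1L, 0L, 1L), c(0L, 1L, 1L))   # ind4: g = 1, 1, 2
  truth <- tiny_panel(truth_hap)
  dos <- rbind(c(0.0, 0.1, 0.3),
               c(1.0, 0.9, 1.1),
               c(2.0, 1.8, 0.2),
               c(1.0, 1.2, 1.9))
  imputed <- structure(list(
    variants = dplyr::mutate(truth$variants, rsq = c(0.9, 0.5, 0.2),
                             typed = FALSE),
    hap_dosages = matrix(0.5, 8, 3), geno_dosages = dos,
    most_likely = round(dos), individual_ids = truth$individual_ids),
    class = "imputed_set")
  plan <- tibble::tibble(individual_id = truth$individual_ids, fold = 1L)
  acc <- per_variant_accuracy(list(imputed), truth = truth, fold_plan = plan)
  expect_equal(acc$empirical_r[1], 1)
  expect_equal(acc$empirical_r[2], cor(c(0.1, 0.9, 1.8, 1.2), c(0, 1, 2, 1)))
  expect_equal(acc$excluded_reason[3], "monomorphic_truth")
  expect_true(is.na(acc$empirical_r[3]))
})

test_that("individuals imputed in two folds are rejected", {
  s <- small_sim()
  sub <- subset_panel(s$panel, individuals = s$panel$individual_ids[1:4])
  ref <- filter_reference(
    subset_panel(s$panel, individuals = s$panel$individual_ids[5:30]),
    keep_positions = s$arrays$LD)
  tg <- mask_to_panel(sub, s$arrays$LD)
  imp <- impute_panel(tg, ref, s$arrays$LD)
  plan <- tibble::tibble(individual_id = sub$individual_ids, fold = 1L)
  expect_error(per_variant_accuracy(list(imp, imp), truth = s$panel,
                                    fold_plan = plan),
               "more than one fold")
})

test_that("threshold policies follow the declared boundary semantics", {
  acc <- tibble::tibble(
    chrom = "chr1", pos = 1:3, empirical_r = c(0.5, 0.6, 0.7),
    rsq = c(0.2, 0.40, 0.41), maf = 0.1, window_id = "chr1:0",
    annotation_class = "intergenic", n_individuals = 10L,
    excluded_reason = "none")
  thr4 <- apply_threshold(acc, "thr4")
  expect_equal(thr4$acc$rsq, 0.41)
  expect_equal(thr4$retained_count + thr4$discarded_count, 3L)
  thr04 <- apply_threshold(acc, "thr0-4")
  expect_equal(thr04$acc$rsq, c(0.2, 0.40))
  thr0 <- apply_threshold(acc, "thr0")
  expect_equal(thr0$retained_count, 3L)
  expect_error(threshold_policy("thr5"))
})

test_that("stratified summaries reproduce a brute-force group-by and conserve counts", {
  s <- small_sim()
  cv <- run_crossval(s$panel, s$arrays$LD, hmm_params(),
                     target_ids = s$panel$individual_ids[1:20],
                     k = 4, seed = 9)
  acc <- per_variant_accuracy(cv)
  for (str in c("rsq_bins", "windows_1mb", "annotation_class", "chromosome",
                "maf_bands")) {
    sm <- stratified_summary(acc, str)
    excl <- attr(sm, "exclusions")
    expect_equal(sum(sm$n) + sum(excl$n), nrow(acc))
  }
  # brute-force recomputation of the rsq-bin means
  sm <- stratified_summary(acc, "rsq_bins")
  sc <- acc[acc$excluded_reason == "none", ]
  bin <- pmin(floor(pmin(pmax(sc$rsq, 0), 1) / 0.01), 99)
  for (b in unique(bin)) {
    lab <- sprintf("%.2f-%.2f", b * 0.01, b * 0.01 + 0.01)
    expect_equal(sm$mean_r[sm$stratum == lab],
                 mean(sc$empirical_r[bin == b]))
    expect_equal(sm$n[sm$stratum == lab], sum(bin == b))
  }
  # bin placement example: clamped rsq 0.405 falls in [0.40, 0.41)
  expect_equal(sprintf("%.2f-%.2f", floor(0.405 / 0.01) * 0.01,
                       floor(0.405 / 0.01) * 0.01 + 0.01), "0.40-0.41")
})

test_that("window means are plain arithmetic means and windows are half-open", {
  acc <- tibble::tibble(
    chrom = "chr1", pos = c(1.2e6, 1.9e6, 2.0e6),
    empirical_r = c(0.8, 0.6, 0.4), rsq = 0.9, maf = 0.2,
    window_id = paste0("chr1:", c(1.2e6, 1.9e6, 2.0e6) %/% 1e6),
    annotation_class = "intronic", n_individuals = 10L,
    excluded_reason = "none")
  sm <- stratified_summary(acc, "windows_1mb")
  w1 <- sm[sm$window_start == 1e6, ]
  expect_equal(w1$mean_r, 0.7)  # 1.2 Mb and 1.9 Mb share window [1, 2) Mb
  expect_equal(w1$n, 2L)
  expect_equal(sm$mean_r[sm$window_start == 2e6], 0.4)
})
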