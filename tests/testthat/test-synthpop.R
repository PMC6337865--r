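test_that("simulation is bit-identical under a fixed seed", {
  cfg <- sim_config(seed = 7, n_chroms = 1L, chrom_length_bp = 2e6,
                    n_variants = 800L, n_ancestral_haps = 60L,
                    breeds = list(A = list(n_individuals = 10L,
                                           n_founder_haps = 40L,
                                           n_gen = 20L, ne_haps = 120L)),
                    crosses = list(), array_sizes = c(HD = 100L))
  p1 <- simulate_population(cfg)
  p2 <- simulate_population(cfg)
  expect_identical(p1$haplotypes, p2$haplotypes)
  expect_identical(p1$variants, p2$variants)
})

test_that("site-frequency spectrum is rare-skewed", {
  s <- small_sim()
  v <- s$panel$variants
  expect_gt(mean(v$maf < 0.05), 0.40)
  expect_gt(sum(v$maf < 0.05), sum(v$maf >= 0.45))
})

test_that("breed divergence: Fst grows with divergence generations and matches a brute-force estimator", {
  fst_at <- function(gens, seed) {
    cfg <- sim_config(seed = seed, n_chroms = 1L, chrom_length_bp = 5e6,
                      n_variants = 2000L, n_ancestral_haps = 80L,
                      breeds = list(
                        A = list(n_individuals = 25L, n_founder_haps = 50L,
                                 n_gen = as.integer(gens), ne_haps = 100L),
                        B = list(n_individuals = 25L, n_founder_haps = 50L,
                                 n_gen = as.integer(gens), ne_haps = 100L)),
                      crosses = list(), array_sizes = c(HD = 100L))
    hudson_fst(simulate_population(cfg), "A", "B")
  }
  seeds <- c(101, 202, 303)
  f5 <- mean(sapply(seeds, function(s) fst_at(5, s)))
  f20 <- mean(sapply(seeds, function(s) fst_at(20, s)))
  f50 <- mean(sapply(seeds, function(s) fst_at(50, s)))
  expect_lt(f5, f20)
  expect_lt(f20, f50)

  # package estimator agrees with the long-hand per-site computation
  s <- small_sim()
  ia <- which(s$panel$breed_labels == "A")
  ib <- which(s$panel$breed_labels == "B")
  ha <- s$panel$haplotypes[as.vector(rbind(2 * ia - 1, 2 * ia)), ]
  hb <- s$panel$haplotypes[as.vector(rbind(2 * ib - 1, 2 * ib)), ]
  expect_equal(hudson_fst(s$panel, "A", "B"), brute_hudson_fst(ha, hb),
               tolerance = 1e-12)
})

test_that("undiverged breeds show Fst near zero", {
  cfg <- sim_config(seed = 9, n_chroms = 1L, chrom_length_bp = 5e6,
                    n_variants = 3000L, n_ancestral_haps = 100L,
                    breeds = list(
                      A = list(n_individuals = 30L, n_founder_haps = 100L,
                               n_gen = 0L, ne_haps = 200L),
                      B = list(n_individuals = 30L, n_founder_haps = 100L,
                               n_gen = 0L, ne_haps = 200L)),
                    crosses = list(), array_sizes = c(HD = 100L))
  # n_gen = 0: both breeds resample the shared pool directly; Fst should sit
  # within sampling noise of 0 (3 SE over per-site estimates)
  p <- simulate_population(cfg)
  f <- hudson_fst(p, "A", "B")
  expect_lt(abs(f), 0.02)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(breeds = list(A = list(n_individuals = 5L,
                                                 n_founder_haps = 10L,
                                                 n_gen = 5L, ne_haps = 20L)),
                          crosses = list(F1 = list(parents = c("A", "B"),
                                                   n_individuals = 2L))),
               "at least 2 breeds")
  expect_error(sim_config(n_variants = 50L, array_sizes = c(HD = 100L)),
               "smaller than the largest array")
  expect_error(sim_config(class_proportions = c(intergenic = 0.5,
                                                intronic = 0.4,
                                                updownstream5kb = 0.05,
                                                missense = 0.01, utr = 0.01)),
               "sum to 1")
})

test_that("array ascertainment enforces the MAF floor and flattens the spectrum", {
  s <- small_sim()
  hd <- s$arrays$HD
  v <- s$panel$variants
  keys <- paste(v$chrom, v$pos)
  maf_hd <- v$maf[match(paste(hd$chrom, hd$pos), keys)]
  expect_true(all(maf_hd >= 0.05))
  expect_true(!is.unsorted(hd$pos, strictly = TRUE))

  # uniform_maf balances decile counts better than random_common
  decile_counts <- function(arr) {
    m <- v$maf[match(paste(arr$chrom, arr$pos), keys)]
    tabulate(cut(m, seq(0.05, 0.5, length.out = 11),
                 include.lowest = TRUE, labels = FALSE), 10)
  }
  a_u <- ascertain_array_panel(s$panel, 200L, maf_floor = 0.05,
                               scheme = "uniform_maf", seed = 3)
  a_r <- ascertain_array_panel(s$panel, 200L, maf_floor = 0.05,
                               scheme = "random_common", seed = 3)
  expect_lt(sd(decile_counts(a_u)), sd(decile_counts(a_r)))
})

test_that("ascertainment edge cases: exhaustive selection and shortfall", {
  s <- small_sim()
  eligible <- sum(s$panel$variants$maf >= 0.3)
  full <- ascertain_array_panel(s$panel, eligible, maf_floor = 0.3, seed = 1)
  expect_equal(nrow(full), eligible)
  expect_setequal(paste(full$chrom, full$pos),
                  paste(s$panel$variants$chrom,
                        s$panel$variants$pos)[s$panel$variants$maf >= 0.3])
  expect_error(ascertain_array_panel(s$panel, eligible + 1, maf_floor = 0.3),
               "deficit 1")
})

test_that("nested panels satisfy LD within 50k within HD exactly", {
  s <- small_sim()
  key <- function(a) paste(a$chrom, a$pos)
  expect_true(all(key(s$arrays$LD) %in% key(s$arrays$`50k`)))
  expect_true(all(key(s$arrays$`50k`) %in% key(s$arrays$HD)))
  expect_equal(nrow(s$arrays$LD), 60L)
  expect_equal(nrow(s$arrays$HD), 400L)
})

test_that("annotation classes hit requested proportions and MAF bias", {
  s <- small_sim()
  v <- assign_annotation_classes(s$panel$variants, seed = 11)
  props <- table(v$annotation_class) / nrow(v)
  expect_equal(unname(props[["intergenic"]]), 0.63, tolerance = 0.01)
  expect_equal(unname(props[["intronic"]]), 0.30, tolerance = 0.01)
  # rare-skew: missense rare fraction exceeds intergenic rare fraction
  rare <- tapply(v$maf < 0.05, v$annotation_class, mean)
  expect_gt(rare[["missense"]], rare[["intergenic"]])

  all_ig <- assign_annotation_classes(
    s$panel$variants,
    class_proportions = c(intergenic = 1, intronic = 0,
                          updownstream5kb = 0, missense = 0, utr = 0),
    seed = 1)
  expect_true(all(all_ig$annotation_class == "intergenic"))
})

test_that("phenotype simulation realises the target heritability", {
  s <- small_sim()
  ph <- simulate_phenotypes(s$panel, n_causal = 50L, target_h2 = 0.3,
                            seed = 5)
  ratio <- var(ph$true_breeding_value) / var(ph$y_adj)
  expect_equal(ratio, 0.3, tolerance = 0.02)

  ph0 <- simulate_phenotypes(s$panel, n_causal = 50L, target_h2 = 0,
                             seed = 5)
  expect_true(all(ph0$true_breeding_value == 0))

  ph1 <- simulate_phenotypes(s$panel, n_causal = 50L, target_h2 = 1,
                             seed = 5)
  expect_equal(ph1$y_adj, ph1$true_breeding_value)

  expect_error(simulate_phenotypes(s$panel, 50L, target_h2 = 1.2),
               "target_h2")
})

test_that("low-fidelity region injection respects bounds, density and identity", {
  s <- small_sim()
  p <- s$panel
  expect_identical(inject_low_fidelity_region(p, list(chrom = "chr1",
                                                      start = 1e6, end = 2e6),
                                              error_rate = 0,
                                              density_multiplier = 1), p)

  region <- list(chrom = "chr1", start = 2e6, end = 5e6)
  p2 <- inject_low_fidelity_region(p, region, error_rate = 0.2,
                                   density_multiplier = 3, seed = 8)
  in_reg <- function(pp) sum(pp$variants$pos >= 2e6 & pp$variants$pos < 5e6)
  n0 <- in_reg(p); n2 <- in_reg(p2)
  # ~3x the original count, Poisson tolerance (4 sd)
  expect_gt(n2, 3 * n0 - 4 * sqrt(2 * n0))
  expect_lt(n2, 3 * n0 + 4 * sqrt(2 * n0))
  # inserted positions stay inside the region; outside is untouched
  new_keys <- setdiff(variant_key(p2$variants), variant_key(p$variants))
  new_pos <- as.numeric(sub("chr1:", "", new_keys))
  expect_true(all(new_pos >= 2e6 & new_pos < 5e6))
  out_idx2 <- which(!(p2$variants$pos >= 2e6 & p2$variants$pos < 5e6))
  out_idx1 <- which(!(p$variants$pos >= 2e6 & p$variants$pos < 5e6))
  expect_identical(p2$haplotypes[, out_idx2], p$haplotypes[, out_idx1])

  expect_error(inject_low_fidelity_region(p, list(chrom = "chr9",
                                                  start = 0, end = 1e6)),
               "not present")
})
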