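# Independent brute-force oracles and small fixture builders shared by the
# test files. Everything here is deliberately naive: enumeration, direct
# formula evaluation, hand-rolled group-bys.

# hand-built phased panel: haplotypes is a plain matrix (rows = haplotypes);
# an odd row count (pure reference haplotype sets) bypasses the diploid
# individual bookkeeping, which the copying HMM never consults
tiny_panel <- function(haplotypes, pos = NULL, chrom = "chr1",
                       breeds = NULL) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  m <- ncol(haplotypes)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  variants <- tibble::tibble(chrom = rep(chrom, m), pos = as.integer(pos),
                             ref_allele = rep("A", m),
                             alt_allele = rep("C", m))
  if (nrow(haplotypes) %% 2 == 1) {
    obj <- structure(
      list(haplotypes = haplotypes, variants = variants,
           individual_ids = paste0("hap", seq_len(nrow(haplotypes))),
           breed_labels = rep("X", nrow(haplotypes)), phased = TRUE),
      class = "haplotype_panel")
    return(wgsimpute:::refresh_freqs(obj))
  }
  n_ind <- nrow(haplotypes) / 2
  if (is.null(breeds)) breeds <- rep("X", n_ind)
  haplotype_panel(haplotypes, variants, paste0("ind", seq_len(n_ind)), breeds)
}

# exhaustive hidden-path enumeration for the haplotype-copying HMM.
# ref: H x M 0/1 matrix; obs: length-M with NA at untyped sites;
# rho: length-(M-1) switch probabilities; eps: mismatch probability.
enum_posteriors <- function(ref, obs, rho, eps) {
  H <- nrow(ref); M <- ncol(ref)
  emis <- function(j, h) {
    if (is.na(obs[j])) 1 else if (ref[h, j] == obs[j]) 1 - eps else eps
  }
  trans <- function(r, same) if (same) (1 - r) + r / H else r / H
  paths <- as.matrix(expand.grid(rep(list(seq_len(H)), M)))
  post <- matrix(0, M, H)
  total <- 0
  for (i in seq_len(nrow(paths))) {
    pth <- paths[i, ]
    pr <- 1 / H * emis(1, pth[1])
    if (M > 1) {
      for (j in 2:M) {
        pr <- pr * trans(rho[j - 1], pth[j] == pth[j - 1]) * emis(j, pth[j])
      }
    }
    total <- total + pr
    for (j in seq_len(M)) post[j, pth[j]] <- post[j, pth[j]] + pr
  }
  post <- post / total
  list(posteriors = post,
       dosage = sapply(seq_len(M), function(j) sum(post[j, ] * ref[, j])))
}

# draw a random small HMM instance for property tests
random_hmm_instance <- function() {
  H <- sample(2:3, 1)
  M <- sample(1:4, 1)
  ref <- matrix(sample(0:1, H * M, replace = TRUE), nrow = H)
  obs <- ifelse(runif(M) < 0.6, sample(0:1, M, replace = TRUE), NA)
  rho <- runif(max(M - 1, 0), 0.01, 0.9)
  eps <- runif(1, 0.01, 0.3)
  list(ref = ref, obs = obs, rho = rho, eps = eps)
}

# per-site Hudson Fst, ratio of averages, computed the long way
brute_hudson_fst <- function(ha, hb) {
  nums <- c(); dens <- c()
  for (j in seq_len(ncol(ha))) {
    p1 <- mean(ha[, j]); p2 <- mean(hb[, j])
    if (p1 + p2 == 0 || p1 + p2 == 2) next
    n1 <- nrow(ha); n2 <- nrow(hb)
    nums <- c(nums, (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) -
                p2 * (1 - p2) / (n2 - 1))
    dens <- c(dens, p1 * (1 - p2) + p2 * (1 - p1))
  }
  mean(nums) / mean(dens)
}

# small shared simulation used by several unit tests (built once per run)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(
        seed = 42, n_chroms = 1L, chrom_length_bp = 1e7, n_variants = 4000L,
        n_ancestral_haps = 120L,
        breeds = list(
          A = list(n_individuals = 30L, n_founder_haps = 80L,
                   n_gen = 60L, ne_haps = 400L),
          B = list(n_individuals = 15L, n_founder_haps = 40L,
                   n_gen = 60L, ne_haps = 200L)
        ),
        crosses = list(F1 = list(parents = c("A", "B"), n_individuals = 8L)),
        array_sizes = c(LD = 60L, `50k` = 150L, HD = 400L)
      )
      panel <- assign_annotation_classes(simulate_population(cfg), seed = 1)
      arrays <- ascertain_nested_panels(panel, cfg$array_sizes,
                                        maf_floor = cfg$array_maf_floor,
                                        seed = 2)
      cache <<- list(cfg = cfg, panel = panel, arrays = arrays)
    }
    cache
  }
})
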