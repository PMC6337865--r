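#' Simulation configuration
#'
#' Bundles every knob of the synthetic-population generator. The defaults
#' describe a desk-scale genome (2 chromosomes x 20 Mb, 40k variants,
#' 160 individuals across three pure breeds plus an F1 cross) standing in
#' for a whole-genome multi-breed sequenced reference; every dimension is
#' configurable.
#'
#' @param seed integer seed; every run with the same config is bit-identical.
#' @param n_chroms,chrom_length_bp,n_variants genome dimensions (variants are
#'   spread near-evenly over chromosomes).
#' @param n_ancestral_haps size of the shared ancestral haplotype pool from
#'   which all breeds descend.
#' @param spectrum_skew exponent of the allele-frequency density
#'   \eqn{f^{-skew}} used for ancestral variants; 1 gives the neutral-like
#'   1/f spectrum, strongly rare-skewed.
#' @param recomb_rate_per_bp_per_gen expected crossovers per bp per meiosis.
#' @param breeds named list; each entry a list with `n_individuals`,
#'   `n_founder_haps` (bottleneck draw from the ancestral pool),
#'   `n_gen` (divergence generations of mosaic descent) and `ne_haps`
#'   (haplotypes maintained per generation).
#' @param crosses named list of F1 crosses; each entry a list with
#'   `parents` (two breed names) and `n_individuals`.
#' @param array_sizes named integer vector of SNP-array target sizes,
#'   ordered from sparsest to densest (default LD/50k/HD at reduced scale).
#' @param array_maf_floor ascertainment MAF floor applied to array SNPs.
#' @param class_proportions named proportions over the five annotation
#'   classes (defaults follow the genome-wide mix: 63% intergenic,
#'   30% intronic, 6.4% up/downstream, 0.3% missense, 0.3% UTR).
#' @param class_maf_bias named non-negative weights; classes with larger
#'   bias are preferentially assigned to rare variants
#'   (weight \eqn{\propto e^{-bias \cdot maf}}).
#' @param problem_regions list of low-fidelity regions, each a list with
#'   `chrom`, `start`, `end`, `error_rate`, `density_multiplier`.
#'
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_length_bp = 20e6,
                       n_variants = 52000L,
                       n_ancestral_haps = 320L,
                       spectrum_skew = 1,
                       recomb_rate_per_bp_per_gen = 1.2e-8,
                       breeds = list(
                         MER = list(n_individuals = 80L, n_founder_haps = 240L,
                                    n_gen = 100L, ne_haps = 1440L),
                         PD  = list(n_individuals = 30L, n_founder_haps = 100L,
                                    n_gen = 100L, ne_haps = 600L),
                         BL  = list(n_individuals = 25L, n_founder_haps = 100L,
                                    n_gen = 100L, ne_haps = 600L)
                       ),
                       crosses = list(
                         F1 = list(parents = c("BL", "MER"), n_individuals = 25L)
                       ),
                       array_sizes = c(LD = 250L, `50k` = 800L, HD = 2000L),
                       array_maf_floor = 0.05,
                       class_proportions = c(intergenic = 0.63, intronic = 0.30,
                                             updownstream5kb = 0.064,
                                             missense = 0.003, utr = 0.003),
                       class_maf_bias = c(intergenic = 0, intronic = 0,
                                          updownstream5kb = 3,
                                          missense = 20, utr = 10),
                       problem_regions = list()) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length_bp = as.numeric(chrom_length_bp),
              n_variants = as.integer(n_variants),
              n_ancestral_haps = as.integer(n_ancestral_haps),
              spectrum_skew = spectrum_skew,
              recomb_rate_per_bp_per_gen = recomb_rate_per_bp_per_gen,
              breeds = breeds, crosses = crosses,
              array_sizes = array_sizes, array_maf_floor = array_maf_floor,
              class_proportions = class_proportions,
              class_maf_bias = class_maf_bias,
              problem_regions = problem_regions)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_chroms >= 1, cfg$chrom_length_bp > 0, cfg$n_variants >= 1,
    cfg$n_ancestral_haps >= 2, cfg$recomb_rate_per_bp_per_gen >= 0,
    length(cfg$breeds) >= 1
  )
  for (b in cfg$breeds) {
    stopifnot(b$n_individuals >= 1, b$n_founder_haps >= 2,
              b$n_gen >= 0, b$ne_haps >= 2)
  }
  if (length(cfg$crosses) > 0 && length(cfg$breeds) < 2) {
    stop("crossbred individuals require at least 2 breeds", call. = FALSE)
  }
  for (x in cfg$crosses) {
    if (length(x$parents) != 2 || !all(x$parents %in% names(cfg$breeds))) {
      stop("cross parents must name two configured breeds", call. = FALSE)
    }
  }
  if (length(cfg$array_sizes) && cfg$n_variants < max(cfg$array_sizes)) {
    stop("n_variants is smaller than the largest array target_size",
         call. = FALSE)
  }
  if (abs(sum(cfg$class_proportions) - 1) > 1e-9) {
    stop("class_proportions must sum to 1", call. = FALSE)
  }
  for (r in cfg$problem_regions) {
    if (r$start < 0 || r$end > cfg$chrom_length_bp ||
        !(r$chrom %in% paste0("chr", seq_len(cfg$n_chroms)))) {
      stop("problem region outside the simulated genome", call. = FALSE)
    }
    stopifnot(r$error_rate >= 0, r$error_rate <= 0.5,
              r$density_multiplier >= 1)
  }
  invisible(cfg)
}

# inverse-CDF draw from density proportional to f^(-skew) on [fmin, fmax]
sample_spectrum <- function(n, skew, fmin, fmax = 0.5) {
  u <- runif(n)
  if (abs(skew - 1) < 1e-12) {
    fmin * (fmax / fmin)^u
  } else {
    a <- 1 - skew
    (fmin^a + u * (fmax^a - fmin^a))^(1 / a)
  }
}

# Wright-Fisher drift of founder-lineage weights over n_gen generations at
# population size ne_haps; returns the drifted categorical weights
drift_lineage_weights <- function(n_founders, n_gen, ne_haps) {
  w <- rep(1 / n_founders, n_founders)
  if (n_gen <= 0) return(w)
  for (g in seq_len(n_gen)) {
    w <- as.vector(rmultinom(1, ne_haps, w)) / ne_haps
  }
  w
}

# one breed-pool haplotype: a founder mosaic with breakpoint intensity
# accumulated over the divergence generations (lam per bp) and per-segment
# founder identity drawn from the drifted lineage weights
mosaic_haplotype <- function(founders, w, chrom_cols, chrom_pos, chrom_len,
                             lam) {
  out <- integer(sum(lengths(chrom_cols)))
  nf <- nrow(founders)
  for (c in seq_along(chrom_cols)) {
    idx <- chrom_cols[[c]]
    k <- rpois(1, lam * chrom_len)
    if (k == 0) {
      f <- sample.int(nf, 1L, prob = w)
      out[idx] <- founders[f, idx]
    } else {
      bps <- sort(runif(k, 0, chrom_len))
      seg <- findInterval(chrom_pos[[c]], bps) + 1L
      f_of_seg <- sample.int(nf, k + 1L, replace = TRUE, prob = w)
      out[idx] <- founders[cbind(f_of_seg[seg], idx)]
    }
  }
  out
}

# n_haps breed haplotypes drawn as founder mosaics
breed_haplotypes <- function(breed, n_haps, chrom_cols, chrom_pos, chrom_len) {
  out <- matrix(0L, nrow = n_haps, ncol = ncol(breed$founders))
  for (i in seq_len(n_haps)) {
    out[i, ] <- mosaic_haplotype(breed$founders, breed$w, chrom_cols,
                                 chrom_pos, chrom_len, breed$lam)
  }
  out
}

#' Simulate a phased multi-breed population
#'
#' All breeds descend from a shared ancestral haplotype pool whose variants
#' carry a rare-skewed allele-frequency spectrum. Each breed passes through
#' a founder bottleneck followed by `n_gen` generations of
#' recombination-mosaic descent at population size `ne_haps`. The descent is
#' simulated in condensed form: founder-lineage proportions undergo
#' generation-by-generation Wright-Fisher drift (which differentiates the
#' breeds, increasingly so with `n_gen`), and each present-day breed
#' haplotype is drawn as a founder mosaic whose breakpoint intensity is the
#' per-meiosis recombination rate accumulated over the `n_gen` generations,
#' with per-segment founder identity drawn from the drifted lineage
#' weights. Individuals then take two recombinant haplotypes from their
#' breed's pool; F1 crossbreds take one haplotype from each parent breed.
#' The run is fully deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return A [haplotype_panel()] with per-individual breed labels (use
#'   [subset_panel()] to extract per-breed sub-panels).
#' @export
simulate_population <- function(config) {
  validate_sim_config(config)
  with_seed_if(config$seed, {
    n_chroms <- config$n_chroms
    L <- config$chrom_length_bp
    per_chrom <- diff(floor(seq(0, config$n_variants, length.out = n_chroms + 1)))
    chroms <- paste0("chr", seq_len(n_chroms))
    pos_list <- lapply(per_chrom, function(k) sort(sample.int(L, k)))
    variants <- tibble::tibble(
      chrom = rep(chroms, per_chrom),
      pos = unlist(pos_list)
    )
    M <- nrow(variants)
    bases <- c("A", "C", "G", "T")
    variants$ref_allele <- sample(bases, M, replace = TRUE)
    variants$alt_allele <- unname(vapply(variants$ref_allele, function(r) {
      sample(setdiff(bases, r), 1L)
    }, character(1)))

    chrom_cols <- split(seq_len(M), variants$chrom)[chroms]
    chrom_pos <- split(variants$pos, variants$chrom)[chroms]

    f <- sample_spectrum(M, config$spectrum_skew,
                         fmin = 0.5 / config$n_ancestral_haps)
    pool <- matrix(
      rbinom(config$n_ancestral_haps * M, 1L,
             rep(f, each = config$n_ancestral_haps)),
      nrow = config$n_ancestral_haps
    )

    r_bp <- config$recomb_rate_per_bp_per_gen
    breed_pools <- list()
    for (bn in names(config$breeds)) {
      b <- config$breeds[[bn]]
      breed_pools[[bn]] <- list(
        founders = pool[sample.int(nrow(pool), b$n_founder_haps,
                                   replace = TRUE), , drop = FALSE],
        w = drift_lineage_weights(b$n_founder_haps, b$n_gen, b$ne_haps),
        lam = b$n_gen * r_bp
      )
    }

    hap_rows <- list()
    ids <- character(0)
    labels <- character(0)
    for (bn in names(config$breeds)) {
      b <- config$breeds[[bn]]
      haps <- breed_haplotypes(breed_pools[[bn]], 2L * b$n_individuals,
                               chrom_cols, chrom_pos, L)
      hap_rows[[bn]] <- haps
      ids <- c(ids, paste0(bn, "_", seq_len(b$n_individuals)))
      labels <- c(labels, rep(bn, b$n_individuals))
    }
    for (xn in names(config$crosses)) {
      x <- config$crosses[[xn]]
      h1 <- breed_haplotypes(breed_pools[[x$parents[1]]], x$n_individuals,
                             chrom_cols, chrom_pos, L)
      h2 <- breed_haplotypes(breed_pools[[x$parents[2]]], x$n_individuals,
                             chrom_cols, chrom_pos, L)
      haps <- matrix(0L, nrow = 2L * x$n_individuals, ncol = M)
      haps[seq(1L, nrow(haps), 2L), ] <- h1
      haps[seq(2L, nrow(haps), 2L), ] <- h2
      hap_rows[[xn]] <- haps
      ids <- c(ids, paste0(xn, "_", seq_len(x$n_individuals)))
      labels <- c(labels, rep(xn, x$n_individuals))
    }

    haplotypes <- do.call(rbind, hap_rows)
    haplotype_panel(haplotypes, variants, ids, labels)
  })
}
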