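#' Phased haplotype panel
#'
#' The central genotype container: a matrix of phased haplotypes (one row per
#' haplotype, two consecutive rows per diploid individual; one column per
#' variant) together with a variant table carrying coordinates, alleles,
#' realised minor allele frequency/count and (optionally) an annotation
#' class.
#'
#' @param haplotypes integer matrix of 0/1 alleles, `2 * n_individuals` rows.
#' @param variants tibble with columns `chrom`, `pos`, `ref_allele`,
#'   `alt_allele`; `maf`, `mac` and `annotation_class` are recomputed/kept.
#' @param individual_ids character vector, one id per diploid individual.
#' @param breed_labels character vector, one breed (or cross) tag per
#'   individual.
#'
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(haplotypes, variants, individual_ids,
                            breed_labels = rep(NA_character_, length(individual_ids))) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  variants <- tibble::as_tibble(variants)
  stopifnot(
    nrow(haplotypes) %% 2 == 0,
    nrow(haplotypes) == 2L * length(individual_ids),
    ncol(haplotypes) == nrow(variants),
    length(breed_labels) == length(individual_ids),
    all(haplotypes %in% c(0L, 1L))
  )
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      stop("variant positions must be strictly increasing within chromosome ", ch)
    }
  }
  if (!"annotation_class" %in% names(variants)) {
    variants$annotation_class <- NA_character_
  }
  obj <- structure(
    list(haplotypes = haplotypes, variants = variants,
         individual_ids = as.character(individual_ids),
         breed_labels = as.character(breed_labels), phased = TRUE),
    class = "haplotype_panel"
  )
  refresh_freqs(obj)
}

# recompute maf/mac columns from the haplotype matrix
refresh_freqs <- function(panel) {
  H <- nrow(panel$haplotypes)
  alt <- colSums(panel$haplotypes)
  panel$variants$alt_freq <- alt / H
  panel$variants$maf <- pmin(panel$variants$alt_freq, 1 - panel$variants$alt_freq)
  panel$variants$mac <- as.integer(pmin(alt, H - alt))
  panel
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("<haplotype_panel> ", n_individuals(x), " individuals (",
      nrow(x$haplotypes), " haplotypes) x ", n_variants(x), " variants on ",
      length(unique(x$variants$chrom)), " chromosome(s)\n", sep = "")
  br <- table(x$breed_labels, useNA = "no")
  if (length(br)) {
    cat("  breeds:", paste(names(br), br, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Panel dimensions
#' @param panel a [haplotype_panel()].
#' @return integer count.
#' @export
n_individuals <- function(panel) length(panel$individual_ids)

#' @rdname n_individuals
#' @export
n_variants <- function(panel) nrow(panel$variants)

#' Variant key (chrom:pos) used to align panels
#' @keywords internal
variant_key <- function(variants) {
  sprintf("%s:%d", variants$chrom, as.integer(variants$pos))
}

#' Subset a panel by individuals and/or variants
#'
#' @param panel a [haplotype_panel()].
#' @param individuals individual ids (or logical/integer index over
#'   individuals) to keep; `NULL` keeps all.
#' @param variant_idx integer/logical index over variant columns; `NULL`
#'   keeps all.
#' @return A new `haplotype_panel`; allele frequencies are recomputed on the
#'   retained individuals.
#' @export
subset_panel <- function(panel, individuals = NULL, variant_idx = NULL) {
  ind_idx <- seq_along(panel$individual_ids)
  if (!is.null(individuals)) {
    if (is.character(individuals)) {
      ind_idx <- match(individuals, panel$individual_ids)
      if (anyNA(ind_idx)) {
        stop("unknown individual id(s): ",
             paste(individuals[is.na(ind_idx)], collapse = ", "))
      }
    } else {
      ind_idx <- seq_along(panel$individual_ids)[individuals]
    }
  }
  hap_idx <- as.vector(rbind(2L * ind_idx - 1L, 2L * ind_idx))
  if (is.null(variant_idx)) variant_idx <- seq_len(n_variants(panel))
  haplotype_panel(
    panel$haplotypes[hap_idx, variant_idx, drop = FALSE],
    panel$variants[variant_idx, , drop = FALSE],
    panel$individual_ids[ind_idx],
    panel$breed_labels[ind_idx]
  )
}

#' Diploid genotype matrix (0/1/2) of a panel
#' @param panel a [haplotype_panel()].
#' @return integer matrix, individuals x variants, with dimnames.
#' @export
genotype_matrix <- function(panel) {
  H <- nrow(panel$haplotypes)
  odd <- seq(1L, H, by = 2L)
  g <- panel$haplotypes[odd, , drop = FALSE] +
    panel$haplotypes[odd + 1L, , drop = FALSE]
  dimnames(g) <- list(panel$individual_ids, variant_key(panel$variants))
  g
}

#' Hudson's Fst between two breeds of a panel
#'
#' Ratio-of-averages Hudson estimator over all polymorphic sites:
#' numerator \eqn{(p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)},
#' denominator \eqn{p_1(1-p_2) + p_2(1-p_1)}, both averaged over sites
#' before taking the ratio.
#'
#' @param panel a [haplotype_panel()] with breed labels.
#' @param breed_a,breed_b breed labels to compare.
#' @return Fst estimate (double).
#' @export
hudson_fst <- function(panel, breed_a, breed_b) {
  ia <- which(panel$breed_labels == breed_a)
  ib <- which(panel$breed_labels == breed_b)
  if (!length(ia) || !length(ib)) stop("breed label not present in panel")
  ha <- panel$haplotypes[as.vector(rbind(2L * ia - 1L, 2L * ia)), , drop = FALSE]
  hb <- panel$haplotypes[as.vector(rbind(2L * ib - 1L, 2L * ib)), , drop = FALSE]
  n1 <- nrow(ha); n2 <- nrow(hb)
  p1 <- colMeans(ha); p2 <- colMeans(hb)
  keep <- (p1 + p2) > 0 & (p1 + p2) < 2
  p1 <- p1[keep]; p2 <- p2[keep]
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  mean(num) / mean(den)
}
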