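#' Inject a poorly imputable genomic region
#'
#' Emulates regions (segmental duplications, assembly errors, the MHC) where
#' imputation breaks down: within `region`, variant density is multiplied by
#' `density_multiplier` (new variants are inserted with haplotype alleles
#' assigned at random, carrying no local LD) and existing haplotype entries
#' are flipped independently at `error_rate`, degrading haplotype sharing.
#' The panel outside the region is untouched.
#'
#' @param panel a [haplotype_panel()].
#' @param region list or vector with `chrom`, `start`, `end` (bp,
#'   half-open `[start, end)`).
#' @param error_rate per-entry flip probability in `[0, 0.5]`.
#' @param density_multiplier factor >= 1 applied to variant density.
#' @param seed optional integer seed.
#' @return A new [haplotype_panel()].
#' @export
inject_low_fidelity_region <- function(panel, region, error_rate = 0.2,
                                       density_multiplier = 2, seed = NULL) {
  chrom <- region$chrom %||% region[["chrom"]]
  start <- as.numeric(region$start)
  end <- as.numeric(region$end)
  if (!chrom %in% panel$variants$chrom) {
    stop("region chromosome not present in panel", call. = FALSE)
  }
  if (start < 0 || end <= start) stop("invalid region bounds", call. = FALSE)
  if (error_rate < 0 || error_rate > 0.5) {
    stop("error_rate must lie in [0, 0.5]", call. = FALSE)
  }
  if (density_multiplier < 1) {
    stop("density_multiplier must be >= 1", call. = FALSE)
  }
  if (error_rate == 0 && density_multiplier == 1) return(panel)

  v <- panel$variants
  H <- nrow(panel$haplotypes)
  in_region <- v$chrom == chrom & v$pos >= start & v$pos < end

  with_seed_if(seed, {
    n_in <- sum(in_region)
    n_new <- rpois(1, (density_multiplier - 1) * n_in)
    hap <- panel$haplotypes
    if (n_new > 0) {
      taken <- v$pos[v$chrom == chrom]
      cand <- setdiff(seq.int(ceiling(start), floor(end) - 1), taken)
      n_new <- min(n_new, length(cand))
      new_pos <- sort(sample(cand, n_new))
      f <- sample_spectrum(n_new, 1, fmin = 0.5 / H)
      new_hap <- matrix(rbinom(H * n_new, 1L, rep(f, each = H)), nrow = H)
      bases <- c("A", "C", "G", "T")
      ref <- sample(bases, n_new, replace = TRUE)
      cls <- if (all(is.na(v$annotation_class))) {
        rep(NA_character_, n_new)
      } else {
        sample(v$annotation_class[!is.na(v$annotation_class)], n_new,
               replace = TRUE)
      }
      new_v <- tibble::tibble(
        chrom = chrom, pos = new_pos, ref_allele = ref,
        alt_allele = unname(vapply(ref, function(r) {
          sample(setdiff(bases, r), 1L)
        }, character(1))),
        annotation_class = cls
      )
      v2 <- dplyr::bind_rows(
        v[, c("chrom", "pos", "ref_allele", "alt_allele", "annotation_class")],
        new_v
      )
      hap <- cbind(hap, new_hap)
      ord <- order(match(v2$chrom, unique(panel$variants$chrom)), v2$pos)
      v2 <- v2[ord, ]
      hap <- hap[, ord, drop = FALSE]
    } else {
      v2 <- v[, c("chrom", "pos", "ref_allele", "alt_allele", "annotation_class")]
    }
    flip_cols <- which(v2$chrom == chrom & v2$pos >= start & v2$pos < end)
    if (error_rate > 0 && length(flip_cols)) {
      block <- hap[, flip_cols, drop = FALSE]
      flips <- matrix(rbinom(length(block), 1L, error_rate),
                      nrow = nrow(block))
      hap[, flip_cols] <- as.integer(xor(block, flips))
    }
    out <- haplotype_panel(hap, v2, panel$individual_ids, panel$breed_labels)
    attr(out, "low_fidelity_region") <- list(
      chrom = chrom, start = start, end = end, error_rate = error_rate,
      density_multiplier = density_multiplier
    )
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
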