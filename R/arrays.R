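#' SNP-array panel ascertainment
#'
#' Selects a subset of panel variants emulating a genotyping array. Real
#' arrays are ascertained towards common, evenly spread SNPs, which flattens
#' their MAF spectrum relative to sequence; `scheme = "uniform_maf"`
#' reproduces that by balancing the selection across MAF deciles of
#' `[maf_floor, 0.5]` as far as the supply in each decile allows.
#' `scheme = "random_common"` samples uniformly among all variants passing
#' the floor.
#'
#' @param panel a [haplotype_panel()].
#' @param target_size number of array SNPs requested.
#' @param maf_floor ascertainment MAF floor (every array SNP has
#'   MAF >= `maf_floor`).
#' @param scheme `"uniform_maf"` or `"random_common"`.
#' @param seed optional integer seed.
#' @param name panel label (e.g. `"HD"`).
#' @param within optional parent `array_panel`; when given, selection is
#'   restricted to its positions so that nested hierarchies
#'   (LD within 50k within HD) hold exactly.
#'
#' @return An `array_panel`: a tibble of ordered `(chrom, pos)` rows with
#'   attributes `name`, `target_size` and `maf_floor`.
#' @export
ascertain_array_panel <- function(panel, target_size, maf_floor = 0.05,
                                  scheme = c("uniform_maf", "random_common"),
                                  seed = NULL, name = "array", within = NULL) {
  scheme <- match.arg(scheme)
  v <- panel$variants
  eligible <- which(v$maf >= maf_floor)
  if (!is.null(within)) {
    eligible <- intersect(
      eligible, which(variant_key(v) %in% variant_key(within))
    )
  }
  if (length(eligible) < target_size) {
    stop("array ascertainment shortfall: need ", target_size,
         " variants with MAF >= ", maf_floor, " but only ",
         length(eligible), " are eligible (deficit ",
         target_size - length(eligible), ")", call. = FALSE)
  }
  sel <- with_seed_if(seed, {
    if (scheme == "random_common") {
      sample(eligible, target_size)
    } else {
      edges <- seq(maf_floor, 0.5, length.out = 11L)
      bin <- cut(v$maf[eligible], breaks = edges, include.lowest = TRUE,
                 labels = FALSE)
      by_bin <- split(eligible, bin)
      # round-robin fill: one draw per decile per round so short deciles
      # exhaust gracefully and the rest absorb the remainder
      by_bin <- lapply(by_bin, function(ix) ix[sample.int(length(ix))])
      picked <- integer(0)
      while (length(picked) < target_size) {
        for (bkey in names(by_bin)) {
          if (length(picked) >= target_size) break
          ix <- by_bin[[bkey]]
          if (length(ix)) {
            picked <- c(picked, ix[1L])
            by_bin[[bkey]] <- ix[-1L]
          }
        }
      }
      picked
    }
  })
  sel <- sort(sel)
  out <- tibble::tibble(chrom = v$chrom[sel], pos = v$pos[sel])
  structure(out, name = name, target_size = as.integer(target_size),
            maf_floor = maf_floor,
            class = c("array_panel", class(out)))
}

#' Nested LD / 50k / HD array hierarchy
#'
#' Builds the densest panel first, then ascertains each sparser panel from
#' within the next denser one, so the subset chain (e.g. LD within 50k
#' within HD) holds exactly.
#'
#' @param panel a [haplotype_panel()].
#' @param sizes named integer vector of panel sizes, sparsest first.
#' @param maf_floor,scheme,seed passed to [ascertain_array_panel()].
#' @return Named list of `array_panel`s in the order of `sizes`.
#' @export
ascertain_nested_panels <- function(panel, sizes, maf_floor = 0.05,
                                    scheme = "uniform_maf", seed = NULL) {
  stopifnot(!is.null(names(sizes)), all(diff(as.numeric(sizes)) > 0))
  with_seed_if(seed, {
    out <- vector("list", length(sizes))
    names(out) <- names(sizes)
    parent <- NULL
    for (i in rev(seq_along(sizes))) {
      out[[i]] <- ascertain_array_panel(
        panel, sizes[[i]], maf_floor = maf_floor, scheme = scheme,
        seed = NULL, name = names(sizes)[i], within = parent
      )
      parent <- out[[i]]
    }
    out
  })
}
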