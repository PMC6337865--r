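#' Read a phased VCF into a haplotype panel
#'
#' Parses a VCF (via vcfR), rejects multiallelic records (counted in the
#' removal log) and requires every GT to be phased (`|` separator).
#' Positions stay 1-based; sample order is preserved. Breed labels are
#' recovered from a `##wgsimpute_breeds=` provenance header line when
#' present.
#'
#' @param path VCF file path (plain text or gzipped).
#' @return A [haplotype_panel()] with a `removal_log` attribute.
#' @export
read_phased_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(haplotype_panel(
      matrix(integer(0), nrow = 2 * (ncol(v@gt) - 1), ncol = 0),
      tibble::tibble(chrom = character(0), pos = integer(0),
                     ref_allele = character(0), alt_allele = character(0)),
      colnames(v@gt)[-1]
    ))
  }
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- fix[!multi, , drop = FALSE]
  gt <- gt[!multi, , drop = FALSE]

  unphased <- matrix(grepl("/", gt, fixed = TRUE), nrow = nrow(gt))
  if (any(unphased)) {
    first <- which(unphased, arr.ind = TRUE)[1, ]
    stop("unphased genotype at ", fix$CHROM[first[1]], ":", fix$POS[first[1]],
         " (sample ", colnames(gt)[first[2]], ")", call. = FALSE)
  }
  a1 <- matrix(as.integer(substr(gt, 1, 1)), nrow = nrow(gt))
  a2 <- matrix(as.integer(substr(gt, 3, 3)), nrow = nrow(gt))
  n_samp <- ncol(gt)
  hap <- matrix(0L, nrow = 2L * n_samp, ncol = nrow(fix))
  hap[seq(1L, 2L * n_samp, 2L), ] <- t(a1)
  hap[seq(2L, 2L * n_samp, 2L), ] <- t(a2)

  breeds <- rep(NA_character_, n_samp)
  meta <- grep("^##wgsimpute_breeds=", v@meta, value = TRUE)
  if (length(meta) == 1) {
    lab <- strsplit(sub("^##wgsimpute_breeds=", "", meta), ",", fixed = TRUE)[[1]]
    if (length(lab) == n_samp) breeds <- lab
  }
  out <- haplotype_panel(
    hap,
    tibble::tibble(chrom = fix$CHROM, pos = as.integer(fix$POS),
                   ref_allele = fix$REF, alt_allele = fix$ALT),
    colnames(gt), breeds
  )
  attr(out, "removal_log") <- tibble::tibble(
    reason = c("multiallelic", "retained"),
    n = c(sum(multi), nrow(fix))
  )
  out
}

#' Write a haplotype panel as a phased VCF
#'
#' Writes VCF 4.2 with phased GT fields and provenance (`##wgsimpute_*`)
#' header lines carrying the breed labels and any extra metadata.
#'
#' @param panel a [haplotype_panel()].
#' @param path output path.
#' @param provenance named character vector written as
#'   `##wgsimpute_<name>=<value>` header lines.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path, provenance = character(0)) {
  v <- panel$variants
  H <- panel$haplotypes
  odd <- seq(1L, nrow(H), by = 2L)
  gt <- matrix(paste0(H[odd, , drop = FALSE], "|", H[odd + 1L, , drop = FALSE]),
               nrow = length(odd))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=wgsimpute",
    paste0("##wgsimpute_breeds=", paste(panel$breed_labels, collapse = ",")),
    if (length(provenance)) {
      paste0("##wgsimpute_", names(provenance), "=", provenance)
    },
    paste0("##contig=<ID=", unique(v$chrom), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$individual_ids), collapse = "\t")
  )
  body <- paste(v$chrom, v$pos, ".", v$ref_allele, v$alt_allele, ".", "PASS",
                ".", "GT", sep = "\t")
  body <- paste(body, apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write an imputed set as a dosage VCF
#'
#' Mirrors the output conventions of dosage-emitting imputation tools:
#' per-sample `GT` (most-likely genotype) and `DS` (genotype dosage, 3
#' decimal places) fields, and per-variant INFO keys `R2` (raw quality
#' statistic), `MAF` and the `TYPED` flag on array positions.
#'
#' @param imputed an `imputed_set` (or `imputation_cv`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_imputed_vcf <- function(imputed, path) {
  v <- imputed$variants
  gt_code <- c("0|0", "0|1", "1|1")
  gt <- matrix(gt_code[imputed$most_likely + 1L],
               nrow = nrow(imputed$most_likely))
  ds <- matrix(sprintf("%.3f", imputed$geno_dosages),
               nrow = nrow(imputed$geno_dosages))
  info <- paste0("R2=", signif(v$rsq, 6), ";MAF=", signif(v$maf, 6),
                 ifelse(v$typed, ";TYPED", ""))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=wgsimpute",
    paste0("##contig=<ID=", unique(v$chrom), ">"),
    "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation quality statistic\">",
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Reference minor allele frequency\">",
    "##INFO=<ID=TYPED,Number=0,Type=Flag,Description=\"Array (observed) position\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Most likely genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Genotype dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", imputed$individual_ids), collapse = "\t")
  )
  cells <- matrix(paste0(gt, ":", ds), nrow = nrow(gt))
  body <- paste(v$chrom, v$pos, ".", v$ref_allele, v$alt_allele, ".", "PASS",
                info, "GT:DS", sep = "\t")
  body <- paste(body, apply(cells, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a dosage VCF written by [write_imputed_vcf()]
#'
#' @param path VCF path.
#' @return List with `variants` (tibble incl. `rsq`, `maf`, `typed`),
#'   `geno_dosages` and `most_likely` matrices (individuals x variants).
#' @export
read_imputed_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  ds <- t(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE))
  gtc <- t(vcfR::extract.gt(v, element = "GT"))
  most <- matrix(match(gtc, c("0|0", "0|1", "1|1")) - 1L, nrow = nrow(gtc))
  get_info <- function(key) {
    m <- regmatches(fix$INFO, regexpr(paste0("(?<=", key, "=)[^;]+"),
                                      fix$INFO, perl = TRUE))
    as.numeric(m)
  }
  variants <- tibble::tibble(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref_allele = fix$REF, alt_allele = fix$ALT,
    rsq = get_info("R2"), maf = get_info("MAF"),
    typed = grepl("TYPED", fix$INFO, fixed = TRUE)
  )
  rownames(ds) <- rownames(gtc)
  list(variants = variants, geno_dosages = ds, most_likely = most,
       individual_ids = rownames(gtc))
}
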