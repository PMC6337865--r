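#' Run the full evaluation pipeline from a config
#'
#' Orchestrates simulate -> ascertain -> (inject regions) -> phenotypes ->
#' fivefold masked imputation -> accuracy evaluation -> (optional)
#' quality-stratified genomic prediction, writing VCF/TSV/JSON outputs and
#' a run manifest with per-stage wall-clock times and md5 checksums of
#' every output file. Deterministic stages are checksum-identical across
#' re-runs with the same config.
#'
#' @param config path to a YAML config file, or an equivalent named list.
#'   Top-level keys: `seed`; `sim` (arguments to [sim_config()]);
#'   `arrays` (`sizes`, `maf_floor`); `regions` (list of low-fidelity
#'   regions); `phenotypes` (`n_causal`, `target_h2`); `crossval`
#'   (`k`, `array`, `min_mac`); `gpred` (`enabled`, `set_size`, `n_sets`,
#'   `n_chains`, `n_iter`, `n_burnin`, `target_fraction`).
#' @param out_dir output directory (created if needed).
#' @param seed optional override of the config seed.
#' @return The run manifest (list), invisibly written to
#'   `manifest.json` in `out_dir`.
#' @export
run_experiment <- function(config, out_dir, seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("wgsimpute")),
    seed = cfg$seed,
    config_hash = digest_config(cfg),
    stages = list(), files = list()
  )
  files <- character(0)
  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(code), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      write_manifest(manifest, files, out_dir)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      status = "ok", seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  sim_args <- cfg$sim %||% list()
  sim_args$seed <- cfg$seed
  scfg <- do.call(sim_config, sim_args)

  panel <- stage("simulate", simulate_population(scfg))
  panel <- stage("annotate", assign_annotation_classes(
    panel, scfg$class_proportions, scfg$class_maf_bias,
    seed = cfg$seed + 1L))

  arrays <- stage("ascertain", ascertain_nested_panels(
    panel, scfg$array_sizes, maf_floor = scfg$array_maf_floor,
    seed = cfg$seed + 2L))
  for (an in names(arrays)) {
    f <- file.path(out_dir, paste0("array_", gsub("[^A-Za-z0-9]", "", an), ".tsv"))
    write.table(as.data.frame(arrays[[an]])[, c("chrom", "pos")], f,
                sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }

  for (r in scfg$problem_regions) {
    panel <- stage(paste0("inject_", r$chrom, "_", r$start), {
      inject_low_fidelity_region(panel, r, r$error_rate,
                                 r$density_multiplier, seed = cfg$seed + 3L)
    })
  }
  f <- file.path(out_dir, "panel.vcf")
  write_panel_vcf(panel, f, provenance = c(seed = cfg$seed))
  files <- c(files, f)

  ph_cfg <- cfg$phenotypes %||% list(n_causal = 100L, target_h2 = 0.3)
  phen <- stage("phenotypes", simulate_phenotypes(
    panel, ph_cfg$n_causal, ph_cfg$target_h2, seed = cfg$seed + 4L))
  f <- file.path(out_dir, "phenotypes.tsv")
  write.table(as.data.frame(phen), f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  files <- c(files, f)

  cv_cfg <- cfg$crossval %||% list()
  arr_name <- cv_cfg$array %||% names(arrays)[length(arrays)]
  cv <- stage("impute", run_crossval(
    panel, arrays[[arr_name]], hmm_params(),
    k = cv_cfg$k %||% 5L, min_mac = cv_cfg$min_mac %||% 5L,
    seed = cfg$seed + 5L))
  f <- file.path(out_dir, "imputed.vcf")
  write_imputed_vcf(cv, f)
  files <- c(files, f)

  acc <- stage("evaluate", per_variant_accuracy(cv))
  f <- file.path(out_dir, "accuracy_per_variant.tsv")
  write.table(as.data.frame(acc), f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  files <- c(files, f)
  for (str in c("maf_bands", "rsq_bins", "windows_1mb", "annotation_class",
                "chromosome")) {
    s <- stratified_summary(acc, str)
    f <- file.path(out_dir, paste0("summary_", str, ".tsv"))
    write.table(as.data.frame(s), f, sep = "\t", quote = FALSE,
                row.names = FALSE)
    files <- c(files, f)
  }

  gp_cfg <- cfg$gpred %||% list(enabled = FALSE)
  if (isTRUE(gp_cfg$enabled)) {
    gp <- stage("gpred", {
      ids <- cv$individual_ids
      n_target <- max(3L, round((gp_cfg$target_fraction %||% 0.25) * length(ids)))
      target_ids <- with_seed_if(cfg$seed + 6L, sample(ids, n_target))
      train_ids <- setdiff(ids, target_ids)
      X <- cv$geno_dosages
      rownames(X) <- ids
      run_stratified_prediction(
        X, cv$variants, phen, train_ids, target_ids,
        strata = gp_cfg$strata %||% c("thr0-4", "thr4", "thr8"),
        set_size = gp_cfg$set_size %||% 300L,
        n_sets = gp_cfg$n_sets %||% 3L,
        config = bayesr_config(
          n_iter = gp_cfg$n_iter %||% 1500L,
          n_burnin = gp_cfg$n_burnin %||% 750L,
          n_chains = gp_cfg$n_chains %||% 2L),
        seed = cfg$seed + 7L)
    })
    f <- file.path(out_dir, "prediction.json")
    jsonlite::write_json(
      list(per_stratum = gp$per_stratum, per_set = gp$per_set,
           h2_reference = gp$h2_reference),
      f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  }

  write_manifest(manifest, files, out_dir)
}

digest_config <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg), tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(manifest, files, out_dir) {
  manifest$files <- lapply(files, function(f) {
    list(path = basename(f), md5 = unname(tools::md5sum(f)))
  })
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
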