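#' BayesR sampler configuration
#'
#' @param mixture_fracs the four mixture-component variances as fractions of
#'   the genetic variance; the first must be exactly 0 (the null component).
#'   Default `c(0, 1e-4, 1e-3, 1e-2)`.
#' @param n_iter,n_burnin Gibbs schedule. The desk default is 4,000/2,000;
#'   `preset = "full"` switches to the production-scale 40,000/20,000
#'   schedule with 5 chains.
#' @param n_chains chains run (and averaged) per variant set.
#' @param dirichlet_prior concentration vector for the mixing proportions.
#' @param df_prior degrees of freedom of the scaled inverse chi-square
#'   priors on the genetic and residual variances (scales are data-derived:
#'   half the phenotypic variance each).
#' @param preset `"desk"` or `"full"`.
#' @param fix_pi,fix_sigma_g,fix_sigma_e optionally pin mixing proportions /
#'   variances (used e.g. for the ridge-regression limit check).
#' @return A `bayesr_config` list.
#' @export
bayesr_config <- function(mixture_fracs = c(0, 1e-4, 1e-3, 1e-2),
                          n_iter = 4000L, n_burnin = 2000L, n_chains = 5L,
                          dirichlet_prior = c(1, 1, 1, 1), df_prior = 4,
                          preset = c("desk", "full"),
                          fix_pi = NULL, fix_sigma_g = NULL,
                          fix_sigma_e = NULL) {
  preset <- match.arg(preset)
  if (preset == "full") {
    n_iter <- 40000L
    n_burnin <- 20000L
    n_chains <- 5L
  }
  if (length(mixture_fracs) != 4 || mixture_fracs[1] != 0) {
    stop("mixture_fracs must have 4 components with the first exactly 0",
         call. = FALSE)
  }
  if (n_burnin >= n_iter) stop("n_burnin must be below n_iter", call. = FALSE)
  stopifnot(all(dirichlet_prior > 0), df_prior > 0)
  structure(list(mixture_fracs = mixture_fracs, n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin),
                 n_chains = as.integer(n_chains),
                 dirichlet_prior = dirichlet_prior, df_prior = df_prior,
                 fix_pi = fix_pi, fix_sigma_g = fix_sigma_g,
                 fix_sigma_e = fix_sigma_e),
            class = "bayesr_config")
}

#' Fit BayesR by Gibbs sampling
#'
#' Bayesian whole-genome regression in which every variant effect comes
#' from a four-component normal mixture with variances `(0, 1e-4, 1e-3,
#' 1e-2)` times the genetic variance. A single-site Gibbs sweep updates,
#' per iteration: each variant's mixture class and effect, the mixing
#' proportions (Dirichlet posterior), and the genetic and residual
#' variances (scaled inverse chi-square posteriors). Genotype dosages are
#' centred by their training-set column means, not standardised, so effects
#' stay on the allele-count scale. The per-iteration genomic heritability
#' is Var(X beta)/Var(y) over the training individuals; posterior summaries
#' use post-burn-in draws only.
#'
#' @param X numeric genotype/dosage matrix, individuals x variants (no
#'   missing values).
#' @param y adjusted phenotypes.
#' @param config a [bayesr_config()].
#' @param seed optional integer seed.
#' @return A `bayesr_fit` with posterior-mean effects, per-variant mixture
#'   class probabilities, kept-iteration draws of h2, mixing proportions
#'   and variances, the intercept and the training column centres.
#' @export
bayesr <- function(X, y, config = bayesr_config(), seed = NULL) {
  X <- as.matrix(X)
  if (!all(is.finite(y))) stop("phenotypes must be finite", call. = FALSE)
  if (nrow(X) != length(y)) stop("nrow(X) must match length(y)", call. = FALSE)
  if (nrow(X) < 30) stop("need at least 30 training individuals", call. = FALSE)
  centers <- colMeans(X)
  Xc <- sweep(X, 2, centers)
  vy <- var(y)
  res <- with_seed_if(seed, {
    bayesr_gibbs_cpp(Xc, y, config$mixture_fracs, config$n_iter,
                     config$n_burnin, config$dirichlet_prior,
                     config$df_prior, S0g = vy / 2, S0e = vy / 2,
                     fix_pi = config$fix_pi, fix_sg2 = config$fix_sigma_g,
                     fix_se2 = config$fix_sigma_e)
  })
  structure(c(res, list(centers = centers, config = config,
                        n = nrow(X), m = ncol(X))),
            class = "bayesr_fit")
}

#' @export
print.bayesr_fit <- function(x, ...) {
  cat("<bayesr_fit> n =", x$n, ", m =", x$m,
      ", posterior mean h2 =", round(mean(x$h2_samples), 3), "\n")
  invisible(x)
}

#' @rdname bayesr
#' @param x a `bayesr_fit`.
#' @param ... unused.
#' @export
tidy.bayesr_fit <- function(x, ...) {
  tibble::tibble(
    term = paste0("snp", seq_len(x$m)),
    estimate = as.numeric(x$effect_means),
    prob_nonzero = 1 - x$component_probs[, 1]
  )
}

#' @rdname bayesr
#' @export
glance.bayesr_fit <- function(x, ...) {
  tibble::tibble(
    h2_mean = mean(x$h2_samples), h2_sd = sd(x$h2_samples),
    sigma_g = mean(x$sigma_g_samples), sigma_e = mean(x$sigma_e_samples),
    pi_null = mean(x$pi_samples[, 1]),
    n = x$n, m = x$m,
    n_iter = x$config$n_iter, n_burnin = x$config$n_burnin
  )
}

#' Genomic estimated breeding values
#'
#' Linear score `X_target %*% effect_means` with the target genotypes
#' centred by the training-set column means stored in the fit.
#'
#' @param X_target genotype/dosage matrix of the target individuals, columns
#'   aligned with the training matrix.
#' @param fit a `bayesr_fit`, or a numeric effect vector (then no centring
#'   constants are available and columns are used as-is).
#' @return Numeric GEBV vector.
#' @export
compute_gebv <- function(X_target, fit) {
  X_target <- as.matrix(X_target)
  if (inherits(fit, "bayesr_fit")) {
    if (ncol(X_target) != fit$m) {
      stop("target matrix has ", ncol(X_target), " columns but the fit has ",
           fit$m, call. = FALSE)
    }
    drop(sweep(X_target, 2, fit$centers) %*% fit$effect_means)
  } else {
    if (ncol(X_target) != length(fit)) {
      stop("column/effect length mismatch", call. = FALSE)
    }
    drop(X_target %*% fit)
  }
}

#' Genomic prediction accuracy and its standard error
#'
#' Accuracy is the Pearson correlation between GEBV and the adjusted
#' phenotype divided by the square root of the (genomic) heritability;
#' the standard error over independently sampled variant sets is the
#' standard deviation of the set-level accuracies divided by the square
#' root of the number of sets.
#'
#' @param gebv,y_adj aligned numeric vectors (>= 3 individuals).
#' @param h2 heritability in `(0, 1]`.
#' @return `prediction_accuracy()`: a single accuracy value (`NA` with a
#'   warning if the GEBV are constant).
#' @export
prediction_accuracy <- function(gebv, y_adj, h2) {
  if (h2 <= 0 || h2 > 1) stop("h2 must lie in (0, 1]", call. = FALSE)
  if (length(gebv) < 3) stop("need >= 3 target individuals", call. = FALSE)
  if (sd(gebv) == 0) {
    warning("constant GEBV: correlation undefined")
    return(NA_real_)
  }
  cor(gebv, y_adj) / sqrt(h2)
}

#' @rdname prediction_accuracy
#' @param accuracies set-level accuracies (>= 2).
#' @export
accuracy_se <- function(accuracies) {
  if (length(accuracies) < 2) stop("need >= 2 set-level accuracies", call. = FALSE)
  sd(accuracies) / sqrt(length(accuracies))
}

#' Specification of matched variant sets for one quality stratum
#'
#' @param stratum `"thr0-4"`, `"thr4"` or `"thr8"` (see
#'   [threshold_policy()]).
#' @param set_size variants per set (50,000 at full scale; desk default
#'   1,000).
#' @param n_sets number of sets (default 5).
#' @param maf_floor strict MAF floor (variants must have MAF > `maf_floor`).
#' @param af_match_bins allele-frequency bin edges used to match the MAF
#'   distribution across sets (default: deciles of `(maf_floor, 0.5]`).
#' @param seed optional integer seed.
#' @return A `variant_set_spec` list.
#' @export
variant_set_spec <- function(stratum = c("thr4", "thr8", "thr0-4"),
                             set_size = 1000L, n_sets = 5L, maf_floor = 0.01,
                             af_match_bins = seq(0.01, 0.5, length.out = 11),
                             seed = NULL) {
  stratum <- match.arg(stratum)
  stopifnot(set_size >= 1, n_sets >= 1)
  structure(list(stratum = stratum, set_size = as.integer(set_size),
                 n_sets = as.integer(n_sets), maf_floor = maf_floor,
                 af_match_bins = af_match_bins, seed = seed),
            class = "variant_set_spec")
}

#' Select allele-frequency-matched variant sets within a quality stratum
#'
#' From the pool of variants passing the stratum's quality-statistic
#' predicate and the MAF floor (strict `maf > maf_floor`), draws `n_sets`
#' sets of exactly `set_size` variants whose per-AF-bin counts are
#' identical across sets by construction: fixed per-bin quotas are derived
#' from the pool's AF histogram (largest-remainder apportionment) and each
#' set fills every quota. Sets are disjoint whenever the per-bin supply
#' allows; any forced overlap is recorded in the `overlap` attribute.
#'
#' @param variants tibble with `maf` and `rsq` columns (e.g. the variant
#'   table of an imputed set); row indices identify variants.
#' @param spec a [variant_set_spec()].
#' @return List of integer vectors (row indices into `variants`), one per
#'   set, with attributes `quota` and `overlap`.
#' @export
select_matched_variant_sets <- function(variants, spec) {
  policy <- threshold_policy(spec$stratum)
  pool <- which(policy$rule(variants$rsq) & variants$maf > spec$maf_floor)
  if (length(pool) < spec$set_size) {
    stop("variant pool shortfall in stratum ", spec$stratum, ": need ",
         spec$set_size, ", have ", length(pool), " (deficit ",
         spec$set_size - length(pool), ")", call. = FALSE)
  }
  edges <- spec$af_match_bins
  bin <- cut(variants$maf[pool], breaks = edges, include.lowest = TRUE,
             labels = FALSE)
  bin[is.na(bin)] <- length(edges) - 1L  # maf above the last edge
  by_bin <- split(pool, bin)
  # largest-remainder quotas proportional to the pool histogram
  raw <- lengths(by_bin) / length(pool) * spec$set_size
  quota <- floor(raw)
  left <- spec$set_size - sum(quota)
  if (left > 0) {
    extra <- order(raw - quota, decreasing = TRUE)[seq_len(left)]
    quota[extra] <- quota[extra] + 1
  }
  # a quota cannot exceed its bin supply for a single set
  over <- quota > lengths(by_bin)
  while (any(over)) {
    excess <- sum(quota[over] - lengths(by_bin)[over])
    quota[over] <- lengths(by_bin)[over]
    room <- which(quota < lengths(by_bin))
    for (i in room) {
      if (excess == 0) break
      add <- min(excess, lengths(by_bin)[i] - quota[i])
      quota[i] <- quota[i] + add
      excess <- excess - add
    }
    over <- quota > lengths(by_bin)
    if (excess > 0) break
  }

  with_seed_if(spec$seed, {
    sets <- replicate(spec$n_sets, integer(0), simplify = FALSE)
    overlap <- 0L
    for (bkey in names(by_bin)) {
      q <- quota[[bkey]]
      if (q == 0) next
      supply <- by_bin[[bkey]][sample.int(length(by_bin[[bkey]]))]
      need <- q * spec$n_sets
      if (length(supply) >= need) {
        draw <- supply[seq_len(need)]
      } else {
        overlap <- overlap + (need - length(supply))
        draw <- c(supply, sample(supply, need - length(supply), replace = TRUE))
      }
      for (s in seq_len(spec$n_sets)) {
        sets[[s]] <- c(sets[[s]], draw[((s - 1) * q + 1):(s * q)])
      }
    }
    sets <- lapply(sets, sort)
    attr(sets, "quota") <- quota
    attr(sets, "overlap") <- overlap
    sets
  })
}

#' Quality-stratified genomic prediction experiment
#'
#' For each quality stratum (`thr0-4`, `thr4`, `thr8`): selects
#' allele-frequency-matched variant sets with
#' [select_matched_variant_sets()], fits `n_chains` BayesR chains per set
#' on the training individuals, averages genomic heritability and GEBV
#' accuracy across chains within each set, and reports the per-stratum mean
#' accuracy with its standard error over sets. Training and target
#' individuals must be disjoint.
#'
#' @param X genotype/dosage matrix (individuals x variants) covering
#'   training and target individuals; row names are individual ids.
#' @param variants variant table aligned with `X`'s columns, with `maf`
#'   and `rsq`.
#' @param phenotypes tibble with `individual_id` and `y_adj` (training and
#'   target rows).
#' @param train_ids,target_ids disjoint id vectors.
#' @param strata stratum names to evaluate.
#' @param set_size,n_sets passed to [variant_set_spec()].
#' @param config a [bayesr_config()].
#' @param h2_reference heritability used in the accuracy denominator;
#'   `NULL` (default) uses the mean posterior genomic heritability across
#'   all analyses of the run, mirroring the use of a single trait-level
#'   estimate.
#' @param seed optional integer seed.
#' @return A `stratified_prediction` list with `per_set` and `per_stratum`
#'   tibbles and the `h2_reference` used.
#' @export
run_stratified_prediction <- function(X, variants, phenotypes, train_ids,
                                      target_ids,
                                      strata = c("thr0-4", "thr4", "thr8"),
                                      set_size = 1000L, n_sets = 5L,
                                      config = bayesr_config(),
                                      h2_reference = NULL, seed = NULL) {
  if (length(intersect(train_ids, target_ids))) {
    stop("training and target individuals must be disjoint", call. = FALSE)
  }
  ph <- setNames(phenotypes$y_adj, phenotypes$individual_id)
  y_train <- ph[train_ids]
  y_target <- ph[target_ids]
  if (anyNA(y_train) || anyNA(y_target)) {
    stop("missing phenotypes for some individuals", call. = FALSE)
  }
  with_seed_if(seed, {
    rows <- list()
    for (st in strata) {
      spec <- variant_set_spec(stratum = st, set_size = set_size,
                               n_sets = n_sets)
      sets <- select_matched_variant_sets(variants, spec)
      for (s in seq_along(sets)) {
        idx <- sets[[s]]
        Xtr <- X[train_ids, idx, drop = FALSE]
        Xtg <- X[target_ids, idx, drop = FALSE]
        for (ch in seq_len(config$n_chains)) {
          fit <- bayesr(Xtr, y_train, config)
          gebv <- compute_gebv(Xtg, fit)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            stratum = st, set = s, chain = ch,
            h2 = mean(fit$h2_samples),
            cor_gebv = if (sd(gebv) == 0) NA_real_ else cor(gebv, y_target)
          )
        }
      }
    }
    per_chain <- dplyr::bind_rows(rows)
    h2_ref <- h2_reference %||% mean(per_chain$h2)
    per_set <- per_chain |>
      dplyr::group_by(.data$stratum, .data$set) |>
      dplyr::summarise(h2 = mean(.data$h2),
                       accuracy = mean(.data$cor_gebv) / sqrt(h2_ref),
                       .groups = "drop")
    per_stratum <- per_set |>
      dplyr::group_by(.data$stratum) |>
      dplyr::summarise(h2_mean = mean(.data$h2),
                       accuracy_se = if (dplyr::n() >= 2) {
                         sd(.data$accuracy) / sqrt(dplyr::n())
                       } else NA_real_,
                       accuracy = mean(.data$accuracy),
                       n_sets = dplyr::n(), .groups = "drop")
    structure(list(per_chain = per_chain, per_set = per_set,
                   per_stratum = per_stratum, h2_reference = h2_ref),
              class = "stratified_prediction")
  })
}

#' @export
print.stratified_prediction <- function(x, ...) {
  cat("<stratified_prediction> h2 reference =", round(x$h2_reference, 3), "\n")
  print(x$per_stratum)
  invisible(x)
}
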