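#' Plot a stratified accuracy summary
#'
#' Quality-statistic bins and MAF bands are drawn as point-line profiles of
#' mean empirical accuracy; 1-Mb windows as a genome track facetted by
#' chromosome; annotation classes and chromosomes as bar charts.
#'
#' @param object an `accuracy_summary` from [stratified_summary()].
#' @param min_n hide strata holding fewer variants than this.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.accuracy_summary <- function(object, min_n = 1L, ...) {
  stratifier <- attr(object, "stratifier")
  df <- dplyr::filter(object, .data$n >= min_n, !is.na(.data$mean_r))
  if (stratifier == "windows_1mb") {
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$window_start / 1e6,
                                       y = .data$mean_r)) +
        ggplot2::geom_line(colour = "grey40") +
        ggplot2::geom_point(size = 0.8) +
        ggplot2::facet_wrap(~chrom, scales = "free_x") +
        ggplot2::labs(x = "position (Mb)", y = "mean empirical accuracy") +
        ggplot2::theme_minimal()
    )
  }
  if (stratifier == "rsq_bins") {
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$midpoint, y = .data$mean_r)) +
        ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.6) +
        ggplot2::geom_line(colour = "grey40") +
        ggplot2::scale_size_area(max_size = 3) +
        ggplot2::labs(x = "quality statistic (bin midpoint)",
                      y = "mean empirical accuracy", size = "variants") +
        ggplot2::theme_minimal()
    )
  }
  df$stratum <- factor(df$stratum, levels = object$stratum[!duplicated(object$stratum)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stratum, y = .data$mean_r)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(min(df$mean_r) * 0.95, 1)) +
    ggplot2::labs(x = stratifier, y = "mean empirical accuracy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a quality-stratified prediction result
#'
#' Per-stratum mean genomic heritability and GEBV accuracy (with one
#' standard error over variant sets).
#'
#' @param object a `stratified_prediction` from
#'   [run_stratified_prediction()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.stratified_prediction <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$per_stratum, c("h2_mean", "accuracy"),
    names_to = "measure", values_to = "value")
  df$se <- ifelse(df$measure == "accuracy", object$per_stratum$accuracy_se[
    match(df$stratum, object$per_stratum$stratum)], NA)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stratum, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$value - .data$se,
                   ymax = .data$value + .data$se),
      width = 0.2, na.rm = TRUE) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "quality stratum", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
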