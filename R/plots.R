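#' Plot an LD decay profile
#'
#' Mean r-squared per distance bin against physical distance, the
#' standard LD-decay panel.
#'
#' @param object An `ld_profile` from [ld_decay()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ld_profile
#' @export
autoplot.ld_profile <- function(object, ...) {
  ggplot2::ggplot(object$binned,
                  ggplot2::aes(x = .data$bin_mid / 1000, y = .data$mean_r2)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "Distance between SNPs (Kb)",
                  y = expression(mean ~ r^2)) +
    ggplot2::theme_minimal()
}

#' Plot a variance-component comparison grid
#'
#' Stacked bars of the proportion of phenotypic variance per component,
#' one bar per relatedness source, faceted by age class, trait and model.
#'
#' @param object A `vc_grid` from [run_comparison()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot vc_grid
#' @export
autoplot.vc_grid <- function(object, ...) {
  dat <- dplyr::filter(tibble::as_tibble(object), .data$status == "ok")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$source, y = .data$ratio,
                                    fill = .data$term)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_grid(age_class ~ trait + model) +
    ggplot2::labs(x = NULL, y = "Proportion of phenotypic variance",
                  fill = "Component") +
    ggplot2::theme_minimal()
}

#' Plot a marker-subsampling curve
#'
#' Box-and-whisker summaries of the replicate heritability estimates per
#' marker fraction, with the per-fraction medians joined.
#'
#' @param object A `subsampling_curve` from [marker_subsampling()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot subsampling_curve
#' @export
autoplot.subsampling_curve <- function(object, ...) {
  dat <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$h2))
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$n_markers), y = .data$h2)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::stat_summary(fun = stats::median, geom = "line",
                          ggplot2::aes(group = 1), colour = "grey40") +
    ggplot2::labs(x = "Number of markers", y = expression(h^2)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
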