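#' Plot methods
#'
#' `autoplot()` methods for the package's result types: a `cl_sweep`
#' (sensitivity and specificity against the threshold), a `cl_roc`
#' (the ROC curve with its AUC), and `plot_cl_trajectories()` for the
#' longitudinal cervical-length profiles of a cohort by outcome subgroup.
#'
#' @param object A `cl_sweep` or `cl_roc`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name cltriage-plots
NULL

#' @rdname cltriage-plots
#' @method autoplot cl_sweep
#' @export
autoplot.cl_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[, c("block", "threshold", "sensitivity", "specificity")],
    c("sensitivity", "specificity"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$threshold, .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$block)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "threshold", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname cltriage-plots
#' @method autoplot cl_roc
#' @export
autoplot.cl_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  subtitle = sprintf("AUC = %.3f", attr(object, "auc"))) +
    ggplot2::theme_minimal()
}

#' @rdname cltriage-plots
#' @param cohort A cohort tibble.
#' @param max_per_group Trajectories drawn per subgroup (default 60).
#' @export
plot_cl_trajectories <- function(cohort, max_per_group = 60) {
  if (!"subgroup" %in% names(cohort)) cohort <- add_risk_group(cohort)
  cohort <- censor_post_cerclage(cohort)
  long <- cohort |>
    dplyr::group_by(.data$subgroup) |>
    dplyr::slice_head(n = max_per_group) |>
    dplyr::ungroup() |>
    tidyr::pivot_longer(c("cl_a", "cl_b", "cl_c"),
                        names_to = "timepoint", values_to = "cl") |>
    dplyr::filter(!is.na(.data$cl)) |>
    dplyr::mutate(timepoint = toupper(sub("cl_", "", .data$timepoint)))
  ggplot2::ggplot(long, ggplot2::aes(.data$timepoint, .data$cl,
                                     group = .data$id)) +
    ggplot2::geom_line(alpha = 0.25) +
    ggplot2::geom_hline(yintercept = 25, linetype = 2, colour = "red") +
    ggplot2::facet_wrap(ggplot2::vars(.data$subgroup)) +
    ggplot2::labs(x = "screening timepoint", y = "cervical length (mm)") +
    ggplot2::theme_minimal()
}
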