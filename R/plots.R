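# ggplot2 displays for the main result types.

#' Histogram of imputed-success counts by covariate group
#'
#' Displays the output of [table2_experiment()] in the style of a
#' method-comparison panel: the distribution over imputations of the number
#' of imputed successes among the missing outcomes in each `x` group.  A
#' well-behaved strategy concentrates near 0 in the perfectly predicted
#' group and near 50 in the balanced group; the unremediated
#' normal-approximation draw is bimodal at 0 and 100.
#'
#' @param counts Tibble from [table2_experiment()].
#' @param binwidth Histogram bin width (default 2).
#' @return A ggplot object.
#' @export
plot_imputed_successes <- function(counts, binwidth = 2) {
  long <- tidyr::pivot_longer(counts, dplyr::starts_with("successes_"),
                              names_to = "group", names_prefix = "successes_",
                              values_to = "successes")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$successes)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey35") +
    ggplot2::facet_wrap(~group, nrow = 1,
                        labeller = ggplot2::labeller(
                          group = c(x0 = "x = 0 (perfectly predicted)",
                                    x1 = "x = 1 (balanced)"))) +
    ggplot2::labs(x = "imputed successes per imputation", y = "imputations")
}

#' Expected-imputed-successes trade-off curve
#'
#' Plots [augmentation_tradeoff_curve()]: the Gauss--Hermite expectation of
#' the number of imputed successes against the pseudo-count h, one line per
#' failure count f.  The curve is minimised near h = 0.5, the per-cell
#' pseudo-count implied by a total augmentation weight of one per parameter.
#'
#' @param curve Tibble from [augmentation_tradeoff_curve()].
#' @return A ggplot object.
#' @export
plot_augmentation_tradeoff <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$h,
                                      y = .data$expected_successes,
                                      colour = factor(.data$f))) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "pseudo-count h added to each cell",
                  y = "mean imputed successes",
                  colour = "failures f")
}

#' @describeIn impute_univariate Plot the distribution of imputed levels per
#'   imputation for one variable of an imputation run.
#' @param variable Variable to display (default: first imputed variable).
#' @method autoplot imputation_run
#' @export
autoplot.imputation_run <- function(object, variable = NULL, ...) {
  variable <- variable %||% object$audit$variable[[1]]
  long <- purrr::map_dfr(seq_len(object$m), function(i) {
    tibble::tibble(imputation = i,
                   value = as.character(object$completed[[i]][[variable]]))
  })
  counts <- dplyr::count(long, .data$imputation, .data$value)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$value, y = .data$n)) +
    ggplot2::geom_boxplot(ggplot2::aes(group = .data$value)) +
    ggplot2::labs(x = variable, y = "count per completed dataset",
                  title = sprintf("Imputed '%s' across %d imputations (%s)",
                                  variable, object$m, object$config$method))
}
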