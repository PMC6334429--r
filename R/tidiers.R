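#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a selection run
#'
#' `tidy()` returns the per-generation history (one row per generation:
#' fitness scalar `r`, the generation's best accuracy and subset size, the
#' running hall-of-fame values, and cache counters). `glance()` returns a
#' one-row summary of the run.
#'
#' @param x A `gsp_result` from [gsp()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.gsp_result <- function(x, ...) {
  x$history
}

#' @rdname tidy.gsp_result
#' @export
glance.gsp_result <- function(x, ...) {
  tibble(
    best_accuracy = x$best_accuracy,
    best_size = x$best_size,
    generations_run = x$generations_run,
    best_generation = x$best_generation,
    distinct_subsets = x$counters$distinct_subsets,
    classifier_trainings = x$counters$classifier_trainings,
    n_samples = x$n_samples,
    n_attributes = x$n_attributes,
    seed = x$seed
  )
}

#' Selected attributes of a run as a tibble
#'
#' One row per selected attribute, joined with its Information-Gain rank and
#' roulette weight.
#'
#' @param x A `gsp_result`.
#' @return A tibble with columns `attribute`, `info_gain`, `weight`.
#' @export
selected_genes <- function(x) {
  stopifnot(inherits(x, "gsp_result"))
  dplyr::semi_join(tibble::as_tibble(x$weights),
                   tibble(attribute = x$best_subset),
                   by = "attribute")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the convergence of a selection run
#'
#' Two stacked panels over generations: the hall-of-fame LOOCV accuracy and
#' the hall-of-fame subset size. A run that behaves as intended shows
#' accuracy saturating early and the subset shrinking afterwards.
#'
#' @param object A `gsp_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gsp_result <- function(object, ...) {
  hist <- object$history
  long <- tidyr::pivot_longer(
    hist[, c("generation", "hof_accuracy", "hof_size")],
    cols = c("hof_accuracy", "hof_size"),
    names_to = "metric", values_to = "value"
  )
  long$metric <- factor(long$metric, levels = c("hof_accuracy", "hof_size"),
                        labels = c("LOOCV accuracy", "subset size"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$generation, y = .data$value)) +
    ggplot2::geom_step(linewidth = 0.6) +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "generation", y = NULL,
                  title = "Gene selection convergence") +
    ggplot2::theme_minimal()
}

#' Plot attribute weights
#'
#' Bar plot of the top-ranked attributes' Information-Gain weights, the
#' distribution the roulette wheel samples terminals from.
#'
#' @param weights An `attribute_weights` table from [rank_attributes()].
#' @param top_n Number of attributes shown.
#' @return A ggplot object.
#' @export
plot_attribute_weights <- function(weights, top_n = 20L) {
  top <- dplyr::slice_max(tibble::as_tibble(weights), .data$weight,
                          n = top_n, with_ties = FALSE)
  top <- dplyr::filter(top, .data$weight > 0)
  ggplot2::ggplot(top, ggplot2::aes(x = stats::reorder(.data$attribute, .data$weight),
                                    y = .data$weight)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "roulette weight",
                  title = "Information-Gain attribute weights") +
    ggplot2::theme_minimal()
}
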