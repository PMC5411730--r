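#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an environment screen
#'
#' Bar chart of environment counts by viability class (host-viable,
#' novel, unreachable), faceted by swapped element.
#'
#' @param object an `environment_screen`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.environment_screen <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::mutate(class = dplyr::case_when(
      .data$host_viable ~ "host viable",
      .data$novel ~ "novel",
      TRUE ~ "unreachable"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class, fill = .data$class)) +
    ggplot2::geom_bar(show.legend = FALSE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$element)) +
    ggplot2::labs(x = NULL, y = "environments",
                  title = "Single-swap environment screen") +
    ggplot2::theme_minimal()
}

#' Distribution of minimal added-reaction set sizes
#'
#' Histogram of the minimal number of reactions that must be added per
#' novel environment — the innovation-complexity profile of the
#' reachable nutrient space.
#'
#' @param enumerations list of `minimal_set_enumeration` objects (or a
#'   tibble with a `minimal_size` column).
#' @return a ggplot.
#' @export
plot_minimal_sizes <- function(enumerations) {
  d <- if (is.data.frame(enumerations)) enumerations
  else dplyr::bind_rows(lapply(enumerations, glance))
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$minimal_size))) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = "minimal reaction set size",
                  y = "novel environments") +
    ggplot2::theme_minimal()
}

#' Plot a pair classification
#'
#' Counts of growth-promoting reaction pairs by category: beneficial only
#' jointly versus beneficial with an individually beneficial
#' (stepping-stone) member.
#'
#' @param object a `pair_classification`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pair_classification <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::mutate(category = gsub("_", " ", sub("^beneficial_", "", .data$category)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, fill = .data$category)) +
    ggplot2::geom_bar(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "reaction pairs",
                  title = "Growth-promoting reaction pairs") +
    ggplot2::theme_minimal()
}

#' Plot a co-gain randomization null distribution
#'
#' Histogram of shuffled-pair mean co-gain fractions with the observed
#' mean marked.
#'
#' @param object a `cogain_randomization`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cogain_randomization <- function(object, ...) {
  d <- tibble::tibble(mean_f = object$shuffled_means)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_f)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed_mean,
                        colour = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "mean co-gain fraction (shuffled pairs)", y = "replicates",
                  subtitle = paste0("P = ", format(object$p_value, digits = 3))) +
    ggplot2::theme_minimal()
}
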