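#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot elution profiles for selected proteins
#'
#' @param profiles tibble `protein` + fraction columns.
#' @param proteins character vector of protein ids to show.
#' @return a ggplot object (fraction on x, ratio on y, one line per
#'   protein).
#' @export
plot_profiles <- function(profiles, proteins = head(profiles$protein, 6)) {
  long <- profiles %>%
    filter(.data$protein %in% proteins) %>%
    tidyr::pivot_longer(-"protein", names_to = "fraction",
                        values_to = "ratio") %>%
    mutate(fraction = as.integer(sub("fraction_", "", .data$fraction)))
  ggplot2::ggplot(long, ggplot2::aes(.data$fraction, .data$ratio,
                                     colour = .data$protein)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "SEC fraction", y = "SILAC ratio",
                  colour = "protein") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.pcp_calibration
#' @export
autoplot.pcp_calibration <- function(object, type = c("accumulation",
                                                      "precision_recall"),
                                     ...) {
  type <- match.arg(type)
  curve <- object$curve
  if (type == "accumulation") {
    ggplot2::ggplot(curve, ggplot2::aes(.data$rank, .data$precision)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "accumulated number of interactions",
                    y = "precision") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(curve, ggplot2::aes(.data$recall, .data$precision)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "recall", y = "precision") +
      ggplot2::theme_minimal()
  }
}

#' Plot methods for calibration and validation results
#'
#' `autoplot.pcp_calibration` draws precision against accumulated
#' interactions or the precision-recall curve; `autoplot.pcp_validation`
#' draws the null distribution of a rewired-network metric with the
#' observed value marked.
#'
#' @param object the fitted object.
#' @param type which calibration view to draw.
#' @param ... unused.
#' @return a ggplot object.
#' @name autoplot.pcp_calibration
NULL

#' @rdname autoplot.pcp_calibration
#' @export
autoplot.pcp_validation <- function(object, ...) {
  nulls <- tibble(value = attr(object, "null_values"))
  ggplot2::ggplot(nulls, ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(x = object$metric[1], y = "null count",
                  subtitle = sprintf("z = %.2f, empirical p = %.3g",
                                     object$z[1], object$p_empirical[1])) +
    ggplot2::theme_minimal()
}
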