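#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the confidence composition of an annotation table
#'
#' Bar chart of annotation counts per confidence statement, split by line
#' kind, so a summarised file shows at a glance how much evidence is
#' congruent, conflicting or rejected.
#'
#' @param records An annotation-record tibble.
#' @return A ggplot object.
#' @export
plot_confidence_composition <- function(records) {
  d <- dplyr::count(records,
                    confidence = dplyr::coalesce(.data$confidence, "(none)"),
                    .data$line_kind)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n,
                                  y = stats::reorder(.data$confidence, .data$n),
                                  fill = .data$line_kind)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "annotation lines", y = NULL, fill = "line kind",
                  title = "Confidence statements in annotation file") +
    ggplot2::theme_minimal()
}

#' Plot a validation report
#'
#' @param object A `cio_validation` tibble from [validate_annotations()].
#' @param ... Unused.
#' @return A ggplot object; findings per severity, labelled by input line.
#' @export
autoplot.cio_validation <- function(object, ...) {
  if (nrow(object) == 0) {
    return(
      ggplot2::ggplot() +
        ggplot2::annotate("text", x = 0, y = 0, label = "no findings") +
        ggplot2::theme_void()
    )
  }
  d <- dplyr::count(object, .data$severity)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$severity, y = .data$n,
                                  fill = .data$severity)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "findings", title = "Validation report") +
    ggplot2::theme_minimal()
}
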