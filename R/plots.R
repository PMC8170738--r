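#' Plot integrity-counter progress
#'
#' Horizontal bars of each analyte's validation count against its target,
#' coloured by whether automated reporting is enabled — the package's
#' version of the per-project validation recording screen.
#'
#' @param session A [lab_session()].
#' @return A ggplot object.
#' @export
plot_counters <- function(session) {
  d <- counters(session)
  ggplot2::ggplot(d, ggplot2::aes(x = count, y = analyte_code,
                                  fill = auto_enabled)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::geom_point(ggplot2::aes(x = target), shape = "|", size = 6,
                        colour = "grey30") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "#8da0cb",
                                          `TRUE` = "#66c2a5"),
                               name = "auto release") +
    ggplot2::labs(x = "validated unmodified releases",
                  y = NULL,
                  title = "Integrity validation progress",
                  subtitle = "tick marks the validation target") +
    ggplot2::theme_minimal()
}

#' Plot warning colours of a result stream
#'
#' @param warnings Tibble from [evaluate_results()].
#' @return A ggplot object.
#' @export
plot_warnings <- function(warnings) {
  d <- dplyr::count(warnings, analyte_code, color)
  ggplot2::ggplot(d, ggplot2::aes(x = analyte_code, y = n, fill = color)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_manual(values = c(green = "#4daf4a", red = "#e41a1c",
                                          purple = "#984ea3")) +
    ggplot2::labs(x = NULL, y = "tests", title = "Automatic warning colours") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname plot_counters
#' @param object A `lab_session`.
#' @param ... Ignored.
#' @export
autoplot.lab_session <- function(object, ...) plot_counters(object)

#' Plot the workload comparison
#'
#' Side-by-side step durations of the manual and system-driven validation
#' methods.
#'
#' @param object An [workload_model()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.av_workload <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(step), y = hours, fill = method)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::scale_fill_manual(values = c(manual = "#fc8d62",
                                          new = "#66c2a5")) +
    ggplot2::labs(x = "step", y = "hours",
                  title = "Validation time by step") +
    ggplot2::theme_minimal()
}

#' Plot the correctness-phase summary
#'
#' @param object An `av_correctness_summary`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.av_correctness_summary <- function(object, ...) {
  d <- tibble(
    group = c("rules", "rules", "validations", "validations"),
    part = c("verified", "deleted", "released", "intercepted"),
    n = c(object$n_verified, object$n_deleted, object$n_released,
          object$n_intercepted)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = group, y = n, fill = part)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Correctness verification outcomes") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
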