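#' Bar chart of mean balanced accuracy by method
#'
#' Mirrors the usual committee-comparison figure: one bar per
#' classification method plus the voting meta-classifier, at the mean
#' performance over studies.
#'
#' @param result An `internal_result` or `external_result`.
#' @return A ggplot object.
#' @export
plot_performance <- function(result) {
  df <- filter(result$performance, .data$study == "mean") |>
    mutate(method = factor(.data$method, levels = c(METHOD_NAMES, "Voting")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$bacc)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = "Balanced accuracy",
      title = if (inherits(result, "internal_result")) {
        "Internal 10x10 CV performance"
      } else {
        sprintf("External validation (%s)", result$regime)
      }
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_performance
#' @param object An experiment result.
#' @param ... Unused.
#' @export
autoplot.internal_result <- function(object, ...) plot_performance(object)

#' @rdname plot_performance
#' @export
autoplot.external_result <- function(object, ...) plot_performance(object)

#' Heat map of pairwise comparison significance
#'
#' Tiles the 28 pairwise repeated-downsampling comparisons by
#' `-log10(median p)`.
#'
#' @param comparisons Tibble with `method_a`, `method_b`, `median_p`
#'   (the `comparisons` element of an experiment result).
#' @return A ggplot object.
#' @export
plot_comparison_matrix <- function(comparisons) {
  lv <- c(METHOD_NAMES, "Voting")
  df <- mutate(comparisons,
    method_a = factor(.data$method_a, levels = lv),
    method_b = factor(.data$method_b, levels = lv),
    neglog_p = -log10(pmax(.data$median_p, 1e-300))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$method_a, .data$method_b,
                                   fill = .data$neglog_p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = expression(-log[10](median ~ p))) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
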