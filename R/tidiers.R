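#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted model's selected features
#'
#' @param x A `fitted_model`.
#' @param ... Unused.
#' @return Tibble with one row per selected feature, in importance order.
#' @export
tidy.fitted_model <- function(x, ...) {
  tibble(
    term = x$features,
    importance_rank = seq_along(x$features),
    method = x$method
  )
}

#' One-row summary of a fitted model
#'
#' @param x A `fitted_model`.
#' @param ... Unused.
#' @export
glance.fitted_model <- function(x, ...) {
  dplyr::bind_cols(
    tibble(
      method = x$method,
      n_features = length(x$features),
      train_study = x$train_study
    ),
    x$cv_performance
  )
}

#' Per-repetition detail of a classifier comparison
#'
#' @param x A `comparison_result` from [compare_methods()].
#' @param ... Unused.
#' @return Tibble with one row per downsampling repetition.
#' @export
tidy.comparison_result <- function(x, ...) {
  mutate(x$per_rep,
    rep = dplyr::row_number(),
    method_a = x$method_a, method_b = x$method_b
  )
}

#' One-row summary of a classifier comparison
#'
#' @param x A `comparison_result`.
#' @param ... Unused.
#' @export
glance.comparison_result <- function(x, ...) {
  tibble(
    method_a = x$method_a, method_b = x$method_b,
    n_reps = x$n_reps, median_p = x$median_p
  )
}

#' Tidy an experiment result
#'
#' @param x An `internal_result` or `external_result`.
#' @param ... Unused.
#' @return The performance tibble (per-study and mean rows).
#' @export
tidy.internal_result <- function(x, ...) x$performance

#' @rdname tidy.internal_result
#' @export
tidy.external_result <- function(x, ...) x$performance

#' Experiment-level summary: mean balanced accuracies
#'
#' @param x An `internal_result` or `external_result`.
#' @param ... Unused.
#' @return One-row tibble with the voting bAcc, the mean per-method bAcc,
#'   and the best single method.
#' @export
glance.internal_result <- function(x, ...) {
  m <- filter(x$performance, .data$study == "mean")
  methods_only <- filter(m, .data$method != "Voting")
  tibble(
    voting_bacc = m$bacc[m$method == "Voting"],
    mean_method_bacc = mean(methods_only$bacc),
    best_method = methods_only$method[which.max(methods_only$bacc)],
    best_method_bacc = max(methods_only$bacc)
  )
}

#' @rdname glance.internal_result
#' @export
glance.external_result <- glance.internal_result
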