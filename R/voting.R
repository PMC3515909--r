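#' Consolidate a sample's ten cross-validation votes into one label
#'
#' Each sample receives ten votes per method during 10x10 CV. To prevent
#' ties, only the nine first votes (by repetition index) decide the class:
#' nine is odd, so a majority always exists; the tenth vote is ignored.
#'
#' @param votes Integer 0/1 vector of exactly 10 votes, ordered by CV
#'   repetition index.
#' @return A single 0/1 label.
#' @export
consolidate_method_votes <- function(votes) {
  if (length(votes) != 10 || anyNA(votes)) {
    abort_input("need exactly 10 non-missing votes per (sample, method)")
  }
  majority_label(votes[1:9])
}

#' Majority vote across the seven classification methods
#'
#' @param labels Integer 0/1 vector of exactly 7 labels, one per method;
#'   seven is odd, so a majority always exists.
#' @return A single 0/1 label.
#' @export
cross_method_vote <- function(labels) {
  if (length(labels) != 7 || anyNA(labels)) {
    abort_input("need exactly 7 non-missing labels, one per method")
  }
  majority_label(labels)
}

#' Two-level majority-voting meta-classification
#'
#' Internal mode consumes a CV vote table (10 votes per sample and
#' method), first consolidating each method's votes via
#' [consolidate_method_votes()] and then taking the cross-method majority;
#' external mode consumes one vote per sample and method and takes the
#' cross-method majority directly.
#'
#' @param votes A tibble with columns `sample_id`, `method`, `label`, and
#'   (internal mode) `cv_repeat`. The methods present must be exactly the
#'   seven committee methods.
#' @param mode `"internal"` or `"external"`.
#' @return A tibble with `sample_id` and the voted `label`.
#' @export
vote_classify <- function(votes, mode = c("internal", "external")) {
  mode <- match.arg(mode)
  if (!all(c("sample_id", "method", "label") %in% names(votes))) {
    abort_input("`votes` needs columns sample_id, method, label")
  }
  methods_seen <- sort(unique(votes$method))
  if (!identical(methods_seen, sort(METHOD_NAMES))) {
    abort_input(sprintf(
      "vote table must contain exactly the 7 methods; got: %s",
      paste(methods_seen, collapse = ", ")
    ))
  }
  if (mode == "internal") {
    if (!"cv_repeat" %in% names(votes)) {
      abort_input("internal vote tables need a `cv_repeat` column")
    }
    per_method <- votes |>
      group_by(.data$sample_id, .data$method) |>
      arrange(.data$cv_repeat, .by_group = TRUE) |>
      summarise(
        label = consolidate_method_votes(.data$label),
        .groups = "drop"
      )
  } else {
    counts <- dplyr::count(votes, .data$sample_id, .data$method)
    if (any(counts$n != 1)) {
      abort_input("external vote tables need exactly 1 vote per (sample, method)")
    }
    per_method <- votes
  }
  per_method |>
    group_by(.data$sample_id) |>
    summarise(label = cross_method_vote(.data$label), .groups = "drop")
}
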