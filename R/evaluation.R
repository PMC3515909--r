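#' Sensitivity, specificity and balanced accuracy
#'
#' Sensitivity is the true-positive rate on the metastasis class (label
#' 1), specificity the true-negative rate on the non-metastasis class,
#' and balanced accuracy (bAcc) their mean — a performance measure that
#' is insensitive to class imbalance.
#'
#' @param labels Integer 0/1 true labels; both classes must be present.
#' @param preds Integer 0/1 predicted labels, same length.
#' @return A one-row tibble: `sensitivity`, `specificity`, `bacc`,
#'   `n_samples`, `n_positives`.
#' @export
performance_summary <- function(labels, preds) {
  if (length(labels) != length(preds)) {
    abort_input("`labels` and `preds` must have equal length")
  }
  if (anyNA(labels) || anyNA(preds)) abort_input("labels/preds contain NA")
  pos <- labels == 1L
  if (!any(pos) || all(pos)) {
    abort_input("balanced accuracy needs both classes present in `labels`")
  }
  sens <- mean(preds[pos] == 1L)
  spec <- mean(preds[!pos] == 0L)
  tibble(
    sensitivity = sens,
    specificity = spec,
    bacc = (sens + spec) / 2,
    n_samples = length(labels),
    n_positives = sum(pos)
  )
}

#' Downsample the majority class to a balanced subset
#'
#' Returns sample indices of a class-balanced subset: all minority-class
#' samples plus an equal number of majority-class samples drawn uniformly
#' without replacement.
#'
#' @param labels Integer 0/1 labels; both classes present.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return Sorted integer vector of retained indices; the identity when
#'   the classes are already balanced.
#' @export
downsample_balance <- function(labels, seed = NULL) {
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) abort_input("both classes must be present")
  draw <- function() {
    if (n1 == n0) {
      return(seq_along(labels))
    }
    minority <- if (n1 < n0) 1L else 0L
    min_ix <- which(labels == minority)
    maj_ix <- which(labels != minority)
    keep_maj <- maj_ix[sample.int(length(maj_ix), length(min_ix))]
    sort(c(min_ix, keep_maj))
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

#' Binomial chi-squared test on discordant counts
#'
#' Pearson chi-squared test (1 df, no continuity correction) of the two
#' discordant counts — samples correct under method A only versus method
#' B only — against an even split: a McNemar-style test of equal
#' classifier accuracy. With no discordant samples the p-value is 1 by
#' convention. `exact = TRUE` instead uses the exact two-sided binomial
#' test of `a_only` successes in `a_only + b_only` trials at rate 1/2.
#'
#' @param a_only,b_only Nonnegative discordant counts.
#' @param exact Use the exact binomial test instead of the chi-squared
#'   approximation.
#' @return A p-value.
#' @export
binom_chi2 <- function(a_only, b_only, exact = FALSE) {
  if (a_only < 0 || b_only < 0) abort_input("counts must be nonnegative")
  m <- a_only + b_only
  if (m == 0) {
    return(1)
  }
  if (exact) {
    return(binom.test(a_only, m, p = 0.5)$p.value)
  }
  stat <- (a_only - b_only)^2 / m
  pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Repeated downsampled binomial test comparing two classifiers
#'
#' Compares two classifiers' predictions on an imbalanced test set in
#' five steps, repeated `n_reps` times: (1) draw a class-balanced subset
#' by downsampling the majority class; (2) count the samples correct
#' under A but not B (`a_only`) and vice versa (`b_only`) on the subset;
#' (3) test the discordant counts with [binom_chi2()]; (4) store the
#' p-value; then (5) report the median p-value over all repetitions as
#' the significance of the performance difference.
#'
#' @param labels Integer 0/1 true labels.
#' @param preds_a,preds_b Predicted labels of the two methods.
#' @param n_reps Number of downsampling repetitions (default 1000).
#' @param seed Integer seed; the whole procedure is deterministic given
#'   it, and symmetric: swapping A and B with the same seed gives the
#'   same median p.
#' @param exact Passed to [binom_chi2()].
#' @param method_a,method_b Optional display names.
#' @return An object of class `comparison_result` with `per_rep`
#'   (tibble `a_only`, `b_only`, `p_value`) and `median_p`. The median of
#'   an even number of p-values is the mean of the two central order
#'   statistics.
#' @export
compare_methods <- function(labels, preds_a, preds_b, n_reps = 1000,
                            seed = 1, exact = FALSE,
                            method_a = "A", method_b = "B") {
  if (length(preds_a) != length(labels) || length(preds_b) != length(labels)) {
    abort_input("`labels`, `preds_a`, `preds_b` must have equal length")
  }
  correct_a <- preds_a == labels
  correct_b <- preds_b == labels
  a_only <- integer(n_reps)
  b_only <- integer(n_reps)
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(n_reps)) {
      ix <- downsample_balance(labels)
      a_only[r] <- sum(correct_a[ix] & !correct_b[ix])
      b_only[r] <- sum(correct_b[ix] & !correct_a[ix])
    }
  })
  p <- vapply(
    seq_len(n_reps),
    function(r) binom_chi2(a_only[r], b_only[r], exact = exact),
    numeric(1)
  )
  structure(
    list(
      method_a = method_a, method_b = method_b, n_reps = n_reps,
      per_rep = tibble(a_only = a_only, b_only = b_only, p_value = p),
      median_p = median(p)
    ),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "<comparison_result> %s vs %s: median p = %.4g over %d downsampled repetitions\n",
    x$method_a, x$method_b, x$median_p, x$n_reps
  ))
  invisible(x)
}
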