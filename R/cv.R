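# Stratified fold assignment: within each outcome class, samples are
# shuffled and dealt round-robin, so every fold keeps the class mix.
make_cv_folds <- function(y, n_folds, seed) {
  folds <- integer(length(y))
  withr::with_seed(as.integer(seed), {
    for (cls in unique(y)) {
      ix <- which(y == cls)
      ix <- ix[sample.int(length(ix))]
      folds[ix] <- rep(seq_len(n_folds), length.out = length(ix))
    }
  })
  folds
}

#' Ten-times repeated stratified 10-fold cross-validation
#'
#' Runs `n_repeats` independent repetitions of stratified `n_folds`-fold
#' cross-validation of one classification method on one training study.
#' Each sample is predicted exactly once per repetition, so every sample
#' accumulates exactly `n_repeats` votes, ordered by repetition index.
#' The performance summary pools all out-of-fold predictions.
#'
#' In the default (`rank_in_fold = NULL`) protocol the feature set is
#' fixed up front — the leakage-prone protocol in which importance
#' ranking has already seen all samples. Supplying
#' `rank_in_fold = list(pool = ..., k = ..., ntree = ..., seed = ...)`
#' instead re-ranks the pool by random-forest importance inside every
#' training fold and uses that fold's top `k` genes (the leakage-free
#' protocol).
#'
#' @param train An [expression_study()] with >= 20 samples.
#' @param method A [method_spec()].
#' @param features Character vector of gene symbols to use (ignored when
#'   `rank_in_fold` is given).
#' @param hyperparams One-row tibble of hyperparameters (default: first
#'   row of the method's grid).
#' @param seed Integer seed controlling fold shuffles and model fits.
#' @param n_repeats,n_folds Cross-validation shape (default 10 x 10).
#' @param rank_in_fold Optional within-fold ranking spec (see above).
#'
#' @return A list with `votes` (tibble `sample_id`, `method`, `cv_repeat`,
#'   `label`), `votes_matrix` (samples x repeats), and `performance`
#'   (a one-row [performance_summary()] tibble over all pooled
#'   out-of-fold predictions).
#' @export
cv10x10 <- function(train, method, features, hyperparams = NULL, seed = 1,
                    n_repeats = 10, n_folds = 10, rank_in_fold = NULL) {
  if (n_samples(train) < 20) {
    abort_input("cross-validation needs >= 20 samples")
  }
  check_two_classes(train)
  hyperparams <- hyperparams %||% method$grid[1, ]
  y <- unname(train$outcome)
  n <- length(y)
  if (min(table(y)) < 2) {
    abort_config("sample size too small: a fold would lose an outcome class")
  }
  if (is.null(rank_in_fold)) {
    missing <- setdiff(features, train$gene_ids)
    if (length(missing) > 0) {
      abort_input(sprintf(
        "feature(s) not in training study: %s", paste(missing, collapse = ", ")
      ))
    }
    x_all <- t(train$matrix[features, , drop = FALSE])
  }

  votes <- matrix(NA_integer_, n, n_repeats)
  for (r in seq_len(n_repeats)) {
    folds <- make_cv_folds(y, n_folds, derive_seed(seed, paste0("fold", r)))
    for (f in seq_len(n_folds)) {
      in_tr <- folds != f
      if (!any(in_tr)) next
      if (length(unique(y[in_tr])) < 2) {
        abort_config("sample size too small: a fold lost an outcome class")
      }
      if (is.null(rank_in_fold)) {
        x_tr <- x_all[in_tr, , drop = FALSE]
        x_te <- x_all[!in_tr, , drop = FALSE]
      } else {
        fold_study <- train
        fold_study$matrix <- train$matrix[, in_tr, drop = FALSE]
        fold_study$outcome <- train$outcome[in_tr]
        ranked <- importance_rank(
          fold_study, rank_in_fold$pool,
          seed = derive_seed(rank_in_fold$seed %||% seed,
                             paste0("rank", r, "_", f)),
          ntree = rank_in_fold$ntree %||% 500
        )
        feats <- head(ranked, rank_in_fold$k)
        x_tr <- t(train$matrix[feats, in_tr, drop = FALSE])
        x_te <- t(train$matrix[feats, !in_tr, drop = FALSE])
      }
      clf <- fit_classifier(
        method$name, x_tr, y[in_tr], hyperparams,
        seed = derive_seed(seed, paste0("fit", r, "_", f))
      )
      votes[!in_tr, r] <- predict_classifier(clf, x_te)
    }
  }

  perf <- performance_summary(rep(y, n_repeats), as.vector(votes))
  vote_tbl <- tibble(
    sample_id = rep(colnames(train$matrix), n_repeats),
    method = method$name,
    cv_repeat = rep(seq_len(n_repeats), each = n),
    label = as.vector(votes)
  )
  list(votes = vote_tbl, votes_matrix = votes, performance = perf)
}
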