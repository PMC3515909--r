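#' Rank a gene pool by random-forest permutation importance
#'
#' Fits a random forest on the full training study and orders the pool by
#' decreasing permutation importance (the standardized drop in prediction
#' accuracy when a feature's values are permuted out-of-bag).
#'
#' @param train An [expression_study()] with both classes present.
#' @param pool Character vector of candidate gene symbols, all present in
#'   `train`.
#' @param seed Integer seed (the forest, and hence tie order among equally
#'   important genes, is deterministic given the seed).
#' @param ntree Number of trees (default 2000).
#' @return `pool` reordered by decreasing importance.
#' @export
importance_rank <- function(train, pool, seed = 1, ntree = 2000) {
  check_two_classes(train)
  missing <- setdiff(pool, train$gene_ids)
  if (length(missing) > 0) {
    abort_input(sprintf(
      "pool gene(s) not in training study: %s",
      paste(missing, collapse = ", ")
    ))
  }
  if (length(pool) == 1) {
    return(pool)
  }
  x <- t(train$matrix[pool, , drop = FALSE])
  yf <- factor(unname(train$outcome), levels = c(0L, 1L))
  rf <- ranger::ranger(
    x = x, y = yf, num.trees = ntree,
    importance = "permutation", scale.permutation.importance = TRUE,
    seed = as.integer(seed), num.threads = 1
  )
  pool[order(-rf$variable.importance)]
}

#' Importance-ranked forward model building with grid search
#'
#' Builds the best model of one classification method by jointly searching
#' prefix lengths of the importance ranking (adding one feature at a time,
#' top down) and the method's hyperparameter grid. Every candidate
#' `(k, grid point)` is scored by repeated stratified cross-validation
#' ([cv10x10()], with identical fold shuffles across candidates), and the
#' candidate with the best balanced accuracy wins; ties prefer the more
#' balanced sensitivity/specificity, then fewer features, then the earlier
#' grid row. The winner is refit on the full training study.
#'
#' With `mode = "nested"`, candidate scoring re-ranks the pool inside
#' every training fold (no leakage); the final refit still uses
#' `ranked_features`.
#'
#' @param train An [expression_study()].
#' @param method A [method_spec()].
#' @param ranked_features Importance-ordered gene symbols from
#'   [importance_rank()].
#' @param grid Hyperparameter grid (default: the method's own).
#' @param seed Integer seed.
#' @param max_features Largest prefix length searched (default 40; models
#'   on data of this kind typically settle well below that).
#' @param n_repeats,n_folds Cross-validation shape.
#' @param mode `"prerank"` (default): features ranked once on the full
#'   training study before CV — the leakage-prone protocol this package
#'   re-enacts; `"nested"`: within-fold re-ranking (needs `pool` and
#'   `rank_ntree`).
#' @param pool,rank_ntree Pool and forest size for `mode = "nested"`.
#'
#' @return An object of class `fitted_model`: method name, ordered
#'   selected `features`, chosen `hyperparams`, `cv_performance` and
#'   `cv_votes` of the winning candidate, the `search` table of all
#'   candidates, and the refit classifier.
#' @export
forward_select <- function(train, method, ranked_features,
                           grid = method$grid, seed = 1,
                           max_features = 40,
                           n_repeats = 10, n_folds = 10,
                           mode = c("prerank", "nested"),
                           pool = NULL, rank_ntree = 500) {
  mode <- match.arg(mode)
  if (length(ranked_features) == 0) {
    abort_input("`ranked_features` must be nonempty")
  }
  grid <- as_tibble(grid)
  if (nrow(grid) == 0) abort_config("hyperparameter grid is empty")
  max_features <- min(max_features, length(ranked_features))
  cv_seed <- derive_seed(seed, "cv")

  candidates <- tidyr::expand_grid(
    k = seq_len(max_features),
    grid_row = seq_len(nrow(grid))
  )
  scored <- purrr::pmap(candidates, function(k, grid_row) {
    rif <- if (mode == "nested") {
      list(
        pool = pool %||% ranked_features, k = k,
        ntree = rank_ntree, seed = derive_seed(seed, "foldrank")
      )
    }
    res <- cv10x10(
      train, method,
      features = head(ranked_features, k),
      hyperparams = grid[grid_row, ],
      seed = cv_seed, n_repeats = n_repeats, n_folds = n_folds,
      rank_in_fold = rif
    )
    list(perf = res$performance, votes = res)
  })
  search <- dplyr::bind_cols(
    candidates,
    dplyr::bind_rows(purrr::map(scored, "perf"))
  )

  best <- order(
    -search$bacc,
    abs(search$sensitivity - search$specificity),
    search$k,
    search$grid_row
  )[1]
  k_best <- search$k[best]
  hp_best <- grid[search$grid_row[best], ]
  features <- head(ranked_features, k_best)

  clf <- fit_classifier(
    method$name,
    t(train$matrix[features, , drop = FALSE]),
    unname(train$outcome),
    hp_best,
    seed = derive_seed(seed, "final")
  )

  structure(
    list(
      method = method$name,
      features = features,
      hyperparams = as.list(hp_best),
      cv_performance = scored[[best]]$perf,
      cv_votes = scored[[best]]$votes$votes,
      cv_votes_matrix = scored[[best]]$votes$votes_matrix,
      search = search,
      classifier = clf,
      train_study = train$study_id,
      seed = as.integer(seed)
    ),
    class = "fitted_model"
  )
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf(
    "<fitted_model> %s on %s: %d feature(s), cv bAcc %.3f\n",
    x$method, x$train_study, length(x$features), x$cv_performance$bacc
  ))
  invisible(x)
}

#' Predict class labels for a study with a fitted model
#'
#' @param object A `fitted_model` from [forward_select()].
#' @param study An [expression_study()] containing every model feature
#'   (run [match_genes()] first); an informative error names any missing
#'   gene.
#' @param ... Unused.
#' @return Named integer vector of 0/1 labels, one per sample.
#' @export
predict.fitted_model <- function(object, study, ...) {
  missing <- setdiff(object$features, study$gene_ids)
  if (length(missing) > 0) {
    abort_input(sprintf(
      "model feature(s) missing from study '%s': %s",
      study$study_id, paste(missing, collapse = ", ")
    ))
  }
  xnew <- t(study$matrix[object$features, , drop = FALSE])
  predict_classifier(object$classifier, xnew)
}
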