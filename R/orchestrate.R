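#' Configuration of a full comparison experiment
#'
#' Bundles the simulation conditions, the method committee, and every
#' pipeline tuning knob for [run_internal()] / [run_external()]. All
#' randomness is governed by the single `seed`: named sub-seeds
#' (simulate / rank / cv / platform / compare) are derived from it, so
#' stages can be re-run independently with identical results.
#'
#' @param simulation A [simulation_config()] with at least 5 studies (the
#'   default role split needs feature definers, two training studies and
#'   two test studies).
#' @param methods Named list of the seven [method_spec()] objects
#'   (default: full grids via [method_set()]).
#' @param fdr_threshold FDR cutoff for feature selection.
#' @param mode `"prerank"` (importance ranking on the full training study
#'   before CV, the leakage-prone protocol) or `"nested"` (within-fold
#'   re-ranking).
#' @param n_reps_compare Downsampling repetitions per pairwise comparison.
#' @param min_studies Minimum studies per gene in [meta_rank_significance()]
#'   (default: all ranking studies).
#' @param n_permutations Permutations for rank significance.
#' @param max_features Forward-selection cap.
#' @param rank_ntree Trees for the importance-ranking forest.
#' @param n_repeats,n_folds Cross-validation shape.
#' @param seed Master integer seed.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(simulation = simulation_config(),
                              methods = method_set(),
                              fdr_threshold = 0.05,
                              mode = c("prerank", "nested"),
                              n_reps_compare = 1000,
                              min_studies = NULL,
                              n_permutations = 1000,
                              max_features = 40,
                              rank_ntree = 2000,
                              n_repeats = 10,
                              n_folds = 10,
                              seed = 1) {
  mode <- match.arg(mode)
  if (!inherits(simulation, "simulation_config")) {
    abort_config("`simulation` must be a `simulation_config`")
  }
  if (simulation$n_studies < 5) {
    abort_config("experiments need >= 5 studies (definers + 2 train + 2 test)")
  }
  if (!identical(sort(names(methods)), sort(METHOD_NAMES))) {
    abort_config("`methods` must be a named list of the 7 committee methods")
  }
  structure(
    list(
      simulation = simulation, methods = methods,
      fdr_threshold = fdr_threshold, mode = mode,
      n_reps_compare = as.integer(n_reps_compare),
      min_studies = min_studies,
      n_permutations = as.integer(n_permutations),
      max_features = as.integer(max_features),
      rank_ntree = as.integer(rank_ntree),
      n_repeats = as.integer(n_repeats),
      n_folds = as.integer(n_folds),
      seed = as.integer(seed)
    ),
    class = "experiment_config"
  )
}

#' Desk-scale configuration of the three comparison experiments
#'
#' A ready-made [experiment_config()] small enough to run all three
#' experiments in about a minute each, while keeping their qualitative
#' structure: seven studies (three feature definers, two training
#' studies, two larger test cohorts of 250 samples, matching the field's
#' cohort-size range), 150 genes per platform of which 70% are shared, a
#' 25-gene signature at a standardized effect of 1.25 expressed with 60%
#' penetrance per tumour (molecular-subgroup-style within-class
#' heterogeneity), a 30% metastasis class, reduced hyperparameter grids,
#' models of up to 4 features, and a strong cross-platform distortion
#' (per-gene scale SD 0.3, shift SD 3 on the standardized scale — the
#' regime in which cross-platform transfer degrades towards chance).
#'
#' Two signal regimes are provided. `"subtyped"` (the default) expresses
#' the signature with 60% penetrance per tumour — the molecular-subgroup
#' heterogeneity under which committee members err on different samples
#' and majority voting pays off; it is the regime for the internal and
#' same-platform experiments. `"uniform"` plants a homogeneous signature
#' (every metastasis sample carries every signature gene), the regime in
#' which within-platform transfer is tight and the cross-platform
#' experiment isolates the distortion penalty from transfer variance.
#'
#' @param seed Master seed.
#' @param n_reps_compare Downsampling repetitions per pairwise comparison.
#' @param signal `"subtyped"` or `"uniform"` (see above).
#' @return An [experiment_config()].
#' @export
demo_experiment_config <- function(seed = 1, n_reps_compare = 1000,
                                   signal = c("subtyped", "uniform")) {
  signal <- match.arg(signal)
  experiment_config(
    simulation = simulation_config(
      n_studies = 7, genes_per_platform = 150, shared_gene_fraction = 0.7,
      n_planted = 25, effect_size = 1.25,
      signal_penetrance = if (signal == "subtyped") 0.6 else 1,
      samples_per_study = c(60, 60, 60, 60, 60, 250, 250),
      metastasis_fraction = 0.3,
      platform_scale_sd = 0.3, platform_shift_sd = 4
    ),
    methods = method_set(reduced = TRUE),
    n_permutations = 250, max_features = 4, rank_ntree = 300,
    n_reps_compare = n_reps_compare, seed = seed
  )
}

#' Shared front end of the comparison experiments
#'
#' Simulates the study collection, selects rank-significant genes on the
#' non-test studies (on the raw, unstandardized data), intersects the
#' selection with the gene sets of all training and test studies, and
#' returns the matched, per-study standardized studies. [run_internal()]
#' and [run_external()] call this themselves; precompute it once and pass
#' it as `.prep` to run several experiments on the same configuration
#' without repeating the simulation and permutation test.
#'
#' @param config An [experiment_config()].
#' @return A list with the simulated collection, the rank table, the gene
#'   pool, the standardized studies, and the train/test study ids.
#' @export
prepare_pipeline <- function(config) {
  prepare_experiment(config)
}

prepare_experiment <- function(config) {
  simcfg <- config$simulation
  simcfg$seed <- derive_seed(config$seed, "simulate")
  sim <- simulate_multistudy(simcfg)
  roles <- vapply(sim$studies, function(s) s$role, character(1))
  ranking_studies <- sim$studies[roles != "test"]
  downstream <- sim$studies[roles %in% c("train", "test")]

  mrr <- meta_rank_significance(
    ranking_studies,
    min_studies = config$min_studies %||% length(ranking_studies),
    n_permutations = config$n_permutations,
    seed = derive_seed(config$seed, "rank"),
    fdr_threshold = config$fdr_threshold
  )
  selected <- mrr$gene_id[mrr$selected]
  pool <- intersect_pool(selected, downstream)
  if (length(pool) == 0) {
    abort_input(
      "no rank-significant gene is shared by all train/test studies; lower the FDR stringency or increase the shared gene fraction"
    )
  }
  matched <- match_genes(downstream, pool)
  std <- lapply(matched$studies, standardize_study)
  names(std) <- vapply(std, function(s) s$study_id, character(1))

  list(
    sim = sim, meta_rank = mrr, pool = matched$common_gene_ids,
    studies = std,
    train_ids = names(std)[vapply(std, function(s) s$role, character(1)) == "train"],
    test_ids = names(std)[vapply(std, function(s) s$role, character(1)) == "test"]
  )
}

# Train all seven methods on one (standardized) training study.
train_committee <- function(train, config, pool, seed_tag) {
  ranked <- importance_rank(
    train, pool,
    seed = derive_seed(config$seed, paste0("imprank_", seed_tag)),
    ntree = config$rank_ntree
  )
  models <- lapply(config$methods, function(ms) {
    forward_select(
      train, ms, ranked,
      grid = ms$grid,
      seed = derive_seed(config$seed, paste0("fs_", seed_tag, "_", ms$name)),
      max_features = config$max_features,
      n_repeats = config$n_repeats, n_folds = config$n_folds,
      mode = config$mode, pool = pool, rank_ntree = config$rank_ntree
    )
  })
  names(models) <- names(config$methods)
  list(ranked = ranked, models = models)
}

mean_performance_rows <- function(perf) {
  perf |>
    group_by(.data$method) |>
    summarise(
      study = "mean",
      sensitivity = mean(.data$sensitivity),
      specificity = mean(.data$specificity),
      bacc = mean(.data$bacc),
      n_samples = sum(.data$n_samples),
      n_positives = sum(.data$n_positives),
      .groups = "drop"
    ) |>
    select("study", "method", "sensitivity", "specificity",
           "bacc", "n_samples", "n_positives")
}

# All pairwise repeated-downsampling comparisons among the predictors
# (7 methods + Voting), on pooled predictions.
all_pair_comparisons <- function(labels, pred_list, config) {
  nms <- names(pred_list)
  pairs <- combn(nms, 2)
  purrr::map(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]
    b <- pairs[2, j]
    cmp <- compare_methods(
      labels, pred_list[[a]], pred_list[[b]],
      n_reps = config$n_reps_compare,
      seed = derive_seed(config$seed, paste0("cmp_", a, "_", b)),
      method_a = a, method_b = b
    )
    tibble(method_a = a, method_b = b, median_p = cmp$median_p)
  }) |> dplyr::bind_rows()
}

#' Internal 10x10 cross-validation comparison of the committee
#'
#' Re-enacts the within-dataset experiment on simulated studies: for each
#' training study, rank the shared significant-gene pool by importance,
#' forward-select a model per method, consolidate each method's ten CV
#' votes per sample into one label, form the cross-method voting label,
#' and summarise balanced accuracy per method and for voting; the mean
#' over training studies is reported alongside. All pairwise method
#' comparisons (7 methods + Voting, 28 pairs) use the repeated
#' downsampled binomial test on the pooled consolidated predictions.
#'
#' @param config An [experiment_config()].
#' @param .prep Optional precomputed result of the shared simulate /
#'   select / match / standardize front end (see [prepare_pipeline()]);
#'   lets several experiments on the same configuration reuse it.
#' @return An object of class `internal_result`: `performance` (tibble
#'   `study`, `method`, `sensitivity`, `specificity`, `bacc`, ... with
#'   per-study and `"mean"` rows), `comparisons` (tibble `method_a`,
#'   `method_b`, `median_p`), plus the fitted models, the feature-selection
#'   table and the pool.
#' @export
run_internal <- function(config, .prep = NULL) {
  prep <- .prep %||% prepare_experiment(config)
  labels_all <- integer()
  pred_all <- NULL
  perf <- list()
  fits <- list()

  for (id in prep$train_ids) {
    ts <- prep$studies[[id]]
    committee <- train_committee(ts, config, prep$pool, seed_tag = id)
    fits[[id]] <- committee

    cons <- lapply(committee$models, function(m) {
      apply(m$cv_votes_matrix, 1, consolidate_method_votes)
    })
    vote_tbl <- dplyr::bind_rows(lapply(committee$models, function(m) m$cv_votes))
    voted <- vote_classify(vote_tbl, mode = "internal")
    voted_labels <- voted$label[match(colnames(ts$matrix), voted$sample_id)]

    preds <- c(cons, list(Voting = voted_labels))
    perf[[id]] <- dplyr::bind_rows(lapply(names(preds), function(nm) {
      dplyr::bind_cols(
        tibble(study = id, method = nm),
        performance_summary(unname(ts$outcome), preds[[nm]])
      )
    }))

    labels_all <- c(labels_all, unname(ts$outcome))
    pred_all <- if (is.null(pred_all)) {
      lapply(preds, unname)
    } else {
      purrr::map2(pred_all, preds, function(acc, p) c(acc, unname(p)))
    }
  }

  perf <- dplyr::bind_rows(perf)
  perf <- dplyr::bind_rows(perf, mean_performance_rows(perf))
  comparisons <- all_pair_comparisons(labels_all, pred_all, config)

  structure(
    list(
      performance = perf, comparisons = comparisons,
      fits = fits, meta_rank = prep$meta_rank, pool = prep$pool,
      config = config
    ),
    class = "internal_result"
  )
}

#' External validation of the committee on independent test studies
#'
#' Trains every method (with forward selection) on the designated
#' training study and transfers the entire fitted classifiers — features,
#' hyperparameters and decision rules — to the independent test studies.
#' With `same_platform = FALSE` the standardized training study is first
#' passed through [apply_platform_effect()] with the simulation's
#' distortion SDs, emulating a classifier developed on a different array
#' platform whose residual location/scale mismatch standardization did
#' not remove; with zero distortion SDs the two regimes are identical.
#' The external voting label is the cross-method majority of the seven
#' single votes per sample.
#'
#' @param config An [experiment_config()].
#' @param same_platform `TRUE` for the same-platform regime, `FALSE` to
#'   inject the cross-platform distortion into the training study.
#' @param .prep Optional precomputed front end, as in [run_internal()].
#' @return An object of class `external_result` with per-test-study and
#'   mean `performance` rows, pairwise `comparisons` on the pooled test
#'   samples, the fitted models, and the regime label.
#' @export
run_external <- function(config, same_platform = TRUE, .prep = NULL) {
  prep <- .prep %||% prepare_experiment(config)
  train_id <- prep$train_ids[1]
  train <- prep$studies[[train_id]]
  if (!same_platform) {
    train <- apply_platform_effect(
      train,
      scale_sd = config$simulation$platform_scale_sd,
      shift_sd = config$simulation$platform_shift_sd,
      seed = derive_seed(config$seed, "platform")
    )
  }
  committee <- train_committee(train, config, prep$pool, seed_tag = "ext")

  labels_all <- integer()
  pred_all <- NULL
  perf <- list()
  for (id in prep$test_ids) {
    test <- prep$studies[[id]]
    preds <- lapply(committee$models, function(m) unname(predict(m, test)))
    vote_tbl <- dplyr::bind_rows(purrr::imap(preds, function(p, nm) {
      tibble(sample_id = colnames(test$matrix), method = nm, label = p)
    }))
    voted <- vote_classify(vote_tbl, mode = "external")
    voted_labels <- voted$label[match(colnames(test$matrix), voted$sample_id)]
    preds <- c(preds, list(Voting = voted_labels))

    perf[[id]] <- dplyr::bind_rows(lapply(names(preds), function(nm) {
      dplyr::bind_cols(
        tibble(study = id, method = nm),
        performance_summary(unname(test$outcome), preds[[nm]])
      )
    }))
    labels_all <- c(labels_all, unname(test$outcome))
    pred_all <- if (is.null(pred_all)) {
      preds
    } else {
      purrr::map2(pred_all, preds, c)
    }
  }

  perf <- dplyr::bind_rows(perf)
  perf <- dplyr::bind_rows(perf, mean_performance_rows(perf))
  comparisons <- all_pair_comparisons(labels_all, pred_all, config)

  structure(
    list(
      performance = perf, comparisons = comparisons,
      fits = committee, train_id = train_id,
      regime = if (same_platform) "same-platform" else "cross-platform",
      meta_rank = prep$meta_rank, pool = prep$pool, config = config
    ),
    class = "external_result"
  )
}

#' Run one of the three comparison experiments
#'
#' Dispatches to [run_internal()] or [run_external()] and optionally
#' writes the machine-readable report TSVs (`performance.tsv`,
#' `comparisons.tsv`) to `out_dir`. Reports are byte-identical across
#' runs with the same configuration and master seed.
#'
#' @param config An [experiment_config()].
#' @param experiment `"internal"`, `"external-same"`, or
#'   `"external-cross"`.
#' @param out_dir Optional output directory for the report TSVs.
#' @return The `internal_result` / `external_result`, invisibly when
#'   `out_dir` is given.
#' @export
run_experiment <- function(config,
                           experiment = c("internal", "external-same",
                                          "external-cross"),
                           out_dir = NULL) {
  experiment <- match.arg(experiment)
  result <- switch(experiment,
    "internal" = run_internal(config),
    "external-same" = run_external(config, same_platform = TRUE),
    "external-cross" = run_external(config, same_platform = FALSE)
  )
  if (!is.null(out_dir)) {
    write_experiment_report(result, out_dir)
    return(invisible(result))
  }
  result
}

#' Write an experiment's report tables
#'
#' @param result An `internal_result` or `external_result`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_experiment_report <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(result$performance, file.path(dir, "performance.tsv"))
  readr::write_tsv(result$comparisons, file.path(dir, "comparisons.tsv"))
  invisible(dir)
}

#' @export
print.internal_result <- function(x, ...) {
  cat("<internal_result> 10x10 CV committee comparison\n")
  print(filter(x$performance, .data$study == "mean"))
  invisible(x)
}

#' @export
print.external_result <- function(x, ...) {
  cat(sprintf("<external_result> %s validation (train: %s)\n",
              x$regime, x$train_id))
  print(filter(x$performance, .data$study == "mean"))
  invisible(x)
}
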