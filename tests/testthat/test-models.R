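test_that("hyperparameter grids carry the documented axes", {
  expect_equal(sort(unique(default_grid("RF")$ntree)),
               c(2000, 3000, 4000, 5000))
  expect_equal(nrow(default_grid("RF")), 20)
  expect_equal(sort(unique(default_grid("P-SVM")$degree)), c(2, 3, 4))
  expect_equal(sort(unique(default_grid("R-SVM")$cost)), c(0.01, 0.1, 1, 10))
  expect_equal(sort(unique(default_grid("S-SVM")$gamma)),
               c(0.001, 0.01, 0.1, 1))
  expect_false("gamma" %in% names(default_grid("L-SVM")))
  expect_equal(nrow(default_grid("LR")), 1)
  expect_named(method_set(), c("RF", "LR", "R-SVM", "L-SVM", "P-SVM",
                               "S-SVM", "NNET"))
  expect_error(method_spec("QDA"), "unknown method")
})

test_that("mtry rules resolve as sqrt-multiples clipped to [1, p]", {
  resolve <- crossvote:::resolve_mtry
  expect_equal(resolve("one", 100), 1L)
  expect_equal(resolve("sqrt", 100), 10L)
  expect_equal(resolve("half_sqrt", 100), 5L)
  expect_equal(resolve("twice_sqrt", 100), 20L)
  expect_equal(resolve("all", 100), 100L)
  expect_equal(resolve("twice_sqrt", 2), 2L)  # clipped to p
  expect_equal(resolve("half_sqrt", 1), 1L)   # floored at 1
})

test_that("importance ranking puts a strongly planted gene first", {
  hits <- vapply(1:10, function(seed) {
    s <- signal_study(n = 100, n_genes = 51, informative = 26, effect = 3,
                      seed = 100 + seed)
    ranked <- importance_rank(s, s$gene_ids, seed = seed, ntree = 200)
    ranked[1] == "G26"
  }, logical(1))
  expect_true(all(hits))
  # size-1 pool is returned as-is
  s <- signal_study(seed = 1)
  expect_identical(importance_rank(s, "G05", seed = 1), "G05")
  expect_error(importance_rank(s, c("G01", "nope"), seed = 1), "nope")
})

test_that("cv10x10 gives every sample exactly 10 ordered votes", {
  s <- signal_study(n = 40, n_genes = 6, seed = 7)
  res <- cv10x10(s, method_spec("L-SVM", tibble::tibble(cost = 1)),
                 features = c("G01", "G02"), seed = 3)
  expect_equal(dim(res$votes_matrix), c(40L, 10L))
  expect_false(anyNA(res$votes_matrix))
  counts <- dplyr::count(res$votes, sample_id)
  expect_true(all(counts$n == 10))
  expect_equal(sort(unique(res$votes$cv_repeat)), 1:10)
  expect_equal(res$performance$n_samples, 400)
  # identical seed reproduces identical votes
  res2 <- cv10x10(s, method_spec("L-SVM", tibble::tibble(cost = 1)),
                  features = c("G01", "G02"), seed = 3)
  expect_identical(res$votes_matrix, res2$votes_matrix)
  expect_error(
    cv10x10(signal_study(n = 16), method_spec("LR"), "G01"),
    "20 samples"
  )
})

test_that("cv10x10 separates separable data and is honest on permuted labels", {
  sep <- separable_study(n = 60, seed = 5)
  res <- cv10x10(sep, method_spec("L-SVM", tibble::tibble(cost = 1)),
                 features = c("G01", "G02"), seed = 2)
  expect_gte(res$performance$bacc, 0.95)

  baccs <- vapply(1:5, function(seed) {
    s <- signal_study(n = 60, n_genes = 4, informative = 1:2, effect = 2,
                      seed = 200 + seed)
    s$outcome[] <- withr::with_seed(seed, sample(s$outcome))
    cv10x10(s, method_spec("RF", tibble::tibble(ntree = 200, mtry_rule = "sqrt")),
            features = c("G01", "G02"), seed = seed)$performance$bacc
  }, numeric(1))
  expect_gt(mean(baccs), 0.40)
  expect_lt(mean(baccs), 0.60)
})

test_that("forward selection maximizes CV balanced accuracy over (k, grid)", {
  s <- signal_study(n = 60, n_genes = 8, informative = 1:2, effect = 1.5,
                    seed = 11)
  ms <- method_spec("L-SVM", tibble::tibble(cost = c(0.1, 1)))
  fm <- forward_select(s, ms, ranked_features = s$gene_ids, seed = 4,
                       max_features = 3)
  # argmax dominance over the k = 1, first-grid-point candidate
  base <- fm$search[fm$search$k == 1 & fm$search$grid_row == 1, ]
  expect_gte(fm$cv_performance$bacc, base$bacc)
  expect_identical(fm$features, head(s$gene_ids, length(fm$features)))
  expect_true(length(fm$features) <= 3)
  expect_s3_class(glance(fm), "tbl_df")
  expect_equal(tidy(fm)$term, fm$features)

  fm1 <- forward_select(s, ms, s$gene_ids, seed = 4, max_features = 1)
  expect_length(fm1$features, 1)
  expect_error(forward_select(s, ms, character(), seed = 1), "nonempty")
})

test_that("forward selection recovers a small informative feature set", {
  ok_k <- logical(5); ok_feats <- logical(5)
  for (i in 1:5) {
    s <- signal_study(n = 200, n_genes = 20, informative = 1:2, effect = 1.5,
                      seed = 300 + i)
    ranked <- importance_rank(s, s$gene_ids, seed = i, ntree = 300)
    fm <- forward_select(s, method_spec("L-SVM", tibble::tibble(cost = 1)),
                         ranked, seed = i, max_features = 8)
    ok_k[i] <- length(fm$features) <= 8
    ok_feats[i] <- all(c("G01", "G02") %in% fm$features)
  }
  expect_true(all(ok_k))
  expect_true(all(ok_feats))
})

test_that("fitted models predict deterministically and transfer sanely", {
  s <- signal_study(n = 80, n_genes = 10, informative = 1:2, effect = 2,
                    seed = 21)
  ranked <- importance_rank(s, s$gene_ids, seed = 2, ntree = 300)
  fm <- forward_select(
    s, method_spec("RF", tibble::tibble(ntree = 300, mtry_rule = "sqrt")),
    ranked, seed = 2, max_features = 3
  )
  # resubstitution optimism: training-set bAcc >= cv bAcc
  resub <- performance_summary(s$outcome, predict(fm, s))
  expect_gte(resub$bacc, fm$cv_performance$bacc - 1e-9)
  # identical copy of the training study -> identical labels
  expect_identical(predict(fm, s), predict(fm, s))
  # permuted-label test study scores near chance
  null_test <- signal_study(n = 200, n_genes = 10, informative = 1:2,
                            effect = 2, seed = 22, id = "nulltest")
  null_test$outcome[] <- withr::with_seed(9, sample(null_test$outcome))
  perf <- performance_summary(null_test$outcome, predict(fm, null_test))
  expect_gt(perf$bacc, 0.35)
  expect_lt(perf$bacc, 0.65)
  # missing feature is named in the error
  small <- null_test
  small$matrix <- small$matrix[-match(fm$features[1], small$gene_ids), ]
  small$gene_ids <- rownames(small$matrix)
  expect_error(predict(fm, small), fm$features[1], fixed = TRUE)
})

test_that("whole-data ranking inflates CV accuracy relative to within-fold ranking", {
  diffs <- vapply(1:10, function(i) {
    s <- signal_study(n = 50, n_genes = 12, informative = 1:2, effect = 1,
                      seed = 400 + i)
    ranked <- importance_rank(s, s$gene_ids, seed = i, ntree = 150)
    ms <- method_spec("L-SVM", tibble::tibble(cost = 1))
    prerank <- forward_select(s, ms, ranked, seed = i, max_features = 3,
                              mode = "prerank")
    nested <- forward_select(s, ms, ranked, seed = i, max_features = 3,
                             mode = "nested", pool = s$gene_ids,
                             rank_ntree = 150)
    prerank$cv_performance$bacc - nested$cv_performance$bacc
  }, numeric(1))
  expect_gte(mean(diffs), 0)
})
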