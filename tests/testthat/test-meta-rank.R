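test_that("signal_to_noise matches hand computations and is antisymmetric", {
  expect_equal(signal_to_noise(c(5, 5, 5), c(5, 5, 5)), 0)
  expect_equal(signal_to_noise(c(1, 3), c(-1, 1)),
               2 / (sd(c(1, 3)) + sd(c(-1, 1))), tolerance = 1e-12)
  expect_equal(signal_to_noise(c(1, 3), c(-1, 1)), 0.7071, tolerance = 1e-4)
  withr::with_seed(4, {
    for (i in 1:20) {
      a <- rnorm(sample(2:8, 1))
      b <- rnorm(sample(2:8, 1))
      expect_equal(signal_to_noise(a, b), -signal_to_noise(b, a),
                   tolerance = 1e-12)
    }
  })
  expect_error(signal_to_noise(1, c(1, 2)), "class")
})

test_that("within-study ranking orders by signed statistic with deterministic ties", {
  # three genes engineered to have s2n ordered G1 > G3 > G2
  m <- rbind(
    c(4, 6, -5, -5),   # strongly up
    c(-4, -6, 5, 5),   # strongly down
    c(1, 2, -1, 0)     # mildly up
  )
  s <- toy_study(m, c(1L, 1L, 0L, 0L))
  tab <- rank_within_study(s)
  expect_equal(tab$rank, c(1L, 3L, 2L))
  expect_equal(tab$norm_rank, c(0.25, 0.75, 0.5))

  # identical rows: all statistics tie; ranks are still a permutation,
  # assigned by lexicographic gene id
  m2 <- matrix(rep(c(1, 2, 3, 4), each = 3), 3, 4, byrow = FALSE)
  s2 <- toy_study(m2, c(1L, 1L, 0L, 0L))
  tab2 <- rank_within_study(s2)
  expect_setequal(tab2$rank, 1:3)
  expect_equal(tab2$rank, rank(tab2$gene_id))

  # single-class study is an input error
  expect_error(rank_within_study(toy_study(m, c(1L, 1L, 1L, 1L))), "class")
})

test_that("a large enough boost to one gene strictly improves its rank", {
  s <- signal_study(n = 30, n_genes = 10, informative = integer(), seed = 6)
  before <- rank_within_study(s)
  boosted <- s
  boosted$matrix["G07", s$outcome == 1L] <-
    boosted$matrix["G07", s$outcome == 1L] + 10
  after <- rank_within_study(boosted)
  expect_lt(after$rank[after$gene_id == "G07"],
            before$rank[before$gene_id == "G07"])
  expect_equal(after$rank[after$gene_id == "G07"], 1L)
})

test_that("mean_rank averages normalized ranks and filters by study count", {
  t1 <- tibble::tibble(study_id = "a", gene_id = c("A", "B"),
                       s2n = c(1, -1), rank = c(1L, 2L),
                       norm_rank = c(0.25, 0.75))
  t2 <- tibble::tibble(study_id = "b", gene_id = c("A", "C"),
                       s2n = c(2, 0), rank = c(1L, 2L),
                       norm_rank = c(0.75, 0.25))
  mr <- mean_rank(list(t1, t2), min_studies = 1)
  expect_equal(mr$mean_normalized_rank[mr$gene_id == "A"], 0.5)
  mr2 <- mean_rank(list(t1, t2), min_studies = 2)
  expect_identical(mr2$gene_id, "A")
  expect_error(mean_rank(list(t1)), ">= 2")
})

test_that("a gene ranked first everywhere attains the minimum mean rank", {
  studies <- lapply(1:3, function(i) {
    signal_study(n = 30, n_genes = 8, informative = 1, effect = 10,
                 seed = i, id = paste0("s", i))
  })
  tabs <- lapply(studies, rank_within_study)
  mr <- mean_rank(tabs)
  expect_equal(min(mr$mean_normalized_rank),
               mr$mean_normalized_rank[mr$gene_id == "G01"])
  expect_equal(mr$mean_normalized_rank[mr$gene_id == "G01"], 1 / 9)
})

test_that("exact permutation p-values match an independent brute-force oracle", {
  # 2 studies x 4 samples (2 per class): 6 * 6 = 36 label assignments
  studies <- lapply(1:2, function(i) {
    withr::with_seed(20 + i, {
      toy_study(matrix(rnorm(5 * 4), 5, 4), c(1L, 1L, 0L, 0L),
                id = paste0("s", i))
    })
  })
  res <- meta_rank_significance(studies, n_permutations = 100, seed = 1,
                                exact = "always")

  # oracle: direct enumeration with scalar signal_to_noise and base rank()
  genes <- sprintf("G%02d", 1:5)
  norm_ranks_for <- function(study, pos_idx) {
    s2n <- vapply(seq_len(5), function(g) {
      signal_to_noise(study$matrix[g, pos_idx],
                      study$matrix[g, setdiff(1:4, pos_idx)])
    }, numeric(1))
    ord <- order(-s2n, genes)
    r <- integer(5); r[ord] <- 1:5
    r / 6
  }
  combos <- combn(4, 2, simplify = FALSE)
  all_mr <- do.call(cbind, lapply(combos, function(c1) {
    sapply(combos, function(c2) {
      (norm_ranks_for(studies[[1]], c1) + norm_ranks_for(studies[[2]], c2)) / 2
    })
  }))  # 5 genes x 36 label assignments
  obs <- (norm_ranks_for(studies[[1]], 1:2) +
            norm_ranks_for(studies[[2]], 1:2)) / 2
  p_oracle <- vapply(1:5, function(g) {
    mean(abs(all_mr[g, ] - 0.5) >= abs(obs[g] - 0.5))
  }, numeric(1))

  expect_equal(res$p_value[match(genes, res$gene_id)], p_oracle,
               tolerance = 1e-12)
  expect_equal(res$mean_normalized_rank[match(genes, res$gene_id)], obs,
               tolerance = 1e-12)

  # q-values equal a hand-rolled Benjamini-Hochberg step-up
  p <- res$p_value
  m <- length(p)
  o <- order(p)
  q_hand <- numeric(m)
  q_hand[o] <- rev(cummin(rev(p[o] * m / seq_len(m))))
  expect_equal(res$q_value, pmin(q_hand, 1), tolerance = 1e-12)
})

test_that("permutation mode is deterministic given a seed and plus-one corrected", {
  studies <- lapply(1:2, function(i) {
    signal_study(n = 24, n_genes = 12, informative = 1:2, effect = 2,
                 seed = 30 + i, id = paste0("s", i))
  })
  r1 <- meta_rank_significance(studies, n_permutations = 150, seed = 5,
                               exact = "never")
  r2 <- meta_rank_significance(studies, n_permutations = 150, seed = 5,
                               exact = "never")
  expect_identical(r1, r2)
  expect_true(all(r1$p_value >= 1 / 151))
  expect_true(all(r1$p_value <= 1))
  expect_error(
    meta_rank_significance(studies, n_permutations = 50),
    "n_permutations"
  )
})

test_that("intersect_pool keeps order and drops genes absent from any study", {
  s1 <- toy_study(matrix(0, 2, 4,
                         dimnames = list(c("A", "B"), sprintf("S%d", 1:4))),
                  c(1L, 1L, 0L, 0L))
  s2 <- toy_study(matrix(0, 3, 4,
                         dimnames = list(c("A", "B", "C"), sprintf("S%d", 1:4))),
                  c(1L, 1L, 0L, 0L))
  expect_identical(intersect_pool(c("C", "A", "B"), list(s1, s2)), c("A", "B"))
  expect_identical(intersect_pool(character(), list(s1, s2)), character())
})
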