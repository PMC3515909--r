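# Shared fixture builders. Everything is generated in code at test time.

# A small expression study with explicit values.
toy_study <- function(mat, outcome, id = "toy", platform = "P1",
                      role = "train", validate = TRUE) {
  if (is.null(rownames(mat))) {
    rownames(mat) <- sprintf("G%02d", seq_len(nrow(mat)))
  }
  if (is.null(colnames(mat))) {
    colnames(mat) <- sprintf("S%02d", seq_len(ncol(mat)))
  }
  expression_study(id, platform, mat, outcome, role = role,
                   validate = validate)
}

# Two-gene linearly separable study: gene G01 separates the classes.
separable_study <- function(n = 60, gap = 6, seed = 1) {
  withr::with_seed(seed, {
    n_pos <- n / 2
    m <- rbind(
      c(rnorm(n_pos, gap / 2, 0.5), rnorm(n - n_pos, -gap / 2, 0.5)),
      rnorm(n, 0, 1)
    )
    toy_study(m, c(rep(1L, n_pos), rep(0L, n - n_pos)), id = "sep")
  })
}

# Study with planted informative genes among nulls (standardized scale).
signal_study <- function(n = 60, n_genes = 20, informative = 1:2,
                         effect = 2, frac_pos = 0.3, seed = 1,
                         id = "sig") {
  withr::with_seed(seed, {
    n_pos <- round(frac_pos * n)
    outcome <- c(rep(1L, n_pos), rep(0L, n - n_pos))
    m <- matrix(rnorm(n_genes * n), n_genes, n)
    m[informative, outcome == 1L] <- m[informative, outcome == 1L] + effect
    toy_study(m, outcome, id = id)
  })
}

# One-row-per-method external vote table for vote_classify().
external_vote_table <- function(label_matrix, sample_ids = NULL) {
  methods <- c("RF", "LR", "R-SVM", "L-SVM", "P-SVM", "S-SVM", "NNET")
  stopifnot(ncol(label_matrix) == 7)
  sample_ids <- sample_ids %||% sprintf("S%02d", seq_len(nrow(label_matrix)))
  tibble::tibble(
    sample_id = rep(sample_ids, 7),
    method = rep(methods, each = nrow(label_matrix)),
    label = as.integer(label_matrix[cbind(
      rep(seq_len(nrow(label_matrix)), 7),
      rep(seq_len(7), each = nrow(label_matrix))
    )])
  )
}

`%||%` <- rlang::`%||%`
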