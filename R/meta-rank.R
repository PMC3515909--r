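#' Signal-to-noise ratio of one gene between two classes
#'
#' The per-gene class-separation statistic
#' `(mean1 - mean0) / (sd1 + sd0)`, with sample (n-1) standard deviations
#' and the denominator floored at `1e-8` to guard degenerate genes. The
#' sign carries direction: positive means higher in the metastasis class.
#'
#' @param values_class1 Numeric values in the metastasis class (>= 2).
#' @param values_class0 Numeric values in the non-metastasis class (>= 2).
#' @return A single number.
#' @export
signal_to_noise <- function(values_class1, values_class0) {
  if (length(values_class1) < 2 || length(values_class0) < 2) {
    abort_input("each class needs >= 2 values for a signal-to-noise ratio")
  }
  (mean(values_class1) - mean(values_class0)) /
    max(sd(values_class1) + sd(values_class0), 1e-8)
}

# Vectorized signal-to-noise over the rows of a genes x samples matrix.
s2n_rows <- function(mat, pos) {
  x1 <- mat[, pos, drop = FALSE]
  x0 <- mat[, !pos, drop = FALSE]
  m1 <- rowMeans(x1)
  m0 <- rowMeans(x0)
  s1 <- sqrt(pmax(rowSums((x1 - m1)^2) / (ncol(x1) - 1), 0))
  s0 <- sqrt(pmax(rowSums((x0 - m0)^2) / (ncol(x0) - 1), 0))
  (m1 - m0) / pmax(s1 + s0, 1e-8)
}

# Within-study ranks: 1 = most positive statistic; ties broken by
# lexicographic gene id (radix order, locale-independent).
norm_rank_vec <- function(s2n, gene_ids) {
  ord <- order(-s2n, gene_ids, method = "radix")
  r <- integer(length(s2n))
  r[ord] <- seq_along(s2n)
  list(rank = r, norm = r / (length(s2n) + 1))
}

#' Rank all genes of a study by signal-to-noise ratio
#'
#' Rank 1 is the largest signed statistic (most metastasis-up gene);
#' normalized rank is `rank / (n_genes + 1)`, strictly inside (0, 1) so
#' ranks are comparable across platforms with different gene counts.
#'
#' @param study An [expression_study()] with both outcome classes present.
#' @return A tibble with columns `study_id`, `gene_id`, `s2n`, `rank`,
#'   `norm_rank`.
#' @export
rank_within_study <- function(study) {
  check_two_classes(study)
  s2n <- s2n_rows(study$matrix, study$outcome == 1L)
  nr <- norm_rank_vec(s2n, study$gene_ids)
  tibble(
    study_id = study$study_id,
    gene_id = study$gene_ids,
    s2n = unname(s2n),
    rank = nr$rank,
    norm_rank = nr$norm
  )
}

#' Mean normalized rank across studies
#'
#' Averages each gene's normalized signal-to-noise rank over the studies
#' containing it; genes present in fewer than `min_studies` studies are
#' dropped.
#'
#' @param tables List of rank tables from [rank_within_study()].
#' @param min_studies Minimum number of studies a gene must appear in
#'   (default: all supplied studies).
#' @return A tibble with `gene_id`, `n_studies`, `mean_normalized_rank`.
#' @export
mean_rank <- function(tables, min_studies = NULL) {
  if (length(tables) < 2) abort_input("need rank tables from >= 2 studies")
  min_studies <- min_studies %||% length(tables)
  dplyr::bind_rows(tables) |>
    group_by(.data$gene_id) |>
    summarise(
      n_studies = n(),
      mean_normalized_rank = mean(.data$norm_rank),
      .groups = "drop"
    ) |>
    filter(.data$n_studies >= min_studies)
}

#' Cross-study rank-based feature selection with permutation significance
#'
#' Ranks every gene within every study by signal-to-noise ratio, averages
#' the normalized ranks across the studies containing the gene, and tests
#' whether each mean rank is significantly high or low (two-sided) against
#' a permutation null in which outcome labels are permuted independently
#' within each study and all statistics re-ranked. P-values are converted
#' to Benjamini-Hochberg q-values; `selected` flags genes at
#' `q <= fdr_threshold`.
#'
#' When the number of distinct within-study label assignments is small
#' (product over studies of `choose(n, n_pos)` at most `exact_limit`),
#' the null is enumerated exhaustively and p-values are exact fractions;
#' otherwise `n_permutations` random permutations are drawn and p-values
#' carry the usual plus-one correction.
#'
#' @param studies List of [expression_study()] objects (>= 2), each with
#'   both classes present.
#' @param min_studies Minimum studies a gene must appear in (default all).
#' @param n_permutations Number of random permutations (>= 100).
#' @param seed Integer seed for the permutation draws.
#' @param fdr_threshold FDR significance cutoff (default 0.05).
#' @param exact `"auto"` (default), `"never"`, or `"always"` exhaustive
#'   enumeration of the label-assignment null.
#' @param exact_limit Enumeration cap for `exact = "auto"`.
#'
#' @return A tibble with one row per retained gene: `gene_id`,
#'   `n_studies`, `mean_normalized_rank`, `p_value`, `q_value`,
#'   `selected`, ordered by decreasing rank extremity.
#' @export
meta_rank_significance <- function(studies,
                                   min_studies = length(studies),
                                   n_permutations = 1000,
                                   seed = 1,
                                   fdr_threshold = 0.05,
                                   exact = c("auto", "never", "always"),
                                   exact_limit = 5000) {
  exact <- match.arg(exact)
  if (length(studies) < 2) abort_input("need >= 2 studies")
  if (n_permutations < 100) {
    abort_config("`n_permutations` must be >= 100")
  }
  lapply(studies, check_two_classes)

  mats <- lapply(studies, function(s) s$matrix)
  ids <- lapply(studies, function(s) s$gene_ids)
  n_pos <- vapply(studies, function(s) sum(s$outcome == 1L), integer(1))
  n_smp <- vapply(studies, n_samples, integer(1))
  all_genes <- sort(unique(unlist(ids)), method = "radix")
  idx <- lapply(ids, match, table = all_genes)
  presence <- integer(length(all_genes))
  for (i in idx) presence[i] <- presence[i] + 1L

  nr_matrix <- function(pos_sets) {
    nr <- matrix(NA_real_, length(all_genes), length(studies))
    for (s in seq_along(studies)) {
      stat <- s2n_rows(mats[[s]], pos_sets[[s]])
      nr[idx[[s]], s] <- norm_rank_vec(stat, ids[[s]])$norm
    }
    rowMeans(nr, na.rm = TRUE)
  }

  obs_pos <- lapply(studies, function(s) s$outcome == 1L)
  obs_mr <- nr_matrix(obs_pos)
  obs_dev <- abs(obs_mr - 0.5)

  n_assign <- vapply(
    seq_along(studies),
    function(s) choose(n_smp[s], n_pos[s]), numeric(1)
  )
  total <- prod(n_assign)
  use_exact <- exact == "always" ||
    (exact == "auto" && is.finite(total) && total <= exact_limit)

  if (use_exact) {
    combos <- lapply(seq_along(studies), function(s) {
      combn(n_smp[s], n_pos[s])
    })
    grid <- do.call(
      expand.grid,
      lapply(combos, function(cm) seq_len(ncol(cm)))
    )
    cnt <- numeric(length(all_genes))
    for (r in seq_len(nrow(grid))) {
      pos_sets <- lapply(seq_along(studies), function(s) {
        pos <- logical(n_smp[s])
        pos[combos[[s]][, grid[r, s]]] <- TRUE
        pos
      })
      mr <- nr_matrix(pos_sets)
      cnt <- cnt + (abs(mr - 0.5) >= obs_dev)
    }
    p <- cnt / nrow(grid)
  } else {
    cnt <- numeric(length(all_genes))
    withr::with_seed(as.integer(seed), {
      for (b in seq_len(n_permutations)) {
        pos_sets <- lapply(seq_along(studies), function(s) {
          pos <- logical(n_smp[s])
          pos[sample.int(n_smp[s], n_pos[s])] <- TRUE
          pos
        })
        mr <- nr_matrix(pos_sets)
        cnt <- cnt + (abs(mr - 0.5) >= obs_dev)
      }
    })
    p <- (1 + cnt) / (n_permutations + 1)
  }

  keep <- presence >= min_studies
  res <- tibble(
    gene_id = all_genes[keep],
    n_studies = presence[keep],
    mean_normalized_rank = obs_mr[keep],
    p_value = p[keep]
  ) |>
    mutate(
      q_value = p.adjust(.data$p_value, method = "BH"),
      selected = .data$q_value <= fdr_threshold
    ) |>
    arrange(desc(abs(.data$mean_normalized_rank - 0.5)), .data$gene_id)
  res
}

#' Intersect selected genes with the gene sets of further studies
#'
#' Returns the selected genes present in *every* study passed in (the
#' training and testing sets), preserving the order of `selected_genes`.
#'
#' @param selected_genes Character vector of gene symbols.
#' @param studies List of [expression_study()] objects.
#' @return Character vector, a subset of `selected_genes`.
#' @export
intersect_pool <- function(selected_genes, studies) {
  if (length(selected_genes) == 0) {
    return(character())
  }
  common <- Reduce(intersect, lapply(studies, function(s) s$gene_ids))
  selected_genes[selected_genes %in% common]
}
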