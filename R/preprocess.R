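#' Standardize a study gene-wise
#'
#' Rescales every gene (row) to mean zero and standard deviation one across
#' the study's samples, using the study's own statistics. Constant genes
#' map to all-zero rows. Standardization is computed independently per
#' dataset: test sets are standardized with their own means and SDs, never
#' the training set's.
#'
#' @param study An [expression_study()].
#' @return The standardized `expression_study`.
#' @export
standardize_study <- function(study) {
  if (n_samples(study) < 2) {
    abort_input("standardization needs >= 2 samples")
  }
  m <- study$matrix
  mu <- rowMeans(m)
  centered <- m - mu
  s <- sqrt(rowSums(centered^2) / (ncol(m) - 1))
  constant <- s < 1e-12
  s[constant] <- 1
  z <- centered / s
  z[constant, ] <- 0
  study$matrix <- z
  study
}

# Collapse duplicate gene symbols within a study, keeping per symbol the
# row with the highest variance (common microarray probe-collapse rule).
collapse_duplicates <- function(study) {
  ids <- rownames(study$matrix)
  if (!anyDuplicated(ids)) {
    return(study)
  }
  v <- apply(study$matrix, 1, stats::var)
  keep <- unsplit(
    lapply(split(seq_along(ids), ids), function(ix) ix == ix[which.max(v[ix])]),
    ids
  )
  study$matrix <- study$matrix[keep, , drop = FALSE]
  study$gene_ids <- rownames(study$matrix)
  study
}

#' Restrict studies to a common, identically ordered gene set
#'
#' Restricts every study to `pool` intersected with the genes present in
#' all studies, in the order of `pool`. Duplicate symbols within a study
#' are first collapsed to the highest-variance row.
#'
#' @param studies List of [expression_study()] objects.
#' @param pool Character vector of candidate gene symbols (e.g. the
#'   rank-significant genes from [meta_rank_significance()]).
#' @return An object of class `gene_matched_set`: list with
#'   `common_gene_ids` and `studies` (row-reordered to the common set).
#' @export
match_genes <- function(studies, pool) {
  if (length(pool) == 0) abort_input("`pool` must be nonempty")
  studies <- lapply(studies, collapse_duplicates)
  common <- Reduce(intersect, lapply(studies, function(s) s$gene_ids))
  ids <- pool[pool %in% common]
  if (length(ids) == 0) {
    abort_input(paste(
      "no pool gene is present in every study;",
      "supply a larger candidate pool or fewer studies"
    ))
  }
  studies <- lapply(studies, function(s) {
    s$matrix <- s$matrix[ids, , drop = FALSE]
    s$gene_ids <- ids
    s
  })
  structure(
    list(common_gene_ids = ids, studies = studies),
    class = "gene_matched_set"
  )
}

#' @export
print.gene_matched_set <- function(x, ...) {
  cat(sprintf(
    "<gene_matched_set> %d common genes across %d studies\n",
    length(x$common_gene_ids), length(x$studies)
  ))
  invisible(x)
}
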