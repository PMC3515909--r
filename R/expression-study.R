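#' Construct an expression study
#'
#' An `expression_study` bundles one study's genes-by-samples log-scale
#' expression matrix with a binary outcome label per sample (1 = metastasis,
#' 0 = no metastasis), a platform tag, and a pipeline role.
#'
#' @param study_id Single string identifying the study.
#' @param platform Single string naming the (real or simulated) array
#'   platform; studies on the same platform share a gene set and, in the
#'   simulator, per-gene distortion parameters.
#' @param matrix Numeric matrix, genes in rows (rownames = gene symbols,
#'   unique unless `validate = FALSE`), samples in columns (colnames =
#'   sample ids).
#' @param outcome Integer/numeric vector of 0/1 labels, one per column of
#'   `matrix`, no missing values.
#' @param role One of `"feature_definer"`, `"train"`, `"test"`; how the
#'   study is used by [run_internal()]/[run_external()].
#' @param validate Set `FALSE` to skip invariant checks (used internally,
#'   e.g. to represent duplicate-probe studies before [match_genes()]
#'   collapses them).
#'
#' @return An object of class `expression_study`.
#' @seealso [simulate_multistudy()], [standardize_study()], [match_genes()]
#' @export
expression_study <- function(study_id, platform, matrix, outcome,
                             role = c("feature_definer", "train", "test"),
                             validate = TRUE) {
  role <- match.arg(role)
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    abort_input("`matrix` must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    abort_input("`matrix` needs rownames (gene ids) and colnames (sample ids)")
  }
  outcome <- as.integer(outcome)
  if (validate) {
    if (anyDuplicated(rownames(matrix))) {
      abort_input(sprintf("duplicate gene ids in study '%s'", study_id))
    }
    if (length(outcome) != ncol(matrix) || anyNA(outcome) ||
        !all(outcome %in% c(0L, 1L))) {
      abort_input("`outcome` must be 0/1, one label per sample, no NAs")
    }
  }
  names(outcome) <- colnames(matrix)
  structure(
    list(
      study_id = as.character(study_id),
      platform = as.character(platform),
      gene_ids = rownames(matrix),
      matrix = matrix,
      outcome = outcome,
      role = role
    ),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf(
    "<expression_study> %s [%s, %s]: %d genes x %d samples (%d metastasis)\n",
    x$study_id, x$platform, x$role, nrow(x$matrix), ncol(x$matrix),
    sum(x$outcome)
  ))
  invisible(x)
}

n_genes <- function(study) nrow(study$matrix)
n_samples <- function(study) ncol(study$matrix)

check_two_classes <- function(study) {
  tab <- table(factor(study$outcome, levels = c(0L, 1L)))
  if (any(tab < 2)) {
    abort_input(sprintf(
      "study '%s' needs >= 2 samples in each outcome class (got %d/%d)",
      study$study_id, tab[["0"]], tab[["1"]]
    ))
  }
  invisible(study)
}
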