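#' Write a study collection to a directory of TSV files
#'
#' One expression TSV per study (first column `gene_id`, remaining columns
#' samples), one phenotype TSV per study (`sample_id`, `outcome`), a
#' `manifest.tsv` listing study ids, platforms, roles and file names, and
#' `truth_genes.txt` with the planted gene symbols when writing a
#' [simulate_multistudy()] result. Output is byte-stable: rewriting the
#' same object gives identical files.
#'
#' @param x A `multistudy_sim` or a list of [expression_study()] objects.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_studies <- function(x, dir) {
  studies <- if (inherits(x, "multistudy_sim")) x$studies else x
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- purrr::map(studies, function(s) {
    expr_file <- paste0(s$study_id, "_expr.tsv")
    pheno_file <- paste0(s$study_id, "_pheno.tsv")
    expr <- tibble::as_tibble(s$matrix, rownames = "gene_id")
    readr::write_tsv(expr, file.path(dir, expr_file))
    readr::write_tsv(
      tibble(sample_id = colnames(s$matrix), outcome = s$outcome),
      file.path(dir, pheno_file)
    )
    tibble(
      study_id = s$study_id, platform = s$platform, role = s$role,
      expr_file = expr_file, pheno_file = pheno_file
    )
  }) |> dplyr::bind_rows()
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  if (inherits(x, "multistudy_sim")) {
    writeLines(x$planted_genes, file.path(dir, "truth_genes.txt"))
  }
  invisible(dir)
}

#' Read a study collection written by [write_studies()]
#'
#' @param dir Directory containing `manifest.tsv`.
#' @return A list with `studies` (list of [expression_study()]) and
#'   `planted_genes` (character vector, empty if no `truth_genes.txt`).
#' @export
read_studies <- function(dir) {
  manifest_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(manifest_path)) {
    abort_input(sprintf("no manifest.tsv under '%s'", dir))
  }
  manifest <- readr::read_tsv(manifest_path, show_col_types = FALSE)
  studies <- purrr::pmap(manifest, function(study_id, platform, role,
                                            expr_file, pheno_file) {
    expr <- readr::read_tsv(file.path(dir, expr_file), show_col_types = FALSE)
    m <- as.matrix(expr[, -1, drop = FALSE])
    rownames(m) <- expr$gene_id
    pheno <- readr::read_tsv(file.path(dir, pheno_file), show_col_types = FALSE)
    m <- m[, pheno$sample_id, drop = FALSE]
    expression_study(study_id, platform, m, pheno$outcome, role = role)
  })
  truth_path <- file.path(dir, "truth_genes.txt")
  planted <- if (file.exists(truth_path)) readLines(truth_path) else character()
  list(studies = studies, planted_genes = planted)
}
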