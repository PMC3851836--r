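#' Parallel miRNA/mRNA expression datasets
#'
#' A parallel dataset consists of two expression matrices measured over the
#' same ordered set of experimental conditions: one with miRNA rows and one
#' with mRNA (gene) rows. TFs are protein-coding genes, so their transcript
#' profiles live in the mRNA matrix.
#'
#' @param mirna_matrix Numeric matrix, rows = miRNA identifiers (rownames),
#'   columns = conditions (colnames). Row names are consolidated to root
#'   form on construction.
#' @param mrna_matrix Numeric matrix, rows = gene symbols, columns =
#'   conditions. Column names must equal those of `mirna_matrix`, in order.
#' @return An object of class `parallel_dataset`: list with `$mirna`,
#'   `$mrna` and `$conditions`.
#' @export
parallel_dataset <- function(mirna_matrix, mrna_matrix) {
  for (nm in c("mirna_matrix", "mrna_matrix")) {
    m <- get(nm)
    if (!is.matrix(m) || !is.numeric(m) || is.null(rownames(m)) || is.null(colnames(m))) {
      abort(sprintf("`%s` must be a numeric matrix with row and column names.", nm))
    }
  }
  if (!identical(colnames(mirna_matrix), colnames(mrna_matrix))) {
    abort("The miRNA and mRNA matrices must share identical ordered condition columns.")
  }
  if (ncol(mrna_matrix) < 3) abort("At least 3 conditions are required.")
  rownames(mirna_matrix) <- consolidate_mirna_name(rownames(mirna_matrix))
  if (anyDuplicated(rownames(mirna_matrix))) {
    dup <- rownames(mirna_matrix)[duplicated(rownames(mirna_matrix))][1]
    abort(sprintf("Duplicate miRNA row after root-form consolidation: '%s'. Aggregate duplicate rows before loading.", dup))
  }
  if (anyDuplicated(rownames(mrna_matrix))) {
    abort("Duplicate gene rows in the mRNA matrix.")
  }
  both <- intersect(rownames(mirna_matrix), rownames(mrna_matrix))
  if (length(both) > 0) {
    abort(sprintf("Identifier(s) present in both matrices: %s.",
                  paste(utils::head(both, 5), collapse = ", ")))
  }
  structure(
    list(mirna = mirna_matrix, mrna = mrna_matrix,
         conditions = colnames(mrna_matrix)),
    class = "parallel_dataset"
  )
}

#' Read a parallel miRNA/mRNA dataset from two delimited matrices
#'
#' Each file holds one matrix: a header row of condition labels, then one
#' row per molecule with the identifier in the first column. The delimiter
#' is chosen by extension (`.csv` comma, otherwise tab). The two header
#' rows must be strictly identical.
#'
#' @param mirna_path,mrna_path Paths to the miRNA and mRNA matrix files.
#' @return A [parallel_dataset].
#' @export
read_parallel_dataset <- function(mirna_path, mrna_path) {
  parallel_dataset(read_expr_matrix(mirna_path), read_expr_matrix(mrna_path))
}

read_expr_matrix <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: '%s'.", path))
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) readr::read_csv else readr::read_tsv
  tab <- reader(path, show_col_types = FALSE, progress = FALSE,
                name_repair = "minimal")
  if (ncol(tab) < 2) abort(sprintf("'%s' must have an identifier column plus condition columns.", basename(path)))
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) abort(sprintf("Non-numeric expression values in '%s'.", basename(path)))
  rownames(m) <- ids
  m
}

#' Write a parallel dataset as two tab-separated matrices
#'
#' @param dataset A [parallel_dataset].
#' @param mirna_path,mrna_path Output paths.
#' @return The two paths, invisibly.
#' @export
write_parallel_dataset <- function(dataset, mirna_path, mrna_path) {
  stopifnot(inherits(dataset, "parallel_dataset"))
  write_expr_matrix(dataset$mirna, mirna_path)
  write_expr_matrix(dataset$mrna, mrna_path)
  invisible(c(mirna_path, mrna_path))
}

write_expr_matrix <- function(m, path) {
  tab <- tibble::as_tibble(m, rownames = "id")
  readr::write_tsv(tab, path)
}

#' @export
print.parallel_dataset <- function(x, ...) {
  cat(sprintf("<parallel_dataset: %d miRNAs x %d conditions; %d mRNAs x %d conditions>\n",
              nrow(x$mirna), ncol(x$mirna), nrow(x$mrna), ncol(x$mrna)))
  invisible(x)
}
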