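#' miRNA-perturbed gene expression (MPGE) datasets
#'
#' An MPGE experiment transfects one miRNA into a cell line and compares
#' mRNA levels after versus before transfection, giving one expression
#' log-ratio per gene. Negative log-ratios of the miRNA's putative targets
#' are the footprint of target degradation.
#'
#' @param mirna Identifier of the perturbed miRNA (consolidated to root
#'   form on construction).
#' @param ratios Either a named numeric vector (names = gene symbols) or a
#'   data frame whose first two columns are gene symbol and log-ratio.
#' @return An object of class `mpge_dataset`: list with `$mirna` and
#'   `$ratios`, a tibble with columns `gene` and `log_ratio`.
#' @export
mpge_dataset <- function(mirna, ratios) {
  if (!is.character(mirna) || length(mirna) != 1 || is.na(mirna) || mirna == "") {
    abort("`mirna` must be a single non-empty miRNA identifier.")
  }
  if (is.numeric(ratios) && !is.null(names(ratios))) {
    ratios <- tibble::tibble(gene = names(ratios), log_ratio = unname(ratios))
  } else if (is.data.frame(ratios)) {
    ratios <- tibble::tibble(gene = as.character(ratios[[1]]),
                             log_ratio = as.numeric(ratios[[2]]))
  } else {
    abort("`ratios` must be a named numeric vector or a data frame.")
  }
  if (nrow(ratios) < 2 || dplyr::n_distinct(ratios$gene) < 2) {
    abort("An MPGE dataset needs at least 2 distinct genes.")
  }
  dup <- unique(ratios$gene[duplicated(ratios$gene)])
  if (length(dup) > 0) {
    abort(sprintf("Duplicate gene symbol(s): %s.",
                  paste(utils::head(dup, 5), collapse = ", ")))
  }
  if (any(!is.finite(ratios$log_ratio))) {
    abort("All expression log-ratios must be finite.")
  }
  structure(list(mirna = consolidate_mirna_name(mirna), ratios = ratios),
            class = "mpge_dataset")
}

#' Read an MPGE dataset from a CSV file
#'
#' The expected layout: the first line describes the columns; every other
#' line holds a gene symbol and an expression log-ratio in the first and
#' second column, separated by a comma.
#'
#' @param path Path to the CSV file.
#' @param mirna Identifier of the perturbed miRNA.
#' @return An [mpge_dataset].
#' @export
read_mpge <- function(path, mirna) {
  if (!file.exists(path)) abort(sprintf("File not found: '%s'.", path))
  tab <- tryCatch(
    suppressWarnings(readr::read_csv(path, col_types = readr::cols(
      readr::col_character(), readr::col_double(), .default = readr::col_skip()
    ), progress = FALSE)),
    error = function(e) abort(sprintf("Malformed MPGE CSV '%s': %s",
                                      basename(path), conditionMessage(e)))
  )
  probs <- readr::problems(tab)
  if (nrow(probs) > 0) {
    abort(sprintf("Malformed MPGE CSV '%s' at line %d: expected %s.",
                  basename(path), probs$row[1], probs$expected[1]))
  }
  if (ncol(tab) < 2) abort("MPGE CSV must have at least two columns.")
  mpge_dataset(mirna, tab)
}

#' Write an MPGE dataset as CSV
#'
#' @param dataset An [mpge_dataset].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mpge <- function(dataset, path) {
  stopifnot(inherits(dataset, "mpge_dataset"))
  readr::write_csv(
    setNames(dataset$ratios, c("gene_symbol", "log_ratio")), path
  )
  invisible(path)
}

#' @export
print.mpge_dataset <- function(x, ...) {
  cat(sprintf("<mpge_dataset: %s perturbed, %d genes, log-ratio range [%.2f, %.2f]>\n",
              x$mirna, nrow(x$ratios),
              min(x$ratios$log_ratio), max(x$ratios$log_ratio)))
  invisible(x)
}
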