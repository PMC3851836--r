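#' Putative regulation libraries
#'
#' A regulation library is a set of putative regulator -> target edges of a
#' single class: `"TF2gene"` (TF regulates a protein-coding gene, possibly
#' another TF), `"TF2miR"` (TF regulates a miRNA gene at the transcription
#' level) or `"miR2gene"` (miRNA represses a protein-coding transcript,
#' possibly a TF's). Membership of a (regulator, target) pair in a library
#' defines the binary design indicators used by the regression engines.
#'
#' Libraries are tibbles with columns `regulator` and `target`, carrying the
#' class `regulation_library` and an `edge_class` attribute. miRNA
#' identifiers (miR2gene regulators, TF2miR targets) are stored in
#' consolidated root form (see [consolidate_mirna_name()]).
#'
#' @param edges A data frame with columns `regulator` and `target` (extra
#'   columns are dropped).
#' @param edge_class One of `"TF2gene"`, `"TF2miR"`, `"miR2gene"`.
#' @return A `regulation_library` tibble with unique edges.
#' @examples
#' regulation_library(
#'   data.frame(regulator = "hsa-let-7a-1", target = "MYC"),
#'   "miR2gene"
#' )
#' @export
regulation_library <- function(edges, edge_class = c("TF2gene", "TF2miR", "miR2gene")) {
  edge_class <- match.arg(edge_class)
  if (!is.data.frame(edges) || !all(c("regulator", "target") %in% names(edges))) {
    abort("`edges` must be a data frame with columns `regulator` and `target`.")
  }
  lib <- tibble::tibble(
    regulator = as.character(edges$regulator),
    target = as.character(edges$target)
  )
  if (anyNA(lib$regulator) || anyNA(lib$target) ||
      any(lib$regulator == "") || any(lib$target == "")) {
    abort("Library edges must have non-missing, non-empty identifiers.")
  }
  if (edge_class == "miR2gene") lib$regulator <- consolidate_mirna_name(lib$regulator)
  if (edge_class == "TF2miR") lib$target <- consolidate_mirna_name(lib$target)
  validate_library_types(lib, edge_class)
  n_raw <- nrow(lib)
  lib <- dplyr::distinct(lib)
  if (nrow(lib) < n_raw) {
    inform(sprintf(
      "Collapsed %d duplicate %s edge(s); %d unique edge(s) kept.",
      n_raw - nrow(lib), edge_class, nrow(lib)
    ))
  }
  structure(lib, edge_class = edge_class,
            class = c("regulation_library", class(lib)))
}

# Type-rule checks that are possible from bare identifiers: no self-regulation,
# and the miRNA name pattern must agree with the slot the class dictates.
validate_library_types <- function(lib, edge_class) {
  bad_self <- lib$regulator == lib$target
  if (any(bad_self)) {
    abort(sprintf("Self-regulation edge not allowed: '%s'.",
                  lib$regulator[which(bad_self)[1]]))
  }
  if (edge_class == "miR2gene") {
    bad <- is_mirna_name(lib$target)
    if (any(bad)) {
      abort(sprintf(
        "miR2gene targets must be protein-coding genes; miRNA -> miRNA edge found: '%s' -> '%s'.",
        lib$regulator[which(bad)[1]], lib$target[which(bad)[1]]
      ))
    }
    bad <- !is_mirna_name(lib$regulator)
    if (any(bad)) {
      abort(sprintf("miR2gene regulator does not look like a miRNA: '%s'.",
                    lib$regulator[which(bad)[1]]))
    }
  } else {
    bad <- is_mirna_name(lib$regulator)
    if (any(bad)) {
      abort(sprintf("%s regulators must be TFs; miRNA-named regulator found: '%s'.",
                    edge_class, lib$regulator[which(bad)[1]]))
    }
    if (edge_class == "TF2gene" && any(is_mirna_name(lib$target))) {
      abort("TF2gene targets must be protein-coding genes; use TF2miR for TF -> miRNA edges.")
    }
    if (edge_class == "TF2miR" && any(!is_mirna_name(lib$target))) {
      abort("TF2miR targets must be miRNAs.")
    }
  }
  invisible(lib)
}

#' Read a regulation library from a delimited text file
#'
#' The file format is tab-separated text with at least two columns
#' (regulator identifier, target identifier); columns beyond the second are
#' ignored. Lines starting with `#` are comments (an optional header),
#' blank lines are skipped. miRNA names are consolidated to root form on
#' load and duplicate pairs are collapsed with a message.
#'
#' @param path Path to the file.
#' @inheritParams regulation_library
#' @return A `regulation_library` tibble.
#' @seealso [write_regulation_library()]
#' @export
read_regulation_library <- function(path, edge_class = c("TF2gene", "TF2miR", "miR2gene")) {
  edge_class <- match.arg(edge_class)
  if (!file.exists(path)) abort(sprintf("File not found: '%s'.", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) {
    warn(sprintf("'%s' contains no edges; returning an empty %s library.",
                 basename(path), edge_class))
    return(regulation_library(
      tibble::tibble(regulator = character(), target = character()), edge_class
    ))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 2)) {
    bad <- which(keep)[which(n_fields < 2)[1]]
    abort(sprintf("Malformed row at line %d of '%s': expected at least 2 tab-separated columns.",
                  bad, basename(path)))
  }
  regulation_library(
    tibble::tibble(
      regulator = vapply(fields, `[[`, "", 1L),
      target = vapply(fields, `[[`, "", 2L)
    ),
    edge_class
  )
}

#' Write a regulation library to a tab-separated file
#'
#' @param lib A `regulation_library`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regulation_library <- function(lib, path) {
  stopifnot(inherits(lib, "regulation_library"))
  header <- sprintf("# edge_class=%s\tregulator\ttarget", attr(lib, "edge_class"))
  writeLines(c(header, paste(lib$regulator, lib$target, sep = "\t")), path)
  invisible(path)
}

#' @export
print.regulation_library <- function(x, ...) {
  cat(sprintf("<regulation_library: %s, %d edge(s), %d regulator(s)>\n",
              attr(x, "edge_class"), nrow(x), dplyr::n_distinct(x$regulator)))
  NextMethod()
}

edge_class_of <- function(lib) attr(lib, "edge_class")

check_library_class <- function(lib, expected, arg) {
  if (!inherits(lib, "regulation_library") || !identical(edge_class_of(lib), expected)) {
    abort(sprintf("`%s` must be a regulation_library of class %s.", arg, expected))
  }
  invisible(lib)
}

#' Merge the three regulation libraries into a reference network
#'
#' The reference network is the union of all putative regulatory
#' relationships, independent of any expression context. Node types are
#' inferred from the roles identifiers play: anything appearing as a TF2gene
#' or TF2miR regulator is a TF (TFs are themselves protein-coding genes, so
#' an identifier may be both a TF and a miRNA target); miR2gene regulators
#' and TF2miR targets are miRNAs; all remaining targets are plain genes. An
#' identifier typed both TF and miRNA is a namespace collision and errors.
#' Edges are unweighted.
#'
#' @param tf2gene,tf2mir,mir2gene Regulation libraries of the corresponding
#'   edge classes.
#' @return A [regulatory_network].
#' @export
merge_reference_network <- function(tf2gene, tf2mir, mir2gene) {
  check_library_class(tf2gene, "TF2gene", "tf2gene")
  check_library_class(tf2mir, "TF2miR", "tf2mir")
  check_library_class(mir2gene, "miR2gene", "mir2gene")
  edges <- dplyr::bind_rows(
    tibble::tibble(from = tf2gene$regulator, to = tf2gene$target, edge_class = "TF2gene"),
    tibble::tibble(from = tf2mir$regulator, to = tf2mir$target, edge_class = "TF2miR"),
    tibble::tibble(from = mir2gene$regulator, to = mir2gene$target, edge_class = "miR2gene")
  )
  edges$weight <- NA_real_
  tf_ids <- unique(c(tf2gene$regulator, tf2mir$regulator))
  mir_ids <- unique(c(mir2gene$regulator, tf2mir$target))
  collision <- intersect(tf_ids, mir_ids)
  if (length(collision) > 0) {
    abort(sprintf("Identifier(s) typed both TF and miRNA: %s.",
                  paste(utils::head(collision, 5), collapse = ", ")))
  }
  all_ids <- unique(c(edges$from, edges$to))
  types <- dplyr::case_when(
    all_ids %in% tf_ids ~ "TF",
    all_ids %in% mir_ids ~ "MIRNA",
    TRUE ~ "GENE"
  )
  regulatory_network(edges, tibble::tibble(id = all_ids, type = types))
}
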