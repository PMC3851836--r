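#' Consolidate miRNA transcript names into their root forms
#'
#' miRNA transcripts produced from distinct genomic loci carry a trailing
#' copy-index suffix (`hsa-let-7a-1`, `hsa-let-7a-2`, ...) even though they
#' yield the same mature regulator. Regulation libraries and expression rows
#' are matched on the root form, so the copy index is stripped:
#' `hsa-let-7a-1` becomes `hsa-let-7a`.
#'
#' The family number is never mistaken for a copy index (`hsa-miR-1` is
#' already a root form and is returned unchanged), and arm suffixes such as
#' `-5p`/`-3p` are preserved. Concretely, a trailing `-<digits>` group is
#' removed only when the remaining name still ends in a miR/let family token
#' (digits plus optional family letters). The transformation is idempotent;
#' names that do not match the pattern pass through unchanged.
#'
#' @param x Character vector of miRNA identifiers.
#' @return Character vector of the same length with root-form names.
#' @examples
#' consolidate_mirna_name(c("hsa-let-7a-1", "hsa-miR-1", "hsa-miR-17-5p"))
#' @export
consolidate_mirna_name <- function(x) {
  if (!is.character(x)) {
    abort("`x` must be a character vector of miRNA identifiers.")
  }
  sub("^((?:.*-)?(?:miR|mir|let)-[0-9]+[A-Za-z]*)-[0-9]+$", "\\1", x)
}

# Heuristic used when a 2-column edge list gives no explicit node types:
# identifiers shaped like miRNA transcript names ("<prefix>-miR-..." etc.)
# are taken to denote miRNAs.
is_mirna_name <- function(x) {
  grepl("^[A-Za-z]+-(miR|mir|let)-", x)
}
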