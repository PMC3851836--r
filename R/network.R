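#' Typed combinatorial regulatory networks
#'
#' A `regulatory_network` is a directed graph whose nodes are typed `TF`,
#' `MIRNA` or `GENE` and whose edges belong to one of the three regulation
#' classes: `TF2gene` (TF -> gene/TF), `TF2miR` (TF -> miRNA) and `miR2gene`
#' (miRNA -> gene/TF). These are the only legal combinations: plain genes
#' have no out-edges and miRNA -> miRNA regulation does not exist. At most
#' one edge joins an ordered node pair and self-loops are forbidden.
#'
#' @param edges Data frame with columns `from`, `to`, optionally
#'   `edge_class`, `weight` and `p_value`. If `edge_class` is missing it is
#'   derived from the node types.
#' @param nodes Data frame with columns `id` and `type` (`TF`, `MIRNA`,
#'   `GENE`). If `NULL`, types are inferred from edge classes.
#' @return An object of class `regulatory_network`: a list with tibbles
#'   `$nodes` (`id`, `type`) and `$edges` (`from`, `to`, `edge_class`,
#'   `weight`, `p_value`).
#' @examples
#' regulatory_network(
#'   data.frame(from = c("E2F1", "hsa-miR-17-5p"),
#'              to = c("hsa-miR-17-5p", "RB1"))
#' )
#' @export
regulatory_network <- function(edges, nodes = NULL) {
  if (!is.data.frame(edges)) abort("`edges` must be a data frame.")
  if (nrow(edges) == 0) {
    edges <- tibble::tibble(from = character(), to = character(),
                            edge_class = character(), weight = double(),
                            p_value = double())
  }
  edges <- tibble::as_tibble(edges)
  if (!all(c("from", "to") %in% names(edges))) {
    abort("`edges` must have columns `from` and `to`.")
  }
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (!"weight" %in% names(edges)) edges$weight <- NA_real_
  if (!"p_value" %in% names(edges)) edges$p_value <- NA_real_

  if (is.null(nodes)) {
    nodes <- infer_node_types(edges)
  } else {
    nodes <- tibble::as_tibble(nodes)
    if (!all(c("id", "type") %in% names(nodes))) {
      abort("`nodes` must have columns `id` and `type`.")
    }
    nodes$id <- as.character(nodes$id)
    nodes$type <- as.character(nodes$type)
  }
  if (anyDuplicated(nodes$id)) abort("Duplicate node identifiers.")
  if (!all(nodes$type %in% c("TF", "MIRNA", "GENE"))) {
    abort("Node types must be TF, MIRNA or GENE.")
  }
  missing_nodes <- setdiff(unique(c(edges$from, edges$to)), nodes$id)
  if (length(missing_nodes) > 0) {
    abort(sprintf("Edge endpoint(s) missing from `nodes`: %s.",
                  paste(utils::head(missing_nodes, 5), collapse = ", ")))
  }

  type_of <- setNames(nodes$type, nodes$id)
  expected_class <- edge_class_for_types(type_of[edges$from], type_of[edges$to])
  if (anyNA(expected_class)) {
    i <- which(is.na(expected_class))[1]
    abort(sprintf(
      "Illegal edge %s(%s) -> %s(%s): violates the regulation type rules.",
      edges$from[i], type_of[[edges$from[i]]], edges$to[i], type_of[[edges$to[i]]]
    ))
  }
  if (!"edge_class" %in% names(edges)) {
    edges$edge_class <- expected_class
  } else if (!identical(as.character(edges$edge_class), unname(expected_class))) {
    i <- which(edges$edge_class != expected_class)[1]
    abort(sprintf("Edge %s -> %s declared %s but node types imply %s.",
                  edges$from[i], edges$to[i], edges$edge_class[i], expected_class[i]))
  }
  if (any(edges$from == edges$to)) abort("Self-loops are not allowed.")
  if (anyDuplicated(paste(edges$from, edges$to, sep = "\r"))) {
    abort("At most one edge per ordered node pair is allowed.")
  }
  edges <- edges[, c("from", "to", "edge_class", "weight", "p_value")]
  nodes <- dplyr::arrange(nodes[, c("id", "type")], .data$id)
  structure(list(nodes = nodes, edges = edges), class = "regulatory_network")
}

# Edge class implied by endpoint types; NA when the edge is illegal.
edge_class_for_types <- function(from_type, to_type) {
  dplyr::case_when(
    from_type == "TF" & to_type %in% c("GENE", "TF") ~ "TF2gene",
    from_type == "TF" & to_type == "MIRNA" ~ "TF2miR",
    from_type == "MIRNA" & to_type %in% c("GENE", "TF") ~ "miR2gene",
    TRUE ~ NA_character_
  )
}

# Infer node types when only edges are given: sources of TF-class edges are
# TFs; miR2gene sources and TF2miR targets are miRNAs; the rest are genes.
# Uses the declared edge_class if present, else the miRNA name pattern.
infer_node_types <- function(edges) {
  if (!"edge_class" %in% names(edges) && nrow(edges) > 0) {
    from_is_mir <- is_mirna_name(edges$from)
    to_is_mir <- is_mirna_name(edges$to)
    edges$edge_class <- dplyr::case_when(
      from_is_mir ~ "miR2gene",
      to_is_mir ~ "TF2miR",
      TRUE ~ "TF2gene"
    )
  }
  tf_ids <- unique(edges$from[edges$edge_class %in% c("TF2gene", "TF2miR")])
  mir_ids <- unique(c(edges$from[edges$edge_class == "miR2gene"],
                      edges$to[edges$edge_class == "TF2miR"]))
  collision <- intersect(tf_ids, mir_ids)
  if (length(collision) > 0) {
    abort(sprintf("Identifier(s) typed both TF and miRNA: %s.",
                  paste(utils::head(collision, 5), collapse = ", ")))
  }
  ids <- unique(c(edges$from, edges$to))
  tibble::tibble(
    id = ids,
    type = dplyr::case_when(ids %in% tf_ids ~ "TF",
                            ids %in% mir_ids ~ "MIRNA",
                            TRUE ~ "GENE")
  )
}

#' @export
print.regulatory_network <- function(x, ...) {
  comp <- table(factor(x$nodes$type, levels = c("TF", "MIRNA", "GENE")))
  cls <- table(factor(x$edges$edge_class,
                      levels = c("TF2gene", "TF2miR", "miR2gene")))
  cat(sprintf(
    "<regulatory_network: %d nodes (%d TF, %d miRNA, %d gene), %d edges (%d TF2gene, %d TF2miR, %d miR2gene)>\n",
    nrow(x$nodes), comp[["TF"]], comp[["MIRNA"]], comp[["GENE"]],
    nrow(x$edges), cls[["TF2gene"]], cls[["TF2miR"]], cls[["miR2gene"]]
  ))
  invisible(x)
}

#' @export
tidy.regulatory_network <- function(x, ...) x$edges

#' @export
glance.regulatory_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_tfs = sum(x$nodes$type == "TF"),
    n_mirnas = sum(x$nodes$type == "MIRNA"),
    n_genes = sum(x$nodes$type == "GENE"),
    n_edges = nrow(x$edges)
  )
}

as_igraph <- function(network) {
  igraph::graph_from_data_frame(network$edges, directed = TRUE,
                                vertices = network$nodes)
}

#' Write a network edge list to a tab-delimited file
#'
#' Writes columns `source`, `target`, `edge_type`, `weight` and, when any
#' edge carries one, `p_value` — the `network.edge.txt` format produced by
#' the report pipelines and ingestible by graph viewers.
#'
#' @param network A [regulatory_network].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_edges <- function(network, path) {
  stopifnot(inherits(network, "regulatory_network"))
  out <- tibble::tibble(
    source = network$edges$from,
    target = network$edges$to,
    edge_type = network$edges$edge_class,
    weight = network$edges$weight
  )
  if (any(!is.na(network$edges$p_value))) out$p_value <- network$edges$p_value
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a network edge list written by [write_network_edges()]
#'
#' @param path Path to a tab-delimited edge list with columns `source`,
#'   `target`, `edge_type`, `weight` and optionally `p_value`.
#' @return A [regulatory_network].
#' @export
read_network_edges <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: '%s'.", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("source", "target", "edge_type")
  if (!all(need %in% names(tab))) {
    abort("Edge list must have columns source, target, edge_type.")
  }
  edges <- tibble::tibble(
    from = as.character(tab$source),
    to = as.character(tab$target),
    edge_class = as.character(tab$edge_type),
    weight = if ("weight" %in% names(tab)) as.numeric(tab$weight) else NA_real_,
    p_value = if ("p_value" %in% names(tab)) as.numeric(tab$p_value) else NA_real_
  )
  regulatory_network(edges)
}
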