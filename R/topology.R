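#' Rank network vertices by degree and betweenness
#'
#' Degree is total (in + out). Betweenness is computed on the directed
#' graph with unweighted shortest paths (regression coefficients are not
#' distances); the reported values are raw shortest-path pass-through
#' counts (Freeman betweenness, unnormalised). Rank ties are broken by
#' identifier.
#'
#' @param network A [regulatory_network] with at least one node.
#' @return A tibble `id`, `type`, `in_degree`, `out_degree`, `degree`,
#'   `betweenness`, `degree_rank`, `betweenness_rank`, ordered by
#'   decreasing degree.
#' @export
rank_vertices <- function(network) {
  stopifnot(inherits(network, "regulatory_network"))
  if (nrow(network$nodes) == 0) abort("The network has no nodes.")
  g <- as_igraph(network)
  out <- tibble::tibble(
    id = igraph::V(g)$name,
    type = igraph::V(g)$type,
    in_degree = unname(igraph::degree(g, mode = "in")),
    out_degree = unname(igraph::degree(g, mode = "out")),
    betweenness = unname(igraph::betweenness(g, directed = TRUE, weights = NA))
  ) |>
    dplyr::mutate(degree = .data$in_degree + .data$out_degree)
  out$degree_rank <- rank_with_id_ties(out$degree, out$id)
  out$betweenness_rank <- rank_with_id_ties(out$betweenness, out$id)
  out |>
    dplyr::select("id", "type", "in_degree", "out_degree", "degree",
                  "betweenness", "degree_rank", "betweenness_rank") |>
    dplyr::arrange(.data$degree_rank)
}

rank_with_id_ties <- function(metric, id) {
  match(seq_along(metric), order(-metric, id))
}

#' Rank network edges by betweenness
#'
#' Edge betweenness on the directed, unweighted graph; ties broken by
#' source then target identifier.
#'
#' @inheritParams rank_vertices
#' @return A tibble `from`, `to`, `edge_class`, `betweenness`, `rank`,
#'   ordered by rank.
#' @export
rank_edges <- function(network) {
  stopifnot(inherits(network, "regulatory_network"))
  if (nrow(network$edges) == 0) {
    return(tibble::tibble(from = character(), to = character(),
                          edge_class = character(), betweenness = double(),
                          rank = integer()))
  }
  g <- as_igraph(network)
  out <- network$edges |>
    dplyr::select("from", "to", "edge_class") |>
    dplyr::mutate(betweenness = igraph::edge_betweenness(g, directed = TRUE,
                                                         weights = NA))
  out$rank <- match(seq_len(nrow(out)),
                    order(-out$betweenness, out$from, out$to))
  dplyr::arrange(out, .data$rank)
}

#' Detect co-regulating regulator pairs
#'
#' Two regulators co-regulate when they share more targets than expected
#' by chance. For every pair of regulators (nodes with out-degree >= 1)
#' the 2x2 contingency table partitions the target universe (nodes with
#' in-degree >= 1 in the network) by membership in each regulator's target
#' set; significance is the one-sided (enrichment) Fisher exact test.
#'
#' @param network A [regulatory_network] with at least two regulators.
#' @param alpha Report pairs with `p < alpha` (default 0.01, the
#'   conventional report threshold); use `alpha = 1` to keep every pair.
#' @return A tibble `regulator_a`, `regulator_b`, `n_targets_a`,
#'   `n_targets_b`, `shared`, `universe`, `p_value`, sorted by ascending
#'   p-value (ties by identifiers).
#' @export
coregulating_pairs <- function(network, alpha = 0.01) {
  stopifnot(inherits(network, "regulatory_network"))
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha <= 0 || alpha > 1) {
    abort("`alpha` must be a single number in (0, 1].")
  }
  targets_by_reg <- split(network$edges$to, network$edges$from)
  regulators <- sort(names(targets_by_reg))
  if (length(regulators) < 2) {
    abort("Co-regulation analysis needs at least two regulators.")
  }
  universe <- unique(network$edges$to)
  n_univ <- length(universe)
  pairs <- utils::combn(regulators, 2)
  rows <- purrr::map(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    ta <- unique(targets_by_reg[[a]]); tb <- unique(targets_by_reg[[b]])
    shared <- length(intersect(ta, tb))
    tab <- matrix(c(shared, length(ta) - shared,
                    length(tb) - shared,
                    n_univ - length(ta) - length(tb) + shared), nrow = 2)
    tibble::tibble(
      regulator_a = a, regulator_b = b,
      n_targets_a = length(ta), n_targets_b = length(tb),
      shared = shared, universe = n_univ,
      p_value = fisher.test(tab, alternative = "greater")$p.value
    )
  })
  out <- dplyr::bind_rows(rows)
  if (alpha < 1) out <- dplyr::filter(out, .data$p_value < alpha)
  dplyr::arrange(out, .data$p_value, .data$regulator_a, .data$regulator_b)
}

# ---- typed 3-vertex motifs -------------------------------------------------

# Directed edge legality between node types.
type_edge_allowed <- function(from_type, to_type) {
  !is.na(edge_class_for_types(from_type, to_type))
}

# Canonical code of a typed 3-vertex digraph up to isomorphism: minimum over
# vertex permutations of "<types>|<6 adjacency bits>" with bits in the fixed
# ordered-pair order 12,13,21,23,31,32.
perms3 <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
pair_order <- rbind(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2))

motif_canonical_code <- function(types, adj) {
  codes <- vapply(seq_len(nrow(perms3)), function(k) {
    p <- perms3[k, ]
    bits <- adj[cbind(p[pair_order[, 1]], p[pair_order[, 2]])]
    paste0(paste0(substr(types[p], 1, 1), collapse = ""), "|",
           paste0(as.integer(bits), collapse = ""))
  }, "")
  min(codes)
}

motif_has_cycle <- function(adj) {
  mutual <- any(adj & t(adj))
  cyc3 <- (adj[1, 2] && adj[2, 3] && adj[3, 1]) ||
    (adj[1, 3] && adj[3, 2] && adj[2, 1])
  mutual || cyc3
}

#' Enumerate the catalog of typed triple-vertex regulatory motifs
#'
#' A motif is a closed triple-vertex circuit: three typed vertices with
#' every vertex pair joined by at least one directed edge (mutual edges
#' allowed where type-legal), at least one TF and at least one miRNA among
#' the vertices, and all edges obeying the regulation type rules. Motifs
#' are deduplicated up to typed isomorphism. Feed-forward loops (FFL) are
#' acyclic; any directed cycle (a mutual pair or a 3-cycle) makes the
#' motif a feed-backward loop (FBL). There are exactly 18 such motif
#' types: 3 with vertex composition \{TF, miRNA, gene\} and 15 with
#' \{TF, TF, miRNA\} (the \{TF, miRNA, miRNA\} composition is empty
#' because two miRNAs can never be joined).
#'
#' @return A tibble with one row per motif type: `canonical_code`,
#'   `composition` (e.g. `"TF+MIRNA+GENE"`), `loop_class` (`FFL`/`FBL`),
#'   `n_edges`.
#' @export
enumerate_motif_types <- function() {
  compositions <- list(c("TF", "MIRNA", "GENE"),
                       c("TF", "TF", "MIRNA"),
                       c("TF", "MIRNA", "MIRNA"))
  found <- list()
  for (types in compositions) {
    allowed <- outer(types, types, type_edge_allowed)
    diag(allowed) <- FALSE
    for (mask in 0:63) {
      bits <- as.logical(bitwAnd(mask, 2^(0:5)))
      adj <- matrix(FALSE, 3, 3)
      adj[pair_order] <- bits
      if (any(adj & !allowed)) next
      und <- adj | t(adj)
      if (!(und[1, 2] && und[1, 3] && und[2, 3])) next
      code <- motif_canonical_code(types, adj)
      if (is.null(found[[code]])) {
        found[[code]] <- tibble::tibble(
          canonical_code = code,
          composition = paste(sort(types, decreasing = TRUE), collapse = "+"),
          loop_class = if (motif_has_cycle(adj)) "FBL" else "FFL",
          n_edges = sum(adj)
        )
      }
    }
  }
  dplyr::bind_rows(found) |>
    dplyr::arrange(.data$composition, .data$loop_class, .data$canonical_code)
}

#' Count typed triple-vertex motif instances in a network
#'
#' Every unordered vertex triple whose induced subgraph is a closed typed
#' circuit with at least one TF and one miRNA is classified by canonical
#' form and counted once. The full 18-type catalog is always returned,
#' including zero counts.
#'
#' @param network A [regulatory_network].
#' @return A tibble: the [enumerate_motif_types()] catalog plus a `count`
#'   column. The matched triples are attached as attribute `"instances"`,
#'   a tibble with columns `v1`, `v2`, `v3` (sorted identifiers) and
#'   `canonical_code`.
#' @export
count_motif_instances <- function(network) {
  stopifnot(inherits(network, "regulatory_network"))
  catalog <- enumerate_motif_types()
  ids <- network$nodes$id
  n <- length(ids)
  type_of <- setNames(network$nodes$type, ids)
  idx <- setNames(seq_len(n), ids)
  adj <- matrix(FALSE, n, n)
  if (nrow(network$edges) > 0) {
    adj[cbind(idx[network$edges$from], idx[network$edges$to])] <- TRUE
  }
  und <- adj | t(adj)

  # connected triples: for each undirected edge (i<j), common neighbours k>j
  inst <- list()
  edge_idx <- which(und & upper.tri(und), arr.ind = TRUE)
  if (nrow(edge_idx) > 0) {
    for (r in seq_len(nrow(edge_idx))) {
      i <- edge_idx[r, 1]; j <- edge_idx[r, 2]
      ks <- which(und[i, ] & und[j, ])
      ks <- ks[ks > j]
      for (k in ks) {
        tri <- c(i, j, k)
        tys <- unname(type_of[ids[tri]])
        if (!("TF" %in% tys) || !("MIRNA" %in% tys)) next
        code <- motif_canonical_code(tys, adj[tri, tri])
        inst[[length(inst) + 1]] <- tibble::tibble(
          v1 = ids[i], v2 = ids[j], v3 = ids[k], canonical_code = code
        )
      }
    }
  }
  instances <- if (length(inst) > 0) dplyr::bind_rows(inst) else
    tibble::tibble(v1 = character(), v2 = character(), v3 = character(),
                   canonical_code = character())
  counts <- dplyr::count(instances, .data$canonical_code, name = "count")
  out <- catalog |>
    dplyr::left_join(counts, by = "canonical_code") |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L))
  attr(out, "instances") <- instances
  out
}

#' Shuffle a network preserving typed degrees
#'
#' Degree-preserving randomisation by double-edge swaps performed within
#' each edge class separately: two edges (a -> b, c -> d) of the same
#' class are rewired to (a -> d, c -> b) unless the rewiring would create
#' a self-loop or a duplicate edge. Every node's typed in- and out-degree
#' within each class is preserved exactly. Classes with fewer than two
#' edges are left unshuffled with a warning.
#'
#' @param network A [regulatory_network].
#' @param swap_factor Number of swap attempts per edge of each class
#'   (default 10).
#' @return A shuffled [regulatory_network] (weights and p-values dropped).
#' @export
shuffle_network <- function(network, swap_factor = 10) {
  stopifnot(inherits(network, "regulatory_network"))
  edges <- network$edges
  key_env <- new.env(parent = emptyenv(), size = max(16L, 2L * nrow(edges)))
  for (k in paste(edges$from, edges$to, sep = "\r")) assign(k, TRUE, key_env)

  for (cls in unique(edges$edge_class)) {
    sel <- which(edges$edge_class == cls)
    m <- length(sel)
    if (m < 2) {
      warn(sprintf("Edge class %s has fewer than 2 edges; left unshuffled.", cls))
      next
    }
    from <- edges$from[sel]
    to <- edges$to[sel]
    for (attempt in seq_len(ceiling(swap_factor * m))) {
      ij <- sample.int(m, 2)
      a <- from[ij[1]]; b <- to[ij[1]]
      cc <- from[ij[2]]; d <- to[ij[2]]
      if (a == d || cc == b || b == d || a == cc) next
      k1 <- paste(a, d, sep = "\r"); k2 <- paste(cc, b, sep = "\r")
      if (exists(k1, key_env, inherits = FALSE) ||
          exists(k2, key_env, inherits = FALSE)) next
      rm(list = c(paste(a, b, sep = "\r"), paste(cc, d, sep = "\r")),
         envir = key_env)
      assign(k1, TRUE, key_env); assign(k2, TRUE, key_env)
      to[ij[1]] <- d; to[ij[2]] <- b
    }
    edges$from[sel] <- from
    edges$to[sel] <- to
  }
  edges$weight <- NA_real_
  edges$p_value <- NA_real_
  regulatory_network(edges, network$nodes)
}

#' Motif significance by degree-preserving network randomisation
#'
#' Counts every motif type in the observed network and in `replicates`
#' shuffled replicates ([shuffle_network()]), then reports the empirical
#' upper-tail probability `p = (1 + #\{null >= observed\}) /
#' (1 + replicates)` per type — small when the motif recurs more often
#' than its typed degree structure alone explains.
#'
#' @param network A [regulatory_network].
#' @param replicates Number of shuffled replicates (default 1000).
#' @param swap_factor Swap attempts per edge per replicate (default 10).
#' @param seed Optional integer seed for reproducible shuffles.
#' @return A tibble of class `motif_significance`: the motif catalog plus
#'   `observed`, `null_mean` and `p_value` columns.
#' @export
motif_pvalues <- function(network, replicates = 1000, swap_factor = 10,
                          seed = NULL) {
  stopifnot(inherits(network, "regulatory_network"))
  if (!is.numeric(replicates) || replicates < 1) {
    abort("`replicates` must be >= 1.")
  }
  replicates <- as.integer(replicates)
  run <- function() {
    obs <- count_motif_instances(network)
    null_counts <- matrix(0L, nrow(obs), replicates)
    for (r in seq_len(replicates)) {
      null_counts[, r] <- count_motif_instances(
        shuffle_network(network, swap_factor)
      )$count
    }
    obs |>
      dplyr::rename(observed = "count") |>
      dplyr::mutate(
        null_mean = rowMeans(null_counts),
        p_value = (1 + rowSums(null_counts >= .data$observed)) / (1 + replicates)
      )
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  attr(out, "instances") <- NULL
  class(out) <- c("motif_significance", class(out))
  out
}

#' @export
autoplot.motif_significance <- function(object, ...) {
  df <- dplyr::mutate(object, enriched = .data$p_value <= 0.05)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$canonical_code, .data$observed),
    y = .data$observed, fill = .data$enriched
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_point(ggplot2::aes(y = .data$null_mean), shape = 21,
                        fill = "white") +
    ggplot2::coord_flip() +
    ggplot2::facet_grid(.data$composition ~ ., scales = "free_y", space = "free") +
    ggplot2::labs(x = NULL, y = "Motif instances",
                  fill = "p ≤ 0.05",
                  title = "Observed motif counts vs shuffled-network mean")
}
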