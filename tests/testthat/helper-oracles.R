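# Independent oracles used to cross-check the package implementation.
# Each is written from first principles and shares no code with R/.

# Permutation p-value for the one-sided two-sample K-S statistic
# D+ = sup(F_targets - F_nontargets). Labels are shuffled over the pooled
# sample; add-one estimator.
oracle_perm_ks <- function(target_vals, nontarget_vals, B = 1e5, seed = 42) {
  n1 <- length(target_vals)
  n2 <- length(nontarget_vals)
  pool <- c(target_vals, nontarget_vals)
  ord <- order(pool)
  sorted <- pool[ord]
  # last index of each tied run: D+ is attained at run boundaries
  run_end <- which(c(sorted[-1] != sorted[-length(sorted)], TRUE))
  dplus_of <- function(is_target_sorted) {
    diff_cdf <- cumsum(is_target_sorted) / n1 -
      cumsum(!is_target_sorted) / n2
    max(diff_cdf[run_end])
  }
  obs <- dplus_of(c(rep(TRUE, n1), rep(FALSE, n2))[ord])
  cnt <- 0L
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      lab <- logical(n1 + n2)
      lab[sample.int(n1 + n2, n1)] <- TRUE
      if (dplus_of(lab) >= obs - 1e-12) cnt <- cnt + 1L
    }
  })
  (1 + cnt) / (1 + B)
}

# All-pairs shortest-path betweenness (vertex and edge) on a directed,
# unweighted graph, by BFS path counting (no igraph).
oracle_betweenness <- function(edges, ids) {
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  adj_list <- lapply(seq_len(n), function(i) integer())
  for (r in seq_len(nrow(edges))) {
    u <- idx[[edges$from[r]]]
    adj_list[[u]] <- c(adj_list[[u]], idx[[edges$to[r]]])
  }
  d <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0; sigma[s, s] <- 1
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer()
      for (u in frontier) {
        for (v in adj_list[[u]]) {
          if (is.infinite(d[s, v])) {
            d[s, v] <- d[s, u] + 1
            nxt <- c(nxt, v)
          }
          if (d[s, v] == d[s, u] + 1) sigma[s, v] <- sigma[s, v] + sigma[s, u]
        }
      }
      frontier <- unique(nxt)
    }
  }
  vb <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (s == t || s == v || t == v) next
        if (is.finite(d[s, t]) && d[s, v] + d[v, t] == d[s, t]) {
          vb[v] <- vb[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  eb <- numeric(nrow(edges))
  for (r in seq_len(nrow(edges))) {
    u <- idx[[edges$from[r]]]; v <- idx[[edges$to[r]]]
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (s == t) next
        if (is.finite(d[s, t]) && d[s, u] + 1 + d[v, t] == d[s, t]) {
          eb[r] <- eb[r] + sigma[s, u] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  list(vertex = stats::setNames(vb, ids), edge = eb)
}

# Integer canonical form of a typed 3-vertex digraph: minimum over vertex
# permutations of a packed (types, adjacency-bits) code. Independent of the
# package's string-based canonicalisation.
oracle_canon_int <- function(tys, a) {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  tcode <- c(TF = 0, MIRNA = 1, GENE = 2)
  best <- Inf
  for (p in perms) {
    tp <- tcode[tys[p]]
    v <- tp[[1]] * 9 + tp[[2]] * 3 + tp[[3]]
    bits <- c(a[p[1], p[2]], a[p[1], p[3]], a[p[2], p[1]],
              a[p[2], p[3]], a[p[3], p[1]], a[p[3], p[2]])
    code <- v * 64 + sum(as.integer(bits) * 2^(5:0))
    if (code < best) best <- code
  }
  best
}

# Brute-force catalog enumerator for one vertex-type composition: all 2^6
# labeled edge configurations, filtered for edge legality and pairwise
# connectivity, deduplicated by oracle_canon_int. Returns the class codes.
oracle_enumerate_types <- function(types) {
  legal <- function(ft, tt) ft == "TF" || (ft == "MIRNA" && tt != "MIRNA")
  codes <- c()
  pair_ord <- rbind(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2))
  for (mask in 0:63) {
    bits <- as.logical(bitwAnd(mask, 2^(0:5)))
    a <- matrix(FALSE, 3, 3)
    a[pair_ord] <- bits
    ok <- TRUE
    for (r in seq_len(6)) {
      if (bits[r] && !legal(types[pair_ord[r, 1]], types[pair_ord[r, 2]])) ok <- FALSE
    }
    if (!ok) next
    u <- a | t(a)
    if (!(u[1, 2] && u[1, 3] && u[2, 3])) next
    codes <- c(codes, oracle_canon_int(types, a))
  }
  sort(unique(codes))
}

# Exhaustive motif count: every C(n,3) triple, classified by an integer
# canonical form (min over vertex permutations of a packed type/bit code).
oracle_motif_counts <- function(network) {
  ids <- network$nodes$id
  n <- length(ids)
  type_of <- stats::setNames(network$nodes$type, ids)
  idx <- stats::setNames(seq_len(n), ids)
  adj <- matrix(FALSE, n, n)
  if (nrow(network$edges) > 0) {
    adj[cbind(idx[network$edges$from], idx[network$edges$to])] <- TRUE
  }
  canon_int <- oracle_canon_int
  rows <- list()
  if (n >= 3) {
    for (tri in utils::combn(n, 3, simplify = FALSE)) {
      a <- adj[tri, tri]
      u <- a | t(a)
      if (!(u[1, 2] && u[1, 3] && u[2, 3])) next
      tys <- unname(type_of[ids[tri]])
      if (!("TF" %in% tys) || !("MIRNA" %in% tys)) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        triple = paste(sort(ids[tri]), collapse = "|"),
        key = canon_int(tys, a)
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(triple = character(), key = double()))
  }
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive best-subset linear model selection by AIC (extractAIC scale,
# matching step()'s criterion). Returns the column names of the best subset.
oracle_best_subset_aic <- function(y, X) {
  p <- ncol(X)
  best_aic <- Inf
  best <- character()
  for (mask in 0:(2^p - 1)) {
    take <- as.logical(bitwAnd(mask, 2^(seq_len(p) - 1)))
    dat <- data.frame(y = y, X[, take, drop = FALSE], check.names = FALSE)
    fit <- stats::lm(y ~ ., data = dat)
    aic <- stats::extractAIC(fit)[2]
    if (aic < best_aic - 1e-9) {
      best_aic <- aic
      best <- colnames(X)[take]
    }
  }
  best
}

# Closed-form one-sided hypergeometric tail P(X >= shared) for a
# co-regulation table: universe N, |targets A| = K, |targets B| = n.
oracle_hyper_tail <- function(shared, n_a, n_b, n_univ) {
  stats::phyper(shared - 1, n_a, n_univ - n_a, n_b, lower.tail = FALSE)
}

# Seeded random typed network generator used by the oracle-equivalence
# checks: draws node types, then each type-legal ordered pair
# independently with probability p_edge.
random_typed_network <- function(seed, n_nodes = 30, p_edge = 0.08) {
  withr::with_seed(seed, {
    n_tf <- max(2, rbinom(1, n_nodes, 0.3))
    n_mir <- max(2, rbinom(1, n_nodes, 0.2))
    n_gene <- max(1, n_nodes - n_tf - n_mir)
    nodes <- tibble::tibble(
      id = c(sprintf("T%02d", seq_len(n_tf)),
             sprintf("hsa-miR-8%02d", seq_len(n_mir)),
             sprintf("G%02d", seq_len(n_gene))),
      type = rep(c("TF", "MIRNA", "GENE"), c(n_tf, n_mir, n_gene))
    )
    legal <- expand.grid(from = seq_len(nrow(nodes)), to = seq_len(nrow(nodes)))
    legal <- legal[legal$from != legal$to, ]
    ft <- nodes$type[legal$from]; tt <- nodes$type[legal$to]
    ok <- (ft == "TF") | (ft == "MIRNA" & tt != "MIRNA")
    legal <- legal[ok, ]
    pick <- legal[runif(nrow(legal)) < p_edge, ]
    edges <- tibble::tibble(from = nodes$id[pick$from], to = nodes$id[pick$to])
    regulatory_network(edges, nodes)
  })
}
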