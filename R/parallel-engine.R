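#' Selection configuration for the parallel-expression engine
#'
#' @param p_survivor Coefficient p-value a regulator must reach to survive
#'   after stepwise AIC selection (iterative backward pruning of the worst
#'   term with refit); `1` disables the filter. Default 0.05.
#' @param repression_only If `TRUE`, retained miRNA -> gene edges with a
#'   positive coefficient are discarded (degradation implies a negative
#'   regulating strength). Default `FALSE`: no sign constraint.
#' @return A list of class `parallel_config`.
#' @export
parallel_config <- function(p_survivor = 0.05, repression_only = FALSE) {
  if (!is.numeric(p_survivor) || length(p_survivor) != 1 ||
      is.na(p_survivor) || p_survivor <= 0 || p_survivor > 1) {
    abort("`p_survivor` must be a single number in (0, 1].")
  }
  structure(list(p_survivor = p_survivor,
                 repression_only = isTRUE(repression_only)),
            class = "parallel_config")
}

# Bidirectional stepwise AIC regression of y on the columns of X (entered
# in column order), followed by backward pruning until every survivor's
# coefficient p-value is <= p_survivor. Guards: zero-variance columns are
# dropped; if more candidates than n - 2, only the top n - 2 by univariate
# |correlation| are considered; collinear columns are dropped in order.
# Returns a tibble (predictor, coefficient, p_value).
stepwise_profile_fit <- function(y, X, p_survivor = 0.05) {
  n <- length(y)
  if (ncol(X) > 0) {
    const <- apply(X, 2, function(v) sd(v) == 0)
    if (any(const)) {
      warn(sprintf("Dropping zero-variance candidate profile(s): %s.",
                   paste(colnames(X)[const], collapse = ", ")))
      X <- X[, !const, drop = FALSE]
    }
  }
  if (ncol(X) > n - 2) {
    k <- n - 2
    warn(sprintf("%d candidates but only %d conditions; keeping the top %d by |correlation|.",
                 ncol(X), n, k))
    r <- abs(suppressWarnings(cor(y, X)))[1, ]
    r[is.na(r)] <- 0
    keep <- order(-r, colnames(X))[seq_len(k)]
    X <- X[, sort(keep), drop = FALSE]
  }
  if (ncol(X) > 0) {
    kept <- drop_collinear(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")), X)
    X <- X[, kept, drop = FALSE]
  }
  empty <- tibble::tibble(predictor = character(), coefficient = double(),
                          p_value = double())
  if (ncol(X) == 0 || sd(y) == 0) return(empty)

  dat <- data.frame(y = y, X, check.names = FALSE)
  base <- lm(y ~ 1, data = dat)
  upper <- stats::reformulate(sprintf("`%s`", colnames(X)), response = "y")
  fit <- suppressWarnings(
    step(base, scope = list(lower = y ~ 1, upper = upper),
         direction = "both", trace = 0)
  )

  repeat {
    cf <- suppressWarnings(summary(fit))$coefficients
    terms_kept <- setdiff(rownames(cf), "(Intercept)")
    if (length(terms_kept) == 0) return(empty)
    p <- cf[terms_kept, 4]
    # NaN p (saturated/noiseless fit) counts as passing: the coefficient is exact
    p_eff <- ifelse(is.nan(p), 0, p)
    if (all(p_eff <= p_survivor)) break
    worst <- terms_kept[which.max(p_eff)]
    fit <- stats::update(fit, stats::as.formula(paste(". ~ . -", worst)))
  }
  cf <- suppressWarnings(summary(fit))$coefficients
  terms_kept <- setdiff(rownames(cf), "(Intercept)")
  tibble::tibble(
    predictor = gsub("^`|`$", "", terms_kept),
    coefficient = unname(cf[terms_kept, 1]),
    p_value = unname(cf[terms_kept, 4])
  )
}

#' Infer the regulators of one gene from parallel expression profiles
#'
#' Regresses the gene's mRNA profile on the transcript profiles of its
#' candidate regulators — the TFs targeting it in `TF2gene` and the miRNAs
#' targeting it in `miR2gene`, restricted to molecules measured in the
#' dataset (TF profiles come from the mRNA matrix). Candidates enter in
#' deterministic order (TFs, then miRNAs, each lexicographic); selection is
#' bidirectional stepwise AIC with a survivor p filter (see
#' [parallel_config()]).
#'
#' @param dataset A [parallel_dataset].
#' @param gene A gene symbol present in the mRNA matrix.
#' @param tf2gene,mir2gene Regulation libraries of those classes.
#' @param config A [parallel_config()].
#' @return A tibble of retained edges: `from`, `to`, `edge_class`, `weight`
#'   (fitted coefficient), `p_value`.
#' @export
fit_gene_equation <- function(dataset, gene, tf2gene, mir2gene,
                              config = parallel_config()) {
  stopifnot(inherits(dataset, "parallel_dataset"))
  check_library_class(tf2gene, "TF2gene", "tf2gene")
  check_library_class(mir2gene, "miR2gene", "mir2gene")
  if (!gene %in% rownames(dataset$mrna)) {
    abort(sprintf("Gene '%s' is not in the mRNA matrix.", gene))
  }
  tf_cand <- sort(intersect(
    setdiff(tf2gene$regulator[tf2gene$target == gene], gene),
    rownames(dataset$mrna)
  ))
  mir_cand <- sort(intersect(
    mir2gene$regulator[mir2gene$target == gene],
    rownames(dataset$mirna)
  ))
  X <- cbind(
    t(dataset$mrna[tf_cand, , drop = FALSE]),
    t(dataset$mirna[mir_cand, , drop = FALSE])
  )
  res <- stepwise_profile_fit(dataset$mrna[gene, ], X, config$p_survivor)
  out <- tibble::tibble(
    from = res$predictor,
    to = rep(gene, nrow(res)),
    edge_class = as.character(ifelse(res$predictor %in% mir_cand,
                                     "miR2gene", "TF2gene")),
    weight = res$coefficient,
    p_value = res$p_value
  )
  if (config$repression_only) {
    out <- dplyr::filter(out, !(.data$edge_class == "miR2gene" & .data$weight > 0))
  }
  out
}

#' Infer the TF regulators of one miRNA from parallel expression profiles
#'
#' Same contract as [fit_gene_equation()], with the miRNA's profile as the
#' response and its `TF2miR` library regulators (measured in the mRNA
#' matrix) as candidates.
#'
#' @inheritParams fit_gene_equation
#' @param mirna A miRNA identifier present in the miRNA matrix.
#' @param tf2mir `TF2miR` regulation library.
#' @return A tibble of retained `TF2miR` edges.
#' @export
fit_mirna_equation <- function(dataset, mirna, tf2mir,
                               config = parallel_config()) {
  stopifnot(inherits(dataset, "parallel_dataset"))
  check_library_class(tf2mir, "TF2miR", "tf2mir")
  if (!mirna %in% rownames(dataset$mirna)) {
    abort(sprintf("miRNA '%s' is not in the miRNA matrix.", mirna))
  }
  tf_cand <- sort(intersect(tf2mir$regulator[tf2mir$target == mirna],
                            rownames(dataset$mrna)))
  X <- t(dataset$mrna[tf_cand, , drop = FALSE])
  res <- stepwise_profile_fit(dataset$mirna[mirna, ], X, config$p_survivor)
  tibble::tibble(
    from = res$predictor, to = rep(mirna, nrow(res)),
    edge_class = rep("TF2miR", nrow(res)),
    weight = res$coefficient, p_value = res$p_value
  )
}

#' Assemble retained per-target fits into one combinatorial network
#'
#' @param gene_fits Tibble of edges from [fit_gene_equation()] calls
#'   (classes `TF2gene` and `miR2gene`).
#' @param mirna_fits Tibble of edges from [fit_mirna_equation()] calls
#'   (class `TF2miR`).
#' @return A [regulatory_network] with coefficient weights and per-edge
#'   p-values; node types are derived from the edge classes.
#' @export
assemble_network <- function(gene_fits, mirna_fits) {
  edges <- dplyr::bind_rows(gene_fits, mirna_fits)
  if (nrow(edges) == 0) {
    return(regulatory_network(edges))
  }
  # a target of a TF2gene edge that also regulates (TF2gene/TF2miR source)
  # is a TF; sources of miR2gene and targets of TF2miR are miRNAs
  regulatory_network(edges)
}

#' Infer the genome-wide combinatorial network from a parallel dataset
#'
#' Runs [fit_gene_equation()] for every gene in the mRNA matrix and
#' [fit_mirna_equation()] for every miRNA in the miRNA matrix, then unions
#' the retained edges into one typed network (TF -> gene and miRNA -> gene
#' edges from the mRNA equations, TF -> miRNA edges from the miRNA
#' equations).
#'
#' @inheritParams fit_gene_equation
#' @param tf2mir `TF2miR` regulation library.
#' @return A [regulatory_network].
#' @export
fit_parallel_network <- function(dataset, tf2gene, tf2mir, mir2gene,
                                 config = parallel_config()) {
  stopifnot(inherits(dataset, "parallel_dataset"))
  gene_fits <- purrr::map(
    sort(rownames(dataset$mrna)),
    function(g) fit_gene_equation(dataset, g, tf2gene, mir2gene, config)
  ) |> dplyr::bind_rows()
  mirna_fits <- purrr::map(
    sort(rownames(dataset$mirna)),
    function(m) fit_mirna_equation(dataset, m, tf2mir, config)
  ) |> dplyr::bind_rows()
  assemble_network(gene_fits, mirna_fits)
}
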