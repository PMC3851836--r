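#' One-sided Kolmogorov-Smirnov test of miRNA target degradation
#'
#' If the perturbed miRNA degrades its targets, the expression log-ratios of
#' its putative targets (library edges of the perturbed miRNA intersected
#' with measured genes) are shifted down relative to the non-targets (all
#' remaining measured genes). The test statistic is the one-sided
#' Kolmogorov-Smirnov distance
#' \eqn{D^+ = \sup_x [F_{targets}(x) - F_{nontargets}(x)]},
#' large when the target distribution is stochastically smaller.
#'
#' The p-value is exact (the full permutation distribution of \eqn{D^+},
#' tie-aware) whenever `n_targets * n_nontargets <= 10000`, and asymptotic
#' otherwise; `exact` overrides the switch.
#'
#' @param dataset An [mpge_dataset].
#' @param mir2gene `miR2gene` [regulation_library()].
#' @param exact `NULL` (default, size-based switch), `TRUE` or `FALSE`.
#' @return An object of class `ks_degradation`: list with `statistic`,
#'   `p_value`, `n_targets`, `n_nontargets` and `pp_points`, a tibble of
#'   paired empirical CDF coordinates for the PP-plot (`value`,
#'   `cdf_targets`, `cdf_nontargets`).
#' @seealso [refine_targets()] for per-gene refinement, [autoplot.ks_degradation()].
#' @export
ks_degradation_test <- function(dataset, mir2gene, exact = NULL) {
  stopifnot(inherits(dataset, "mpge_dataset"))
  check_library_class(mir2gene, "miR2gene", "mir2gene")
  split <- split_targets(dataset, mir2gene)
  t_vals <- split$target_ratios
  n_vals <- split$nontarget_ratios
  if (is.null(exact)) exact <- length(t_vals) * length(n_vals) <= 10000
  kt <- suppressWarnings(
    ks.test(t_vals, n_vals, alternative = "greater", exact = exact)
  )
  grid <- sort(unique(c(t_vals, n_vals)))
  pp <- tibble::tibble(
    value = grid,
    cdf_targets = stats::ecdf(t_vals)(grid),
    cdf_nontargets = stats::ecdf(n_vals)(grid)
  )
  structure(
    list(
      statistic = unname(kt$statistic),
      p_value = unname(kt$p.value),
      n_targets = length(t_vals),
      n_nontargets = length(n_vals),
      exact = exact,
      mirna = dataset$mirna,
      pp_points = pp
    ),
    class = "ks_degradation"
  )
}

# Partition the measured genes into putative targets of the perturbed miRNA
# and non-targets (the complement). Errors when either side is empty.
split_targets <- function(dataset, mir2gene) {
  putative <- mir2gene$target[mir2gene$regulator == dataset$mirna]
  is_target <- dataset$ratios$gene %in% putative
  if (!any(is_target)) {
    abort(sprintf("No putative target of %s is present in the dataset.",
                  dataset$mirna))
  }
  if (all(is_target)) {
    abort(sprintf("No non-target of %s is present in the dataset.",
                  dataset$mirna))
  }
  list(
    targets = dataset$ratios$gene[is_target],
    target_ratios = dataset$ratios$log_ratio[is_target],
    nontarget_ratios = dataset$ratios$log_ratio[!is_target]
  )
}

#' @export
print.ks_degradation <- function(x, ...) {
  cat(sprintf(
    "One-sided K-S degradation test for %s\n  D+ = %.4f, p = %.3g (%s), %d targets vs %d non-targets\n",
    x$mirna, x$statistic, x$p_value, if (x$exact) "exact" else "asymptotic",
    x$n_targets, x$n_nontargets
  ))
  invisible(x)
}

#' @export
tidy.ks_degradation <- function(x, ...) {
  tibble::tibble(
    mirna = x$mirna, statistic = x$statistic, p_value = x$p_value,
    n_targets = x$n_targets, n_nontargets = x$n_nontargets,
    method = if (x$exact) "exact" else "asymptotic"
  )
}

#' @export
glance.ks_degradation <- function(x, ...) tidy(x)

#' PP-plot of target versus non-target expression log-ratios
#'
#' Plots the empirical CDF of the putative targets against that of the
#' non-targets; points above the diagonal indicate the downward shift
#' expected from target degradation.
#'
#' @param object A `ks_degradation` result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ks_degradation <- function(object, ...) {
  ggplot2::ggplot(object$pp_points,
                  ggplot2::aes(x = .data$cdf_nontargets, y = .data$cdf_targets)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "Empirical CDF, non-targets", y = "Empirical CDF, putative targets",
      title = sprintf("%s target degradation (D+ = %.3f, p = %.2g)",
                      object$mirna, object$statistic, object$p_value)
    )
}

#' Refine degraded targets by per-gene empirical tail probability
#'
#' Every putative target gene g is compared against the non-target
#' log-ratio distribution: the empirical one-sided p-value is
#' `(1 + #\{non-targets <= E_g\}) / (1 + n_nontargets)`, small when g is
#' more strongly down-regulated than the bulk of non-targets. P-values are
#' Benjamini-Hochberg adjusted across the putative targets and the refined
#' set keeps genes with adjusted p at or below `alpha`. The procedure is
#' rank-based and therefore invariant under monotone transformation of the
#' log-ratios.
#'
#' @inheritParams ks_degradation_test
#' @param alpha False-discovery-rate level in (0, 1); default 0.05.
#' @return A tibble with one row per putative target present in the
#'   dataset: `gene`, `log_ratio`, `p_value`, `p_adjusted`, `refined`
#'   (logical), ordered by increasing p.
#' @export
refine_targets <- function(dataset, mir2gene, alpha = 0.05) {
  stopifnot(inherits(dataset, "mpge_dataset"))
  check_library_class(mir2gene, "miR2gene", "mir2gene")
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single number in (0, 1).")
  }
  split <- split_targets(dataset, mir2gene)
  non_sorted <- sort(split$nontarget_ratios)
  n_non <- length(non_sorted)
  p_emp <- (1 + findInterval(split$target_ratios, non_sorted)) / (1 + n_non)
  tibble::tibble(
    gene = split$targets,
    log_ratio = split$target_ratios,
    p_value = p_emp,
    p_adjusted = p.adjust(p_emp, method = "BH")
  ) |>
    dplyr::mutate(refined = .data$p_adjusted <= alpha) |>
    dplyr::arrange(.data$p_value, .data$gene)
}

#' Pre-filter candidate TFs by univariate regression
#'
#' For each TF i with at least one library target among the measured genes,
#' fits the univariate linear model `E_g = c0 + c1 * b_ig` across all genes,
#' where `b_ig` indicates membership of g in the TF's putative target set.
#' TFs whose slope p-value is at or below `p_threshold` are retained,
#' ordered by increasing p (ties broken by TF identifier), and fed to the
#' multivariate stepwise stage. TFs whose indicator is constant over the
#' measured genes cannot be tested and are skipped with a warning.
#'
#' @param dataset An [mpge_dataset].
#' @param tf2gene `TF2gene` [regulation_library()].
#' @param p_threshold Retention threshold on the slope p-value, default 0.01.
#' @return A tibble `tf`, `n_targets`, `effect` (slope estimate), `p_value`,
#'   ordered by ascending p.
#' @export
prefilter_tfs <- function(dataset, tf2gene, p_threshold = 0.01) {
  stopifnot(inherits(dataset, "mpge_dataset"))
  check_library_class(tf2gene, "TF2gene", "tf2gene")
  if (!is.numeric(p_threshold) || length(p_threshold) != 1 ||
      is.na(p_threshold) || p_threshold <= 0 || p_threshold > 1) {
    abort("`p_threshold` must be a single number in (0, 1].")
  }
  genes <- dataset$ratios$gene
  e <- dataset$ratios$log_ratio
  lib <- dplyr::filter(tf2gene, .data$target %in% genes)
  tfs <- sort(unique(lib$regulator))
  if (length(tfs) == 0) {
    abort("No TF in the library has a target among the measured genes.")
  }
  n <- length(e)
  rows <- purrr::map(tfs, function(tf) {
    b <- as.numeric(genes %in% lib$target[lib$regulator == tf])
    n1 <- sum(b)
    if (n1 == 0 || n1 == n) {
      warn(sprintf("TF %s has a constant target indicator over the measured genes; skipped.", tf))
      return(NULL)
    }
    # closed-form simple-regression slope test, identical to lm(e ~ b)
    m1 <- mean(e[b == 1]); m0 <- mean(e[b == 0]); n0 <- n - n1
    rss <- sum((e[b == 1] - m1)^2) + sum((e[b == 0] - m0)^2)
    s2 <- rss / (n - 2)
    se <- sqrt(s2 * (1 / n1 + 1 / n0))
    tstat <- if (se == 0) ifelse(m1 == m0, 0, Inf * sign(m1 - m0)) else (m1 - m0) / se
    tibble::tibble(tf = tf, n_targets = n1, effect = m1 - m0,
                   p_value = 2 * pt(-abs(tstat), df = n - 2))
  })
  dplyr::bind_rows(rows) |>
    dplyr::filter(.data$p_value <= p_threshold) |>
    dplyr::arrange(.data$p_value, .data$tf)
}

#' Fit the combinatorial miRNA + TF linear model by stepwise selection
#'
#' Models the per-gene expression log-ratio as
#' `E_g = a_m * b_mg + sum_i a_TFi * b_TFig + intercept + noise`, with
#' binary indicators `b_mg` (g belongs to the refined miRNA target set) and
#' `b_TFig` (g is a putative library target of candidate TF i). Candidate
#' TF terms are chosen by bidirectional stepwise selection minimising AIC;
#' the miRNA indicator is always retained. Candidates enter in the order
#' given (the pre-filter order), which makes the procedure deterministic;
#' indicator columns collinear with earlier ones are dropped with a
#' warning.
#'
#' @param dataset An [mpge_dataset].
#' @param mir_targets Character vector of genes forming the miRNA indicator
#'   support — typically the refined target set from [refine_targets()], or
#'   a tibble with columns `gene` and `refined` as returned by it.
#' @param candidate_tfs Character vector of candidate TF identifiers in
#'   entry order, or the tibble returned by [prefilter_tfs()].
#' @param tf2gene `TF2gene` [regulation_library()].
#' @return An object of class `mpge_model`: list with `mirna_coefficient`
#'   (`a_m`), `mirna_p_value`, `tf_table` (tibble `tf`, `coefficient`,
#'   `p_value` for retained TFs), `genes`, `mir_targets`, and the
#'   underlying `lm` fit.
#' @export
fit_combinatorial_model <- function(dataset, mir_targets, candidate_tfs, tf2gene) {
  stopifnot(inherits(dataset, "mpge_dataset"))
  check_library_class(tf2gene, "TF2gene", "tf2gene")
  if (is.data.frame(mir_targets)) {
    if ("refined" %in% names(mir_targets)) {
      mir_targets <- mir_targets$gene[mir_targets$refined]
    } else {
      mir_targets <- mir_targets$gene
    }
  }
  if (is.data.frame(candidate_tfs)) candidate_tfs <- candidate_tfs$tf
  candidate_tfs <- as.character(candidate_tfs)

  genes <- dataset$ratios$gene
  e <- dataset$ratios$log_ratio
  b_m <- as.numeric(genes %in% mir_targets)
  X <- vapply(candidate_tfs, function(tf) {
    as.numeric(genes %in% tf2gene$target[tf2gene$regulator == tf])
  }, numeric(length(genes)))
  X <- matrix(X, nrow = length(genes),
              dimnames = list(NULL, candidate_tfs))

  if (length(genes) <= length(candidate_tfs) + 2) {
    abort("Need more genes than candidate predictors plus one.")
  }

  keep <- drop_collinear(cbind(`(Intercept)` = 1, b_m = b_m), X)
  X <- X[, keep, drop = FALSE]

  dat <- data.frame(e = e, b_m = b_m, X, check.names = FALSE)
  base <- lm(e ~ b_m, data = dat)
  # an already-perfect base fit leaves nothing for selection to explain
  # (and step() cannot compare -Inf AICs)
  perfect <- stats::deviance(base) <= 1e-12 * max(1, sum(e^2))
  if (ncol(X) > 0 && !perfect) {
    upper <- stats::reformulate(c("b_m", sprintf("`%s`", colnames(X))),
                                response = "e")
    fit <- suppressWarnings(step(base,
                                 scope = list(lower = e ~ b_m, upper = upper),
                                 direction = "both", trace = 0))
  } else {
    fit <- base
  }

  cf <- suppressWarnings(summary(fit))$coefficients
  terms_kept <- setdiff(rownames(cf), c("(Intercept)", "b_m"))
  tf_names <- gsub("^`|`$", "", terms_kept)
  new_mpge_model(
    mirna = dataset$mirna,
    mirna_coefficient = unname(coef(fit)[["b_m"]]),
    mirna_p_value = if ("b_m" %in% rownames(cf)) unname(cf["b_m", 4]) else NA_real_,
    tf_table = tibble::tibble(
      tf = tf_names,
      coefficient = unname(cf[terms_kept, 1]),
      p_value = unname(cf[terms_kept, 4])
    ) |> dplyr::arrange(.data$p_value, .data$tf),
    genes = genes,
    mir_targets = intersect(mir_targets, genes),
    candidates = candidate_tfs,
    fit = fit
  )
}

new_mpge_model <- function(...) structure(list(...), class = "mpge_model")

# Among columns of X (in order), drop any column linearly dependent on the
# base columns plus earlier X columns. Returns names of kept columns.
drop_collinear <- function(base, X) {
  if (ncol(X) == 0) return(character())
  kept <- character()
  M <- base
  for (j in seq_len(ncol(X))) {
    cand <- cbind(M, X[, j])
    if (qr(cand)$rank > qr(M)$rank) {
      M <- cand
      kept <- c(kept, colnames(X)[j])
    } else {
      warn(sprintf("Candidate indicator '%s' is collinear with earlier terms; dropped.",
                   colnames(X)[j]))
    }
  }
  kept
}

#' @export
print.mpge_model <- function(x, ...) {
  cat(sprintf("Combinatorial MPGE model for %s\n  a_m = %.4f over %d genes; %d TF(s) retained\n",
              x$mirna, x$mirna_coefficient, length(x$genes), nrow(x$tf_table)))
  if (nrow(x$tf_table) > 0) print(x$tf_table)
  invisible(x)
}

#' @export
tidy.mpge_model <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = x$mirna, role = "miRNA",
                   estimate = x$mirna_coefficient, p_value = x$mirna_p_value),
    tibble::tibble(term = x$tf_table$tf, role = "TF",
                   estimate = x$tf_table$coefficient,
                   p_value = x$tf_table$p_value)
  )
}

#' @export
glance.mpge_model <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    r_squared = s$r.squared, adj_r_squared = s$adj.r.squared,
    sigma = s$sigma, aic = stats::AIC(x$fit),
    n_genes = length(x$genes), n_tfs_retained = nrow(x$tf_table)
  )
}

#' Assemble the two-layer network centred on the perturbed miRNA
#'
#' The first layer connects the perturbed miRNA to its refined direct
#' targets and to its mediating TFs — retained model TFs that are
#' themselves putative targets of the miRNA in the `miR2gene` library. The
#' second layer connects every retained TF to its library targets among the
#' modelled genes. miRNA -> target edges are weighted by `a_m`, TF -> gene
#' edges by the TF's fitted coefficient; miRNA -> TF edges carry no
#' separate coefficient.
#'
#' @param model An [fit_combinatorial_model()] result.
#' @param refined_targets Character vector of refined direct targets, or
#'   the tibble from [refine_targets()] (its `refined` rows are used).
#' @param mir2gene,tf2gene The regulation libraries.
#' @return A [regulatory_network]. Only miRNA -> TF, miRNA -> gene,
#'   TF -> gene and TF -> TF edges can occur.
#' @export
build_two_layer_network <- function(model, refined_targets, mir2gene, tf2gene) {
  stopifnot(inherits(model, "mpge_model"))
  check_library_class(mir2gene, "miR2gene", "mir2gene")
  check_library_class(tf2gene, "TF2gene", "tf2gene")
  if (is.data.frame(refined_targets)) {
    refined_targets <- refined_targets$gene[refined_targets$refined]
  }
  m <- model$mirna
  tfs <- model$tf_table$tf
  mir_putative <- mir2gene$target[mir2gene$regulator == m]
  mediating <- intersect(tfs, mir_putative)

  direct <- setdiff(intersect(refined_targets, model$genes), mediating)
  tf_edges <- tf2gene |>
    dplyr::filter(.data$regulator %in% tfs, .data$target %in% model$genes,
                  .data$target != m) |>
    dplyr::left_join(
      tibble::tibble(regulator = model$tf_table$tf,
                     w = model$tf_table$coefficient),
      by = "regulator"
    )

  edges <- dplyr::bind_rows(
    tibble::tibble(from = m, to = direct, edge_class = "miR2gene",
                   weight = model$mirna_coefficient),
    tibble::tibble(from = m, to = mediating, edge_class = "miR2gene",
                   weight = NA_real_),
    tibble::tibble(from = tf_edges$regulator, to = tf_edges$target,
                   edge_class = "TF2gene", weight = tf_edges$w)
  ) |>
    dplyr::distinct(.data$from, .data$to, .keep_all = TRUE)

  ids <- unique(c(edges$from, edges$to))
  nodes <- tibble::tibble(
    id = ids,
    type = dplyr::case_when(ids == m ~ "MIRNA",
                            ids %in% tfs ~ "TF",
                            TRUE ~ "GENE")
  )
  regulatory_network(edges, nodes)
}
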