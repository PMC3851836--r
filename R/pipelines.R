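#' Run the full MPGE analysis and write a report bundle
#'
#' Executes the complete miRNA-perturbation workflow — K-S degradation
#' test, target refinement, TF pre-filter, stepwise combinatorial model,
#' two-layer network assembly — and writes the three report sections as
#' tab-delimited files into `out_dir`:
#' \describe{
#'   \item{`targets.txt`}{putative targets with empirical and adjusted
#'     p-values and the refined flag}
#'   \item{`pp_plot.txt`}{paired empirical CDF coordinates of the
#'     degradation PP-plot}
#'   \item{`mediator_tfs.txt`}{retained TFs with coefficients, p-values
#'     and the mediating flag}
#'   \item{`network.edge.txt`}{the two-layer network edge list (source,
#'     target, edge_type, weight)}
#'   \item{`run_config.txt`}{the thresholds used, echoed for provenance}
#' }
#' The workflow is deterministic: rerunning with the same inputs gives
#' byte-identical outputs.
#'
#' @param dataset An [mpge_dataset], or a path to an MPGE CSV file (then
#'   `mirna` must name the perturbed miRNA).
#' @param mir2gene,tf2gene Regulation libraries, or paths to library
#'   files.
#' @param out_dir Output directory (created if missing).
#' @param alpha FDR level of target refinement (default 0.05).
#' @param p_prefilter Univariate TF pre-filter threshold (default 0.01).
#' @param mirna Perturbed miRNA identifier when `dataset` is a path.
#' @return Invisibly, a list with the `ks` result, `targets`,
#'   `mediators`, `model` and `network`.
#' @export
run_mpge <- function(dataset, mir2gene, tf2gene, out_dir,
                     alpha = 0.05, p_prefilter = 0.01, mirna = NULL) {
  if (is.character(dataset)) {
    if (is.null(mirna)) abort("`mirna` is required when `dataset` is a file path.")
    dataset <- read_mpge(dataset, mirna)
  }
  if (is.character(mir2gene)) mir2gene <- read_regulation_library(mir2gene, "miR2gene")
  if (is.character(tf2gene)) tf2gene <- read_regulation_library(tf2gene, "TF2gene")
  if (!dataset$mirna %in% mir2gene$regulator) {
    abort(sprintf("Perturbed miRNA '%s' has no entry in the miR2gene library.",
                  dataset$mirna))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ks <- ks_degradation_test(dataset, mir2gene)
  targets <- refine_targets(dataset, mir2gene, alpha = alpha)
  candidates <- prefilter_tfs(dataset, tf2gene, p_threshold = p_prefilter)
  model <- fit_combinatorial_model(dataset, targets, candidates, tf2gene)
  network <- build_two_layer_network(model, targets, mir2gene, tf2gene)

  mediating <- intersect(model$tf_table$tf,
                         mir2gene$target[mir2gene$regulator == dataset$mirna])
  mediators <- dplyr::mutate(model$tf_table,
                             mediating = .data$tf %in% mediating)

  readr::write_tsv(targets, file.path(out_dir, "targets.txt"))
  readr::write_tsv(ks$pp_points, file.path(out_dir, "pp_plot.txt"))
  readr::write_tsv(mediators, file.path(out_dir, "mediator_tfs.txt"))
  write_network_edges(network, file.path(out_dir, "network.edge.txt"))
  write_run_config(file.path(out_dir, "run_config.txt"), list(
    module = "mpge", mirna = dataset$mirna, n_genes = nrow(dataset$ratios),
    alpha = alpha, p_prefilter = p_prefilter,
    ks_statistic = ks$statistic, ks_p_value = ks$p_value,
    mirna_coefficient = model$mirna_coefficient
  ))
  inform(sprintf(
    "MPGE run for %s: D+ = %.3f (p = %.3g), %d/%d targets refined, %d TF(s) retained (%d mediating).",
    dataset$mirna, ks$statistic, ks$p_value, sum(targets$refined),
    nrow(targets), nrow(model$tf_table), length(mediating)
  ))
  invisible(list(ks = ks, targets = targets, mediators = mediators,
                 model = model, network = network))
}

#' Run the full parallel-expression analysis and write a report bundle
#'
#' Infers the genome-wide combinatorial network from a parallel
#' miRNA/mRNA dataset, then runs the topology analytics, writing into
#' `out_dir`: `network.edge.txt` (edge list with coefficients and
#' p-values), `vertex_ranking.txt`, `edge_ranking.txt`,
#' `coregulating_pairs.txt`, `motif_significance.txt` (always all 18
#' catalog rows), `motif_instances.txt` and `run_config.txt`. With a
#' fixed `seed` reruns are byte-identical.
#'
#' @param dataset A [parallel_dataset], or the path to the miRNA matrix
#'   (then `mrna_path` must give the mRNA matrix).
#' @param tf2gene,tf2mir,mir2gene Regulation libraries or paths.
#' @param out_dir Output directory (created if missing).
#' @param config A [parallel_config()].
#' @param pair_alpha Report threshold of the co-regulation test (default
#'   0.01).
#' @param motif_replicates Shuffled replicates for motif significance
#'   (default 1000).
#' @param seed Seed for the motif null model.
#' @param mrna_path mRNA matrix path when `dataset` is a path.
#' @return Invisibly, a list with `network`, `vertices`, `edges`,
#'   `pairs` and `motifs`.
#' @export
run_parallel <- function(dataset, tf2gene, tf2mir, mir2gene, out_dir,
                         config = parallel_config(), pair_alpha = 0.01,
                         motif_replicates = 1000, seed = 1,
                         mrna_path = NULL) {
  if (is.character(dataset)) {
    if (is.null(mrna_path)) abort("`mrna_path` is required when `dataset` is a file path.")
    dataset <- read_parallel_dataset(dataset, mrna_path)
  }
  if (is.character(tf2gene)) tf2gene <- read_regulation_library(tf2gene, "TF2gene")
  if (is.character(tf2mir)) tf2mir <- read_regulation_library(tf2mir, "TF2miR")
  if (is.character(mir2gene)) mir2gene <- read_regulation_library(mir2gene, "miR2gene")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  network <- fit_parallel_network(dataset, tf2gene, tf2mir, mir2gene, config)
  res <- run_topology(network, out_dir, pair_alpha = pair_alpha,
                      motif_replicates = motif_replicates, seed = seed,
                      .config_extra = list(
                        module = "parallel",
                        n_conditions = length(dataset$conditions),
                        p_survivor = config$p_survivor,
                        repression_only = config$repression_only
                      ))
  invisible(res)
}

#' Topology report for an existing network
#'
#' Runs vertex/edge ranking, co-regulating pair detection and motif
#' significance on a network (or an edge-list file) and writes the
#' tables described under [run_parallel()].
#'
#' @param network A [regulatory_network] or the path to an edge list in
#'   [write_network_edges()] format.
#' @inheritParams run_parallel
#' @param .config_extra Internal; extra provenance entries.
#' @return Invisibly, a list with `network`, `vertices`, `edges`,
#'   `pairs` and `motifs`.
#' @export
run_topology <- function(network, out_dir, pair_alpha = 0.01,
                         motif_replicates = 1000, seed = 1,
                         .config_extra = list(module = "topology")) {
  if (is.character(network)) network <- read_network_edges(network)
  stopifnot(inherits(network, "regulatory_network"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  empty <- nrow(network$edges) == 0
  vertices <- if (empty) {
    tibble::tibble(id = character(), type = character(),
                   in_degree = integer(), out_degree = integer(),
                   degree = integer(), betweenness = double(),
                   degree_rank = integer(), betweenness_rank = integer())
  } else {
    rank_vertices(network)
  }
  edges <- rank_edges(network)
  n_regulators <- dplyr::n_distinct(network$edges$from)
  pairs <- if (n_regulators >= 2) {
    coregulating_pairs(network, alpha = pair_alpha)
  } else {
    tibble::tibble(regulator_a = character(), regulator_b = character(),
                   n_targets_a = integer(), n_targets_b = integer(),
                   shared = integer(), universe = integer(),
                   p_value = double())
  }
  motifs <- if (empty) {
    m <- dplyr::mutate(enumerate_motif_types(), observed = 0L,
                       null_mean = 0, p_value = 1)
    attr(m, "instances") <- tibble::tibble(
      v1 = character(), v2 = character(), v3 = character(),
      canonical_code = character()
    )
    m
  } else {
    suppressWarnings(
      motif_pvalues(network, replicates = motif_replicates, seed = seed)
    )
  }
  instances <- attr(count_motif_instances(network), "instances") %||%
    tibble::tibble(v1 = character(), v2 = character(), v3 = character(),
                   canonical_code = character())

  write_network_edges(network, file.path(out_dir, "network.edge.txt"))
  readr::write_tsv(vertices, file.path(out_dir, "vertex_ranking.txt"))
  readr::write_tsv(edges, file.path(out_dir, "edge_ranking.txt"))
  readr::write_tsv(pairs, file.path(out_dir, "coregulating_pairs.txt"))
  readr::write_tsv(as.data.frame(motifs), file.path(out_dir, "motif_significance.txt"))
  readr::write_tsv(instances, file.path(out_dir, "motif_instances.txt"))
  write_run_config(file.path(out_dir, "run_config.txt"), c(.config_extra, list(
    pair_alpha = pair_alpha, motif_replicates = motif_replicates, seed = seed,
    n_nodes = nrow(network$nodes), n_edges = nrow(network$edges)
  )))
  inform(sprintf(
    "Topology run: %d nodes, %d edges, %d co-regulating pair(s) at p < %g, %d motif instance(s).",
    nrow(network$nodes), nrow(network$edges), nrow(pairs), pair_alpha,
    nrow(instances)
  ))
  invisible(list(network = network, vertices = vertices, edges = edges,
                 pairs = pairs, motifs = motifs))
}

write_run_config <- function(path, entries) {
  writeLines(sprintf("%s=%s", names(entries),
                     vapply(entries, format, "", digits = 15)), path)
  invisible(path)
}
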