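#' Simulate a miRNA-perturbed gene expression experiment
#'
#' Generates an MPGE dataset together with the miR2gene and TF2gene
#' libraries and the planted ground truth, for validating the MPGE engine
#' without external data. Per-gene log-ratios follow the additive linear
#' model the engine assumes:
#' `E_g = mir_effect * b_mg + sum_i a_TFi * b_TFig + N(0, noise_sd)`.
#'
#' The perturbed miRNA receives `n_mir_targets` planted direct targets
#' (shifted by `mir_effect`), `n_decoy_targets` decoy targets (library
#' edges with zero effect) and one library edge to every effective TF —
#' the planted mediating TFs, whose own expression rows are shifted like
#' any direct target. Each TF targets `targets_per_tf` genes drawn from
#' the background (disjoint from the miRNA's planted and decoy target
#' sets, so that each planted mechanism is separately identifiable);
#' `n_decoy_tfs` additional TFs have zero effect. All draws are governed
#' by `seed`; identical seeds give identical output.
#'
#' @param n_genes Number of background protein-coding genes (default 2000).
#' @param n_mir_targets Planted direct targets of the miRNA (default 50).
#' @param n_decoy_targets Zero-effect library targets (default 50).
#' @param mir_effect Log-ratio shift of true targets (default -2).
#' @param tf_effects Coefficients of the effective (mediating) TFs
#'   (default `c(1, -1, 0.8)`).
#' @param n_decoy_tfs Zero-effect TFs in the library (default 7).
#' @param targets_per_tf Library targets per TF (default 100).
#' @param noise_sd Additive Gaussian noise standard deviation (default 0.5).
#' @param mirna Identifier of the perturbed miRNA.
#' @param seed Integer seed (required).
#' @return A list with `dataset` ([mpge_dataset]), `mir2gene`, `tf2gene`
#'   ([regulation_library]s) and `truth` — a list holding
#'   `direct_targets`, `decoy_targets`, `mediator_tfs` (named coefficient
#'   vector), `decoy_tfs`, `mir_effect`, `noise_sd`, `seed`.
#' @export
simulate_mpge <- function(n_genes = 2000, n_mir_targets = 50,
                          n_decoy_targets = 50, mir_effect = -2,
                          tf_effects = c(1, -1, 0.8), n_decoy_tfs = 7,
                          targets_per_tf = 100, noise_sd = 0.5,
                          mirna = "hsa-miR-901", seed) {
  if (missing(seed)) abort("`seed` is required for reproducible simulation.")
  if (n_mir_targets + n_decoy_targets > n_genes) {
    abort("More planted miRNA targets than genes.")
  }
  n_tfs <- length(tf_effects) + n_decoy_tfs
  if (n_tfs > 0 && targets_per_tf > n_genes - n_mir_targets - n_decoy_targets) {
    abort("`targets_per_tf` exceeds the available background gene pool.")
  }
  withr::with_seed(seed, {
    genes <- sprintf("G%05d", seq_len(n_genes))
    tfs <- if (n_tfs > 0) sprintf("TF%02d", seq_len(n_tfs)) else character()
    eff_tfs <- utils::head(tfs, length(tf_effects))
    decoy_tfs <- setdiff(tfs, eff_tfs)

    pick <- sample(genes, n_mir_targets + n_decoy_targets)
    direct <- pick[seq_len(n_mir_targets)]
    decoys <- setdiff(pick, direct)
    background <- setdiff(genes, pick)

    tf_lib <- purrr::map(tfs, function(tf) {
      tibble::tibble(regulator = tf,
                     target = sample(background, targets_per_tf))
    }) |> dplyr::bind_rows()
    if (nrow(tf_lib) == 0) {
      tf_lib <- tibble::tibble(regulator = character(), target = character())
    }

    mir_lib <- tibble::tibble(
      regulator = mirna, target = c(direct, decoys, eff_tfs)
    )

    e <- setNames(numeric(n_genes), genes)
    e[direct] <- e[direct] + mir_effect
    for (i in seq_along(eff_tfs)) {
      e[tf_lib$target[tf_lib$regulator == eff_tfs[i]]] <-
        e[tf_lib$target[tf_lib$regulator == eff_tfs[i]]] + tf_effects[i]
    }
    e_tf <- setNames(rep(0, n_tfs), tfs)
    e_tf[eff_tfs] <- mir_effect   # mediators are degraded targets themselves
    ratios <- c(e, e_tf)
    ratios <- ratios + stats::rnorm(length(ratios), 0, noise_sd)

    list(
      dataset = mpge_dataset(mirna, ratios),
      mir2gene = regulation_library(mir_lib, "miR2gene"),
      tf2gene = regulation_library(tf_lib, "TF2gene"),
      truth = list(
        direct_targets = direct,
        decoy_targets = decoys,
        mediator_tfs = setNames(tf_effects, eff_tfs),
        decoy_tfs = decoy_tfs,
        mir_effect = mir_effect,
        noise_sd = noise_sd,
        seed = seed
      )
    )
  })
}

#' Simulate a parallel miRNA/mRNA expression dataset
#'
#' Generates paired expression matrices over shared conditions, the three
#' regulation libraries and the planted regulatory network, for validating
#' the parallel engine. TF profiles are i.i.d. standard normal per
#' condition; each miRNA is a planted linear combination of its regulating
#' TFs plus noise; each gene is a planted linear combination of its TF and
#' miRNA regulators plus noise. Planted coefficients are drawn uniformly
#' from `[coeff_range[1], coeff_range[2]]` with random sign. Libraries
#' contain the planted edges plus `decoy_ratio` times as many random
#' type-legal decoy edges. A gene is never assigned both a miRNA and one
#' of that miRNA's own driver TFs: at zero noise their profiles are
#' exactly collinear and the planted coefficients would be
#' unidentifiable.
#'
#' @param n_conditions Number of shared conditions (default 60).
#' @param n_tfs,n_mirnas,n_genes Numbers of TFs, miRNAs and non-TF genes
#'   (defaults 15, 10, 100).
#' @param regulators_per_gene Inclusive range of planted regulators per
#'   gene, sampled uniformly (default `c(0, 3)`).
#' @param tfs_per_mirna Inclusive range of planted TF regulators per miRNA
#'   (default `c(1, 2)`).
#' @param coeff_range Magnitude range of planted coefficients (default
#'   `c(0.5, 2)`).
#' @param noise_sd Additive Gaussian noise sd (default 0.5).
#' @param decoy_ratio Decoy edges per planted edge in each library
#'   (default 1).
#' @param seed Integer seed (required).
#' @return A list with `dataset` ([parallel_dataset]), `tf2gene`,
#'   `tf2mir`, `mir2gene` ([regulation_library]s) and `truth` — a list
#'   holding `edges` (tibble `from`, `to`, `edge_class`, `coefficient`),
#'   `noise_sd`, `seed`.
#' @export
simulate_parallel <- function(n_conditions = 60, n_tfs = 15, n_mirnas = 10,
                              n_genes = 100, regulators_per_gene = c(0, 3),
                              tfs_per_mirna = c(1, 2),
                              coeff_range = c(0.5, 2), noise_sd = 0.5,
                              decoy_ratio = 1, seed) {
  if (missing(seed)) abort("`seed` is required for reproducible simulation.")
  if (n_conditions < 3) abort("At least 3 conditions are required.")
  withr::with_seed(seed, {
    conds <- sprintf("C%02d", seq_len(n_conditions))
    tfs <- sprintf("TF%02d", seq_len(n_tfs))
    mirs <- sprintf("hsa-miR-9%02d", seq_len(n_mirnas))
    genes <- sprintf("G%04d", seq_len(n_genes))

    draw_coef <- function(k) {
      runif(k, coeff_range[1], coeff_range[2]) * sample(c(-1, 1), k, replace = TRUE)
    }
    tf_prof <- matrix(rnorm(n_tfs * n_conditions), n_tfs,
                      dimnames = list(tfs, conds))

    sample_count <- function(range) {
      ks <- seq(range[1], range[2])
      ks[sample.int(length(ks), 1)]
    }
    mir_truth <- purrr::map(mirs, function(m) {
      k <- sample_count(tfs_per_mirna)
      if (k == 0) return(NULL)
      tibble::tibble(from = sample(tfs, k), to = m, edge_class = "TF2miR",
                     coefficient = draw_coef(k))
    }) |> dplyr::bind_rows()
    mir_prof <- matrix(rnorm(n_mirnas * n_conditions, 0, noise_sd), n_mirnas,
                       dimnames = list(mirs, conds))
    for (i in seq_len(nrow(mir_truth))) {
      mir_prof[mir_truth$to[i], ] <- mir_prof[mir_truth$to[i], ] +
        mir_truth$coefficient[i] * tf_prof[mir_truth$from[i], ]
    }

    regulators <- c(tfs, mirs)
    # planted regulator sets must be identifiable at zero noise, where every
    # miRNA profile is an exact combination of its driver TFs: expressed in
    # the TF basis, the selected regulators' profiles must be linearly
    # independent (e.g. a miRNA together with its sole driver TF, or two
    # miRNAs sharing one driver, would be exactly collinear)
    basis_row <- function(reg) {
      v <- numeric(n_tfs)
      if (reg %in% tfs) {
        v[match(reg, tfs)] <- 1
      } else {
        sel <- mir_truth$to == reg
        v[match(mir_truth$from[sel], tfs)] <- mir_truth$coefficient[sel]
      }
      v
    }
    keep_independent <- function(regs) {
      kept <- character()
      M <- NULL
      for (reg in regs) {
        cand <- rbind(M, basis_row(reg))
        if (qr(cand)$rank == nrow(cand)) {
          M <- cand
          kept <- c(kept, reg)
        }
      }
      kept
    }
    gene_truth <- purrr::map(genes, function(g) {
      k <- sample_count(regulators_per_gene)
      if (k == 0) return(NULL)
      regs <- keep_independent(sample(regulators, k))
      if (length(regs) == 0) return(NULL)
      tibble::tibble(from = regs, to = g,
                     edge_class = ifelse(regs %in% mirs, "miR2gene", "TF2gene"),
                     coefficient = draw_coef(length(regs)))
    }) |> dplyr::bind_rows()
    gene_prof <- matrix(rnorm(n_genes * n_conditions, 0, noise_sd), n_genes,
                        dimnames = list(genes, conds))
    for (i in seq_len(nrow(gene_truth))) {
      src <- gene_truth$from[i]
      prof <- if (src %in% mirs) mir_prof[src, ] else tf_prof[src, ]
      gene_prof[gene_truth$to[i], ] <- gene_prof[gene_truth$to[i], ] +
        gene_truth$coefficient[i] * prof
    }

    truth_edges <- dplyr::bind_rows(gene_truth, mir_truth)
    if (nrow(truth_edges) == 0) {
      truth_edges <- tibble::tibble(from = character(), to = character(),
                                    edge_class = character(),
                                    coefficient = double())
    }
    libs <- purrr::map(
      c(TF2gene = "TF2gene", TF2miR = "TF2miR", miR2gene = "miR2gene"),
      function(cls) {
        planted <- dplyr::filter(truth_edges, .data$edge_class == cls)
        from_pool <- if (cls == "miR2gene") mirs else tfs
        to_pool <- if (cls == "TF2miR") mirs else c(genes, tfs)
        all_pairs <- tidyr::expand_grid(regulator = from_pool, target = to_pool) |>
          dplyr::filter(.data$regulator != .data$target) |>
          dplyr::anti_join(
            tibble::tibble(regulator = planted$from, target = planted$to),
            by = c("regulator", "target")
          )
        n_decoys <- min(nrow(all_pairs), round(decoy_ratio * nrow(planted)))
        decoys <- all_pairs[sample.int(nrow(all_pairs), n_decoys), ]
        lib <- dplyr::bind_rows(
          tibble::tibble(regulator = planted$from, target = planted$to),
          decoys
        )
        if (nrow(lib) == 0) {
          warn(sprintf("Planted %s library is empty.", cls))
        }
        regulation_library(lib, cls)
      }
    )

    mrna <- rbind(gene_prof, tf_prof)
    list(
      dataset = parallel_dataset(mir_prof, mrna),
      tf2gene = libs$TF2gene,
      tf2mir = libs$TF2miR,
      mir2gene = libs$miR2gene,
      truth = list(edges = truth_edges, noise_sd = noise_sd, seed = seed)
    )
  })
}
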