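make_mpge <- function(target_vals, nontarget_vals, mirna = "hsa-miR-1") {
  n_t <- length(target_vals)
  n_n <- length(nontarget_vals)
  genes <- c(sprintf("T%03d", seq_len(n_t)), sprintf("N%03d", seq_len(n_n)))
  dataset <- mpge_dataset(mirna, setNames(c(target_vals, nontarget_vals), genes))
  lib <- regulation_library(
    data.frame(regulator = mirna, target = sprintf("T%03d", seq_len(n_t))),
    "miR2gene"
  )
  list(dataset = dataset, mir2gene = lib)
}

test_that("K-S degradation test: identical distributions give D+ = 0, p = 1", {
  fx <- make_mpge(c(-1, 0, 1), c(-1, 0, 1))
  res <- ks_degradation_test(fx$dataset, fx$mir2gene)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$n_targets + res$n_nontargets, 6)
})

test_that("K-S degradation test detects a planted down-shift", {
  non <- withr::with_seed(11, rnorm(100))
  fx <- make_mpge(non - 1.0, non)
  res <- ks_degradation_test(fx$dataset, fx$mir2gene)
  expect_lt(res$p_value, 1e-6)
  expect_gt(res$statistic, 0.3)
  # PP coordinates are valid paired ECDFs
  expect_true(all(diff(res$pp_points$cdf_targets) >= 0))
  expect_equal(max(res$pp_points$cdf_targets), 1)
  expect_equal(max(res$pp_points$cdf_nontargets), 1)
})

test_that("K-S exact p agrees with a permutation oracle within MC error", {
  withr::with_seed(21, {
    non <- rnorm(60)
    tgt <- rnorm(40) - 0.45
  })
  fx <- make_mpge(tgt, non)
  res <- ks_degradation_test(fx$dataset, fx$mir2gene)
  expect_true(res$exact)
  p_perm <- oracle_perm_ks(tgt, non, B = 2e4)
  se <- sqrt(p_perm * (1 - p_perm) / 2e4)
  expect_lt(abs(res$p_value - p_perm), 3 * se + 1e-6)
})

test_that("K-S test preconditions are enforced", {
  fx <- make_mpge(c(-1, 0), c(0, 1))
  other <- regulation_library(
    data.frame(regulator = "hsa-miR-999", target = "X1"), "miR2gene"
  )
  expect_error(ks_degradation_test(fx$dataset, other), "No putative target")
  all_targets <- regulation_library(
    data.frame(regulator = "hsa-miR-1",
               target = fx$dataset$ratios$gene), "miR2gene"
  )
  expect_error(ks_degradation_test(fx$dataset, all_targets), "non-target")
})

test_that("refinement p-values follow the empirical rank formula", {
  non <- withr::with_seed(3, rnorm(999))
  fx <- make_mpge(c(min(non) - 1, stats::median(non)), non)
  tg <- refine_targets(fx$dataset, fx$mir2gene, alpha = 0.05)
  below_all <- tg[tg$log_ratio < min(non), ]
  expect_equal(below_all$p_value, 1 / 1000)
  at_median <- tg[tg$log_ratio == stats::median(non), ]
  expect_gt(at_median$p_value, 0.5)
  expect_false(at_median$refined)
  expect_error(refine_targets(fx$dataset, fx$mir2gene, alpha = 0), "alpha")
  expect_error(refine_targets(fx$dataset, fx$mir2gene, alpha = 1.2), "alpha")
})

test_that("refinement recovers planted targets and rejects decoys", {
  sim <- simulate_mpge(n_genes = 1000, n_mir_targets = 50, n_decoy_targets = 50,
                       mir_effect = -2, tf_effects = numeric(0), n_decoy_tfs = 0,
                       noise_sd = 0.5, seed = 5)
  tg <- refine_targets(sim$dataset, sim$mir2gene)
  refined <- tg$gene[tg$refined]
  expect_gte(sum(sim$truth$direct_targets %in% refined), 45)
  expect_lte(sum(sim$truth$decoy_targets %in% refined), 5)
})

test_that("refinement is invariant under monotone transforms of the ratios", {
  sim <- simulate_mpge(n_genes = 300, n_mir_targets = 25, n_decoy_targets = 25,
                       targets_per_tf = 40, seed = 9)
  tg1 <- refine_targets(sim$dataset, sim$mir2gene)
  warped <- sim$dataset
  warped$ratios$log_ratio <- sinh(warped$ratios$log_ratio / 2)
  tg2 <- refine_targets(warped, sim$mir2gene)
  expect_equal(tg1$p_value[order(tg1$gene)], tg2$p_value[order(tg2$gene)])
  expect_identical(sort(tg1$gene[tg1$refined]), sort(tg2$gene[tg2$refined]))
})

test_that("TF pre-filter retains effective TFs and drops null ones", {
  genes <- sprintf("G%03d", 1:60)
  vals <- rep(0, 60)
  vals[1:10] <- -3                      # TF1 targets, perfect separation
  dataset <- mpge_dataset("hsa-miR-1", setNames(vals, genes))
  lib <- regulation_library(dplyr::bind_rows(
    data.frame(regulator = "TFA", target = genes[1:10]),
    data.frame(regulator = "TFB", target = genes[c(11:15, 26:30)])  # null
  ), "TF2gene")
  res <- prefilter_tfs(dataset, lib, p_threshold = 0.01)
  expect_identical(res$tf, "TFA")
  expect_lt(res$p_value, 1e-10)
})

test_that("TF pre-filter ranks match a two-sample t-test oracle", {
  sim <- simulate_mpge(seed = 31)
  res <- prefilter_tfs(sim$dataset, sim$tf2gene, p_threshold = 1)
  # oracle: equal-variance two-sample t test per TF
  genes <- sim$dataset$ratios$gene
  e <- sim$dataset$ratios$log_ratio
  oracle_p <- vapply(res$tf, function(tf) {
    b <- genes %in% sim$tf2gene$target[sim$tf2gene$regulator == tf]
    stats::t.test(e[b], e[!b], var.equal = TRUE)$p.value
  }, 0)
  expect_equal(res$p_value, unname(oracle_p), tolerance = 1e-12)
  # effective TFs head the list at the default threshold
  top <- prefilter_tfs(sim$dataset, sim$tf2gene)$tf
  expect_setequal(utils::head(top, 3), names(sim$truth$mediator_tfs))
})

test_that("TFs with constant indicators are skipped with a warning", {
  genes <- sprintf("G%03d", 1:20)
  dataset <- mpge_dataset("hsa-miR-1", setNames(rnorm(20), genes))
  lib <- regulation_library(dplyr::bind_rows(
    data.frame(regulator = "TFALL", target = genes),
    data.frame(regulator = "TFA", target = genes[1:5])
  ), "TF2gene")
  expect_warning(prefilter_tfs(dataset, lib, p_threshold = 1), "constant")
})

test_that("stepwise combinatorial fit is exact on noiseless data", {
  genes <- sprintf("G%03d", 1:100)
  b_m <- as.numeric(seq_along(genes) <= 30)
  b_t1 <- as.numeric(seq_along(genes) %in% c(11:40, 91:100))
  e <- -2 * b_m + 1.5 * b_t1
  dataset <- mpge_dataset("hsa-miR-1", setNames(e, genes))
  lib <- regulation_library(dplyr::bind_rows(
    data.frame(regulator = "TF1", target = genes[b_t1 == 1]),
    data.frame(regulator = "TF2", target = genes[51:70])
  ), "TF2gene")
  mod <- fit_combinatorial_model(dataset, genes[b_m == 1], c("TF1", "TF2"), lib)
  expect_equal(mod$mirna_coefficient, -2, tolerance = 1e-10)
  expect_identical(mod$tf_table$tf, "TF1")
  expect_equal(mod$tf_table$coefficient, 1.5, tolerance = 1e-10)
})

test_that("stepwise fit on an all-zero response retains nothing", {
  genes <- sprintf("G%03d", 1:50)
  dataset <- mpge_dataset("hsa-miR-1", setNames(rep(0, 50), genes))
  lib <- regulation_library(
    data.frame(regulator = "TF1", target = genes[1:10]), "TF2gene"
  )
  mod <- fit_combinatorial_model(dataset, genes[21:30], "TF1", lib)
  expect_equal(mod$mirna_coefficient, 0)
  expect_equal(nrow(mod$tf_table), 0)
})

test_that("planted mediator TFs are recovered with sign-correct coefficients", {
  sim <- simulate_mpge(n_genes = 3000, mir_effect = -1.5, noise_sd = 0.3,
                       seed = 17)
  tg <- refine_targets(sim$dataset, sim$mir2gene)
  cand <- prefilter_tfs(sim$dataset, sim$tf2gene)
  mod <- fit_combinatorial_model(sim$dataset, tg, cand, sim$tf2gene)
  truth <- sim$truth$mediator_tfs
  expect_true(all(names(truth) %in% mod$tf_table$tf))
  fitted <- setNames(mod$tf_table$coefficient, mod$tf_table$tf)[names(truth)]
  expect_true(all(abs(fitted - truth) < 0.2))
  expect_true(all(sign(fitted) == sign(truth)))
})

test_that("collinear candidate indicators are dropped with a warning", {
  genes <- sprintf("G%03d", 1:40)
  e <- withr::with_seed(2, rnorm(40))
  dataset <- mpge_dataset("hsa-miR-1", setNames(e, genes))
  lib <- regulation_library(dplyr::bind_rows(
    data.frame(regulator = "TF1", target = genes[1:10]),
    data.frame(regulator = "TF2", target = genes[1:10])   # same column
  ), "TF2gene")
  expect_warning(
    mod <- fit_combinatorial_model(dataset, genes[30:35], c("TF1", "TF2"), lib),
    "collinear"
  )
  expect_false("TF2" %in% mod$candidates[mod$candidates %in% mod$tf_table$tf])
})

test_that("two-layer assembly wires miRNA, mediators and targets correctly", {
  genes <- c(sprintf("G%03d", 1:40), "TFM")
  b_m <- genes %in% c(sprintf("G%03d", 1:10), "TFM")
  b_t <- genes %in% sprintf("G%03d", c(5, 11, 12))
  e <- -2 * b_m + 1.2 * b_t
  dataset <- mpge_dataset("hsa-miR-1", setNames(e, genes))
  mir2gene <- regulation_library(
    data.frame(regulator = "hsa-miR-1", target = genes[b_m]), "miR2gene"
  )
  tf2gene <- regulation_library(
    data.frame(regulator = "TFM", target = genes[b_t]), "TF2gene"
  )
  tg <- refine_targets(dataset, mir2gene)
  mod <- fit_combinatorial_model(dataset, tg, "TFM", tf2gene)
  net <- build_two_layer_network(mod, tg, mir2gene, tf2gene)
  type_of <- setNames(net$nodes$type, net$nodes$id)
  expect_identical(unname(type_of[["TFM"]]), "TF")
  expect_identical(unname(type_of[["hsa-miR-1"]]), "MIRNA")
  # the mediator is reached from the miRNA and feeds its own targets
  expect_true(any(net$edges$from == "hsa-miR-1" & net$edges$to == "TFM"))
  expect_setequal(net$edges$to[net$edges$from == "TFM"],
                  sprintf("G%03d", c(5, 11, 12)))
  # module-level edge-type invariant: no TF -> miRNA, no gene out-edges
  expect_false(any(net$edges$edge_class == "TF2miR"))
  expect_false(any(type_of[net$edges$from] == "GENE"))
})

test_that("with no TFs retained the two-layer network is a star", {
  fx <- make_mpge(rep(-2, 5), withr::with_seed(8, rnorm(50)))
  tg <- refine_targets(fx$dataset, fx$mir2gene)
  lib <- regulation_library(
    data.frame(regulator = "TFX", target = "N001"), "TF2gene"
  )
  mod <- fit_combinatorial_model(fx$dataset, tg, character(), lib)
  net <- build_two_layer_network(mod, tg, fx$mir2gene, lib)
  expect_true(all(net$edges$from == "hsa-miR-1"))
  expect_setequal(net$edges$to, tg$gene[tg$refined])
})

test_that("MPGE CSV round-trips and malformed files are rejected", {
  sim <- simulate_mpge(n_genes = 50, n_mir_targets = 10, n_decoy_targets = 5,
                       tf_effects = numeric(0), n_decoy_tfs = 0, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_mpge(sim$dataset, path)
  back <- read_mpge(path, sim$dataset$mirna)
  expect_equal(back$ratios, sim$dataset$ratios)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,ratio", "A,1.0", "B,notanumber"), bad)
  expect_error(read_mpge(bad, "hsa-miR-1"), "line 3")
})
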