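test_that("vertex and edge betweenness follow shortest-path counting", {
  # miRNA -> TF -> gene path: the middle vertex carries the single path
  p <- regulatory_network(data.frame(from = c("hsa-miR-9", "T1"),
                                     to = c("T1", "G1")))
  rv <- rank_vertices(p)
  expect_equal(rv$betweenness[rv$id == "T1"], 1)
  expect_equal(rv$betweenness[rv$id != "T1"], c(0, 0))

  # 3-cycle (TF, TF, miRNA): full symmetry, all degrees equal
  cyc <- regulatory_network(data.frame(from = c("T1", "T2", "hsa-miR-9"),
                                       to = c("T2", "hsa-miR-9", "T1")))
  rvc <- rank_vertices(cyc)
  expect_true(all(rvc$in_degree == 1) && all(rvc$out_degree == 1))
  expect_equal(length(unique(rvc$betweenness)), 1)
})

test_that("betweenness matches the brute-force all-pairs oracle", {
  for (s in 1:4) {
    net <- random_typed_network(seed = 600 + s, n_nodes = 25)
    rv <- rank_vertices(net)
    re <- rank_edges(net)
    oracle <- oracle_betweenness(net$edges, net$nodes$id)
    expect_equal(setNames(rv$betweenness, rv$id)[names(oracle$vertex)],
                 oracle$vertex, tolerance = 1e-9)
    key <- paste(net$edges$from, net$edges$to)
    expect_equal(setNames(re$betweenness, paste(re$from, re$to))[key],
                 setNames(oracle$edge, key), tolerance = 1e-9)
  }
})

test_that("co-regulation p-values are one-sided hypergeometric tails", {
  # identical single target in a 2-target universe
  net <- regulatory_network(data.frame(
    from = c("T1", "T2", "T3"), to = c("G1", "G1", "G2")
  ))
  pr <- coregulating_pairs(net, alpha = 1)
  p12 <- pr$p_value[pr$regulator_a == "T1" & pr$regulator_b == "T2"]
  expect_equal(p12, 0.5, tolerance = 1e-12)

  # universe 20, |A| = |B| = 10, 9 shared: closed form 101/184756
  e <- rbind(data.frame(from = "T1", to = sprintf("G%02d", 1:10)),
             data.frame(from = "T2", to = sprintf("G%02d", c(1:9, 11))),
             data.frame(from = "T3", to = sprintf("G%02d", 12:20)))
  pr2 <- coregulating_pairs(regulatory_network(e), alpha = 1)
  expect_equal(pr2$p_value[pr2$regulator_a == "T1" & pr2$regulator_b == "T2"],
               101 / 184756, tolerance = 1e-12)
  # disjoint pair: p = 1 under the enrichment alternative, filtered at 0.01
  expect_equal(pr2$p_value[pr2$regulator_a == "T1" & pr2$regulator_b == "T3"], 1)
  pr3 <- coregulating_pairs(regulatory_network(e), alpha = 0.01)
  expect_equal(nrow(pr3), 1)

  solo <- regulatory_network(data.frame(from = "T1", to = "G1"))
  expect_error(coregulating_pairs(solo), "at least two regulators")
})

test_that("the motif catalog has 18 types with the expected breakdown", {
  ct <- enumerate_motif_types()
  expect_equal(nrow(ct), 18)
  comp <- table(ct$composition)
  expect_equal(unname(comp[["TF+MIRNA+GENE"]]), 3)
  expect_equal(unname(comp[["TF+TF+MIRNA"]]), 15)
  expect_false("TF+MIRNA+MIRNA" %in% names(comp))
  expect_false(anyDuplicated(ct$canonical_code) > 0)

  # brute-force configuration enumerator agrees per composition
  expect_equal(length(oracle_enumerate_types(c("TF", "MIRNA", "GENE"))), 3)
  expect_equal(length(oracle_enumerate_types(c("TF", "TF", "MIRNA"))), 15)
  expect_equal(length(oracle_enumerate_types(c("TF", "MIRNA", "MIRNA"))), 0)

  # FFL/FBL split: acyclic motifs are FFLs, any cycle is an FBL
  expect_setequal(unique(ct$loop_class), c("FFL", "FBL"))
  expect_equal(sum(ct$loop_class == "FFL"), 5)
})

test_that("single closed triads are classified and counted once", {
  ffl <- regulatory_network(data.frame(
    from = c("T1", "hsa-miR-9", "T1"),
    to = c("hsa-miR-9", "G1", "G1")
  ))
  mc <- count_motif_instances(ffl)
  expect_equal(sum(mc$count), 1)
  hit <- mc[mc$count == 1, ]
  expect_identical(hit$loop_class, "FFL")
  expect_identical(hit$composition, "TF+MIRNA+GENE")
  inst <- attr(mc, "instances")
  expect_equal(nrow(inst), 1)

  no_mir <- regulatory_network(data.frame(from = c("T1", "T2", "T1"),
                                          to = c("G1", "G1", "G2")))
  expect_equal(sum(count_motif_instances(no_mir)$count), 0)
})

test_that("motif counts equal exhaustive triple enumeration on random networks", {
  for (s in 1:4) {
    net <- random_typed_network(seed = 700 + s, n_nodes = 25, p_edge = 0.15)
    mc <- count_motif_instances(net)
    inst <- attr(mc, "instances")
    got <- split(paste(inst$v1, inst$v2, inst$v3, sep = "|"),
                 inst$canonical_code)
    oracle <- oracle_motif_counts(net)
    want <- split(oracle$triple, oracle$key)
    # identical partition of the same triple set into isomorphism classes
    expect_setequal(unlist(got, use.names = FALSE), oracle$triple)
    expect_setequal(
      unname(vapply(got, function(x) paste(sort(x), collapse = ";"), "")),
      unname(vapply(want, function(x) paste(sort(x), collapse = ";"), ""))
    )
    # every instance maps to a catalog entry (catalog completeness)
    expect_true(all(inst$canonical_code %in% enumerate_motif_types()$canonical_code))
  }
})

test_that("shuffling preserves typed in/out degrees within each edge class", {
  net <- random_typed_network(seed = 42, n_nodes = 30, p_edge = 0.1)
  deg_sig <- function(n) {
    e <- n$edges
    list(out = sort(paste(e$from, e$edge_class)),
         inn = sort(paste(e$to, e$edge_class)))
  }
  ref <- deg_sig(net)
  withr::with_seed(9, {
    for (r in 1:20) {
      sh <- suppressWarnings(shuffle_network(net))
      expect_identical(deg_sig(sh), ref)
    }
  })
})

test_that("motif significance is seeded, reproducible and bounded", {
  # degenerate bound: one replicate, absent motif type has p = 1
  small <- regulatory_network(data.frame(
    from = c("T1", "hsa-miR-9", "T1"),
    to = c("hsa-miR-9", "G1", "G1")
  ))
  mp1 <- suppressWarnings(motif_pvalues(small, replicates = 1, seed = 1))
  expect_true(all(mp1$p_value[mp1$observed == 0] == 1))
  expect_true(all(mp1$p_value > 0 & mp1$p_value <= 1))

  # planted enrichment: disjoint FFLs + background are significant at 0.05
  k <- 10
  planted <- dplyr::bind_rows(
    data.frame(from = sprintf("T%02d", 1:k), to = sprintf("hsa-miR-7%02d", 1:k)),
    data.frame(from = sprintf("T%02d", 1:k), to = sprintf("G%02d", 1:k)),
    data.frame(from = sprintf("hsa-miR-7%02d", 1:k), to = sprintf("G%02d", 1:k))
  )
  background <- data.frame(
    from = rep(sprintf("T%02d", 1:k), each = 2),
    to = c(sprintf("G%02d", c(11:20, 21:30)))
  )
  net <- regulatory_network(dplyr::bind_rows(planted, background))
  mp <- motif_pvalues(net, replicates = 200, seed = 11)
  ffl_row <- mp[mp$observed >= k, ]
  expect_gte(nrow(ffl_row), 1)
  expect_lte(min(ffl_row$p_value), 0.05)

  mp_again <- motif_pvalues(net, replicates = 200, seed = 11)
  expect_identical(mp$p_value, mp_again$p_value)
})
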