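make_regulon <- function(tf, targets, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(targets))
  structure(list(tf = tf, targets = targets,
                 weights = stats::setNames(weights, targets)),
            class = "regulon")
}
as_regulon_list <- function(...) {
  rl <- list(...)
  names(rl) <- vapply(rl, `[[`, character(1), "tf")
  structure(rl, class = "regulon_list")
}

test_that("TF graph weights follow Jaccard and direct-regulation rules", {
  rl <- as_regulon_list(
    make_regulon("TFA", c("G1", "G2", "G3")),
    make_regulon("TFB", c("G1", "G2", "G4")),
    make_regulon("TFC", c("G9", "G8")))

  g <- build_tf_graph(rl, "shared_target_jaccard")
  e <- g$edges
  expect_equal(e$weight[e$tf1 == "TFA" & e$tf2 == "TFB"], 2 / 4)
  expect_false(any(e$tf1 == "TFC" | e$tf2 == "TFC"))  # disjoint: no edge
  expect_true(all(e$weight >= 0 & e$weight <= 1))
  expect_true(all(e$tf1 != e$tf2))

  # identical target sets -> weight 1
  rl2 <- as_regulon_list(make_regulon("TFA", c("G1", "G2")),
                         make_regulon("TFB", c("G1", "G2")))
  expect_equal(build_tf_graph(rl2)$edges$weight, 1)

  # direct regulation sums both directions
  rl3 <- as_regulon_list(
    make_regulon("TFA", c("TFB", "G1"), c(0.7, 0.1)),
    make_regulon("TFB", c("TFA", "G2"), c(0.2, 0.1)))
  g3 <- build_tf_graph(rl3, "direct_regulation")
  expect_equal(g3$edges$weight, 0.9)

  expect_error(build_tf_graph(rl, "nope"))
  expect_error(build_tf_graph(as_regulon_list()), "at least one")
})

test_that("five-regulon Jaccard matrix equals direct set arithmetic", {
  set.seed(5)
  pools <- lapply(1:5, function(i) sample(sprintf("G%02d", 1:30), 8))
  rl <- do.call(as_regulon_list, lapply(1:5, function(i)
    make_regulon(sprintf("TF%d", i), pools[[i]])))
  g <- build_tf_graph(rl)
  for (i in 1:4) for (j in (i + 1):5) {
    jac <- length(intersect(pools[[i]], pools[[j]])) /
      length(union(pools[[i]], pools[[j]]))
    row <- g$edges[g$edges$tf1 == sprintf("TF%d", i) &
                   g$edges$tf2 == sprintf("TF%d", j), ]
    if (jac == 0) expect_equal(nrow(row), 0)
    else expect_equal(row$weight, jac)
  }
})

test_that("component clustering matches connected components", {
  rl <- as_regulon_list(
    make_regulon("TFA", c("G1", "G2")), make_regulon("TFB", c("G2", "G3")),
    make_regulon("TFC", c("H1", "H2")), make_regulon("TFD", c("H2", "H3")))
  g <- build_tf_graph(rl)
  cl <- cluster_regulons(g, method = "components")
  expect_equal(cl$k, 2)
  expect_equal(cl$cluster_of_tf[["TFA"]], cl$cluster_of_tf[["TFB"]])
  expect_equal(cl$cluster_of_tf[["TFC"]], cl$cluster_of_tf[["TFD"]])
  expect_false(cl$cluster_of_tf[["TFA"]] == cl$cluster_of_tf[["TFC"]])
})

test_that("single TF forms a singleton cluster and k is validated", {
  rl <- as_regulon_list(make_regulon("TFA", c("G1", "G2")))
  g <- build_tf_graph(rl)
  cl <- cluster_regulons(g)
  expect_equal(cl$k, 1)
  expect_equal(unname(cl$cluster_of_tf), 1L)
  expect_error(cluster_regulons(g, k = 5), "exceeds")
})

test_that("planted block structure is recovered and order-invariant", {
  planted_graph <- function(n_blocks, per_block, seed) {
    set.seed(seed)
    tfs <- sprintf("TF%02d", seq_len(n_blocks * per_block))
    block <- rep(seq_len(n_blocks), each = per_block)
    edges <- list()
    for (i in seq_along(tfs)) for (j in seq_along(tfs)) {
      if (i >= j) next
      w <- if (block[i] == block[j]) stats::runif(1, 0.6, 1)
           else stats::runif(1, 0, 0.05)
      edges[[length(edges) + 1]] <-
        data.frame(tf1 = tfs[i], tf2 = tfs[j], weight = w)
    }
    list(graph = structure(list(nodes = tfs, edges = do.call(rbind, edges),
                                weight_kind = "shared_target_jaccard"),
                           class = "tf_graph"),
         truth = block)
  }
  ok <- 0
  for (s in 1:5) {
    pg <- planted_graph(4, 3, s)
    cl <- cluster_regulons(pg$graph, k = 4)
    if (ari(cl$cluster_of_tf, pg$truth) >= 0.9) ok <- ok + 1
  }
  expect_gte(ok, 4)

  # silhouette selection finds the planted k without being told
  pg <- planted_graph(4, 3, 99)
  cl_auto <- cluster_regulons(pg$graph)
  expect_equal(cl_auto$k, 4)

  # node input order does not change the partition (fixed k)
  pg2 <- planted_graph(3, 4, 7)
  g_rev <- pg2$graph
  g_rev$nodes <- rev(g_rev$nodes)
  cl_a <- cluster_regulons(pg2$graph, k = 3)
  cl_b <- cluster_regulons(g_rev, k = 3)
  tfs <- pg2$graph$nodes
  expect_equal(ari(cl_a$cluster_of_tf[tfs], cl_b$cluster_of_tf[tfs]), 1)
})

test_that("role deconvolution applies the within-cluster out-degree rule", {
  rl <- as_regulon_list(
    make_regulon("TFA", c("TFB", "G1", "G2"), c(0.9, 0.5, 0.4)),
    make_regulon("TFB", c("G2", "G3"), c(0.8, 0.2)),
    make_regulon("TFC", c("H1", "H2"), c(0.6, 0.3)))
  g <- build_tf_graph(rl)
  cl <- cluster_regulons(g, method = "components")
  cl <- deconvolute_roles(cl, rl)

  lab_a <- cl$cluster_of_tf[["TFA"]]
  roles_a <- cl$roles[[as.character(lab_a)]]
  # TFs regulating cluster members are upstream regulators
  expect_true(all(c("TFA", "TFB") %in% roles_a$subset_b))
  # target-only genes are end targets
  expect_true(all(c("G1", "G2", "G3") %in% roles_a$subset_a))

  # partition is exhaustive and exclusive in every cluster
  for (lab in names(cl$clusters)) {
    r <- cl$roles[[lab]]
    expect_length(intersect(r$subset_a, r$subset_b), 0)
    expect_setequal(c(r$subset_a, r$subset_b), cl$clusters[[lab]])
  }
})

test_that("shared targets go to the cluster with the strongest edge", {
  rl <- as_regulon_list(
    make_regulon("TFA", c("G1", "G2"), c(0.9, 0.3)),
    make_regulon("TFB", c("G1", "G3"), c(0.4, 0.5)))
  g <- structure(list(nodes = c("TFA", "TFB"),
                      edges = data.frame(tf1 = character(0),
                                         tf2 = character(0),
                                         weight = numeric(0)),
                      weight_kind = "shared_target_jaccard"),
                 class = "tf_graph")
  cl <- cluster_regulons(g, method = "components")
  expect_equal(cl$k, 2)
  cl <- deconvolute_roles(cl, rl)
  cl_of <- function(g) {
    hits <- vapply(cl$clusters, function(m) g %in% m, logical(1))
    as.integer(names(which(hits)))
  }
  expect_equal(cl_of("G1"), unname(cl$cluster_of_tf[["TFA"]]))  # 0.9 > 0.4
  expect_length(cl_of("G1"), 1)                                  # only once
})

test_that("noise-free round trip recovers an 18-regulator/37-target split", {
  tr <- generate_grn_truth(18, 10, 1, reg_fraction = 0, end_pool_size = 37,
                           seed = 1)
  b <- simulate_bulk(tr, 150, noise_sd = 1e-6, n_decoys = 0, seed = 2)
  et <- infer_network(b$expression, tr$tf_ids, n_trees = 100, seed = 3)
  rl <- build_regulons(threshold_edges(et, 1), min_targets = 1)
  g <- build_tf_graph(rl)
  cl <- deconvolute_roles(cluster_regulons(g, k = 1), rl)
  expect_equal(cl$counts$n_upstream_regulators, 18)
  expect_equal(cl$counts$n_end_targets, 37)
  expect_setequal(cl$roles[["1"]]$subset_b, tr$tf_ids)
  expect_setequal(cl$roles[["1"]]$subset_a,
                  names(tr$role_of_gene)[tr$role_of_gene == "end_target"])
})
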