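# Randomization ensembles and the Wilcoxon/FDR topology comparison.

test_that("node sampling: exhaustive sample reproduces the network, n=1 is edgeless", {
  set.seed(2)
  g <- random_graph(15, 0.3)
  ens_all <- sample_node_subnetworks(g$edges, n_nodes = 15,
                                     replicates = 3, rng_seed = 1)
  for (rep in ens_all$replicates) {
    expect_identical(rep$edges[, c("from", "to")],
                     methprior:::canonical_edges(g$edges))
  }
  ens1 <- sample_node_subnetworks(g$edges, 1, replicates = 5, rng_seed = 1)
  expect_true(all(vapply(ens1$replicates,
                         function(r) nrow(r$edges) == 0L, logical(1))))
  expect_error(sample_node_subnetworks(g$edges, 100), "exceeds")
})

test_that("induced-subgraph edge counts match the sampling expectation", {
  set.seed(3)
  g <- random_graph(40, 0.25)
  n_sub <- 20L
  ens <- sample_node_subnetworks(g$edges, n_sub, replicates = 300,
                                 rng_seed = 7)
  mean_edges <- mean(vapply(ens$replicates, function(r) nrow(r$edges),
                            numeric(1)))
  # each edge survives iff both endpoints are sampled:
  # P = n(n-1) / (N(N-1)) without replacement
  expected <- nrow(g$edges) * n_sub * (n_sub - 1) / (40 * 39)
  expect_lt(abs(mean_edges - expected) / expected, 0.1)
  expect_lt(mean_edges, nrow(g$edges))
})

test_that("tertile binning splits ranks into thirds with ID tie-breaks", {
  bins <- methprior:::tertile_bins(1:9, letters[1:9])
  expect_equal(bins, rep(1:3, each = 3))
  # massive ties: deterministic split by ID order
  tied <- methprior:::tertile_bins(rep(0, 6), letters[1:6])
  expect_equal(tied, rep(1:3, each = 2))
})

test_that("topology-matched draws come from the matching degree-clustering cell", {
  set.seed(4)
  g <- random_graph(30, 0.25)
  stats_tbl <- graph_clustering(g$edges)
  cells <- paste0(
    "d", methprior:::tertile_bins(stats_tbl$degree, stats_tbl$gene),
    "c", methprior:::tertile_bins(stats_tbl$clustering, stats_tbl$gene))
  names(cells) <- stats_tbl$gene
  target <- sample(stats_tbl$gene, 12)
  ens <- sample_topology_matched(g$edges, target, replicates = 20,
                                 rng_seed = 9)
  for (rep in ens$replicates) {
    expect_equal(length(rep$nodes), 12L)
    expect_equal(anyDuplicated(rep$nodes), 0L)
    # multiset of cells of drawn nodes equals the targets' multiset
    expect_equal(sort(unname(cells[rep$nodes])),
                 sort(unname(cells[target])))
  }
  # identical seeds give identical ensembles
  ens2 <- sample_topology_matched(g$edges, target, replicates = 20,
                                  rng_seed = 9)
  expect_identical(ens$replicates, ens2$replicates)
})

test_that("degree-preserving rewiring keeps every node's degree exactly", {
  set.seed(6)
  g <- random_graph(20, 0.25)
  deg0 <- graph_degrees(g$edges, g$nodes)
  ens <- rewire_degree_preserving(g$edges, replicates = 25, rng_seed = 3)
  for (rep in ens$replicates) {
    d <- graph_degrees(rep$edges, rep$nodes)
    expect_equal(d$degree[match(deg0$gene, d$gene)], deg0$degree)
    expect_false(any(rep$edges$from == rep$edges$to))
    expect_equal(anyDuplicated(paste(rep$edges$from, rep$edges$to)), 0L)
  }
})

test_that("rigid graphs rewire to themselves; 4-cycles stay 4-cycles", {
  tri <- tibble::tibble(from = c("A", "A", "B"), to = c("B", "C", "C"))
  ens <- rewire_degree_preserving(tri, replicates = 10, rng_seed = 1)
  for (rep in ens$replicates) {
    expect_identical(rep$edges[, c("from", "to")],
                     methprior:::canonical_edges(tri))
  }
  cyc <- tibble::tibble(from = c("A", "B", "C", "A"),
                        to = c("B", "C", "D", "D"))
  ens4 <- rewire_degree_preserving(cyc, replicates = 20, rng_seed = 2)
  for (rep in ens4$replicates) {
    d <- graph_degrees(rep$edges, rep$nodes)
    expect_equal(d$degree, rep(2L, 4))
    g <- igraph::graph_from_data_frame(rep$edges, directed = FALSE)
    expect_true(igraph::is_connected(g))   # a single 4-cycle
  }
  expect_error(rewire_degree_preserving(
    tibble::tibble(from = "A", to = "B")), "2 edges")
})

test_that("the Wilcoxon comparison behaves at its boundaries", {
  set.seed(8)
  g <- random_graph(20, 0.3)
  self_ens <- sample_node_subnetworks(g$edges, length(g$nodes),
                                      replicates = 5, rng_seed = 2)
  cmp <- compare_topology(g$edges, self_ens, metrics = "degree")
  expect_gte(cmp$p_value, 0.9)   # identical distributions

  # complete separation at n >= 50 per group
  p_sep <- suppressWarnings(
    wilcox.test(rep(10, 50) + runif(50), runif(50),
                exact = FALSE)$p.value)
  expect_lt(p_sep, 1e-6)

  expect_error(compare_topology(g$edges, list()), "ensemble")
})

test_that("q-values are monotone in p-values and flagged at the FDR level", {
  set.seed(12)
  g <- random_graph(25, 0.3)
  ens <- sample_node_subnetworks(g$edges, 10, replicates = 30,
                                 rng_seed = 5)
  cmp <- compare_topology(g$edges, ens)
  ord <- order(cmp$p_value)
  expect_true(all(diff(cmp$q_value[ord]) >= -1e-12))
  expect_equal(cmp$significant, cmp$q_value < attr(cmp, "fdr_level"))
})
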