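# Synthetic-data generator: graph shape, planted correlations, seeds,
# expression, determinism.

test_that("preferential attachment yields the pinned edge counts and a simple connected graph", {
  e <- simulate_ppi(sim_config(n_genes = 5, attachment_m = 1, n_seeds = 0,
                            n_planted_candidates = 0, rng_seed = 1))
  expect_equal(nrow(e), 4L)   # m = 1 gives a tree on n nodes
  g <- igraph::graph_from_data_frame(e, directed = FALSE)
  expect_true(igraph::is_connected(g))
  expect_equal(igraph::ecount(g), igraph::vcount(g) - 1L)

  e2 <- simulate_ppi(sim_config(n_genes = 200, attachment_m = 3, n_seeds = 0,
                                n_planted_candidates = 0, rng_seed = 2))
  expect_equal(nrow(e2), 3L * (200L - 3L))   # m (n - m)
  expect_false(any(e2$from == e2$to))
  expect_equal(anyDuplicated(paste(e2$from, e2$to)), 0L)
  g2 <- igraph::graph_from_data_frame(e2, directed = FALSE)
  expect_true(igraph::is_connected(g2))
  expect_true(all(grepl("^G\\d{6}$", c(e2$from, e2$to))))
})

test_that("invalid configurations are rejected naming the offending field", {
  expect_error(sim_config(n_genes = 3, attachment_m = 3), "n_genes")
  expect_error(sim_config(rho_planted = 0), "rho_planted")
  expect_error(sim_config(frac_true_edges = 1.2), "frac_true_edges")
  expect_error(sim_config(n_seeds = 400, n_planted_candidates = 200,
                          n_genes = 500), "n_seeds")
})

test_that("methylation values are beta-like and planted edges carry the target correlation", {
  cfg <- sim_config(n_genes = 300, n_samples = 100, frac_true_edges = 0.2,
                    rho_planted = 0.8, rng_seed = 5)
  e <- simulate_ppi(cfg)
  meth <- simulate_methylation(cfg, e)
  m <- as.matrix(meth[, -1]); rownames(m) <- meth$gene
  expect_true(all(m >= 0 & m <= 1))

  pe <- attr(meth, "planted_edges")
  expect_gt(nrow(pe), 20)
  r <- vapply(seq_len(nrow(pe)), function(i)
    cor(m[pe$from[i], ], m[pe$to[i], ]), numeric(1))
  # squash distortion stays within the 0.1 calibration tolerance
  expect_lt(abs(mean(abs(r)) - 0.8), 0.1)
  expect_true(all(sign(r) == pe$sign))
})

test_that("planted-correlation calibration holds across seeds and the null decays", {
  vals <- vapply(1:3, function(s) {
    cfg <- sim_config(n_genes = 200, n_samples = 100, frac_true_edges = 0.2,
                      rho_planted = 0.8, rng_seed = s)
    e <- simulate_ppi(cfg)
    meth <- simulate_methylation(cfg, e)
    m <- as.matrix(meth[, -1]); rownames(m) <- meth$gene
    pe <- attr(meth, "planted_edges")
    mean(abs(vapply(seq_len(nrow(pe)), function(i)
      cor(m[pe$from[i], ], m[pe$to[i], ]), numeric(1))))
  }, numeric(1))
  expect_true(all(abs(vals - 0.8) < 0.1))

  cfg0 <- sim_config(n_genes = 100, n_samples = 500, attachment_m = 2,
                     n_seeds = 0, n_planted_candidates = 0,
                     frac_true_edges = 0, rng_seed = 9)
  e0 <- simulate_ppi(cfg0)
  meth0 <- simulate_methylation(cfg0, e0)
  m0 <- as.matrix(meth0[, -1]); rownames(m0) <- meth0$gene
  r0 <- vapply(seq_len(nrow(e0)), function(i)
    cor(m0[e0$from[i], ], m0[e0$to[i], ]), numeric(1))
  expect_lt(mean(abs(r0)), 0.1)
})

test_that("a duplicated profile under the identity squash correlates exactly", {
  cfg <- sim_config(n_genes = 50, n_samples = 30, attachment_m = 1,
                    n_seeds = 0, n_planted_candidates = 0,
                    frac_true_edges = 1, rho_planted = 1,
                    frac_negative = 0, squash = "identity", rng_seed = 2)
  e <- simulate_ppi(cfg)
  meth <- simulate_methylation(cfg, e)
  m <- as.matrix(meth[, -1]); rownames(m) <- meth$gene
  pe <- attr(meth, "planted_edges")
  r <- vapply(seq_len(nrow(pe)), function(i)
    cor(m[pe$from[i], ], m[pe$to[i], ]), numeric(1))
  expect_equal(r, rep(1, nrow(pe)))
})

test_that("degenerate sample counts are refused", {
  cfg <- sim_config(n_genes = 20, n_samples = 3, attachment_m = 1,
                    n_seeds = 0, n_planted_candidates = 0)
  e <- simulate_ppi(cfg)
  expect_error(simulate_methylation(cfg, e), "degenerate")
})

test_that("seed designation and candidate planting respect adjacency", {
  cfg <- sim_config(n_genes = 150, n_samples = 20, n_seeds = 10,
                    n_planted_candidates = 5, rng_seed = 4)
  e <- simulate_ppi(cfg)
  sd <- simulate_seeds(cfg, e)
  expect_equal(nrow(sd$seeds), 10L)
  expect_true(all(lengths(sd$seeds$types) >= 1 &
                    lengths(sd$seeds$types) <= 4))
  # every planted candidate is adjacent to its anchor seed
  key <- paste(pmin(sd$planted_candidates$gene, sd$planted_candidates$seed),
               pmax(sd$planted_candidates$gene, sd$planted_candidates$seed))
  expect_true(all(key %in% paste(e$from, e$to)))
  expect_false(any(sd$planted_candidates$gene %in% sd$seeds$gene))

  cfg0 <- sim_config(n_genes = 150, n_seeds = 0,
                     n_planted_candidates = 0)
  sd0 <- simulate_seeds(cfg0, e)
  expect_equal(nrow(sd0$seeds), 0L)
  expect_equal(nrow(sd0$planted_candidates), 0L)

  cfg_bad <- sim_config(n_genes = 10, attachment_m = 1, n_seeds = 2,
                        n_planted_candidates = 1)
  one_edge <- tibble::tibble(from = "A", to = "B")
  expect_error(simulate_seeds(cfg_bad, one_edge), "not enough")
})

test_that("expression planting produces detectable shifts and respects class minima", {
  cfg <- sim_config(n_genes = 100, n_seeds = 0, n_planted_candidates = 0,
                    n_de_genes = 10, de_effect = 3,
                    n_case = 20, n_control = 20, rng_seed = 6)
  ex <- simulate_expression(cfg, sprintf("G%06d", 1:100))
  m <- as.matrix(ex$expression[, -1]); rownames(m) <- ex$expression$gene
  is_case <- ex$labels$class == "case"
  tstat <- apply(m[ex$de_genes, ], 1, function(x)
    t.test(x[is_case], x[!is_case])$statistic)
  expect_gte(mean(tstat > 2), 0.9)

  cfg_bad <- sim_config(n_case = 2, n_control = 20, n_seeds = 0,
                        n_planted_candidates = 0)
  expect_error(simulate_expression(cfg_bad, "G000001"), "3 samples")
})

test_that("the bundle is deterministic in its seed and truth sets are consistent", {
  cfg <- sim_config(n_genes = 80, n_samples = 20, attachment_m = 2,
                    n_seeds = 8, n_planted_candidates = 4, n_de_genes = 3,
                    rng_seed = 42)
  b1 <- simulate_bundle(cfg)
  b2 <- simulate_bundle(cfg)
  expect_identical(b1$edges, b2$edges)
  expect_identical(b1$methylation$gene, b2$methylation$gene)
  expect_identical(as.matrix(b1$methylation[, -1]),
                   as.matrix(b2$methylation[, -1]))
  expect_identical(b1$seeds, b2$seeds)
  expect_identical(b1$truth, b2$truth)

  universe <- unique(c(b1$edges$from, b1$edges$to))
  expect_true(all(b1$truth$planted_candidates$gene %in% universe))
  expect_true(all(b1$truth$de_genes %in% b1$expression$expression$gene))

  # byte-identical files from identical seeds
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_bundle(b1, d1); write_bundle(b2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})
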