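# Readers/writers: edge lists, probe collapsing, matrices, GraphML.

test_that("edge lists deduplicate, drop self-loops and report malformed lines", {
  f <- withr::local_tempfile(lines = c("A\tB", "B\tA", "A\tA"))
  expect_message(e <- read_edge_list(f, header = FALSE), "self-loop")
  expect_equal(nrow(e), 1L)
  expect_equal(e$from, "A"); expect_equal(e$to, "B")

  f3 <- withr::local_tempfile(
    lines = c("from\tto", "A\tB", "C\tD", "E\tF"))
  expect_equal(nrow(read_edge_list(f3)), 3L)

  fbad <- withr::local_tempfile(lines = c("A\tB", "loner", "C\tD"))
  expect_error(read_edge_list(fbad, header = FALSE), "line 2")

  fempty <- withr::local_tempfile(lines = "# only a comment")
  expect_error(read_edge_list(fempty, header = FALSE), "no edges")
})

test_that("edge loading is insensitive to input line order", {
  lines <- c("G2\tG7", "G1\tG9", "G3\tG2", "G7\tG2")
  f1 <- withr::local_tempfile(lines = lines)
  f2 <- withr::local_tempfile(lines = rev(lines))
  expect_identical(read_edge_list(f1, header = FALSE),
                   read_edge_list(f2, header = FALSE))
})

test_that("probe collapsing averages probes within genes", {
  probes <- tibble::tibble(probe = c("p1", "p2"), s1 = c(0.2, 0.4))
  ann <- tibble::tibble(probe = c("p1", "p2"), gene = c("geneX", "geneX"))
  out <- collapse_probes(probes, ann)
  expect_equal(out$s1, 0.3)

  probes3 <- tibble::tibble(probe = c("p1", "p2", "p3", "q1"),
                            s1 = c(0.1, 0.2, 0.6, 0.5),
                            s2 = c(0.0, 0.3, 0.9, 0.5))
  ann3 <- tibble::tibble(probe = c("p1", "p2", "p3", "q1"),
                         gene = c("gA", "gA", "gA", "gB"))
  out3 <- collapse_probes(probes3, ann3)
  expect_equal(out3$s1[out3$gene == "gA"], 0.3)
  expect_equal(out3$s2[out3$gene == "gA"], 0.4)
  # single-probe gene passes through unchanged
  expect_equal(out3$s1[out3$gene == "gB"], 0.5)

  expect_error(collapse_probes(
    tibble::tibble(probe = c("p1", "p1"), s1 = c(0.1, 0.2)), ann),
    "duplicate probe")
  expect_message(collapse_probes(
    tibble::tibble(probe = c("p1", "zz"), s1 = c(0.1, 0.2)), ann),
    "unmapped")
  expect_error(collapse_probes(
    tibble::tibble(probe = "zz", s1 = 0.1), ann), "no probe")
})

test_that("methylation loading enforces the beta-value range", {
  tbl <- tibble::tibble(gene = c("a", "b"), s1 = c(0.5, 1.4),
                        s2 = c(0.1, 0.2))
  f <- withr::local_tempfile()
  readr::write_tsv(tbl, f)
  expect_error(read_methylation(f), "outside")
  expect_message(out <- read_methylation(f, clip = TRUE), "clipped")
  expect_equal(out$s1[2], 1)

  tbl_na <- tibble::tibble(gene = "a", s1 = NA_real_)
  fna <- withr::local_tempfile(); readr::write_tsv(tbl_na, fna)
  expect_error(read_methylation(fna), "issing|non-numeric")
})

test_that("matrix and seed tables round-trip through TSV", {
  cfg <- sim_config(n_genes = 40, n_samples = 8, attachment_m = 1,
                    n_seeds = 5, n_planted_candidates = 2,
                    n_de_genes = 3, rng_seed = 3)
  b <- simulate_bundle(cfg)
  f <- withr::local_tempfile()
  write_methylation(b$methylation, f)
  back <- read_methylation(f)
  expect_equal(as.matrix(back[, -1]), as.matrix(b$methylation[, -1]),
               tolerance = 1e-12)

  fs <- withr::local_tempfile()
  write_seed_genes(b$seeds, fs)
  seeds2 <- read_seed_genes(fs)
  expect_identical(seeds2$gene, b$seeds$gene)
  expect_identical(seeds2$types, b$seeds$types)
})

test_that("GraphML round-trips networks losslessly", {
  w <- make_whpn(c("n1"), c("n2"), -0.7)
  f <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(w, f)
  back <- read_graphml(f)
  expect_equal(back$edges$weight, -0.7)
  expect_equal(sort(back$nodes$gene), c("n1", "n2"))

  # empty network still produces valid GraphML
  f0 <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(tibble::tibble(from = character(0), to = character(0)), f0)
  expect_equal(nrow(read_graphml(f0)$nodes), 0L)

  # a CASN survives with roles, categories and weights intact
  w2 <- make_whpn(c("s1", "s1", "c1"), c("c1", "c2", "c2"),
                  c(0.9, -0.5, 0.3))
  casn <- extract_casn(w2, make_seeds("s1", list(c("gbm", "ovarian"))))
  f2 <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(casn, f2)
  back2 <- read_graphml(f2)
  expect_equal(nrow(back2$nodes), nrow(casn$nodes))
  expect_equal(back2$nodes$is_seed,
               casn$nodes$role[match(back2$nodes$gene,
                                     casn$nodes$gene)] == "seed")
  expect_equal(back2$nodes$category,
               casn$nodes$category[match(back2$nodes$gene,
                                         casn$nodes$gene)])
  expect_equal(dplyr::arrange(back2$edges, from, to),
               dplyr::arrange(casn$edges, from, to))
})

test_that("expression loading validates labels", {
  cfg <- sim_config(n_genes = 10, attachment_m = 1, n_seeds = 0,
                    n_planted_candidates = 0, n_case = 3,
                    n_control = 3, n_de_genes = 0)
  ex <- simulate_expression(cfg, sprintf("G%06d", 1:10))
  fe <- withr::local_tempfile(); fl <- withr::local_tempfile()
  write_matrix_tsv(ex$expression, fe)
  readr::write_tsv(ex$labels, fl)
  back <- read_expression(fe, fl)
  expect_equal(back$labels$class, ex$labels$class)

  readr::write_tsv(dplyr::mutate(ex$labels, class = "weird"), fl)
  expect_error(read_expression(fe, fl), "case")
})
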