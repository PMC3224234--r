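# Randomization null models: uniform node sampling, topology-matched node
# sampling, and degree-preserving edge rewiring, plus the Wilcoxon/FDR
# comparison of topology statistics against these ensembles.

new_ensemble <- function(scheme, replicates, rng_seed) {
  structure(list(scheme = scheme, replicates = replicates,
                 n_replicates = length(replicates),
                 rng_seed = as.integer(rng_seed)),
            class = "network_ensemble")
}

#' @export
print.network_ensemble <- function(x, ...) {
  cat("<network_ensemble> scheme:", x$scheme, "-", x$n_replicates,
      "replicates\n")
  invisible(x)
}

induced_edges <- function(edges, nodes) {
  edges[edges$from %in% nodes & edges$to %in% nodes, , drop = FALSE]
}

#' Random subnetworks by uniform node sampling
#'
#' Each replicate is the induced subgraph of the network on a uniform
#' sample of `n_nodes` nodes drawn without replacement (connections among
#' sampled nodes are kept).
#'
#' @param whpn a `whpn` object or edge tibble defining the parent network.
#' @param n_nodes nodes per replicate (at most the parent's node count).
#' @param replicates number of replicates (default 1000).
#' @param rng_seed integer seed.
#' @return a `network_ensemble` whose replicates are lists with `nodes`
#'   and induced `edges`.
#' @export
sample_node_subnetworks <- function(whpn, n_nodes, replicates = 1000L,
                                    rng_seed = 1L) {
  edges <- as_network_edges(whpn)
  universe <- sort(unique(c(edges$from, edges$to)))
  if (n_nodes > length(universe)) {
    stop("n_nodes (", n_nodes, ") exceeds the network's node count (",
         length(universe), ")")
  }
  with_substream(rng_seed, "node_sample", {
    reps <- lapply(seq_len(replicates), function(i) {
      nodes <- sample(universe, n_nodes)
      list(nodes = sort(nodes), edges = induced_edges(edges, nodes))
    })
    new_ensemble("node_sample", reps, rng_seed)
  })
}

# Split nodes into tertiles by value rank, ties broken by node ID order.
tertile_bins <- function(values, ids) {
  n <- length(values)
  bins <- integer(n)
  bins[order(values, ids)] <- ceiling(3 * seq_len(n) / n)
  bins
}

#' Topology-matched random subnetworks
#'
#' Parent-network nodes are split into degree tertiles and clustering
#' tertiles (rank splits, ties broken by node ID); crossing them yields nine
#' topological cells. For each replicate, every target node is replaced by a
#' node drawn from the same cell (without replacement within a cell), and
#' the induced subgraph on the drawn nodes is returned.
#'
#' @inheritParams sample_node_subnetworks
#' @param target_nodes character vector of nodes to match (e.g. the CASN
#'   node set); must be a subset of the parent network's nodes.
#' @return a `network_ensemble`; each replicate carries `nodes`, `edges`
#'   and `cells` (the cell label of every drawn node, for auditing).
#' @export
sample_topology_matched <- function(whpn, target_nodes, replicates = 1000L,
                                    rng_seed = 1L) {
  edges <- as_network_edges(whpn)
  stats_tbl <- graph_clustering(edges)   # gene, degree, clustering
  if (nrow(stats_tbl) < 9L) stop("parent network needs at least 9 nodes")
  missing <- setdiff(target_nodes, stats_tbl$gene)
  if (length(missing)) {
    stop("target node(s) absent from the parent network: ",
         paste(utils::head(missing, 3L), collapse = ", "))
  }
  stats_tbl$cell <- paste0(
    "d", tertile_bins(stats_tbl$degree, stats_tbl$gene),
    "c", tertile_bins(stats_tbl$clustering, stats_tbl$gene))
  cell_of <- stats::setNames(stats_tbl$cell, stats_tbl$gene)
  members <- split(stats_tbl$gene, stats_tbl$cell)
  need <- table(cell_of[target_nodes])
  for (cl in names(need)) {
    if (length(members[[cl]]) < need[[cl]]) {
      stop("cell ", cl, " has ", length(members[[cl]]),
           " member(s) but ", need[[cl]], " draws are needed")
    }
  }
  with_substream(rng_seed, "topology_matched", {
    reps <- lapply(seq_len(replicates), function(i) {
      drawn <- unlist(lapply(names(need), function(cl) {
        sample(members[[cl]], need[[cl]])
      }), use.names = FALSE)
      list(nodes = sort(drawn),
           edges = induced_edges(edges, drawn),
           cells = stats::setNames(cell_of[drawn], drawn))
    })
    new_ensemble("topology_matched", reps, rng_seed)
  })
}

#' Degree-preserving random rewirings
#'
#' Each replicate rewires the input graph by repeated double-edge swaps
#' (two edges (a,b), (c,d) become (a,d), (c,b) when no self-loop or
#' multi-edge would result), preserving every node's degree exactly. The
#' node set, edge count and degree sequence of every replicate equal the
#' input's.
#'
#' @param casn a `casn` object or edge tibble to rewire.
#' @param replicates number of replicates.
#' @param rng_seed integer seed.
#' @param swaps_per_edge attempted swaps per edge per replicate (default 10).
#' @return a `network_ensemble`.
#' @export
rewire_degree_preserving <- function(casn, replicates = 1000L,
                                     rng_seed = 1L, swaps_per_edge = 10L) {
  edges <- as_network_edges(casn)
  if (nrow(edges) < 2L) stop("need at least 2 edges to rewire")
  nodes <- if (inherits(casn, "casn")) casn$nodes$gene
           else sort(unique(c(edges$from, edges$to)))
  g <- edges_to_igraph(edges[, c("from", "to")], nodes)
  niter <- as.integer(swaps_per_edge) * igraph::ecount(g)
  with_substream(rng_seed, "rewire", {
    reps <- lapply(seq_len(replicates), function(i) {
      gr <- igraph::rewire(g, with = igraph::keeping_degseq(
        loops = FALSE, niter = niter))
      el <- igraph::as_data_frame(gr, what = "edges")
      list(nodes = sort(nodes),
           edges = canonical_edges(tibble::as_tibble(el)))
    })
    new_ensemble("degree_preserving", reps, rng_seed)
  })
}

# Pool a per-node metric across all replicates of an ensemble.
ensemble_metric_values <- function(ensemble, metric) {
  unlist(lapply(ensemble$replicates, function(rep) {
    replicate_metric_values(rep$edges, rep$nodes, metric)
  }), use.names = FALSE)
}

replicate_metric_values <- function(edges, nodes, metric) {
  switch(metric,
    degree = graph_degrees(edges, nodes)$degree,
    clustering = graph_clustering(edges, nodes)$clustering,
    path_length = {
      v <- graph_path_stats(edges, nodes)$node_paths$mean_path
      v[is.finite(v)]
    },
    stop("unknown metric: ", metric))
}

#' Compare network topology against randomization ensembles
#'
#' For each metric and each ensemble, the observed per-node values are
#' compared with the pooled per-node values of the null replicates by a
#' two-sided Wilcoxon rank-sum test; p-values are Benjamini-Hochberg
#' adjusted across the whole family and flagged at `fdr_level`.
#'
#' @param observed a `casn`, `whpn` or edge tibble providing the observed
#'   network.
#' @param ensembles a `network_ensemble` or list of them.
#' @param metrics subset of `c("degree", "clustering", "path_length")`
#'   (per-node mean shortest-path distance).
#' @param fdr_level significance level on the adjusted q-values
#'   (default 0.01).
#' @return a tibble of class `topology_comparison` with one row per metric
#'   x ensemble: medians, Wilcoxon `p_value`, BH `q_value`, `significant`.
#' @export
compare_topology <- function(observed, ensembles,
                             metrics = c("degree", "clustering",
                                         "path_length"),
                             fdr_level = 0.01) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (inherits(ensembles, "network_ensemble")) ensembles <- list(ensembles)
  if (!length(ensembles)) stop("need at least one ensemble")
  obs_edges <- as_network_edges(observed)
  obs_nodes <- if (inherits(observed, "casn")) observed$nodes$gene
               else sort(unique(c(obs_edges$from, obs_edges$to)))
  rows <- purrr::map_dfr(ensembles, function(ens) {
    purrr::map_dfr(metrics, function(m) {
      obs <- replicate_metric_values(obs_edges, obs_nodes, m)
      null <- ensemble_metric_values(ens, m)
      if (!length(obs) || !length(null)) {
        stop("empty value vector for metric ", m)
      }
      tibble::tibble(
        metric = m, scheme = ens$scheme,
        n_obs = length(obs), n_null = length(null),
        obs_median = stats::median(obs),
        null_median = stats::median(null),
        p_value = suppressWarnings(
          wilcox.test(obs, null, exact = FALSE)$p.value))
    })
  })
  rows$q_value <- p.adjust(rows$p_value, method = "BH")
  rows$significant <- rows$q_value < fdr_level
  attr(rows, "fdr_level") <- fdr_level
  class(rows) <- c("topology_comparison", class(rows))
  rows
}
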