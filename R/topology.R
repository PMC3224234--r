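# Topology statistics: degree, clustering coefficient, shortest-path
# statistics, and the log-log least-squares power-law exponent of the
# degree distribution.

# Accept a whpn, casn, or plain edge tibble; return canonical edges.
as_network_edges <- function(x) {
  if (inherits(x, c("whpn", "casn"))) x$edges
  else canonical_edges(tibble::as_tibble(x))
}

as_network_igraph <- function(x, nodes = NULL) {
  edges <- as_network_edges(x)
  if (is.null(nodes) && inherits(x, "casn")) nodes <- x$nodes$gene
  g <- edges_to_igraph(edges, nodes)
  if (igraph::vcount(g) == 0L) stop("network is empty")
  g
}

#' Node degrees and mean degree
#'
#' @param network a `whpn`, `casn`, or edge tibble (`from`, `to`).
#' @param nodes optional full node set (needed to count isolated nodes).
#' @return tibble with `gene`, `degree`; the network mean degree
#'   (2 x edges / nodes) is attached as attribute `mean_degree`.
#' @examples
#' tri <- tibble::tibble(from = c("A", "A", "B"), to = c("B", "C", "C"))
#' attr(graph_degrees(tri), "mean_degree")
#' @export
graph_degrees <- function(network, nodes = NULL) {
  g <- as_network_igraph(network, nodes)
  out <- tibble::tibble(gene = igraph::V(g)$name,
                        degree = as.integer(igraph::degree(g)))
  attr(out, "mean_degree") <- 2 * igraph::ecount(g) / igraph::vcount(g)
  out
}

#' Local clustering coefficients
#'
#' `C_i = 2 E_i / (k_i (k_i - 1))` where `E_i` counts edges among the
#' neighbors of node i; nodes with fewer than two neighbors get `C_i = 0`
#' and contribute 0 to the network mean.
#'
#' @inheritParams graph_degrees
#' @return tibble with `gene`, `degree`, `clustering`; network mean attached
#'   as attribute `mean_clustering`.
#' @export
graph_clustering <- function(network, nodes = NULL) {
  g <- as_network_igraph(network, nodes)
  ci <- unname(igraph::transitivity(g, type = "local", weights = NA))
  ci[!is.finite(ci)] <- 0
  out <- tibble::tibble(gene = igraph::V(g)$name,
                        degree = as.integer(igraph::degree(g)),
                        clustering = ci)
  attr(out, "mean_clustering") <- mean(ci)
  out
}

#' Shortest-path statistics
#'
#' Unweighted breadth-first shortest paths. The average path length `L` is
#' the mean distance over connected (finite-distance) unordered pairs; the
#' diameter `D` is the maximum over those pairs; disconnected pairs are
#' counted and excluded.
#'
#' @inheritParams graph_degrees
#' @return list with `node_paths` (tibble `gene`, `mean_path`: mean distance
#'   to reachable other nodes, NA for isolated nodes),
#'   `avg_path_length`, `diameter`, `n_connected_pairs`, and
#'   `n_disconnected_pairs`. With a single node, `L` and `D` are undefined
#'   and returned as NA.
#' @export
graph_path_stats <- function(network, nodes = NULL) {
  g <- as_network_igraph(network, nodes)
  n <- igraph::vcount(g)
  d <- igraph::distances(g, weights = NA)
  diag(d) <- NA_real_
  finite_rows <- rowSums(is.finite(d))
  node_paths <- tibble::tibble(
    gene = igraph::V(g)$name,
    mean_path = ifelse(finite_rows > 0,
                       rowSums(ifelse(is.finite(d), d, 0)) /
                         pmax(finite_rows, 1L), NA_real_))
  up <- d[upper.tri(d)]
  fin <- is.finite(up)
  if (n < 2L || !any(fin)) {
    if (n < 2L) message("single-node network: path length undefined")
    return(list(node_paths = node_paths, avg_path_length = NA_real_,
                diameter = NA_real_, n_connected_pairs = 0L,
                n_disconnected_pairs = sum(!fin)))
  }
  list(node_paths = node_paths,
       avg_path_length = mean(up[fin]),
       diameter = max(up[fin]),
       n_connected_pairs = sum(fin),
       n_disconnected_pairs = sum(!fin))
}

#' Fit a power-law degree distribution by log-log least squares
#'
#' Fits `n_k = a * k^(-r)` by ordinary least squares of `ln(n_k)` on
#' `ln(k)` over observed degrees `k >= kmin` with `n_k > 0` (this is the
#' straight-line fit to the log-transformed degree histogram; using counts
#' or probabilities changes `a` but not `r`). Maximum-likelihood fitting is
#' the statistically rigorous alternative; the histogram regression is used
#' here because the exponent is read off exactly that presentation of the
#' degree distribution.
#'
#' @param x either a numeric vector of node degrees, or a data frame with
#'   columns `k` and `n_k` (counts may be real-valued).
#' @param kmin smallest degree included in the fit (default 1).
#' @return an object of class `powerlaw_fit`: list with `a` (scale), `r`
#'   (exponent), `n_support` (points used) and `data` (the fitted
#'   histogram).
#' @examples
#' fit_powerlaw(data.frame(k = 1:20, n_k = 1000 * (1:20)^-2))$r
#' @export
fit_powerlaw <- function(x, kmin = 1) {
  if (is.data.frame(x)) {
    stopifnot(all(c("k", "n_k") %in% names(x)))
    hist <- tibble::tibble(k = as.numeric(x$k), n_k = as.numeric(x$n_k))
  } else {
    ks <- as.integer(x)
    tab <- table(ks[ks >= kmin])
    hist <- tibble::tibble(k = as.numeric(names(tab)),
                           n_k = as.numeric(tab))
  }
  hist <- hist[hist$k >= kmin & hist$n_k > 0, , drop = FALSE]
  if (nrow(hist) < 3L) {
    stop("need at least 3 degree values with positive counts to fit ",
         "(have ", nrow(hist), ")")
  }
  fit <- lm(log(n_k) ~ log(k), data = hist)
  structure(list(a = unname(exp(coef(fit)[1])),
                 r = unname(-coef(fit)[2]),
                 n_support = nrow(hist),
                 data = hist), class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat("<powerlaw_fit> n_k = a * k^(-r): a =", signif(x$a, 5),
      ", r =", signif(x$r, 5), "(", x$n_support, "support points )\n")
  invisible(x)
}

#' Full topology profile of a network
#'
#' Computes per-node degree, clustering coefficient and mean shortest-path
#' distance, the degree histogram with its power-law fit, and the
#' network-level summaries (mean degree 2L/N, mean clustering, average path
#' length over connected pairs, diameter).
#'
#' @inheritParams graph_degrees
#' @param kmin smallest degree used in the power-law fit.
#' @return an object of class `topology_profile`: list with `node_stats`
#'   (tibble `gene`, `degree`, `clustering`, `mean_path`), `degree_dist`
#'   (tibble `k`, `n_k`, `p_k`), and `summary` (named list of scalars;
#'   `powerlaw_r` is NA when the fit has fewer than 3 support points).
#' @export
topology_profile <- function(network, nodes = NULL, kmin = 1) {
  deg <- graph_degrees(network, nodes)
  clu <- graph_clustering(network, nodes)
  pst <- graph_path_stats(network, nodes)
  node_stats <- deg |>
    dplyr::left_join(clu[, c("gene", "clustering")], by = "gene") |>
    dplyr::left_join(pst$node_paths, by = "gene")
  tab <- table(deg$degree[deg$degree >= 1])
  degree_dist <- tibble::tibble(k = as.numeric(names(tab)),
                                n_k = as.numeric(tab))
  degree_dist$p_k <- degree_dist$n_k / sum(degree_dist$n_k)
  pl <- tryCatch(fit_powerlaw(deg$degree, kmin = kmin),
                 error = function(e) NULL)
  structure(list(
    node_stats = node_stats,
    degree_dist = degree_dist,
    powerlaw = pl,
    summary = list(
      n_nodes = nrow(node_stats),
      n_edges = sum(node_stats$degree) / 2,
      mean_degree = attr(deg, "mean_degree"),
      mean_clustering = attr(clu, "mean_clustering"),
      avg_path_length = pst$avg_path_length,
      diameter = pst$diameter,
      n_disconnected_pairs = pst$n_disconnected_pairs,
      powerlaw_a = if (is.null(pl)) NA_real_ else pl$a,
      powerlaw_r = if (is.null(pl)) NA_real_ else pl$r)
  ), class = "topology_profile")
}

#' @export
print.topology_profile <- function(x, ...) {
  s <- x$summary
  cat("<topology_profile>\n")
  cat(sprintf("  %d nodes, %d edges; mean degree %.4g\n",
              s$n_nodes, as.integer(s$n_edges), s$mean_degree))
  cat(sprintf("  mean clustering %.4g; L = %.4g; D = %s; power-law r = %.4g\n",
              s$mean_clustering, s$avg_path_length,
              format(s$diameter), s$powerlaw_r))
  invisible(x)
}

#' @describeIn topology_profile per-node statistics as a tibble.
#' @param x a `topology_profile`.
#' @param ... unused.
#' @export
tidy.topology_profile <- function(x, ...) x$node_stats

#' @describeIn topology_profile one-row tibble of network-level summaries.
#' @export
glance.topology_profile <- function(x, ...) tibble::as_tibble(x$summary)

#' @describeIn topology_profile log-log degree distribution with the fitted
#'   power law.
#' @param object a `topology_profile`.
#' @export
autoplot.topology_profile <- function(object, ...) {
  df <- object$degree_dist
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$n_k)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree k", y = "number of nodes",
                  title = "Degree distribution (log-log)") +
    ggplot2::theme_minimal()
  if (!is.null(object$powerlaw)) {
    pl <- object$powerlaw
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(k = df$k, n_k = pl$a * df$k^(-pl$r)),
      color = "firebrick")
  }
  p
}
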