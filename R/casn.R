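# Cancer-associated subnetwork: seeds mapped into the weighted network plus
# their direct neighbors, with cancer-type multiplicity categories.

#' Extract the cancer-associated subnetwork (CASN)
#'
#' Maps the seed genes into a weighted network and returns the induced
#' subgraph on the seeds plus every gene directly connected to a seed
#' (candidate genes). Edge weights are inherited; candidate-candidate edges
#' present in the network are kept (full induced subgraph). Seeds absent
#' from the network are reported in the result, not silently dropped. Each
#' gene is categorized 1-4 by cancer-type multiplicity: a seed by the size
#' of its own type set, a candidate by the size of the union of its adjacent
#' seeds' type sets.
#'
#' @param whpn a [build_whpn()] result.
#' @param seeds seed-gene tibble with `gene` and a `types` list-column.
#' @return an object of class `casn`: list with `edges` (tibble `from`,
#'   `to`, `weight`), `nodes` (tibble `gene`, `role` seed/candidate,
#'   `category`), `seeds` (mapped seeds with types), and `unmapped_seeds`.
#' @export
extract_casn <- function(whpn, seeds) {
  stopifnot(inherits(whpn, "whpn"))
  if (nrow(whpn$edges) == 0L) stop("weighted network is empty")
  stopifnot(all(c("gene", "types") %in% names(seeds)))
  nodes <- whpn_nodes(whpn)
  mapped <- seeds$gene %in% nodes
  if (!any(mapped)) {
    stop("no seed gene maps into the weighted network (",
         nrow(seeds), " seeds given)")
  }
  seed_tbl <- seeds[mapped, , drop = FALSE]
  seed_ids <- seed_tbl$gene
  inc <- whpn$edges$from %in% seed_ids | whpn$edges$to %in% seed_ids
  neighbors <- setdiff(unique(c(whpn$edges$from[inc],
                                whpn$edges$to[inc])), seed_ids)
  casn_nodes <- sort(c(seed_ids, neighbors))
  in_casn <- whpn$edges$from %in% casn_nodes & whpn$edges$to %in% casn_nodes
  edges <- whpn$edges[in_casn, , drop = FALSE]

  # cancer-type multiplicity per gene
  seed_types <- stats::setNames(seed_tbl$types, seed_tbl$gene)
  adj_seed_types <- function(g) {
    on_edge <- (edges$from == g & edges$to %in% seed_ids) |
      (edges$to == g & edges$from %in% seed_ids)
    adj <- intersect(unique(c(edges$from[on_edge], edges$to[on_edge])),
                     seed_ids)
    sort(unique(unlist(seed_types[adj])))
  }
  node_tbl <- tibble::tibble(
    gene = casn_nodes,
    role = ifelse(casn_nodes %in% seed_ids, "seed", "candidate"))
  node_tbl$category <- vapply(seq_len(nrow(node_tbl)), function(i) {
    g <- node_tbl$gene[i]
    if (node_tbl$role[i] == "seed") length(seed_types[[g]])
    else length(adj_seed_types(g))
  }, integer(1))

  structure(list(
    edges = edges,
    nodes = node_tbl,
    seeds = seed_tbl,
    unmapped_seeds = seeds$gene[!mapped]
  ), class = "casn")
}

#' Cancer-type multiplicity categories for CASN genes
#'
#' @param casn a [extract_casn()] result.
#' @param genes gene IDs to look up (default: all CASN genes); a gene
#'   outside the subnetwork is an error.
#' @return named integer vector of categories (1-4).
#' @export
categorize_genes <- function(casn, genes = NULL) {
  stopifnot(inherits(casn, "casn"))
  if (is.null(genes)) genes <- casn$nodes$gene
  missing <- setdiff(genes, casn$nodes$gene)
  if (length(missing)) {
    stop("gene(s) outside the subnetwork: ",
         paste(utils::head(missing, 3L), collapse = ", "))
  }
  stats::setNames(
    casn$nodes$category[match(genes, casn$nodes$gene)], genes)
}

#' @export
print.casn <- function(x, ...) {
  cat("<casn> cancer-associated subnetwork\n")
  cat("  ", nrow(x$nodes), " genes (", sum(x$nodes$role == "seed"),
      " seeds + ", sum(x$nodes$role == "candidate"), " candidates), ",
      nrow(x$edges), " edges\n", sep = "")
  if (length(x$unmapped_seeds)) {
    cat("  ", length(x$unmapped_seeds),
        " seed(s) did not map into the network\n", sep = "")
  }
  invisible(x)
}

#' @describeIn extract_casn per-gene table (role, category).
#' @param x a `casn` object.
#' @param ... unused.
#' @export
tidy.casn <- function(x, ...) x$nodes

#' @describeIn extract_casn one-row summary (node/edge/seed/candidate counts).
#' @export
glance.casn <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_seeds = sum(x$nodes$role == "seed"),
    n_candidates = sum(x$nodes$role == "candidate"),
    n_unmapped_seeds = length(x$unmapped_seeds),
    mean_degree = 2 * nrow(x$edges) / nrow(x$nodes))
}
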