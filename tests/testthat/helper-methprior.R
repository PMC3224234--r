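# Shared fixture builders. Everything is generated in code; no stored data.

# A `whpn` object with prescribed edge weights, bypassing the permutation
# filter (for unit tests of downstream modules).
make_whpn <- function(from, to, weight) {
  edges <- tibble::tibble(from = from, to = to, weight = weight)
  edges <- methprior:::canonical_edges(edges)
  structure(list(
    edges = edges,
    records = tibble::tibble(from = edges$from, to = edges$to,
                             r_true = edges$weight,
                             rank_position = NA_integer_,
                             n_perm_ge = NA_integer_, retained = TRUE),
    provenance = list(n_input_edges = nrow(edges),
                      n_dropped_missing_methylation = 0L,
                      n_dropped_constant = 0L, n_tested = nrow(edges),
                      n_retained = nrow(edges), n_perm = NA_integer_,
                      tail_frac = NA_real_, rng_seed = NA_integer_)
  ), class = "whpn")
}

make_seeds <- function(genes, types) {
  if (!is.list(types)) types <- lapply(seq_along(genes), function(i) types)
  tibble::tibble(gene = genes, types = types)
}

# methylation tibble from a named list of per-gene profiles
make_meth <- function(profiles) {
  m <- do.call(rbind, profiles)
  rownames(m) <- names(profiles)
  colnames(m) <- sprintf("S%03d", seq_len(ncol(m)))
  tibble::as_tibble(m, rownames = "gene")
}

# Erdos-Renyi style random edge set on `n` nodes (node IDs returned too)
random_graph <- function(n, p) {
  ids <- sprintf("N%02d", seq_len(n))
  pairs <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < p
  list(nodes = ids,
       edges = tibble::tibble(from = ids[pairs[keep, 1]],
                              to = ids[pairs[keep, 2]]))
}

# independent shortest-path oracle: matrix-form Floyd-Warshall
fw_distances <- function(nodes, edges) {
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]
    d[a, b] <- 1; d[b, a] <- 1
  }
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], `+`))
  }
  d
}

# independent clustering oracle: count edges among neighbors directly
clustering_oracle <- function(nodes, edges) {
  adj <- matrix(FALSE, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    adj[edges$from[i], edges$to[i]] <- TRUE
    adj[edges$to[i], edges$from[i]] <- TRUE
  }
  vapply(nodes, function(v) {
    nb <- nodes[adj[v, ]]
    k <- length(nb)
    if (k < 2) return(0)
    e <- sum(adj[nb, nb]) / 2
    2 * e / (k * (k - 1))
  }, numeric(1))
}
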