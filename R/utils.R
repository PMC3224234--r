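# Internal helpers shared across modules.

#' Derive a reproducible sub-seed for a named stage
#'
#' All randomness in a run flows from one integer seed; each stage draws from
#' its own substream so that re-running a single stage reproduces its output
#' bit-for-bit regardless of what ran before it.
#'
#' @param seed integer master seed.
#' @param label character stage label.
#' @return an integer seed below 2^31.
#' @keywords internal
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(seed) + 1000003 * h) %% .Machine$integer.max)
}

#' Canonicalize an undirected edge table
#'
#' Orders each pair lexicographically, drops self-loops and duplicates
#' (A-B and B-A collapse to one edge).
#'
#' @param edges data frame with columns `from` and `to` (character); extra
#'   columns are preserved (first occurrence wins on duplicates).
#' @return tibble with canonical `from` < `to`, no self-loops, no duplicates.
#' @keywords internal
canonical_edges <- function(edges) {
  stopifnot(all(c("from", "to") %in% names(edges)))
  a <- as.character(edges$from)
  b <- as.character(edges$to)
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out <- edges
  out$from <- a
  out$to <- b
  out <- out[a != b, , drop = FALSE]
  out <- out[!duplicated(paste(out$from, out$to, sep = "\r")), , drop = FALSE]
  dplyr::arrange(tibble::as_tibble(out), .data$from, .data$to)
}

#' Convert a wide methylation/expression tibble to a numeric matrix
#'
#' @param tbl tibble whose first column `gene` holds identifiers and whose
#'   remaining columns are numeric sample values.
#' @return numeric matrix with gene row names.
#' @keywords internal
as_gene_matrix <- function(tbl) {
  stopifnot(names(tbl)[1] == "gene")
  if (anyDuplicated(tbl$gene)) {
    stop("duplicate gene identifiers: ",
         paste(head(tbl$gene[duplicated(tbl$gene)], 3L), collapse = ", "))
  }
  m <- as.matrix(tbl[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in matrix columns")
  rownames(m) <- tbl$gene
  m
}

#' Convert a numeric gene x sample matrix back to a wide tibble
#' @keywords internal
as_gene_tibble <- function(m) {
  tibble::as_tibble(m, rownames = "gene")
}

#' Build an igraph object from an edge table and an optional node set
#'
#' Isolated nodes are only representable when `nodes` is given explicitly.
#'
#' @keywords internal
edges_to_igraph <- function(edges, nodes = NULL) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$from, edges$to)))
  df <- as.data.frame(edges[, intersect(c("from", "to", "weight"), names(edges))])
  igraph::graph_from_data_frame(df, directed = FALSE,
                                vertices = data.frame(name = nodes))
}

#' Row-standardize a matrix so that cross-products give Pearson correlations
#'
#' Each row is centred and scaled so that `rowSums(xs[i, ] * xs[j, ])` equals
#' `cor(x[i, ], x[j, ])`. Rows with zero variance become NA.
#'
#' @keywords internal
standardize_rows <- function(m) {
  mu <- rowMeans(m)
  cen <- m - mu
  ss <- sqrt(rowSums(cen^2))
  out <- cen / ss
  out[ss == 0, ] <- NA_real_
  out
}
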