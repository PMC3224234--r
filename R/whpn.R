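# Weighted human PPI network construction: per-edge Pearson correlation of
# methylation profiles, matrix-permutation significance, edge filtering.

#' Pearson correlation between two methylation profiles
#'
#' The signed product-moment correlation used as an edge weight. Profiles
#' must be equal-length and non-constant.
#'
#' @param x,y numeric vectors of beta values over the same samples.
#' @return correlation in \[-1, 1\].
#' @examples
#' pearson_weight(c(1, 2, 3, 4), c(1, 3, 2, 4))
#' @export
pearson_weight <- function(x, y) {
  if (length(x) != length(y)) stop("profiles differ in length")
  if (length(x) < 3L) stop("profiles too short for a meaningful correlation")
  if (sd(x) == 0 || sd(y) == 0) {
    stop("constant profile: correlation undefined")
  }
  cor(x, y)
}

#' Build the methylation-weighted PPI network
#'
#' Every interaction edge whose two genes both have methylation profiles is
#' weighted by the Pearson correlation of those profiles. Significance is
#' assessed against a matrix-permutation null: the methylation matrix is
#' perturbed `n_perm` times by independently permuting each gene's profile
#' across samples (destroying inter-gene correlation while preserving
#' marginals), and each edge's true correlation is ranked among its own
#' `n_perm` permuted correlations. An edge is retained iff its true value is
#' in the top `tail_frac` or bottom `tail_frac` of that ranking (order
#' statistics; ties retain). Retained edges keep their true correlation as
#' the linkage weight; all others are removed.
#'
#' @param edges tibble of interaction edges (`from`, `to`).
#' @param methylation gene-level methylation tibble (`gene` + sample
#'   columns).
#' @param n_perm number of matrix perturbations (at least 20; default 1000).
#' @param tail_frac one-sided tail fraction of the two-sided retention rule
#'   (default 0.05, i.e. top or bottom five percent). `0.5` retains every
#'   testable edge; `0` retains none.
#' @param rng_seed integer seed for the permutation stream.
#' @return an object of class `whpn`: list with `edges` (retained edges with
#'   `weight`), `records` (one row per tested edge: `r_true`,
#'   `rank_position` = number of permuted values strictly below the true
#'   one, `n_perm_ge`, `retained`) and `provenance` counts.
#' @export
build_whpn <- function(edges, methylation, n_perm = 1000L,
                       tail_frac = 0.05, rng_seed = 1L) {
  n_perm <- as.integer(n_perm)
  if (n_perm < 20L) stop("n_perm must be at least 20 for meaningful quantiles")
  if (tail_frac < 0 || tail_frac > 0.5) stop("tail_frac must lie in [0, 0.5]")
  edges <- canonical_edges(edges)
  m <- as_gene_matrix(methylation)
  if (ncol(m) < 4L) stop("need at least 4 samples: correlation degenerate")

  n_input <- nrow(edges)
  covered <- edges$from %in% rownames(m) & edges$to %in% rownames(m)
  n_missing <- sum(!covered)
  edges <- edges[covered, , drop = FALSE]
  if (n_missing > 0) {
    message("dropped ", n_missing, " edge(s) lacking methylation rows")
  }
  if (nrow(edges) == 0L) stop("no edge is covered by the methylation matrix")

  genes <- sort(unique(c(edges$from, edges$to)))
  xs <- standardize_rows(m[genes, , drop = FALSE])
  const <- rownames(xs)[!is.finite(rowSums(xs))]
  ok <- !(edges$from %in% const | edges$to %in% const)
  n_const <- sum(!ok)
  if (n_const > 0) {
    message("dropped ", n_const,
            " edge(s) with a constant methylation profile")
    edges <- edges[ok, , drop = FALSE]
    genes <- sort(unique(c(edges$from, edges$to)))
    xs <- xs[genes, , drop = FALSE]
  }
  if (nrow(edges) == 0L) stop("no testable edges remain")

  ia <- match(edges$from, genes)
  ib <- match(edges$to, genes)
  r_true <- unname(rowSums(xs[ia, , drop = FALSE] * xs[ib, , drop = FALSE]))

  ns <- ncol(xs)
  n_le <- integer(nrow(edges))
  n_ge <- integer(nrow(edges))
  n_lt <- integer(nrow(edges))
  with_substream(rng_seed, "whpn_perm", {
    for (b in seq_len(n_perm)) {
      xp <- xs
      for (g in seq_len(nrow(xs))) xp[g, ] <- xs[g, sample.int(ns)]
      r_perm <- rowSums(xp[ia, , drop = FALSE] * xp[ib, , drop = FALSE])
      n_le <- n_le + (r_perm <= r_true)
      n_ge <- n_ge + (r_perm >= r_true)
      n_lt <- n_lt + (r_perm < r_true)
    }
  })

  if (tail_frac == 0) {
    retained <- rep(FALSE, nrow(edges))
  } else {
    j_up <- ceiling((1 - tail_frac) * n_perm)   # upper order statistic index
    i_lo <- ceiling(tail_frac * n_perm)         # lower order statistic index
    retained <- (n_le >= j_up) | (n_ge >= n_perm - i_lo + 1L)
  }

  records <- tibble::tibble(
    from = edges$from, to = edges$to, r_true = r_true,
    rank_position = n_lt, n_perm_ge = n_ge, retained = retained)
  kept <- tibble::tibble(from = edges$from[retained],
                         to = edges$to[retained],
                         weight = r_true[retained])
  structure(list(
    edges = kept,
    records = records,
    provenance = list(
      n_input_edges = n_input, n_dropped_missing_methylation = n_missing,
      n_dropped_constant = n_const, n_tested = nrow(edges),
      n_retained = sum(retained), n_perm = n_perm,
      tail_frac = tail_frac, rng_seed = as.integer(rng_seed))
  ), class = "whpn")
}

#' Nodes of a weighted network (genes incident to a retained edge)
#' @param x a `whpn` object.
#' @return character vector of gene IDs.
#' @export
whpn_nodes <- function(x) {
  stopifnot(inherits(x, "whpn"))
  sort(unique(c(x$edges$from, x$edges$to)))
}

#' @export
print.whpn <- function(x, ...) {
  p <- x$provenance
  cat("<whpn> methylation-weighted PPI network\n")
  cat("  ", length(whpn_nodes(x)), " genes, ", nrow(x$edges),
      " retained edges (of ", p$n_tested, " tested, ", p$n_input_edges,
      " input)\n", sep = "")
  cat("  permutations: ", p$n_perm, ", two-sided tail: ", p$tail_frac,
      "\n", sep = "")
  invisible(x)
}

#' @describeIn build_whpn per-edge permutation records as a tibble.
#' @param x a `whpn` object.
#' @param ... unused.
#' @export
tidy.whpn <- function(x, ...) x$records

#' @describeIn build_whpn one-row summary of the construction.
#' @export
glance.whpn <- function(x, ...) {
  tibble::as_tibble(x$provenance) |>
    dplyr::mutate(n_nodes = length(whpn_nodes(x)), .before = 1)
}

#' @describeIn build_whpn histogram of retained edge weights by sign.
#' @param object a `whpn` object.
#' @export
autoplot.whpn <- function(object, ...) {
  df <- dplyr::mutate(object$edges,
                      sign = ifelse(.data$weight >= 0, "positive",
                                    "negative"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$weight, fill = .data$sign)) +
    ggplot2::geom_histogram(bins = 40, boundary = 0) +
    ggplot2::labs(x = "methylation correlation (edge weight)",
                  y = "edges", fill = NULL,
                  title = "Retained edge weights") +
    ggplot2::theme_minimal()
}
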