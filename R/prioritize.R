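# Neighborhood-weighting prioritization: candidate score S_i = sum of
# |edge weight| over adjacent seeds, compared against per-candidate
# permutation nulls.

# candidate-seed edges of a casn, oriented candidate -> seed
candidate_seed_edges <- function(casn) {
  stopifnot(inherits(casn, "casn"))
  role <- stats::setNames(casn$nodes$role, casn$nodes$gene)
  rf <- role[casn$edges$from]
  rt <- role[casn$edges$to]
  cs <- (rf == "candidate" & rt == "seed") |
        (rf == "seed" & rt == "candidate")
  e <- casn$edges[cs, , drop = FALSE]
  swap <- role[e$from] == "seed"
  tibble::tibble(
    candidate = ifelse(swap, e$to, e$from),
    seed = ifelse(swap, e$from, e$to),
    weight = e$weight)
}

#' Neighborhood-weighting scores for candidate genes
#'
#' Each candidate's score is `S_i = sum_j |w_ij|` over its edges to seed
#' genes, `w_ij` being the methylation-correlation edge weight;
#' candidate-candidate edges contribute nothing.
#'
#' @param casn a [extract_casn()] result with at least one candidate.
#' @return tibble with `gene`, `n_seed_edges`, `score`, sorted by
#'   decreasing score.
#' @export
score_candidates <- function(casn) {
  stopifnot(inherits(casn, "casn"))
  cands <- casn$nodes$gene[casn$nodes$role == "candidate"]
  if (!length(cands)) stop("subnetwork has no candidate genes")
  cs <- candidate_seed_edges(casn)
  if (!all(cands %in% cs$candidate)) {
    # cannot happen for a well-formed CASN: every candidate neighbors a seed
    stop("candidate(s) without any seed edge: ",
         paste(utils::head(setdiff(cands, cs$candidate), 3L),
               collapse = ", "))
  }
  cs |>
    dplyr::group_by(gene = .data$candidate) |>
    dplyr::summarise(n_seed_edges = dplyr::n(),
                     score = sum(abs(.data$weight)), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$score), .data$gene)
}

#' Select optimized genes by per-candidate permutation
#'
#' Recomputes the candidate-seed edge weights from `n_perm` perturbed
#' methylation matrices (each gene's profile independently permuted across
#' samples, the same scheme used to build the weighted network), forming
#' `n_perm` permuted scores per candidate. A candidate is selected
#' ("optimized") iff its true score strictly exceeds every one of its own
#' permuted scores; any tie rejects.
#'
#' @param casn a [extract_casn()] result.
#' @param methylation gene-level methylation tibble covering all genes on
#'   candidate-seed edges.
#' @param n_perm number of perturbation replicates (default 1000).
#' @param rng_seed integer seed for the permutation stream.
#' @param keep_permuted keep the full candidate x replicate matrix of
#'   permuted scores as attribute `permuted_scores`.
#' @return a tibble of class `priority_result`: `gene`, `category`,
#'   `n_seed_edges`, `score`, `n_exceeded` (permuted scores >= the true
#'   score), `max_permuted`, `selected`.
#' @export
prioritize_candidates <- function(casn, methylation, n_perm = 1000L,
                                  rng_seed = 1L, keep_permuted = FALSE) {
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("n_perm must be at least 1")
  scores <- score_candidates(casn)
  cs <- candidate_seed_edges(casn)
  m <- as_gene_matrix(methylation)
  genes <- unique(c(cs$candidate, cs$seed))
  missing <- setdiff(genes, rownames(m))
  if (length(missing)) {
    stop("methylation matrix lacks gene(s): ",
         paste(utils::head(missing, 3L), collapse = ", "))
  }
  xs <- standardize_rows(m[genes, , drop = FALSE])
  if (any(!is.finite(rowSums(xs)))) {
    stop("constant methylation profile among candidate/seed genes")
  }
  ia <- match(cs$candidate, genes)
  ib <- match(cs$seed, genes)
  ns <- ncol(xs)
  # rowsum() groups by sorted unique candidate; align score vector to that
  cand_sorted <- sort(scores$gene)
  s_true <- scores$score[match(cand_sorted, scores$gene)]

  n_exceeded <- integer(length(cand_sorted))
  max_perm <- rep(-Inf, length(cand_sorted))
  perm_mat <- if (keep_permuted) {
    matrix(NA_real_, length(cand_sorted), n_perm,
           dimnames = list(cand_sorted, NULL))
  }
  with_substream(rng_seed, "prioritize_perm", {
    for (b in seq_len(n_perm)) {
      xp <- xs
      for (g in seq_len(nrow(xs))) xp[g, ] <- xs[g, sample.int(ns)]
      r_perm <- rowSums(xp[ia, , drop = FALSE] * xp[ib, , drop = FALSE])
      s_perm <- rowsum(abs(r_perm), cs$candidate)[, 1]
      s_perm <- s_perm[cand_sorted]
      n_exceeded <- n_exceeded + (s_perm >= s_true)
      max_perm <- pmax(max_perm, s_perm)
      if (keep_permuted) perm_mat[, b] <- s_perm
    }
  })

  out <- scores |>
    dplyr::mutate(
      category = unname(categorize_genes(casn, .data$gene)),
      n_exceeded = n_exceeded[match(.data$gene, cand_sorted)],
      max_permuted = max_perm[match(.data$gene, cand_sorted)],
      selected = .data$n_exceeded == 0L) |>
    dplyr::relocate("category", .after = "gene")
  attr(out, "n_perm") <- n_perm
  attr(out, "rng_seed") <- as.integer(rng_seed)
  if (keep_permuted) attr(out, "permuted_scores") <- perm_mat
  class(out) <- c("priority_result", class(out))
  out
}

#' @describeIn prioritize_candidates one-row summary of the selection.
#' @param x a `priority_result`.
#' @param ... unused.
#' @export
glance.priority_result <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x),
    n_selected = sum(x$selected),
    selection_rate = mean(x$selected),
    n_perm = attr(x, "n_perm"))
}

#' @describeIn prioritize_candidates observed score against the permutation
#'   null maximum per candidate.
#' @param object a `priority_result`.
#' @export
autoplot.priority_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$max_permuted, y = .data$score,
                                   color = .data$selected)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "max permuted score", y = "observed score S",
                  color = "selected",
                  title = "Neighborhood-weighting selection") +
    ggplot2::theme_minimal()
}
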