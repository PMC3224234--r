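# Synthetic-data generator: scale-free PPI graph, methylation beta profiles
# with planted edge correlations, seed genes with planted aberrant neighbors,
# and case/control expression with planted differential expression.

#' Evaluate an expression under a labelled RNG substream
#'
#' Sets the RNG state from `substream_seed(seed, label)` for the duration of
#' `expr` and restores the caller's state afterwards, so stages are
#' individually reproducible and mutually independent.
#'
#' @keywords internal
with_substream <- function(seed, label, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(substream_seed(seed, label))
  expr
}

sim_gene_ids <- function(n) sprintf("G%06d", seq_len(n))
sim_sample_ids <- function(n, prefix = "S") sprintf("%s%04d", prefix, seq_len(n))

#' Generate a scale-free interaction graph by preferential attachment
#'
#' Classic preferential attachment: `attachment_m` initial nodes, then each
#' new node attaches `attachment_m` edges to distinct existing nodes chosen
#' with probability proportional to current degree (the first added node
#' links to every initial node, so the graph is connected). The result has
#' exactly `attachment_m * (n_genes - attachment_m)` edges and an
#' asymptotically power-law degree distribution.
#'
#' @param config a [sim_config()] object.
#' @return tibble of undirected edges with columns `from`, `to` (canonical
#'   order, no self-loops or duplicates); gene IDs are `"G000001"` style.
#' @examples
#' simulate_ppi(sim_config(n_genes = 5, attachment_m = 1))
#' @export
simulate_ppi <- function(config) {
  config <- validate_sim_config(config)
  n <- config$n_genes
  m <- config$attachment_m
  ids <- sim_gene_ids(n)
  with_substream(config$rng_seed, "ppi", {
    deg <- integer(n)
    from <- integer(m * (n - m))
    to <- integer(m * (n - m))
    k <- 0L
    for (v in seq.int(m + 1L, n)) {
      existing <- seq_len(v - 1L)
      targets <- if (v == m + 1L) existing else {
        sample(existing, m, prob = deg[existing])
      }
      idx <- k + seq_along(targets)
      from[idx] <- v
      to[idx] <- targets
      k <- k + length(targets)
      deg[v] <- deg[v] + length(targets)
      deg[targets] <- deg[targets] + 1L
    }
    canonical_edges(tibble::tibble(from = ids[from], to = ids[to]))
  })
}

# Pick a subset of edges, no two sharing a node, of size up to `target`.
# Disjointness keeps each planted correlation independent of the others.
disjoint_edge_sample <- function(edges, target) {
  if (target == 0L || nrow(edges) == 0L) return(integer(0))
  ord <- sample.int(nrow(edges))
  used <- character(0)
  keep <- integer(0)
  for (i in ord) {
    a <- edges$from[i]; b <- edges$to[i]
    if (!(a %in% used) && !(b %in% used)) {
      keep <- c(keep, i)
      used <- c(used, a, b)
      if (length(keep) == target) break
    }
  }
  keep
}

squash_beta <- function(latent, baseline, squash) {
  if (squash == "logistic") {
    plogis(baseline + latent)
  } else {
    pmin(pmax(latent, 0), 1)   # operand order keeps the matrix dims
  }
}

#' Generate methylation beta profiles with planted edge correlations
#'
#' Each gene gets a latent Gaussian profile over samples. A node-disjoint
#' subset of edges (fraction `frac_true_edges`) is "planted": the second
#' gene's latent profile is `rho * z + sqrt(1 - rho^2) * eps` against the
#' first gene's `z`, negated for a `frac_negative` share of planted edges.
#' Latents are mapped to beta values in \[0, 1\] by a per-gene logistic
#' squash (or clipped identity). Non-planted gene pairs are independent.
#'
#' @param config a [sim_config()] object.
#' @param edges edge tibble from [simulate_ppi()].
#' @return tibble with `gene` and one numeric column per sample; attributes
#'   `latent` (the pre-squash matrix), `baseline` (per-gene logistic offsets)
#'   and `planted_edges` (tibble `from`, `to`, `sign`).
#' @export
simulate_methylation <- function(config, edges) {
  config <- validate_sim_config(config)
  if (nrow(edges) == 0L) stop("edge list is empty")
  if (config$n_samples < 4L) {
    stop("n_samples must be at least 4: correlation undefined/degenerate")
  }
  genes <- sort(unique(c(edges$from, edges$to)))
  ns <- config$n_samples
  with_substream(config$rng_seed, "methylation", {
    latent <- matrix(rnorm(length(genes) * ns), nrow = length(genes),
                     dimnames = list(genes, sim_sample_ids(ns)))
    baseline <- stats::setNames(rnorm(length(genes)), genes)
    target <- round(config$frac_true_edges * nrow(edges))
    idx <- disjoint_edge_sample(edges, target)
    sgn <- if (length(idx)) {
      ifelse(runif(length(idx)) < config$frac_negative, -1, 1)
    } else numeric(0)
    rho <- config$rho_planted
    for (j in seq_along(idx)) {
      a <- edges$from[idx[j]]; b <- edges$to[idx[j]]
      z <- latent[a, ]
      latent[b, ] <- sgn[j] * (rho * z + sqrt(1 - rho^2) * rnorm(ns))
    }
    beta <- squash_beta(latent, baseline, config$squash)
    out <- as_gene_tibble(beta)
    attr(out, "latent") <- latent
    attr(out, "baseline") <- baseline
    attr(out, "planted_edges") <- tibble::tibble(
      from = edges$from[idx], to = edges$to[idx], sign = sgn)
    out
  })
}

#' Designate seed genes and plant aberrant candidate neighbors
#'
#' Seeds are drawn uniformly from nodes with degree at least one and each is
#' labelled with a uniformly sized (1 up to the number of configured types)
#' subset of cancer types. Planted candidates are drawn from the non-seed
#' neighbors of seeds; each records the single adjacent seed it will be
#' correlated with (see [replant_candidates()]).
#'
#' @param config a [sim_config()] object.
#' @param edges edge tibble from [simulate_ppi()].
#' @return list with `seeds` (tibble `gene`, `types` list-column) and
#'   `planted_candidates` (tibble `gene`, `seed`).
#' @export
simulate_seeds <- function(config, edges) {
  config <- validate_sim_config(config)
  genes <- sort(unique(c(edges$from, edges$to)))
  if (config$n_seeds == 0L) {
    return(list(
      seeds = tibble::tibble(gene = character(0), types = list()),
      planted_candidates = tibble::tibble(gene = character(0),
                                          seed = character(0))))
  }
  if (length(genes) < config$n_seeds) {
    stop("graph has fewer than n_seeds nodes with degree >= 1")
  }
  with_substream(config$rng_seed, "seeds", {
    seeds <- sort(sample(genes, config$n_seeds))
    k_types <- sample.int(length(config$cancer_types), config$n_seeds,
                          replace = TRUE)
    types <- lapply(k_types, function(k) sort(sample(config$cancer_types, k)))
    adj <- dplyr::bind_rows(
      edges[, c("from", "to")],
      stats::setNames(edges[, c("to", "from")], c("from", "to")))
    nbr <- adj[adj$from %in% seeds & !(adj$to %in% seeds), ]
    pool <- sort(unique(nbr$to))
    if (length(pool) < config$n_planted_candidates) {
      stop("not enough seed-adjacent non-seed genes to plant ",
           config$n_planted_candidates, " candidates (have ",
           length(pool), ")")
    }
    cand <- sort(sample(pool, config$n_planted_candidates))
    anchor <- vapply(cand, function(g) {
      s <- nbr$from[nbr$to == g]
      if (length(s) == 1L) s else sample(s, 1L)
    }, character(1))
    list(
      seeds = tibble::tibble(gene = seeds, types = types),
      planted_candidates = tibble::tibble(gene = cand,
                                          seed = unname(anchor)))
  })
}

#' Re-draw planted candidates' methylation to correlate with their seed
#'
#' Each planted candidate's latent profile is replaced by
#' `sign * (rho * z_seed + sqrt(1 - rho^2) * eps)` using the anchor seed's
#' latent profile, then squashed back to beta values. This is the signal the
#' neighborhood-weighting prioritizer is expected to recover.
#'
#' @param methylation tibble from [simulate_methylation()] (must carry its
#'   `latent` and `baseline` attributes).
#' @param planted tibble `gene`, `seed` from [simulate_seeds()].
#' @param config a [sim_config()] object.
#' @return methylation tibble with the candidate rows re-drawn; attributes
#'   updated in place.
#' @export
replant_candidates <- function(methylation, planted, config) {
  config <- validate_sim_config(config)
  latent <- attr(methylation, "latent")
  baseline <- attr(methylation, "baseline")
  if (is.null(latent)) stop("methylation lacks its latent attribute")
  if (nrow(planted) == 0L) return(methylation)
  with_substream(config$rng_seed, "replant", {
    rho <- config$rho_planted
    ns <- ncol(latent)
    sgn <- ifelse(runif(nrow(planted)) < config$frac_negative, -1, 1)
    for (j in seq_len(nrow(planted))) {
      g <- planted$gene[j]; s <- planted$seed[j]
      latent[g, ] <- sgn[j] * (rho * latent[s, ] +
                                 sqrt(1 - rho^2) * rnorm(ns))
    }
    beta <- squash_beta(latent, baseline, config$squash)
    out <- as_gene_tibble(beta)
    attr(out, "latent") <- latent
    attr(out, "baseline") <- baseline
    attr(out, "planted_edges") <- attr(methylation, "planted_edges")
    out
  })
}

#' Generate case/control expression with planted differential expression
#'
#' Background expression is standard Gaussian; `n_de_genes` genes drawn at
#' random are shifted by `de_effect` in the case class.
#'
#' @param config a [sim_config()] object.
#' @param genes character vector of gene IDs to simulate.
#' @return list with `expression` (tibble `gene` + sample columns), `labels`
#'   (tibble `sample`, `class` in case/control) and `de_genes` (character).
#' @export
simulate_expression <- function(config, genes) {
  config <- validate_sim_config(config)
  if (config$n_case < 3L || config$n_control < 3L) {
    stop("need at least 3 samples per class (n_case = ", config$n_case,
         ", n_control = ", config$n_control, ")")
  }
  if (config$n_de_genes > length(genes)) {
    stop("n_de_genes exceeds the number of genes")
  }
  with_substream(config$rng_seed, "expression", {
    nc <- config$n_case; nk <- config$n_control
    samples <- c(sim_sample_ids(nc, "case_"), sim_sample_ids(nk, "ctrl_"))
    labels <- tibble::tibble(sample = samples,
                             class = rep(c("case", "control"), c(nc, nk)))
    m <- matrix(rnorm(length(genes) * (nc + nk)), nrow = length(genes),
                dimnames = list(genes, samples))
    de <- if (config$n_de_genes > 0L) sort(sample(genes, config$n_de_genes))
          else character(0)
    m[de, labels$class == "case"] <- m[de, labels$class == "case"] +
      config$de_effect
    list(expression = as_gene_tibble(m), labels = labels, de_genes = de)
  })
}

#' Generate a complete synthetic study
#'
#' Runs every generator stage off its own RNG substream of
#' `config$rng_seed`: interaction graph, methylation with planted edge
#' correlations, seed genes, planted aberrant candidates (methylation
#' re-drawn to correlate with an adjacent seed), and case/control
#' expression.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `synthetic_bundle`: a list with `config`,
#'   `edges`, `methylation`, `seeds`, `expression` (list of `expression`,
#'   `labels`), and `truth` (planted edges, planted candidates with their
#'   anchor seed, planted DE genes).
#' @examples
#' bundle <- simulate_bundle(sim_config(n_genes = 60, n_samples = 30,
#'                                      n_seeds = 6, n_planted_candidates = 3,
#'                                      n_de_genes = 2))
#' names(bundle$truth)
#' @export
simulate_bundle <- function(config) {
  config <- validate_sim_config(config)
  edges <- simulate_ppi(config)
  meth <- simulate_methylation(config, edges)
  sd <- simulate_seeds(config, edges)
  meth <- replant_candidates(meth, sd$planted_candidates, config)
  genes <- meth$gene
  expr <- simulate_expression(config, genes)
  structure(list(
    config = config,
    edges = edges,
    methylation = meth,
    seeds = sd$seeds,
    expression = expr[c("expression", "labels")],
    truth = list(
      planted_edges = attr(meth, "planted_edges"),
      planted_candidates = sd$planted_candidates,
      de_genes = expr$de_genes)
  ), class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("<synthetic_bundle>\n")
  cat("  genes:", x$config$n_genes, " edges:", nrow(x$edges),
      " samples:", x$config$n_samples, "\n")
  cat("  planted edges:", nrow(x$truth$planted_edges),
      " seeds:", nrow(x$seeds),
      " planted candidates:", nrow(x$truth$planted_candidates), "\n")
  cat("  expression:", x$config$n_case, "cases /", x$config$n_control,
      "controls,", length(x$truth$de_genes), "DE genes\n")
  invisible(x)
}

#' Write a synthetic bundle to a directory of plain-text files
#'
#' Writes `edges.tsv`, `methylation.tsv`, `seeds.tsv`, `expression.tsv`,
#' `labels.tsv` and `truth.json`.
#'
#' @param bundle a `synthetic_bundle`.
#' @param dir output directory (created if missing).
#' @return invisibly, a character vector of the written paths.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    edges = file.path(dir, "edges.tsv"),
    methylation = file.path(dir, "methylation.tsv"),
    seeds = file.path(dir, "seeds.tsv"),
    expression = file.path(dir, "expression.tsv"),
    labels = file.path(dir, "labels.tsv"),
    truth = file.path(dir, "truth.json"))
  write_edge_list(bundle$edges, paths[["edges"]])
  write_methylation(bundle$methylation, paths[["methylation"]])
  write_seed_genes(bundle$seeds, paths[["seeds"]])
  write_matrix_tsv(bundle$expression$expression, paths[["expression"]])
  readr::write_tsv(bundle$expression$labels, paths[["labels"]])
  jsonlite::write_json(list(
    planted_edges = bundle$truth$planted_edges,
    planted_candidates = bundle$truth$planted_candidates,
    de_genes = bundle$truth$de_genes
  ), paths[["truth"]], auto_unbox = FALSE, digits = NA)
  invisible(paths)
}
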