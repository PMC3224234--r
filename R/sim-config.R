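#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults describe
#' the study conditions under which the pipeline is exercised end-to-end: a
#' scale-free interaction graph, methylation beta profiles in which a fraction
#' of edges carry a planted correlation of 0.9 absolute value over 100
#' samples, seed genes labelled with up to four cancer types, planted aberrant
#' candidates adjacent to seeds, and case/control expression with a
#' three-standard-deviation planted shift.
#'
#' @param n_genes number of genes (graph nodes).
#' @param n_samples number of methylation samples (columns).
#' @param attachment_m edges attached per new node during preferential
#'   attachment; the generated graph has `attachment_m * (n_genes -
#'   attachment_m)` edges.
#' @param frac_true_edges fraction of graph edges given a planted methylation
#'   correlation.
#' @param rho_planted target absolute latent correlation of planted edges,
#'   in (0, 1].
#' @param frac_negative fraction of planted edges whose correlation is
#'   negative.
#' @param n_seeds number of seed genes.
#' @param cancer_types character vector of 1-4 cancer-type labels.
#' @param n_planted_candidates number of non-seed neighbors of seeds whose
#'   methylation is re-drawn to correlate with an adjacent seed (the "truly
#'   aberrant" genes the prioritizer should recover).
#' @param n_case,n_control expression sample counts per class.
#' @param n_de_genes number of planted differentially expressed genes.
#' @param de_effect standardized mean shift added to cases for planted DE
#'   genes.
#' @param squash transform mapping latent Gaussian profiles onto beta values
#'   in \[0, 1\]: `"logistic"` (default) or `"identity"` (clip only; useful
#'   for exact-correlation checks).
#' @param rng_seed integer master seed; every stage derives its own
#'   substream from it.
#' @return an object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_genes = 50, n_samples = 20, n_seeds = 5,
#'                   n_planted_candidates = 3)
#' cfg$rho_planted
#' @export
sim_config <- function(n_genes = 500L,
                       n_samples = 100L,
                       attachment_m = 3L,
                       frac_true_edges = 0.10,
                       rho_planted = 0.9,
                       frac_negative = 0.3,
                       n_seeds = 30L,
                       cancer_types = c("glioblastoma", "ovarian",
                                        "hepatocellular", "leukemia"),
                       n_planted_candidates = 20L,
                       n_case = 20L,
                       n_control = 20L,
                       n_de_genes = 10L,
                       de_effect = 3,
                       squash = c("logistic", "identity"),
                       rng_seed = 1L) {
  squash <- match.arg(squash)
  cfg <- list(
    n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
    attachment_m = as.integer(attachment_m),
    frac_true_edges = frac_true_edges, rho_planted = rho_planted,
    frac_negative = frac_negative, n_seeds = as.integer(n_seeds),
    cancer_types = as.character(cancer_types),
    n_planted_candidates = as.integer(n_planted_candidates),
    n_case = as.integer(n_case), n_control = as.integer(n_control),
    n_de_genes = as.integer(n_de_genes), de_effect = de_effect,
    squash = squash, rng_seed = as.integer(rng_seed)
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) stop("invalid configuration: `", field, "` ", msg, call. = FALSE)
  }
  chk(cfg$n_genes >= 1L, "n_genes", "must be a positive integer")
  chk(cfg$n_samples >= 1L, "n_samples", "must be a positive integer")
  chk(cfg$attachment_m >= 1L, "attachment_m", "must be a positive integer")
  chk(cfg$n_genes >= cfg$attachment_m + 1L, "n_genes",
      "must be at least attachment_m + 1")
  chk(cfg$frac_true_edges >= 0 && cfg$frac_true_edges <= 1,
      "frac_true_edges", "must lie in [0, 1]")
  chk(cfg$rho_planted > 0 && cfg$rho_planted <= 1,
      "rho_planted", "must lie in (0, 1]")
  chk(cfg$frac_negative >= 0 && cfg$frac_negative <= 1,
      "frac_negative", "must lie in [0, 1]")
  chk(cfg$n_seeds >= 0L, "n_seeds", "must be non-negative")
  chk(length(cfg$cancer_types) >= 1L && length(cfg$cancer_types) <= 4L,
      "cancer_types", "must name 1-4 cancer types")
  chk(cfg$n_planted_candidates >= 0L, "n_planted_candidates",
      "must be non-negative")
  chk(cfg$n_seeds + cfg$n_planted_candidates <= cfg$n_genes, "n_seeds",
      "+ n_planted_candidates must not exceed n_genes")
  chk(cfg$n_de_genes >= 0L, "n_de_genes", "must be non-negative")
  structure(cfg, class = "sim_config")
}

#' Read a simulation configuration from a YAML file
#'
#' Fields absent from the file keep the [sim_config()] defaults.
#'
#' @param path path to a YAML file of `sim_config` fields.
#' @return a `sim_config` object.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(sim_config, vals)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) {
    cat("  ", nm, ": ", paste(format(x[[nm]]), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
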