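# End-to-end orchestration: simulate -> weighted network -> subnetwork ->
# topology + randomization -> prioritization -> differential expression,
# with checkpoint files and a run manifest.

#' Run the full analysis pipeline on a synthetic study
#'
#' Executes every stage in order, writing checkpoint files under `out_dir`
#' (when given) and recording per-stage counts, seeds and file digests in a
#' run manifest. All stage seeds derive from `config$rng_seed`. Stage
#' failures abort with the stage name; the manifest of completed stages is
#' attached to the error condition.
#'
#' The `"small"` profile (200 genes, 100 permutations/replicates/resamples)
#' gives a fast smoke run; the default profile uses the 1000-replicate
#' settings of the method.
#'
#' @param config a [sim_config()] object.
#' @param out_dir output directory for checkpoint files, or `NULL` to keep
#'   results in memory only.
#' @param n_perm permutations for edge filtering and prioritization.
#' @param tail_frac two-sided tail fraction of the edge-retention rule.
#' @param random_replicates replicates per randomization ensemble.
#' @param n_resamples SAM resampling count.
#' @param stability_threshold stability cutoff on the call count (strictly
#'   exceeded; default 90 percent of `n_resamples`).
#' @param delta SAM call cutoff on `|d|`.
#' @param profile `"default"` or `"small"`; `"small"` overrides the
#'   simulation size and replicate counts for a quick run.
#' @return an object of class `methprior_run`: list with every stage result
#'   (`bundle`, `whpn`, `casn`, `topology`, `comparison`, `priority`,
#'   `diffexpr`) and the `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         n_perm = 1000L, tail_frac = 0.05,
                         random_replicates = 1000L, n_resamples = 1000L,
                         stability_threshold = round(0.9 * n_resamples),
                         delta = 2, profile = c("default", "small")) {
  profile <- match.arg(profile)
  if (profile == "small") {
    config$n_genes <- min(config$n_genes, 200L)
    config <- validate_sim_config(config)
    n_perm <- 100L
    random_replicates <- 100L
    n_resamples <- 100L
    stability_threshold <- 90L
  }
  seed <- config$rng_seed
  manifest <- list(
    package_version = as.character(utils::packageVersion("methprior")),
    config = unclass(config),
    profile = profile,
    parameters = list(n_perm = n_perm, tail_frac = tail_frac,
                      random_replicates = random_replicates,
                      n_resamples = n_resamples,
                      stability_threshold = stability_threshold,
                      delta = delta),
    stages = list(), files = list())
  out <- list()
  save_file <- function(name, path) {
    manifest$files[[name]] <<- list(
      path = path, md5 = unname(tools::md5sum(path)))
  }
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      cond <- simpleError(paste0("stage '", name, "' failed: ",
                                 conditionMessage(e)))
      cond$manifest <- manifest
      stop(cond)
    })
    res
  }
  writing <- !is.null(out_dir)
  if (writing) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  out$bundle <- stage("simulate", simulate_bundle(config))
  manifest$stages$simulate <- list(
    n_genes = config$n_genes, n_edges = nrow(out$bundle$edges),
    n_planted_edges = nrow(out$bundle$truth$planted_edges),
    n_seeds = nrow(out$bundle$seeds),
    n_planted_candidates = nrow(out$bundle$truth$planted_candidates))
  if (writing) {
    paths <- write_bundle(out$bundle, file.path(out_dir, "bundle"))
    for (nm in names(paths)) save_file(paste0("bundle_", nm), paths[[nm]])
  }

  out$whpn <- stage("build_whpn", build_whpn(
    out$bundle$edges, out$bundle$methylation, n_perm = n_perm,
    tail_frac = tail_frac, rng_seed = substream_seed(seed, "stage_whpn")))
  manifest$stages$build_whpn <- out$whpn$provenance
  if (writing) {
    p <- file.path(out_dir, "whpn.graphml")
    write_graphml(out$whpn, p); save_file("whpn_graphml", p)
    p <- file.path(out_dir, "whpn_records.tsv")
    readr::write_tsv(out$whpn$records, p); save_file("whpn_records", p)
  }

  out$casn <- stage("extract_casn", extract_casn(out$whpn,
                                                 out$bundle$seeds))
  manifest$stages$extract_casn <- as.list(glance(out$casn))
  if (writing) {
    p <- file.path(out_dir, "casn.graphml")
    write_graphml(out$casn, p); save_file("casn_graphml", p)
    p <- file.path(out_dir, "casn_report.tsv")
    readr::write_tsv(out$casn$nodes, p); save_file("casn_report", p)
  }

  out$topology <- stage("topology", list(
    whpn = topology_profile(out$whpn),
    casn = topology_profile(out$casn)))
  manifest$stages$topology <- list(
    whpn = out$topology$whpn$summary, casn = out$topology$casn$summary)
  if (writing) {
    p <- file.path(out_dir, "topology.tsv")
    readr::write_tsv(dplyr::bind_rows(
      whpn = glance(out$topology$whpn),
      casn = glance(out$topology$casn), .id = "network"), p)
    save_file("topology", p)
  }

  out$ensembles <- stage("randomize", {
    casn_n <- nrow(out$casn$nodes)
    list(
      node_sample = sample_node_subnetworks(
        out$whpn, casn_n, random_replicates,
        rng_seed = substream_seed(seed, "stage_node_sample")),
      topology_matched = sample_topology_matched(
        out$whpn, out$casn$nodes$gene, random_replicates,
        rng_seed = substream_seed(seed, "stage_topology_matched")),
      degree_preserving = rewire_degree_preserving(
        out$casn, random_replicates,
        rng_seed = substream_seed(seed, "stage_rewire")))
  })
  out$comparison <- stage("compare", compare_topology(
    out$casn, out$ensembles))
  manifest$stages$compare <- list(
    n_tests = nrow(out$comparison),
    n_significant = sum(out$comparison$significant))
  if (writing) {
    p <- file.path(out_dir, "comparison.tsv")
    readr::write_tsv(tibble::as_tibble(out$comparison), p)
    save_file("comparison", p)
  }

  out$priority <- stage("prioritize", prioritize_candidates(
    out$casn, out$bundle$methylation, n_perm = n_perm,
    rng_seed = substream_seed(seed, "stage_prioritize")))
  manifest$stages$prioritize <- as.list(glance(out$priority))
  if (writing) {
    p <- file.path(out_dir, "optimized.tsv")
    readr::write_tsv(tibble::as_tibble(out$priority), p)
    save_file("optimized", p)
  }

  out$diffexpr <- stage("diffexpr", resample_stability(
    out$bundle$expression$expression, out$bundle$expression$labels,
    n_resamples = n_resamples, stability_threshold = stability_threshold,
    delta = delta, rng_seed = substream_seed(seed, "stage_diffexpr")))
  manifest$stages$diffexpr <- as.list(glance(out$diffexpr))
  if (writing) {
    p <- file.path(out_dir, "diffscore.tsv")
    readr::write_tsv(tibble::as_tibble(out$diffexpr), p)
    save_file("diffscore", p)
  }

  if (writing) {
    mpath <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  }
  out$manifest <- manifest
  structure(out, class = "methprior_run")
}

#' @export
print.methprior_run <- function(x, ...) {
  cat("<methprior_run>\n")
  cat("  WHPN:", length(whpn_nodes(x$whpn)), "genes,",
      nrow(x$whpn$edges), "edges\n")
  cat("  CASN:", nrow(x$casn$nodes), "genes,", nrow(x$casn$edges),
      "edges\n")
  cat("  optimized genes:", sum(x$priority$selected), "of",
      nrow(x$priority), "candidates\n")
  cat("  stable DE genes:", sum(x$diffexpr$stable), "\n")
  invisible(x)
}
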