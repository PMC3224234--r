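# Readers and writers for the plain-text formats used across the pipeline:
# TSV edge lists, gene x sample matrices, seed-gene tables, GraphML networks.
# All tables are tab-separated with a header row; lines starting with `#`
# are comments.

#' Read an undirected edge list from a TSV file
#'
#' The first two tab-separated columns are gene identifiers; extra columns
#' (e.g. evidence codes) are ignored. Edges are canonicalized: `A-B` and
#' `B-A` collapse to one edge, self-loops are dropped (a message reports the
#' count).
#'
#' @param path path to the file.
#' @param header whether the first non-comment line is a header row.
#' @return tibble with columns `from`, `to`.
#' @export
read_edge_list <- function(path, header = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (header && length(lines)) {
    lines <- lines[-1]
    lineno <- lineno[-1]
  }
  if (!length(lines)) stop("no edges in file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) {
    stop("malformed edge line ", lineno[bad[1]], " in ", path,
         " (need at least 2 tab-separated columns): ",
         utils::head(lines[bad], 1L))
  }
  raw <- tibble::tibble(from = vapply(parts, `[[`, "", 1L),
                        to = vapply(parts, `[[`, "", 2L))
  n_loops <- sum(raw$from == raw$to)
  out <- canonical_edges(raw)
  if (n_loops > 0) message("dropped ", n_loops, " self-loop(s)")
  out
}

#' Write an edge list as TSV
#' @param edges tibble with columns `from`, `to` (and optionally more).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_edge_list <- function(edges, path) {
  readr::write_tsv(edges, path)
  invisible(path)
}

# shared reader for gene x sample TSV matrices
read_matrix_tsv <- function(path, id_col = "gene") {
  if (!file.exists(path)) stop("file not found: ", path)
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if (ncol(tbl) < 2L) stop("matrix file needs an ID column plus samples: ", path)
  names(tbl)[1] <- id_col
  if (anyDuplicated(names(tbl))) stop("duplicate sample IDs in ", path)
  if (anyDuplicated(tbl[[1]])) {
    stop("duplicate ", id_col, " IDs in ", path, ": ",
         paste(utils::head(unique(tbl[[1]][duplicated(tbl[[1]])]), 3L),
               collapse = ", "))
  }
  vals <- as.matrix(tbl[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric values in ", path)
  if (anyNA(vals)) stop("missing values are not allowed: ", path)
  tbl
}

#' Write a gene x sample tibble as TSV
#' @param tbl tibble with a `gene` column followed by numeric sample columns.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_matrix_tsv <- function(tbl, path) {
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Read a gene-level methylation matrix
#'
#' Beta values must be finite and inside \[0, 1\]; out-of-range values are an
#' error unless `clip = TRUE`, in which case they are clipped and a message
#' reports the count. Missing values are always an error.
#'
#' @param path path to a TSV with a gene ID column followed by per-sample
#'   beta values.
#' @param clip clip out-of-range values into \[0, 1\] instead of failing.
#' @return tibble with `gene` plus sample columns.
#' @export
read_methylation <- function(path, clip = FALSE) {
  tbl <- read_matrix_tsv(path, "gene")
  vals <- as.matrix(tbl[, -1, drop = FALSE])
  out_of_range <- !is.finite(vals) | vals < 0 | vals > 1
  if (any(out_of_range)) {
    if (!clip || any(!is.finite(vals))) {
      stop(sum(out_of_range), " beta value(s) outside [0, 1] in ", path,
           if (!clip) " (use clip = TRUE to clip)" else "")
    }
    message("clipped ", sum(out_of_range), " beta value(s) into [0, 1]")
    vals <- pmin(pmax(vals, 0), 1)
    tbl[, -1] <- tibble::as_tibble(vals)
  }
  tbl
}

#' Write a methylation matrix as TSV
#' @inheritParams write_matrix_tsv
#' @return invisibly, `path`.
#' @export
write_methylation <- function(tbl, path) write_matrix_tsv(tbl, path)

#' Collapse probe-level methylation to gene level
#'
#' Gene-level methylation is the arithmetic mean of the gene's probe values
#' within each sample. Probes missing from the annotation are dropped with a
#' message.
#'
#' @param probes tibble with a `probe` ID column followed by numeric sample
#'   columns (duplicate probe IDs are an error).
#' @param annotation tibble with columns `probe`, `gene`; each probe maps to
#'   exactly one gene.
#' @return gene-level methylation tibble (`gene` + sample columns), genes in
#'   sorted order.
#' @examples
#' probes <- tibble::tibble(probe = c("p1", "p2"), s1 = c(0.2, 0.4))
#' ann <- tibble::tibble(probe = c("p1", "p2"), gene = "geneX")
#' collapse_probes(probes, ann)
#' @export
collapse_probes <- function(probes, annotation) {
  stopifnot(names(probes)[1] == "probe",
            all(c("probe", "gene") %in% names(annotation)))
  if (anyDuplicated(probes$probe)) {
    stop("duplicate probe IDs: ",
         paste(utils::head(probes$probe[duplicated(probes$probe)], 3L),
               collapse = ", "))
  }
  if (anyDuplicated(annotation$probe)) {
    stop("annotation maps some probe to more than one gene")
  }
  unmapped <- setdiff(probes$probe, annotation$probe)
  if (length(unmapped) == nrow(probes)) {
    stop("no probe in the matrix is present in the annotation")
  }
  if (length(unmapped)) {
    message("dropped ", length(unmapped), " unmapped probe(s)")
  }
  probes |>
    dplyr::inner_join(annotation[, c("probe", "gene")], by = "probe") |>
    dplyr::select(-"probe") |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), mean),
                     .groups = "drop") |>
    dplyr::arrange(.data$gene)
}

#' Read a seed-gene table
#'
#' Expects columns `gene` and `types`, the latter a comma-separated list of
#' cancer-type names (non-empty for every seed).
#'
#' @param path path to the TSV file.
#' @return tibble with `gene` and a `types` list-column of character vectors.
#' @export
read_seed_genes <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  stopifnot(all(c("gene", "types") %in% names(tbl)))
  if (anyDuplicated(tbl$gene)) stop("duplicate seed gene IDs in ", path)
  types <- lapply(strsplit(as.character(tbl$types), ","), trimws)
  if (any(lengths(types) == 0L) || any(vapply(types, function(x)
    any(!nzchar(x)), logical(1)))) {
    stop("every seed gene needs at least one cancer type: ", path)
  }
  tibble::tibble(gene = tbl$gene, types = lapply(types, sort))
}

#' Write a seed-gene table
#' @param seeds tibble with `gene` and a `types` list-column.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_seed_genes <- function(seeds, path) {
  out <- tibble::tibble(
    gene = seeds$gene,
    types = vapply(seeds$types, paste, "", collapse = ","))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a case/control expression dataset
#'
#' @param path TSV with a gene ID column followed by per-sample values.
#' @param labels_path TSV with columns `sample`, `class` (values `case` /
#'   `control`), one row per expression column.
#' @return list with `expression` (tibble) and `labels` (tibble).
#' @export
read_expression <- function(path, labels_path) {
  expr <- read_matrix_tsv(path, "gene")
  labels <- readr::read_tsv(labels_path, comment = "#",
                            show_col_types = FALSE)
  stopifnot(all(c("sample", "class") %in% names(labels)))
  samples <- names(expr)[-1]
  if (!setequal(labels$sample, samples) ||
      nrow(labels) != length(samples)) {
    stop("labels do not match the expression sample columns")
  }
  labels <- labels[match(samples, labels$sample), ]
  if (!all(labels$class %in% c("case", "control"))) {
    stop("labels must be 'case' or 'control'")
  }
  if (any(table(factor(labels$class, c("case", "control"))) < 2L)) {
    stop("need at least 2 samples per class")
  }
  list(expression = expr, labels = labels)
}

# Normalize any network-ish object to nodes/edges tibbles for export.
network_parts <- function(x) {
  if (inherits(x, "casn")) {
    list(nodes = tibble::tibble(
      gene = x$nodes$gene,
      is_seed = x$nodes$role == "seed",
      category = as.integer(x$nodes$category)),
      edges = x$edges[, c("from", "to", "weight")])
  } else if (inherits(x, "whpn")) {
    nodes <- whpn_nodes(x)
    list(nodes = tibble::tibble(gene = nodes, is_seed = FALSE,
                                category = 0L),
         edges = x$edges[, c("from", "to", "weight")])
  } else {
    edges <- tibble::as_tibble(x)
    if (!"weight" %in% names(edges)) edges$weight <- 1
    nodes <- sort(unique(c(edges$from, edges$to)))
    list(nodes = tibble::tibble(gene = nodes, is_seed = FALSE,
                                category = 0L),
         edges = edges[, c("from", "to", "weight")])
  }
}

#' Export a network as GraphML
#'
#' Writes edge attribute `weight` (the signed methylation correlation) and
#' node attributes `is_seed` and `category` (0 when unassigned). The file
#' round-trips losslessly through [read_graphml()].
#'
#' @param x a `whpn`, `casn`, or edge tibble with `from`, `to` and
#'   optionally `weight`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_graphml <- function(x, path) {
  parts <- network_parts(x)
  g <- igraph::graph_from_data_frame(
    as.data.frame(parts$edges), directed = FALSE,
    vertices = as.data.frame(parts$nodes))
  tryCatch(igraph::write_graph(g, path, format = "graphml"),
           error = function(e) stop("failed to write GraphML to ", path,
                                    ": ", conditionMessage(e)))
  invisible(path)
}

#' Read a GraphML network written by [write_graphml()]
#'
#' @param path path to the GraphML file.
#' @return list with `nodes` (tibble `gene`, `is_seed`, `category`) and
#'   `edges` (tibble `from`, `to`, `weight`, canonical order).
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  g <- igraph::read_graph(path, format = "graphml")
  n <- igraph::vcount(g)
  va <- igraph::vertex_attr(g)
  nodes <- tibble::tibble(
    gene = as.character(if (n) va$name else character(0)),
    is_seed = if (!is.null(va$is_seed)) as.logical(va$is_seed)
              else rep(FALSE, n),
    category = if (!is.null(va$category)) as.integer(va$category)
               else rep(0L, n))
  el <- igraph::as_data_frame(g, what = "edges")
  edges <- tibble::tibble(
    from = as.character(el$from), to = as.character(el$to),
    weight = if ("weight" %in% names(el)) as.numeric(el$weight)
             else rep(1, nrow(el)))
  list(nodes = dplyr::arrange(nodes, .data$gene),
       edges = canonical_edges(edges))
}
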