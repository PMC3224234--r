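# Resampling-stabilized SAM differential expression: moderated d statistic,
# stratified bootstrap stability counts n_i, and the diff_score ranking.

expr_matrix_and_classes <- function(expression, labels) {
  m <- as_gene_matrix(expression)
  stopifnot(all(c("sample", "class") %in% names(labels)))
  if (!setequal(labels$sample, colnames(m)) ||
      nrow(labels) != ncol(m)) {
    stop("labels do not match the expression sample columns")
  }
  cls <- labels$class[match(colnames(m), labels$sample)]
  if (!all(cls %in% c("case", "control"))) {
    stop("labels must be 'case' or 'control'")
  }
  list(m = m, case = which(cls == "case"), control = which(cls == "control"))
}

sam_d_from_matrix <- function(m, case_idx, ctrl_idx, s0) {
  n1 <- length(case_idx); n2 <- length(ctrl_idx)
  x1 <- m[, case_idx, drop = FALSE]
  x2 <- m[, ctrl_idx, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2)
  v2 <- rowSums((x2 - m2)^2)
  pooled <- (v1 + v2) / (n1 + n2 - 2)
  s <- sqrt(pooled * (1 / n1 + 1 / n2))
  if (is.null(s0)) s0 <- sam_fudge_factor(s)
  list(d = (m1 - m2) / (s + s0), s = s, s0 = s0)
}

#' Fudge factor for the SAM statistic
#'
#' A small positive offset added to every gene's standard error so that
#' genes with tiny variance cannot dominate the statistic. The default
#' policy takes a low percentile of the gene-wise standard errors.
#'
#' @param s numeric vector of gene-wise pooled standard errors.
#' @param probs percentile used (default 0.05).
#' @return a single non-negative number.
#' @export
sam_fudge_factor <- function(s, probs = 0.05) {
  unname(quantile(s, probs, na.rm = TRUE))
}

#' SAM moderated difference statistic
#'
#' `d_i = (mean_case - mean_control) / (s_i + s0)` where `s_i` is the
#' pooled two-sample standard error and `s0` a fudge factor stabilizing
#' low-variance genes.
#'
#' @param expression tibble with a `gene` column and per-sample numeric
#'   columns.
#' @param labels tibble with `sample`, `class` (`case` / `control`); at
#'   least 2 samples per class.
#' @param s0 fudge factor; `NULL` (default) applies the percentile policy
#'   of [sam_fudge_factor()].
#' @return tibble with `gene`, `d`, `s` and the `s0` used (attribute
#'   `s0`).
#' @examples
#' expr <- tibble::tibble(gene = "g1", a = 3, b = 4, c = 5,
#'                        d = 0, e = 1, f = 2)
#' lab <- tibble::tibble(sample = letters[1:6],
#'                       class = rep(c("case", "control"), each = 3))
#' sam_statistic(expr, lab, s0 = 0)
#' @export
sam_statistic <- function(expression, labels, s0 = NULL) {
  p <- expr_matrix_and_classes(expression, labels)
  if (length(p$case) < 2L || length(p$control) < 2L) {
    stop("need at least 2 samples per class")
  }
  res <- sam_d_from_matrix(p$m, p$case, p$control, s0)
  out <- tibble::tibble(gene = rownames(p$m), d = unname(res$d),
                        s = unname(res$s))
  attr(out, "s0") <- res$s0
  out
}

#' Stability-screened differential expression by resampled SAM
#'
#' The dataset is resampled `n_resamples` times, keeping the case/control
#' ratio: by default a stratified bootstrap (each class drawn with
#' replacement at its original size), or, with `replace = FALSE`, a
#' stratified subsample of a fraction of each class. SAM is run on each
#' resample and gene i is "called" in resample j iff `|d_ij| >= delta`.
#' `n_i` counts the calling resamples; a gene is stable iff `n_i` strictly
#' exceeds `stability_threshold`, and its
#' `diff_score_i = sum_j d_ij / n_i` averages the SAM score over exactly
#' the calling resamples (non-calling resamples contribute zero to the
#' sum). Genes are ranked by `|diff_score|`, signed value reported.
#'
#' @inheritParams sam_statistic
#' @param n_resamples number of resampled datasets (default 1000).
#' @param stability_threshold minimum exceeded call count for stability
#'   (default 900; a gene with `n_i` equal to the threshold is not stable).
#' @param delta significance cutoff on `|d|` per resample (must be
#'   positive; default 2).
#' @param s0 fudge factor; `NULL` re-applies the percentile policy within
#'   each resample.
#' @param replace stratified bootstrap (`TRUE`, default) or stratified
#'   subsampling without replacement.
#' @param subsample_frac per-class fraction kept when `replace = FALSE`.
#' @param rng_seed integer seed.
#' @return a tibble of class `diff_score_table`: `gene`, `n_called`,
#'   `diff_score` (NA when never called), `stable`, ordered by
#'   `|diff_score|` descending.
#' @export
resample_stability <- function(expression, labels, n_resamples = 1000L,
                               stability_threshold = 900L, delta = 2,
                               s0 = NULL, replace = TRUE,
                               subsample_frac = 0.8, rng_seed = 1L) {
  n_resamples <- as.integer(n_resamples)
  if (delta <= 0) stop("delta must be positive")
  if (stability_threshold >= n_resamples) {
    stop("stability_threshold must be below n_resamples")
  }
  p <- expr_matrix_and_classes(expression, labels)
  if (length(p$case) < 2L || length(p$control) < 2L) {
    stop("need at least 2 samples per class")
  }
  genes <- rownames(p$m)
  n_called <- integer(length(genes))
  d_sum <- numeric(length(genes))
  draw <- function(idx) {
    if (replace) sample(idx, length(idx), replace = TRUE)
    else sample(idx, max(2L, floor(subsample_frac * length(idx))))
  }
  with_substream(rng_seed, "resample_sam", {
    for (j in seq_len(n_resamples)) {
      ci <- draw(p$case)
      ki <- draw(p$control)
      stopifnot(!replace || (length(ci) == length(p$case) &&
                               length(ki) == length(p$control)))
      d <- sam_d_from_matrix(p$m, ci, ki, s0)$d
      called <- is.finite(d) & abs(d) >= delta
      called[!is.finite(d)] <- TRUE   # zero spread, zero s0: infinite d
      n_called <- n_called + called
      d_sum <- d_sum + ifelse(called & is.finite(d), d, 0)
    }
  })
  out <- tibble::tibble(
    gene = genes,
    n_called = n_called,
    diff_score = ifelse(n_called > 0, d_sum / n_called, NA_real_),
    stable = n_called > stability_threshold) |>
    dplyr::arrange(dplyr::desc(abs(.data$diff_score)), .data$gene)
  attr(out, "params") <- list(
    n_resamples = n_resamples, stability_threshold = stability_threshold,
    delta = delta, s0 = s0, replace = replace,
    subsample_frac = subsample_frac, rng_seed = as.integer(rng_seed))
  class(out) <- c("diff_score_table", class(out))
  out
}

#' @describeIn resample_stability one-row summary of the screen.
#' @param x a `diff_score_table`.
#' @param ... unused.
#' @export
glance.diff_score_table <- function(x, ...) {
  prm <- attr(x, "params")
  tibble::tibble(
    n_genes = nrow(x),
    n_ever_called = sum(x$n_called > 0),
    n_stable = sum(x$stable),
    n_resamples = prm$n_resamples,
    stability_threshold = prm$stability_threshold,
    delta = prm$delta)
}

#' @describeIn resample_stability call counts against diff_score with the
#'   stability threshold marked.
#' @param object a `diff_score_table`.
#' @export
autoplot.diff_score_table <- function(object, ...) {
  prm <- attr(object, "params")
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$diff_score,
                                   y = .data$n_called,
                                   color = .data$stable)) +
    ggplot2::geom_point(alpha = 0.7, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = prm$stability_threshold,
                        linetype = 2) +
    ggplot2::labs(x = "diff_score (mean SAM d over calling resamples)",
                  y = sprintf("n called (of %d resamples)",
                              prm$n_resamples),
                  color = "stable",
                  title = "Resampling-stabilized differential expression") +
    ggplot2::theme_minimal()
}
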