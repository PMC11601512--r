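#' Differential expression, pseudobulk profiles, and scores
#'
#' Rank-sum differential expression with Benjamini-Hochberg control,
#' pseudobulk mean profiles correlated over the top control-expressed
#' genes, gene-set scores as the mean pseudobulk z change over a set, the
#' zonation score as periportal minus pericentral z sums, and per-channel
#' intensity effects with Benjamini-Yekutieli control.
#'
#' @name screen_stats
NULL

#' Per-gene differential expression versus control
#'
#' Two-sided mid-rank Mann-Whitney tests per gene on the tp10k-log layer,
#' Benjamini-Hochberg adjusted, with the pseudobulk log2 fold-change
#' reported alongside.
#'
#' @param layer Cells x genes tp10k-log matrix.
#' @param group_idx,control_idx Row indices of the two populations.
#' @param alpha Significance level on adjusted p. Default 0.05.
#' @return Tibble: `gene`, `statistic`, `p`, `p_adj`, `log2fc`,
#'   `significant`.
#' @export
differential_expression <- function(layer, group_idx, control_idx,
                                    alpha = 0.05) {
  stopifnot(length(group_idx) > 0, length(control_idx) > 0)
  tests <- rank_sum_tests(layer, group_idx, control_idx)
  mean_g <- colMeans(expm1_safe(layer[group_idx, , drop = FALSE]))
  mean_c <- colMeans(expm1_safe(layer[control_idx, , drop = FALSE]))
  log2fc <- log2((mean_g + 1) / (mean_c + 1))
  p_adj <- stats::p.adjust(tests$p, method = "BH")
  tibble::tibble(
    gene = colnames(layer), statistic = tests$statistic, p = tests$p,
    p_adj = p_adj, log2fc = unname(log2fc), significant = p_adj < alpha
  )
}

expm1_safe <- function(x) expm1(pmin(x, 50))

#' Pseudobulk mean profiles and their pairwise correlations
#'
#' Per-group mean of the supplied layer (typically z); correlations are
#' Pearson, computed over the `top_n` genes with the highest mean
#' tp10k-log expression in control cells.
#'
#' @param layer Cells x genes matrix to average (e.g. the z layer).
#' @param labels Per-cell group labels.
#' @param control Control label (defines the expression ranking and is
#'   included as a profile).
#' @param control_expression Cells x genes tp10k-log matrix used to rank
#'   genes; defaults to `layer`.
#' @param top_n Genes entering the correlation. Default 250.
#' @return List: `profiles` (groups x genes matrix), `correlations`
#'   (groups x groups), `support_genes` (the `top_n` genes used).
#' @export
pseudobulk_profiles <- function(layer, labels, control,
                                control_expression = layer, top_n = 250L) {
  layer <- as.matrix(layer)
  top_n <- min(top_n, ncol(layer))
  ctrl_mean <- colMeans(control_expression[labels == control, , drop = FALSE])
  support <- names(sort(ctrl_mean, decreasing = TRUE))[seq_len(top_n)]
  groups <- unique(labels)
  profiles <- t(vapply(groups, function(g) {
    colMeans(layer[labels == g, , drop = FALSE])
  }, numeric(ncol(layer))))
  rownames(profiles) <- groups
  correlations <- stats::cor(t(profiles[, support, drop = FALSE]))
  list(profiles = profiles, correlations = correlations,
       support_genes = support)
}

#' Mean gene-set score per guide
#'
#' The pseudobulk z-scored change relative to control cells, averaged
#' over all genes in the set, per guide; significance versus control
#' cells by rank-sum on per-cell set means with Benjamini-Yekutieli
#' correction.
#'
#' @param z Cells x genes z-layer.
#' @param gene_set Character vector of genes (must intersect the panel;
#'   genes absent from the panel raise an error naming them).
#' @param labels Per-cell guide labels.
#' @param control Control label.
#' @param alpha Level on adjusted p. Default 0.05.
#' @return Tibble: `guide`, `score`, `p`, `p_adj`, `significant`.
#' @export
gene_set_score <- function(z, gene_set, labels, control, alpha = 0.05) {
  missing <- setdiff(gene_set, colnames(z))
  if (length(missing) > 0) {
    stop("gene(s) absent from panel: ", paste(missing, collapse = ", "))
  }
  if (length(gene_set) == 0) stop("empty gene set")
  cell_score <- rowMeans(z[, gene_set, drop = FALSE])
  ctrl_idx <- which(labels == control)
  guides <- setdiff(unique(labels), control)
  res <- purrr::map_dfr(guides, function(g) {
    gi <- which(labels == g)
    test <- rank_sum_tests(matrix(cell_score, ncol = 1), gi, ctrl_idx)
    tibble::tibble(guide = g, score = mean(cell_score[gi]), p = test$p)
  })
  res$p_adj <- stats::p.adjust(res$p, method = "BY")
  res$significant <- res$p_adj < alpha
  res
}

#' Zonation score from marker z-scores
#'
#' Sum of z over the periportal markers minus the sum over the
#' pericentral markers, per cell; optionally the two partial sums
#' separately.
#'
#' @param z Cells x genes z-layer.
#' @param markers List with `periportal` and `pericentral` character
#'   vectors; default [zonation_markers()]. Markers absent from the panel
#'   raise an error naming them.
#' @param split Return the two partial sums as separate columns.
#'   Default `FALSE`.
#' @return Tibble with `cell` (row index) and `score`, or `periportal` /
#'   `pericentral` partial sums when `split = TRUE`.
#' @export
zonation_score <- function(z, markers = zonation_markers(), split = FALSE) {
  missing <- setdiff(unlist(markers), colnames(z))
  if (length(missing) > 0) {
    stop("marker(s) absent from panel: ", paste(missing, collapse = ", "))
  }
  pp <- rowSums(z[, markers$periportal, drop = FALSE])
  pc <- rowSums(z[, markers$pericentral, drop = FALSE])
  if (split) {
    tibble::tibble(cell = seq_len(nrow(z)), periportal = pp,
                   pericentral = pc)
  } else {
    tibble::tibble(cell = seq_len(nrow(z)), score = pp - pc)
  }
}

#' Per-(guide, channel) intensity effects
#'
#' Each channel is z-scored against control cells within its imaging
#' sample, samples are concatenated, and each (guide, channel) pair is
#' tested against controls by rank-sum with Benjamini-Yekutieli
#' correction across all pairs.
#'
#' @param intensities Cells x channels numeric matrix.
#' @param labels Per-cell guide labels.
#' @param control Control label.
#' @param sample Per-cell imaging-sample labels (default: one sample).
#' @param alpha Level on adjusted p. Default 0.05.
#' @return Tibble: `guide`, `channel`, `mean_z`, `p`, `p_adj`,
#'   `significant`.
#' @export
intensity_effects <- function(intensities, labels, control, sample = NULL,
                              alpha = 0.05) {
  intensities <- as.matrix(intensities)
  if (is.null(sample)) sample <- rep("sample1", nrow(intensities))
  z <- intensities
  for (s in unique(sample)) {
    in_s <- sample == s
    ctrl <- in_s & labels == control
    if (!any(ctrl)) stop(sprintf("no control cells in sample '%s'", s))
    mu <- colMeans(intensities[ctrl, , drop = FALSE])
    sd <- apply(intensities[ctrl, , drop = FALSE], 2L, stats::sd)
    z[in_s, ] <- sweep(sweep(intensities[in_s, , drop = FALSE], 2L, mu, "-"),
                       2L, sd, "/")
  }
  ctrl_idx <- which(labels == control)
  guides <- setdiff(unique(labels), control)
  res <- purrr::map_dfr(guides, function(g) {
    gi <- which(labels == g)
    tests <- rank_sum_tests(z, gi, ctrl_idx)
    tibble::tibble(guide = g, channel = colnames(z) %||%
                     as.character(seq_len(ncol(z))),
                   mean_z = colMeans(z[gi, , drop = FALSE]), p = tests$p)
  })
  res$p_adj <- stats::p.adjust(res$p, method = "BY")
  res$significant <- res$p_adj < alpha
  res
}
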