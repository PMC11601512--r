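#' Per-cell perturbation calling and count filtering
#'
#' Imaging barcodes are called with a strict "> threshold molecules"
#' rule; sequencing sgRNA probes with an inclusive ">= threshold UMIs"
#' rule. Only cells with exactly one called guide (`status == "single"`)
#' enter perturbation analyses.
#'
#' @name perturbation_calling
NULL

call_status <- function(n) {
  dplyr::case_when(n == 0L ~ "none", n == 1L ~ "single", TRUE ~ "multiple")
}

#' Call perturbations from imaging barcode counts
#'
#' A guide is called for a cell when its molecule count is strictly
#' greater than `threshold` (default 3, the "> 3 molecules per cell"
#' rule).
#'
#' @param counts Cells x barcodes integer matrix (or data frame) of
#'   retained molecule counts; rownames are cell ids.
#' @param threshold Strict calling threshold. Default 3.
#' @return Tibble: `cell_id`, `status` (`none`/`single`/`multiple`),
#'   `called_guides` (list-col), `guide` (the single call or `NA`).
#' @export
call_imaging_barcodes <- function(counts, threshold = 3L) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0))
  called <- counts > threshold
  finish_calls(called, rownames(counts), colnames(counts))
}

#' Call sgRNAs from sequencing guide-probe UMIs
#'
#' A guide is called when its UMI count is at least its threshold
#' (inclusive). The default global threshold is the maximum of `min_umis`
#' and the `ambient_quantile` quantile of ambient counts, where ambient
#' counts are the per-cell guide-probe counts excluding each cell's
#' argmax probe.
#'
#' @param umis Cells x guide-probes integer matrix; rownames are cell
#'   ids.
#' @param thresholds Per-guide named vector of thresholds, a single
#'   number, or `NULL` to estimate the default global threshold.
#' @param min_umis Floor on the estimated threshold. Default 5.
#' @param ambient_quantile Quantile of ambient counts used by the
#'   estimate. Default 0.95.
#' @return As [call_imaging_barcodes()], plus a `threshold` attribute.
#' @export
call_sequencing_sgrnas <- function(umis, thresholds = NULL, min_umis = 5L,
                                   ambient_quantile = 0.95) {
  umis <- as.matrix(umis)
  if (is.null(thresholds)) {
    top <- max.col(umis, ties.method = "first")
    ambient <- umis
    ambient[cbind(seq_len(nrow(umis)), top)] <- NA_integer_
    q <- stats::quantile(ambient, ambient_quantile, na.rm = TRUE) + 1
    thresholds <- max(min_umis, q)
  }
  stopifnot(all(thresholds >= 1))
  th <- if (length(thresholds) == 1L) {
    rep(thresholds, ncol(umis))
  } else {
    thresholds[colnames(umis)]
  }
  called <- sweep(umis, 2L, th, ">=")
  out <- finish_calls(called, rownames(umis), colnames(umis))
  attr(out, "threshold") <- thresholds
  out
}

finish_calls <- function(called, cell_ids, guide_names) {
  if (is.null(cell_ids)) cell_ids <- as.character(seq_len(nrow(called)))
  n_called <- rowSums(called)
  guides <- lapply(seq_len(nrow(called)), function(i) {
    guide_names[called[i, ]]
  })
  tibble::tibble(
    cell_id = cell_ids,
    status = call_status(n_called),
    called_guides = guides,
    guide = unname(ifelse(n_called == 1L,
                          vapply(guides, function(g) g[1] %||% NA_character_,
                                 character(1)),
                          NA_character_))
  )
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Filter cells and genes of a count matrix
#'
#' Cells with fewer than `min_molecules` or more than `max_molecules`
#' total molecules are removed (boundaries kept), then genes with nonzero
#' counts in fewer than `min_cells_per_gene` of the remaining cells are
#' removed. The order (cells first, then genes) is fixed.
#'
#' @param counts Cells x genes matrix.
#' @param min_molecules,max_molecules Inclusive per-cell total bounds.
#'   Defaults 25 and 1500.
#' @param min_cells_per_gene Minimum expressing cells per gene.
#'   Default 3.
#' @return The filtered matrix (possibly with zero rows or columns).
#' @export
filter_cells_genes <- function(counts, min_molecules = 25L,
                               max_molecules = 1500L,
                               min_cells_per_gene = 3L) {
  counts <- as.matrix(counts)
  totals <- rowSums(counts)
  counts <- counts[totals >= min_molecules & totals <= max_molecules, ,
                   drop = FALSE]
  expressing <- colSums(counts > 0)
  counts[, expressing >= min_cells_per_gene, drop = FALSE]
}
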