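#' Energy-distance permutation testing on PC scores
#'
#' For each perturbation group the energy distance to the control
#' population is computed on the first `n_pcs` principal components of
#' the supplied expression layer:
#' E(X, Y) = 2 mean d(X, Y) - mean d(X, X') - mean d(Y, Y'), with d the
#' squared Euclidean distance by default (configurable to Euclidean). The
#' null is built by permuting group-vs-control labels; the familywise
#' error over groups is controlled by step-down Holm-Sidak.
#'
#' @param layer Cells x genes numeric matrix (e.g. the `z` layer).
#' @param labels Per-cell group labels.
#' @param control Label of the control population.
#' @param n_pcs PCs used. Default 20.
#' @param n_permutations Permutations per group. Default 1000.
#' @param alpha Familywise level. Default 0.05.
#' @param distance `"sqeuclidean"` (default) or `"euclidean"`.
#' @param pca_per_comparison Fit the PCA on each group + control pair
#'   (`TRUE`, default) or once on all cells.
#' @param seed RNG seed for the permutations.
#' @return An `edist_result` tibble: `group`, `n_cells`, `statistic`,
#'   `p`, `p_adj`, `significant`; the distance convention and settings
#'   are recorded in attributes.
#' @export
energy_distance_test <- function(layer, labels, control, n_pcs = 20L,
                                 n_permutations = 1000L, alpha = 0.05,
                                 distance = c("sqeuclidean", "euclidean"),
                                 pca_per_comparison = TRUE, seed = 1L) {
  distance <- match.arg(distance)
  layer <- as.matrix(layer)
  keep_cols <- colSums(!is.finite(layer)) == 0
  layer <- layer[, keep_cols, drop = FALSE]
  groups <- setdiff(unique(labels), control)
  ctrl_idx <- which(labels == control)
  stopifnot(length(ctrl_idx) >= 2)
  global_pcs <- NULL
  if (!pca_per_comparison) {
    global_pcs <- pc_scores(layer, n_pcs)
  }
  res <- withr_seed(seed, purrr::map_dfr(groups, function(g) {
    gi <- which(labels == g)
    if (length(gi) < 2) stop(sprintf("group '%s' has fewer than 2 cells", g))
    if (pca_per_comparison) {
      scores <- pc_scores(layer[c(gi, ctrl_idx), , drop = FALSE], n_pcs)
      gsel <- seq_along(gi)
    } else {
      scores <- global_pcs[c(gi, ctrl_idx), , drop = FALSE]
      gsel <- seq_along(gi)
    }
    d <- pair_dists(scores, distance)
    obs <- edist_from_d(d, gsel)
    perm <- edist_permutations(d, length(gi), n_permutations)
    p <- (1 + sum(perm >= obs)) / (1 + n_permutations)
    tibble::tibble(group = g, n_cells = length(gi), statistic = obs, p = p)
  }))
  res$p_adj <- holm_sidak(res$p)
  res$significant <- res$p_adj < alpha
  structure(res, class = c("edist_result", class(res)),
            distance = distance, n_pcs = n_pcs,
            n_permutations = n_permutations, alpha = alpha, seed = seed)
}

pc_scores <- function(x, n_pcs) {
  n_pcs <- min(n_pcs, ncol(x), nrow(x) - 1L)
  stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)$x
}

pair_dists <- function(scores, distance) {
  g <- tcrossprod(scores)
  sq <- diag(g)
  d <- outer(sq, sq, "+") - 2 * g
  d[d < 0] <- 0
  if (distance == "euclidean") d <- sqrt(d)
  d
}

# Energy distance between rows `gsel` and the rest, from a full pairwise
# distance matrix.
edist_from_d <- function(d, gsel) {
  n <- nrow(d)
  x <- gsel
  y <- setdiff(seq_len(n), gsel)
  nx <- length(x); ny <- length(y)
  between <- sum(d[x, y]) / (nx * ny)
  within_x <- sum(d[x, x]) / (nx * nx)
  within_y <- sum(d[y, y]) / (ny * ny)
  2 * between - within_x - within_y
}

# Vectorised permutation null: indicator matrix Z (n x B) of random
# group assignments of size nx; all block sums come from one D %*% Z.
edist_permutations <- function(d, nx, n_perm) {
  n <- nrow(d)
  z <- matrix(0, n, n_perm)
  for (b in seq_len(n_perm)) z[sample.int(n, nx), b] <- 1
  t_mat <- d %*% z
  ny <- n - nx
  row_tot <- rowSums(d)
  sum_xx <- colSums(z * t_mat)
  sum_xy <- colSums((1 - z) * t_mat)
  sum_yy <- sum(d) - 2 * sum_xy - sum_xx
  2 * sum_xy / (nx * ny) - sum_xx / (nx * nx) - sum_yy / (ny * ny)
}

#' @export
print.edist_result <- function(x, ...) {
  cat(sprintf("<edist_result> %d group(s) vs control; %s distance on %d PCs, %d permutations; %d significant at alpha = %g (Holm-Sidak)\n",
              nrow(x), attr(x, "distance"), attr(x, "n_pcs"),
              attr(x, "n_permutations"), sum(x$significant),
              attr(x, "alpha")))
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.edist_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.edist_result <- function(x, ...) {
  tibble::tibble(
    n_groups = nrow(x),
    n_significant = sum(x$significant),
    distance = attr(x, "distance"),
    n_pcs = attr(x, "n_pcs"),
    n_permutations = attr(x, "n_permutations"),
    alpha = attr(x, "alpha")
  )
}
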