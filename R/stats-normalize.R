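#' Normalization and control-referenced z-scoring
#'
#' Counts are scaled per cell to a total of 10,000 and log1p-transformed
#' (tp10k-log). Optional covariates (e.g. cell area, molecules per cell)
#' are removed per gene by least squares, and the residuals are z-scored
#' against the per-gene mean and standard deviation of control cells,
#' within batch, then concatenated.
#'
#' @param counts Cells x genes matrix.
#' @param control Logical vector marking control cells (nonempty per
#'   batch).
#' @param batch Optional batch labels (default: one batch).
#' @param covariates Optional numeric matrix/data frame of per-cell
#'   covariates to regress out.
#' @return A `normalized_screen` list of layers: `tp10k_log`, `residual`,
#'   `z` (all cells x genes), plus `control`, `batch` and
#'   `dropped_genes` (zero control variance within some batch; their z
#'   columns are NA).
#' @export
normalize_and_zscore <- function(counts, control, batch = NULL,
                                 covariates = NULL) {
  counts <- as.matrix(counts)
  stopifnot(length(control) == nrow(counts))
  if (is.null(batch)) batch <- rep("batch1", nrow(counts))
  totals <- rowSums(counts)
  if (any(totals == 0)) stop("zero-total cell(s); filter cells first")
  tp10k_log <- log1p(counts / totals * 1e4)

  residual <- tp10k_log
  if (!is.null(covariates)) {
    x <- stats::model.matrix(~ ., data = as.data.frame(covariates))
    fit <- stats::lm.fit(x, tp10k_log)
    residual <- tp10k_log - x %*% fit$coefficients
  }

  z <- matrix(NA_real_, nrow(counts), ncol(counts),
              dimnames = dimnames(counts))
  dropped <- character()
  for (b in unique(batch)) {
    in_b <- batch == b
    ctrl_b <- in_b & control
    if (!any(ctrl_b)) stop(sprintf("no control cells in batch '%s'", b))
    mu <- colMeans(residual[ctrl_b, , drop = FALSE])
    sd <- apply(residual[ctrl_b, , drop = FALSE], 2L, stats::sd)
    bad <- !is.finite(sd) | sd == 0
    dropped <- union(dropped, colnames(counts)[bad])
    sd[bad] <- NA_real_
    z[in_b, ] <- sweep(sweep(residual[in_b, , drop = FALSE], 2L, mu, "-"),
                       2L, sd, "/")
  }
  if (length(dropped) > 0) {
    message("zero-variance gene(s) in controls excluded from z layer: ",
            paste(dropped, collapse = ", "))
  }
  structure(list(tp10k_log = tp10k_log, residual = residual, z = z,
                 control = control, batch = batch,
                 dropped_genes = dropped),
            class = "normalized_screen")
}

#' @export
print.normalized_screen <- function(x, ...) {
  cat(sprintf("<normalized_screen> %d cells x %d genes (%d control, %d batch(es), %d gene(s) dropped from z)\n",
              nrow(x$z), ncol(x$z), sum(x$control),
              length(unique(x$batch)), length(x$dropped_genes)))
  invisible(x)
}

# Step-down Sidak (Holm-Sidak) familywise-error adjustment.
holm_sidak <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

# Vectorised two-sided Mann-Whitney (rank-sum) tests, one per column of
# `x`, comparing rows in `g1` vs rows in `g2`: mid-ranks, normal
# approximation with tie correction and continuity correction.
rank_sum_tests <- function(x, g1, g2) {
  n1 <- length(g1); n2 <- length(g2)
  sub <- x[c(g1, g2), , drop = FALSE]
  p <- numeric(ncol(x))
  stat <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    v <- sub[, j]
    r <- rank(v)
    u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    ties <- table(v)
    tie_term <- sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))
    sigma2 <- n1 * n2 / 12 * ((n1 + n2 + 1) - tie_term)
    if (sigma2 <= 0) {
      p[j] <- 1
      stat[j] <- u
      next
    }
    zstat <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p[j] <- 2 * stats::pnorm(-abs(zstat))
    stat[j] <- u
  }
  list(statistic = stat, p = pmin(p, 1))
}
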