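#' Data-driven tissue zone segmentation and zone enrichment
#'
#' The field is binned at 50 um, per-class (Hep1+Hep2 pericentral,
#' Hep5+Hep6 periportal) 2-D cell-count histograms are Gaussian-blurred
#' (sigma in bin units) and normalized by their grid maximum, and every
#' bin is labeled by the larger normalized density; ties break toward
#' pericentral. Per-guide zone occupancy is then compared to controls by
#' Fisher's exact test with Benjamini-Hochberg correction.
#'
#' @name spatial_zonation
NULL

#' Build a pericentral/periportal zone map from cell positions
#'
#' @param cells Tibble with `x`, `y` (um) and `subtype`
#'   (`Hep1`..`Hep6`; other values ignored).
#' @param field_um Field side length (um); default the data extent.
#' @param bin_um Bin size. Default 50.
#' @param sigma Gaussian blur sigma in bin units. Default 0.5.
#' @return A `zone_map` list: `bin_um`, `pericentral` and `periportal`
#'   normalized grids (max 1), `zone` character matrix
#'   (`"pericentral"`/`"periportal"`), and the bin edges.
#' @export
build_zone_map <- function(cells, field_um = NULL, bin_um = 50, sigma = 0.5) {
  pc_cells <- cells$subtype %in% c("Hep1", "Hep2")
  pp_cells <- cells$subtype %in% c("Hep5", "Hep6")
  if (!any(pc_cells) || !any(pp_cells)) {
    stop("need at least one Hep1/Hep2 and one Hep5/Hep6 cell")
  }
  if (is.null(field_um)) field_um <- max(cells$x, cells$y)
  n_bins <- max(1L, ceiling(field_um / bin_um))
  bin_of <- function(v) pmin(pmax(floor(v / bin_um) + 1L, 1L), n_bins)
  hist2d <- function(sel) {
    h <- matrix(0, n_bins, n_bins)
    if (any(sel)) {
      tab <- table(factor(bin_of(cells$x[sel]), levels = seq_len(n_bins)),
                   factor(bin_of(cells$y[sel]), levels = seq_len(n_bins)))
      h <- h + unclass(tab)
    }
    h
  }
  blur <- function(h) gaussian_blur(h, sigma)
  g_pc <- blur(hist2d(pc_cells))
  g_pp <- blur(hist2d(pp_cells))
  g_pc <- g_pc / max(g_pc)
  g_pp <- g_pp / max(g_pp)
  zone <- ifelse(g_pp > g_pc, "periportal", "pericentral") # tie: pericentral
  structure(list(bin_um = bin_um, sigma = sigma, n_bins = n_bins,
                 pericentral = g_pc, periportal = g_pp, zone = zone),
            class = "zone_map")
}

# Separable Gaussian blur with a small truncated kernel (sigma in bins).
gaussian_blur <- function(h, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-half:half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_conv <- function(m) {
    # convolve along rows with zero padding
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (o in seq_along(k)) {
      shift <- o - half - 1L
      src <- seq_len(n) + shift
      ok <- src >= 1 & src <= n
      out[ok, ] <- out[ok, ] + k[o] * m[src[ok], , drop = FALSE]
    }
    out
  }
  t(pad_conv(t(pad_conv(h))))
}

#' @export
print.zone_map <- function(x, ...) {
  cat(sprintf("<zone_map> %d x %d bins of %g um (sigma = %g); %d pericentral, %d periportal\n",
              x$n_bins, x$n_bins, x$bin_um, x$sigma,
              sum(x$zone == "pericentral"), sum(x$zone == "periportal")))
  invisible(x)
}

#' Look up the zone of positions on a zone map
#'
#' @param zone_map A `zone_map`.
#' @param x,y Coordinates in micrometers.
#' @return Character vector of zone labels.
#' @export
zone_at <- function(zone_map, x, y) {
  n <- zone_map$n_bins
  bx <- pmin(pmax(floor(x / zone_map$bin_um) + 1L, 1L), n)
  by <- pmin(pmax(floor(y / zone_map$bin_um) + 1L, 1L), n)
  zone_map$zone[cbind(bx, by)]
}

#' Per-guide zone occupancy and enrichment versus control
#'
#' Occupancy fractions per guide plus a two-sided Fisher exact test of
#' each guide's pericentral/periportal counts against the pooled control
#' counts, Benjamini-Hochberg adjusted.
#'
#' @param calls Tibble with `x`, `y` (um) and `guide` per called cell.
#' @param zone_map A `zone_map`.
#' @param control Control guide label (or a vector of control labels).
#' @param alpha Level on adjusted p. Default 0.05.
#' @return Tibble: `guide`, `n_cells`, `frac_pericentral`,
#'   `frac_periportal`, `p`, `p_adj`, `significant`.
#' @export
zone_enrichment <- function(calls, zone_map, control, alpha = 0.05) {
  calls$zone <- zone_at(zone_map, calls$x, calls$y)
  is_ctrl <- calls$guide %in% control
  ctrl_tab <- c(pericentral = sum(calls$zone[is_ctrl] == "pericentral"),
                periportal = sum(calls$zone[is_ctrl] == "periportal"))
  guides <- setdiff(unique(calls$guide), control)
  res <- purrr::map_dfr(guides, function(g) {
    sel <- calls$guide == g
    tab <- c(pericentral = sum(calls$zone[sel] == "pericentral"),
             periportal = sum(calls$zone[sel] == "periportal"))
    p <- stats::fisher.test(rbind(tab, ctrl_tab))$p.value
    tibble::tibble(guide = g, n_cells = sum(sel),
                   frac_pericentral = tab[1] / sum(tab),
                   frac_periportal = tab[2] / sum(tab), p = p)
  })
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$p_adj < alpha
  res
}
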