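#' Ground-truthed synthetic screens
#'
#' The generator emulates a pooled in vivo liver screen: hepatocytes on a
#' lobule-like field with a zonal coordinate z in \[0, 1\] (0 pericentral,
#' 1 periportal), subtypes Hep1-Hep6 as sextiles of z, Poisson low-MOI
#' lentiviral barcode transduction, multiplicative knockout effect models
#' on negative-binomial counts, rendered per-bit amplicon images with flip
#' noise and blank molecules, and Flex-style UMI tables with sgRNA
#' spike-in probe counts. Every downstream quantity is traceable to a
#' ground-truth record.
#'
#' @name synthetic_data
NULL

ZONATION_MARKERS <- list(
  periportal = c("Cyp2f2", "Hal", "Hsd17b13", "Sds", "Ctsc", "Aldh1b1",
                 "Pck1"),
  pericentral = c("Cyp4a14", "Cyp2d9", "Gstm3", "Cyp4a10", "Mup17",
                  "Slc1a2", "Slc22a1", "Cyp1a2", "Aldh1a1", "Cyp2a5",
                  "Gulo", "Cyp2c37", "Lect2", "Cyp2e1", "Oat", "Glul")
)

#' Curated hepatocyte zonation marker sets
#'
#' Seven periportal and sixteen pericentral marker genes; periportal
#' expression contributes positively and pericentral negatively to the
#' zonation score.
#'
#' @return List with character vectors `periportal` and `pericentral`.
#' @export
zonation_markers <- function() ZONATION_MARKERS

#' Build a gene panel and a perturbation library
#'
#' The panel contains the zonation marker genes (periportal markers with
#' positive zonal slope, pericentral with negative slope) plus unzonated
#' filler genes, each with a lognormal baseline abundance. The library has
#' two guides per targeted gene plus negative controls; effect templates
#' are target depletion only (knockout transcript loss through
#' nonsense-mediated decay), gene-set induction (a UPR-like set scaled by
#' `induction_z`), and zonal shift (the zonal factor is evaluated at
#' z + delta_z).
#'
#' @param n_genes Panel size. Default 209 (the measured gene panel).
#' @param n_targets Genes targeted by guides. Default 202.
#' @param n_controls Negative control guides. Default 50.
#' @param guides_per_target Default 2.
#' @param depletion_factor Multiplier on the targeted gene's mean.
#'   Default 0.2.
#' @param n_induction Number of targets whose knockout induces the
#'   UPR-like set. Default 5.
#' @param n_zonal_shift Number of targets whose knockout shifts the zonal
#'   coordinate. Default 5.
#' @param induction_z Planted z-scale induction of the gene set.
#'   Default 1.
#' @param delta_z Planted zonal shift for zonal-shift guides.
#'   Default -0.3.
#' @param seed RNG seed.
#' @return List with `panel` (tibble: `gene`, `baseline`, `zonal_slope`)
#'   and `library` (tibble: `guide`, `target`, `is_control`, `template`,
#'   `depletion_factor`, `induced_set` list-col, `induction_z`,
#'   `delta_z`).
#' @export
build_panel_and_library <- function(n_genes = 209L, n_targets = 202L,
                                    n_controls = 50L,
                                    guides_per_target = 2L,
                                    depletion_factor = 0.2,
                                    n_induction = 5L, n_zonal_shift = 5L,
                                    induction_z = 1, delta_z = -0.3,
                                    seed = 1L) {
  markers <- unlist(ZONATION_MARKERS, use.names = FALSE)
  stopifnot(n_genes >= length(markers), n_targets <= n_genes)
  withr_seed(seed, {
    filler <- sprintf("Gene%03d", seq_len(n_genes - length(markers)))
    genes <- c(markers, filler)
    slope <- c(rep(2, length(ZONATION_MARKERS$periportal)),
               rep(-2, length(ZONATION_MARKERS$pericentral)),
               rep(0, length(filler)))
    baseline <- stats::rlnorm(n_genes, meanlog = 2, sdlog = 1)
    panel <- tibble::tibble(gene = genes, baseline = baseline,
                            zonal_slope = slope)
    # gene-set scoring targets well-detected genes, so the UPR-like set is
    # drawn from the most abundant unzonated genes
    upr_set <- head(filler[order(baseline[match(filler, genes)],
                                 decreasing = TRUE)], 10L)

    targets <- sample(genes, n_targets)
    template <- rep("depletion", n_targets)
    n_induction <- min(n_induction, n_targets %/% 3)
    n_zonal_shift <- min(n_zonal_shift, n_targets %/% 3)
    special <- sample.int(n_targets, n_induction + n_zonal_shift)
    template[special[seq_len(n_induction)]] <- "induction"
    template[special[n_induction + seq_len(n_zonal_shift)]] <- "zonal_shift"
    tmpl_exp <- rep(template, each = guides_per_target)
    lib_targets <- tibble::tibble(
      guide = sprintf("sg%s_%d", rep(targets, each = guides_per_target),
                      rep(seq_len(guides_per_target), n_targets)),
      target = rep(targets, each = guides_per_target),
      is_control = FALSE,
      template = tmpl_exp,
      depletion_factor = depletion_factor,
      induction_z = ifelse(tmpl_exp == "induction", induction_z, 0),
      delta_z = ifelse(tmpl_exp == "zonal_shift", delta_z, 0)
    )
    lib_controls <- tibble::tibble(
      guide = sprintf("sgCtrl_%02d", seq_len(n_controls)),
      target = NA_character_, is_control = TRUE, template = "control",
      depletion_factor = 1, induction_z = 0, delta_z = 0
    )
    library <- dplyr::bind_rows(lib_targets, lib_controls)
    library$induced_set <- purrr::map(library$template,
                                      ~ if (.x == "induction") upr_set else character())
    list(panel = panel, library = library, upr_set = upr_set)
  })
}

#' Simulate a lobule-like tissue with Poisson barcode transduction
#'
#' Cells are placed on a jittered grid of non-overlapping disks. The zonal
#' coordinate of each cell is its normalized distance between a planted
#' central-vein point set and a portal point set (z = d_cv / (d_cv +
#' d_pp)); hepatocyte subtypes Hep1-Hep6 are the sextiles of z, Hep1 the
#' most pericentral. Each cell receives Poisson(`lambda`) barcodes with
#' identities uniform over the library; optional clonal patches copy a
#' neighboring cell's barcode set.
#'
#' @param n_cells Number of cells.
#' @param field_um Side of the square field in micrometers.
#' @param lambda Transduction multiplicity (Poisson mean barcodes per
#'   cell). Default 0.3, matching the targeted low MOI.
#' @param library Perturbation library tibble (needs a `guide` column), or
#'   `NULL` for barcode-free tissue.
#' @param n_veins Number of central-vein anchor points (an equal number of
#'   portal points is interleaved). Default 4.
#' @param clone_prob Probability that a cell copies the barcode multiset
#'   of a previously placed neighbor instead of drawing fresh (clonal
#'   patches). Default 0.
#' @param seed RNG seed.
#' @return A `sim_screen` list: `cells` tibble (`cell_id`, `x`, `y`,
#'   `radius`, `z`, `subtype`, `barcodes` list-col of guide names),
#'   `field_um`, `lambda`, `library`, `seed`.
#' @export
simulate_tissue <- function(n_cells, field_um = 500, lambda = 0.3,
                            library = NULL, n_veins = 4L, clone_prob = 0,
                            seed = 1L) {
  stopifnot(lambda > 0)
  withr_seed(seed, {
    side <- ceiling(sqrt(n_cells))
    pitch <- field_um / side
    idx <- seq_len(n_cells) - 1L
    gx <- (idx %% side + 0.5) * pitch
    gy <- (idx %/% side + 0.5) * pitch
    # jitter keeps disks of radius 0.35*pitch disjoint (max offset 0.1*pitch)
    x <- gx + stats::runif(n_cells, -0.1, 0.1) * pitch
    y <- gy + stats::runif(n_cells, -0.1, 0.1) * pitch
    radius <- rep(0.35 * pitch, n_cells)

    # planted vasculature: central veins and portal triads on interleaved
    # lattices so zones tile the field
    k <- max(1L, ceiling(sqrt(n_veins)))
    vx <- as.vector(outer((seq_len(k) - 0.5) / k, rep(1, k))) * field_um
    vy <- as.vector(outer(rep(1, k), (seq_len(k) - 0.5) / k)) * field_um
    px <- as.vector(outer((seq_len(k + 1) - 1) / k, rep(1, k + 1))) * field_um
    py <- as.vector(outer(rep(1, k + 1), (seq_len(k + 1) - 1) / k)) * field_um
    d_cv <- min_dist_to(x, y, vx, vy)
    d_pp <- min_dist_to(x, y, px, py)
    z <- d_cv / (d_cv + d_pp)
    subtype <- paste0("Hep", pmin(6L, floor(z * 6) + 1L))

    cells <- tibble::tibble(cell_id = seq_len(n_cells), x = x, y = y,
                            radius = radius, z = z, subtype = subtype)
    if (!is.null(library)) {
      n_bc <- stats::rpois(n_cells, lambda)
      ids <- sample(library$guide, sum(n_bc), replace = TRUE)
      barcodes <- split(ids, rep.int(seq_len(n_cells), n_bc))
      cells$barcodes <- rep(list(character()), n_cells)
      cells$barcodes[as.integer(names(barcodes))] <- unname(barcodes)
      if (clone_prob > 0) {
        clone <- stats::runif(n_cells) < clone_prob
        clone[1L] <- FALSE
        for (i in which(clone)) {
          cells$barcodes[[i]] <- cells$barcodes[[i - 1L]]
        }
      }
    }
    structure(list(cells = cells, field_um = field_um, lambda = lambda,
                   library = library, seed = seed),
              class = "sim_screen")
  })
}

min_dist_to <- function(x, y, ax, ay) {
  d2 <- matrix(Inf, length(x), length(ax))
  for (j in seq_along(ax)) d2[, j] <- (x - ax[j])^2 + (y - ay[j])^2
  sqrt(apply(d2, 1L, min))
}

#' @export
print.sim_screen <- function(x, ...) {
  cat(sprintf("<sim_screen> %d cells on a %.0f um field (lambda = %.2g)\n",
              nrow(x$cells), x$field_um, x$lambda))
  if (!is.null(x$true_counts)) {
    cat(sprintf("  true_counts: %d x %d\n", nrow(x$true_counts),
                ncol(x$true_counts)))
  }
  if (!is.null(x$images)) {
    cat(sprintf("  images: %d x %d x %d bits\n", dim(x$images)[1],
                dim(x$images)[2], dim(x$images)[3]))
  }
  invisible(x)
}

# Per-gene zonal factor: exp(slope * (z - 0.5)), monotone in z.
zonal_factor <- function(z, slope) exp(outer(z - 0.5, slope))

# Per-cell x gene expected expression under the planted model.
# `ind_folds` maps guide -> named fold-change vector over its induced
# set, pre-calibrated so that `induction_z` is planted in z units.
expected_means <- function(cells, panel, library, mean_library_size,
                           ind_folds = list()) {
  z_eff <- cells$z
  fc <- matrix(1, nrow(cells), nrow(panel),
               dimnames = list(NULL, panel$gene))
  if (!is.null(library) && !is.null(cells$barcodes)) {
    lib <- library
    for (i in seq_len(nrow(cells))) {
      for (g in cells$barcodes[[i]]) {
        row <- lib[lib$guide == g, ]
        if (nrow(row) == 0 || row$is_control) next
        if (row$template %in% c("depletion", "induction", "zonal_shift") &&
            !is.na(row$target)) {
          fc[i, row$target] <- fc[i, row$target] * row$depletion_factor
        }
        if (row$template == "induction" && !is.null(ind_folds[[g]])) {
          set <- names(ind_folds[[g]])
          fc[i, set] <- fc[i, set] * ind_folds[[g]]
        }
        if (row$template == "zonal_shift") {
          z_eff[i] <- min(1, max(0, z_eff[i] + row$delta_z))
        }
      }
    }
  }
  mu <- sweep(zonal_factor(z_eff, panel$zonal_slope), 2L, panel$baseline, "*") * fc
  sweep(mu, 1L, rowSums(mu), "/") * mean_library_size
}

#' Simulate true per-cell transcript counts
#'
#' Per-cell gene means are baseline x zonal factor(z) x perturbation
#' fold-changes, scaled to `mean_library_size` molecules per cell, then
#' drawn negative-binomially with the given dispersion. The targeted gene
#' of a depletion guide is additionally multiplied by its depletion
#' factor. Gene-set induction guides plant their effect in z units: an
#' unperturbed pilot draw estimates the per-gene control sd of
#' log1p(tp10k), and each set gene's mean is multiplied by
#' exp(induction_z x sd) so that the realized z-shift approximates
#' `induction_z`.
#'
#' @param screen A `sim_screen`.
#' @param panel Gene panel tibble.
#' @param mean_library_size Expected molecules per cell. Default 300.
#' @param dispersion NB dispersion (1/size); 0 gives Poisson.
#'   Default 0.15.
#' @param seed RNG seed.
#' @return The screen with `true_counts` (cells x genes integer matrix)
#'   and `panel` attached.
#' @export
simulate_counts <- function(screen, panel, mean_library_size = 300,
                            dispersion = 0.15, seed = 1L) {
  draw <- function(mu, s) {
    withr_seed(s, {
      if (dispersion > 0) {
        matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
               nrow(mu), ncol(mu))
      } else {
        matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu))
      }
    })
  }
  ind_folds <- list()
  carried <- if (is.null(screen$cells$barcodes)) character() else
    unique(unlist(screen$cells$barcodes))
  ind_lib <- if (is.null(screen$library)) NULL else
    screen$library[screen$library$template == "induction" &
                     screen$library$guide %in% carried, ]
  if (!is.null(ind_lib) && nrow(ind_lib) > 0) {
    # pilot draw without perturbations: per induced gene, find the fold f
    # whose mean log1p(tp10k) shift equals induction_z x control sd
    mu0 <- expected_means(screen$cells, panel, library = NULL,
                          mean_library_size)
    pilot <- draw(mu0, seed + 1000L)
    tot <- pmax(rowSums(pilot), 1)
    tp10k <- pilot / tot * 1e4
    lp_mean <- colMeans(log1p(tp10k))
    lp_sd <- apply(log1p(tp10k), 2L, stats::sd)
    names(lp_mean) <- names(lp_sd) <- panel$gene
    share <- colMeans(tp10k) / 1e4
    names(share) <- panel$gene
    for (r in seq_len(nrow(ind_lib))) {
      set <- ind_lib$induced_set[[r]]
      zshift <- ind_lib$induction_z[r]
      # inducing the set inflates the cell total, which deflates tp10k of
      # every gene; iterate the fold search with that renormalization
      folds <- stats::setNames(rep(1, length(set)), set)
      for (it in 1:6) {
        denom <- 1 + sum(share[set] * (folds - 1))
        folds <- vapply(set, function(gn) {
          v <- tp10k[, match(gn, panel$gene)]
          target <- zshift * lp_sd[gn]
          if (all(v == 0) || !is.finite(target)) return(1)
          root <- tryCatch(
            stats::uniroot(function(lf) {
              mean(log1p(exp(lf) * v / denom)) - lp_mean[gn] - target
            }, interval = c(-10, 10))$root,
            error = function(e) zshift * lp_sd[gn] # sparse-gene fallback
          )
          exp(root)
        }, numeric(1))
      }
      ind_folds[[ind_lib$guide[r]]] <- folds
    }
  }
  mu <- expected_means(screen$cells, panel, screen$library,
                       mean_library_size, ind_folds)
  counts <- draw(mu, seed)
  dimnames(counts) <- list(screen$cells$cell_id, panel$gene)
  screen$true_counts <- counts
  screen$panel <- panel
  screen
}

#' Simulate Flex-style UMI tables with sgRNA spike-in probes
#'
#' Transcriptome UMIs are a binomial thinning of the true counts at the
#' capture efficiency. Each guide in the library gets a spike-in probe
#' column: a cell's true guides receive Poisson(`true_guide_mean`) UMIs
#' and every other guide probe receives Poisson(`ambient_rate`) ambient
#' UMIs.
#'
#' @param screen A `sim_screen` with `true_counts`.
#' @param capture_efficiency Per-molecule capture probability.
#'   Default 0.6.
#' @param true_guide_mean Mean UMIs of a truly present guide probe.
#'   Default 50.
#' @param ambient_rate Mean ambient UMIs of an absent guide probe.
#'   Default 0.05.
#' @param seed RNG seed.
#' @return The screen with `flex_umis` (cells x (genes + guide probes)
#'   integer matrix; guide probe columns are named `probe_<guide>`).
#' @export
simulate_flex_counts <- function(screen, capture_efficiency = 0.6,
                                 true_guide_mean = 50, ambient_rate = 0.05,
                                 seed = 1L) {
  stopifnot(!is.null(screen$true_counts), !is.null(screen$library))
  tc <- screen$true_counts
  withr_seed(seed, {
    umis <- matrix(stats::rbinom(length(tc), tc, capture_efficiency),
                   nrow(tc), ncol(tc), dimnames = dimnames(tc))
    guides <- screen$library$guide
    gp <- matrix(stats::rpois(nrow(tc) * length(guides), ambient_rate),
                 nrow(tc), length(guides),
                 dimnames = list(rownames(tc), paste0("probe_", guides)))
    for (i in seq_len(nrow(tc))) {
      for (g in screen$cells$barcodes[[i]]) {
        j <- match(paste0("probe_", g), colnames(gp))
        gp[i, j] <- gp[i, j] + stats::rpois(1L, true_guide_mean)
      }
    }
  })
  screen$flex_umis <- cbind(umis, gp)
  screen
}
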