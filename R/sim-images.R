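#' Render per-bit amplicon image stacks from a simulated screen
#'
#' Every true molecule is placed uniformly inside its cell's disk and
#' rendered as a Gaussian spot in each on-bit plane of its codeword, after
#' independent per-bit flips (an on-bit drops out with probability
#' `p_1to0`; an off-bit lights up with probability `p_0to1`). Blank
#' molecules are injected at `blank_rate` (relative to the true molecule
#' count) using the blank codewords. Gaussian background noise is added to
#' every plane and a 16-bit style label mask is rendered from the cell
#' disks.
#'
#' @param screen A `sim_screen` with `true_counts`.
#' @param codebook A named `codebook` covering every panel gene.
#' @param pixel_um Pixel size in micrometers. Default 1.
#' @param psf_sigma_um Gaussian spot sigma in micrometers. Default 1.
#' @param brightness_meanlog,brightness_sdlog Lognormal amplicon
#'   brightness parameters. Defaults 4 and 0.3.
#' @param p_1to0,p_0to1 Per-bit flip probabilities. Defaults 0.04
#'   and 0.01.
#' @param blank_rate Blank molecules per true molecule. Default 0.
#' @param background_sd SD of additive Gaussian background. Default 1.
#' @param placement `"random"` (uniform in the cell disk) or `"spaced"`
#'   (jittered lattice of pitch `min_spacing_um` inside the disk, which
#'   guarantees resolvable spots; errors if a cell holds more molecules
#'   than lattice positions).
#' @param min_spacing_um Lattice pitch for spaced placement. Default 4.
#' @param seed RNG seed.
#' @return The screen with `images` (H x W x n_bits array), `masks`
#'   (H x W integer label matrix, 0 = background) and `molecules` (ground
#'   truth tibble: `molecule_id`, `x`, `y`, `gene`, `cell_id`,
#'   `codeword_index`, `is_blank`, `bits_true`, `bits_rendered`
#'   list-cols).
#' @export
render_bit_images <- function(screen, codebook, pixel_um = 1,
                              psf_sigma_um = 1, brightness_meanlog = 4,
                              brightness_sdlog = 0.3, p_1to0 = 0.04,
                              p_0to1 = 0.01, blank_rate = 0,
                              background_sd = 1,
                              placement = c("random", "spaced"),
                              min_spacing_um = 4, seed = 1L) {
  placement <- match.arg(placement)
  stopifnot(!is.null(screen$true_counts))
  n_bits <- attr(codebook, "n_bits")
  genes <- colnames(screen$true_counts)
  cw_row <- match(genes, codebook$name)
  if (anyNA(cw_row)) stop("codebook does not name every panel gene")
  cwm <- codeword_matrix(codebook)

  withr_seed(seed, {
    counts <- screen$true_counts
    cell_of <- rep(seq_len(nrow(counts)), times = rowSums(counts))
    gene_of <- unlist(lapply(seq_len(nrow(counts)), function(i) {
      rep.int(seq_len(ncol(counts)), counts[i, ])
    }))
    n_mol <- length(cell_of)
    if (placement == "random") {
      # uniform positions within each molecule's cell disk
      r <- screen$cells$radius[cell_of] * sqrt(stats::runif(n_mol))
      th <- stats::runif(n_mol, 0, 2 * pi)
      mx <- screen$cells$x[cell_of] + r * cos(th)
      my <- screen$cells$y[cell_of] + r * sin(th)
    } else {
      mx <- numeric(n_mol); my <- numeric(n_mol)
      for (ci in unique(cell_of)) {
        sel <- which(cell_of == ci)
        cx <- screen$cells$x[ci]; cy <- screen$cells$y[ci]
        rad <- screen$cells$radius[ci]
        g <- seq(-rad, rad, by = min_spacing_um)
        grid <- expand.grid(gx = g, gy = g)
        grid <- grid[grid$gx^2 + grid$gy^2 <= (rad - 1)^2, , drop = FALSE]
        if (length(sel) > nrow(grid)) {
          stop(sprintf(
            "cell %d holds %d molecules but spaced placement fits only %d; lower the library size or min_spacing_um",
            ci, length(sel), nrow(grid)))
        }
        pick <- grid[sample.int(nrow(grid), length(sel)), , drop = FALSE]
        jit <- min_spacing_um * 0.1
        mx[sel] <- cx + pick$gx + stats::runif(length(sel), -jit, jit)
        my[sel] <- cy + pick$gy + stats::runif(length(sel), -jit, jit)
      }
    }
    mol <- tibble::tibble(
      molecule_id = seq_len(n_mol), x = mx, y = my,
      gene = genes[gene_of], cell_id = screen$cells$cell_id[cell_of],
      codeword_index = codebook$id[cw_row[gene_of]], is_blank = FALSE
    )
    # blank injections, uniform over cells
    blank_rows <- which(codebook$is_blank)
    n_blank_mol <- if (blank_rate > 0 && length(blank_rows) > 0) {
      stats::rpois(1L, blank_rate * n_mol)
    } else 0L
    if (n_blank_mol > 0) {
      bc <- sample(seq_len(nrow(screen$cells)), n_blank_mol, replace = TRUE)
      br <- screen$cells$radius[bc] * sqrt(stats::runif(n_blank_mol))
      bth <- stats::runif(n_blank_mol, 0, 2 * pi)
      mol <- dplyr::bind_rows(mol, tibble::tibble(
        molecule_id = n_mol + seq_len(n_blank_mol),
        x = screen$cells$x[bc] + br * cos(bth),
        y = screen$cells$y[bc] + br * sin(bth),
        gene = NA_character_, cell_id = screen$cells$cell_id[bc],
        codeword_index = codebook$id[sample(blank_rows, n_blank_mol,
                                            replace = TRUE)],
        is_blank = TRUE
      ))
    }
    true_bits <- cwm[match(mol$codeword_index, codebook$id), , drop = FALSE]
    flips <- matrix(stats::runif(length(true_bits)), nrow(true_bits))
    rendered <- ifelse(true_bits == 1L,
                       ifelse(flips < p_1to0, 0L, 1L),
                       ifelse(flips < p_0to1, 1L, 0L))
    mol$bits_true <- asplit(true_bits, 1L)
    mol$bits_rendered <- asplit(rendered, 1L)
    mol$brightness <- stats::rlnorm(nrow(mol), brightness_meanlog,
                                    brightness_sdlog)

    hw <- ceiling(screen$field_um / pixel_um)
    images <- array(stats::rnorm(hw * hw * n_bits, 0, background_sd),
                    dim = c(hw, hw, n_bits))
    sigma_px <- psf_sigma_um / pixel_um
    half <- max(1L, ceiling(3 * sigma_px))
    offs <- -half:half
    kern_1d <- exp(-offs^2 / (2 * sigma_px^2))
    kern <- outer(kern_1d, kern_1d)
    px <- pmin(pmax(round(mol$x / pixel_um + 0.5), 1L), hw)
    py <- pmin(pmax(round(mol$y / pixel_um + 0.5), 1L), hw)
    for (m in seq_len(nrow(mol))) {
      rows <- px[m] + offs
      cols <- py[m] + offs
      ok_r <- rows >= 1 & rows <= hw
      ok_c <- cols >= 1 & cols <= hw
      patch <- kern[ok_r, ok_c, drop = FALSE] * mol$brightness[m]
      for (b in which(mol$bits_rendered[[m]] == 1L)) {
        images[rows[ok_r], cols[ok_c], b] <-
          images[rows[ok_r], cols[ok_c], b] + patch
      }
    }

    masks <- matrix(0L, hw, hw)
    gx <- (seq_len(hw) - 0.5) * pixel_um
    for (i in seq_len(nrow(screen$cells))) {
      cx <- screen$cells$x[i]; cy <- screen$cells$y[i]
      rad <- screen$cells$radius[i]
      xr <- which(abs(gx - cx) <= rad)
      yr <- which(abs(gx - cy) <= rad)
      if (length(xr) == 0 || length(yr) == 0) next
      d2 <- outer((gx[xr] - cx)^2, (gx[yr] - cy)^2, "+")
      sub <- masks[xr, yr, drop = FALSE]
      sub[d2 <= rad^2] <- screen$cells$cell_id[i]
      masks[xr, yr] <- sub
    }
  })
  screen$molecules <- mol
  screen$images <- images
  screen$masks <- masks
  screen$pixel_um <- pixel_um
  screen$codebook <- codebook
  screen
}

#' Simulate decoded-spot intensity vectors directly
#'
#' A desk-scale shortcut around full image rendering for large molecule
#' populations: per-molecule per-bit intensities are drawn from the same
#' generative model as the rendered images (lognormal amplicon brightness
#' on post-flip on-bits, Gaussian background on off-bits) without rasterizing
#' spots, producing a spot table ready for [decode_spots()] along with its
#' ground truth.
#'
#' @param n_molecules Number of coding molecules.
#' @param codebook A named `codebook` (blank codewords drawn at
#'   `blank_rate`).
#' @param p_1to0,p_0to1 Per-bit flip probabilities.
#' @param blank_rate Physical blank molecules per coding molecule;
#'   normally 0 (the default) since blank codewords exist precisely so
#'   that no real molecule carries them and every blank call is a
#'   decoding error.
#' @param brightness_meanlog,brightness_sdlog Lognormal brightness.
#' @param background_sd Off-bit intensity SD (mean 0, truncated at 0).
#' @param seed RNG seed.
#' @return List with `spots` (tibble: `spot_id`, `x`, `y`, `area`, per-bit
#'   intensity matrix in `intensity`) and `truth` (tibble: `spot_id`,
#'   `codeword_index`, `gene`, `is_blank`).
#' @export
simulate_spot_intensities <- function(n_molecules, codebook,
                                      p_1to0 = 0.04, p_0to1 = 0.01,
                                      blank_rate = 0,
                                      brightness_meanlog = 4,
                                      brightness_sdlog = 0.3,
                                      background_sd = 1, seed = 1L) {
  n_bits <- attr(codebook, "n_bits")
  cwm <- codeword_matrix(codebook)
  coding_rows <- which(!codebook$is_blank & !is.na(codebook$name))
  blank_rows <- which(codebook$is_blank)
  withr_seed(seed, {
    n_blank <- if (length(blank_rows) > 0) {
      stats::rpois(1L, blank_rate * n_molecules)
    } else 0L
    rows <- c(sample(coding_rows, n_molecules, replace = TRUE),
              if (n_blank > 0) sample(blank_rows, n_blank, replace = TRUE))
    n <- length(rows)
    bits <- cwm[rows, , drop = FALSE]
    flips <- matrix(stats::runif(length(bits)), n)
    rendered <- ifelse(bits == 1L, ifelse(flips < p_1to0, 0L, 1L),
                       ifelse(flips < p_0to1, 1L, 0L))
    bright <- stats::rlnorm(n, brightness_meanlog, brightness_sdlog)
    noise <- matrix(abs(stats::rnorm(n * n_bits, 0, background_sd)), n)
    spot_scale <- matrix(stats::rlnorm(n * n_bits, 0, 0.2), n)
    intensity <- rendered * bright * spot_scale + noise
    spots <- tibble::tibble(
      spot_id = seq_len(n),
      x = stats::runif(n, 0, 100), y = stats::runif(n, 0, 100),
      area = 4 + stats::rpois(n, 3)
    )
    spots$intensity <- intensity
    truth <- tibble::tibble(
      spot_id = spots$spot_id,
      codeword_index = codebook$id[rows],
      gene = codebook$name[rows],
      is_blank = codebook$is_blank[rows]
    )
    list(spots = spots, truth = truth)
  })
}
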