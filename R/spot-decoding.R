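#' Spot detection, decoding, misidentification filtering, cell assignment
#'
#' Amplicon spots are detected as local maxima of the across-bit maximum
#' projection, decoded against the codebook after per-bit normalization
#' and binarization, scored by a blank-trained gradient-boosted classifier
#' and thresholded at an adaptive blank-based misidentification rate, then
#' assigned to cells through the label mask.
#'
#' @name spot_decoding
NULL

#' Detect amplicon spots in a bit-image stack
#'
#' Local maxima of the across-bit max projection above
#' `intensity_threshold`, with non-maximum suppression at
#' `min_separation` pixels; per-bit intensity is the maximum within
#' `radius` pixels of the spot center.
#'
#' @param images H x W x n_bits array.
#' @param min_separation Minimum center-to-center spot distance (px).
#'   Default 3.
#' @param intensity_threshold Minimum max-projection value. Default 5.
#' @param radius Per-bit readout radius (px). Default 1.
#' @param pixel_um Pixel size for reporting coordinates in micrometers.
#'   Default 1.
#' @return Tibble: `spot_id`, `x`, `y` (um), `area` (px above half the
#'   peak), `intensity` (n_spots x n_bits matrix column).
#' @export
detect_spots <- function(images, min_separation = 3, intensity_threshold = 5,
                         radius = 1L, pixel_um = 1) {
  proj <- apply(images, c(1, 2), max)
  hw <- dim(proj)
  cand <- which(proj > intensity_threshold, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    return(tibble::tibble(spot_id = integer(), x = numeric(),
                          y = numeric(), area = numeric(),
                          intensity = matrix(numeric(), 0, dim(images)[3])))
  }
  vals <- proj[cand]
  ord <- order(vals, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  vals <- vals[ord]
  keep <- logical(nrow(cand))
  kept_xy <- matrix(numeric(), 0, 2)
  for (i in seq_len(nrow(cand))) {
    if (nrow(kept_xy) == 0 ||
        all((kept_xy[, 1] - cand[i, 1])^2 + (kept_xy[, 2] - cand[i, 2])^2 >=
              min_separation^2)) {
      keep[i] <- TRUE
      kept_xy <- rbind(kept_xy, cand[i, ])
    }
  }
  centers <- cand[keep, , drop = FALSE]
  n_bits <- dim(images)[3]
  offs <- -radius:radius
  intensity <- matrix(0, nrow(centers), n_bits)
  area <- numeric(nrow(centers))
  for (s in seq_len(nrow(centers))) {
    rows <- centers[s, 1] + offs
    cols <- centers[s, 2] + offs
    rows <- rows[rows >= 1 & rows <= hw[1]]
    cols <- cols[cols >= 1 & cols <= hw[2]]
    patch_proj <- proj[rows, cols, drop = FALSE]
    area[s] <- sum(patch_proj >= proj[centers[s, 1], centers[s, 2]] / 2)
    for (b in seq_len(n_bits)) {
      intensity[s, b] <- max(images[rows, cols, b])
    }
  }
  out <- tibble::tibble(
    spot_id = seq_len(nrow(centers)),
    x = (centers[, 1] - 0.5) * pixel_um,
    y = (centers[, 2] - 0.5) * pixel_um,
    area = area
  )
  out$intensity <- intensity
  out
}

#' Decode detected spots against a codebook
#'
#' Per-bit intensities are scaled by a per-bit normalization factor (the
#' `norm_quantile` quantile of that bit's clearly-on values, i.e. values
#' above 30% of the bit's maximum, which is robust to uneven bit usage
#' across the panel), then binarized
#' per spot at `binarize_threshold` times the spot's maximum normalized
#' intensity (amplicon brightness varies over orders of magnitude, so the
#' cutoff must track the spot, not the panel), and decoded with
#' single-bit correction. Quality
#' features (mean normalized on-bit and off-bit intensity relative to the
#' assigned codeword, their ratio, Hamming distance, spot area) are
#' attached for misidentification filtering.
#'
#' @param spots Tibble from [detect_spots()] or
#'   [simulate_spot_intensities()].
#' @param codebook A named `codebook`.
#' @param max_correction Correction radius (0 or 1). Default 1.
#' @param norm_quantile Quantile of each bit's on-values used as its
#'   normalization factor. Default 0.5 (median).
#' @param binarize_threshold Normalized-intensity cutoff, as a fraction
#'   of the spot's maximum normalized intensity. Default 0.5.
#' @return Tibble of decoded molecules: spot columns plus `outcome`,
#'   `codeword_index`, `gene`, `hamming_distance`, `mean_on`, `mean_off`,
#'   `on_off_ratio`.
#' @export
decode_spots <- function(spots, codebook, max_correction = 1L,
                         norm_quantile = 0.5, binarize_threshold = 0.5) {
  if (nrow(spots) == 0) return(tibble::tibble())
  intensity <- spots$intensity
  norm <- apply(intensity, 2L, function(v) {
    on_vals <- v[v > 0.3 * max(v)]
    if (length(on_vals) == 0) return(1)
    stats::quantile(on_vals, norm_quantile)
  })
  norm[!is.finite(norm) | norm <= 0] <- 1
  scaled <- sweep(intensity, 2L, norm, "/")
  spot_max <- apply(scaled, 1L, max)
  spot_max[spot_max <= 0] <- 1
  bits <- (scaled >= binarize_threshold * spot_max) * 1L
  calls <- decode_bit_matrix(bits, codebook, max_correction)
  cwm <- codeword_matrix(codebook)
  assigned <- match(calls$codeword_index, codebook$id)
  on_mask <- cwm[ifelse(is.na(assigned), 1L, assigned), , drop = FALSE]
  mean_on <- rowSums(scaled * on_mask) / rowSums(on_mask)
  mean_off <- rowSums(scaled * (1 - on_mask)) / rowSums(1 - on_mask)
  mean_on[is.na(assigned)] <- NA_real_
  mean_off[is.na(assigned)] <- NA_real_
  out <- dplyr::bind_cols(
    dplyr::select(spots, -"intensity"),
    calls,
    tibble::tibble(
      gene = codebook$name[assigned],
      mean_on = mean_on, mean_off = mean_off,
      on_off_ratio = mean_on / pmax(mean_off, 1e-6)
    )
  )
  out
}

misid_features <- function(molecules) {
  as.matrix(molecules[, c("mean_on", "mean_off", "on_off_ratio",
                          "hamming_distance", "area")])
}

#' Fit the blank-trained misidentification classifier
#'
#' Gradient-boosted trees discriminating blank-assigned from
#' coding-assigned molecules on the decode quality features, trained with
#' k-fold cross-fitting: the score of every molecule comes from the model
#' whose training fold excluded it, so no molecule is scored by a model
#' that saw it.
#'
#' @param molecules Decoded molecules (outcome `target` or `blank`;
#'   `no_call` rows are ignored).
#' @param n_folds Cross-fitting folds. Default 5.
#' @param nrounds Boosting rounds. Default 50.
#' @param seed RNG seed.
#' @return A `misid_filter` object with per-molecule scores (probability
#'   of being a correctly decoded coding molecule) aligned to the rows of
#'   `molecules`.
#' @export
fit_misid_filter <- function(molecules, n_folds = 5L, nrounds = 50L,
                             seed = 1L) {
  called <- molecules$outcome %in% c("target", "blank")
  y <- as.integer(molecules$outcome[called] == "target")
  if (length(unique(y)) < 2L) {
    stop("degenerate input: need at least one blank-assigned and one ",
         "coding-assigned molecule to train the misidentification filter")
  }
  x <- misid_features(molecules[called, ])
  idx <- which(called)
  score <- rep(NA_real_, nrow(molecules))
  withr_seed(seed, {
    fold <- sample(rep_len(seq_len(n_folds), length(y)))
    models <- vector("list", n_folds)
    for (f in seq_len(n_folds)) {
      train <- fold != f
      dtrain <- xgboost::xgb.DMatrix(x[train, , drop = FALSE],
                                     label = y[train])
      models[[f]] <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 3,
                      eta = 0.3, nthread = 1, seed = seed),
        data = dtrain, nrounds = nrounds, verbose = 0
      )
      score[idx[fold == f]] <- stats::predict(
        models[[f]], xgboost::xgb.DMatrix(x[fold == f, , drop = FALSE]))
    }
  })
  structure(list(models = models, n_folds = n_folds, score = score,
                 feature_names = colnames(x), seed = seed),
            class = "misid_filter")
}

#' @export
print.misid_filter <- function(x, ...) {
  cat(sprintf("<misid_filter> %d-fold cross-fitted xgboost on features: %s\n",
              x$n_folds, paste(x$feature_names, collapse = ", ")))
  invisible(x)
}

#' Retain molecules at an adaptive misidentification threshold
#'
#' The misidentification rate at score cutoff c is the per-codeword blank
#' rate over the per-codeword coding rate among molecules scoring at least
#' c: m(c) = (retained blanks / blank codewords) / (retained coding /
#' coding codewords). The smallest cutoff with m(c) <= `target_rate` is
#' used, so as many molecules as possible are kept; blank-assigned
#' molecules are never exported.
#'
#' @param molecules Decoded molecules.
#' @param filter A `misid_filter` fitted on the same molecules.
#' @param codebook The `codebook` used for decoding (codeword counts enter
#'   the rate).
#' @param target_rate Target misidentification rate. Default 0.05.
#' @return List: `molecules` (with `score` and `retained` columns; only
#'   coding molecules can be retained), `achieved_rate`, `cutoff`.
#' @export
apply_adaptive_threshold <- function(molecules, filter, codebook,
                                     target_rate = 0.05) {
  stopifnot(length(filter$score) == nrow(molecules))
  n_blank_cw <- sum(codebook$is_blank)
  n_coding_cw <- sum(!codebook$is_blank & !is.na(codebook$name))
  molecules$score <- filter$score
  is_coding <- molecules$outcome == "target"
  is_blank <- molecules$outcome == "blank"
  called <- which(is_coding | is_blank)
  ord <- called[order(molecules$score[called], decreasing = TRUE)]
  # cumulative retained counts when the cutoff sits just below each score
  cum_blank <- cumsum(is_blank[ord])
  cum_coding <- cumsum(is_coding[ord])
  sc_sorted <- molecules$score[ord]
  # valid cutoff boundaries: after the last of a run of tied scores
  boundary <- c(sc_sorted[-1] < sc_sorted[-length(sc_sorted)], TRUE)
  m_k <- ifelse(cum_coding == 0, Inf,
                (cum_blank / n_blank_cw) / (cum_coding / n_coding_cw))
  ok <- which(boundary & m_k <= target_rate)
  if (length(ok) == 0) {
    warning("no score cutoff achieves the target misidentification rate; ",
            "retaining nothing")
    molecules$retained <- FALSE
    return(list(molecules = molecules, achieved_rate = NA_real_,
                cutoff = NA_real_))
  }
  k <- max(ok) # most molecules retained, i.e. smallest admissible cutoff
  cutoff <- sc_sorted[k]
  molecules$retained <- is_coding & !is.na(molecules$score) &
    molecules$score >= cutoff
  list(molecules = molecules, achieved_rate = m_k[k], cutoff = cutoff)
}

#' Assign retained molecules to cells via the label mask
#'
#' Each molecule takes the label at its pixel; label 0 is background
#' (unassigned). Counts are summed per (cell, target).
#'
#' @param molecules Decoded molecule tibble with `x`, `y` (um) and `gene`;
#'   typically the retained set.
#' @param masks H x W integer label matrix.
#' @param pixel_um Pixel size (um).
#' @return List: `molecules` with `cell_id` (`NA` = unassigned), `counts`
#'   (cells x genes integer matrix over assigned molecules).
#' @export
assign_to_cells <- function(molecules, masks, pixel_um = 1) {
  px <- pmin(pmax(round(molecules$x / pixel_um + 0.5), 1L), nrow(masks))
  py <- pmin(pmax(round(molecules$y / pixel_um + 0.5), 1L), ncol(masks))
  lab <- masks[cbind(px, py)]
  molecules$cell_id <- ifelse(lab == 0L, NA_integer_, lab)
  assigned <- molecules[!is.na(molecules$cell_id) & !is.na(molecules$gene), ]
  tab <- table(cell_id = assigned$cell_id, gene = assigned$gene)
  counts <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                   dimnames = dimnames(tab))
  list(molecules = molecules, counts = counts)
}
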