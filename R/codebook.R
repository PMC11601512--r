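#' Constant-weight error-robust codebooks
#'
#' A codebook is a set of binary codewords of fixed length (`n_bits`), all of
#' the same Hamming weight, with every pair of codewords at Hamming distance
#' at least `min_distance`. Distance-4 codes detect two-bit errors and
#' correct single-bit errors, which is what makes MERFISH readout robust to
#' occasional mis-called hybridization rounds. Codebooks are represented as
#' tibbles with one row per codeword and metadata stored in attributes.
#'
#' @name codebook
NULL

new_codebook <- function(words, n_bits, weight, min_distance, seed) {
  cb <- tibble::tibble(
    id = seq_len(nrow(words)),
    name = NA_character_,
    is_blank = FALSE,
    bit_string = apply(words, 1L, paste, collapse = "")
  )
  attr(cb, "n_bits") <- as.integer(n_bits)
  attr(cb, "weight") <- as.integer(weight)
  attr(cb, "min_distance") <- as.integer(min_distance)
  attr(cb, "schedule") <- NULL
  attr(cb, "seed") <- as.integer(seed)
  class(cb) <- c("codebook", class(cb))
  cb
}

#' Extract the codeword bit matrix of a codebook
#'
#' @param codebook A `codebook` tibble.
#' @return Integer 0/1 matrix with one row per codeword and `n_bits` columns.
#' @export
codeword_matrix <- function(codebook) {
  n_bits <- attr(codebook, "n_bits")
  m <- matrix(
    as.integer(unlist(strsplit(codebook$bit_string, "", fixed = TRUE))),
    ncol = n_bits, byrow = TRUE
  )
  rownames(m) <- codebook$id
  m
}

# All weight-w words of length n as a 0/1 matrix (rows = words).
all_constant_weight_words <- function(n_bits, weight) {
  combs <- utils::combn(n_bits, weight)
  words <- matrix(0L, nrow = ncol(combs), ncol = n_bits)
  words[cbind(rep(seq_len(ncol(combs)), each = weight), as.vector(combs))] <- 1L
  words
}

# Pairwise Hamming distances for constant-weight words via inner products:
# d(x, y) = w_x + w_y - 2 * <x, y>.
hamming_matrix <- function(words) {
  w <- rowSums(words)
  inner <- tcrossprod(words)
  outer(w, w, "+") - 2L * inner
}

#' Generate a constant-weight code with guaranteed minimum distance
#'
#' Builds a binary code in which every codeword has exactly `weight` on-bits
#' and all pairwise Hamming distances are at least `min_distance`. The
#' construction partitions all weight-`weight` words by the sum of their
#' on-bit positions modulo `n_bits`: moving a single bit changes that sum by
#' a nonzero residue, so two distinct words in one class differ by at least
#' two bit moves and hence sit at distance >= 4. The largest class is taken
#' as the base code and then greedily augmented with words from the other
#' classes, visited in seeded-shuffled order, keeping any word compatible
#' with everything accepted so far. The class construction alone guarantees
#' at least `floor(choose(n_bits, weight) / n_bits)` codewords.
#'
#' @param n_bits Codeword length in bits.
#' @param weight Number of on-bits per codeword.
#' @param min_distance Required minimum pairwise Hamming distance (even;
#'   only 4 is guaranteed by the class construction, larger values are
#'   enforced by filtering and may be infeasible).
#' @param n_needed Number of codewords required; an error is raised if the
#'   search finishes with fewer.
#' @param seed Integer seed controlling the augmentation order.
#' @return A `codebook` tibble (unnamed, no schedule yet) with at least
#'   `n_needed` rows.
#' @examples
#' cb <- generate_constant_weight_code(21, 4, 4, 209)
#' nrow(cb)
#' @export
generate_constant_weight_code <- function(n_bits, weight, min_distance,
                                          n_needed, seed = 1L) {
  stopifnot(n_bits >= weight, weight >= 1, n_needed >= 1)
  if (min_distance %% 2 != 0) {
    stop("`min_distance` must be even: constant-weight codewords always ",
         "differ at an even number of positions.")
  }
  words <- all_constant_weight_words(n_bits, weight)
  pos_sum <- as.integer(words %*% seq_len(n_bits)) %% n_bits
  class_sizes <- table(pos_sum)
  base_class <- as.integer(names(class_sizes)[which.max(class_sizes)])
  accepted <- words[pos_sum == base_class, , drop = FALSE]
  if (min_distance > 4 && nrow(accepted) > 1) {
    # the class guarantee is distance 4; prune greedily for stricter codes
    keep <- 1L
    for (i in seq_len(nrow(accepted))[-1]) {
      d <- colSums(abs(t(accepted[keep, , drop = FALSE]) - accepted[i, ]))
      if (all(d >= min_distance)) keep <- c(keep, i)
    }
    accepted <- accepted[keep, , drop = FALSE]
  }
  rest <- words[pos_sum != base_class, , drop = FALSE]
  if (nrow(rest) > 0) {
    # distances to the whole base set in one product (equal weights):
    # min_j d(cand, base_j) = 2w - 2 max_j <cand, base_j>
    inner <- rest %*% t(accepted)
    max_inner <- inner[cbind(seq_len(nrow(rest)), max.col(inner))]
    rest <- rest[2 * weight - 2 * max_inner >= min_distance, ,
                 drop = FALSE]
  }
  if (nrow(rest) > 0) {
    order_rest <- withr_seed(seed, sample.int(nrow(rest)))
    extra <- matrix(0L, nrow = nrow(rest), ncol = n_bits)
    n_extra <- 0L
    for (i in order_rest) {
      cand <- rest[i, ]
      ok <- n_extra == 0L ||
        all(2 * weight - 2 * as.vector(
          extra[seq_len(n_extra), , drop = FALSE] %*% cand) >= min_distance)
      if (ok) {
        n_extra <- n_extra + 1L
        extra[n_extra, ] <- cand
      }
    }
    accepted <- rbind(accepted, extra[seq_len(n_extra), , drop = FALSE])
  }
  rownames(accepted) <- NULL
  if (nrow(accepted) < n_needed) {
    stop(sprintf(
      "code search exhausted: needed %d codewords but only %d attainable at (n_bits=%d, weight=%d, min_distance=%d)",
      n_needed, nrow(accepted), n_bits, weight, min_distance
    ))
  }
  new_codebook(accepted, n_bits, weight, min_distance, seed)
}

# Run `expr` under a local RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Randomly assign target names and blank codewords
#'
#' Names are mapped onto codewords by a seeded random bijection; a further
#' `n_blanks` codewords are flagged blank. Blank codewords are carried
#' through decoding like any other codeword but correspond to no real
#' target; molecules decoded to blanks estimate the misidentification rate.
#'
#' @param codebook A `codebook`.
#' @param target_names Character vector of target names.
#' @param n_blanks Number of blank codewords to flag. Default 10% of the
#'   number of names (rounded up).
#' @param seed Integer seed for the assignment.
#' @return The codebook with `name` and `is_blank` filled in; unused
#'   codewords keep `name = NA` and `is_blank = FALSE`.
#' @export
assign_targets <- function(codebook, target_names,
                           n_blanks = ceiling(0.1 * length(target_names)),
                           seed = 1L) {
  stopifnot(!anyDuplicated(target_names))
  k <- length(target_names) + n_blanks
  if (k > nrow(codebook)) {
    stop(sprintf("need %d codewords for %d names + %d blanks but codebook has %d",
                 k, length(target_names), n_blanks, nrow(codebook)))
  }
  picked <- withr_seed(seed, sample.int(nrow(codebook), k))
  codebook$name <- NA_character_
  codebook$is_blank <- FALSE
  codebook$name[picked[seq_along(target_names)]] <- target_names
  if (n_blanks > 0) {
    blank_rows <- picked[length(target_names) + seq_len(n_blanks)]
    codebook$is_blank[blank_rows] <- TRUE
    codebook$name[blank_rows] <- sprintf("Blank-%02d", seq_len(n_blanks))
  }
  codebook
}

#' Assign bits to imaging rounds and color channels
#'
#' Bits are laid out consecutively: bit 1 is (round 1, channel 1), bit 2 is
#' (round 1, channel 2), and so on, wrapping to a new round every
#' `colors_per_round` bits. 21 bits at 3 colors gives the 7-round schedule
#' used for gene panels.
#'
#' @param codebook A `codebook`.
#' @param colors_per_round Number of color channels imaged per round.
#' @return The codebook with a `schedule` attribute: a tibble with columns
#'   `bit`, `round`, `channel`.
#' @export
schedule_rounds <- function(codebook, colors_per_round = 3L) {
  stopifnot(colors_per_round >= 1)
  n_bits <- attr(codebook, "n_bits")
  bit <- seq_len(n_bits)
  attr(codebook, "schedule") <- tibble::tibble(
    bit = bit,
    round = ((bit - 1L) %/% colors_per_round) + 1L,
    channel = ((bit - 1L) %% colors_per_round) + 1L
  )
  codebook
}

#' Decode one measured bit vector against a codebook
#'
#' An exact match decodes at distance 0. Otherwise, if exactly one codeword
#' lies within `max_correction` bits, the vector is corrected to it (the
#' flipped bit index is reported). Any tie or a nearest codeword beyond the
#' correction radius yields `no_call`; ties are never broken arbitrarily.
#'
#' @param bits Integer 0/1 vector of length `n_bits`.
#' @param codebook A `codebook`.
#' @param max_correction Correction radius, 0 (strict) or 1 (the MHD4
#'   single-error guarantee). Default 1.
#' @return A one-row tibble: `outcome` (`"target"`, `"blank"`, `"no_call"`),
#'   `codeword_index`, `hamming_distance`, `corrected_bit`.
#' @export
decode_bit_vector <- function(bits, codebook, max_correction = 1L) {
  stopifnot(length(bits) == attr(codebook, "n_bits"),
            max_correction %in% c(0L, 1L))
  m <- codeword_matrix(codebook)
  d <- rowSums(m != rep(as.integer(bits), each = nrow(m)))
  dmin <- min(d)
  hits <- which(d == dmin)
  if (dmin > max_correction || length(hits) != 1L) {
    return(tibble::tibble(outcome = "no_call", codeword_index = NA_integer_,
                          hamming_distance = as.integer(dmin),
                          corrected_bit = NA_integer_))
  }
  idx <- hits[1L]
  corrected <- if (dmin == 0L) NA_integer_ else which(m[idx, ] != bits)[1L]
  outcome <- if (isTRUE(codebook$is_blank[idx])) "blank" else "target"
  tibble::tibble(outcome = outcome, codeword_index = codebook$id[idx],
                 hamming_distance = as.integer(dmin),
                 corrected_bit = corrected)
}

# Vectorised decoding of many bit vectors (rows of `bits_mat`); used by the
# spot decoder and the exhaustive error-correction checks.
decode_bit_matrix <- function(bits_mat, codebook, max_correction = 1L) {
  m <- codeword_matrix(codebook)
  w_code <- rowSums(m)
  w_obs <- rowSums(bits_mat)
  # d(x, c) = |x| + |c| - 2 <x, c>
  inner <- bits_mat %*% t(m)
  d <- outer(w_obs, w_code, "+") - 2 * inner
  argmin <- max.col(-d, ties.method = "first")
  dmin <- d[cbind(seq_len(nrow(d)), argmin)]
  n_at_min <- rowSums(d == dmin)
  callable <- dmin <= max_correction & n_at_min == 1L
  idx <- ifelse(callable, argmin, NA_integer_)
  outcome <- rep("no_call", nrow(bits_mat))
  outcome[callable] <- ifelse(codebook$is_blank[idx[callable]], "blank", "target")
  tibble::tibble(
    outcome = outcome,
    codeword_index = codebook$id[idx],
    hamming_distance = as.integer(dmin)
  )
}

#' Restrict a codebook to its active (named or blank) codewords
#'
#' Decoding should only consider codewords that are in use: molecules
#' landing on unused codewords would otherwise be silently absorbed
#' instead of counted as no-calls.
#'
#' @param codebook A `codebook` after [assign_targets()].
#' @return The codebook with unused codewords removed (attributes kept).
#' @export
active_codebook <- function(codebook) {
  keep <- !is.na(codebook$name)
  out <- codebook[keep, ]
  for (a in c("n_bits", "weight", "min_distance", "schedule", "seed")) {
    attr(out, a) <- attr(codebook, a)
  }
  class(out) <- class(codebook)
  out
}

#' Exhaustively verify a codebook
#'
#' Brute-force O(K^2 n) computation of the minimum pairwise Hamming
#' distance, the set of codeword weights, and the code size. This is the
#' oracle against which generated codebooks are checked; it shares no logic
#' with the generator.
#'
#' @param codebook A `codebook`.
#' @return A list with `size`, `weights` (sorted unique weights) and
#'   `min_distance` (`NA` with message `"undefined"` for a single codeword).
#' @export
verify_code <- function(codebook) {
  stopifnot(nrow(codebook) >= 1)
  m <- codeword_matrix(codebook)
  if (nrow(m) == 1L) {
    return(list(size = 1L, weights = sum(m), min_distance = NA_integer_,
                note = "undefined"))
  }
  d <- hamming_matrix(m)
  list(
    size = nrow(m),
    weights = sort(unique(rowSums(m))),
    min_distance = min(d[upper.tri(d)])
  )
}

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf(
    "<codebook> %d codewords, %d bits, weight %d, min distance %d (%d named, %d blank)\n",
    nrow(x), attr(x, "n_bits"), attr(x, "weight"), attr(x, "min_distance"),
    sum(!is.na(x$name) & !x$is_blank), sum(x$is_blank)
  ))
  NextMethod()
}

#' Write / read a codebook as CSV
#'
#' The on-disk format is `name,id,is_blank,bit_string` with `bit_string` an
#' `n_bits`-character 0/1 string (bit 1 leftmost); the schedule, when
#' present, is written alongside as `<path>.schedule.csv` with columns
#' `bit,round,channel`.
#'
#' @param codebook A `codebook`.
#' @param path Output CSV path.
#' @return `path`, invisibly (`write_codebook`); a `codebook`
#'   (`read_codebook`).
#' @export
write_codebook <- function(codebook, path) {
  utils::write.csv(
    data.frame(name = codebook$name, id = codebook$id,
               is_blank = codebook$is_blank, bit_string = codebook$bit_string),
    path, row.names = FALSE, quote = FALSE, na = ""
  )
  sched <- attr(codebook, "schedule")
  if (!is.null(sched)) {
    utils::write.csv(as.data.frame(sched), paste0(path, ".schedule.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_codebook
#' @param weight,min_distance Metadata to attach on read (not stored in the
#'   CSV); `weight` defaults to the popcount of the first codeword.
#' @export
read_codebook <- function(path, min_distance = 4L, weight = NULL) {
  df <- utils::read.csv(path, colClasses = c(
    name = "character", id = "integer", is_blank = "logical",
    bit_string = "character"
  ))
  n_bits <- nchar(df$bit_string[1L])
  if (is.null(weight)) {
    weight <- sum(as.integer(strsplit(df$bit_string[1L], "")[[1L]]))
  }
  cb <- tibble::as_tibble(df)
  cb$name[cb$name == ""] <- NA_character_
  attr(cb, "n_bits") <- as.integer(n_bits)
  attr(cb, "weight") <- as.integer(weight)
  attr(cb, "min_distance") <- as.integer(min_distance)
  attr(cb, "seed") <- NA_integer_
  sched_path <- paste0(path, ".schedule.csv")
  if (file.exists(sched_path)) {
    attr(cb, "schedule") <- tibble::as_tibble(utils::read.csv(sched_path))
  }
  class(cb) <- c("codebook", class(cb))
  cb
}
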