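# Shared fixtures, built fresh per test run.

# Small named gene codebook: 21 bits, weight 4, distance 4.
small_gene_codebook <- function(n_targets = 30, n_blanks = 5, seed = 6) {
  cb <- generate_constant_weight_code(21, 4, 4, n_targets + n_blanks)
  assign_targets(cb, sprintf("G%03d", seq_len(n_targets)),
                 n_blanks = n_blanks, seed = seed)
}

# Tiny panel/library/screen for pipeline tests.
small_screen <- function(n_cells = 100, seed = 3, lambda = 0.3,
                         mean_library_size = 10) {
  pl <- build_panel_and_library(n_genes = 30, n_targets = 10,
                                n_controls = 5, seed = 2)
  scr <- simulate_tissue(n_cells, field_um = 320, lambda = lambda,
                         library = pl$library, seed = seed)
  scr <- simulate_counts(scr, pl$panel,
                         mean_library_size = mean_library_size,
                         dispersion = 0.1, seed = seed + 1)
  list(screen = scr, panel = pl$panel, library = pl$library,
       upr_set = pl$upr_set)
}

# Codebook naming an explicit gene set.
codebook_for <- function(genes, n_blanks = 5, seed = 6) {
  cb <- generate_constant_weight_code(21, 4, 4, length(genes) + n_blanks)
  assign_targets(cb, genes, n_blanks = n_blanks, seed = seed)
}

# Independent brute-force Hamming distance between two 0/1 vectors.
hamming_bf <- function(a, b) sum(a != b)

# Independent brute-force minimum pairwise distance of a codebook.
min_distance_bf <- function(codebook) {
  m <- codeword_matrix(codebook)
  best <- Inf
  for (i in seq_len(nrow(m) - 1)) {
    for (j in (i + 1):nrow(m)) {
      best <- min(best, hamming_bf(m[i, ], m[j, ]))
    }
  }
  best
}

bits_of <- function(codebook, row) {
  as.integer(strsplit(codebook$bit_string[row], "")[[1]])
}
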