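test_that("nearest-neighbor Tm matches an independent hand computation", {
  # expected value computed independently by summing the published unified
  # nearest-neighbor table for this 30-mer (300 mM Na+, 5 nM strands)
  seq30 <- "ATGCTGACCGTTAGCTAGGATCCATGCAAT"
  expect_equal(melting_temperature(seq30), 68.732824, tolerance = 1e-6)
  # duplex symmetry: a sequence and its reverse complement melt identically
  expect_equal(melting_temperature(merscreen:::revcomp(seq30)),
               melting_temperature(seq30))
  # linear formamide correction: 30% at -0.6 C/% lowers Tm by 18 C
  expect_equal(melting_temperature(seq30, formamide_pct = 30),
               melting_temperature(seq30) - 18)
  expect_error(melting_temperature("ATGNNATGCATG"), "ambiguous")
  expect_error(melting_temperature("ATGC"), "at least 8")
})

test_that("specificity indices count shared k-mers across genes/isoforms", {
  private <- random_transcript(200, seed = 31)
  other <- random_transcript(200, seed = 32)
  tx <- tibble::tibble(
    transcript_id = c("t1", "t2"), gene = c("g1", "g2"),
    seq = c(private, other)
  )
  idx <- build_kmer_index(tx, k = 15)
  probe <- substr(private, 50, 109)
  si <- specificity_indices(probe, idx, "g1", "t1")
  expect_equal(unname(si), c(1, 1))
  # sequence duplicated verbatim in a second gene: every k-mer shared
  dup <- tibble::tibble(
    transcript_id = c("t1", "t2"), gene = c("g1", "g2"),
    seq = c(private, paste0(substr(other, 1, 50), probe))
  )
  idx2 <- build_kmer_index(dup, k = 15)
  si2 <- specificity_indices(probe, idx2, "g1", "t1")
  expect_equal(unname(si2[["gene_si"]]), 0)
  # a second isoform of the same gene hits isoform_si, not gene_si
  iso <- tibble::tibble(
    transcript_id = c("t1", "t1b"), gene = c("g1", "g1"),
    seq = c(private, probe)
  )
  idx3 <- build_kmer_index(iso, k = 15)
  si3 <- specificity_indices(probe, idx3, "g1", "t1")
  expect_equal(unname(si3[["gene_si"]]), 1)
  expect_equal(unname(si3[["isoform_si"]]), 0)
  expect_error(merscreen:::all_kmers("ACGT", 10), "k longer")
})

test_that("candidate filters enforce the printed design rules", {
  tx <- random_transcript(400, seed = 41)
  sites <- evaluate_candidate(candidate_sites("tx", tx))
  # GC rule: 10 G/C in 30 nt (0.333) is inside [0.30, 0.70]
  th <- probe_thresholds()
  expect_true(10 / 30 >= th$gc[1] && 10 / 30 <= th$gc[2])
  # junction rule: windows whose midpoint base is G or C fail
  g_or_c <- sites$junction_base %in% c("G", "C")
  expect_equal(sites$pass_junction, !g_or_c)
  expect_true(all(!sites$pass[g_or_c]))
  # contaminant rule: a 16-nt exact match fails, 15-nt does not
  rrna <- paste0(merscreen:::revcomp(random_transcript(60, seed = 51)),
                 substr(tx, 101, 116)) # 16 nt shared with window at 100
  sites_c <- evaluate_candidate(
    candidate_sites("tx", tx, contaminants = rrna))
  hit <- sites_c[sites_c$start == 100, ]
  expect_gte(hit$max_rrna_match, 16)
  expect_false(hit$pass_contaminant)
  clean <- sites_c[sites_c$start == 300, ]
  expect_true(clean$pass_contaminant)
  # arms are reverse complements of adjacent transcript halves
  s0 <- sites[sites$start == 0, ]
  expect_equal(s0$arm_acceptor, merscreen:::revcomp(substr(tx, 1, 30)))
  expect_equal(s0$arm_donor, merscreen:::revcomp(substr(tx, 31, 60)))
})

test_that("probe sets hit the per-target budgets and re-pass all filters", {
  tx <- random_transcript(2000, seed = 42)
  ro <- generate_readout_pool(21)
  cw <- integer(21); cw[c(1, 5, 9, 13)] <- 1L
  probes <- design_probe_set("tx1", tx, cw, ro, n_probes = 8)
  expect_equal(nrow(probes), 8)
  # non-overlapping on transcript coordinates
  expect_true(all(diff(sort(probes$start)) >= 60))
  # idempotent filtering: every emitted probe re-passes every rule
  resites <- evaluate_candidate(
    candidate_sites("tx1", tx)[match(probes$start,
                                     candidate_sites("tx1", tx)$start), ])
  expect_true(all(resites$pass))
  # exactly 4 readout complements, matching the codeword's on-bits
  expect_true(all(vapply(probes$readout_bits, identical,
                         logical(1), y = c(1L, 5L, 9L, 13L))))
  ro_rc <- merscreen:::revcomp(ro$sequence[c(1, 5, 9, 13)])
  expect_true(all(vapply(seq_len(8), function(i) {
    all(vapply(ro_rc, grepl, logical(1), x = probes$padlock_sequence[i],
               fixed = TRUE))
  }, logical(1))))
  # assembled padlock length within the expected range
  expect_true(all(probes$length >= 140 & probes$length <= 170))
  # barcode target: 3 probes at length 170
  bc <- generate_barcodes(1, seed = 5)
  cwb <- integer(18); cwb[c(2, 4, 6, 8, 10, 12)] <- 1L
  rob <- generate_readout_pool(18, seed = 8)
  bp <- design_probe_set("bc1", bc, cwb, rob, n_probes = 3, step = 1)
  expect_equal(nrow(bp), 3)
  expect_true(all(bp$length >= 140 & bp$length <= 170))
  # supply-limited target: warning, not error
  short_tx <- random_transcript(200, seed = 43)
  expect_warning(
    few <- design_probe_set("short", short_tx, cw, ro, n_probes = 8),
    "of 8 requested"
  )
  expect_lt(nrow(few), 8)
})

test_that("padlock assembly lays out arms, backbone and handles correctly", {
  tx <- random_transcript(300, seed = 44)
  ro <- generate_readout_pool(21)
  cw <- integer(21); cw[c(2, 3, 7, 11)] <- 1L
  sites <- evaluate_candidate(candidate_sites("tx", tx))
  site <- sites[which(sites$pass)[1], ]
  probe <- assemble_padlock(site, cw, ro)
  el <- padlock_elements()
  # 5'->3': donor arm, RCA primer site, readout complements, acceptor arm
  expect_equal(substr(probe$padlock_sequence, 1, 30), site$arm_donor)
  expect_equal(substr(probe$padlock_sequence, 31, 50), el$rca_primer_site)
  expect_equal(substr(probe$padlock_sequence,
                      probe$length - 29, probe$length), site$arm_acceptor)
  expect_equal(probe$full_sequence,
               paste0(el$handle_left, probe$padlock_sequence,
                      el$handle_right))
  # in-silico ligation: hybridizing the arms to the transcript leaves a
  # nick whose donor-side base is the stored junction base
  target_window <- substr(tx, site$start + 1, site$start + 60)
  expect_equal(merscreen:::revcomp(site$arm_acceptor),
               substr(target_window, 1, 30))
  expect_equal(merscreen:::revcomp(site$arm_donor),
               substr(target_window, 31, 60))
  expect_equal(site$junction_base, substr(target_window, 31, 31))
  # length arithmetic: 60 arm + 20 primer site + 4 x 15 readouts
  expect_equal(probe$length, 60 + 20 + 4 * 15)
  # an internal liberation site is rejected with its position
  bad_site <- site
  bad_site$arm_donor <- paste0(substr(site$arm_donor, 1, 24), "GTATCC")
  expect_error(assemble_padlock(bad_site, cw, ro), "position")
  # uncovered on-bit is an error
  cw_na <- integer(21); cw_na[c(1, 2, 3, 4)] <- 1L
  ro_short <- ro[ro$bit > 4, ]
  expect_error(assemble_padlock(site, cw_na, ro_short), "on-bit")
})

test_that("readout pools and barcodes avoid liberation sites", {
  ro <- generate_readout_pool(21, seed = 7)
  expect_equal(nrow(ro), 21)
  expect_false(any(vapply(merscreen:::revcomp(ro$sequence),
                          merscreen:::has_restriction_site, logical(1))))
  expect_equal(anyDuplicated(ro$sequence), 0)
  bcs <- generate_barcodes(2, seed = 5)
  expect_true(all(nchar(bcs) == 185))
})
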