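#' Padlock encoding probe design
#'
#' Each target is covered by padlock probes whose two 30-nt arms hybridize
#' to adjacent halves of a 60-nt window on the transcript. Upon ligation the
#' probe circularizes and is amplified by rolling circle amplification; the
#' probe backbone carries an RCA primer site and the reverse complements of
#' the readout sequences for the on-bits of the target's codeword.
#' Candidate windows are filtered on per-arm GC content, nearest-neighbor
#' melting temperature, gene/isoform specificity indices, homology to
#' rRNA/tRNA contaminants, and the identity of the base at the ligation
#' junction (a G or C at the donor 5'-phosphorylated end blocks efficient
#' ligation and is excluded).
#'
#' @name probe_design
NULL

# SantaLucia (unified) nearest-neighbor parameters.
# dH in kcal/mol, dS in cal/(mol K).
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
# terminal initiation terms
INIT_DH <- c(G = 0.1, C = 0.1, A = 2.3, T = 2.3)
INIT_DS <- c(G = -2.8, C = -2.8, A = 4.1, T = 4.1)

GAS_R <- 1.987 # cal/(mol K)

#' Nearest-neighbor duplex melting temperature
#'
#' Two-state nearest-neighbor Tm with the entropic monovalent-salt
#' correction (0.368 * N * ln\[Na+\] added to the stack entropy, N = number
#' of stacks) and a linear formamide correction of
#' `formamide_coef` degrees C per percent formamide. The strand term uses
#' CT/4 for non-self-complementary duplexes.
#'
#' @param sequence Unambiguous A/C/G/T string, length >= 8.
#' @param na_molar Monovalent cation concentration (mol/L). Default 0.3.
#' @param formamide_pct Percent formamide in the hybridization buffer.
#' @param conc_nM Total strand concentration in nM. Default 5.
#' @param formamide_coef Tm depression per percent formamide (degrees C).
#' @return Melting temperature in degrees C.
#' @export
melting_temperature <- function(sequence, na_molar = 0.3, formamide_pct = 0,
                                conc_nM = 5, formamide_coef = 0.6) {
  sequence <- toupper(sequence)
  if (nchar(sequence) < 8) stop("sequence must be at least 8 nt")
  bases <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    stop("ambiguous or non-ACGT bases in sequence")
  }
  stacks <- paste0(bases[-length(bases)], bases[-1L])
  dh <- sum(NN_DH[stacks]) + INIT_DH[bases[1L]] + INIT_DH[bases[length(bases)]]
  ds <- sum(NN_DS[stacks]) + INIT_DS[bases[1L]] + INIT_DS[bases[length(bases)]]
  ds_salt <- ds + 0.368 * length(stacks) * log(na_molar)
  ct <- conc_nM * 1e-9
  tm_k <- dh * 1000 / (ds_salt + GAS_R * log(ct / 4))
  unname(tm_k - 273.15 - formamide_coef * formamide_pct)
}

revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(x, function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]),
                                     collapse = ""), character(1),
                USE.NAMES = FALSE))
}

gc_fraction <- function(x) {
  vapply(x, function(s) {
    b <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
    mean(b %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

all_kmers <- function(sequence, k) {
  n <- nchar(sequence)
  if (k > n) stop("k longer than sequence")
  substring(sequence, seq_len(n - k + 1L), k:n)
}

#' Build a k-mer specificity index from a transcriptome
#'
#' Maps every k-mer of every transcript to the set of genes and isoforms
#' containing it. Transcripts sharing a `gene` value are isoforms of that
#' gene.
#'
#' @param transcriptome Tibble with columns `transcript_id`, `gene`, `seq`.
#' @param k K-mer length; default 15, matching the contaminant homology
#'   rule.
#' @return A `kmer_index` list used by [specificity_indices()].
#' @export
build_kmer_index <- function(transcriptome, k = 15L) {
  stopifnot(all(c("transcript_id", "gene", "seq") %in% names(transcriptome)))
  recs <- purrr::pmap(transcriptome, function(transcript_id, gene, seq, ...) {
    km <- unique(all_kmers(toupper(seq), k))
    tibble::tibble(kmer = km, gene = gene, transcript_id = transcript_id)
  })
  tab <- dplyr::bind_rows(recs)
  structure(list(
    k = k,
    gene_by_kmer = tapply(tab$gene, tab$kmer, function(g) unique(g)),
    iso_by_kmer = tapply(tab$transcript_id, tab$kmer, function(t) unique(t)),
    iso_gene = stats::setNames(transcriptome$gene, transcriptome$transcript_id)
  ), class = "kmer_index")
}

#' Gene and isoform specificity indices of a sequence
#'
#' `gene_si` is the fraction of the sequence's k-mers that occur in no gene
#' other than `gene`; `isoform_si` is the fraction occurring in no other
#' isoform of the same gene. K-mers absent from the index (e.g. probe arms
#' that span no annotated transcript) count as specific.
#'
#' @param sequence Nucleotide string.
#' @param index A `kmer_index` from [build_kmer_index()].
#' @param gene,transcript_id Identity of the target the sequence derives
#'   from.
#' @return Named numeric vector `c(gene_si =, isoform_si =)` in \[0, 1\].
#' @export
specificity_indices <- function(sequence, index, gene, transcript_id) {
  km <- all_kmers(toupper(sequence), index$k)
  genes_hit <- index$gene_by_kmer[km]
  isos_hit <- index$iso_by_kmer[km]
  gene_ok <- vapply(genes_hit, function(g) is.null(g) || all(g == gene),
                    logical(1))
  iso_ok <- vapply(isos_hit, function(tr) {
    if (is.null(tr)) return(TRUE)
    same_gene <- index$iso_gene[tr] == gene
    all(!same_gene | tr == transcript_id)
  }, logical(1))
  c(gene_si = mean(gene_ok), isoform_si = mean(iso_ok))
}

#' Longest exact match of a sequence to a contaminant set
#'
#' Length (nt) of the longest substring of `sequence` occurring verbatim in
#' any contaminant sequence (both orientations of the contaminants are
#' checked, since probes may hybridize to either strand sense).
#'
#' @param sequence Query string.
#' @param contaminants Character vector of contaminant sequences (e.g.
#'   rRNA/tRNA).
#' @param max_check Upper bound on match length searched. Default 40.
#' @return Integer match length (0 if no shared 8-mer).
#' @export
longest_contaminant_match <- function(sequence, contaminants, max_check = 40L) {
  if (length(contaminants) == 0) return(0L)
  seqs <- toupper(c(contaminants, revcomp(contaminants)))
  sequence <- toupper(sequence)
  shared_at <- function(k) {
    km <- unique(all_kmers(sequence, k))
    any(vapply(seqs, function(s) any(vapply(km, grepl, logical(1), x = s,
                                            fixed = TRUE)), logical(1)))
  }
  lo <- 8L
  if (!shared_at(lo)) return(0L)
  hi <- min(max_check, nchar(sequence))
  while (lo < hi) { # binary search on longest shared substring length
    mid <- (lo + hi + 1L) %/% 2L
    if (shared_at(mid)) lo <- mid else hi <- mid - 1L
  }
  lo
}

#' Default probe-filter thresholds
#'
#' The printed design rules: per-arm GC in \[0.30, 0.70\], per-arm Tm in
#' \[60, 80\] degrees C, gene specificity index in \[0.75, 1\], isoform
#' specificity index in \[0.70, 1\], longest contaminant homology <= 15 nt,
#' and no G/C at the donor (5'-phosphorylated) end of the ligation
#' junction.
#'
#' @return Named list of thresholds consumed by [evaluate_candidate()].
#' @export
probe_thresholds <- function() {
  list(gc = c(0.30, 0.70), tm = c(60, 80), gene_si = c(0.75, 1),
       isoform_si = c(0.70, 1), max_contaminant = 15L,
       forbidden_junction = c("G", "C"))
}

#' Enumerate and score candidate 60-nt probe sites on a transcript
#'
#' Tiles half-open 60-nt windows at `step`-nt spacing. The acceptor arm is
#' the reverse complement of the first 30 nt of the window and the donor
#' arm (5'-phosphorylated) the reverse complement of the second 30 nt; the
#' junction base is the transcript base at the window midpoint (the base
#' paired to the donor 5' end).
#'
#' @param transcript_id,seq Identity and sequence of the transcript.
#' @param gene Gene the transcript belongs to.
#' @param index Optional `kmer_index`; when `NULL` specificity indices are
#'   set to 1 (single-target design).
#' @param contaminants Character vector of rRNA/tRNA sequences (may be
#'   empty).
#' @param step Tiling step in nt. Default 5.
#' @param na_molar,formamide_pct Tm conditions (see
#'   [melting_temperature()]).
#' @return Tibble of candidate sites with per-arm metrics.
#' @export
candidate_sites <- function(transcript_id, seq, gene = transcript_id,
                            index = NULL, contaminants = character(),
                            step = 5L, na_molar = 0.3, formamide_pct = 0) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 60) stop("transcript shorter than one 60-nt window")
  starts <- seq.int(0L, n - 60L, by = step)
  purrr::map_dfr(starts, function(s) {
    window <- substr(seq, s + 1L, s + 60L)
    first_half <- substr(window, 1L, 30L)
    second_half <- substr(window, 31L, 60L)
    si <- if (is.null(index)) {
      c(gene_si = 1, isoform_si = 1)
    } else {
      specificity_indices(window, index, gene, transcript_id)
    }
    tibble::tibble(
      transcript_id = transcript_id, gene = gene, start = s,
      arm_acceptor = revcomp(first_half),
      arm_donor = revcomp(second_half),
      gc_acceptor = gc_fraction(first_half),
      gc_donor = gc_fraction(second_half),
      tm_acceptor = melting_temperature(first_half, na_molar, formamide_pct),
      tm_donor = melting_temperature(second_half, na_molar, formamide_pct),
      gene_si = si[["gene_si"]],
      isoform_si = si[["isoform_si"]],
      junction_base = substr(window, 31L, 31L),
      max_rrna_match = longest_contaminant_match(window, contaminants)
    )
  })
}

#' Apply the printed filter rules to candidate sites
#'
#' @param sites Tibble from [candidate_sites()].
#' @param thresholds List from [probe_thresholds()].
#' @return `sites` with one logical column per rule (`pass_gc`, `pass_tm`,
#'   `pass_gene_si`, `pass_isoform_si`, `pass_contaminant`,
#'   `pass_junction`) and an overall `pass`.
#' @export
evaluate_candidate <- function(sites, thresholds = probe_thresholds()) {
  th <- thresholds
  in_range <- function(x, r) x >= r[1] & x <= r[2]
  dplyr::mutate(
    sites,
    pass_gc = in_range(.data$gc_acceptor, th$gc) & in_range(.data$gc_donor, th$gc),
    pass_tm = in_range(.data$tm_acceptor, th$tm) & in_range(.data$tm_donor, th$tm),
    pass_gene_si = in_range(.data$gene_si, th$gene_si),
    pass_isoform_si = in_range(.data$isoform_si, th$isoform_si),
    pass_contaminant = .data$max_rrna_match <= th$max_contaminant,
    pass_junction = !(toupper(.data$junction_base) %in% th$forbidden_junction),
    pass = .data$pass_gc & .data$pass_tm & .data$pass_gene_si &
      .data$pass_isoform_si & .data$pass_contaminant & .data$pass_junction
  )
}

# Greedy farthest-point selection of up to n mutually non-overlapping sites
# (60-nt windows), maximizing spread along the transcript. The greedy pass
# is restarted from several seed sites and the best result kept, ranked by
# number of sites then by minimum pairwise gap.
select_spread_sites <- function(sites, n_probes) {
  if (nrow(sites) == 0) return(sites)
  sites <- dplyr::arrange(sites, .data$start)
  starts <- sites$start
  greedy_from <- function(seed_i) {
    chosen <- seed_i
    while (length(chosen) < n_probes) {
      cand <- setdiff(seq_along(starts), chosen)
      cand <- cand[vapply(cand, function(i) {
        all(abs(starts[i] - starts[chosen]) >= 60)
      }, logical(1))]
      if (length(cand) == 0) break
      dist_min <- vapply(cand, function(i) min(abs(starts[i] - starts[chosen])),
                         numeric(1))
      chosen <- c(chosen, cand[which.max(dist_min)])
    }
    sort(chosen)
  }
  seeds <- if (length(starts) <= 40) {
    seq_along(starts)
  } else {
    unique(round(seq(1, length(starts), length.out = 40)))
  }
  best <- NULL
  best_key <- c(-Inf, -Inf)
  for (s in seeds) {
    ch <- greedy_from(s)
    gap <- if (length(ch) > 1) min(diff(starts[ch])) else Inf
    key <- c(length(ch), gap)
    if (key[1] > best_key[1] || (key[1] == best_key[1] && key[2] > best_key[2])) {
      best <- ch
      best_key <- key
    }
  }
  sites[best, , drop = FALSE]
}

#' Deterministic readout sequence pool
#'
#' One 15-nt readout sequence per bit, generated from a seeded RNG with
#' balanced composition and screened against the liberation-enzyme
#' recognition sites.
#'
#' @param n_bits Number of bits.
#' @param length Readout length in nt. Default 15.
#' @param seed RNG seed.
#' @return Tibble with columns `bit`, `sequence`.
#' @export
generate_readout_pool <- function(n_bits, length = 15L, seed = 7L) {
  primer_site <- padlock_elements()$rca_primer_site
  withr_seed(seed, {
    seqs <- character(0)
    while (length(seqs) < n_bits) {
      s <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                 collapse = "")
      gc <- gc_fraction(s)
      if (gc < 0.4 || gc > 0.6) next
      rc <- revcomp(s)
      if (has_restriction_site(rc)) next
      # no recognition site may form across any junction the probe backbone
      # can contain: primer site -> readout complement, and readout
      # complement -> readout complement in either order
      last5 <- function(x) substr(x, nchar(x) - 4L, nchar(x))
      junction_ok <- !has_restriction_site(paste0(last5(primer_site),
                                                  substr(rc, 1, 5))) &&
        all(vapply(revcomp(seqs), function(o) {
          !has_restriction_site(paste0(last5(o), substr(rc, 1, 5))) &&
            !has_restriction_site(paste0(last5(rc), substr(o, 1, 5)))
        }, logical(1)))
      if (!junction_ok) next
      if (s %in% seqs) next
      seqs <- c(seqs, s)
    }
    tibble::tibble(bit = seq_len(n_bits), sequence = seqs)
  })
}

# BciVI (GTATCC) and BccI (CCATC) recognition sites, either orientation.
RESTRICTION_SITES <- c(BciVI = "GTATCC", BciVI_rc = "GGATAC",
                       BccI = "CCATC", BccI_rc = "GATGG")

has_restriction_site <- function(seq) {
  any(vapply(RESTRICTION_SITES, grepl, logical(1), x = toupper(seq),
             fixed = TRUE))
}

find_restriction_sites <- function(seq) {
  hits <- purrr::map_dfr(names(RESTRICTION_SITES), function(nm) {
    pos <- gregexpr(RESTRICTION_SITES[[nm]], toupper(seq), fixed = TRUE)[[1L]]
    pos <- pos[pos > 0]
    tibble::tibble(site = nm, position = as.integer(pos))
  })
  hits
}

#' Default structural elements of the padlock construct
#'
#' The RCA primer site is the probe-borne complement of the first 20 nt of
#' the RCA primer; the PCR handles carry the BciVI (left) and BccI (right)
#' recognition sites used to liberate the mature phosphorylated probe after
#' amplification.
#'
#' @return Named list with `rca_primer_site`, `handle_left`,
#'   `handle_right`.
#' @export
padlock_elements <- function() {
  rca_primer <- "TCTTCACCCGGGGCAGCTGAAGT"
  list(
    rca_primer_site = revcomp(substr(rca_primer, 1L, 20L)),
    handle_left = paste0("CGATTAGGTATCCAGTCCAT"),   # contains GTATCC (BciVI)
    handle_right = paste0("ATGGACTACCATCTTAGCGA")   # contains CCATC (BccI)
  )
}

#' Assemble a full padlock encoding probe
#'
#' Lays the probe out 5' to 3' as donor arm, backbone (RCA primer site plus
#' one readout complement per on-bit of the codeword), then acceptor arm;
#' PCR handles are appended outside. After liberation the donor arm 5' end
#' is phosphorylated, and upon hybridization the two arms abut on the
#' target with the nick at the window midpoint. The probe body (everything
#' between the handles) must be free of either liberation enzyme's
#' recognition site.
#'
#' @param site One-row tibble from [candidate_sites()].
#' @param codeword_bits 0/1 vector, the target's codeword.
#' @param readout_pool Tibble `bit`, `sequence` covering every on-bit.
#' @param elements List from [padlock_elements()].
#' @return One-row tibble: target coordinates, `readout_bits` (list
#'   column), `padlock_sequence`, `full_sequence` (with handles), `length`
#'   (of the liberated padlock).
#' @export
assemble_padlock <- function(site, codeword_bits, readout_pool,
                             elements = padlock_elements()) {
  on_bits <- which(codeword_bits == 1L)
  ro <- readout_pool$sequence[match(on_bits, readout_pool$bit)]
  if (anyNA(ro)) stop("readout pool does not cover every on-bit")
  backbone <- paste0(elements$rca_primer_site,
                     paste(revcomp(ro), collapse = ""))
  padlock <- paste0(site$arm_donor, backbone, site$arm_acceptor)
  hits <- find_restriction_sites(padlock)
  if (nrow(hits) > 0) {
    stop(sprintf("internal restriction site %s at position %d of probe body",
                 hits$site[1L], hits$position[1L]))
  }
  full <- paste0(elements$handle_left, padlock, elements$handle_right)
  tibble::tibble(
    target = site$gene, transcript_id = site$transcript_id,
    start = site$start,
    arm_acceptor = site$arm_acceptor, arm_donor = site$arm_donor,
    junction_base = site$junction_base,
    readout_bits = list(on_bits),
    padlock_sequence = padlock,
    full_sequence = full,
    length = nchar(padlock)
  )
}

#' Design the encoding probe set for one target
#'
#' Tiles the transcript, filters candidates through
#' [evaluate_candidate()], selects up to `n_probes` mutually
#' non-overlapping sites by greedy farthest-point spread, and assembles the
#' padlock for each. Candidates whose assembly would contain an internal
#' liberation-enzyme site are skipped. A warning (not an error) is emitted
#' when fewer than `n_probes` survive.
#'
#' @inheritParams candidate_sites
#' @param codeword_bits The target's codeword (0/1 vector).
#' @param readout_pool Tibble `bit`, `sequence`.
#' @param n_probes Probes to design; the panel defaults are 8 per
#'   endogenous gene and 3 per barcode.
#' @param thresholds Filter thresholds, [probe_thresholds()].
#' @param elements Structural elements, [padlock_elements()].
#' @return Tibble of assembled probes (possibly empty), one row per probe.
#' @export
design_probe_set <- function(transcript_id, seq, codeword_bits, readout_pool,
                             n_probes = 8L, gene = transcript_id,
                             index = NULL, contaminants = character(),
                             thresholds = probe_thresholds(), step = 5L,
                             elements = padlock_elements()) {
  sites <- candidate_sites(transcript_id, seq, gene = gene, index = index,
                           contaminants = contaminants, step = step)
  sites <- evaluate_candidate(sites, thresholds)
  passing <- dplyr::filter(sites, .data$pass)
  # drop candidates whose assembled body would carry a liberation site
  assemblable <- vapply(seq_len(nrow(passing)), function(i) {
    !inherits(try(assemble_padlock(passing[i, ], codeword_bits, readout_pool,
                                   elements), silent = TRUE), "try-error")
  }, logical(1))
  passing <- passing[assemblable, , drop = FALSE]
  chosen <- select_spread_sites(passing, n_probes)
  if (nrow(chosen) < n_probes) {
    warning(sprintf("%s: only %d of %d requested probes could be designed",
                    transcript_id, nrow(chosen), n_probes))
  }
  if (nrow(chosen) == 0) return(tibble::tibble())
  probes <- purrr::map_dfr(seq_len(nrow(chosen)), function(i) {
    assemble_padlock(chosen[i, ], codeword_bits, readout_pool, elements)
  })
  dplyr::bind_cols(
    probes,
    dplyr::select(chosen, dplyr::starts_with(c("gc_", "tm_")),
                  "gene_si", "isoform_si", "max_rrna_match")
  )
}

#' Generate designable perturbation barcode sequences
#'
#' Perturbation barcodes are synthetic 185-mers expressed in the 3' UTR of
#' the reporter transcript; unlike endogenous genes their sequence is free,
#' so they are drawn to be probe-friendly: a candidate barcode is kept only
#' if the three tiling 60-nt windows at starts 0, 62 and 124 all pass the
#' probe filters, guaranteeing that three non-overlapping encoding probes
#' can be designed against it.
#'
#' @param n Number of barcodes.
#' @param length Barcode length in nt. Default 185.
#' @param seed RNG seed.
#' @param thresholds Filter thresholds, [probe_thresholds()].
#' @return Character vector of `n` barcode sequences.
#' @export
generate_barcodes <- function(n, length = 185L, seed = 1L,
                              thresholds = probe_thresholds()) {
  stopifnot(length >= 184)
  withr_seed(seed, {
    out <- character(n)
    i <- 1L
    while (i <= n) {
      s <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                 collapse = "")
      sites <- candidate_sites(sprintf("bc%03d", i), s, step = 62L)
      sites <- sites[sites$start %in% c(0L, 62L, 124L), ]
      sites <- evaluate_candidate(sites, thresholds)
      arms_clean <- !vapply(c(sites$arm_acceptor, sites$arm_donor),
                            has_restriction_site, logical(1))
      primer5 <- substr(padlock_elements()$rca_primer_site, 1, 5)
      junc_clean <- !vapply(sites$arm_donor, function(a) {
        has_restriction_site(paste0(substr(a, 26, 30), primer5))
      }, logical(1))
      if (nrow(sites) == 3L && all(sites$pass) && all(arms_clean) &&
          all(junc_clean)) {
        out[i] <- s
        i <- i + 1L
      }
    }
    out
  })
}

#' Generate a synthetic transcript with balanced composition
#'
#' Seeded i.i.d. sequence at the requested GC content; at typical lengths
#' its 15-mers are globally unique with overwhelming probability, making it
#' a permissive design substrate.
#'
#' @param length Transcript length (nt).
#' @param gc Target GC fraction. Default 0.5.
#' @param seed RNG seed.
#' @return Nucleotide string.
#' @export
random_transcript <- function(length, gc = 0.5, seed = 1L) {
  withr_seed(seed, paste(
    sample(c("A", "T", "G", "C"), length, replace = TRUE,
           prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
    collapse = ""
  ))
}
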