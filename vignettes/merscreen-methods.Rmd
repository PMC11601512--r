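---
title: "Models and methods behind merscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind merscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(merscreen)
```

merscreen implements the computational core of an image-based pooled
CRISPR screening platform: error-robust binary codebooks read out by
multiplexed FISH of rolling-circle-amplified padlock probes, per-cell
perturbation genotyping from either imaging barcodes or sequencing
guide probes, and the statistics used to call perturbation phenotypes.
Because real tissue data cannot be regenerated at a desk, the package
ships a fully ground-truthed synthetic-screen generator; every
downstream method is tested against quantities that the generator
plants by construction.

## Error-robust codebooks

Each RNA target is encoded as a binary codeword of fixed length (21
bits for gene panels, 18 for perturbation barcodes) and constant
Hamming weight (4 and 6 respectively), with every pair of codewords at
Hamming distance at least 4. Constant weight makes the expected number
of bright bits per molecule uniform across targets; minimum distance 4
yields single-bit error correction, since the radius-1 spheres around
codewords are disjoint.

`generate_constant_weight_code()` uses a position-sum-class
construction: the $\binom{n}{w}$ weight-$w$ words are partitioned by
the sum of their on-bit positions modulo $n$. Two distinct words in
one class can never differ by a single bit move (that would change the
class), so every within-class pair sits at distance $\ge 4$. The
largest class already holds at least
$\lfloor \binom{n}{w} / n \rfloor$ words — 285 at $(21, 4)$ and 1031
at $(18, 6)$, comfortably above the 209 genes and 456 barcodes a
screen needs — and is then greedily augmented with compatible words
from the other classes in seeded-shuffled order. The construction is
deterministic given the seed; `verify_code()` re-checks any codebook
by exhaustive $O(K^2 n)$ comparison and is deliberately independent of
the generator.

Decoding (`decode_bit_vector()`) accepts an exact match, corrects a
unique distance-1 neighbor, and otherwise reports `no_call`. Distance
ties are never broken arbitrarily: an ambiguous vector is a `no_call`.
Blank codewords — codewords assigned to no real target — travel
through decoding like any other and anchor the misidentification
estimate downstream. By default 10% of assigned codewords are blanks;
the count is configurable.

## Padlock probe design

Every target is covered by padlock probes (8 per endogenous gene, 3
per 185-nt barcode) whose two 30-nt arms hybridize to adjacent halves
of a 60-nt window; ligation of the nick between the arms circularizes
the probe for rolling circle amplification. Candidate windows must
satisfy, per arm: GC content in [0.30, 0.70], melting temperature in
[60, 80] °C, gene specificity index in [0.75, 1], isoform specificity
index in [0.70, 1], no exact match longer than 15 nt to rRNA/tRNA
contaminants, and no G or C at the donor (5′-phosphorylated) end of
the ligation junction, which would inhibit ligation.

Design choices where the procedure was open:

* **Tm model.** Unified nearest-neighbor thermodynamics with the
  entropic monovalent-salt correction ($0.368 N \ln[\mathrm{Na}^+]$
  added to the stack entropy) and a linear formamide correction of
  −0.6 °C per percent. Defaults: 300 mM Na⁺, 5 nM total strands, 0%
  formamide — the candidate filter is evaluated at standard reference
  conditions, with the formamide term available for modeling
  hybridization buffers.
* **Specificity indices.** Defined as unique-$k$-mer fractions with
  $k = 15$, matching the 15-nt contaminant-homology rule: the gene
  index is the fraction of a window's 15-mers found in no other gene,
  the isoform index the analogue within the gene. Transcript-abundance
  weighting is deliberately omitted.
* **Tiling and selection.** Windows are tiled at a 5-nt step (1 nt for
  short barcode targets) and up to $n$ mutually non-overlapping sites
  are chosen by greedy farthest-point selection restarted from several
  seeds, ranked by site count then minimum pairwise gap — even
  coverage of the transcript without an exact search.
* **Probe layout.** 5′→3′: donor arm (30 nt), RCA primer site (20 nt),
  one 15-nt readout complement per on-bit (4 or 6), acceptor arm
  (30 nt); PCR handles carrying the BciVI (left) and BccI (right)
  liberation sites flank the construct for synthesis. Liberated probe
  lengths are therefore 140 nt (genes) and 170 nt (barcodes). The
  probe body must not contain either recognition site internally;
  readout pools are screened for sites including those that could form
  across element junctions, and assembly fails loudly (naming the
  position) if one slips through.
* **Barcode sequences** are free synthetic sequences, so
  `generate_barcodes()` rejection-samples until the three tiling
  windows of a candidate barcode pass every filter with
  restriction-clean arms — mirroring the fact that real barcode pools
  are designed, not found.

## The synthetic screen generator

`simulate_tissue()` places cells as non-overlapping disks on a
jittered grid. A planted vasculature (interleaved lattices of
central-vein and portal anchor points) defines the zonal coordinate
$z = d_{cv} / (d_{cv} + d_{pp}) \in [0, 1]$; hepatocyte subtypes
Hep1–Hep6 are the sextiles of $z$, Hep1 most pericentral. Barcode
transduction is Poisson with mean `lambda` (default 0.3, inside the
10–30% low-MOI regime screens target); identities are uniform over the
library. At $\lambda = 0.3$ the analytic single-barcode share among
positive cells is $\lambda e^{-\lambda} / (1 - e^{-\lambda}) =
85.7\%$, the anchor the tests check. Optional clonal patches copy a
neighbor's barcode set; their spatial statistics are a free parameter
(default off, preserving the exact Poisson structure).

`simulate_counts()` draws negative-binomial counts (dispersion 0.15 by
default; the noise model is a package choice) around means of the
form baseline × zonal factor × perturbation fold-changes, scaled to a
fixed expected library size (300 molecules per cell by default, a
realistic per-cell MERFISH yield for a ~200-gene panel). The zonal
factor is $e^{s(z - 1/2)}$ with per-gene slope $s$ (+2 for periportal
markers, −2 for pericentral, 0 otherwise). Perturbation templates:

* **depletion** — the targeted gene's mean is multiplied by a
  depletion factor (default 0.2, standing in for
  nonsense-mediated-decay loss of the targeted transcript);
* **gene-set induction** — a UPR-like set is induced by a planted
  z-shift. Because "one z unit" depends on the control noise scale,
  the generator calibrates the fold for each set gene on a pilot
  unperturbed draw, solving for the fold whose mean log1p(tp10k) shift
  equals `induction_z` × control sd, iterating with the
  library-renormalization term (inducing a large set inflates cell
  totals and deflates everything else). The set is drawn from the most
  abundant unzonated genes, as pathway scoring in practice relies on
  well-detected genes;
* **zonal shift** — the zonal factor is evaluated at $z + \delta_z$
  (clamped to [0, 1]), defaulting to $\delta_z = -0.3$.

`render_bit_images()` turns molecules into Gaussian spots (σ = 1 µm,
lognormal brightness) in each on-bit plane after independent per-bit
flips (defaults: 4% on→off drop-out, 1% off→on gain), with Gaussian
background. Rendering is 2-D — a single focal plane rather than a
z-stack — and cell masks are exact disks, because segmentation quality
is out of scope. `placement = "spaced"` puts molecules on a per-cell
lattice so that spots are guaranteed resolvable; it is what makes the
noiseless end-to-end identity test exact rather than probabilistic.
For molecule counts far beyond what a rendered field can hold,
`simulate_spot_intensities()` draws per-bit intensity vectors from the
same generative model without rasterizing.

What the generator does **not** emulate: optical aberrations and
z-stack registration, segmentation errors, cell-type mixtures beyond
hepatocytes, spatially correlated noise, and barcode swapping during
library production. Passing tests therefore demonstrate correctness of
the computation, not robustness to every artifact of real tissue.

## Spot decoding and misidentification filtering

Decoding is spot-based: local maxima of the across-bit max projection
(non-maximum suppression at 3 px), per-bit intensity read within 1 px
of the center. This replaces pixel-based decoding deliberately —
RCA amplicons are bright, compact objects, and spot-based decoding is
tractable at desk scale.

Numerical choices: per-bit intensities are normalized by the median of
that bit's clearly-on values (values above 30% of the bit's maximum).
A fixed high quantile over all spots fails when bit usage is uneven
across a panel — a bit that is on in few spots would be normalized by
background. Binarization is then per spot, at 0.5 of the spot's
maximum normalized intensity, because amplicon brightness spans orders
of magnitude and a global cutoff would shear dim molecules' on-bits.

The misidentification filter is a gradient-boosted tree classifier
(XGBoost) trained to separate blank-assigned from coding-assigned
molecules on the decode quality features (mean on-bit and off-bit
intensity, their ratio, Hamming distance, spot area), with 5-fold
cross-fitting so no molecule is scored by a model that saw it —
stricter than training on a subset and scoring the rest, and free of
leakage. `apply_adaptive_threshold()` sweeps the score cutoff and
keeps the smallest cutoff whose blank-based misidentification estimate

$$ m(c) = \frac{\text{retained blanks} / \text{blank codewords}}
              {\text{retained coding} / \text{coding codewords}} $$

is at or below the target (default 5%). Blank-assigned molecules are
never exported. With only single-bit correction, a two-flip corruption
of an MHD4 codeword can never be silently mis-decoded (it is at
distance ≥ 2 from every codeword), so residual errors require ≥ 3
flips — which is why the achieved rate on default-noise simulations
sits well below the 5% ceiling.

## Perturbation calling

Imaging barcodes call a guide when its per-cell molecule count is
strictly greater than 3 (the printed rule, applied to filter-retained
molecules). Sequencing guide probes call at an inclusive per-guide UMI
threshold; "over the chosen threshold" does not state strictness at
equality, and the inclusive reading is used and documented. The
default global sequencing threshold is max(5, 95th percentile of
ambient counts), where ambient counts exclude each cell's argmax probe
— a data-driven stand-in for the empirical knockdown-maximizing choice
that needs real targets. Only cells with exactly one called guide
enter perturbation analyses. Cell/gene filtering removes cells with
< 25 or > 1500 total molecules (boundaries kept) and then genes
expressed in fewer than 3 remaining cells, in that fixed order.

## Screen statistics

Counts are scaled to 10,000 per cell and log1p-transformed; optional
covariates (cell area, molecule count) are removed per gene by least
squares; z-scores use the per-gene mean and sd of control cells,
within batch, then concatenate. Zero-variance genes in controls are
excluded from the z layer and logged.

The energy-distance test compares each perturbation population to
controls on the first 20 PCs. The pairwise distance convention is
squared Euclidean by default (the convention of the energy-statistics
implementation commonly used for perturbation screens), configurable
to Euclidean, and recorded in the result's attributes. The PCA is fit
per comparison (perturbed + control cells) after z-scoring; fitting
once globally is available. The permutation null (default 1,000
permutations; the count is a package choice) re-labels cells between
group and control; because the pairwise distance matrix is invariant
under relabeling, all permutation statistics come from one matrix
product, which is what keeps 50 groups × 1,000 permutations in
seconds. Family-wise error is controlled by step-down Holm–Šídák
(implemented directly; it is not among `p.adjust`'s methods).

Differential expression uses two-sided mid-rank Mann–Whitney tests
per gene (normal approximation with tie and continuity corrections,
cross-checked against `wilcox.test` in the test suite) with
Benjamini–Hochberg control, reporting the pseudobulk log2 fold-change
alongside. Pseudobulk correlations are Pearson, restricted to the
top 250 (or 1,000) control-expressed genes. Gene-set scores average
the pseudobulk z change over the set; the zonation score is the sum of
z over 7 periportal markers minus the sum over 16 pericentral markers,
with a split mode returning the two partial sums. Intensity effects
z-score each channel against control cells within imaging sample and
test per (guide, channel) with Benjamini–Yekutieli control, matching
the more conservative correction used for score-type analyses.

## Tissue zone segmentation

`build_zone_map()` bins cell positions at 50 µm, builds per-class
histograms (Hep1+Hep2 vs Hep5+Hep6), blurs with a Gaussian of
σ = 0.5 bin units, normalizes each grid by its maximum, and labels
each bin by the larger normalized density. Ties break toward
pericentral (the tie direction is not prescribed anywhere and is
logged here as a fixed convention). Zone enrichment per guide uses
Fisher's exact test of the guide's pericentral/periportal counts
against pooled controls with Benjamini–Hochberg adjustment — a
deliberate choice of exact test for the 2×2 occupancy table, since no
test is prescribed for this comparison. Per-replicate maps with pooled
counts are the intended usage when replicates exist.

## Problem sizes and determinism

The test suite and the acceptance script run at desk scale by design:
codebooks at the full panel geometries (285 and 1,044 codewords),
error-correction checks by complete enumeration (all single- and
two-bit corruptions of every codeword), decoding/filtering at 50,000
molecules, MOI checks at 10⁵–10⁶ cells, the null energy-distance
family at 50 groups × 1,000 permutations, and planted-effect recovery
at 500 cells per arm. All generators and fitted models are
bit-reproducible under a fixed seed; xgboost runs single-threaded with
a fixed seed for that reason.

## Known limitations

* The specificity index is a $k$-mer proxy; it ignores thermodynamic
  off-target strength and transcript abundance.
* Spot-based decoding assumes resolvable amplicons; heavily
  overlapping spots (very dense panels or tight cells) degrade it in
  ways the pixel-based alternative might tolerate.
* The misidentification estimate inherits the usual blank-codeword
  assumptions: blanks must be geometrically exchangeable with coding
  codewords, and the estimate is noisy when few blanks are decoded.
* Planted z-shift calibration is approximate for very sparse genes
  (it falls back to a lognormal-scale fold when the root search is
  degenerate).
* The energy-distance permutation p-values are lower-bounded at
  1/(B+1); with 1,000 permutations, Holm–Šídák significance across
  many groups requires the smallest attainable p-value, so B must be
  raised for larger families.
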