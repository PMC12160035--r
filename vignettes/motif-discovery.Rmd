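---
title: "Tripeptide motif discovery from phage-display biopanning screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tripeptide motif discovery from phage-display biopanning screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagescan)
```

## The problem

In vivo biopanning selects, from a phage library displaying random
disulfide-constrained heptapeptides (a C7C library: Cys-X7-Cys fused to
pIII), the clones that bind a tissue of interest. After several rounds
of selection and amplification, surviving clones are picked, their
insert region is amplified and sequenced, and the displayed peptides
are decoded. The analytical questions `phagescan` answers are:

1. Which sequenced clones carry a genuine library insert, and which are
   wild-type contamination or sequencing errors?
2. Which short peptide motifs are enriched in the surviving pool beyond
   what a random pool of the same residue composition would show?
3. Can the enriched tripeptides be extended into longer (4--6 residue)
   consensus motifs shared by several parent peptides?
4. Did the selection itself work: do round-wise recovery rates rise and
   plateau, and which clones bind the activated target cells in ELISA?

## Decoding and quality control

The 21-nt random region sits between fixed vector sequence; the read
may come off the sequencer on either strand, so extraction searches the
read as given and then its reverse complement for exact anchor matches
(`extract_insert`). Anchors are fixed vector sequence in an amplicon,
so no mismatches are tolerated; a read without anchors on either strand
is flagged, not dropped silently. An `N` anywhere in the extracted
insert flags the record rather than guessing a base.

The library is built from NNK degenerate codons (N = any base, K = G or
T), which encode all twenty amino acids while excluding the ochre (TAA)
and opal (TGA) stops. Two consequences drive the QC stage
(`validate_nnk`, `filter_library`):

* the third base of every codon in the random region must be G or T; a
  codon ending in A or C cannot come from the designed library, so the
  clone is excluded (per clone, with all failing codons listed 1-based,
  matching how such anomalies are reported in practice);
* the amber stop TAG *is* a valid NNK codon. Libraries of this design
  are propagated in supE suppressor hosts (ER2738), where TAG is read
  as glutamine, so `translate_codons` translates TAG as `Q` by default
  (`amber_as` is configurable); TAA/TGA remain hard errors.

No base-quality filter is applied by default: amplicon reads of these
screens have tightly distributed Phred scores (mid/high 30s), and the
codon rule itself is the discriminative filter. Qualities are parsed
and retained so a user can filter upstream if their data warrant it.

## Dereplication

Clones displaying the same heptapeptide are collapsed by exact string
identity (`dereplicate`), keeping multiplicity and parent clone ids.
Sub-identity clustering (as general-purpose tools like CD-HIT offer) is
deliberately not implemented: at 7 residues, "one mismatch" is already
a 14% divergence and collapsing near-neighbours would erase exactly the
signal the motif statistics look for. Requesting `identity < 1` raises
an explicit not-implemented error instead of silently approximating.
Downstream abundance is computed on the non-redundant pool by default;
`weight_by_multiplicity = TRUE` re-expands clones for sensitivity
analysis.

## The motif statistic

Each 7-mer is segmented into five overlapping tripeptide windows read
forward and five read from the reversed sequence
(`segment_tripeptides`), ten windows per peptide. A tripeptide and its
reversal are distinct keys — both orders appear as distinct motifs in
real screens — so the reverse windows add information rather than
duplicating it; palindromic tripeptides accrue counts from both
directions. The **abundance** of a motif is its total occurrence count
across all windows of the pool (`count_abundance`); abundances sum to
exactly ten times the pool size, a conservation law asserted in the
test suite and preserved inside every permutation replicate.

### Permutation null

Significance is assessed by a residue-shuffling permutation test
(`permutation_test`). The default null pools all residues of all
peptides, shuffles them jointly, and re-deals them into peptides of the
original lengths. This preserves the pool's global amino-acid
composition and the peptide count/length structure while destroying
residue co-occurrence — the weakest assumption that still targets motif
structure rather than composition bias. A `"within-peptide"` variant
(which additionally preserves each peptide's own composition) is
available for sensitivity analysis. The raw p-value uses the add-one
estimator, p = (1 + b) / (1 + B) with b the number of replicates whose
null abundance reaches the observed one; it can never be zero, which is
the honest behaviour of a finite Monte-Carlo permutation test. Given
`rng_seed`, the replicate stream is exactly reproducible.

### Correction and selection

Bonferroni correction multiplies raw p-values by the number of tests
(`bonferroni_adjust`). The default multiplicity is the number of
distinct tripeptides actually observed in the pool — the literal
reading of testing each observed motif; `"all-8000"` (20^3) is
available for the stricter family. A motif is selected
(`select_motifs`) when its abundance is strictly above the threshold
(default 20; "above" is read strictly) **or** its adjusted p-value is
below alpha (default 0.05), with the firing criterion recorded. All
rankings break ties deterministically: abundance descending, adjusted p
ascending, then lexicographic.

Note an interaction worth knowing: with the add-one estimator the
smallest attainable adjusted p is m/(B+1), so resolving Bonferroni
significance across m ≈ 3700 observed motifs requires B ≫ m/alpha
permutations. The package default of B = 10000 resolves abundant
motifs' raw p-values well; users chasing adjusted significance across
the whole motif family should raise `n_permutations` accordingly.

### Extension to 4--6 residue motifs

For each selected tripeptide, all parent heptapeptides containing it —
forward, or as its reversal, in which case the peptide is reversed so
the anchor reads forward — are aligned by pinning the anchor
(`extend_motifs`). Since 7-mers sharing an exact 3-mer admit a unique
gap-free anchoring, a general gapped aligner (ClustalW and kin) adds
only nondeterminism here; the anchored star alignment is exact and
reproducible, and is reported as such. A consensus residue is called in
a column when a unique modal residue reaches `column_support_min`
(default 0.5) of **all** supporters, supporters not covering the column
counting as disagreement — a conservative choice that stops ragged
alignment ends from fabricating consensus. The reported motif is the
longest contiguous run of called columns containing the anchor, within
4--6 residues (a longer run is clipped to the 6-residue subwindow of
highest mean support, leftmost on ties); runs below 4 yield the anchor
alone, flagged unextended. Anchors with fewer than two supporters are
skipped with a notice.

## Panning and ELISA metrics

Titer arithmetic is the standard plate computation: titer =
plaques x dilution / volume (pfu/ml), with a warning above 300 plaques
(outside the countable range). The recovery rate of a round is
recovered/input titer; enrichment is reported against round 1 — the
screen's summary statistic — while the saturation flag compares the
last two rounds: the selection has plateaued when their relative change
is within `saturation_tol` (default 0.10; with fewer than two rounds
the verdict is `NA`). ELISA positivity uses the stretched/static OD450
ratio with an inclusive 3-fold boundary ("3-fold higher" is read as
meeting the fold); non-positive static ODs are unevaluable, excluded
from the denominator with a warning. No background-OD subtraction is
performed — inputs are assumed blank-corrected.

## What the simulator emulates — and what it does not

`generate_nnk_library` draws each insert as seven i.i.d. NNK codons, so
every simulated insert is valid by construction and TAG appears at its
natural 1/32-per-codon rate. Spiked motifs are embedded at uniform
offsets and back-translated through uniformly sampled NNK-compatible
codons, making spikes invisible at the DNA-composition level. Reads are
emitted on a random strand behind fixed synthetic anchors.
`corrupt_library` applies exactly-n corruption (one third-codon base
flipped to A/C per invalid clone; anchor-free random sequence for
wild-type reads) so fixture compositions are deterministic — a 723-read
fixture with 16 violations passes exactly 707 clones, every time.
`simulate_elisa` rejection-resamples noisy ODs at the label boundary so
the constructed positive count is exact; `simulate_panning` grows
recovery rates geometrically to a plateau (held within 5%) and draws
plaque counts Poisson at a countable ten-fold dilution.

The simulator does **not** model amplification bias between rounds,
host-range or propagation-rate differences among clones, position-
dependent residue preferences of real C7C libraries, chimeric reads, or
indel sequencing errors. Passing tests therefore demonstrate that the
pipeline's logic and statistics behave correctly under the library's
design assumptions, not that any particular biological screen is free
of those artefacts.

Poisson counting noise also bounds what the saturation flag can see on
*measured* titers: a plate expected to hold ~25--250 plaques has a
counting CV of 6--20%, which can mask a 2% plateau. The test suite
scores the flag against the simulator's exact trajectory and checks
measured counts against their Poisson bound separately; users applying
`enrichment_profile` to real plate counts should choose
`saturation_tol` with their counting depth in mind.

## Numerical and design choices

* **Problem sizes.** Routine tests and the shipped acceptance script
  run pools of 638 peptides (the scale at which the statistics operate)
  with permutation counts in the hundreds, and the single-peptide
  enumeration check at B = 10000 against the exact 5040-order null;
  these sizes give Monte-Carlo error comfortably below the asserted
  tolerances while keeping a full run under a minute.
* **Determinism.** Every stochastic entry point takes an explicit seed;
  the discovery orchestrator refuses to run without one. Identical
  seeds give bitwise-identical motif tables.
* **Degenerate inputs.** Empty read files yield empty tables (exit 0 at
  the command line); empty pools yield empty statistics; single-round
  panning tables yield an `NA` saturation verdict; an all-identical
  pool gives p = 1 for its only motif.
* **Tie-breaks.** All orderings are total (abundance, adjusted p,
  lexicographic), so outputs are stable across platforms.

## Worked example

```{r example, eval = FALSE}
sim <- generate_nnk_library(638, rng_seed = 1, spikes = c(SPFPT = 0.15))
inserts <- extract_inserts(sim$reads, sim$flank5, sim$flank3)
qc <- filter_library(inserts)
pool <- dereplicate(qc$peptides)
disc <- discover_motifs(pool, discovery_config(n_permutations = 1000,
                                               rng_seed = 2))
disc
summary(disc)
```

The spiked pentapeptide's constituent tripeptides dominate the
abundance ranking and the pentapeptide itself is reconstructed by the
anchored extension — the full-pipeline property asserted in the test
suite.

## Known limitations

* Exact-identity dereplication only; near-duplicate collapsing is out
  of scope by design.
* The anchored-star consensus is a deterministic stand-in for a general
  multiple aligner and is labelled as such in reports; it cannot
  produce gapped motifs.
* Bonferroni across thousands of motifs with finite permutations is
  very conservative (see above); motifs are usually carried by the
  abundance criterion unless B is large.
* The ELISA classifier assumes blank-corrected ODs and does not fit
  dose-response curves.
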