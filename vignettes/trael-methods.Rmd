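---
title: "TrAEL-seq processing: models, conventions and design choices"
author: "traelr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TrAEL-seq processing: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traelr)
```

## The signal TrAEL-seq measures

TrAEL-seq labels free single-stranded DNA 3′ ends. Terminal transferase
(TdT) adds a short adenosine tail to an exposed 3′ end, a hairpin adaptor
carrying an 8-nt unique molecular identifier (UMI) is ligated, and after
library construction the sequencing read is the *reverse complement* of
the sequence ending at the labelled 3′ end — the first read base is the
complement of the last nucleotide 5′ of the break. Two consequences shape
everything in this package:

1. **Reads map antisense to the cleaved strand.** A 3′ end on the forward
   genomic strand produces a reverse-mapping read whose 5′-most aligned
   base sits exactly on the end's coordinate, and vice versa. We keep all
   tracks in *read-strand* space (reads are not inverted), so a labelled
   forward-strand end appears as an `R` count. Comparison with methods
   that invert reads (GLOE-seq-style break-strand space) only flips the
   sign of polarity.
2. **The A-tail is indistinguishable from genome-encoded A's.** The tail
   appears as a run of T's at the read start (after the UMI); trimming it
   can consume genome-encoded T's, and leaving part of it behind can be
   absorbed by a genomic A across the cut. This is why trimming is capped
   and why mapping accuracy at A-flanked ends is ±1 nt rather than exact.

## Read layout and trimming

A raw read is `UMI (8 nt) [barcode (4 nt)] (T)n insert`. Preprocessing
(`trael_layout()`, `parse_reads()`, `preprocess_fastq()`):

* moves the UMI onto the read identifier (`id:UMI`), using a delimiter
  that survives aligners truncating names at whitespace;
* matches the optional sample barcode exactly — the paired-library
  barcodes `AGTC`/`GACT` differ at all four positions, and no mismatch
  tolerance is defined for them, so 0-mismatch matching is both safe and
  faithful; N's or mismatches go to `unassigned`;
* removes at most `polyT_cap = 3` leading T's. Only literal `T` counts;
  an `N` terminates the run because it cannot be confidently assigned to
  the tail. Reads shorter than the fixed prefix are dropped and counted,
  never raised as errors.

The cap of 3 interacts with tail-length biology: tails average 2–4 nt
(the simulator's default tail model is uniform on {2, 3, 4}; a uniform
{1, 2, 3} preset reflects in vitro measurements on a test substrate). At
an end whose flanking bases are A on its own strand, the enumeration is
exact: a 2-nt tail over-trims one genomic base (call shifted 1 nt into
the fragment), a 3-nt tail trims exactly, and a 4-nt tail leaves one
residual T that is absorbed by the genomic A across the cut (call shifted
1 nt outward). All three cases stay within ±1 nt, which the acceptance
simulations verify on >10,000 reads. At non-A-flanked ends the residual T
of a 4-nt tail matches nothing, so those reads simply fail exact
alignment instead of being mis-mapped — accuracy conditions on mapped
reads.

Adapter and quality trimming are deliberately not re-implemented: in
production they run between preprocessing and alignment using standard
tools, and simulated reads are generated adapter-free.

## Deduplication

PCR duplicates are collapsed on the exact key *(reference, leftmost
position, orientation, UMI)*, keeping the first record in file order —
deterministic for coordinate-sorted input, and the retained key *set* is
invariant under input permutation (a property the tests check). The
mapping position is used as reported, without soft-clip back-projection,
and UMIs are compared exactly (no edit-distance clustering); both choices
match the behaviour expected of the standard UMI deduplicators for this
library type. All primary alignments are retained by default, with an
optional MAPQ threshold for multi-mapper filtering.

## Single-nucleotide end tracks and windows

Each deduplicated read is truncated to its 5′-most aligned base — for
soft-clipped alignments this is the first *aligned* base, since tail
absorption operates in alignment space. Counts accumulate per
(chromosome, base, read strand) into dense vectors. Conventions:

* all R-level coordinates are 1-based inclusive (the Bioconductor
  convention); BED and bedGraph files are 0-based half-open per their
  format standards, handled by rtracklayer;
* RPM normalisation is `count × 1e6 / total_mapped`; re-normalising is an
  error (a flag guards it). For two barcoded samples pooled into one
  library, `paired_normalize()` scales both by the *combined* mapped
  total, preserving the between-sample ratio — the correct normalisation
  when relative signal between conditions is the quantity of interest;
* sliding windows (`window_counts()`) exclude windows clipped at
  chromosome ends, and a mask of non-single-copy regions (rDNA, 2µ,
  mtDNA, Ty/LTR, subtelomeres in yeast practice) removes any overlapping
  window entirely — partial weighting would make window values depend on
  mask geometry. The mask is user-supplied since its extent (e.g. of
  subtelomeric regions) is a judgement call.

## Read polarity, origins and comparisons

Polarity per window is `(R − F)/(R + F)`, in [−1, 1], `NA` when
`F + R < min_reads` (default 1: polarity is computed wherever reads
exist; sparse mammalian libraries should raise it). The companion
`percent_reverse` satisfies `polarity = 2·percent_reverse/100 − 1`.

Rightward-moving forks expose forward-strand leading 3′ ends, i.e.
reverse-mapping reads, so polarity is positive right of an origin and the
profile switches negative→positive at active origins and
positive→negative where forks converge. `call_origins()` smooths polarity
with a centered rolling mean over `smooth_windows = 5` windows, finds
sign crossings (runs of exact zeros are skipped until the sign truly
flips, which makes origin/termination labels exactly swap under
negation — a tested invariant), and requires the right-minus-left flank
mean difference to reach `min_swing = 0.5`. Both defaults are exposed:
origin calling in the field is often done by eye, and these values were
chosen to separate genuine plateau-to-plateau swings (≈2×plateau) from
window noise at typical coverage. `NA` runs break chromosomes into
independent segments; a track shorter than the smoothing span yields an
empty result with a warning.

`compare_groups()` performs a per-window two-sample t-test between
replicate groups — Welch by default, since equal variances between
conditions is an unnecessary assumption and the choice is configurable —
followed by Benjamini–Hochberg correction across all tested windows, and
flags windows with adjusted p below `alpha = 0.01` *and* absolute mean
polarity difference above `min_delta = 0.4`. The two-filter design is
deliberately conservative; on null simulations the flagged fraction is
far below alpha (a tested property). Windows `NA` in any replicate are
excluded from testing. `ma_compare()` provides the MA-style view of
count changes per strand with a 0.5 pseudocount; note that with
per-sample library normalisation a global fold change cancels, so joint
(paired-barcode) totals should be supplied when absolute changes matter.

`metaprofile()` averages per-base signal in non-overlapping bins around
each feature's 5′ anchor, mirroring reverse-strand features (coordinates
flipped *and* strands swapped), or orienting by the sign of local
polarity when profiles should be in replication-direction space; features
within one flank of a chromosome end are dropped.

## Stall peaks and hotspot detection

Fork barriers appear as sharp single-base pileups on the strand opposite
to fork direction. `call_stall_peaks()` flags bases whose raw count
reaches `local mean + peak_z × local SD`, computing the local statistics
over ±`local_flank = 2000` bp excluding the candidate base (running sums,
so the scan is linear); adjacent qualifying bases merge into one peak
reported at the maximum. The threshold form, flank and `peak_z = 5`
default are this package's design — no published constants exist — and
`peak_z` should be raised on very low-coverage tracks where the local SD
is dominated by Poisson noise (the unit tests use a higher value on a
λ = 1 background for exactly this reason).

Interval sets (e.g. annotated DSB hotspots) are quantified by summed end
counts and tested by the 2-SDs-above-background rule: for each distinct
query length, `n_background = 10000` length-matched intervals are drawn
uniformly from a user-supplied mappable space (seeded, reproducible, and
restorable RNG state), and an interval is detected when its count reaches
`mean + z × SD` of that background (default `z = 2`). The background
definition — length-matched random mappable intervals — is the standard
null for interval enrichment; whether published tallies used per-length
or global backgrounds is not stated anywhere we know of, so the
per-length choice is documented and flagged here. Detection is monotone
in `z` (tested), and the mappable space must span at least 10× the total
query length or the background would be undersampled (hard error).

## The simulator

The simulator exists so that every claim above is testable without
external data. It emulates:

* i.i.d. random genomes at a stated GC content (default 0.38,
  yeast-like);
* restriction digests with IUPAC-degenerate recognition patterns and
  explicit top/bottom cut offsets. Built-ins: NotI `GC^GGCCGC` (4-nt 5′
  overhang), PmeI `GTTT^AAAC` (blunt), SfiI `GGCCNNNN^NGGCC` (3-nt 3′
  overhang, cutting after site offset 8 on the top strand and after
  offset 5 on the bottom). The derived 3′ ends — forward at offset
  `top_cut`, reverse at `bottom_cut + 1` — are verified against a
  brute-force oracle that literally builds both strand strings, cuts
  them, and maps the termini back;
* TdT tails (categorical length model, A only);
* replication-fork ends: positions uniform between origins, fork
  direction deterministic (away from the nearest origin, midpoint rule
  between adjacent origins — a stochastic firing-time model adds nothing
  for the consumers of these tracks and is a non-goal), and the end
  strand matching that direction with probability `polarity_strength`.
  Windowed polarity then plateaus at `2 × polarity_strength − 1`; the
  default 0.8 gives the strong (up to ~90% leading-strand) bias seen in
  real libraries. Stall sites are point masses with fixed strand and a
  weight expressed relative to the uniform background (total weight 1);
* DSB hotspots: centers drawn by weight, positions scattered by a rounded
  normal dispersion, both end strands emitted symmetrically since a DSB
  cuts both strands and the method maps 3′ ends at the original break
  even after resection;
* reads: `UMI + [barcode] + T^k + revcomp(W bases ending at the end)`,
  all at one raw length; ends too close to a contig edge are dropped and
  recorded as unrepresentable. An optional PCR duplication factor emits
  duplicate reads sharing the molecule's UMI. Alongside the reads, the
  expected *post-trimming* alignment of every read is computed by
  replaying capped trimming against the known genome (including over- and
  under-trim shifts), so downstream stages can run from truth alignments
  without any aligner — and the tests verify the real pipeline agrees
  with this replay record for record;
* an exact mapper (`exact_map()`): full-length exact matching of each
  read against both strands via a preprocessed dictionary; reads with
  zero or multiple hits are reported unmapped with a reason. It stands in
  for a production aligner only on simulated, error-free data.

Not emulated: chromatin or mappability biases, Okazaki fragments,
sequencing errors (off by default; a uniform substitution mode would only
serve robustness tests), and blunting-based (END-seq-style) chemistry.
Passing tests therefore demonstrate correctness of the *computational*
pipeline under clean conditions, not robustness to alignment artefacts or
genome repeat structure in real data.

## Problem sizes and numerical notes

The test suite runs the mapping-accuracy studies at 10,000 reads on a
1 Mb genome with 120 planted sites, origin recovery at 10 origins and
10^5 ends on 1 Mb with 1 kb/100 bp windows, dedup equivalence at 10^5
records, and hotspot detection at 1,000 intervals over a 1 Mb Poisson
background — sizes at which binomial/Poisson sampling error is well below
the tested tolerances while the whole suite stays fast. Degenerate inputs
are defined rather than accidental: empty tracks window to zeros, a zero
denominator gives `NA` polarity, an empty strand exports an empty
bedGraph data section, flat tracks yield no peaks (the peak test requires
strict exceedance of the local mean, so a constant track can never
qualify), and re-normalisation or gapped windowing (`step >
window_size`) are errors.

One acceptance check — the census of SfiI cut-flank categories across the
real S. cerevisiae R64-1-1 assembly — needs the ~12 Mb reference FASTA,
which cannot be bundled; the census function itself
(`sfi_site_census()`) is fully implemented and oracle-tested on synthetic
genomes, and reports both site-level and strand-specific end-level
tallies because published counts are ambiguous between the two
conventions.

## Limitations

* The exact mapper requires modest genome sizes and error-free reads; it
  is a verification tool, not an aligner.
* Origin calling reports crossing midpoints at window resolution; it does
  not model firing efficiency or timing, and termination "midpoints" in
  broad termination zones are population averages, not discrete sites.
* Group comparison treats windows independently; no spatial smoothing or
  autocorrelation correction is applied before BH.
* Polarity conventions are read-strand space throughout; users comparing
  against inverted-pipeline datasets must negate one side.
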