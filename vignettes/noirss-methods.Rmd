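---
title: "Molecular-barcode error elimination and repertoire estimation for TCRB CDR3 sequencing"
author: "noirss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular-barcode error elimination and repertoire estimation for TCRB CDR3 sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noirss)
```

## The problem

High-throughput sequencing of the T-cell receptor beta chain (TCRB)
complementarity-determining region 3 (CDR3) characterises a T-cell
repertoire as a molecular population: which rearrangements are present, at
what abundance, and how large the underlying repertoire is. Two obstacles
stand in the way. First, sequencer error rates (particularly the
insertion/deletion-dominant errors of semiconductor sequencers) are far
above the frequency of many real clonotypes, so raw reads badly
overestimate diversity. Second, read counts confound PCR amplification
with molecular abundance, so raw reads cannot count molecules.

The approach implemented here attaches a 12-base random barcode (a unique
molecular identifier) to each cDNA molecule at reverse transcription. All
reads carrying the same barcode tag derive from one molecule, so (i) a
per-molecule consensus sequence suppresses sequencing errors, and (ii) the
number of distinct retained tags *is* the number of sequenced molecules,
giving absolute quantitation. The remaining difficulty is errors inside
the barcode itself, which would split one molecule into several spurious
tags; detecting and removing those erroneous tags is the heart of the
method.

## Read architecture and demultiplexing

Each single-end read is laid out 5'→3' as

```
5-bp sample index | 12-bp random barcode | spacer GTACATATTGTCGTT |
C-region primer CTCTGCTTCTGATGGCTCAAAC | antisense TCRB: C→J→CDR3→V
```

`parseReads()` matches the first five bases exactly against the known
sample indices (five bases leave essentially no edit slack, so no
mismatches are tolerated), then locates the spacer as the best match with
at most one edit starting at offsets 15–20 from the read start. The
window and the single allowed edit let a tag that has gained or lost a
base still anchor its boundary; the bases between index and spacer are
the observed tag, the bases after the spacer are the payload. Reads whose
spacer-plus-payload is shorter than 150 bases are discarded
(`lengthFilter()`): shorter fragments cannot span J, CDR3 and enough V
for reliable annotation.

## Monitoring and removing erroneous barcode tags

Because indels dominate the error profile, most barcode errors change the
*length* of the tag: a true 12-bp tag with one deletion reads as 11 bp,
with one insertion as 13 bp. `mergeLengthVariants()` marks every 11/13-bp
tag that differs from a 12-bp tag by exactly one indel as that tag's
*derivative*; a derivative within one indel of several parents goes to
the parent with more reads (then the lexicographically smaller tag).
Derivative reads are used only for monitoring and are never pooled into
the parent's consensus: their tag identity is uncertain, and the
conservative choice costs only a small fraction of reads. Substitution
errors inside the tag keep it 12 bp long and are not individually
detectable; they are handled statistically by the read-count threshold
below, and 12-bp tags at Hamming distance 1 from each other are
deliberately *not* merged — only length variants are.

Erroneous tags receive few reads (each arises from one or a few error
events), while real molecules accumulate many PCR duplicates. Binning
tags by reads-per-tag `r`, `tagErrorProfile()` computes the error-free
fraction `n12 / (n12 + n_derivative)` per bin and chooses the threshold
`r*` as the smallest `r` such that every non-empty bin at or above `r`
has an error-free fraction of at least 90%. This operationalises the
removal of the contaminated low-read fraction as a single deterministic
cut; if no bin passes, the run is unusable for counting and the pipeline
aborts with the full per-bin table. `applyThreshold()` then retains
12-bp, non-derivative tags with at least `r*` reads; the retained count
is the sample's absolute molecule count. Whether the cut should be
applied per sample or globally is not fixed by the procedure; this
implementation applies it per sample.

## Consensus calling

Within each retained tag group the reads are nearly identical (they are
sequencing replicates of one molecule), so a full progressive multiple
alignment is unnecessary. `starAlign()` uses a center-star alignment: the
longest read is the center, every other read is globally aligned to it
(match +1, mismatch −1, first gap base −2, each further gap base −1), and
pairwise gaps are projected into a common frame ("once a gap, always a
gap"). Groups larger than 50 reads are capped at the 50 longest
(`capReads()`), bounding per-group cost while favouring reads that span
the most sequence. `callConsensus()` emits, per column, the symbol whose
relative frequency among covering rows is strictly greater than 80%
(terminal gaps from length differences do not vote); a winning gap emits
nothing, and a column with no winner emits `N`. The 80% rule is strict —
exactly 80% fails — which means groups with five or fewer reads emit `N`
wherever any single read disagrees. Molecules whose `N` lands inside the
CDR3 are discarded downstream as `ambiguous_base`; this is the
conservative resolution of an undefined corner (emit-N versus
discard-the-molecule), and it is recorded per molecule rather than
silently dropped.

## V/J annotation and CDR3 extraction

Consensus sequences are reverse-complemented onto the mRNA sense strand
(`orientSequence()`; the library chemistry fixes the orientation, but an
auto-detect mode chooses the strand by the better J-segment seed score).
`alignSegments()` locally aligns every germline V and J segment against
the sense sequence with the same scoring as above and keeps the best hit
per kind (ties: higher identity, then lexicographically smaller name),
requiring the J hit to start 3' of the V hit start. The minimum scores
(20 for V, 15 for J) reject random matches on ~300-nt sequences with
margin while accepting the short J segments.

The CDR3 is defined by the two conserved junction anchors: the cysteine
codon near the V 3' end and the phenylalanine codon of the J F-G-X-G
motif. Anchor coordinates are stored explicitly in the reference
(0-based, half-open throughout) and mapped through the alignments;
`extractCDR3()` returns the junction from the first base of the cysteine
codon through the last base of the phenylalanine codon, inclusive. The
inclusive convention is the default because reported CDR3 motifs
conventionally run C…F; an exclusive mode dropping both anchor codons is
available. `translateFilter()` discards junctions that are out of frame,
contain an ambiguous base, or translate with a stop codon.
`aggregateClonotypes()` groups molecules into nucleotide-level clonotypes
by (V, J, CDR3 nt) and amino-acid-level clonotypes by CDR3 aa alone —
convergent recombination makes distinct rearrangements encode the same
peptide, and shared amino-acid sequences need not share V usage.

## Repertoire statistics

With error-free counts per clonotype, repertoire size is estimated with
the Chao–Lee abundance-based coverage estimator (ACE), fed by the
clonotypes observed 1–10 times (`aceRichness()`, rare cutoff `k = 10`,
configurable). Writing `F_i` for the number of clonotypes seen `i` times:

$$
S_{ACE} = S_{abund} + \frac{S_{rare}}{C_{ACE}} +
\frac{F_1}{C_{ACE}}\,\gamma^2,\qquad
C_{ACE} = 1 - F_1/N_{rare},
$$

with `gamma^2` the (non-negative) squared coefficient of variation of the
rare-group abundances. Degenerate inputs are handled explicitly: no rare
clonotypes → the estimate is the abundant count; an all-singleton rare
group (`C_ACE = 0`) → Chao1 fallback with a warning rather than a crash.

`rarefactionCurve()` gives the expected number of distinct clonotypes in
a without-replacement subsample of `m` molecules in closed form,
$E[S_m] = \sum_j \left(1 - \binom{N-N_j}{m}\big/\binom{N}{m}\right)$,
computed with log-binomials for stability; the default reporting grid is
20 log-spaced points. `subsampleCounts()` draws a fixed-size
(default 100,000-molecule) subsample so abundance distributions can be
compared across samples of unequal depth, and `frequencyClasses()` bins
clonotype frequencies into low (< 0.01%), middle (0.01–0.1%, left-closed)
and high (≥ 0.1%) classes. `sharingTable()` reports, for clonotypes
present in `m ≥ 2` samples, counts per class under two rules: the class
attained in *all* sharing samples (the minimum class) and the class
attained in *at least one* sample (the maximum). Both nt- and aa-level
spectra are computed wherever both are meaningful.

## The simulator: what it emulates, and what it does not

`simulateRepertoire()` and `generateRun()` generate fully ground-truthed
runs so every stage can be tested without external data. Clones are built
by V–J recombination with 0–6 nt trimmed from each side of the junction
and 0–15 random inserted nt, padded so the CDR3 is in frame; junctions
with stop codons are redrawn, so simulated repertoires are productive by
construction. Abundances are uniform or power-law (`frequency ∝
rank^-alpha`). Molecules are multinomial draws from the clone
frequencies; each gets an independent uniform random 12-mer barcode
(collisions occur at the birthday rate — a `distinctBarcodes` switch
forces uniqueness for exact round-trip checks); reads per molecule are
`1 + NB(mu = 9, size = 20)` (mean 10, variance ≈ 15, minimum 1) — a
mildly overdispersed duplication model chosen once as realistic for a
single-batch amplification; and errors are injected per base at
`ins = del = 0.004`, `sub = 0.001`, an indel-dominant, semiconductor-like
profile (no published per-base rates accompany the protocol, so these
magnitudes are the package's defaults, not measured values). All
randomness derives from the configured seed.

The germline reference bundled for simulation is *synthetic*: 8 V, 6 J
and 1 C segment of realistic length and anchor structure but random
sequence. Real V genes are homologous families with shared motifs and
alleles; random segments are easier to tell apart than real ones, so
passing tests demonstrate the machinery (parsing, counting, consensus,
anchor mapping, estimation), not annotation accuracy against a real IMGT
reference — a user-supplied reference in the same FASTA + anchor-table
format slots in directly. The simulator also omits PCR chimeras,
quality-score structure, amplification bias between protocols, and
flow-space error correlation.

## Numerical and design choices

* Coordinates are 0-based, half-open everywhere; anchors are stored
  explicitly rather than inferred from numbering systems.
* Alignment scoring is fixed (match +1, mismatch −1, gap 1+L for length
  L) and identical in the consensus and annotation aligners; ties are
  broken deterministically (score, identity, name; read order for
  equal-length capping), so all outputs are order-independent and
  reproducible byte-for-byte given a seed.
* The center-star aligner replaces a general-purpose multiple aligner:
  at the ≥ 99% within-group identity of tag groups the two are
  effectively equivalent, and an in-package aligner keeps the pipeline
  hermetic. The V/J search uses `Biostrings::pairwiseAlignment`, batched
  one segment against all consensus sequences.
* ACE and rarefaction are validated against independently coded oracles
  (a literal transcription of the Chao–Lee formula; exhaustive subset
  enumeration at `N ≤ 12`) and cross-checked against `vegan`.
* Problem sizes in the test suite are scaled for a single CPU: the
  round-trip and counting checks use 10^4 molecules (~10^5 reads), the
  richness-recovery check samples 40,000 molecules from 2,000 clones
  over 10 seeds, and the skewed-versus-flat contrast samples 30,000
  molecules from 30,000-clone flat and 1,500-clone power-law repertoires.
  The estimator-level checks (richness recovery, contrast) draw molecule
  counts directly from the simulated repertoires — the fidelity of the
  read-level counting stage is established separately by the round-trip
  and 2%-counting checks, so re-sequencing 40,000 molecules per seed
  would add cost without adding information.

## Known limitations

* The 90% rule assumes erroneous tags concentrate at low reads-per-tag;
  with very shallow sequencing (mean ~1–2 reads per molecule) no
  threshold separates them and the pipeline deliberately aborts.
* Counting is slightly conservative: molecules whose correct-tag reads
  fall below `r*` are lost (about 1–2% at the default depth), and
  barcode collisions merge molecules at the birthday rate
  (~3 in 10^4 for 12-mers).
* Groups of ≤ 5 reads cannot satisfy a strict > 80% majority when any
  single read disagrees, so their consensus carries `N`s and they are
  disproportionately discarded at annotation.
* aa-level clonotypes ignore V/J identity by design (for sharing
  analyses); analyses needing V-restricted aa clonotypes should group
  the nt table themselves.
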