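# noirss

Molecular-barcode error elimination and absolute molecule counting for
T-cell receptor beta chain (TCRB) CDR3 repertoire sequencing, with a
ground-truthed V(D)J read simulator and the repertoire statistics used to
characterise such data.

## Who this is for

Immunogenomics analysts working with barcode-tagged (UMI) TCRB amplicon
libraries on error-prone single-end platforms, and method developers who
need a fully simulatable, inspectable reference implementation of
barcode-based consensus sequencing. The package takes raw FASTQ reads laid
out as

```
5-bp sample index | 12-bp random barcode | spacer | C-region primer | antisense TCRB (C -> J -> CDR3 -> V)
```

and produces error-corrected clonotype tables with absolute molecule
counts, plus repertoire-size estimates.

## The method

1. **Demultiplex and tag extraction** — exact 5-bp index match; spacer
   located with at most one edit; reads with spacer+payload < 150 bases
   discarded.
2. **Erroneous-tag removal** — indel errors dominate, so barcode errors
   mostly change tag length. 11/13-bp tags one indel away from a 12-bp tag
   are marked as its derivatives; per reads-per-tag bin *r* the error-free
   fraction `n12 / (n12 + n_derivative)` is computed, and the smallest
   threshold `r*` whose upper bins all reach 90% is applied. Retained
   12-bp tags with ≥ `r*` reads are the sample's molecules — counting is
   absolute, not read-based.
3. **Consensus** — per tag group (capped at the 50 longest reads), a
   center-star multiple alignment and a strict > 80% per-column majority.
4. **Annotation** — local alignment against a germline V/J reference;
   CDR3 extracted from the conserved V cysteine codon through the
   J phenylalanine codon (IMGT-style anchors); out-of-frame, stop-codon
   and ambiguous junctions discarded.
5. **Statistics** — Chao–Lee ACE repertoire-size estimation fed by
   clonotypes seen 1–10 times:

   `S_ACE = S_abund + S_rare / C_ACE + (F1 / C_ACE) * gamma^2`,
   `C_ACE = 1 - F1 / N_rare`

   plus closed-form rarefaction `E[S_m] = sum_j (1 - C(N - N_j, m) / C(N, m))`,
   fixed-size subsampling, low/middle/high abundance classes
   (< 0.01%, 0.01–0.1%, ≥ 0.1%), V/J usage, and multi-sample sharing
   tables at nucleotide and amino-acid level.

A simulator (`simulateRepertoire()`, `generateRun()`) generates clone
repertoires, V–J junctions, barcoded molecules, PCR duplication and
indel-dominant per-base errors in the exact read architecture, with a
truth table, so the full pipeline is testable offline; a small synthetic
germline reference is bundled. See the methods vignette
(`vignettes/noirss-methods.Rmd`) for assumptions, parameter defaults and
limitations.

## Worked example

```r
library(noirss)
cfg <- pipelineConfig(sim = simConfig(nClones = 300, nMolecules = 2000, seed = 42))
out <- runPipeline(cfg)
str(out$manifest$counts)
#> $ reads_total           : int 20128
#> $ rejected_unknown_index: int 809
#> $ rejected_no_spacer    : int 122
#> $ dropped_short         : int 0
#> $ reads_grouped         : int 19197
#> $ tags_total            : int 4072
#> $ tags_12bp             : int 2240
#> $ tags_derivative       : int 1777
#> $ molecules_retained    : int 1976
#> $ annotated_ok          : int 1669
#> $ nt_clonotypes         : int 300
out$profile
#> TagLengthReport: 22 bins, threshold r* = 3 (cut 0.90)
a <- out$stats$nt$ace
sprintf("S_obs %d  S_ACE %.1f  C_ACE %.3f", a$s_obs, a$s_ace, a$c_ace)
#> "S_obs 300  S_ACE 301.3  C_ACE 0.996"
```

Reading the numbers: of 20,128 simulated reads, 931 fail index/spacer
parsing; the 19,197 grouped reads form 4,072 tags, of which 1,777 are
single-indel derivatives of 12-bp tags — erroneous tags are the *majority*
of tags but sit in the low reads-per-tag bins, so the 90% rule sets
`r* = 3` and retains 1,976 molecules (truth: 2,000; barcode-error losses
are ~1–2%). Consensus + annotation recover all 300 simulated clonotypes,
and ACE estimates 301.3 against a true richness of 300.

A thin CLI wraps the same functions
(`inst/scripts/noirss <simulate|demux|consensus|annotate|stats|all>`):

```sh
Rscript inst/scripts/noirss all --n-clones 300 --n-molecules 2000 --seed 42 --out-dir run1
```

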