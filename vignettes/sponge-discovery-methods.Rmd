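---
title: "Methods: finding miRNA sponge transcripts in AGO2 iCLIP data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: finding miRNA sponge transcripts in AGO2 iCLIP data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spongeclip)
```

## The problem

A competing endogenous RNA ("miRNA sponge") is a transcript that sequesters
miRNAs through its miRNA-response elements, relieving repression of other
targets of those miRNAs. AGO2 iCLIP gives a direct readout of
miRNA-programmed RISC occupancy: UV crosslinking followed by AGO2
immunoprecipitation yields cDNA tags whose 5' (truncation) position marks
the crosslinked nucleotide at single-nucleotide resolution. A candidate
sponge then shows a characteristic signature when a stimulus (here, a
TGF-β-type treatment inducing an epithelial–mesenchymal transition) is
applied: a large treatment-induced gain of crosslink sites and of
RISC-associated reads, plus an unusually high density of miRNA seed-match
sites per kilobase.

`spongeclip` implements that screen as a transcript-coordinate pipeline:

1. keep the longest transcript per gene;
2. pool replicates per condition and call single-nucleotide crosslink
   sites from truncation pileups;
3. widen sites to 40-bp binding regions and flag treated regions with no
   positional overlap with any control region ("treatment-specific");
4. quantify RISC association per gene — tags within binding regions, RPKM,
   treated/control fold enrichment, site counts;
5. scan treatment-specific regions for miRNA seed-match patterns, map
   matches to transcript features, and rank transcripts by seed matches
   per kilobase.

All coordinates are transcript-space, 0-based and half-open. Because tags
are aligned to a transcriptome, no genome-space or strand arithmetic is
needed anywhere; synthetic data are generated directly in transcript space.

## Crosslink-site calling

Established iCLIP site callers fit a hidden Markov model over crosslink
diagnostics. This package deliberately replaces that machinery with an
explicit, fully testable rule operating on the pooled (replicate-merged)
truncation pileup of each condition. A position $p$ with count $c(p)$ is a
crosslink site iff

* $c(p) \ge$ `min_count` (default 4 truncation events, the conventional
  minimum evidence for a site), and
* $c(p)$ is a local maximum over $[p - d, p + d]$ with
  `merge_distance` $d = 8$ nt: no strictly greater count in the window and
  no tied count at a smaller coordinate.

The tie rule resolves flat doublets toward the smaller coordinate and
suppresses the larger-coordinate twin, so tied peaks within one window
yield exactly one site. `merge_distance = 8` is roughly a seed-match
footprint; both parameters are exposed in `caller_config()`. Sites are
single-nucleotide, as in HMM-based callers' output; widening happens only
at the binding-region step. Raising `min_count` can only remove sites
(monotonicity), which the test suite asserts.

The published site totals obtained by an HMM caller on the real deposited
libraries are a property of that tool and data and are not targets for
this rule; the synthetic benchmark below is the yardstick instead.

## Binding regions and treatment specificity

Each site is widened to $[\max(0, p-20), \min(L, p+20))$ — a 40-bp window
including the site, clipped at transcript edges. A symmetric ±20 window
around a point spans 41 positions; since the regions are defined as 40 bp
wide, the right boundary is excluded (half-open), leaving the window
asymmetric by one base on the right. Overlapping regions are kept
individually (region count = site count).

A treated-condition region is *treatment-specific* iff it shares zero
positions with every control region on the same transcript, under
half-open semantics — abutting regions do not overlap. Specificity is
computed per timepoint against control independently. The overlap test is
interval algebra (IRanges); the test suite checks it against a brute-force
all-pairs oracle.

## RISC-association statistics

For one treated-vs-control contrast, per gene:

* `reads_<cond>`: tags whose truncation position falls inside any of the
  gene's binding regions of that condition (half-open membership; a tag
  under $k$ overlapping regions counts once);
* `rpkm_<cond>` = reads / (transcript length / 1000) / (total mapped tags
  of the condition / 10^6). The denominator is the condition's full
  library, not only in-region tags, and the length is the gene's longest
  transcript — the standard RPKM definition applied to per-gene counts;
* `enrichment` = treated RPKM / control RPKM, computed unrounded and
  displayed at 2 decimals. A gene with zero control RPKM has an undefined
  ratio: it is flagged `treated_only` and listed separately at the top of
  the ranking rather than being given an infinite or pseudo-count value.
  An optional `pseudocount` (default 0) adds a constant to both RPKMs
  when a finite ratio is explicitly wanted.

Replicate concordance is reported as pairwise Pearson correlation of
`log2(count + 1)` per-gene tag totals within each condition; a principal
component analysis of the same counts would serve the same purpose, and
the correlation matrix is the simpler summary of it.

## Seed matching

The seed of a mature miRNA is taken as nucleotides 2–8 (a 7-mer). The
convention in the field varies between 2–7 and 2–8; the 7-mer is the
stricter default and `seed_span = c(2, 7)` selects the 6-mer. The pattern
searched on the transcript strand is the reverse complement of the seed
in DNA alphabet (U pairs as A) — the canonical miRNA-response element.

Matching is exact string matching (`max_mismatch = 0` by default). For a
7-nt ungapped single-sequence motif, a probabilistic motif scanner at its
default threshold admits exactly the exact matches, so exact matching is
the faithful primitive; a Hamming tolerance is exposed for exploration.
All occurrences are reported, overlapping ones included, and every match
is verifiable by substring equality at its recorded position. A match is
assigned the feature (5'UTR / CDS exon k / 3'UTR) of its *start* position;
matches straddling a boundary are not split. Densities are distinct
matches (miRNA × position) per kilobase of transcript, computed by default
over treatment-specific binding regions only — the regions that carry the
treatment-induced RISC signal.

Seed records may be filtered to a user-supplied list of miRNAs expressed
in the cell system under study; the package takes that list as input
rather than bundling any expression atlas.

## The synthetic study design

`simulation_config()` encodes the study the pipeline is benchmarked on.
Defaults (all overridable, chosen once as the package's reference
conditions):

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 20 | one transcript per gene |
| `length_range` | 1000–4000 nt | non-sponge transcript lengths |
| sponge architecture | fixed | 3000 nt, 8 exons, CDS [150, 2250) |
| `background_rate` | 0.005 /nt/replicate | uniform Poisson truncation noise |
| `peak_height` | 5 /replicate | expected truncations at a planted site |
| sponge sites | 2 shared + 32 treated-only | 2 control vs 34 treated sites |
| `sponge_enrichment` | 10 | treated-condition tag-yield multiplier |
| `n_replicates` | 3 | per condition |
| `conditions` | control, tgfb4h | two-condition contrast |
| planted miRNA | 1 | 1 seed site in CDS exon 3, 2 in the 3'UTR |
| `housekeeping_sites` | 3 per non-sponge gene | condition-independent signal |

Counts are Poisson at every position (background) and site (peak), drawn
per replicate and pooled by the caller; the pooled expectation at a
planted site is $3 \times 5 = 15$ against a pooled background of 0.015,
a 1000-fold peak-to-background ratio that a 4-count threshold detects
essentially without error. The 2-vs-34 site layout and the one-CDS-exon-3
plus two-3'UTR seed placement mirror the sponge architecture the screen
is designed to detect; housekeeping sites on every other gene give all
genes defined (≈1 before library-size effects) enrichment ratios, so the
sponge's top rank is earned against non-degenerate competition.

Sequences are uniform-composition random DNA, rejection-resampled (cap
1,000 attempts) so that no planted seed pattern occurs anywhere outside
its ground-truth positions: any match the scanner finds is planted by
construction, which makes density ranking exactly checkable. Tags are
emitted pre-deduplicated — UMI collapsing happens upstream of this data
representation in a real experiment.

What the simulation does *not* emulate: overdispersed counts, crosslink
sequence bias (real iCLIP truncations favour uridine-rich contexts),
positional spread of truncations around a site, sequencing error, and the
~10^6-tag depth of a real library. Passing the recovery benchmark
therefore shows the pipeline's logic is correct under its stated count
model, not that the simplified caller matches an HMM caller on real data.

## Numerical and degenerate-input choices

* Longest-isoform ties break toward the lexicographically smallest
  transcript_id; the filter is idempotent.
* Non-coding transcripts use the sentinel `cds_start = cds_end = length`
  and classify every position as plain "exon".
* An empty tag table classifies to an empty table, not an error.
* `rpkm()` refuses `total_mapped = 0`; `fold_enrichment()` returns `NA`
  (not `Inf`) at zero control.
* All randomness flows from a single integer seed: the transcriptome uses
  `rng_seed`, the tag draw `rng_seed + 1`, so identical configs give
  byte-identical FASTA/GTF/BED/TSV outputs.
* Pipeline outputs are staged in a temporary directory and renamed into
  place at the end, so a failed stage leaves no partial outputs.

## Problem sizes

The package's reference runs use the default 20-gene configuration
(~8–9 thousand tags per run), which executes the full pipeline in a few
seconds; the test suite's oracle comparisons use 100–150 random fixtures
per operation at transcript lengths of a few hundred nucleotides. These
sizes make every published-arithmetic, recovery and equivalence check
cheap enough to run on every test invocation.

## Known limitations

* The simplified caller has no covariate model; at a lower
  peak-to-background ratio than the reference conditions its
  recall degrades before an HMM caller's would.
* Treatment specificity is positional overlap on the same transcript;
  paralogous regions on different transcripts are not compared.
* Seed matching is sequence-only: no thermodynamics, conservation,
  context scoring or 3'-supplementary pairing.
* RPKM fold enrichment inherits RPKM's library-size coupling: a gene with
  unchanged binding loses apparent enrichment when the treated library
  gains tags elsewhere. Ranking, not the absolute ratio, is the
  pipeline's endpoint.
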