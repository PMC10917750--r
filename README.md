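# spongeclip

Discovery of miRNA sponge transcripts (competing endogenous RNAs) from
AGO2 iCLIP data.

## The problem

AGO2 iCLIP captures, at single-nucleotide resolution, where the
miRNA-programmed RISC complex contacts the transcriptome: reverse
transcription truncates at the crosslinked nucleotide, so each tag's 5'
position marks an AGO2–RNA contact. A transcript acting as a miRNA sponge
shows a distinctive signature when cells are stimulated (e.g. TGF-β-driven
EMT induction): a large treatment-induced gain of crosslink sites and of
RISC-associated reads, together with an unusually high density of miRNA
seed-match sites per kilobase.

`spongeclip` implements that screen as a transcript-coordinate pipeline
(0-based, half-open throughout):

1. **Longest isoform** — keep one transcript per gene (maximal length,
   ties to smallest id).
2. **Crosslink sites** — pool replicates per condition; call position *p*
   a site iff its truncation count ≥ `min_count` (default 4) and it is a
   local maximum over ±`merge_distance` (default 8 nt), ties resolved
   toward the smaller coordinate.
3. **Binding regions** — widen each site to the 40-bp window
   [*p*−20, *p*+20), clipped at transcript edges; flag treated regions
   with zero positional overlap with any control region as
   treatment-specific.
4. **RISC quantification** — per gene: tags inside binding regions, RPKM
   (reads / (transcript kb) / (million mapped tags of the condition)),
   fold enrichment = treated RPKM / control RPKM, and site counts.
5. **Seed scan** — seed = mature miRNA nucleotides 2–8; the search pattern
   is its reverse complement in DNA; exact matches in treatment-specific
   regions are mapped to transcript features (5'UTR / CDS exon *k* /
   3'UTR by match start) and transcripts ranked by matches per kb.

A synthetic-data generator plants a sponge transcript (condition-specific
crosslink sites, enriched treated tag yield, seed sites in known features)
in a toy transcriptome with full ground truth, so site recovery, rankings
and feature mapping are exactly checkable.

## Worked example

```r
library(spongeclip)

cfg <- simulation_config(rng_seed = 1L)   # 20 genes, sponge = g001
res <- run_pipeline(pipeline_config(out_dir = "demo_out", sim = cfg))
print(res)
#> <sponge_screen>
#>   20 genes, 8616 tags, 150 crosslink sites
#>   30 treatment-specific regions, 3 seed matches
#>   top fold enrichment: g001 (31.76)
#>   top seed density:    g001 (1.00 per kb)
summary(res)
#> Per-gene RISC association (top 5 by enrichment):
#>  gene_id reads_control rpkm_control reads_treated rpkm_treated enrichment_2dp
#>     g001            38     7931.538          5305   251935.223          31.76
#>     g007            32     5351.915            46     1750.438           0.33
#>     ...
#>  sites_control sites_treated
#>              2            34
#>              3             3
#> ...
#> Seed-match locations:
#>  mirna_name transcript_id gene_id n_matches             locations
#>   miR-sim-1          t001    g001         3 Exon 3 (1), 3'UTR (2)
```

Reading the output: the planted sponge `g001` goes from 2 crosslink sites
in control to 34 under treatment, its RISC-associated RPKM rises ~32-fold
(its 10-fold tag-yield enrichment compounded with its extra treated
binding regions and the library-size shift), and it is the only transcript
with seed matches — one in CDS exon 3 and two in the 3'UTR, exactly as
planted. Non-sponge genes sit near-constant (enrichment < 1 because the
treated library is larger) with their 3 condition-independent sites.

`run_pipeline()` writes per-condition site BEDs, the region table with
specificity flags, the per-gene statistics TSV, seed matches, the feature
report, the density ranking and a run log into `out_dir`. The same
analysis runs on pre-generated files (`gtf`, `fasta`, `tag_bed`,
`mirna_file` arguments, or `scripts/run_pipeline.R` from a shell).

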