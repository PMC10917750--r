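#!/usr/bin/env Rscript
# Thin command-line wrapper around spongeclip::run_pipeline().
#
#   Simulated study:   Rscript scripts/run_pipeline.R --out results --seed 1
#   Pre-existing data: Rscript scripts/run_pipeline.R --out results \
#                        --gtf tx.gtf --fasta tx.fa --tags tags.bed \
#                        --mirna mature.fa [--expressed list.txt]

suppressPackageStartupMessages({
  library(spongeclip)
  library(optparse)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--out", type = "character", default = "spongeclip_out"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--gtf", type = "character", default = NULL),
  make_option("--fasta", type = "character", default = NULL),
  make_option("--tags", type = "character", default = NULL),
  make_option("--mirna", type = "character", default = NULL),
  make_option("--expressed", type = "character", default = NULL,
              help = "file with one expressed miRNA name per line"),
  make_option("--min-count", type = "integer", default = 4L),
  make_option("--merge-distance", type = "integer", default = 8L),
  make_option("--flank", type = "integer", default = 20L),
  make_option("--pseudocount", type = "double", default = 0),
  make_option("--control", type = "character", default = "control"),
  make_option("--treated", type = "character", default = "tgfb4h"))))

simulated <- is.null(opts$gtf)
status <- tryCatch({
  cfg <- pipeline_config(
    out_dir = opts$out,
    sim = if (simulated) simulation_config(rng_seed = opts$seed) else NULL,
    gtf = opts$gtf, fasta = opts$fasta, tag_bed = opts$tags,
    mirna_file = opts$mirna,
    expressed_mirnas = if (!is.null(opts$expressed))
      readLines(opts$expressed) else NULL,
    caller = caller_config(opts$`min-count`, opts$`merge-distance`),
    flank = opts$flank, pseudocount = opts$pseudocount,
    control = opts$control, treated = opts$treated)
  print(run_pipeline(cfg))
  0L
}, error = function(e) {
  message(conditionMessage(e))
  if (grepl("pipeline stage", conditionMessage(e))) 2L else 1L
})
quit(status = status)
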