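#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs. Inputs are either a
#' [simulation_config()] (`sim`) or pre-generated files (`gtf`, `fasta`,
#' `tag_bed`); miRNA seed input is either a file (`mirna_file`) or, for
#' simulated runs, the planted miRNAs from the simulation config.
#'
#' @param out_dir Output directory (created; written atomically at the end).
#' @param sim A [simulation_config()], or `NULL` to analyse provided files.
#' @param gtf,fasta,tag_bed Input paths used when `sim` is `NULL`.
#' @param mirna_file Optional mature-miRNA FASTA/TSV for [load_mirnas()].
#' @param expressed_mirnas Optional character vector; when given, seed
#'   records are restricted to these names before scanning.
#' @param caller A [caller_config()].
#' @param flank Binding-region half-width in nt (default 20).
#' @param seed_span Seed definition, see [seed_match_pattern()].
#' @param pseudocount RPKM pseudocount for enrichment ratios (default 0).
#' @param control,treated Condition labels contrasted in the report.
#' @param max_mismatch Seed-scan mismatch tolerance (default 0 = exact).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            sim = simulation_config(),
                            gtf = NULL, fasta = NULL, tag_bed = NULL,
                            mirna_file = NULL, expressed_mirnas = NULL,
                            caller = caller_config(), flank = 20L,
                            seed_span = c(2L, 8L), pseudocount = 0,
                            control = "control", treated = "tgfb4h",
                            max_mismatch = 0L) {
  if (is.null(sim)) {
    for (p in c(gtf, fasta, tag_bed))
      if (!file.exists(p)) stop("input file not found: ", p)
    if (is.null(gtf) || is.null(fasta) || is.null(tag_bed))
      stop("without a simulation config, gtf, fasta and tag_bed are required")
  }
  structure(list(out_dir = out_dir, sim = sim, gtf = gtf, fasta = fasta,
                 tag_bed = tag_bed, mirna_file = mirna_file,
                 expressed_mirnas = expressed_mirnas, caller = caller,
                 flank = as.integer(flank), seed_span = as.integer(seed_span),
                 pseudocount = pseudocount, control = control,
                 treated = treated, max_mismatch = as.integer(max_mismatch)),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the sponge-discovery pipeline
#'
#' Executes the full analysis — simulate (or load) the transcriptome and
#' tags, select the longest transcript per gene, merge replicates, call
#' crosslink sites per condition, widen to binding regions, flag
#' treatment-specific regions, compute per-gene RISC statistics, scan the
#' treatment-specific regions for miRNA seed matches, map matches to
#' transcript features and rank transcripts by seed density per kb.
#'
#' All outputs are written into `cfg$out_dir` atomically at the end of the
#' run (a failed stage leaves no partial outputs): per-condition site BED
#' files, a region table with specificity flags, the per-gene statistics
#' TSV, the seed-match TSV, the aggregated feature report, the density
#' ranking and a run log.
#'
#' @param cfg A [pipeline_config()].
#' @return (Invisibly) a `sponge_screen` object collecting every
#'   intermediate and final table.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  if (!is.null(cfg$sim)) {
    simres <- .stage("simulate", simulate_study(cfg$sim))
    ts <- simres$ts; tags <- simres$tags; truth <- simres$truth
    note("simulate: %d transcripts, %d tags", length(ts), nrow(tags))
  } else {
    ts <- .stage("load_annotation", load_annotation(cfg$gtf, cfg$fasta))
    tags <- .stage("load_tags", read_tag_bed(cfg$tag_bed))
    truth <- NULL
    note("load: %d transcripts, %d tags", length(ts), nrow(tags))
  }

  ts <- .stage("longest_isoform", select_longest_per_gene(ts))
  note("longest_isoform: %d transcripts kept", length(ts))

  records <- .stage("mirnas", {
    if (!is.null(cfg$mirna_file)) load_mirnas(cfg$mirna_file, cfg$seed_span)
    else if (!is.null(cfg$sim) && length(cfg$sim$planted_seeds))
      mirna_seed_records(
        vapply(cfg$sim$planted_seeds, `[[`, character(1L), "name"),
        vapply(cfg$sim$planted_seeds, `[[`, character(1L), "mature"),
        cfg$seed_span)
    else stop("no miRNA input: give mirna_file or simulate planted seeds")
  })
  if (!is.null(cfg$expressed_mirnas))
    records <- filter_expressed_mirnas(records, cfg$expressed_mirnas)
  note("mirnas: %d seed records", nrow(records))

  pooled <- .stage("merge_replicates", merge_replicates(tags))
  sites <- .stage("call_sites", call_sites_all(pooled, ts, cfg$caller))
  site_tab <- table(sites$condition)
  note("call_sites: %d sites (%s)", nrow(sites),
       paste(sprintf("%s=%d", names(site_tab), as.integer(site_tab)),
             collapse = ", "))

  regions <- .stage("regions", extend_to_regions(sites, ts, cfg$flank))
  treated_regions <- .stage("specific", select_condition_specific(
    regions[regions$condition == cfg$treated, ],
    regions[regions$condition == cfg$control, ]))
  note("regions: %d treated, %d treatment-specific",
       nrow(treated_regions), sum(treated_regions$treatment_specific))

  stats <- .stage("risc_stats", gene_risc_stats(
    tags, sites, regions, ts, control = cfg$control, treated = cfg$treated,
    pseudocount = cfg$pseudocount))
  ranking <- rank_by_enrichment(stats)
  note("risc_stats: top gene by enrichment = %s", ranking$gene_id[1L])

  spec_regions <- treated_regions[treated_regions$treatment_specific, ]
  matches <- .stage("seed_scan",
                    scan_regions(records, spec_regions, ts, cfg$max_mismatch))
  feature_map <- .stage("feature_map", map_matches_to_features(matches, ts))
  density <- .stage("density", seed_density_per_kb(matches, ts))
  note("seed_scan: %d matches in %d specific regions; top density = %s",
       nrow(matches), nrow(spec_regions), density$gene_id[1L])

  tag_loc <- .stage("tag_locations", classify_tag_locations(pooled, ts))

  res <- structure(list(ts = ts, tags = tags, truth = truth, sites = sites,
                        regions = regions, treated_regions = treated_regions,
                        stats = stats, ranking = ranking, matches = matches,
                        feature_map = feature_map, density = density,
                        tag_locations = tag_loc, records = records,
                        config = cfg, log = log),
                   class = "sponge_screen")
  .write_outputs(res)
  invisible(res)
}

# stage all files in a temporary sibling directory, then rename into place:
# a failure part-way leaves out_dir untouched
.write_outputs <- function(res) {
  cfg <- res$config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_dir <- tempfile("spongeclip_stage_", tmpdir = cfg$out_dir)
  dir.create(stage_dir)
  on.exit(unlink(stage_dir, recursive = TRUE), add = TRUE)

  write_sites_bed(res$sites, stage_dir)
  all_regions <- rbind(
    cbind(res$regions[res$regions$condition == cfg$control, ],
          treatment_specific = FALSE),
    res$treated_regions)
  write_regions_bed(all_regions, file.path(stage_dir, "regions.tsv"))
  write_gene_stats(res$ranking, file.path(stage_dir, "gene_stats.tsv"))
  utils::write.table(res$matches, file.path(stage_dir, "seed_matches.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$feature_map,
                     file.path(stage_dir, "seed_feature_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$density, file.path(stage_dir, "seed_density.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  versions <- sprintf("%s %s", c("spongeclip", "R"),
                      c(as.character(utils::packageVersion("spongeclip")),
                        paste(R.version$major, R.version$minor, sep = ".")))
  writeLines(c(res$log, versions), file.path(stage_dir, "run_log.txt"))
  if (!is.null(res$truth)) write_ground_truth(res$truth, stage_dir)
  if (!is.null(cfg$sim))
    write_config_log(cfg$sim, file.path(stage_dir, "sim_config.txt"))

  for (f in list.files(stage_dir)) {
    to <- file.path(cfg$out_dir, f)
    if (file.exists(to)) unlink(to)
    file.rename(file.path(stage_dir, f), to)
  }
  invisible(cfg$out_dir)
}

#' @export
print.sponge_screen <- function(x, ...) {
  cat("<sponge_screen>\n")
  cat(sprintf("  %d genes, %d tags, %d crosslink sites\n",
              length(x$ts$gene_index), nrow(x$tags), nrow(x$sites)))
  cat(sprintf("  %d treatment-specific regions, %d seed matches\n",
              sum(x$treated_regions$treatment_specific), nrow(x$matches)))
  cat(sprintf("  top fold enrichment: %s (%.2f)\n", x$ranking$gene_id[1L],
              x$ranking$enrichment[1L]))
  cat(sprintf("  top seed density:    %s (%.2f per kb)\n",
              x$density$gene_id[1L], x$density$density_per_kb[1L]))
  invisible(x)
}

#' @export
summary.sponge_screen <- function(object, ...) {
  cat("Per-gene RISC association (top 5 by enrichment):\n")
  print(utils::head(object$ranking[c("gene_id", "reads_control",
                                     "rpkm_control", "reads_treated",
                                     "rpkm_treated", "enrichment_2dp",
                                     "sites_control", "sites_treated")], 5L),
        row.names = FALSE)
  cat("\nSeed density per kb (top 5):\n")
  print(utils::head(object$density, 5L), row.names = FALSE)
  if (nrow(object$feature_map)) {
    cat("\nSeed-match locations:\n")
    print(object$feature_map, row.names = FALSE)
  }
  invisible(object)
}
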