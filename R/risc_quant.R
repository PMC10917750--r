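#' Count tags falling in a gene's binding regions
#'
#' A tag is counted for a gene iff its truncation position lies within any
#' of that gene's binding regions (half-open, so a tag at `end` is outside).
#' A tag covered by several overlapping regions of one gene counts once.
#' Every gene of the transcript set is reported, with 0 where it has no
#' regions or no tags.
#'
#' @param tags Pooled tag `data.frame` of one condition.
#' @param regions Region `data.frame` of the same condition.
#' @param ts A `transcript_set` (one transcript per gene).
#' @return `data.frame` with columns `gene_id` and `count`.
#' @export
count_tags_in_regions <- function(tags, regions, ts) {
  stopifnot(inherits(ts, "transcript_set"))
  genes <- sort(names(ts$gene_index))
  counts <- stats::setNames(integer(length(genes)), genes)
  for (tid in unique(regions$transcript_id)) {
    t <- get_transcript(ts, tid)
    r <- regions[regions$transcript_id == tid, ]
    cover <- logical(t$length)
    for (j in seq_len(nrow(r)))
      if (r$end[j] > r$start[j]) cover[(r$start[j] + 1L):r$end[j]] <- TRUE
    pos <- tags$position[tags$transcript_id == tid]
    counts[t$gene_id] <- counts[t$gene_id] + sum(cover[pos + 1L])
  }
  data.frame(gene_id = genes, count = as.integer(counts), row.names = NULL)
}

#' Reads per kilobase of transcript per million mapped tags
#'
#' `count / (transcript_length / 1000) / (total_mapped / 1e6)`. Vectorised.
#'
#' @param count Tag count(s) in the gene's binding regions.
#' @param transcript_length Length in nt of the gene's (longest) transcript.
#' @param total_mapped Total mapped tags of the condition (the library
#'   size), not only in-region tags.
#' @return RPKM value(s).
#' @export
rpkm <- function(count, transcript_length, total_mapped) {
  if (any(total_mapped <= 0)) stop("total_mapped must be > 0")
  if (any(transcript_length <= 0)) stop("transcript_length must be > 0")
  count / (transcript_length / 1000) / (total_mapped / 1e6)
}

#' Fold enrichment of RISC association
#'
#' `rpkm_treated / rpkm_control`, vectorised. Where the control RPKM is 0
#' the ratio is undefined and `NA` is returned — such genes are flagged
#' "treated-only" downstream rather than given an infinite value. Report at
#' 2 decimals for display; computation stays unrounded.
#'
#' @param rpkm_control,rpkm_treated RPKM values.
#' @return Numeric fold ratios with `NA` where control is 0.
#' @export
fold_enrichment <- function(rpkm_control, rpkm_treated) {
  ifelse(rpkm_control > 0, rpkm_treated / rpkm_control, NA_real_)
}

#' Per-gene RISC-association statistics
#'
#' Assembles the per-gene report for one treated-vs-control contrast:
#' tag counts within each condition's binding regions, RPKM against the
#' condition's total mapped tags, fold enrichment, crosslink-site counts,
#' and a `treated_only` flag for genes with zero control RPKM. With
#' `pseudocount > 0` the enrichment is computed as
#' `(rpkm_treated + pc) / (rpkm_control + pc)` so treated-only genes also
#' get a finite ratio.
#'
#' @param tags Pooled tag `data.frame` covering both conditions.
#' @param sites Site `data.frame` from [call_sites_all()].
#' @param regions Region `data.frame` covering both conditions.
#' @param ts A `transcript_set`.
#' @param control,treated Condition labels to contrast.
#' @param pseudocount RPKM pseudocount for the ratio (default 0: undefined
#'   ratios are `NA` + `treated_only`).
#' @return `data.frame` with columns `gene_id`, `reads_control`,
#'   `rpkm_control`, `reads_treated`, `rpkm_treated`, `enrichment`,
#'   `enrichment_2dp`, `treated_only`, `sites_control`, `sites_treated`.
#' @export
gene_risc_stats <- function(tags, sites, regions, ts,
                            control = "control", treated = "tgfb4h",
                            pseudocount = 0) {
  stopifnot(inherits(ts, "transcript_set"), pseudocount >= 0)
  pooled <- merge_replicates(tags)
  tc <- pooled[pooled$condition == control, ]
  tt <- pooled[pooled$condition == treated, ]
  cc <- count_tags_in_regions(tc, regions[regions$condition == control, ], ts)
  ct <- count_tags_in_regions(tt, regions[regions$condition == treated, ], ts)
  genes <- cc$gene_id
  lens <- vapply(genes, function(g) {
    tids <- ts$gene_index[[g]]
    max(vapply(ts$transcripts[tids], `[[`, integer(1L), "length"))
  }, integer(1L))
  rc <- rpkm(cc$count, lens, max(nrow(tc), 1L))
  rt <- rpkm(ct$count, lens, max(nrow(tt), 1L))
  enr <- if (pseudocount > 0) (rt + pseudocount) / (rc + pseudocount)
         else fold_enrichment(rc, rt)
  sc <- count_sites_per_gene(sites[sites$condition == control, ], ts,
                             conditions = control)[[control]]
  st <- count_sites_per_gene(sites[sites$condition == treated, ], ts,
                             conditions = treated)[[treated]]
  data.frame(gene_id = genes,
             reads_control = cc$count, rpkm_control = rc,
             reads_treated = ct$count, rpkm_treated = rt,
             enrichment = enr, enrichment_2dp = round(enr, 2L),
             treated_only = rc == 0 & rt > 0,
             sites_control = sc, sites_treated = st,
             row.names = NULL)
}

#' Rank genes by RISC fold enrichment
#'
#' Treated-only genes (undefined ratio) are listed separately at the top,
#' ordered by treated RPKM; the remainder follow in descending enrichment,
#' ties broken by gene_id.
#'
#' @param stats Output of [gene_risc_stats()].
#' @return The reordered table with a `rank` column.
#' @export
rank_by_enrichment <- function(stats) {
  tonly <- stats[stats$treated_only %in% TRUE, ]
  rest <- stats[!stats$treated_only %in% TRUE, ]
  tonly <- tonly[order(-tonly$rpkm_treated, tonly$gene_id), ]
  rest <- rest[order(-ifelse(is.na(rest$enrichment), -Inf, rest$enrichment),
                     rest$gene_id), ]
  out <- rbind(tonly, rest)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Pairwise replicate concordance per condition
#'
#' Pearson correlation of `log2(count + 1)` per-gene tag totals between
#' every replicate pair within a condition; the diagonal is 1. A replicate
#' with zero tags has undefined correlations, reported as `NA`. Conditions
#' with a single replicate give a 1x1 matrix.
#'
#' @param tags Tag `data.frame` with replicate labels.
#' @param ts A `transcript_set` defining the gene universe.
#' @return Named list (by condition) of symmetric correlation matrices.
#' @export
replicate_concordance <- function(tags, ts) {
  stopifnot(inherits(ts, "transcript_set"))
  tid2gene <- vapply(ts$transcripts, `[[`, character(1L), "gene_id")
  genes <- sort(unique(tid2gene))
  out <- list()
  for (cond in unique(tags$condition)) {
    tc <- tags[tags$condition == cond, ]
    reps <- sort(unique(tc$replicate))
    if (length(reps) < 2L) {
      out[[cond]] <- matrix(numeric(0), 0L, 0L)
      next
    }
    m <- vapply(reps, function(r) {
      g <- tid2gene[tc$transcript_id[tc$replicate == r]]
      vapply(genes, function(x) sum(g == x), numeric(1L))
    }, numeric(length(genes)))
    m <- log2(matrix(m, nrow = length(genes)) + 1)
    cm <- suppressWarnings(stats::cor(m))
    diag(cm) <- ifelse(colSums(m) == 0, NA_real_, 1)
    dimnames(cm) <- list(paste0("rep", reps), paste0("rep", reps))
    out[[cond]] <- cm
  }
  out
}

#' Write the per-gene RISC report as TSV
#' @param stats Output of [gene_risc_stats()] or [rank_by_enrichment()].
#' @param path Output file.
#' @export
write_gene_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
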