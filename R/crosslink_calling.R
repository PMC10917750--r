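#' Caller configuration
#'
#' @param min_count Minimum pooled truncation count for a position to be
#'   called a crosslink site (default 4, the conventional minimum number of
#'   truncation events supporting a site).
#' @param merge_distance Half-width in nt of the local-maximum window used to
#'   collapse nearby candidate positions into one site (default 8, roughly a
#'   seed-match footprint).
#' @return A `caller_config` list.
#' @export
caller_config <- function(min_count = 4L, merge_distance = 8L) {
  min_count <- as.integer(min_count)
  merge_distance <- as.integer(merge_distance)
  stopifnot(min_count >= 1L, merge_distance >= 0L)
  structure(list(min_count = min_count, merge_distance = merge_distance),
            class = "caller_config")
}

#' Pool replicate tags within each condition
#'
#' Drops the replicate label, preserving the multiset of
#' (transcript, position) tags per condition exactly. Replicates are pooled
#' before site calling so that the evidence threshold applies to the
#' combined truncation counts of a condition.
#'
#' @param tags Tag `data.frame` with columns `transcript_id`, `position`,
#'   `condition`, `replicate`.
#' @return The same tags without the `replicate` column.
#' @export
merge_replicates <- function(tags) {
  stopifnot(all(c("transcript_id", "position", "condition") %in% names(tags)))
  tags[setdiff(names(tags), "replicate")]
}

#' Per-position truncation pileup for one transcript
#'
#' @param tags Pooled tags restricted to transcript `t` (rows with a
#'   different transcript_id are an error).
#' @param t A `transcript_model`.
#' @return Integer vector of length `t$length`; element `i` is the
#'   truncation count at 0-based position `i - 1`.
#' @export
pileup_truncations <- function(tags, t) {
  stopifnot(inherits(t, "transcript_model"))
  if (nrow(tags) == 0L) return(integer(t$length))
  if (any(tags$transcript_id != t$transcript_id))
    stop("tags contain transcripts other than ", t$transcript_id)
  if (min(tags$position) < 0L || max(tags$position) >= t$length)
    stop("tag position out of bounds on ", t$transcript_id)
  as.integer(tabulate(tags$position + 1L, nbins = t$length))
}

#' Call crosslink sites from a truncation pileup
#'
#' A position `p` is called a site iff its count is at least
#' `cfg$min_count` and it is a local maximum over the window
#' `[p - merge_distance, p + merge_distance]`: no position in the window has
#' a strictly greater count, and no position at a smaller coordinate ties
#' it. Ties are thereby resolved toward the smaller coordinate, which also
#' suppresses the larger-coordinate member of a tied pair. Site score is the
#' count at `p`. Output is sorted by position.
#'
#' @param pileup Integer count vector from [pileup_truncations()].
#' @param cfg A [caller_config()].
#' @return `data.frame` with columns `position` (0-based) and `score`.
#' @export
call_crosslink_sites <- function(pileup, cfg = caller_config()) {
  stopifnot(inherits(cfg, "caller_config"))
  n <- length(pileup)
  cand <- which(pileup >= cfg$min_count)
  d <- cfg$merge_distance
  keep <- vapply(cand, function(i) {
    lo <- max(1L, i - d); hi <- min(n, i + d)
    win <- pileup[lo:hi]
    if (any(win > pileup[i])) return(FALSE)
    left <- if (i > lo) pileup[lo:(i - 1L)] else integer()
    !any(left == pileup[i])
  }, logical(1L))
  data.frame(position = cand[keep] - 1L, score = pileup[cand[keep]])
}

#' Call crosslink sites for every transcript and condition
#'
#' Convenience wrapper: pools replicates, builds the per-transcript pileup
#' for each condition and applies [call_crosslink_sites()].
#'
#' @param tags Tag `data.frame` (with or without replicate labels).
#' @param ts A `transcript_set`.
#' @param cfg A [caller_config()].
#' @return `data.frame` of sites: `transcript_id`, `position`, `score`,
#'   `condition`.
#' @export
call_sites_all <- function(tags, ts, cfg = caller_config()) {
  stopifnot(inherits(ts, "transcript_set"))
  pooled <- merge_replicates(tags)
  out <- list()
  for (cond in unique(pooled$condition)) {
    tc <- pooled[pooled$condition == cond, ]
    for (tid in unique(tc$transcript_id)) {
      t <- get_transcript(ts, tid)
      sites <- call_crosslink_sites(
        pileup_truncations(tc[tc$transcript_id == tid, ], t), cfg)
      if (nrow(sites))
        out[[length(out) + 1L]] <-
          data.frame(transcript_id = tid, position = sites$position,
                     score = sites$score, condition = cond)
    }
  }
  if (!length(out))
    return(data.frame(transcript_id = character(), position = integer(),
                      score = integer(), condition = character()))
  sites <- do.call(rbind, out)
  sites <- sites[order(sites$condition, sites$transcript_id, sites$position), ]
  rownames(sites) <- NULL
  sites
}

#' Count crosslink sites per gene and condition
#'
#' Genes without sites are reported with 0, mirroring a per-gene
#' crosslink-site summary table across conditions.
#'
#' @param sites Site `data.frame` from [call_sites_all()].
#' @param ts The `transcript_set` the sites were called on.
#' @param conditions Conditions to report (default: those present in
#'   `sites`).
#' @return `data.frame` with `gene_id` and one integer column per condition.
#' @export
count_sites_per_gene <- function(sites, ts, conditions = NULL) {
  stopifnot(inherits(ts, "transcript_set"))
  if (is.null(conditions)) conditions <- sort(unique(sites$condition))
  genes <- sort(names(ts$gene_index))
  tid2gene <- vapply(ts$transcripts, `[[`, character(1L), "gene_id")
  out <- data.frame(gene_id = genes)
  for (cond in conditions) {
    sc <- sites[sites$condition == cond, ]
    g <- tid2gene[sc$transcript_id]
    out[[cond]] <- as.integer(vapply(genes, function(x) sum(g == x),
                                     integer(1L)))
  }
  out
}

#' Write called sites as BED6, one file per condition
#'
#' Rows are `transcript_id  pos  pos+1  site_<n>  score  +`.
#'
#' @param sites Site `data.frame` from [call_sites_all()].
#' @param dir Output directory.
#' @return Named character vector of written paths.
#' @export
write_sites_bed <- function(sites, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (cond in unique(sites$condition)) {
    s <- sites[sites$condition == cond, ]
    bed <- data.frame(s$transcript_id, s$position, s$position + 1L,
                      sprintf("site_%d", seq_len(nrow(s))), s$score, "+")
    p <- file.path(dir, paste0("sites_", cond, ".bed"))
    utils::write.table(bed, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths[cond] <- p
  }
  invisible(paths)
}
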