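#' Widen crosslink sites to binding regions
#'
#' Each single-nucleotide site at position `p` becomes the half-open
#' interval `[max(0, p - flank), min(length, p + flank))` — 40 bp in the
#' interior at the default flank of 20, clipped at transcript edges.
#' Overlapping regions are retained individually (no merging), so region
#' count equals site count.
#'
#' @param sites Site `data.frame` (`transcript_id`, `position`, `condition`).
#' @param ts A `transcript_set`.
#' @param flank Half-width in nt (default 20).
#' @return `data.frame` of regions: `transcript_id`, `start`, `end`,
#'   `center_site`, `condition`.
#' @export
extend_to_regions <- function(sites, ts, flank = 20L) {
  stopifnot(inherits(ts, "transcript_set"), flank >= 0L)
  flank <- as.integer(flank)
  lens <- vapply(ts$transcripts, `[[`, integer(1L), "length")
  unknown <- setdiff(unique(sites$transcript_id), names(lens))
  if (length(unknown)) stop("site on unknown transcript: ", unknown[1L])
  len <- lens[sites$transcript_id]
  data.frame(transcript_id = sites$transcript_id,
             start = pmax(0L, sites$position - flank),
             end = pmin(len, sites$position + flank),
             center_site = sites$position,
             condition = sites$condition,
             row.names = NULL)
}

#' Flag treated regions with no positional overlap with control
#'
#' A treated-condition region is treatment-specific iff it shares zero
#' positions (half-open semantics, same transcript) with every control
#' region: abutting regions do not overlap. All treated regions are
#' returned, with the flag set.
#'
#' @param treated,control Region `data.frame`s from [extend_to_regions()],
#'   on the same transcript set.
#' @return `treated` with an added logical column `treatment_specific`.
#' @export
select_condition_specific <- function(treated, control) {
  if (nrow(treated) == 0L) {
    treated$treatment_specific <- logical(0L)
    return(treated)
  }
  specific <- rep(TRUE, nrow(treated))
  if (nrow(control) > 0L) {
    # half-open [s, e) -> closed 1-based [s+1, e] for IRanges
    for (tid in unique(treated$transcript_id)) {
      ti <- which(treated$transcript_id == tid)
      ci <- which(control$transcript_id == tid)
      if (!length(ci)) next
      tr <- IRanges::IRanges(start = treated$start[ti] + 1L,
                             end = treated$end[ti])
      cr <- IRanges::IRanges(start = control$start[ci] + 1L,
                             end = control$end[ci])
      specific[ti] <- IRanges::countOverlaps(tr, cr) == 0L
    }
  }
  treated$treatment_specific <- specific
  treated
}

#' Extract region sequences from the transcript set
#'
#' Exact substring `[start, end)` of each region's transcript sequence; the
#' record name encodes transcript and coordinates as
#' `<transcript_id>:<start>-<end>`.
#'
#' @param regions Region `data.frame`.
#' @param ts A `transcript_set`.
#' @return Named character vector of DNA sequences (possibly empty).
#' @export
extract_region_sequences <- function(regions, ts) {
  stopifnot(inherits(ts, "transcript_set"))
  if (nrow(regions) == 0L) return(stats::setNames(character(), character()))
  out <- character(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    t <- get_transcript(ts, regions$transcript_id[i])
    s <- regions$start[i]; e <- regions$end[i]
    if (s < 0L || e > t$length || s > e)
      stop("region [", s, ", ", e, ") out of bounds on ", t$transcript_id)
    out[i] <- substr(t$sequence, s + 1L, e)
  }
  names(out) <- sprintf("%s:%d-%d", regions$transcript_id, regions$start,
                        regions$end)
  out
}

#' Write binding regions as BED6 + specificity flag
#'
#' Columns: transcript_id, start, end, `region_<center>_<condition>`, score
#' (center position), strand, `treatment_specific` (0/1; 0 where the flag is
#' absent, e.g. control regions).
#'
#' @param regions Region `data.frame`, optionally with `treatment_specific`.
#' @param path Output TSV.
#' @export
write_regions_bed <- function(regions, path) {
  flag <- if ("treatment_specific" %in% names(regions))
    as.integer(regions$treatment_specific) else rep(0L, nrow(regions))
  bed <- data.frame(regions$transcript_id, regions$start, regions$end,
                    sprintf("region_%d_%s", regions$center_site,
                            regions$condition),
                    regions$center_site, "+", flag)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
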