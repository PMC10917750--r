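#' Construct a transcript model
#'
#' A transcript is represented entirely in transcript coordinates (0-based,
#' half-open), the natural frame for iCLIP data aligned to a transcriptome:
#' exons tile `[0, length)` without gaps, and the CDS is a single half-open
#' interval `[cds_start, cds_end)`. Positions before `cds_start` are 5'UTR,
#' positions at or after `cds_end` are 3'UTR.
#'
#' Non-coding transcripts use the sentinel `cds_start == cds_end == length`;
#' all their positions are labelled plain `"exon"` with no UTR/CDS split.
#'
#' @param transcript_id,gene_id,gene_name Identifier strings.
#' @param exon_bounds Two-column integer matrix of half-open exon intervals
#'   `[start, end)` in transcript coordinates, ordered 5' to 3'. They must
#'   tile `[0, length)` exactly.
#' @param cds_start,cds_end CDS bounds, 0-based half-open. For non-coding
#'   transcripts pass `cds_start = cds_end = length`.
#' @param sequence DNA string over `{A,C,G,T}` with `nchar(sequence)` equal to
#'   the transcript length.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, gene_name = gene_id,
                             exon_bounds, cds_start, cds_end, sequence) {
  exon_bounds <- matrix(as.integer(exon_bounds), ncol = 2L,
                        dimnames = list(NULL, c("start", "end")))
  if (nrow(exon_bounds) < 1L) stop("transcript '", transcript_id, "': no exons")
  len <- unname(exon_bounds[nrow(exon_bounds), "end"])
  if (exon_bounds[1L, "start"] != 0L)
    stop("transcript '", transcript_id, "': first exon must start at 0")
  if (any(exon_bounds[, "end"] <= exon_bounds[, "start"]))
    stop("transcript '", transcript_id, "': empty or inverted exon interval")
  if (nrow(exon_bounds) > 1L &&
      any(exon_bounds[-1L, "start"] != exon_bounds[-nrow(exon_bounds), "end"]))
    stop("transcript '", transcript_id,
         "': exons must tile the transcript without gaps or overlaps")
  cds_start <- as.integer(cds_start); cds_end <- as.integer(cds_end)
  noncoding <- cds_start == len && cds_end == len
  if (!noncoding && !(cds_start >= 0L && cds_start < cds_end && cds_end <= len))
    stop("transcript '", transcript_id, "': invalid CDS bounds [",
         cds_start, ", ", cds_end, ") for length ", len)
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) != len)
    stop("transcript '", transcript_id, "': sequence length ", nchar(sequence),
         " != annotated length ", len)
  if (grepl("[^ACGT]", sequence))
    stop("transcript '", transcript_id, "': sequence contains non-ACGT characters")
  structure(list(transcript_id = as.character(transcript_id),
                 gene_id = as.character(gene_id),
                 gene_name = as.character(gene_name),
                 length = len, exon_bounds = exon_bounds,
                 cds_start = cds_start, cds_end = cds_end,
                 sequence = sequence),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cds <- if (x$cds_start == x$length) "non-coding"
         else sprintf("CDS [%d, %d)", x$cds_start, x$cds_end)
  cat(sprintf("<transcript_model> %s (%s/%s), %d nt, %d exon(s), %s\n",
              x$transcript_id, x$gene_id, x$gene_name, x$length,
              nrow(x$exon_bounds), cds))
  invisible(x)
}

#' Bundle transcript models into a set
#'
#' @param transcripts List of [transcript_model()] objects.
#' @return A `transcript_set`: transcripts keyed by transcript_id plus a
#'   gene index (`gene_id` -> transcript ids).
#' @export
transcript_set <- function(transcripts) {
  stopifnot(length(transcripts) > 0L)
  ok <- vapply(transcripts, inherits, logical(1L), "transcript_model")
  if (!all(ok)) stop("all elements must be transcript_model objects")
  ids <- vapply(transcripts, `[[`, character(1L), "transcript_id")
  if (anyDuplicated(ids)) stop("duplicate transcript_id: ",
                               ids[duplicated(ids)][1L])
  names(transcripts) <- ids
  genes <- vapply(transcripts, `[[`, character(1L), "gene_id")
  structure(list(transcripts = transcripts,
                 gene_index = split(ids, genes)),
            class = "transcript_set")
}

#' @export
length.transcript_set <- function(x) length(x$transcripts)

#' @export
print.transcript_set <- function(x, ...) {
  cat(sprintf("<transcript_set> %d transcript(s), %d gene(s)\n",
              length(x$transcripts), length(x$gene_index)))
  invisible(x)
}

#' Look up one transcript of a set
#' @param ts A `transcript_set`.
#' @param transcript_id Transcript identifier.
#' @export
get_transcript <- function(ts, transcript_id) {
  t <- ts$transcripts[[transcript_id]]
  if (is.null(t)) stop("unknown transcript: ", transcript_id)
  t
}

#' Keep the longest transcript of each gene
#'
#' Standard pre-filter for transcriptome-space CLIP quantification: each gene
#' is represented by its longest isoform so per-gene read counts are not
#' split across isoforms. Length ties are broken toward the lexicographically
#' smallest transcript_id for reproducibility. Idempotent.
#'
#' @param ts A `transcript_set`.
#' @return A `transcript_set` with exactly one transcript per gene.
#' @export
select_longest_per_gene <- function(ts) {
  stopifnot(inherits(ts, "transcript_set"))
  keep <- vapply(ts$gene_index, function(tids) {
    tids <- sort(tids)
    lens <- vapply(ts$transcripts[tids], `[[`, integer(1L), "length")
    tids[which.max(lens)]            # first max after sorting = smallest id
  }, character(1L))
  transcript_set(ts$transcripts[sort(unname(keep))])
}

#' Map transcript positions to features
#'
#' Classifies each position of a transcript as 5'UTR, CDS or 3'UTR (plain
#' "exon" for non-coding transcripts) and reports the 1-based index of the
#' exon containing it. CDS bounds are half-open, so `pos == cds_end` is
#' already 3'UTR.
#'
#' @param t A `transcript_model`.
#' @param pos Integer vector of transcript coordinates, `0 <= pos < length`.
#' @return `data.frame` with columns `position`, `feature`
#'   (one of `"5UTR"`, `"CDS"`, `"3UTR"`, `"exon"`) and `exon` (1-based index).
#' @export
feature_of_position <- function(t, pos) {
  stopifnot(inherits(t, "transcript_model"))
  pos <- as.integer(pos)
  if (length(pos) && (min(pos) < 0L || max(pos) >= t$length))
    stop("position out of range [0, ", t$length, ") on ", t$transcript_id)
  exon <- findInterval(pos, t$exon_bounds[, "start"])
  feature <- if (t$cds_start == t$length && t$cds_end == t$length) {
    rep("exon", length(pos))
  } else {
    ifelse(pos < t$cds_start, "5UTR", ifelse(pos >= t$cds_end, "3UTR", "CDS"))
  }
  data.frame(position = pos, feature = feature, exon = exon)
}

#' Tabulate tag locations by transcript feature
#'
#' Summarises where crosslink tags fall within the transcriptome: 5'UTR,
#' CDS-exon (coding sequence, plus all positions of non-coding transcripts)
#' or 3'UTR. Counts are integers summing to the tag count; fractions sum to 1.
#' An empty tag table yields an empty (0-row) table rather than an error so
#' sparse conditions do not abort a pipeline.
#'
#' @param tags `data.frame` with columns `transcript_id` and `position`.
#' @param ts A `transcript_set` covering every tag's transcript.
#' @return `data.frame` with columns `category`, `count`, `fraction`.
#' @export
classify_tag_locations <- function(tags, ts) {
  stopifnot(inherits(ts, "transcript_set"))
  categories <- c("5UTR", "CDS-exon", "3UTR")
  if (nrow(tags) == 0L)
    return(data.frame(category = character(), count = integer(),
                      fraction = numeric()))
  unknown <- setdiff(unique(tags$transcript_id), names(ts$transcripts))
  if (length(unknown)) stop("tag references unknown transcript: ", unknown[1L])
  feat <- character(nrow(tags))
  for (tid in unique(tags$transcript_id)) {
    i <- tags$transcript_id == tid
    feat[i] <- feature_of_position(get_transcript(ts, tid), tags$position[i])$feature
  }
  cat3 <- ifelse(feat == "5UTR", "5UTR", ifelse(feat == "3UTR", "3UTR", "CDS-exon"))
  count <- vapply(categories, function(k) sum(cat3 == k), integer(1L))
  data.frame(category = categories, count = unname(count),
             fraction = unname(count) / nrow(tags))
}

#' Write a tag-location feature table as TSV
#' @param tab Output of [classify_tag_locations()].
#' @param path Output file.
#' @export
write_feature_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
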