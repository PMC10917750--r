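#' Read a transcript-space annotation (GTF + FASTA)
#'
#' The annotation lives in transcript coordinates: the GTF seqname of every
#' row is a transcript_id, `exon` rows tile the transcript, `CDS` rows (if
#' any) give the coding interval, and the FASTA provides one sequence per
#' transcript keyed by transcript_id. GTF coordinates are 1-based closed as
#' usual and are converted to the package's 0-based half-open convention.
#'
#' Every annotated transcript must have a sequence; a missing sequence is a
#' hard error naming the transcript. Lines that are not 9-field GTF rows are
#' rejected with their line number.
#'
#' @param gtf_path Path to the GTF file (`exon` and `CDS` features with
#'   `transcript_id`, `gene_id` and optionally `gene_name` attributes).
#' @param fasta_path Path to the transcript FASTA.
#' @return A `transcript_set`.
#' @export
load_annotation <- function(gtf_path, fasta_path) {
  lines <- readLines(gtf_path)
  body <- !grepl("^#", lines) & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9L))
    stop("malformed GTF line ", which(body)[nf != 9L][1L], " in ", gtf_path,
         ": expected 9 tab-separated fields")
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))

  md <- S4Vectors::mcols(gr)
  tids <- as.character(GenomicRanges::seqnames(gr))
  models <- lapply(split(seq_along(gr), tids), function(i) {
    tid <- tids[i[1L]]
    type <- as.character(md$type[i])
    ex <- i[type == "exon"]
    if (!length(ex)) stop("transcript '", tid, "' has no exon rows")
    starts <- GenomicRanges::start(gr)[ex] - 1L       # to 0-based half-open
    ends <- GenomicRanges::end(gr)[ex]
    o <- order(starts)
    bounds <- cbind(start = starts[o], end = ends[o])
    len <- bounds[nrow(bounds), "end"]
    cds <- i[type == "CDS"]
    if (length(cds)) {
      cs <- min(GenomicRanges::start(gr)[cds]) - 1L
      ce <- max(GenomicRanges::end(gr)[cds])
    } else {
      cs <- ce <- len
    }
    gid <- as.character(md$gene_id[i[1L]])
    gname <- if (!is.null(md$gene_name)) as.character(md$gene_name[i[1L]]) else gid
    if (is.na(gname)) gname <- gid
    if (is.na(match(tid, names(seqs))))
      stop("no sequence for annotated transcript '", tid, "' in ", fasta_path)
    transcript_model(tid, gid, gname, bounds, cs, ce,
                     as.character(seqs[[tid]]))
  })
  transcript_set(models)
}

#' Write a transcript set as GTF + FASTA
#'
#' Inverse of [load_annotation()]: emits one `exon` row per exon and one
#' `CDS` row per coding transcript, all in transcript coordinates, plus a
#' FASTA of the sequences.
#'
#' @param ts A `transcript_set`.
#' @param gtf_path,fasta_path Output paths.
#' @export
write_annotation <- function(ts, gtf_path, fasta_path) {
  stopifnot(inherits(ts, "transcript_set"))
  rows <- lapply(ts$transcripts, function(t) {
    ex <- GenomicRanges::GRanges(
      seqnames = t$transcript_id,
      ranges = IRanges::IRanges(start = t$exon_bounds[, "start"] + 1L,
                                end = t$exon_bounds[, "end"]),
      strand = "+", type = "exon", phase = NA_integer_)
    if (t$cds_start < t$length) {
      cds <- GenomicRanges::GRanges(
        seqnames = t$transcript_id,
        ranges = IRanges::IRanges(start = t$cds_start + 1L, end = t$cds_end),
        strand = "+", type = "CDS", phase = 0L)
      ex <- c(ex, cds)
    }
    S4Vectors::mcols(ex)$source <- "spongeclip"
    S4Vectors::mcols(ex)$transcript_id <- t$transcript_id
    S4Vectors::mcols(ex)$gene_id <- t$gene_id
    S4Vectors::mcols(ex)$gene_name <- t$gene_name
    ex
  })
  gr <- suppressWarnings(do.call(c, unname(rows)))
  rtracklayer::export(gr, gtf_path, format = "gtf")
  seqs <- Biostrings::DNAStringSet(
    vapply(ts$transcripts, `[[`, character(1L), "sequence"))
  names(seqs) <- names(ts$transcripts)
  Biostrings::writeXStringSet(seqs, fasta_path)
  invisible(c(gtf = gtf_path, fasta = fasta_path))
}

#' Write iCLIP tags as a 6-column BED dialect
#'
#' One row per tag: `transcript_id  start  end  tag_id  1  +`, with
#' `start` the truncation position and `end = start + 1`. The tag_id encodes
#' condition and replicate (`<condition>.rep<k>.<n>`) so the table
#' round-trips through [read_tag_bed()].
#'
#' @param tags Tag `data.frame` (`transcript_id`, `position`, `condition`,
#'   `replicate`).
#' @param path Output file.
#' @export
write_tag_bed <- function(tags, path) {
  id <- sprintf("%s.rep%d.%d", tags$condition, tags$replicate,
                seq_len(nrow(tags)))
  bed <- data.frame(tags$transcript_id, tags$position, tags$position + 1L,
                    id, 1L, "+")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read iCLIP tags from the 6-column BED dialect written by [write_tag_bed()]
#' @param path BED file.
#' @return Tag `data.frame` with `transcript_id`, `position`, `condition`,
#'   `replicate`.
#' @export
read_tag_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("transcript_id", "start", "end",
                                         "name", "score", "strand"),
                           colClasses = c("character", "integer", "integer",
                                          "character", "integer", "character"))
  parts <- strsplit(bed$name, ".", fixed = TRUE)
  data.frame(transcript_id = bed$transcript_id,
             position = bed$start,
             condition = vapply(parts, `[`, character(1L), 1L),
             replicate = as.integer(sub("^rep", "",
                                        vapply(parts, `[`, character(1L), 2L))))
}
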