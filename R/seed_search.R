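#' Seed-match pattern of a mature miRNA
#'
#' The seed is the mature-miRNA substring at positions `seed_span[1]` to
#' `seed_span[2]` (1-based, inclusive; default 2-8, a 7-mer). The pattern a
#' target transcript presents to the RISC is its reverse complement in DNA
#' alphabet (U pairs as A), so scanning transcript sequences for this
#' pattern finds canonical miRNA-response elements.
#'
#' @param mature Mature miRNA sequence, RNA or DNA alphabet, case
#'   insensitive.
#' @param seed_span Length-2 integer vector, default `c(2, 8)`.
#' @return DNA match pattern (character).
#' @export
seed_match_pattern <- function(mature, seed_span = c(2L, 8L)) {
  rna <- chartr("Tt", "Uu", toupper(mature))
  seed <- substr(rna, seed_span[1L], seed_span[2L])
  dna <- Biostrings::DNAString(chartr("U", "T", seed))
  as.character(Biostrings::reverseComplement(dna))
}

#' Build seed records from mature miRNA sequences
#'
#' One record per mature miRNA: normalised RNA sequence, seed, and the DNA
#' match pattern ([seed_match_pattern()]). Sequences shorter than 8 nt are
#' skipped with a warning (they cannot carry a positions-2-8 seed).
#' Duplicate seeds across miRNAs are kept as distinct records, since miRNA
#' families share seeds.
#'
#' @param names miRNA names.
#' @param sequences Mature sequences (RNA or DNA alphabet).
#' @param seed_span See [seed_match_pattern()].
#' @return `data.frame` with columns `mirna_name`, `mature_sequence`,
#'   `seed`, `match_pattern`.
#' @export
mirna_seed_records <- function(names, sequences, seed_span = c(2L, 8L)) {
  stopifnot(length(names) == length(sequences),
            length(seed_span) == 2L, seed_span[1L] >= 1L,
            seed_span[2L] >= seed_span[1L])
  sequences <- unname(chartr("Tt", "Uu", toupper(sequences)))
  names <- unname(names)
  short <- nchar(sequences) < 8L
  if (any(short)) {
    warning(sum(short), " mature sequence(s) shorter than 8 nt skipped: ",
            paste(names[short], collapse = ", "))
    names <- names[!short]; sequences <- sequences[!short]
  }
  data.frame(mirna_name = as.character(names),
             mature_sequence = sequences,
             seed = substr(sequences, seed_span[1L], seed_span[2L]),
             match_pattern = vapply(sequences, seed_match_pattern,
                                    character(1L), seed_span = seed_span,
                                    USE.NAMES = FALSE))
}

#' Load mature miRNAs from FASTA or TSV
#'
#' Accepts a miRBase-style FASTA of mature sequences (ids = miRNA names) or
#' a two-column TSV `name<TAB>mature_sequence` (no header). Format is
#' detected from the first character of the file.
#'
#' @param path Input file.
#' @param seed_span See [seed_match_pattern()].
#' @return Seed records as from [mirna_seed_records()].
#' @export
load_mirnas <- function(path, seed_span = c(2L, 8L)) {
  first <- readChar(path, 1L)
  if (identical(first, ">")) {
    seqs <- Biostrings::readBStringSet(path)
    nms <- sub("\\s.*$", "", names(seqs))
    mirna_seed_records(nms, as.character(seqs), seed_span)
  } else {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             col.names = c("name", "mature"),
                             colClasses = "character")
    mirna_seed_records(tab$name, tab$mature, seed_span)
  }
}

#' Restrict seed records to expressed miRNAs
#'
#' Keeps records whose name is in the user-supplied expressed list
#' (typically taken from an expression atlas of the cell line under study).
#' An empty intersection is a warning, not an error.
#'
#' @param records Seed records.
#' @param expressed Character vector of expressed miRNA names.
#' @return Filtered seed records.
#' @export
filter_expressed_mirnas <- function(records, expressed) {
  out <- records[records$mirna_name %in% expressed, , drop = FALSE]
  if (nrow(out) == 0L)
    warning("no seed record matches the expressed miRNA list")
  rownames(out) <- NULL
  out
}

#' Exact scan of DNA targets for seed-match patterns
#'
#' Reports every exact occurrence of every record's match pattern in every
#' target, including overlapping occurrences and multiple patterns at one
#' position. `max_mismatch > 0` relaxes to Hamming-distance matching.
#' Output order is deterministic: target (input order), position, miRNA
#' name.
#'
#' @param records Seed records from [mirna_seed_records()].
#' @param targets Named character vector (or `DNAStringSet`) of DNA targets.
#' @param max_mismatch Allowed mismatches (default 0: exact).
#' @return `data.frame` with columns `target`, `position` (0-based start)
#'   and `mirna_name`.
#' @export
scan_sequences <- function(records, targets, max_mismatch = 0L) {
  if (!methods::is(targets, "DNAStringSet"))
    targets <- Biostrings::DNAStringSet(targets)
  if (is.null(names(targets))) stop("targets must be named")
  hits <- list()
  for (i in seq_len(nrow(records))) {
    mi <- Biostrings::vmatchPattern(records$match_pattern[i], targets,
                                    max.mismatch = max_mismatch)
    starts <- Biostrings::startIndex(mi)
    for (j in seq_along(targets)) {
      st <- starts[[j]]
      if (length(st))
        hits[[length(hits) + 1L]] <-
          data.frame(target = names(targets)[j], position = st - 1L,
                     mirna_name = records$mirna_name[i])
    }
  }
  if (!length(hits))
    return(data.frame(target = character(), position = integer(),
                      mirna_name = character()))
  out <- do.call(rbind, hits)
  out <- out[order(match(out$target, names(targets)), out$position,
                   out$mirna_name), ]
  rownames(out) <- NULL
  out
}

.feature_label <- function(feature, exon) {
  ifelse(feature == "5UTR", "5'UTR",
         ifelse(feature == "3UTR", "3'UTR", paste0("Exon ", exon)))
}

#' Scan binding regions for seed matches, in transcript coordinates
#'
#' Extracts the region sequences, scans them, and reports each match at its
#' transcript coordinate with the feature containing the match start
#' (a match straddling a feature boundary is labelled by its start and not
#' split). A match inside two overlapping regions is reported once per
#' region (distinct `region_id`).
#'
#' @param records Seed records.
#' @param regions Region `data.frame`.
#' @param ts A `transcript_set`.
#' @param max_mismatch Allowed mismatches (default 0).
#' @return SeedMatch `data.frame`: `mirna_name`, `transcript_id`,
#'   `position`, `feature`, `exon`, `feature_label`, `region_id`.
#' @export
scan_regions <- function(records, regions, ts, max_mismatch = 0L) {
  seqs <- extract_region_sequences(regions, ts)
  empty <- data.frame(mirna_name = character(), transcript_id = character(),
                      position = integer(), feature = character(),
                      exon = integer(), feature_label = character(),
                      region_id = character())
  if (!length(seqs) || nrow(records) == 0L) return(empty)
  # duplicate region coordinates get distinct ids via the row index
  ids <- sprintf("%s#%d", names(seqs), seq_along(seqs))
  names(seqs) <- ids
  hits <- scan_sequences(records, seqs, max_mismatch)
  if (!nrow(hits)) return(empty)
  ri <- as.integer(sub("^.*#", "", hits$target))
  tid <- regions$transcript_id[ri]
  pos <- regions$start[ri] + hits$position
  feats <- do.call(rbind, lapply(seq_along(tid), function(k)
    feature_of_position(get_transcript(ts, tid[k]), pos[k])))
  out <- data.frame(mirna_name = hits$mirna_name, transcript_id = tid,
                    position = pos, feature = feats$feature,
                    exon = feats$exon,
                    feature_label = .feature_label(feats$feature, feats$exon),
                    region_id = sub("#[0-9]+$", "", hits$target))
  out[order(out$transcript_id, out$position, out$mirna_name), ]
}

#' Scan whole transcripts for seed matches
#'
#' Like [scan_regions()] but over full transcript sequences; `region_id` is
#' `NA`.
#'
#' @inheritParams scan_regions
#' @export
scan_transcripts <- function(records, ts, max_mismatch = 0L) {
  seqs <- vapply(ts$transcripts, `[[`, character(1L), "sequence")
  hits <- scan_sequences(records, seqs, max_mismatch)
  if (!nrow(hits))
    return(data.frame(mirna_name = character(), transcript_id = character(),
                      position = integer(), feature = character(),
                      exon = integer(), feature_label = character(),
                      region_id = character()))
  feats <- do.call(rbind, lapply(seq_len(nrow(hits)), function(k)
    feature_of_position(get_transcript(ts, hits$target[k]),
                        hits$position[k])))
  data.frame(mirna_name = hits$mirna_name, transcript_id = hits$target,
             position = hits$position, feature = feats$feature,
             exon = feats$exon,
             feature_label = .feature_label(feats$feature, feats$exon),
             region_id = NA_character_)
}

#' Aggregate seed matches into a per-miRNA feature report
#'
#' Per miRNA and transcript, collapses match locations into a readable
#' summary such as `Exon 3 (1), 3'UTR (2)`: feature labels ordered 5'UTR,
#' exons ascending, 3'UTR, each with its multiplicity (the count is omitted
#' when a miRNA has a single match on the transcript).
#'
#' @param matches SeedMatch `data.frame` from [scan_regions()] or
#'   [scan_transcripts()].
#' @param ts A `transcript_set`.
#' @return `data.frame` with columns `mirna_name`, `transcript_id`,
#'   `gene_id`, `n_matches`, `locations`.
#' @export
map_matches_to_features <- function(matches, ts) {
  stopifnot(inherits(ts, "transcript_set"))
  empty <- data.frame(mirna_name = character(), transcript_id = character(),
                      gene_id = character(), n_matches = integer(),
                      locations = character())
  if (nrow(matches) == 0L) return(empty)
  # distinct sites only: a match listed under two overlapping regions is one site
  key <- unique(matches[c("mirna_name", "transcript_id", "position",
                          "feature", "exon", "feature_label")])
  groups <- split(key, list(key$mirna_name, key$transcript_id), drop = TRUE)
  rows <- lapply(groups, function(g) {
    ord <- order(ifelse(g$feature == "5UTR", -1L,
                        ifelse(g$feature == "3UTR", .Machine$integer.max,
                               g$exon)))
    g <- g[ord, ]
    lab <- rle(g$feature_label)
    locations <- if (nrow(g) == 1L) g$feature_label
    else paste(sprintf("%s (%d)", lab$values, lab$lengths), collapse = ", ")
    data.frame(mirna_name = g$mirna_name[1L],
               transcript_id = g$transcript_id[1L],
               gene_id = get_transcript(ts, g$transcript_id[1L])$gene_id,
               n_matches = nrow(g), locations = locations)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mirna_name, out$transcript_id), ]
  rownames(out) <- NULL
  out
}

#' Rank transcripts by seed-match density per kilobase
#'
#' Density = distinct matches on the transcript / (transcript length /
#' 1000). Matches listed under several overlapping regions count once
#' (distinct miRNA x position). All transcripts of the set are reported,
#' zero-density last; ties broken by gene_id.
#'
#' @param matches SeedMatch `data.frame`.
#' @param ts A `transcript_set`.
#' @param mirnas Optional character vector restricting to a miRNA subset.
#' @return `data.frame` with `transcript_id`, `gene_id`, `length`,
#'   `n_matches`, `density_per_kb`, `rank`, descending by density.
#' @export
seed_density_per_kb <- function(matches, ts, mirnas = NULL) {
  stopifnot(inherits(ts, "transcript_set"))
  if (!is.null(mirnas)) matches <- matches[matches$mirna_name %in% mirnas, ]
  key <- unique(matches[c("mirna_name", "transcript_id", "position")])
  tids <- names(ts$transcripts)
  n <- vapply(tids, function(tid) sum(key$transcript_id == tid), integer(1L))
  lens <- vapply(ts$transcripts, `[[`, integer(1L), "length")
  gids <- vapply(ts$transcripts, `[[`, character(1L), "gene_id")
  out <- data.frame(transcript_id = tids, gene_id = unname(gids),
                    length = unname(lens), n_matches = unname(n),
                    density_per_kb = unname(n / (lens / 1000)))
  out <- out[order(-out$density_per_kb, out$gene_id), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
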