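# Fixture builders shared across test files. All random fixtures are drawn
# under the caller's seed (tests set their own).

rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# a 3-exon coding transcript with known feature layout:
#   exons [0,100) [100,250) [250,400); 5'UTR [0,50), CDS [50,300), 3'UTR [300,400)
toy_transcript <- function(id = "tx1", gene = "gA", seq = NULL) {
  transcript_model(id, gene,
                   exon_bounds = cbind(c(0L, 100L, 250L),
                                       c(100L, 250L, 400L)),
                   cds_start = 50L, cds_end = 300L,
                   sequence = if (is.null(seq)) strrep("ACGT", 100L) else seq)
}

rand_transcript <- function(id, gene, len = sample(200:800, 1L)) {
  n_ex <- sample(1:5, 1L)
  edges <- c(0L, sort(sample(seq_len(len - 1L), n_ex - 1L)), len)
  cs <- sample(0:(len - 2L), 1L)
  ce <- sample((cs + 1L):len, 1L)
  transcript_model(id, gene,
                   exon_bounds = cbind(edges[-length(edges)], edges[-1L]),
                   cds_start = cs, cds_end = ce, sequence = rand_dna(len))
}

# tag table constructor
tag_df <- function(transcript_id, position, condition = "control",
                   replicate = 1L) {
  n <- max(length(transcript_id), length(position))
  data.frame(transcript_id = rep(transcript_id, length.out = n),
             position = as.integer(position),
             condition = rep(condition, length.out = n),
             replicate = rep(as.integer(replicate), length.out = n))
}

# brute-force site caller implementing the documented rule directly,
# independent of the package implementation
oracle_call_sites <- function(pileup, min_count, d) {
  n <- length(pileup)
  hits <- integer()
  for (p in seq_len(n)) {
    if (pileup[p] < min_count) next
    ok <- TRUE
    for (q in max(1L, p - d):min(n, p + d)) {
      if (q == p) next
      if (pileup[q] > pileup[p] || (pileup[q] == pileup[p] && q < p)) {
        ok <- FALSE
        break
      }
    }
    if (ok) hits <- c(hits, p - 1L)
  }
  data.frame(position = hits, score = pileup[hits + 1L])
}

# naive sliding-window exact pattern scan (overlapping occurrences)
oracle_scan <- function(pattern, target) {
  w <- nchar(pattern)
  hits <- integer()
  if (nchar(target) >= w)
    for (i in 0:(nchar(target) - w))
      if (substr(target, i + 1L, i + w) == pattern) hits <- c(hits, i)
  hits
}

small_sim_config <- function(...) {
  simulation_config(n_genes = 6L, length_range = c(400L, 900L), ...)
}
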