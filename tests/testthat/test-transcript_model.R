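test_that("transcript_model enforces its invariants", {
  t <- toy_transcript()
  expect_s3_class(t, "transcript_model")
  expect_identical(t$length, 400L)
  # exon tiling violations
  expect_error(transcript_model("x", "g", exon_bounds = cbind(0L, 0L),
                                cds_start = 0L, cds_end = 0L, sequence = ""),
               "empty or inverted")
  expect_error(transcript_model("x", "g",
                                exon_bounds = cbind(c(0L, 120L), c(100L, 200L)),
                                cds_start = 200L, cds_end = 200L,
                                sequence = strrep("A", 200L)),
               "tile")
  expect_error(transcript_model("x", "g", exon_bounds = cbind(0L, 10L),
                                cds_start = 0L, cds_end = 5L,
                                sequence = "ACGT"),
               "sequence length")
  expect_error(transcript_model("x", "g", exon_bounds = cbind(0L, 10L),
                                cds_start = 8L, cds_end = 4L,
                                sequence = strrep("A", 10L)),
               "CDS")
})

test_that("longest-isoform selection keeps the maximal isoform, ties to smallest id", {
  mk <- function(id, gene, len)
    transcript_model(id, gene, exon_bounds = cbind(0L, len),
                     cds_start = len, cds_end = len,
                     sequence = strrep("A", len))
  ts <- transcript_set(list(mk("tA1", "gA", 500L), mk("tA2", "gA", 800L),
                            mk("tB2", "gB", 300L), mk("tB1", "gB", 300L)))
  out <- select_longest_per_gene(ts)
  expect_identical(sort(names(out$transcripts)), c("tA2", "tB1"))
  expect_identical(out$transcripts$tA2$length, 800L)
})

test_that("longest-isoform selection agrees with brute-force max and is idempotent", {
  set.seed(41)
  for (rep in 1:20) {
    n_genes <- sample(2:5, 1L)
    models <- list()
    for (g in seq_len(n_genes)) {
      for (i in seq_len(sample(1:4, 1L))) {
        len <- sample(100:900, 1L)
        id <- sprintf("g%d_t%d", g, i)
        models[[id]] <- transcript_model(id, paste0("g", g),
                                         exon_bounds = cbind(0L, len),
                                         cds_start = len, cds_end = len,
                                         sequence = strrep("A", len))
      }
    }
    ts <- transcript_set(models)
    out <- select_longest_per_gene(ts)
    # brute force: per gene, max length, then smallest id among maxima
    lens <- vapply(models, `[[`, integer(1L), "length")
    genes <- vapply(models, `[[`, character(1L), "gene_id")
    expected <- vapply(split(names(models), genes), function(ids) {
      mx <- max(lens[ids])
      min(ids[lens[ids] == mx])
    }, character(1L))
    expect_setequal(names(out$transcripts), unname(expected))
    expect_identical(names(select_longest_per_gene(out)$transcripts),
                     names(out$transcripts))
  }
})

test_that("feature_of_position labels boundaries per the half-open convention", {
  t <- toy_transcript()   # 5'UTR [0,50), CDS [50,300), 3'UTR [300,400)
  expect_identical(feature_of_position(t, 0L)$feature, "5UTR")
  expect_identical(feature_of_position(t, 0L)$exon, 1L)
  expect_identical(feature_of_position(t, 49L)$feature, "5UTR")
  expect_identical(feature_of_position(t, 50L)$feature, "CDS")
  expect_identical(feature_of_position(t, 299L)$feature, "CDS")
  expect_identical(feature_of_position(t, 300L)$feature, "3UTR")  # pos == cds_end
  expect_identical(feature_of_position(t, 250L)$exon, 3L)
  expect_error(feature_of_position(t, 400L), "out of range")
  expect_error(feature_of_position(t, -1L), "out of range")
})

test_that("feature_of_position partitions every transcript exactly", {
  t <- toy_transcript()
  fo <- feature_of_position(t, 0:(t$length - 1L))
  expect_identical(as.integer(table(fo$feature)[c("5UTR", "CDS", "3UTR")]),
                   c(50L, 250L, 100L))
  expect_identical(as.integer(table(fo$exon)), c(100L, 150L, 150L))
  # non-coding sentinel: everything is plain exon
  nc <- transcript_model("nc1", "gN", exon_bounds = cbind(c(0L, 30L), c(30L, 90L)),
                         cds_start = 90L, cds_end = 90L,
                         sequence = strrep("G", 90L))
  expect_true(all(feature_of_position(nc, 0:89)$feature == "exon"))
  # random transcripts: feature lengths always sum to transcript length
  set.seed(7)
  for (i in 1:10) {
    t <- rand_transcript(paste0("r", i), "gR")
    fo <- feature_of_position(t, 0:(t$length - 1L))
    expect_identical(nrow(fo), t$length)
    expect_identical(sum(table(fo$feature)), as.integer(t$length))
  }
})

test_that("classify_tag_locations recovers planted fractions and is order-invariant", {
  t <- toy_transcript()
  ts <- transcript_set(list(t))
  # all tags in the 3'UTR
  tags <- tag_df("tx1", 300:399)
  tab <- classify_tag_locations(tags, ts)
  expect_equal(tab$fraction[tab$category == "3UTR"], 1.0)
  expect_identical(sum(tab$count), 100L)
  # empty tag set -> empty table, not an error
  expect_identical(nrow(classify_tag_locations(tag_df(character(), integer()), ts)), 0L)
  # unknown transcript -> error
  expect_error(classify_tag_locations(tag_df("nope", 1L), ts), "unknown")
  # planted fractions 0.2 / 0.5 / 0.3 at n = 10,000 recovered within
  # binomial sampling error (5 sigma)
  set.seed(99)
  n <- 10000L
  pool <- list(`5UTR` = 0:49, `CDS-exon` = 50:299, `3UTR` = 300:399)
  draws <- sample(names(pool), n, replace = TRUE, prob = c(0.2, 0.5, 0.3))
  tags <- tag_df("tx1", vapply(draws, function(k) sample(pool[[k]], 1L),
                               integer(1L)))
  tab <- classify_tag_locations(tags, ts)
  expect_equal(sum(tab$fraction), 1, tolerance = 1e-9)
  expect_lt(abs(tab$fraction[tab$category == "5UTR"] - 0.2),
            5 * sqrt(0.2 * 0.8 / n))
  expect_lt(abs(tab$fraction[tab$category == "CDS-exon"] - 0.5),
            5 * sqrt(0.5 * 0.5 / n))
  expect_lt(abs(tab$fraction[tab$category == "3UTR"] - 0.3),
            5 * sqrt(0.3 * 0.7 / n))
  # permutation invariance
  perm <- sample(nrow(tags))
  expect_identical(classify_tag_locations(tags[perm, ], ts), tab)
})

test_that("annotation round-trips through GTF + FASTA", {
  set.seed(11)
  models <- list(toy_transcript("tx1", "gA", rand_dna(400L)),
                 rand_transcript("tx2", "gB"),
                 transcript_model("tx3", "gC",
                                  exon_bounds = cbind(0L, 120L),
                                  cds_start = 120L, cds_end = 120L,
                                  sequence = rand_dna(120L)))
  ts <- transcript_set(models)
  gtf <- withr::local_tempfile(fileext = ".gtf")
  fa <- withr::local_tempfile(fileext = ".fa")
  write_annotation(ts, gtf, fa)
  back <- load_annotation(gtf, fa)
  expect_identical(length(back), 3L)
  for (id in names(ts$transcripts)) {
    a <- ts$transcripts[[id]]; b <- back$transcripts[[id]]
    expect_identical(b$gene_id, a$gene_id)
    expect_identical(unname(b$exon_bounds), unname(a$exon_bounds))
    expect_identical(b$cds_start, a$cds_start)
    expect_identical(b$cds_end, a$cds_end)
    expect_identical(b$sequence, a$sequence)
  }
})

test_that("load_annotation rejects missing sequences and malformed GTF", {
  ts <- transcript_set(list(toy_transcript("tx1", "gA", rand_dna(400L))))
  gtf <- withr::local_tempfile(fileext = ".gtf")
  fa <- withr::local_tempfile(fileext = ".fa")
  write_annotation(ts, gtf, fa)
  # FASTA with the wrong id
  writeLines(c(">other", strrep("A", 400L)), fa)
  expect_error(load_annotation(gtf, fa), "tx1")
  # malformed line reported with its line number
  lines <- readLines(gtf)
  lines[2] <- "not a gtf line"
  writeLines(lines, gtf)
  expect_error(load_annotation(gtf, fa), "line 2")
})
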