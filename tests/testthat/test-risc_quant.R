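test_that("tag counting in regions is half-open and deduplicated per gene", {
  t <- toy_transcript("tx1", "gA")
  ts <- transcript_set(list(t))
  regions <- data.frame(transcript_id = "tx1", start = c(100L, 110L),
                        end = c(140L, 150L), center_site = c(120L, 130L),
                        condition = "x")
  # 5 tags inside, 3 outside
  tags <- tag_df("tx1", c(100L, 120L, 139L, 149L, 115L, 10L, 200L, 399L))
  cnt <- count_tags_in_regions(tags, regions, ts)
  expect_identical(cnt$count[cnt$gene_id == "gA"], 5L)
  # tag exactly at a region end is outside
  expect_identical(count_tags_in_regions(tag_df("tx1", 150L), regions, ts)$count,
                   0L)
  expect_identical(count_tags_in_regions(tag_df("tx1", 149L), regions, ts)$count,
                   1L)
  # a tag inside two overlapping regions of the gene counts once
  expect_identical(count_tags_in_regions(tag_df("tx1", 120L), regions, ts)$count,
                   1L)
})

test_that("tag counting agrees with the brute-force membership test", {
  set.seed(53)
  t1 <- toy_transcript("tx1", "gA")
  t2 <- toy_transcript("tx2", "gB")
  ts <- transcript_set(list(t1, t2))
  for (i in 1:120) {
    n_r <- sample(1:6, 1L)
    s <- sample(0:360, n_r, TRUE)
    regions <- data.frame(transcript_id = sample(c("tx1", "tx2"), n_r, TRUE),
                          start = s, end = s + sample(5:40, n_r, TRUE),
                          center_site = s, condition = "x")
    regions$end <- pmin(regions$end, 400L)
    tags <- tag_df(sample(c("tx1", "tx2"), 40L, TRUE), sample(0:399, 40L, TRUE))
    got <- count_tags_in_regions(tags, regions, ts)
    for (g in c(gA = "tx1", gB = "tx2")) {
      tid <- unname(g); gid <- names(which(c(gA = "tx1", gB = "tx2") == g))[1]
      inside <- vapply(which(tags$transcript_id == tid), function(k) {
        any(regions$transcript_id == tid &
              regions$start <= tags$position[k] &
              tags$position[k] < regions$end)
      }, logical(1L))
      expect_identical(got$count[got$gene_id == gid], sum(inside))
    }
    # never exceeds the gene's total tag count
    expect_true(all(got$count <= c(sum(tags$transcript_id == "tx1"),
                                   sum(tags$transcript_id == "tx2"))))
  }
})

test_that("rpkm is definitional and scale-invariant", {
  expect_equal(rpkm(10, 1000, 1e7), 1.0)
  expect_equal(rpkm(0, 1234, 5e6), 0.0)
  expect_error(rpkm(1, 1000, 0), "total_mapped")
  set.seed(59)
  for (i in 1:50) {
    cnt <- sample(1:1000, 1); len <- sample(100:5000, 1)
    tot <- sample(1e4:1e7, 1); k <- sample(2:10, 1)
    expect_equal(rpkm(cnt * k, len, tot * k), rpkm(cnt, len, tot))
  }
})

test_that("fold enrichment reproduces self-consistent published RPKM ratios", {
  # ratios of printed (control, treated) RPKM pairs, rounded to 2 dp
  expect_equal(round(fold_enrichment(74.74, 863.58), 2), 11.55)
  expect_equal(round(fold_enrichment(64.66, 328.14), 2), 5.07)
  expect_equal(round(fold_enrichment(49.87, 153.48), 2), 3.08)
  expect_equal(fold_enrichment(3.7, 3.7), 1.0)
  # undefined at zero control: NA, not infinity
  expect_true(is.na(fold_enrichment(0, 12)))
})

test_that("ranking orders by enrichment with treated-only genes on top", {
  stats <- data.frame(gene_id = c("gA", "gB", "gC", "gD"),
                      reads_control = c(10L, 10L, 0L, 10L),
                      rpkm_control = c(2, 2, 0, 2),
                      reads_treated = c(20L, 50L, 30L, 20L),
                      rpkm_treated = c(4, 10, 6, 4),
                      enrichment = c(2, 5, NA, 2),
                      enrichment_2dp = c(2, 5, NA, 2),
                      treated_only = c(FALSE, FALSE, TRUE, FALSE),
                      sites_control = 1L, sites_treated = 1L)
  r <- rank_by_enrichment(stats)
  expect_identical(r$gene_id, c("gC", "gB", "gA", "gD"))  # tie gA < gD by id
  expect_identical(r$rank, 1:4)
  # input order irrelevant
  r2 <- rank_by_enrichment(stats[c(3, 1, 4, 2), ])
  expect_identical(r2$gene_id, r$gene_id)
})

test_that("sponge ranks first by enrichment on the default synthetic study", {
  cfg <- simulation_config(rng_seed = 61L)
  sim <- simulate_study(cfg)
  sites <- call_sites_all(sim$tags, sim$ts)
  regions <- extend_to_regions(sites, sim$ts)
  stats <- gene_risc_stats(sim$tags, sites, regions, sim$ts)
  r <- rank_by_enrichment(stats)
  expect_identical(r$gene_id[1L], cfg$sponge_gene)
  # raising sponge_enrichment never decreases the computed enrichment
  enr_at <- function(se) {
    cfg2 <- simulation_config(rng_seed = 61L, sponge_enrichment = se)
    sim2 <- simulate_study(cfg2)
    sites2 <- call_sites_all(sim2$tags, sim2$ts)
    regions2 <- extend_to_regions(sites2, sim2$ts)
    s <- gene_risc_stats(sim2$tags, sites2, regions2, sim2$ts)
    s$enrichment[s$gene_id == cfg2$sponge_gene]
  }
  e <- vapply(c(2, 5, 10), enr_at, numeric(1L))
  expect_true(all(diff(e) > 0))
})

test_that("pseudocount gives treated-only genes a finite ratio", {
  t <- toy_transcript("tx1", "gA")
  ts <- transcript_set(list(t))
  tags <- tag_df("tx1", rep(100L, 8L), condition = "tgfb4h")
  sites <- data.frame(transcript_id = "tx1", position = 100L, score = 8L,
                      condition = "tgfb4h")
  regions <- extend_to_regions(sites, ts)
  s0 <- gene_risc_stats(tags, sites, regions, ts)
  expect_true(is.na(s0$enrichment))
  expect_true(s0$treated_only)
  s1 <- gene_risc_stats(tags, sites, regions, ts, pseudocount = 1)
  expect_true(is.finite(s1$enrichment))
})

test_that("replicate concordance is high for identically parameterised replicates", {
  # two literally identical replicates correlate at exactly 1
  t <- toy_transcript("tx1", "gA")
  t2 <- toy_transcript("tx2", "gB")
  ts <- transcript_set(list(t, t2))
  tags <- rbind(tag_df(c("tx1", "tx1", "tx2"), c(1L, 2L, 3L), replicate = 1L),
                tag_df(c("tx1", "tx1", "tx2"), c(5L, 6L, 7L), replicate = 2L))
  cm <- replicate_concordance(tags, ts)$control
  expect_equal(cm["rep1", "rep2"], 1.0)
  # single replicate -> empty matrix
  expect_identical(dim(replicate_concordance(tags[tags$replicate == 1L, ],
                                             ts)$control), c(0L, 0L))
  # simulated triplicates at high depth (per-gene totals in the hundreds)
  sim <- simulate_study(simulation_config(rng_seed = 67L,
                                          background_rate = 0.1))
  cms <- replicate_concordance(sim$tags, sim$ts)
  for (cm in cms) {
    off <- cm[upper.tri(cm)]
    expect_true(all(off > 0.9))
    expect_true(all(abs(cm - t(cm)) < 1e-12))
    expect_true(all(diag(cm) == 1))
  }
})
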