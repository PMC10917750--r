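#' Configuration for the synthetic iCLIP study
#'
#' Describes a toy AGO2 iCLIP experiment with a known answer: a small
#' transcriptome in which one designated "sponge" transcript gains
#' crosslink sites and RISC-associated tags upon treatment and carries
#' planted miRNA seed-match sites, against a uniform truncation background.
#'
#' The defaults emulate the structure of a two-condition EMT induction
#' experiment profiled in triplicate: 20 genes of 1-4 kb, a 3,000-nt sponge
#' transcript with 2 crosslink sites shared between conditions and 32
#' treated-only sites (2 control vs 34 treated sites), a 10-fold
#' treated-condition tag yield on the sponge, and one planted miRNA with one
#' seed site in CDS exon 3 and two in the 3'UTR. Every non-sponge gene gets
#' `housekeeping_sites` condition-independent sites so fold enrichment is
#' defined (non-zero control signal) for the whole gene set.
#'
#' @param n_genes Number of genes (one transcript each).
#' @param length_range Min/max transcript length in nt for non-sponge genes.
#' @param sponge_gene gene_id of the designated sponge.
#' @param background_rate Expected background truncations per nt per replicate.
#' @param sponge_enrichment Multiplier on the sponge transcript's expected tag
#'   yield (background and peaks) in every non-control condition.
#' @param peak_height Expected truncation count per replicate at a planted site.
#' @param n_replicates Replicates per condition.
#' @param conditions Condition labels; the first must be `"control"`.
#' @param planted_sites Optional `data.frame(gene_id, position, condition,
#'   peak_height)` overriding the default sponge site layout.
#' @param planted_seeds Optional list of `list(name, mature, positions)`
#'   entries; seed-match patterns (reverse complement of mature positions
#'   `seed_span[1]`..`seed_span[2]`) are inserted into the sponge at
#'   `positions`.
#' @param housekeeping_sites Condition-independent sites per non-sponge gene.
#' @param seed_span Mature-miRNA positions defining the seed (1-based,
#'   inclusive); default nucleotides 2-8.
#' @param rng_seed Integer seed; the whole simulation is a deterministic
#'   function of the config.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 20L,
                              length_range = c(1000L, 4000L),
                              sponge_gene = "g001",
                              background_rate = 0.005,
                              sponge_enrichment = 10,
                              peak_height = 5,
                              n_replicates = 3L,
                              conditions = c("control", "tgfb4h"),
                              planted_sites = NULL,
                              planted_seeds = NULL,
                              housekeeping_sites = 3L,
                              seed_span = c(2L, 8L),
                              rng_seed = 1234L) {
  stopifnot(n_genes >= 1L, length(length_range) == 2L,
            length_range[1L] <= length_range[2L],
            background_rate >= 0, sponge_enrichment > 0, peak_height > 0,
            n_replicates >= 1L, length(conditions) >= 1L)
  if (conditions[1L] != "control")
    stop("the first condition must be 'control'")
  cfg <- list(n_genes = as.integer(n_genes),
              length_range = as.integer(length_range),
              sponge_gene = sponge_gene,
              background_rate = background_rate,
              sponge_enrichment = sponge_enrichment,
              peak_height = peak_height,
              n_replicates = as.integer(n_replicates),
              conditions = conditions,
              planted_sites = planted_sites,
              planted_seeds = planted_seeds,
              housekeeping_sites = as.integer(housekeeping_sites),
              seed_span = as.integer(seed_span),
              rng_seed = as.integer(rng_seed),
              # fixed sponge architecture: 8 exons, CDS [150, 2250), 3'UTR
              # [2250, 3000) -- exon 3 is [500, 900), inside the CDS
              sponge_length = 3000L,
              sponge_exons = c(0L, 200L, 500L, 900L, 1300L, 1700L, 2100L,
                               2400L, 3000L),
              sponge_cds = c(150L, 2250L))
  if (is.null(cfg$planted_sites)) cfg$planted_sites <- .default_sponge_sites(cfg)
  if (is.null(cfg$planted_seeds)) {
    cfg$planted_seeds <- list(list(name = "miR-sim-1",
                                   mature = "UAGGCAUCGUAAGCAUUGCGAU",
                                   positions = c(647L, 2327L, 2647L)))
  }
  .validate_planted(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

# Default sponge layout: sites 600 and 1500 present in every condition
# (2 control sites), plus 32 treated-only sites at 250, 330, ..., 2730
# (34 treated sites in total), all at peak_height.
.default_sponge_sites <- function(cfg) {
  shared <- c(600L, 1500L)
  treated_only <- 250L + 80L * (0:31)
  treated <- setdiff(cfg$conditions, "control")
  rows <- rbind(
    expand.grid(position = shared, condition = cfg$conditions,
                stringsAsFactors = FALSE),
    expand.grid(position = treated_only, condition = treated,
                stringsAsFactors = FALSE))
  data.frame(gene_id = cfg$sponge_gene, position = rows$position,
             condition = rows$condition, peak_height = cfg$peak_height)
}

.validate_planted <- function(cfg) {
  ps <- cfg$planted_sites
  if (any(ps$position < 0L | ps$position >= cfg$sponge_length))
    stop("planted site position outside the sponge transcript")
  if (any(ps$peak_height <= 0)) stop("planted site peak_height must be > 0")
  w <- cfg$seed_span[2L] - cfg$seed_span[1L] + 1L
  ins <- unlist(lapply(cfg$planted_seeds, `[[`, "positions"))
  if (length(ins)) {
    if (any(ins < 0L | ins + w > cfg$sponge_length))
      stop("planted seed position outside the sponge transcript")
    if (any(diff(sort(ins)) < w))
      stop("planted seed patterns overlap; cannot plant without overlap")
  }
  invisible(cfg)
}

.random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

.count_hits <- function(pattern, sequence) {
  Biostrings::countPattern(pattern, Biostrings::DNAString(sequence))
}

#' Generate a toy transcriptome with planted sponge architecture
#'
#' Draws random transcript sequences (uniform base composition), rejecting
#' any sequence containing an accidental occurrence of a planted seed-match
#' pattern (up to 1,000 attempts, then error), then inserts the planted
#' patterns into the sponge transcript at the configured positions. By
#' construction the planted patterns occur in the transcriptome exactly at
#' the ground-truth positions. Fully deterministic given `cfg$rng_seed`.
#'
#' @param cfg A [simulation_config()].
#' @return List with elements `ts` (a `transcript_set`) and `truth`, the
#'   ground truth: `sites` (planted crosslink sites per condition, including
#'   the housekeeping sites added to every non-sponge gene), `seeds`
#'   (planted seed matches with feature labels) and `expected_tags`
#'   (expected tag totals per gene and condition).
#' @export
generate_transcriptome <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$rng_seed)
  gene_ids <- sprintf("g%03d", seq_len(cfg$n_genes))
  tids <- sprintf("t%03d", seq_len(cfg$n_genes))
  if (!cfg$sponge_gene %in% gene_ids)
    stop("sponge_gene '", cfg$sponge_gene, "' not among generated gene ids")
  patterns <- vapply(cfg$planted_seeds, function(s)
    seed_match_pattern(s$mature, cfg$seed_span), character(1L))
  w <- cfg$seed_span[2L] - cfg$seed_span[1L] + 1L

  draw_clean <- function(len) {
    for (i in seq_len(1000L)) {
      s <- .random_dna(len)
      if (!length(patterns) ||
          all(vapply(patterns, .count_hits, integer(1L), sequence = s) == 0L))
        return(s)
    }
    stop("could not draw a pattern-free sequence in 1000 attempts")
  }

  models <- vector("list", cfg$n_genes)
  seed_truth <- NULL
  for (i in seq_len(cfg$n_genes)) {
    gid <- gene_ids[i]
    if (gid == cfg$sponge_gene) {
      len <- cfg$sponge_length
      bounds <- cbind(start = cfg$sponge_exons[-length(cfg$sponge_exons)],
                      end = cfg$sponge_exons[-1L])
      cs <- cfg$sponge_cds[1L]; ce <- cfg$sponge_cds[2L]
      seq <- NULL
      for (attempt in seq_len(1000L)) {
        s <- draw_clean(len)
        for (sd in cfg$planted_seeds) {
          pat <- seed_match_pattern(sd$mature, cfg$seed_span)
          for (p in sd$positions) substr(s, p + 1L, p + w) <- pat
        }
        ok <- all(mapply(function(sd) {
          pat <- seed_match_pattern(sd$mature, cfg$seed_span)
          hits <- Biostrings::start(Biostrings::matchPattern(
            pat, Biostrings::DNAString(s))) - 1L
          identical(sort(as.integer(hits)), sort(as.integer(sd$positions)))
        }, cfg$planted_seeds))
        if (ok) { seq <- s; break }
      }
      if (is.null(seq))
        stop("could not plant seed patterns without stray occurrences")
    } else {
      len <- if (cfg$length_range[1L] == cfg$length_range[2L])
        cfg$length_range[1L]
      else sample(cfg$length_range[1L]:cfg$length_range[2L], 1L)
      n_ex <- sample(2:6, 1L)
      cuts <- sort(sample(seq_len(len - 1L), n_ex - 1L))
      edges <- c(0L, cuts, len)
      bounds <- cbind(start = edges[-length(edges)], end = edges[-1L])
      cs <- as.integer(round(len * stats::runif(1L, 0.05, 0.15)))
      ce <- as.integer(round(len * stats::runif(1L, 0.70, 0.90)))
      seq <- draw_clean(len)
    }
    models[[i]] <- transcript_model(tids[i], gid, toupper(gid), bounds,
                                    cs, ce, seq)
  }
  ts <- transcript_set(models)

  sponge_tid <- tids[match(cfg$sponge_gene, gene_ids)]
  sponge <- get_transcript(ts, sponge_tid)
  if (length(cfg$planted_seeds)) {
    seed_truth <- do.call(rbind, lapply(cfg$planted_seeds, function(sd) {
      fo <- feature_of_position(sponge, sd$positions)
      data.frame(mirna_name = sd$name, transcript_id = sponge_tid,
                 position = as.integer(sd$positions), feature = fo$feature,
                 exon = fo$exon)
    }))
  } else {
    seed_truth <- data.frame(mirna_name = character(),
                             transcript_id = character(),
                             position = integer(), feature = character(),
                             exon = integer())
  }

  # ground-truth site table: configured sponge sites + housekeeping sites
  # at the length quartiles of every non-sponge gene, in every condition
  site_rows <- list(data.frame(gene_id = cfg$planted_sites$gene_id,
                               position = as.integer(cfg$planted_sites$position),
                               condition = cfg$planted_sites$condition,
                               peak_height = cfg$planted_sites$peak_height))
  k <- cfg$housekeeping_sites
  if (k > 0L) {
    for (i in seq_len(cfg$n_genes)) {
      gid <- gene_ids[i]
      if (gid == cfg$sponge_gene) next
      len <- get_transcript(ts, tids[i])$length
      pos <- as.integer(round(len * seq_len(k) / (k + 1L)))
      site_rows[[length(site_rows) + 1L]] <-
        expand.grid(gene_id = gid, position = pos,
                    condition = cfg$conditions, peak_height = cfg$peak_height,
                    stringsAsFactors = FALSE)
    }
  }
  sites <- do.call(rbind, site_rows)
  sites$transcript_id <- tids[match(sites$gene_id, gene_ids)]
  sites <- sites[order(sites$transcript_id, sites$condition, sites$position),
                 c("transcript_id", "gene_id", "position", "condition",
                   "peak_height")]
  rownames(sites) <- NULL

  expected <- do.call(rbind, lapply(cfg$conditions, function(cond) {
    mult <- ifelse(gene_ids == cfg$sponge_gene & cond != "control",
                   cfg$sponge_enrichment, 1)
    lens <- vapply(ts$transcripts[tids], `[[`, integer(1L), "length")
    peaks <- vapply(gene_ids, function(g)
      sum(sites$peak_height[sites$gene_id == g & sites$condition == cond]),
      numeric(1L))
    data.frame(gene_id = gene_ids, condition = cond,
               expected_total = cfg$n_replicates * mult *
                 (lens * cfg$background_rate + peaks))
  }))
  rownames(expected) <- NULL

  list(ts = ts,
       truth = list(sites = sites, seeds = seed_truth,
                    expected_tags = expected))
}

#' Simulate iCLIP truncation tags
#'
#' For every replicate of every condition, truncation counts at each
#' transcript position are Poisson: `background_rate` per nt, plus
#' `peak_height` at the planted sites active in that condition. The sponge
#' transcript's expected counts (background and peaks) are multiplied by
#' `sponge_enrichment` in non-control conditions. Tags are emitted
#' pre-deduplicated (UMI collapsing is upstream of this representation).
#' Deterministic given the config: uses `rng_seed + 1` so the tag draw is
#' independent of the sequence draw.
#'
#' @param ts A `transcript_set` from [generate_transcriptome()].
#' @param cfg The same [simulation_config()].
#' @param truth The ground truth returned by [generate_transcriptome()].
#' @return `data.frame` of tags: `transcript_id`, `position`, `condition`,
#'   `replicate`.
#' @export
simulate_iclip_tags <- function(ts, cfg, truth) {
  stopifnot(inherits(ts, "transcript_set"), inherits(cfg, "simulation_config"))
  set.seed(cfg$rng_seed + 1L)
  sites <- truth$sites
  out <- list()
  for (cond in cfg$conditions) {
    for (rep_i in seq_len(cfg$n_replicates)) {
      for (tid in names(ts$transcripts)) {
        t <- ts$transcripts[[tid]]
        mult <- if (t$gene_id == cfg$sponge_gene && cond != "control")
          cfg$sponge_enrichment else 1
        counts <- stats::rpois(t$length, cfg$background_rate * mult)
        s <- sites[sites$transcript_id == tid & sites$condition == cond, ]
        if (nrow(s))
          counts[s$position + 1L] <- counts[s$position + 1L] +
            stats::rpois(nrow(s), s$peak_height * mult)
        pos <- rep.int(seq_len(t$length) - 1L, counts)
        if (length(pos))
          out[[length(out) + 1L]] <-
            data.frame(transcript_id = tid, position = pos,
                       condition = cond, replicate = rep_i)
      }
    }
  }
  if (!length(out))
    return(data.frame(transcript_id = character(), position = integer(),
                      condition = character(), replicate = integer()))
  tags <- do.call(rbind, out)
  rownames(tags) <- NULL
  tags
}

#' Run the full simulation (transcriptome + tags)
#' @param cfg A [simulation_config()].
#' @return List with `ts`, `tags` and `truth`.
#' @export
simulate_study <- function(cfg) {
  gen <- generate_transcriptome(cfg)
  tags <- simulate_iclip_tags(gen$ts, cfg, gen$truth)
  list(ts = gen$ts, tags = tags, truth = gen$truth)
}

#' Write simulation ground truth as TSV files
#' @param truth Ground-truth list from [generate_transcriptome()].
#' @param dir Output directory (created if needed).
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("sites", "seeds", "expected_tags"))
    utils::write.table(truth[[nm]], file.path(dir, paste0("truth_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write a flat key-value log of a simulation config
#' @param cfg A [simulation_config()].
#' @param path Output file.
#' @export
write_config_log <- function(cfg, path) {
  flat <- cfg[!vapply(cfg, is.list, logical(1L))]
  lines <- vapply(names(flat), function(k)
    paste0(k, " = ", paste(flat[[k]], collapse = ",")), character(1L))
  writeLines(lines, path)
  invisible(path)
}
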