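#' Configuration for the synthetic transcriptome simulator
#'
#' Builds and validates the parameter set controlling
#' [simulate_transcriptome()], [inject_aberrant_isoforms()],
#' [simulate_quant()] and [simulate_rip()]. The defaults describe a small
#' two-condition (WT vs gcKO) bulk RNA-Seq study with biological
#' triplicates, multi-isoform genes, log-normal replicate noise on FPKM,
#' a set of knockout-unique isoforms carrying one insertion or deletion
#' each relative to the gene's standard form, and an IP/IgG RIP assay
#' with a designated bound target set.
#'
#' @param n_genes Number of genes.
#' @param isoforms_per_gene Integer range (lo, hi): isoforms per gene,
#'   sampled uniformly. The first isoform of each gene carries the full
#'   exon chain; additional isoforms skip one internal exon.
#' @param exon_count_range Integer range: exons per gene.
#' @param exon_length_range Integer range (bp): exon lengths.
#' @param utr5_length,utr3_length 5' and 3' UTR lengths (bp) in transcript
#'   coordinates; the CDS spans `[utr5_length, length - utr3_length)`.
#' @param n_unique_isoforms Number of genes receiving one aberrant variant
#'   isoform each (one injected splicing event per variant).
#' @param event_size_range Integer range (bp): insertion/deletion sizes.
#' @param region_weights Named probabilities over
#'   `c("FIVE_UTR", "GENE_BODY", "THREE_UTR")` for event placement; must
#'   sum to 1.
#' @param unique_condition_weights Named probabilities over the two
#'   conditions: which condition each variant is unique to.
#' @param replicates_per_condition RNA-Seq replicates per condition
#'   (at least 2, so the t-test has within-group variance).
#' @param rip_replicates Replicates per RIP assay arm (IP and IgG).
#' @param fpkm_lognormal_mu_sigma Numeric pair `(mu, sigma)`: `mu` is the
#'   meanlog of the per-gene baseline FPKM distribution and `sigma` the
#'   sdlog of the multiplicative log-normal replicate noise. `sigma = 0`
#'   gives noise-free replicate values.
#' @param absent_fpkm_max Upper bound of the uniform FPKM draw for absent
#'   transcripts (default 0.1, the absence threshold itself, so the
#'   classification boundary is exercised).
#' @param bound_fraction Fraction of non-variant transcripts designated as
#'   RIP-bound targets.
#' @param rip_enrichment_range Fold range (all > 2) of IP/IgG enrichment
#'   for true targets; non-targets are centred at fold 1.
#' @param de_fraction Fraction of genes whose standard isoform is
#'   differentially expressed between conditions.
#' @param de_fold_range Fold range for the differential-expression effect.
#' @param conditions Length-2 character vector; the first entry is the
#'   wild-type (reference) condition.
#' @param seed Integer seed; a fixed seed gives byte-identical outputs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 50,
                       isoforms_per_gene = c(1L, 3L),
                       exon_count_range = c(4L, 9L),
                       exon_length_range = c(100L, 300L),
                       utr5_length = 100L,
                       utr3_length = 150L,
                       n_unique_isoforms = 10,
                       event_size_range = c(30L, 150L),
                       region_weights = c(FIVE_UTR = 0.2, GENE_BODY = 0.6,
                                          THREE_UTR = 0.2),
                       unique_condition_weights = c(WT = 0.1, gcKO = 0.9),
                       replicates_per_condition = 3,
                       rip_replicates = 3,
                       fpkm_lognormal_mu_sigma = c(log(20), 0.2),
                       absent_fpkm_max = 0.1,
                       bound_fraction = 0.2,
                       rip_enrichment_range = c(3, 10),
                       de_fraction = 0.15,
                       de_fold_range = c(2.5, 6),
                       conditions = c("WT", "gcKO"),
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    isoforms_per_gene = as.integer(isoforms_per_gene),
    exon_count_range = as.integer(exon_count_range),
    exon_length_range = as.integer(exon_length_range),
    utr5_length = as.integer(utr5_length),
    utr3_length = as.integer(utr3_length),
    n_unique_isoforms = as.integer(n_unique_isoforms),
    event_size_range = as.integer(event_size_range),
    region_weights = region_weights,
    unique_condition_weights = unique_condition_weights,
    replicates_per_condition = as.integer(replicates_per_condition),
    rip_replicates = as.integer(rip_replicates),
    fpkm_lognormal_mu_sigma = as.numeric(fpkm_lognormal_mu_sigma),
    absent_fpkm_max = as.numeric(absent_fpkm_max),
    bound_fraction = as.numeric(bound_fraction),
    rip_enrichment_range = as.numeric(rip_enrichment_range),
    de_fraction = as.numeric(de_fraction),
    de_fold_range = as.numeric(de_fold_range),
    conditions = as.character(conditions),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  rng_ok <- function(r) length(r) == 2 && !anyNA(r) && r[1] <= r[2] && r[1] > 0
  for (f in c("isoforms_per_gene", "exon_count_range", "exon_length_range",
              "event_size_range", "rip_enrichment_range", "de_fold_range")) {
    if (!rng_ok(cfg[[f]])) abort(sprintf("%s must be a non-empty positive range", f))
  }
  if (cfg$n_genes < 1) abort("n_genes must be >= 1")
  if (!setequal(names(cfg$region_weights), REGIONS) ||
      abs(sum(cfg$region_weights) - 1) > 1e-8) {
    abort("region_weights must be named FIVE_UTR/GENE_BODY/THREE_UTR and sum to 1")
  }
  if (length(cfg$conditions) != 2 || anyDuplicated(cfg$conditions)) {
    abort("conditions must be two distinct labels (wild-type first)")
  }
  if (!setequal(names(cfg$unique_condition_weights), cfg$conditions) ||
      abs(sum(cfg$unique_condition_weights) - 1) > 1e-8) {
    abort("unique_condition_weights must be named after the conditions and sum to 1")
  }
  if (cfg$replicates_per_condition < 2) {
    abort("replicates_per_condition must be >= 2 (the t-test needs within-group variance)")
  }
  if (cfg$rip_replicates < 2) abort("rip_replicates must be >= 2")
  if (cfg$n_unique_isoforms > cfg$n_genes) {
    abort("n_unique_isoforms cannot exceed n_genes (one variant per gene)")
  }
  if (!(cfg$bound_fraction > 0 && cfg$bound_fraction < 1)) {
    abort("bound_fraction must lie in (0, 1)")
  }
  if (any(cfg$rip_enrichment_range <= 2)) {
    abort("rip_enrichment_range must be entirely above fold 2")
  }
  min_tx <- cfg$exon_count_range[1] * cfg$exon_length_range[1]
  if (cfg$utr5_length + cfg$utr3_length + 1 > (cfg$exon_count_range[1] - 1) *
        cfg$exon_length_range[1]) {
    abort("UTRs leave no CDS in the shortest possible isoform; shrink utr5_length/utr3_length")
  }
  if (cfg$event_size_range[2] >= min_tx) {
    abort(sprintf(
      "event sizes up to %d bp cannot fit in the shortest transcript (%d bp)",
      cfg$event_size_range[2], min_tx))
  }
  invisible(cfg)
}

# Per-stage derived seeds keep the exported simulators individually
# deterministic while drawing from distinct streams.
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1103L + stage * 12347L) %% 2147483587)
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

sample_range <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1)

#' Simulate a multi-isoform transcriptome
#'
#' Generates gene models and transcript sequences. Each gene gets a chain
#' of exons with random mRNA-sense sequences laid out on a single
#' simulated contig (alternating strands); its first isoform carries the
#' full chain and each additional isoform skips one internal exon, so
#' isoforms of a gene share exon blocks. Every transcript is annotated
#' with a CDS spanning `[utr5_length, length - utr3_length)` in
#' transcript coordinates.
#'
#' @param config A [sim_config()].
#' @return A list with `models` (tibble as from [read_gtf()]) and
#'   `sequences` (named [Biostrings::DNAStringSet]).
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(stage_seed(config$seed, 1L), {
    cursor <- 1000L
    rows <- list()
    seqs <- character()
    for (g in seq_len(config$n_genes)) {
      gene_id <- sprintf("G%04d", g)
      strand <- if (g %% 2 == 0) "-" else "+"
      n_ex <- sample_range(config$exon_count_range)
      ex_len <- vapply(seq_len(n_ex), function(i) sample_range(config$exon_length_range),
                       integer(1))
      introns <- vapply(seq_len(n_ex - 1), function(i) sample(200:800, 1), integer(1))
      starts <- integer(n_ex)
      pos <- cursor
      for (i in seq_len(n_ex)) {
        starts[i] <- pos
        pos <- pos + ex_len[i] + if (i < n_ex) introns[i] else 0L
      }
      # per-exon mRNA-sense sequence, indexed in genomic order
      ex_seq <- vapply(ex_len, rand_dna, character(1))
      # transcript order: genomic order on +, reversed on -
      tx_order <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))

      n_iso <- sample_range(config$isoforms_per_gene)
      skippable <- if (n_ex > 2) 2:(n_ex - 1) else integer(0)
      n_iso <- min(n_iso, 1L + length(skippable))
      skipped <- if (n_iso > 1) sample(skippable, n_iso - 1) else integer(0)

      for (k in seq_len(n_iso)) {
        keep <- if (k == 1) seq_len(n_ex) else setdiff(seq_len(n_ex), skipped[k - 1])
        keep_tx <- tx_order[tx_order %in% keep]
        exons <- tibble(start = starts[keep_tx],
                        end = starts[keep_tx] + ex_len[keep_tx])
        seq <- paste(ex_seq[keep_tx], collapse = "")
        len <- nchar(seq)
        tx_id <- sprintf("%s.T%d", gene_id, k)
        rows[[length(rows) + 1]] <- tibble(
          transcript_id = tx_id, gene_id = gene_id, seqname = "simchr",
          strand = strand, length = len,
          cds_start_tx = config$utr5_length,
          cds_end_tx = len - config$utr3_length,
          exons = list(exons)
        )
        seqs[[tx_id]] <- seq
      }
      cursor <- pos + 5000L  # reserve space for variant placements
    }
    models <- bind_rows(rows)
    list(models = models,
         sequences = Biostrings::DNAStringSet(seqs))
  })
}

# Left-normalize an indel against the standard sequence so that the
# recorded anchor is the leftmost equivalent position (the convention used
# for truth anchors and for called events alike). `floor` bounds the shift
# so normalization never slides into a preceding event.
left_normalize_event <- function(standard_seq, type, anchor, size,
                                 inserted_seq = NA_character_, floor = 0L) {
  if (type == "deletion") {
    while (anchor > floor &&
           substr(standard_seq, anchor, anchor) ==
             substr(standard_seq, anchor + size, anchor + size)) {
      anchor <- anchor - 1L
    }
  } else {
    while (anchor > floor &&
           substr(standard_seq, anchor, anchor) ==
             substr(inserted_seq, size, size)) {
      inserted_seq <- paste0(substr(standard_seq, anchor, anchor),
                             substr(inserted_seq, 1L, size - 1L))
      anchor <- anchor - 1L
    }
  }
  list(anchor = as.integer(anchor), inserted_seq = inserted_seq)
}

region_of_anchor <- function(anchor, cds_start, cds_end) {
  ifelse(anchor < cds_start, "FIVE_UTR",
         ifelse(anchor < cds_end, "GENE_BODY", "THREE_UTR"))
}

shift_cds <- function(cds_start, cds_end, type, anchor, size) {
  if (type == "insertion") {
    if (anchor < cds_start) c(cds_start + size, cds_end + size)
    else if (anchor < cds_end) c(cds_start, cds_end + size)
    else c(cds_start, cds_end)
  } else {
    map1 <- function(p) if (p <= anchor) p else p - min(p - anchor, size)
    c(map1(cds_start), map1(cds_end))
  }
}

#' Inject aberrant variant isoforms
#'
#' Adds one variant isoform to each of `n_unique_isoforms` randomly chosen
#' genes. A variant differs from its gene's standard form (the full-chain
#' first isoform) by exactly one contiguous insertion of novel sequence or
#' one contiguous deletion, placed in a region drawn from
#' `region_weights`. Anchors are recorded left-normalized (the leftmost
#' equivalent indel position), so applying the recorded event to the
#' standard sequence reconstructs the variant exactly and anchors are
#' comparable with pipeline calls regardless of aligner tie-breaking.
#' When a requested region has no admissible anchor the gene is skipped
#' with a warning and recorded as omitted in the truth table.
#'
#' @param sim Output of [simulate_transcriptome()].
#' @param config The [sim_config()] used to build `sim`.
#' @return A list with augmented `models` and `sequences`, plus `truth`:
#'   `injected_events` (gene, variant and standard IDs, type, signed size,
#'   left-normalized anchor, region, inserted sequence) and `true_unique`
#'   (transcript, condition it is unique to).
#' @export
inject_aberrant_isoforms <- function(sim, config) {
  stopifnot(inherits(config, "sim_config"))
  models <- sim$models
  if (nrow(models) == 0) abort("models must be non-empty")
  seqs <- as.character(sim$sequences)
  withr::with_seed(stage_seed(config$seed, 2L), {
    genes <- sort(unique(models$gene_id))
    chosen <- sort(sample(genes, config$n_unique_isoforms))
    ev_rows <- list()
    uniq_rows <- list()
    new_models <- list()
    for (gene in chosen) {
      gm <- filter(models, .data$gene_id == gene)
      std_id <- min(gm$transcript_id)
      std <- filter(gm, .data$transcript_id == std_id)
      std_seq <- seqs[[std_id]]
      L <- std$length
      cs <- std$cds_start_tx
      ce <- std$cds_end_tx

      placed <- FALSE
      for (try in 1:50) {
        type <- sample(c("insertion", "deletion"), 1)
        region <- sample(REGIONS, 1, prob = config$region_weights[REGIONS])
        size <- sample_range(config$event_size_range)
        rng <- switch(region,
          FIVE_UTR = c(0L, cs - 1L),
          GENE_BODY = c(cs, ce - 1L),
          THREE_UTR = c(ce, if (type == "insertion") L else L - size)
        )
        if (type == "deletion") rng[2] <- min(rng[2], L - size)
        if (rng[1] > rng[2]) next
        anchor <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1)
        inserted <- if (type == "insertion") rand_dna(size) else NA_character_
        new_cds <- shift_cds(cs, ce, type, anchor, size)
        if (new_cds[2] - new_cds[1] < 1) next
        norm <- left_normalize_event(std_seq, type, anchor, size, inserted)
        anchor <- norm$anchor
        inserted <- norm$inserted_seq
        var_seq <- if (type == "insertion") {
          paste0(substr(std_seq, 1, anchor), inserted,
                 substr(std_seq, anchor + 1, L))
        } else {
          paste0(substr(std_seq, 1, anchor),
                 substr(std_seq, anchor + size + 1, L))
        }
        var_id <- sprintf("%s.V1", gene)
        var_len <- nchar(var_seq)
        vstart <- max(purrr::map_int(gm$exons, ~ max(.x$end))) + 500L
        new_models[[length(new_models) + 1]] <- tibble(
          transcript_id = var_id, gene_id = gene, seqname = "simchr",
          strand = "+", length = var_len,
          cds_start_tx = new_cds[1], cds_end_tx = new_cds[2],
          exons = list(tibble(start = vstart, end = vstart + var_len))
        )
        seqs[[var_id]] <- var_seq
        cond <- sample(config$conditions, 1,
                       prob = config$unique_condition_weights[config$conditions])
        ev_rows[[length(ev_rows) + 1]] <- tibble(
          gene_id = gene, variant_transcript_id = var_id,
          standard_transcript_id = std_id, type = type,
          signed_size = if (type == "insertion") size else -size,
          size = size, anchor = anchor,
          region = region_of_anchor(anchor, cs, ce),
          inserted_seq = inserted, omitted = FALSE
        )
        uniq_rows[[length(uniq_rows) + 1]] <- tibble(
          transcript_id = var_id, condition = cond)
        placed <- TRUE
        break
      }
      if (!placed) {
        warn(sprintf("gene %s: no admissible event placement; variant omitted", gene))
        ev_rows[[length(ev_rows) + 1]] <- tibble(
          gene_id = gene, variant_transcript_id = NA_character_,
          standard_transcript_id = std_id, type = NA_character_,
          signed_size = NA_integer_, size = NA_integer_,
          anchor = NA_integer_, region = NA_character_,
          inserted_seq = NA_character_, omitted = TRUE
        )
      }
    }
    models <- arrange(bind_rows(models, bind_rows(new_models)),
                      .data$gene_id, .data$transcript_id)
    list(
      models = models,
      sequences = Biostrings::DNAStringSet(seqs[models$transcript_id]),
      truth = list(
        injected_events = bind_rows(ev_rows),
        true_unique = bind_rows(uniq_rows)
      )
    )
  })
}

#' Simulate replicate isoform quantification
#'
#' Draws per-gene baseline FPKM from a log-normal distribution, assigns
#' each truth-unique variant a mean at least 1 in its condition and
#' per-replicate uniform values at most `absent_fpkm_max` in the other,
#' keeps all other isoforms expressed in both conditions (with a
#' differential-expression fold applied to a fraction of standard
#' isoforms), and multiplies log-normal replicate noise onto every
#' expressed value.
#'
#' @param models Model table (with variants injected).
#' @param truth Truth list from [inject_aberrant_isoforms()].
#' @param config The [sim_config()].
#' @return A tibble of `(transcript_id, gene_id, condition, replicate,
#'   fpkm)` with one row per transcript x condition x replicate.
#' @export
simulate_quant <- function(models, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  mu <- config$fpkm_lognormal_mu_sigma[1]
  sigma <- config$fpkm_lognormal_mu_sigma[2]
  wt <- config$conditions[1]
  ko <- config$conditions[2]
  reps <- config$replicates_per_condition
  uniq <- truth$true_unique
  withr::with_seed(stage_seed(config$seed, 3L), {
    genes <- sort(unique(models$gene_id))
    base <- setNames(pmax(5, rlnorm(length(genes), mu, 1.0)), genes)
    std_ids <- models |>
      group_by(.data$gene_id) |>
      summarise(std = min(.data$transcript_id[!grepl("\\.V\\d+$", .data$transcript_id)])) |>
      (\(d) setNames(d$std, d$gene_id))()
    de_genes <- sample(genes, floor(config$de_fraction * length(genes)))
    de_dir <- setNames(rep_len(c("up", "down"), length(de_genes)), de_genes)

    rows <- purrr::pmap(models, function(transcript_id, gene_id, length, ...) {
      m_std <- base[[gene_id]]
      is_var <- transcript_id %in% uniq$transcript_id
      if (is_var) {
        cond_in <- uniq$condition[uniq$transcript_id == transcript_id]
        # unique isoforms are clearly expressed (mean >= 2) so the truth
        # signal sits away from the expressed_min decision boundary; the
        # absent side still samples uniformly up to the absence threshold
        m_in <- min(max(2, m_std * runif(1, 0.1, 0.6)), 0.8 * m_std)
        means <- setNames(c(NA, NA), c(wt, ko))
        means[cond_in] <- m_in
      } else {
        m <- if (transcript_id == std_ids[[gene_id]]) m_std
             else m_std * runif(1, 0.1, 0.6)
        means <- setNames(c(m, m), c(wt, ko))
        if (gene_id %in% de_genes && transcript_id == std_ids[[gene_id]]) {
          f <- runif(1, config$de_fold_range[1], config$de_fold_range[2])
          means[ko] <- if (de_dir[[gene_id]] == "up") m * f else m / f
        }
      }
      purrr::map(c(wt, ko), function(cond) {
        vals <- if (is.na(means[[cond]])) {
          runif(reps, 0, config$absent_fpkm_max)
        } else {
          means[[cond]] * exp(rnorm(reps, 0, sigma))
        }
        tibble(transcript_id = transcript_id, gene_id = gene_id,
               condition = cond, replicate = seq_len(reps), fpkm = vals)
      }) |> bind_rows()
    })
    bind_rows(rows)
  })
}

#' Simulate a RIP assay (IP vs IgG replicate FPKM)
#'
#' Samples a `bound_fraction` of non-variant transcripts as true targets.
#' Targets receive an IP/IgG mean fold drawn from
#' `rip_enrichment_range`; non-targets have fold 1 in expectation. Both
#' arms carry multiplicative log-normal replicate noise.
#'
#' @inheritParams simulate_quant
#' @return A list: `rip`, a tibble of `(transcript_id, assay, replicate,
#'   fpkm)` with assays `IP` and `IgG`; and `true_targets`, the character
#'   vector of bound transcript IDs.
#' @export
simulate_rip <- function(models, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  sigma <- config$fpkm_lognormal_mu_sigma[2]
  reps <- config$rip_replicates
  withr::with_seed(stage_seed(config$seed, 4L), {
    pool <- setdiff(models$transcript_id, truth$true_unique$transcript_id)
    targets <- sort(sample(pool, round(config$bound_fraction * length(pool))))
    rows <- purrr::map(models$transcript_id, function(tx) {
      bg <- rlnorm(1, log(2), 0.5)
      fold <- if (tx %in% targets) {
        runif(1, config$rip_enrichment_range[1], config$rip_enrichment_range[2])
      } else 1
      bind_rows(
        tibble(transcript_id = tx, assay = "IP", replicate = seq_len(reps),
               fpkm = bg * fold * exp(rnorm(reps, 0, sigma))),
        tibble(transcript_id = tx, assay = "IgG", replicate = seq_len(reps),
               fpkm = bg * exp(rnorm(reps, 0, sigma)))
      )
    })
    list(rip = bind_rows(rows), true_targets = targets)
  })
}

#' Simulate a complete ground-truthed dataset
#'
#' Runs [simulate_transcriptome()], [inject_aberrant_isoforms()],
#' [simulate_quant()] and [simulate_rip()] under the config's seed and
#' bundles the results with the machine-readable truth.
#'
#' @param config A [sim_config()].
#' @return A list with `models`, `sequences`, `quant`, `rip`, `truth`
#'   (`injected_events`, `true_unique`, `true_targets`) and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  tx <- simulate_transcriptome(config)
  inj <- inject_aberrant_isoforms(tx, config)
  quant <- simulate_quant(inj$models, inj$truth, config)
  rip <- simulate_rip(inj$models, inj$truth, config)
  truth <- inj$truth
  truth$true_targets <- rip$true_targets
  list(models = inj$models, sequences = inj$sequences, quant = quant,
       rip = rip$rip, truth = truth, config = config)
}

#' Write a simulated dataset to disk
#'
#' Emits `models.gtf`, `transcripts.fa`, `quant.tsv`, `rip.tsv` and
#' `truth.json` under `outdir`. Identical config and seed give
#' byte-identical files.
#'
#' @param sim Output of [simulate_dataset()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_sim_dataset <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_gtf(sim$models, file.path(outdir, "models.gtf"))
  write_fasta(sim$sequences, file.path(outdir, "transcripts.fa"))
  write_quant(sim$quant, file.path(outdir, "quant.tsv"))
  write_rip(sim$rip, file.path(outdir, "rip.tsv"))
  jsonlite::write_json(sim$truth, file.path(outdir, "truth.json"),
                       pretty = TRUE, auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
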