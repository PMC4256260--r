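test_that("degenerate configurations are rejected with a message", {
  expect_error(sim_config(replicates_per_condition = 1), "replicates")
  expect_error(sim_config(region_weights = c(FIVE_UTR = 0.5, GENE_BODY = 0.5,
                                             THREE_UTR = 0.5)), "sum to 1")
  expect_error(sim_config(event_size_range = c(30, 10000)), "shortest transcript")
  expect_error(sim_config(n_genes = 5, n_unique_isoforms = 6), "n_unique_isoforms")
  expect_error(sim_config(rip_enrichment_range = c(1.5, 4)), "above fold 2")
  expect_error(sim_config(bound_fraction = 0), "bound_fraction")
})

test_that("a forced single-gene config yields the constructed transcript", {
  cfg <- sim_config(n_genes = 1, isoforms_per_gene = c(1, 1),
                    exon_count_range = c(3, 3), exon_length_range = c(100, 100),
                    utr5_length = 50, utr3_length = 50,
                    n_unique_isoforms = 0, seed = 5)
  tx <- simulate_transcriptome(cfg)
  expect_equal(nrow(tx$models), 1)
  expect_equal(tx$models$length, 300)
  expect_equal(tx$models$cds_start_tx, 50)
  expect_equal(tx$models$cds_end_tx, 250)
  expect_equal(Biostrings::width(tx$sequences), 300)
  expect_true(grepl("^[ACGT]+$", as.character(tx$sequences[[1]])))
})

test_that("identical seed and config give byte-identical outputs", {
  cfg <- sim_config(n_genes = 8, n_unique_isoforms = 3, seed = 11)
  d1 <- file.path(tempdir(), "simA")
  d2 <- file.path(tempdir(), "simB")
  write_sim_dataset(simulate_dataset(cfg), d1)
  write_sim_dataset(simulate_dataset(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7),
                     label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("the requested number of events is injected and truth is faithful", {
  sim <- default_fixture()
  truth <- sim$truth$injected_events
  expect_equal(sum(!truth$omitted), sim$config$n_unique_isoforms)
  expect_true(all(truth$variant_transcript_id[!truth$omitted] %in%
                    sim$models$transcript_id))
  seqs <- as.character(sim$sequences)
  # string-edit oracle: replaying each truth event on the standard
  # sequence must reproduce the variant byte-exactly
  for (i in which(!truth$omitted)) {
    rebuilt <- oracle_apply_edit(seqs[[truth$standard_transcript_id[i]]],
                                 truth$type[i], truth$anchor[i],
                                 truth$size[i], truth$inserted_seq[i])
    expect_identical(rebuilt, seqs[[truth$variant_transcript_id[i]]],
                     label = truth$variant_transcript_id[i])
  }
  # deletions never exceed the standard length; variants differ by the
  # signed size exactly
  std_len <- sim$models$length[match(truth$standard_transcript_id,
                                     sim$models$transcript_id)]
  var_len <- sim$models$length[match(truth$variant_transcript_id,
                                     sim$models$transcript_id)]
  ok <- !truth$omitted
  expect_true(all(truth$size[ok] <= std_len[ok]))
  expect_equal(var_len[ok] - std_len[ok], truth$signed_size[ok])
})

test_that("a region with zero available span is skipped and recorded omitted", {
  cfg <- sim_config(n_genes = 3, n_unique_isoforms = 2, utr5_length = 0,
                    region_weights = c(FIVE_UTR = 1, GENE_BODY = 0,
                                       THREE_UTR = 0),
                    seed = 9)
  tx <- simulate_transcriptome(cfg)
  warns <- testthat::capture_warnings(inj <- inject_aberrant_isoforms(tx, cfg))
  expect_length(warns, 2)  # one per affected gene
  expect_match(warns, "omitted", all = TRUE)
  expect_true(all(inj$truth$injected_events$omitted))
  expect_equal(nrow(inj$truth$true_unique), 0)
})

test_that("quantification has complete structure and truth-consistent means", {
  sim <- default_fixture()
  reps <- sim$config$replicates_per_condition
  expect_equal(nrow(sim$quant), nrow(sim$models) * 2 * reps)
  expect_true(all(sim$quant$fpkm >= 0))
  validate_sequences(sim$models, sim$sequences)

  means <- sim$quant |>
    dplyr::group_by(transcript_id, condition) |>
    dplyr::summarise(m = mean(fpkm), .groups = "drop")
  uniq <- sim$truth$true_unique
  other_cond <- ifelse(uniq$condition == sim$config$conditions[1],
                       sim$config$conditions[2], sim$config$conditions[1])
  m_out <- means$m[match(paste(uniq$transcript_id, other_cond),
                         paste(means$transcript_id, means$condition))]
  m_in <- means$m[match(paste(uniq$transcript_id, uniq$condition),
                        paste(means$transcript_id, means$condition))]
  expect_true(all(m_out <= sim$config$absent_fpkm_max))
  expect_true(all(m_in >= 1))
  # non-variant transcripts are expressed in both conditions
  nonvar <- setdiff(sim$models$transcript_id, uniq$transcript_id)
  expect_true(all(means$m[means$transcript_id %in% nonvar] > 0.1))
})

test_that("RIP tables encode the designed enrichment", {
  sim <- noisefree_fixture()  # sigma = 0: replicate values equal their means
  rip <- sim$rip
  folds <- rip |>
    dplyr::group_by(transcript_id) |>
    dplyr::summarise(fold = mean(fpkm[assay == "IP"]) / mean(fpkm[assay == "IgG"]),
                     .groups = "drop")
  targets <- sim$truth$true_targets
  f_t <- folds$fold[folds$transcript_id %in% targets]
  f_n <- folds$fold[!folds$transcript_id %in% targets]
  expect_true(all(f_t >= sim$config$rip_enrichment_range[1] - 1e-9))
  expect_true(all(f_t <= sim$config$rip_enrichment_range[2] + 1e-9))
  expect_true(all(abs(f_n - 1) < 1e-9))
  expect_false(any(sim$truth$true_unique$transcript_id %in% targets))
})
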