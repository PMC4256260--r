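test_that("identical sequences align without gaps at identity 1", {
  withr::with_seed(1, s <- rand_seq(300))
  aln <- global_align(s, s)
  expect_equal(aln$identity, 1)
  expect_false(grepl("-", aln$aligned_standard, fixed = TRUE))
  expect_false(grepl("-", aln$aligned_variant, fixed = TRUE))
  expect_equal(nrow(gaps_to_events(aln)), 0)
  expect_error(global_align("", s), "non-empty")
})

test_that("ungapping an alignment recovers the input sequences", {
  withr::with_seed(2, {
    s <- rand_seq(400)
    v <- oracle_apply_edit(s, "deletion", 120, 60)
  })
  aln <- global_align(s, v)
  expect_equal(gsub("-", "", aln$aligned_standard), s)
  expect_equal(gsub("-", "", aln$aligned_variant), v)
  cs <- strsplit(aln$aligned_standard, "")[[1]]
  cv <- strsplit(aln$aligned_variant, "")[[1]]
  expect_false(any(cs == "-" & cv == "-"))
})

test_that("an exon-skipping variant yields one deletion block", {
  withr::with_seed(3, {
    e1 <- rand_seq(100); e2 <- rand_seq(100); e3 <- rand_seq(100)
  })
  std <- paste0(e1, e2, e3)
  var <- paste0(e1, e3)
  aln <- global_align(std, var)
  ev <- gaps_to_events(aln)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "deletion")
  expect_equal(ev$signed_size, -100L)
  expect_equal(ev$anchor, oracle_leftmost_anchor(std, var, "deletion", 100, 100))
})

test_that("a novel inserted block yields one insertion block", {
  withr::with_seed(4, {
    e1 <- rand_seq(100); e2 <- rand_seq(100); x <- rand_seq(30)
  })
  std <- paste0(e1, e2)
  var <- paste0(e1, x, e2)
  ev <- gaps_to_events(global_align(std, var))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "insertion")
  expect_equal(ev$signed_size, 30L)
  expect_equal(ev$anchor, oracle_leftmost_anchor(std, var, "insertion", 100, 30))
  # the recorded inserted sequence rebuilds the variant
  expect_identical(oracle_apply_events(std, ev), var)
})

test_that("location percentages follow the chosen origin and sum to 100", {
  expect_equal(locate_event(500, 1000, "five_prime"), 50)
  expect_equal(locate_event(500, 1000, "three_prime"), 50)
  expect_equal(locate_event(0, 1000, "five_prime"), 0)
  expect_equal(locate_event(0, 1000, "three_prime"), 100)
  expect_equal(locate_event(250, 1000, "five_prime"), 25)
  # duality over arbitrary anchors, termini included
  anchors <- c(0, 1, 17, 250, 999, 1000)
  expect_equal(locate_event(anchors, 1000, "five_prime") +
                 locate_event(anchors, 1000, "three_prime"),
               rep(100, length(anchors)))
  expect_error(locate_event(1001, 1000), "anchor")
})

test_that("regions partition the transcript with half-open boundaries", {
  expect_equal(assign_region(10, 50, 250), "FIVE_UTR")
  expect_equal(assign_region(49, 50, 250), "FIVE_UTR")
  expect_equal(assign_region(50, 50, 250), "GENE_BODY")
  expect_equal(assign_region(249, 50, 250), "GENE_BODY")
  expect_equal(assign_region(250, 50, 250), "THREE_UTR")
  expect_message(r <- assign_region(10, NA, NA), "UNASSIGNED")
  expect_equal(r, "UNASSIGNED")
})

test_that("homology fallback matches by identity threshold", {
  withr::with_seed(5, {
    std1 <- rand_seq(400)
    std2 <- rand_seq(400)
    near <- oracle_apply_edit(std1, "deletion", 100, 40)  # ~90% of columns match
    unrelated <- rand_seq(400)
  })
  standards <- c(S1 = std1, S2 = std2)
  expect_equal(match_homolog(near, standards), "S1")
  expect_true(is.na(match_homolog(unrelated, standards)))
})

test_that("event calling recovers every injected event on the noise-free fixture", {
  sim <- noisefree_fixture()
  ev <- run_event_pipeline(sim)$events
  truth <- sim$truth$injected_events |> dplyr::filter(!omitted)
  called <- tidy(ev)
  expect_equal(glance(ev)$n_events, nrow(truth))
  key <- function(d, id_col) paste(d[[id_col]], d$type, d$signed_size, d$anchor)
  expect_setequal(key(called, "variant_id"), key(truth, "variant_transcript_id"))
  # regions match the truth annotation as well
  m <- match(called$variant_id, truth$variant_transcript_id)
  expect_equal(called$region, truth$region[m])
  # summary counts are consistent with one event per variant
  expect_equal(glance(ev)$n_isoforms, nrow(truth))
  expect_lte(glance(ev)$n_genes, nrow(truth))
})

test_that("called events reconstruct the variant sequence (round trip)", {
  sim <- noisefree_fixture()
  ev <- tidy(run_event_pipeline(sim)$events)
  seqs <- as.character(sim$sequences)
  for (vid in unique(ev$variant_id)) {
    sub <- ev[ev$variant_id == vid, ]
    rebuilt <- oracle_apply_events(seqs[[sub$standard_id[1]]], sub)
    expect_identical(rebuilt, seqs[[vid]], label = vid)
  }
})

test_that("switching the origin convention mirrors locations", {
  sim <- noisefree_fixture()
  e5 <- tidy(run_event_pipeline(sim, origin = "five_prime")$events)
  e3 <- tidy(run_event_pipeline(sim, origin = "three_prime")$events)
  m <- match(paste(e5$variant_id, e5$anchor), paste(e3$variant_id, e3$anchor))
  expect_false(anyNA(m))
  expect_equal(e5$location_pct + e3$location_pct[m], rep(100, nrow(e5)))
})

test_that("alignment events equal the exon-chain-diff oracle on whole-exon variants", {
  withr::with_seed(77, cases <- replicate(40, make_exon_chain_case(),
                                          simplify = FALSE))
  for (cs in cases) {
    ev <- gaps_to_events(global_align(cs$std, cs$variant))
    expect_equal(nrow(ev), 1)
    expect_equal(ev$type, cs$type)
    expect_equal(ev$signed_size, cs$signed_size)
    expect_equal(ev$anchor, cs$anchor)
  }
})

test_that("an empty unique list yields an empty event table", {
  sim <- noisefree_fixture()
  std <- select_standard_form(sim$quant, "WT")
  empty <- call_unique_isoforms(sim$quant, "gcKO", "WT")[0, ]
  ev <- call_splice_events(empty, std, sim$sequences, sim$models)
  expect_equal(glance(ev)$n_events, 0)
  expect_equal(nrow(tidy(ev)), 0)
})

test_that("event calling is deterministic and skips isoforms without sequence", {
  sim <- noisefree_fixture()
  r1 <- run_event_pipeline(sim)
  r2 <- run_event_pipeline(sim)
  expect_identical(tidy(r1$events), tidy(r2$events))

  uq <- r1$unique_calls
  seqs <- sim$sequences[setdiff(names(sim$sequences), uq$transcript_id[1])]
  expect_warning(
    ev <- call_splice_events(uq, r1$standards, seqs, sim$models),
    "no sequence")
  expect_equal(glance(ev)$n_events, glance(r1$events)$n_events - 1)
})
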