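test_that("presence/absence thresholds are inclusive exactly as printed", {
  q <- dplyr::bind_rows(
    quant_row("t_absent", "g", "WT", c(0.05, 0.05, 0.05)),
    quant_row("t_boundary_abs", "g", "WT", c(0.1, 0.1, 0.1)),
    quant_row("t_ambig", "g", "WT", c(0.5, 0.5, 0.5)),
    quant_row("t_boundary_exp", "g", "WT", c(1.0, 1.0, 1.0)),
    quant_row("t_expr", "g", "WT", c(5, 6, 7))
  )
  calls <- classify_expression(q)
  got <- setNames(calls$call, calls$transcript_id)
  expect_equal(got[["t_absent"]], "absent")
  expect_equal(got[["t_boundary_abs"]], "absent")      # <= 0.1 inclusive
  expect_equal(got[["t_ambig"]], "ambiguous")
  expect_equal(got[["t_boundary_exp"]], "expressed")   # >= 1 inclusive
  expect_equal(got[["t_expr"]], "expressed")
})

test_that("a transcript missing from a condition is an error", {
  q <- dplyr::bind_rows(
    quant_row("t1", "g", "WT", c(1, 2, 3)),
    quant_row("t1", "g", "gcKO", c(1, 2, 3)),
    quant_row("t2", "g", "WT", c(1, 2, 3))
  )
  expect_error(classify_expression(q), "missing from one or more conditions")
})

test_that("unique-isoform calling reproduces the Welch t-test and its gates", {
  q <- dplyr::bind_rows(
    quant_row("t1", "g", "gcKO", c(2.0, 1.5, 2.5)),
    quant_row("t1", "g", "WT", c(0.00, 0.05, 0.10))
  )
  uq <- call_unique_isoforms(q, "gcKO", "WT")
  expect_equal(nrow(uq), 1)
  expect_equal(uq$unique_in, "gcKO")
  # one-sided Welch p for these replicates, frozen from an independent
  # statistics oracle
  expect_equal(uq$p_value, 0.010177914, tolerance = 1e-6)

  # expression gate: mean below 1 is never unique, whatever the p-value
  q2 <- dplyr::bind_rows(
    quant_row("t1", "g", "gcKO", c(0.5, 0.6, 0.7)),
    quant_row("t1", "g", "WT", c(0.00, 0.01, 0.02))
  )
  expect_equal(nrow(call_unique_isoforms(q2, "gcKO", "WT")), 0)

  # absence gate: out-condition mean above 0.1 is never unique
  q3 <- dplyr::bind_rows(
    quant_row("t1", "g", "gcKO", c(10, 11, 12)),
    quant_row("t1", "g", "WT", c(0.10, 0.15, 0.12))
  )
  expect_equal(nrow(call_unique_isoforms(q3, "gcKO", "WT")), 0)
})

test_that("swapping the conditions moves the call to the other direction", {
  q <- dplyr::bind_rows(
    quant_row("t1", "g", "gcKO", c(2.0, 1.5, 2.5)),
    quant_row("t1", "g", "WT", c(0.00, 0.05, 0.10))
  )
  a <- call_unique_isoforms(q, "gcKO", "WT")
  b <- call_unique_isoforms(q, "WT", "gcKO")
  expect_equal(b$unique_in, "gcKO")
  expect_equal(a$p_value, b$p_value)
})

test_that("an undefined t-test is treated as not significant with a message", {
  q <- dplyr::bind_rows(
    quant_row("t1", "g", "gcKO", c(2, 2, 2)),
    quant_row("t1", "g", "WT", c(0.05, 0.05, 0.05))
  )
  expect_message(uq <- call_unique_isoforms(q, "gcKO", "WT"), "undefined")
  expect_equal(nrow(uq), 0)
})

test_that("standard-form selection is maximal, tie-broken, and order-invariant", {
  q <- dplyr::bind_rows(
    quant_row("tA", "g1", "WT", c(5, 5, 5)),
    quant_row("tB", "g1", "WT", c(2, 2, 2)),
    quant_row("tC", "g2", "WT", c(3, 3, 3)),   # tie within g2
    quant_row("tD", "g2", "WT", c(3, 3, 3)),
    quant_row("tE", "g3", "WT", c(1, 1, 1))    # single isoform
  )
  std <- select_standard_form(q, "WT")
  expect_equal(std$transcript_id[std$gene_id == "g1"], "tA")
  expect_equal(std$transcript_id[std$gene_id == "g2"], "tC")  # lexicographic
  expect_equal(std$transcript_id[std$gene_id == "g3"], "tE")
  shuffled <- q[sample(nrow(q)), ]
  expect_equal(select_standard_form(shuffled, "WT"), std)
  q_nok <- dplyr::bind_rows(q, quant_row("tF", "g4", "gcKO", c(1, 1, 1)))
  expect_error(select_standard_form(q_nok, "WT"), "g4")
})

test_that("DE calls honor the strict fold cutoff and the p cutoff", {
  # fold of exactly 2 after the 0.1 pseudocount: (3.9+0.1)/(1.9+0.1)
  q <- dplyr::bind_rows(
    quant_row("t_at2", "g", "gcKO", c(3.80, 3.90, 4.00)),
    quant_row("t_at2", "g", "WT", c(1.85, 1.90, 1.95)),
    quant_row("t_up", "g", "gcKO", c(5.9, 6.0, 6.1)),
    quant_row("t_up", "g", "WT", c(0.95, 1.00, 1.05)),
    quant_row("t_flat", "g", "gcKO", c(2, 3, 4)),
    quant_row("t_flat", "g", "WT", c(2, 3, 4))
  )
  de <- call_de(q, "gcKO", "WT")
  got <- setNames(de$direction, de$transcript_id)
  expect_equal(got[["t_at2"]], "unchanged")   # strict > 2
  expect_equal(got[["t_up"]], "up")
  expect_equal(got[["t_flat"]], "unchanged")
  expect_equal(de$log2_fold_change[de$transcript_id == "t_at2"], 1)
  expect_equal(de$log2_fold_change[de$transcript_id == "t_flat"], 0)
})

test_that("call counts are monotone in alpha and fold cutoff", {
  sim <- default_fixture()
  n_unique <- function(alpha) nrow(call_unique_isoforms(
    sim$quant, "gcKO", "WT", alpha = alpha))
  expect_true(n_unique(0.01) <= n_unique(0.05))
  expect_true(n_unique(0.05) <= n_unique(0.1))
  n_de <- function(fc, alpha) sum(call_de(sim$quant, "gcKO", "WT", fc = fc,
                                          alpha = alpha)$direction != "unchanged")
  expect_true(n_de(2, 0.01) <= n_de(2, 0.05))
  expect_true(n_de(3, 0.05) <= n_de(2, 0.05))
  expect_true(n_de(1.5, 0.05) >= n_de(2, 0.05))
})

test_that("unique calls never violate the threshold gates (property)", {
  sim <- default_fixture()
  uq <- call_unique_isoforms(sim$quant, "gcKO", "WT")
  expect_true(all(uq$mean_fpkm_in >= 1))
  expect_true(all(uq$mean_fpkm_out <= 0.1))
  expect_true(all(uq$p_value >= 0 & uq$p_value <= 0.1))
})

test_that("unique-isoform recovery on the seeded fixture is near-perfect", {
  sim <- default_fixture()
  uq <- call_unique_isoforms(sim$quant, "gcKO", "WT")
  truth <- sim$truth$true_unique
  called <- paste(uq$transcript_id, uq$unique_in)
  expected <- paste(truth$transcript_id, truth$condition)
  recall <- mean(expected %in% called)
  precision <- mean(called %in% expected)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})

test_that("noise-free quantification gives exact unique recovery", {
  sim <- noisefree_fixture()
  uq <- call_unique_isoforms(sim$quant, "gcKO", "WT")
  truth <- sim$truth$true_unique
  expect_setequal(paste(uq$transcript_id, uq$unique_in),
                  paste(truth$transcript_id, truth$condition))
})

test_that("gene aggregation marks a gene by its most extreme transcript", {
  de <- tibble::tibble(
    transcript_id = c("t1", "t2", "t3", "t4"),
    gene_id = c("g1", "g1", "g2", "g3"),
    direction = c("up", "unchanged", "down", "unchanged")
  )
  genes <- de_genes(de)
  expect_equal(genes$direction[genes$gene_id == "g1"], "up")
  expect_equal(genes$direction[genes$gene_id == "g2"], "down")
  expect_equal(genes$direction[genes$gene_id == "g3"], "unchanged")
})
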