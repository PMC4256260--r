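#' Classify transcripts as absent, expressed or ambiguous
#'
#' Applies the FPKM presence/absence thresholds to replicate-mean FPKM:
#' a transcript is `absent` in a condition when its mean FPKM is at most
#' `absent_max` (default 0.1) and `expressed` when at least
#' `expressed_min` (default 1); both thresholds are inclusive. Means in
#' the open band between the thresholds are `ambiguous` and satisfy
#' neither side of the condition-unique definition.
#'
#' @param quant Quantification tibble with `transcript_id`, `gene_id`,
#'   `condition`, `replicate`, `fpkm` (as from [read_quant()] or
#'   [simulate_quant()]).
#' @param condition Optional label; if given, only that condition is
#'   classified, otherwise all conditions present.
#' @param absent_max Inclusive upper FPKM bound for absence.
#' @param expressed_min Inclusive lower FPKM bound for expression.
#' @return A tibble `(transcript_id, gene_id, condition, mean_fpkm,
#'   call)` with `call` in `absent`/`expressed`/`ambiguous`.
#' @export
classify_expression <- function(quant, condition = NULL,
                                absent_max = 0.1, expressed_min = 1.0) {
  check_columns(quant, c("transcript_id", "gene_id", "condition", "replicate", "fpkm"),
                "quant")
  if (absent_max >= expressed_min) {
    abort("absent_max must be below expressed_min")
  }
  df <- quant
  if (!is.null(condition)) {
    df <- filter(df, .data$condition %in% !!condition)
    if (nrow(df) == 0) abort(sprintf("condition %s not present in quant", condition))
  }
  # every transcript must be quantified in every requested condition
  n_cond <- dplyr::n_distinct(df$condition)
  incomplete <- df |>
    distinct(.data$transcript_id, .data$condition) |>
    count(.data$transcript_id) |>
    filter(.data$n < n_cond)
  if (nrow(incomplete) > 0) {
    abort(sprintf("transcript %s is missing from one or more conditions",
                  incomplete$transcript_id[1]))
  }
  df |>
    group_by(.data$transcript_id, .data$gene_id, .data$condition) |>
    summarise(mean_fpkm = mean(.data$fpkm), .groups = "drop") |>
    mutate(call = dplyr::case_when(
      .data$mean_fpkm <= absent_max ~ "absent",
      .data$mean_fpkm >= expressed_min ~ "expressed",
      TRUE ~ "ambiguous"
    )) |>
    arrange(.data$transcript_id, .data$condition)
}

#' Call condition-unique transcript isoforms
#'
#' A transcript is unique to condition A when its replicate-mean FPKM is
#' at least `expressed_min` in A, at most `absent_max` in B, and a
#' one-sided two-sample Welch t-test on the replicate FPKM values
#' (alternative: mean in A greater than in B) gives p below `alpha`
#' (default 0.1). Both directions are returned. When the test is
#' undefined (both replicate groups essentially constant), the transcript
#' is treated as not significant and a message is emitted.
#'
#' @inheritParams classify_expression
#' @param cond_a,cond_b The two condition labels to contrast.
#' @param alpha One-sided p-value cutoff.
#' @return A tibble `(transcript_id, gene_id, unique_in, p_value,
#'   mean_fpkm_in, mean_fpkm_out)`, one row per called unique isoform.
#' @export
call_unique_isoforms <- function(quant, cond_a, cond_b, alpha = 0.1,
                                 absent_max = 0.1, expressed_min = 1.0) {
  check_columns(quant, c("transcript_id", "gene_id", "condition", "replicate", "fpkm"),
                "quant")
  for (cc in c(cond_a, cond_b)) {
    if (!cc %in% quant$condition) abort(sprintf("condition %s not present in quant", cc))
  }
  nested <- quant |>
    filter(.data$condition %in% c(cond_a, cond_b)) |>
    group_by(.data$transcript_id, .data$gene_id) |>
    summarise(
      vals_a = list(.data$fpkm[.data$condition == cond_a]),
      vals_b = list(.data$fpkm[.data$condition == cond_b]),
      .groups = "drop"
    )
  if (any(lengths(nested$vals_a) < 2) || any(lengths(nested$vals_b) < 2)) {
    abort("call_unique_isoforms needs at least 2 replicates per condition")
  }
  one_dir <- function(v_in, v_out, id, in_label) {
    m_in <- mean(v_in)
    m_out <- mean(v_out)
    if (m_in < expressed_min || m_out > absent_max) return(NULL)
    p <- welch_p(v_in, v_out, alternative = "greater")
    if (is.na(p)) {
      inform(sprintf(
        "%s: t-test undefined (constant replicates); treated as not significant", id))
      return(NULL)
    }
    if (p >= alpha) return(NULL)
    tibble(unique_in = in_label, p_value = p,
           mean_fpkm_in = m_in, mean_fpkm_out = m_out)
  }
  calls <- purrr::pmap(nested, function(transcript_id, gene_id, vals_a, vals_b) {
    out <- bind_rows(
      one_dir(vals_a, vals_b, transcript_id, cond_a),
      one_dir(vals_b, vals_a, transcript_id, cond_b)
    )
    if (nrow(out) == 0) return(NULL)
    mutate(out, transcript_id = transcript_id, gene_id = gene_id)
  })
  out <- bind_rows(calls)
  if (nrow(out) == 0) {
    return(tibble(transcript_id = character(), gene_id = character(),
                  unique_in = character(), p_value = numeric(),
                  mean_fpkm_in = numeric(), mean_fpkm_out = numeric()))
  }
  out |>
    select("transcript_id", "gene_id", "unique_in", "p_value",
           "mean_fpkm_in", "mean_fpkm_out") |>
    arrange(.data$unique_in, .data$transcript_id)
}

#' Select each gene's standard form
#'
#' The standard form of a gene is the transcript isoform with the highest
#' replicate-mean FPKM in the wild-type condition; ties break to the
#' lexicographically smallest transcript ID, so the result is invariant
#' under row permutation.
#'
#' @inheritParams classify_expression
#' @param wt_condition Label of the wild-type (reference) condition.
#' @return A tibble `(gene_id, transcript_id, wt_mean_fpkm)` with one row
#'   per gene.
#' @export
select_standard_form <- function(quant, wt_condition = "WT") {
  check_columns(quant, c("transcript_id", "gene_id", "condition", "replicate", "fpkm"),
                "quant")
  wt <- filter(quant, .data$condition == wt_condition)
  if (nrow(wt) == 0) abort(sprintf("condition %s not present in quant", wt_condition))
  missing_genes <- setdiff(unique(quant$gene_id), unique(wt$gene_id))
  if (length(missing_genes) > 0) {
    abort(sprintf("gene %s has no quantification in condition %s",
                  missing_genes[1], wt_condition))
  }
  wt |>
    group_by(.data$gene_id, .data$transcript_id) |>
    summarise(wt_mean_fpkm = mean(.data$fpkm), .groups = "drop") |>
    group_by(.data$gene_id) |>
    arrange(dplyr::desc(.data$wt_mean_fpkm), .data$transcript_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select("gene_id", "transcript_id", "wt_mean_fpkm") |>
    arrange(.data$gene_id)
}

#' Call differential expression between two conditions
#'
#' Per transcript: fold change is `(mean_a + pseudocount) /
#' (mean_b + pseudocount)` and significance a two-sided Welch t-test on
#' replicate FPKM. Direction is `up` when fold is strictly greater than
#' `fc` with p below `alpha` (condition A higher), `down` symmetrically
#' (fold below `1/fc`), otherwise `unchanged`. No multiple-testing
#' correction is applied by default, mirroring raw-p cutoffs; set
#' `fdr = TRUE` to use Benjamini-Hochberg adjusted p-values instead.
#'
#' @inheritParams call_unique_isoforms
#' @param fc Fold-change cutoff (strict inequality).
#' @param alpha Two-sided p-value cutoff.
#' @param pseudocount Added to both means before the ratio so folds stay
#'   finite at zero expression.
#' @param fdr Apply Benjamini-Hochberg correction before thresholding.
#' @return A tibble `(transcript_id, gene_id, mean_a, mean_b,
#'   log2_fold_change, p_value, direction)` for every transcript.
#' @export
call_de <- function(quant, cond_a, cond_b, fc = 2.0, alpha = 0.05,
                    pseudocount = 0.1, fdr = FALSE) {
  check_columns(quant, c("transcript_id", "gene_id", "condition", "replicate", "fpkm"),
                "quant")
  for (cc in c(cond_a, cond_b)) {
    if (!cc %in% quant$condition) abort(sprintf("condition %s not present in quant", cc))
  }
  if (fc <= 1) abort("fc must exceed 1")
  nested <- quant |>
    filter(.data$condition %in% c(cond_a, cond_b)) |>
    group_by(.data$transcript_id, .data$gene_id) |>
    summarise(
      vals_a = list(.data$fpkm[.data$condition == cond_a]),
      vals_b = list(.data$fpkm[.data$condition == cond_b]),
      .groups = "drop"
    )
  if (any(lengths(nested$vals_a) < 2) || any(lengths(nested$vals_b) < 2)) {
    abort("call_de needs at least 2 replicates per condition")
  }
  out <- nested |>
    mutate(
      mean_a = purrr::map_dbl(.data$vals_a, mean),
      mean_b = purrr::map_dbl(.data$vals_b, mean),
      fold = (.data$mean_a + pseudocount) / (.data$mean_b + pseudocount),
      log2_fold_change = log2(.data$fold),
      p_value = purrr::map2_dbl(.data$vals_a, .data$vals_b, welch_p)
    )
  p_eff <- if (fdr) p.adjust(out$p_value, method = "BH") else out$p_value
  out |>
    mutate(
      direction = dplyr::case_when(
        !is.na(p_eff) & p_eff < alpha & .data$fold > fc ~ "up",
        !is.na(p_eff) & p_eff < alpha & .data$fold < 1 / fc ~ "down",
        TRUE ~ "unchanged"
      )
    ) |>
    select("transcript_id", "gene_id", "mean_a", "mean_b",
           "log2_fold_change", "p_value", "direction") |>
    arrange(.data$transcript_id)
}

#' Aggregate transcript-level DE calls to genes
#'
#' A gene is `up` if any of its transcripts is up, else `down` if any is
#' down, else `unchanged`.
#'
#' @param de_calls Output of [call_de()].
#' @return A tibble `(gene_id, direction)`.
#' @export
de_genes <- function(de_calls) {
  check_columns(de_calls, c("gene_id", "direction"), "de_calls")
  de_calls |>
    group_by(.data$gene_id) |>
    summarise(direction = dplyr::case_when(
      any(.data$direction == "up") ~ "up",
      any(.data$direction == "down") ~ "down",
      TRUE ~ "unchanged"
    ), .groups = "drop") |>
    arrange(.data$gene_id)
}
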