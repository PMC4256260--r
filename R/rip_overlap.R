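#' Call RIP-enriched target transcripts
#'
#' Per transcript, enrichment is `(mean IP + pseudocount) /
#' (mean IgG + pseudocount)` over replicate FPKM, with significance from
#' a one-sided Welch t-test (alternative: IP greater than IgG). A
#' transcript is a target when the fold change strictly exceeds `fc`
#' (default 2) and p is below `alpha` (default 0.05). With fewer than 3
#' replicates in either arm a message flags the test's limited power.
#'
#' @param rip RIP tibble with `transcript_id`, `assay` (`IP`/`IgG`),
#'   `replicate`, `fpkm` (as from [read_rip()] or [simulate_rip()]).
#' @param fc Fold-change cutoff (strict).
#' @param alpha One-sided p-value cutoff.
#' @param pseudocount Added to both means before the ratio.
#' @param fdr Apply Benjamini-Hochberg correction before thresholding.
#' @return A tibble `(transcript_id, mean_ip, mean_igg, fold_change,
#'   p_value, is_target)` for every transcript.
#' @export
call_rip_targets <- function(rip, fc = 2.0, alpha = 0.05, pseudocount = 0.1,
                             fdr = FALSE) {
  check_columns(rip, c("transcript_id", "assay", "replicate", "fpkm"), "rip")
  if (fc <= 1) abort("fc must exceed 1")
  nested <- rip |>
    group_by(.data$transcript_id) |>
    summarise(
      ip = list(.data$fpkm[.data$assay == "IP"]),
      igg = list(.data$fpkm[.data$assay == "IgG"]),
      .groups = "drop"
    )
  one_armed <- lengths(nested$ip) == 0 | lengths(nested$igg) == 0
  if (any(one_armed)) {
    abort(sprintf("transcript %s is present in only one assay",
                  nested$transcript_id[one_armed][1]))
  }
  if (any(lengths(nested$ip) < 2) || any(lengths(nested$igg) < 2)) {
    abort("call_rip_targets needs at least 2 replicates per assay")
  }
  if (any(lengths(nested$ip) < 3) || any(lengths(nested$igg) < 3)) {
    inform("fewer than 3 replicates in an assay arm: the Welch t-test has limited power")
  }
  out <- nested |>
    mutate(
      mean_ip = purrr::map_dbl(.data$ip, mean),
      mean_igg = purrr::map_dbl(.data$igg, mean),
      fold_change = (.data$mean_ip + pseudocount) / (.data$mean_igg + pseudocount),
      p_value = purrr::map2_dbl(.data$ip, .data$igg, welch_p,
                                alternative = "greater")
    )
  p_eff <- if (fdr) p.adjust(out$p_value, method = "BH") else out$p_value
  out |>
    mutate(is_target = !is.na(p_eff) & p_eff < alpha & .data$fold_change > fc) |>
    select("transcript_id", "mean_ip", "mean_igg", "fold_change",
           "p_value", "is_target") |>
    arrange(.data$transcript_id)
}

#' Classify the regulation of RIP targets
#'
#' Labels each RIP target transcript by its differential-expression
#' direction at a relaxed fold-change cutoff (default 1.5, p below 0.05),
#' re-thresholding the stored fold change and p-value of the DE table.
#' Targets absent from the DE table are counted as `unchanged` with a
#' message.
#'
#' @param targets Output of [call_rip_targets()] (only rows with
#'   `is_target` are used) or a character vector of target transcript
#'   IDs.
#' @param de_calls Output of [call_de()] on the same transcript universe.
#' @param fc Fold-change cutoff (strict) for calling a target up or down.
#' @param alpha p-value cutoff.
#' @return An object of class `target_regulation`: list with
#'   `regulation` (tibble `transcript_id`, `direction`) and `counts`
#'   (tibble `direction`, `n` over up/down/unchanged). [tidy()] returns
#'   the per-transcript table, [glance()] the counts as one row.
#' @export
classify_target_regulation <- function(targets, de_calls, fc = 1.5, alpha = 0.05) {
  if (is.data.frame(targets)) {
    check_columns(targets, c("transcript_id", "is_target"), "targets")
    ids <- targets$transcript_id[targets$is_target]
  } else {
    ids <- as.character(targets)
  }
  check_columns(de_calls, c("transcript_id", "log2_fold_change", "p_value"),
                "de_calls")
  if (fc <= 1) abort("fc must exceed 1")
  de <- de_calls[match(ids, de_calls$transcript_id), ]
  n_absent <- sum(is.na(de$transcript_id))
  if (n_absent > 0) {
    inform(sprintf("%d target(s) absent from the DE table; counted as unchanged",
                   n_absent))
  }
  fold <- 2^de$log2_fold_change
  direction <- dplyr::case_when(
    !is.na(de$p_value) & de$p_value < alpha & fold > fc ~ "up",
    !is.na(de$p_value) & de$p_value < alpha & fold < 1 / fc ~ "down",
    TRUE ~ "unchanged"
  )
  regulation <- tibble(transcript_id = ids, direction = direction) |>
    arrange(.data$transcript_id)
  levels <- c("up", "down", "unchanged")
  n_by_dir <- vapply(levels, function(d) sum(direction == d), integer(1))
  counts <- tibble(direction = levels, n = unname(n_by_dir))
  structure(list(regulation = regulation, counts = counts),
            class = "target_regulation")
}

#' @export
print.target_regulation <- function(x, ...) {
  n <- setNames(x$counts$n, x$counts$direction)
  cat(sprintf("<target_regulation> %d targets: %d up, %d down, %d unchanged\n",
              sum(n), n[["up"]], n[["down"]], n[["unchanged"]]))
  invisible(x)
}

#' Overlap between aberrantly spliced genes and RIP-target genes
#'
#' Computes the intersection of the two gene sets and the percentage of
#' aberrantly spliced genes that are bound targets (exact rational
#' arithmetic; rounding is left to the caller).
#'
#' @param aberrant_genes Character vector of genes with at least one
#'   called splicing event (see [aberrant_gene_set()]).
#' @param target_genes Character vector of genes with at least one
#'   RIP-target transcript (see [target_gene_set()]).
#' @return A one-row tibble `(n_aberrant_genes, n_target_genes,
#'   n_overlap, overlap_pct)` with
#'   `overlap_pct = 100 * n_overlap / n_aberrant_genes` (0 when there
#'   are no aberrant genes).
#' @export
overlap_aberrant_targets <- function(aberrant_genes, target_genes) {
  a <- unique(as.character(aberrant_genes))
  t <- unique(as.character(target_genes))
  n_overlap <- length(intersect(a, t))
  tibble(
    n_aberrant_genes = length(a),
    n_target_genes = length(t),
    n_overlap = n_overlap,
    overlap_pct = if (length(a) == 0) 0 else 100 * n_overlap / length(a)
  )
}

#' Gene sets for the overlap report
#'
#' `aberrant_gene_set()` extracts the distinct genes carrying at least
#' one called splicing event; `target_gene_set()` maps target
#' transcripts to genes ("any transcript of the gene is a target") using
#' a transcript-to-gene lookup.
#'
#' @param events A `splice_event_set` (or its `events` tibble).
#' @return Character vector of gene IDs.
#' @export
aberrant_gene_set <- function(events) {
  ev <- if (inherits(events, "splice_event_set")) events$events else events
  check_columns(ev, "gene_id", "events")
  sort(unique(ev$gene_id))
}

#' @rdname aberrant_gene_set
#' @param targets Output of [call_rip_targets()] or a character vector of
#'   target transcript IDs.
#' @param tx2gene Tibble with `transcript_id` and `gene_id` (e.g. a model
#'   table or quant table).
#' @export
target_gene_set <- function(targets, tx2gene) {
  if (is.data.frame(targets)) {
    check_columns(targets, c("transcript_id", "is_target"), "targets")
    ids <- targets$transcript_id[targets$is_target]
  } else {
    ids <- as.character(targets)
  }
  check_columns(tx2gene, c("transcript_id", "gene_id"), "tx2gene")
  map <- distinct(tx2gene, .data$transcript_id, .data$gene_id)
  genes <- map$gene_id[match(ids, map$transcript_id)]
  if (anyNA(genes)) {
    inform(sprintf("%d target transcript(s) missing from tx2gene; dropped",
                   sum(is.na(genes))))
  }
  sort(unique(genes[!is.na(genes)]))
}

#' Combined pipeline report
#'
#' Assembles the stage outputs into one JSON-serializable report:
#' unique-isoform counts per condition, DE up/down counts (transcript
#' and gene level), the splice-event summary, RIP target counts, target
#' regulation counts, and the aberrant-gene x target overlap. Missing
#' stages are marked absent rather than failing. All thresholds in use
#' are echoed for provenance.
#'
#' @param unique_calls,de_calls,events,targets,regulation,overlap Stage
#'   outputs ([call_unique_isoforms()], [call_de()],
#'   [call_splice_events()], [call_rip_targets()],
#'   [classify_target_regulation()], [overlap_aberrant_targets()]); any
#'   may be `NULL`.
#' @param thresholds Named list of thresholds to echo.
#' @return A list of class `pipeline_report`.
#' @export
build_report <- function(unique_calls = NULL, de_calls = NULL, events = NULL,
                         targets = NULL, regulation = NULL, overlap = NULL,
                         thresholds = list(absent_max = 0.1, expressed_min = 1,
                                           alpha_unique = 0.1, de_fc = 2,
                                           de_alpha = 0.05, rip_fc = 2,
                                           rip_alpha = 0.05, regulation_fc = 1.5)) {
  report <- list(thresholds = thresholds)
  report$unique_isoforms <- if (is.null(unique_calls)) "absent" else {
    as.list(table(factor(unique_calls$unique_in)))
  }
  report$differential_expression <- if (is.null(de_calls)) "absent" else {
    genes <- de_genes(de_calls)
    list(
      transcripts_up = sum(de_calls$direction == "up"),
      transcripts_down = sum(de_calls$direction == "down"),
      genes_up = sum(genes$direction == "up"),
      genes_down = sum(genes$direction == "down")
    )
  }
  report$splice_events <- if (is.null(events)) "absent" else {
    s <- if (inherits(events, "splice_event_set")) events$summary else events
    s[c("n_events", "n_isoforms", "n_genes")]
  }
  report$rip_targets <- if (is.null(targets)) "absent" else {
    list(n_targets = sum(targets$is_target),
         n_tested = nrow(targets))
  }
  report$target_regulation <- if (is.null(regulation)) "absent" else {
    as.list(setNames(regulation$counts$n, regulation$counts$direction))
  }
  report$overlap <- if (is.null(overlap)) "absent" else as.list(overlap)
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(jsonlite::toJSON(unclass(x), pretty = TRUE, auto_unbox = TRUE, digits = NA))
  cat("\n")
  invisible(x)
}

#' @rdname build_report
#' @param report A `pipeline_report`.
#' @param path Output JSON path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, pretty = TRUE, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
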